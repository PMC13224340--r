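#' Run the full ecotype-delineation pipeline on a synthetic dataset
#'
#' Orchestrates simulate -> preprocess -> {PCoA, SOM, network} -> k-means
#' cluster selection -> PERMANOVA -> NMDS/envfit -> COG profiling ->
#' ecotype qualification under a single seed, with per-stage timings and a
#' parameter echo.
#'
#' @param config A [synth_config()]; its seed is overridden by `seed`.
#' @param seed Integer seed governing every random stage.
#' @param net_config A [network_config()].
#' @param n_keep ASVs retained by the network QC; `NULL` (default) keeps
#'   the most abundant half of the surviving ASVs.
#' @param som_rows,som_cols SOM grid size (default 4 x 4, toroidal).
#' @param k_range Candidate k for the sample-based methods (default 2..8).
#' @param module_k_range Candidate k for module detection (default 2..10).
#' @param cog_effect Planted COG enrichment multiplier (default 5).
#' @param n_permutations Permutations for PERMANOVA and envfit
#'   (default 199).
#' @param run_nmds Compute the NMDS + envfit comparison stage
#'   (default TRUE).
#' @param verbose Print per-stage progress and timings.
#' @return A list with the dataset, the processed tables, per-method
#'   ordinations/models/labels, statistics, the `ecotype_report`, the
#'   rendered summary table and a `timings` data frame.
#' @export
run_all <- function(config = synth_config(), seed = 1L,
                    net_config = network_config(), n_keep = NULL,
                    som_rows = 4L, som_cols = 4L, k_range = 2:8,
                    module_k_range = 2:10, cog_effect = 5,
                    n_permutations = 199L, run_nmds = TRUE,
                    verbose = FALSE) {
  config$seed <- as.integer(seed)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    if (verbose) message(sprintf("[%s] %.1fs", stage, timings[[stage]]))
    val
  }

  if (verbose)
    message(sprintf("run_all: n_samples=%d n_asvs=%d n_modules=%d seed=%d",
                    config$n_samples, config$n_asvs, config$n_modules, seed))

  ds <- clock("simulate", generate_dataset(config))
  truth <- ds$truth
  dates <- truth$dates

  ## ---- preprocess ----------------------------------------------------
  prep <- clock("preprocess", {
    counts <- drop_singletons(ds$counts)
    corrected <- normalize_copy_number(
      counts, truth$asv_copy_number[counts$asv_ids])
    rel <- relative_abundance(corrected)
    hel <- hellinger(corrected)
    list(counts = counts, rel = rel, hel = hel)
  })

  ## ---- PCoA + k-means ------------------------------------------------
  pcoa_stage <- clock("pcoa", {
    ## 3 axes: k groups need up to k - 1 dimensions to separate
    d_euc <- pairwise_distance(prep$hel, "euclidean")
    ordn <- pcoa(d_euc, n_axes = 3L)
    kd <- k_diagnostics(ordn$coordinates, k_range, seed = seed)
    k <- choose_k(kd)
    sol <- attr(kd, "solutions")[[as.character(k)]]
    list(distance = d_euc, ordination = ordn, k_report = kd,
         k = as.integer(k), labels = sol$labels)
  })

  ## ---- SOM + k-means -------------------------------------------------
  ## k-means runs on the per-sample BMU codebook vectors (each sample
  ## represented by its unit's prototype); silhouette diagnostics are
  ## computed against the original Hellinger profiles, because on the
  ## collapsed BMU representation every pure-unit cluster scores a
  ## degenerate silhouette of 1.
  som_stage <- clock("som", {
    grid <- build_grid(som_rows, som_cols, toroidal = TRUE)
    model <- train_som(prep$hel, grid, seed = seed)
    mapping <- map_samples(model, prep$hel)
    feats <- model$codebook[mapping$bmu, , drop = FALSE]
    kd <- k_diagnostics(feats, k_range, seed = seed,
                        sil_x = prep$hel$values)
    k <- choose_k(kd)
    sol <- attr(kd, "solutions")[[as.character(k)]]
    list(model = model, mapping = mapping, k_report = kd,
         k = as.integer(k), labels = sol$labels)
  })

  ## ---- co-abundance network ------------------------------------------
  net_stage <- clock("network", {
    nk <- if (is.null(n_keep)) floor(ncol(prep$hel$values) / 2) else
      min(as.integer(n_keep), floor(ncol(prep$hel$values) / 2))
    qc <- network_qc(prep$hel, n_keep = nk)
    model <- tom(signed_adjacency(qc, beta = net_config$beta))
    labels <- detect_modules(model, seed = seed, k_range = module_k_range)
    merged <- merge_modules(qc, labels,
                            merge_threshold = net_config$merge_threshold)
    me <- attr(merged, "eigengenes")
    kept_samples <- match(qc$sample_ids, prep$hel$sample_ids)
    covars <- cbind(ds$traits[kept_samples,
                              c("copy_number", "doubling_time",
                                "genome_size", "gc_content")],
                    ds$metadata[kept_samples,
                                c("chlorophyll_a", "temperature", "salinity",
                                  "latitude", "longitude", "numeric_month")])
    stats_ <- kme_and_trait_stats(qc, me, covars)
    list(qc = qc, model = model, labels = merged, eigengenes = me,
         kme = stats_$kme, module_trait = stats_$module_trait,
         trait_significance = stats_$trait_significance,
         kept_samples = kept_samples)
  })

  ## ---- cluster validation --------------------------------------------
  stats_stage <- clock("stats", {
    list(pcoa = permanova(pcoa_stage$distance, pcoa_stage$labels,
                          n_permutations = n_permutations, seed = seed),
         som = permanova(pcoa_stage$distance, som_stage$labels,
                         n_permutations = n_permutations, seed = seed))
  })

  ## ---- NMDS comparison ordination ------------------------------------
  nmds_stage <- NULL
  if (run_nmds) {
    nmds_stage <- clock("nmds", {
      d_bray <- pairwise_distance(prep$hel, "bray_curtis")
      ordn <- nmds(d_bray, n_starts = 5L, seed = seed)
      ef <- envfit(ordn,
                   ds$metadata[, c("numeric_month", "temperature",
                                   "salinity", "latitude", "longitude")],
                   n_permutations = n_permutations, seed = seed)
      list(ordination = ordn, envfit = ef)
    })
  }

  ## ---- COG table and ecotype qualification ---------------------------
  cog <- clock("cog", generate_cog_table(truth, effect = cog_effect,
                                         seed = seed))
  eco_stage <- clock("ecotypes", {
    traits_md <- cbind(ds$traits, chlorophyll_a = ds$metadata$chlorophyll_a)
    report <- qualify_ecotypes(
      dates = dates,
      sample_labels = list(pcoa = pcoa_stage$labels,
                           som = som_stage$labels),
      module_labels = net_stage$labels,
      rel = prep$rel,
      traits = traits_md,
      module_trait = net_stage$module_trait,
      cog = cog)
    list(report = report, table = render_report(report))
  })

  out <- list(config = config, seed = seed,
              dataset = ds, preprocessed = prep,
              pcoa = pcoa_stage, som = som_stage, network = net_stage,
              stats = stats_stage, nmds = nmds_stage, cog = cog,
              report = eco_stage$report, summary = eco_stage$table,
              timings = data.frame(stage = names(timings),
                                   seconds = unlist(timings),
                                   row.names = NULL))
  class(out) <- "ecotyper_run"
  out
}

#' @export
print.ecotyper_run <- function(x, ...) {
  cat(sprintf("ecotyper run (seed %d): k_pcoa=%d k_som=%d modules=%d, %d ecotype(s)\n",
              x$seed, x$pcoa$k, x$som$k, length(unique(x$network$labels)),
              length(x$report$ecotypes)))
  invisible(x)
}
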