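#' Configuration for the synthetic community generator
#'
#' Describes a seasonal surface-ocean amplicon time series at desk scale:
#' near-daily sampling over roughly eleven months with two excised field
#' gaps, a heavy-tailed ASV abundance distribution including planted
#' singletons, a small number of co-varying ASV modules tracking smooth
#' seasonal latent signals, one optional short-lived "pulse" module, and
#' contiguous sample-level ecotype windows.
#'
#' @param n_samples Number of sampling dates (default 200).
#' @param n_asvs Number of ASVs including background and singletons
#'   (default 800).
#' @param n_modules Number of seasonal co-abundance modules (default 4).
#' @param pulse_module If `TRUE`, add one extra module confined to a burst of
#'   about two days, planted so that exactly two samples are dominated by it
#'   (an outlier pair in sample space).
#' @param n_ecotypes Number of contiguous sample-level ecotype windows
#'   (default 4); ecotype `e` is driven by module `e`.
#' @param depth Sequencing depth (reads per sample, default 50000).
#' @param noise_sd Log-normal standard deviation of per-cell intensity noise
#'   (default 0.3).
#' @param background_fraction Fraction of ASVs that belong to no module
#'   (default 0.3); planted singletons are drawn from this pool.
#' @param singleton_count Number of ASVs planted with a single read in the
#'   whole study (default 20).
#' @param seed Integer RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_samples = 200L, n_asvs = 800L, n_modules = 4L,
                         pulse_module = TRUE, n_ecotypes = 4L,
                         depth = 50000L, noise_sd = 0.3,
                         background_fraction = 0.3, singleton_count = 20L,
                         seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_asvs = as.integer(n_asvs),
              n_modules = as.integer(n_modules),
              pulse_module = isTRUE(pulse_module),
              n_ecotypes = as.integer(n_ecotypes), depth = as.integer(depth),
              noise_sd = noise_sd,
              background_fraction = background_fraction,
              singleton_count = as.integer(singleton_count),
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_samples, n_asvs, n_modules, n_ecotypes) < 1L))
      stop("synth_config: all counts must be >= 1")
    if (depth < 1000L) stop("synth_config: depth must be >= 1000")
    if (background_fraction < 0 || background_fraction >= 1)
      stop("synth_config: background_fraction must be in [0, 1)")
    if (singleton_count < 0) stop("synth_config: singleton_count must be >= 0")
  })
  class(cfg) <- "synth_config"
  cfg
}

# Per-module genetic trait means: doubling time (h), genome size (bp),
# GC content (%), 16S copy number. Row order: modules 1..4 follow the
# seasonal succession fall -> winter/dark -> winter-spring/light -> bloom;
# the pulse module resembles a fast-growing transient; background is an
# average community.
synth_trait_means <- function(n_modules, pulse) {
  base <- data.frame(
    doubling_time = c(8, 40, 30, 5),
    genome_size   = c(3.8e6, 1.6e6, 2.0e6, 4.5e6),
    gc_content    = c(42, 52, 50, 38),
    copy_number   = c(4, 1.2, 1.5, 6))
  if (n_modules > 4) {
    extra <- base[rep_len(seq_len(4), n_modules - 4), , drop = FALSE]
    extra$doubling_time <- extra$doubling_time * 1.3
    base <- rbind(base, extra)
  }
  tm <- base[seq_len(n_modules), , drop = FALSE]
  # pulse: an advected distinct-water-mass community, high GC, unremarkable
  # copy number
  if (pulse)
    tm <- rbind(tm, data.frame(doubling_time = 12, genome_size = 3.2e6,
                               gc_content = 55, copy_number = 2.5))
  tm <- rbind(tm, data.frame(doubling_time = 20, genome_size = 2.8e6,
                             gc_content = 46, copy_number = 2.5))
  rownames(tm) <- c(sprintf("module%d", seq_len(nrow(tm) - 1L)), "background")
  tm
}

#' Generate a synthetic seasonal community dataset with known ground truth
#'
#' Draws raw counts by multinomial sampling at `depth` from per-sample
#' expected compositions. Each module's expected abundance is a Gaussian bump
#' over the date axis (module-specific center and width partitioning the
#' season) multiplied by log-normal per-ASV loadings; background ASVs carry a
#' constant low intensity. Dates are consecutive days starting 2019-10-29
#' with two excised gaps. Environmental covariates are smooth functions of
#' date plus Gaussian noise; sample trait summaries are abundance-weighted
#' module trait means plus noise. Deterministic for a fixed seed.
#'
#' @param config A [synth_config()].
#' @return A list with elements `counts` (`community_table`, raw),
#'   `metadata` (data frame: sample_id, date, numeric_month, latitude,
#'   longitude, temperature, salinity, chlorophyll_a), `traits` (per-sample
#'   data frame: copy_number, genome_size, gc_content, doubling_time) and
#'   `truth` (list: `module_of_asv` with 0 = background, `ecotype_of_sample`,
#'   `latent_signals` (sample x module), `trait_means`, `asv_copy_number`,
#'   `pulse_samples`, `dates`, `config`).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_modules > config$n_asvs)
    stop("generate_dataset: n_modules exceeds n_asvs")
  set.seed(config$seed)
  n <- config$n_samples
  p_asv <- config$n_asvs

  ## --- dates: consecutive days with two excised gaps -------------------
  i1 <- floor(0.30 * n); i2 <- floor(0.75 * n)
  offsets <- seq_len(n) - 1L
  offsets <- offsets + 25L * (seq_len(n) > i1) + 12L * (seq_len(n) > i2)
  dates <- as.Date("2019-10-29") + offsets
  day <- as.numeric(offsets)

  ## --- ASV roles -------------------------------------------------------
  n_bg <- floor(config$background_fraction * p_asv)
  if (config$singleton_count > n_bg)
    stop("generate_dataset: singleton_count exceeds background ASV pool")
  n_mod_asvs <- p_asv - n_bg
  if (n_mod_asvs < config$n_modules)
    stop("generate_dataset: too few non-background ASVs for n_modules")
  # the pulse is a transient bloom of a handful of opportunist taxa
  n_pulse <- if (config$pulse_module) max(5L, round(0.01 * n_mod_asvs)) else 0L
  n_main <- n_mod_asvs - n_pulse
  main_sizes <- rep(n_main %/% config$n_modules, config$n_modules)
  main_sizes[seq_len(n_main %% config$n_modules)] <-
    main_sizes[seq_len(n_main %% config$n_modules)] + 1L
  module_of_asv <- c(rep(seq_len(config$n_modules), main_sizes),
                     rep(if (config$pulse_module) config$n_modules + 1L else
                           integer(0), n_pulse),
                     rep(0L, n_bg))
  asv_ids <- sprintf("ASV%04d", seq_len(p_asv))
  names(module_of_asv) <- asv_ids
  singleton_idx <- if (config$singleton_count > 0)
    (p_asv - config$singleton_count + 1L):p_asv else integer(0)

  ## --- latent seasonal signals ----------------------------------------
  n_lat <- config$n_modules + as.integer(config$pulse_module)
  ## Bumps are parameterized by sample index — a monotone reparametrization
  ## of the date axis that keeps succession smooth in time while making
  ## every bump symmetric about its window in sampling effort. Equal-width,
  ## equal-amplitude bumps then cross exactly at the block boundaries, so
  ## the argmax ground truth coincides with the compositional boundary a
  ## sample-space clustering recovers (the excised gaps would otherwise
  ## skew the crossings).
  ## Flat-topped bumps with logistic shoulders: abundance plateaus within
  ## each seasonal window and hands over to the next module across a
  ## roughly week-long transition — the quasi-discrete succession regime
  ## in which distinct community states alternate. Equal-amplitude bumps
  ## cross at the block boundaries, so the argmax ground truth coincides
  ## with the compositional boundary a sample-space clustering recovers.
  breaks <- round(seq(0, n, length.out = config$n_modules + 1L))
  edge <- 0.5   # logistic edge scale, in samples
  s_idx <- seq_len(n)
  latent <- matrix(0, n, n_lat,
                   dimnames = list(sprintf("S%03d", seq_len(n)),
                                   sprintf("module%d", seq_len(n_lat))))
  for (m in seq_len(config$n_modules))
    latent[, m] <- stats::plogis((s_idx - (breaks[m] + 0.5)) / edge) *
      stats::plogis(((breaks[m + 1L] + 0.5) - s_idx) / edge) + 0.03
  pulse_samples <- integer(0)
  if (config$pulse_module) {
    ip <- floor(0.55 * n)
    # an advected community present for exactly two sampling days: flat
    # low baseline, rectangular two-day burst strong enough to dominate
    # the two affected samples
    latent[, n_lat] <- 0.1
    latent[c(ip, ip + 1L), n_lat] <- 80
    pulse_samples <- c(ip, ip + 1L)
  }

  ## --- expected composition and counts --------------------------------
  loading <- stats::rlnorm(p_asv, meanlog = 0, sdlog = 1.2)
  # pulse taxa: a guild of comparably, moderately abundant opportunists
  if (config$pulse_module)
    loading[module_of_asv == config$n_modules + 1L] <-
      stats::rlnorm(n_pulse, meanlog = 1, sdlog = 0.3)
  bg_level <- stats::runif(p_asv, 0.02, 0.15)
  intensity <- matrix(0, n, p_asv, dimnames = list(rownames(latent), asv_ids))
  for (a in seq_len(p_asv)) {
    m <- module_of_asv[a]
    lat <- if (m == 0L) rep(bg_level[a], n) else latent[, m]
    intensity[, a] <- loading[a] * lat
  }
  if (config$noise_sd > 0)
    intensity <- intensity *
      exp(matrix(stats::rnorm(n * p_asv, 0, config$noise_sd), n, p_asv))
  intensity[, singleton_idx] <- 0

  counts <- matrix(0L, n, p_asv, dimnames = dimnames(intensity))
  host <- sample.int(n, length(singleton_idx), replace = TRUE)
  n_single_in <- tabulate(host, nbins = n)
  keep <- setdiff(seq_len(p_asv), singleton_idx)
  for (s in seq_len(n)) {
    pr <- intensity[s, keep]
    counts[s, keep] <- stats::rmultinom(1, config$depth - n_single_in[s],
                                        pr / sum(pr))[, 1]
  }
  for (j in seq_along(singleton_idx)) counts[host[j], singleton_idx[j]] <- 1L

  ## --- ecotype truth ---------------------------------------------------
  eco_modules <- seq_len(min(config$n_ecotypes, config$n_modules))
  ecotype_of_sample <- apply(latent[, eco_modules, drop = FALSE], 1,
                             which.max)
  names(ecotype_of_sample) <- rownames(latent)

  ## --- environmental metadata -----------------------------------------
  doy <- as.integer(format(dates, "%j"))
  summer <- exp(-0.5 * ((doy - 200) / 55)^2)
  melt <- exp(-0.5 * ((doy - 215) / 45)^2)
  bloom_lat <- latent[, min(config$n_ecotypes, config$n_modules)]
  metadata <- data.frame(
    sample_id = rownames(latent),
    date = as.character(dates),
    numeric_month = as.integer(format(dates, "%m")),
    latitude = 89.1 - 10 * (day - min(day)) / diff(range(day)) +
      stats::rnorm(n, 0, 0.12),
    longitude = 120 - 115 * (day - min(day)) / diff(range(day)) +
      stats::rnorm(n, 0, 2),
    temperature = -1.8 + 2.3 * summer + stats::rnorm(n, 0, 0.12),
    salinity = 32.5 - 2.6 * melt + stats::rnorm(n, 0, 0.18),
    chlorophyll_a = pmax(0.01, 0.04 + 2.5 * (bloom_lat - 0.03) +
                           stats::rnorm(n, 0, 0.08)),
    stringsAsFactors = FALSE)

  ## --- traits ----------------------------------------------------------
  tm <- synth_trait_means(config$n_modules, config$pulse_module)
  asv_copy_number <- tm$copy_number[ifelse(module_of_asv == 0L, nrow(tm),
                                           module_of_asv)] *
    exp(stats::rnorm(p_asv, 0, 0.08))
  names(asv_copy_number) <- asv_ids
  rel <- counts / rowSums(counts)
  grp <- ifelse(module_of_asv == 0L, nrow(tm), module_of_asv)
  w <- t(rowsum(t(rel), group = grp))          # sample x trait-group weights
  w <- w / rowSums(w)
  tm_m <- as.matrix(tm)[as.integer(colnames(w)), , drop = FALSE]
  trait_vals <- w %*% tm_m
  trait_vals <- trait_vals * exp(matrix(stats::rnorm(length(trait_vals),
                                                     0, 0.03),
                                        nrow(trait_vals)))
  traits <- data.frame(sample_id = rownames(latent),
                       copy_number = trait_vals[, "copy_number"],
                       genome_size = trait_vals[, "genome_size"],
                       gc_content = pmin(99, pmax(1, trait_vals[, "gc_content"])),
                       doubling_time = trait_vals[, "doubling_time"],
                       stringsAsFactors = FALSE)
  rownames(traits) <- NULL

  truth <- list(module_of_asv = module_of_asv,
                ecotype_of_sample = ecotype_of_sample,
                latent_signals = latent,
                trait_means = tm,
                asv_copy_number = asv_copy_number,
                pulse_samples = pulse_samples,
                dates = dates,
                config = config)
  list(counts = community_table(counts, "raw"), metadata = metadata,
       traits = traits, truth = truth)
}

#' Generate a synthetic COG category table with planted ecotype enrichment
#'
#' Emulates sparse metagenome coverage of a dense amplicon series: one row
#' per sampled date (default every 12th sample) with tpm abundances per COG
#' category summing to 1e6. Category `e` is planted as enriched (multiplied
#' by `effect`) on dates belonging to ecotype `e`.
#'
#' @param truth Ground-truth list from [generate_dataset()].
#' @param n_categories Number of COG categories (>= 4, default 20).
#' @param effect Enrichment multiplier for the planted category within its
#'   ecotype window (1 = no enrichment).
#' @param seed RNG seed.
#' @param every Subsample stride along the date axis (default 12).
#' @return A data frame (`cog_table`): `date` column then one column per
#'   category `C01..`; attribute `planted_category` maps ecotype to its
#'   enriched category; attribute `ecotype` gives each row's ecotype.
#' @export
generate_cog_table <- function(truth, n_categories = 20L, effect = 5,
                               seed = 1L, every = 12L) {
  if (n_categories < 4) stop("generate_cog_table: n_categories must be >= 4")
  if (effect <= 0) stop("generate_cog_table: effect must be positive")
  set.seed(seed)
  # stride offset: metagenome dates sit within seasonal windows rather
  # than on the few transition days between them
  idx <- seq(max(1L, round(0.75 * every)), length(truth$dates), by = every)
  eco <- truth$ecotype_of_sample[idx]
  n_eco <- length(unique(truth$ecotype_of_sample))
  base_w <- stats::rlnorm(n_categories, 0, 0.5)
  m <- matrix(base_w, nrow = length(idx), ncol = n_categories, byrow = TRUE)
  m <- m * exp(matrix(stats::rnorm(length(m), 0, 0.08), nrow(m)))
  planted <- seq_len(min(n_eco, n_categories))
  for (e in seq_along(planted))
    m[eco == e, planted[e]] <- m[eco == e, planted[e]] * effect
  m <- m / rowSums(m) * 1e6
  colnames(m) <- sprintf("C%02d", seq_len(n_categories))
  out <- data.frame(date = as.character(truth$dates[idx]), m,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "planted_category") <- stats::setNames(colnames(m)[planted],
                                                   seq_along(planted))
  attr(out, "ecotype") <- unname(eco)
  class(out) <- c("cog_table", "data.frame")
  out
}

#' Write a synthetic dataset to a directory of TSV fixtures
#'
#' Files: `counts.tsv` (community table), `metadata.tsv`, `traits.tsv`,
#' `truth_asv.tsv` (asv_id, module, copy_number), `truth_sample.tsv`
#' (sample_id, date, ecotype, is_pulse) and, when given, `cog.tsv`. All
#' tables round-trip bit-identically through [read_fixtures()].
#'
#' @param dataset List from [generate_dataset()].
#' @param dir Output directory (must exist).
#' @param cog Optional COG table from [generate_cog_table()].
#' @return Character vector of written paths, invisibly.
#' @export
write_fixtures <- function(dataset, dir, cog = NULL) {
  if (!dir.exists(dir)) stop("write_fixtures: no such directory: ", dir)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             traits = file.path(dir, "traits.tsv"),
             truth_asv = file.path(dir, "truth_asv.tsv"),
             truth_sample = file.path(dir, "truth_sample.tsv"))
  write_community_tsv(dataset$counts, paths["counts"])
  write_keyed_tsv(dataset$metadata, paths["metadata"])
  write_keyed_tsv(dataset$traits, paths["traits"])
  tr <- dataset$truth
  write_keyed_tsv(data.frame(asv_id = names(tr$module_of_asv),
                             module = unname(tr$module_of_asv),
                             copy_number = unname(tr$asv_copy_number)),
                  paths["truth_asv"])
  is_pulse <- seq_along(tr$ecotype_of_sample) %in% tr$pulse_samples
  write_keyed_tsv(data.frame(sample_id = names(tr$ecotype_of_sample),
                             date = as.character(tr$dates),
                             ecotype = unname(tr$ecotype_of_sample),
                             is_pulse = is_pulse),
                  paths["truth_sample"])
  if (!is.null(cog)) {
    paths <- c(paths, cog = file.path(dir, "cog.tsv"))
    write_keyed_tsv(as.data.frame(cog), paths["cog"])
  }
  invisible(paths)
}

#' Read fixtures written by [write_fixtures()]
#'
#' @param dir Directory containing the fixture TSVs.
#' @return A list with `counts`, `metadata`, `traits`, `truth_asv`,
#'   `truth_sample` and, if present, `cog`.
#' @export
read_fixtures <- function(dir) {
  if (!dir.exists(dir)) stop("read_fixtures: no such directory: ", dir)
  out <- list(counts = read_community_tsv(file.path(dir, "counts.tsv")),
              metadata = read_keyed_tsv(file.path(dir, "metadata.tsv")),
              traits = read_keyed_tsv(file.path(dir, "traits.tsv")),
              truth_asv = read_keyed_tsv(file.path(dir, "truth_asv.tsv")),
              truth_sample = read_keyed_tsv(file.path(dir, "truth_sample.tsv")))
  cg <- file.path(dir, "cog.tsv")
  if (file.exists(cg)) out$cog <- read_keyed_tsv(cg)
  out
}
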