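#' Contiguous time windows of a per-sample labeling
#'
#' Splits a dated label sequence into runs of consecutive dates carrying
#' the same label; a date gap larger than `break_gap_days` breaks a run
#' even if the label is unchanged.
#'
#' @param labels Per-sample labels aligned to `dates`.
#' @param dates `Date` vector (sorted internally).
#' @param break_gap_days Maximum day step that still continues a run
#'   (default 1, i.e. only consecutive days connect).
#' @return Data frame with `label`, `start`, `end`, `n_samples` per window,
#'   ordered by start date; attribute `per_date` is the sorted
#'   (date, label) table.
#' @export
cluster_timeline <- function(labels, dates, break_gap_days = 1) {
  dates <- as.Date(dates)
  ord <- order(dates)
  dates <- dates[ord]
  labels <- labels[ord]
  n <- length(labels)
  if (n == 0) return(data.frame(label = character(0), start = as.Date(character(0)),
                                end = as.Date(character(0)), n_samples = integer(0)))
  new_run <- c(TRUE, labels[-1] != labels[-n] |
                 as.numeric(diff(dates)) > break_gap_days)
  run_id <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(seq_len(n), run_id), function(idx) {
    data.frame(label = labels[idx[1]], start = dates[idx[1]],
               end = dates[idx[length(idx)]], n_samples = length(idx))
  }))
  rownames(out) <- NULL
  attr(out, "per_date") <- data.frame(date = dates, label = labels)
  out
}

#' Dominant co-abundance module per sample
#'
#' Sums the relative abundances of every module's member ASVs per sample
#' and returns the arg-max module — the module-level analogue of a sample
#' cluster assignment.
#'
#' @param rel A `community_table` in state `relative` (or any non-negative
#'   table), restricted to the network ASVs.
#' @param labels Module labels aligned to `rel$asv_ids` (0 entries, if any,
#'   are ignored).
#' @return Integer vector of dominant module per sample; attribute
#'   `module_abundance` holds the sample x module summed-abundance matrix.
#' @export
module_dominance <- function(rel, labels) {
  v <- if (inherits(rel, "community_table")) rel$values else as.matrix(rel)
  if (length(labels) != ncol(v))
    stop("module_dominance: labels not aligned to ASVs")
  keep <- labels != 0
  sums <- t(rowsum(t(v[, keep, drop = FALSE]), group = labels[keep]))
  dom <- as.integer(colnames(sums))[max.col(sums, ties.method = "first")]
  names(dom) <- rownames(v)
  attr(dom, "module_abundance") <- sums
  dom
}

#' Per-cluster COG category profiles
#'
#' Each category is z-scored across the metagenome dates and min-max
#' rescaled to \[0, 1\] (z-scores alone are unbounded, so the rescaling
#' makes profiles comparable across categories); a cluster's profile is
#' the mean scaled value over its dates. Categories constant across dates
#' are uninformative: they are flagged and set to 0.5 everywhere.
#'
#' @param cog A COG table (`date` column plus one numeric column per
#'   category), e.g. from [generate_cog_table()].
#' @param cluster_per_date Cluster label for every COG date (same order as
#'   the rows of `cog`); `NA` rows are dropped.
#' @return List with `profile` (cluster x category matrix in \[0, 1\]),
#'   `scaled` (date x category), `constant_categories`,
#'   `dates_per_cluster`.
#' @export
cog_profile <- function(cog, cluster_per_date) {
  m <- as.matrix(cog[, setdiff(colnames(cog), "date"), drop = FALSE])
  if (length(cluster_per_date) != nrow(m))
    stop("cog_profile: cluster_per_date not aligned to COG rows")
  ok <- !is.na(cluster_per_date)
  m <- m[ok, , drop = FALSE]
  cl <- cluster_per_date[ok]
  sds <- apply(m, 2, stats::sd)
  constant <- colnames(m)[sds == 0]
  z <- scale(m)
  scaled <- apply(z, 2, function(col) {
    r <- range(col)
    if (!is.finite(r[1]) || r[2] - r[1] == 0) return(rep(0.5, length(col)))
    (col - r[1]) / (r[2] - r[1])
  })
  rownames(scaled) <- cog$date[ok]
  profile <- rowsum(scaled, group = cl) / as.vector(table(factor(cl)))
  list(profile = profile, scaled = scaled, constant_categories = constant,
       dates_per_cluster = split(rownames(scaled), cl))
}

# top-n ASVs of a sample subset by mean relative abundance
top_asvs <- function(rel_values, sample_idx, n = 25L) {
  mu <- colMeans(rel_values[sample_idx, , drop = FALSE])
  names(sort(mu, decreasing = TRUE))[seq_len(min(n, length(mu)))]
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# adjacent labels of a candidate in a timeline (the labels of the windows
# immediately before and after each of the candidate's windows)
adjacent_labels <- function(timeline, label) {
  idx <- which(timeline$label == label)
  adj <- c()
  for (i in idx) {
    if (i > 1) adj <- c(adj, timeline$label[i - 1])
    if (i < nrow(timeline)) adj <- c(adj, timeline$label[i + 1])
  }
  setdiff(unique(adj), label)
}

#' Qualify candidate clusters and modules as functional ecotypes
#'
#' Every cluster of every sample-based method and every co-abundance module
#' is a candidate. A candidate qualifies when
#' (trait-distinct OR module-trait-correlated) AND composition-distinct AND
#' COG-validated:
#' \itemize{
#' \item trait_distinct (sample methods): for at least one trait among
#'   `trait_vars`, the adjusted pairwise rank-sum p-value is below `alpha`
#'   against every other cluster of the same method;
#' \item module_trait_correlated (modules): the module eigengene is
#'   significantly correlated (p < `alpha`) with at least 2 of `mt_vars`;
#' \item composition_distinct: Jaccard overlap of the candidate's top-25
#'   most abundant ASVs with those of every temporally adjacent dominant
#'   cluster is below `jaccard_max`;
#' \item cog_validated: at least one COG category whose candidate profile
#'   is at or above `cog_high` while every temporally adjacent cluster sits
#'   at or below `cog_low`; candidates with no matching metagenome date are
#'   flagged and the criterion is skipped with a warning.
#' }
#' Candidates supported by fewer than `min_samples` samples are rejected
#' outright with reason "insufficient support". Qualified candidates whose
#' sample sets overlap (overlap coefficient >= 0.5) are grouped into one
#' ecotype across methods.
#'
#' @param dates `Date` vector for all samples.
#' @param sample_labels Named list of per-sample label vectors for the
#'   sample-based methods (e.g. `list(pcoa = ..., som = ...)`).
#' @param module_labels ASV-level module labels (network ASVs).
#' @param rel A `community_table` of relative abundances (all samples; used
#'   for composition and module dominance; columns restricted to network
#'   ASVs for dominance via `module_labels` names).
#' @param traits Per-sample trait data frame (columns include
#'   `doubling_time`, `genome_size`).
#' @param module_trait Long module-trait data frame from
#'   [kme_and_trait_stats()] (`module`, `trait`, `correlation`, `p_value`).
#' @param cog Optional COG table with a `date` column.
#' @param min_samples Minimum samples supporting a candidate (default 3).
#' @param trait_vars Traits tested for cluster distinctness.
#' @param mt_vars Variables counted for module-trait correlation.
#' @param alpha Significance level (default 0.05).
#' @param jaccard_max Composition-overlap threshold (default 0.5).
#' @param cog_high,cog_low Enrichment thresholds on the \[0, 1\] COG
#'   profile (defaults 0.75 and 0.5).
#' @param break_gap_days Passed to [cluster_timeline()].
#' @return An `ecotype_report`: list with `ecotypes` (list of records:
#'   name, windows, samples, representatives, traits, enriched COG
#'   categories), `candidates` (full evidence table) and `rejected`
#'   (candidate, reason).
#' @export
qualify_ecotypes <- function(dates, sample_labels, module_labels, rel,
                             traits, module_trait, cog = NULL,
                             min_samples = 3L,
                             trait_vars = c("doubling_time", "genome_size"),
                             mt_vars = c("copy_number", "doubling_time",
                                         "genome_size", "gc_content",
                                         "chlorophyll_a"),
                             alpha = 0.05, jaccard_max = 0.5,
                             cog_high = 0.75, cog_low = 0.5,
                             break_gap_days = 1) {
  dates <- as.Date(dates)
  n <- length(dates)
  rel_v <- rel$values
  stopifnot(nrow(rel_v) == n, nrow(traits) == n)

  ## module dominance becomes one more per-sample labeling
  all_labels <- sample_labels
  if (length(module_labels)) {
    net_asvs <- names(module_labels)
    dom <- module_dominance(new_community_table(
      rel_v[, net_asvs, drop = FALSE], rel$state),
      as.integer(module_labels))
    all_labels <- c(all_labels, list(module = dom))
  }

  timelines <- lapply(all_labels, cluster_timeline, dates = dates,
                      break_gap_days = break_gap_days)

  ## COG profiles per method
  cog_profiles <- NULL
  if (!is.null(cog)) {
    cog_dates <- as.Date(cog$date)
    idx <- match(cog_dates, dates)
    cog_profiles <- lapply(all_labels, function(lab)
      cog_profile(cog, lab[idx]))
  }

  ## pairwise trait tests per sample method; clusters below min_samples are
  ## rejected outright, so they are not part of the comparison set either
  trait_tests <- lapply(sample_labels, function(lab) {
    big <- names(table(lab))[table(lab) >= max(2, min_samples)]
    keep <- lab %in% big
    lapply(stats::setNames(trait_vars, trait_vars), function(tv)
      pairwise_wilcoxon(traits[[tv]][keep], lab[keep]))
  })

  rows <- list()
  for (m in names(all_labels)) {
    lab <- all_labels[[m]]
    is_module <- m == "module"
    for (l in sort(unique(lab))) {
      samples <- which(lab == l)
      cand <- sprintf("%s%s", toupper(m), l)
      rec <- list(method = m, label = l, candidate = cand,
                  samples = samples, n = length(samples))
      if (length(samples) < min_samples) {
        rec$qualifies <- FALSE
        rec$reason <- "insufficient support"
        rows[[cand]] <- rec
        next
      }
      ## criterion 1: trait distinctness / module-trait correlation
      if (is_module) {
        mt <- module_trait[module_trait$module == paste0("ME", l) &
                             module_trait$trait %in% mt_vars, , drop = FALSE]
        rec$module_trait_correlated <- sum(mt$p_value < alpha, na.rm = TRUE) >= 2
        rec$trait_distinct <- NA
        ev1 <- rec$module_trait_correlated
      } else {
        per_trait <- vapply(trait_tests[[m]], function(pw) {
          mine <- pw$group1 == as.character(l) | pw$group2 == as.character(l)
          any(mine) && all(pw$p_adjusted[mine] < alpha)
        }, logical(1))
        rec$trait_distinct <- any(per_trait)
        rec$module_trait_correlated <- NA
        ev1 <- rec$trait_distinct
      }
      ## criterion 2: composition distinct from temporal neighbors
      adj <- adjacent_labels(timelines[[m]], l)
      mine_top <- top_asvs(rel_v, samples)
      jac <- vapply(adj, function(a)
        jaccard(mine_top, top_asvs(rel_v, which(lab == a))), numeric(1))
      rec$composition_distinct <- length(jac) == 0 || all(jac < jaccard_max)
      rec$max_adjacent_jaccard <- if (length(jac)) max(jac) else 0
      ## criterion 3: COG validation
      if (is.null(cog_profiles)) {
        rec$cog_validated <- NA
      } else {
        prof <- cog_profiles[[m]]$profile
        if (!as.character(l) %in% rownames(prof)) {
          warning("candidate ", cand,
                  " has no matching metagenome date; COG criterion skipped")
          rec$cog_validated <- NA
        } else {
          mine <- prof[as.character(l), ]
          adj_here <- intersect(as.character(adj), rownames(prof))
          low_ok <- if (length(adj_here))
            apply(prof[adj_here, , drop = FALSE] <= cog_low, 2, all)
          else rep(TRUE, length(mine))
          enriched <- names(mine)[mine >= cog_high & low_ok]
          rec$cog_validated <- length(enriched) > 0
          rec$enriched_cog <- enriched
        }
      }
      cog_ok <- is.na(rec$cog_validated) || rec$cog_validated
      rec$qualifies <- isTRUE(ev1) && isTRUE(rec$composition_distinct) &&
        cog_ok
      if (!rec$qualifies)
        rec$reason <- if (!isTRUE(ev1))
          if (is_module) "not module-trait correlated" else
            "traits not distinct"
        else if (!isTRUE(rec$composition_distinct))
          "composition overlaps temporal neighbors"
        else "no validating COG enrichment"
      rows[[cand]] <- rec
    }
  }

  ## group qualified candidates into cross-method ecotypes by sample overlap
  qual <- Filter(function(r) isTRUE(r$qualifies), rows)
  groups <- integer(0)
  if (length(qual)) {
    q <- length(qual)
    parent <- seq_len(q)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ## Jaccard grouping: a small boundary-straddling cluster cannot chain
    ## two large window groups the way an overlap coefficient would allow
    for (i in seq_len(q)) for (j in seq_len(q)) if (i < j) {
      a <- qual[[i]]$samples; b <- qual[[j]]$samples
      if (length(intersect(a, b)) / length(union(a, b)) >= 0.5)
        parent[find(j)] <- find(i)
    }
    groups <- vapply(seq_len(q), find, integer(1))
  }

  ecotypes <- list()
  if (length(qual)) {
    med_genome_all <- stats::median(traits$genome_size)
    for (g in unique(groups)) {
      members <- qual[groups == g]
      ## consensus sample set: majority vote among member candidates, so a
      ## single method's over-extended cluster cannot stretch the window
      votes <- table(unlist(lapply(members, `[[`, "samples")))
      samp <- sort(as.integer(names(votes)[votes > length(members) / 2]))
      win <- cluster_timeline(rep("e", length(samp)), dates[samp],
                              break_gap_days = break_gap_days)
      reps <- split(vapply(members, `[[`, character(1), "candidate"),
                    vapply(members, `[[`, character(1), "method"))
      enr <- sort(unique(unlist(lapply(members, function(r)
        if (!is.null(r$enriched_cog)) r$enriched_cog else character(0)))))
      ecotypes[[length(ecotypes) + 1L]] <- list(
        samples = samp,
        windows = win[, c("start", "end", "n_samples")],
        representatives = reps,
        median_doubling_time = stats::median(traits$doubling_time[samp]),
        median_genome_size = stats::median(traits$genome_size[samp]),
        genome_size_class = if (stats::median(traits$genome_size[samp]) >=
                                  med_genome_all) "Large" else "Streamlined",
        top_asvs = top_asvs(rel_v, samp, n = 5L),
        enriched_cog = enr)
    }
    ## order by window start, name E1..
    starts <- vapply(ecotypes, function(e) min(e$windows$start), numeric(1))
    ecotypes <- ecotypes[order(starts)]
    for (i in seq_along(ecotypes)) ecotypes[[i]]$name <- paste0("E", i)
  }

  rejected <- Filter(function(r) !isTRUE(r$qualifies), rows)
  out <- list(ecotypes = ecotypes, candidates = rows,
              rejected = lapply(rejected, function(r)
                list(candidate = r$candidate, n = r$n, reason = r$reason)))
  class(out) <- "ecotype_report"
  out
}

#' @export
print.ecotype_report <- function(x, ...) {
  cat(sprintf("ecotype_report: %d qualified ecotype(s), %d rejected candidate(s)\n",
              length(x$ecotypes), length(x$rejected)))
  invisible(x)
}

#' Render an ecotype report as a summary table
#'
#' One row per qualified ecotype: growth-rate rank (1 = fastest, by median
#' doubling time over the ecotype's samples), genome-size class relative to
#' the study median (Large / Streamlined), top representative ASVs,
#' enriched COG categories and contributing cluster ids per method.
#'
#' @param report An `ecotype_report`.
#' @return Data frame (possibly empty) with columns `ecotype`, `window`,
#'   `n_samples`, `growth_rate_rank`, `genome_size_class`, `top_asvs`,
#'   `enriched_cog`, `representatives`.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "ecotype_report"))
  if (!length(report$ecotypes))
    return(data.frame(ecotype = character(0), window = character(0),
                      n_samples = integer(0), growth_rate_rank = integer(0),
                      genome_size_class = character(0),
                      top_asvs = character(0), enriched_cog = character(0),
                      representatives = character(0)))
  dt <- vapply(report$ecotypes, `[[`, numeric(1), "median_doubling_time")
  rank_growth <- rank(dt, ties.method = "first")
  rows <- lapply(seq_along(report$ecotypes), function(i) {
    e <- report$ecotypes[[i]]
    win <- paste(sprintf("%s..%s", e$windows$start, e$windows$end),
                 collapse = "; ")
    data.frame(
      ecotype = e$name, window = win, n_samples = length(e$samples),
      growth_rate_rank = rank_growth[i],
      genome_size_class = e$genome_size_class,
      top_asvs = paste(e$top_asvs, collapse = ","),
      enriched_cog = paste(e$enriched_cog, collapse = ","),
      representatives = paste(unlist(e$representatives), collapse = ","))
  })
  do.call(rbind, rows)
}
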