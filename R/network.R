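#' Network analysis configuration
#'
#' @param beta Soft-thresholding power (default 8).
#' @param r2_target Scale-free topology fit threshold used by
#'   [pick_soft_power()] (default 0.8).
#' @param merge_threshold Eigengene correlation above which modules are
#'   merged (default 0.7).
#' @param n_bins Connectivity histogram bins for the scale-free fit
#'   (default 10).
#' @param candidate_powers Candidate soft powers (default 1..20).
#' @return A `network_config` list.
#' @export
network_config <- function(beta = 8, r2_target = 0.8, merge_threshold = 0.7,
                           n_bins = 10L, candidate_powers = 1:20) {
  if (beta < 1) stop("network_config: beta must be >= 1")
  if (r2_target <= 0 || r2_target >= 1)
    stop("network_config: r2_target must be in (0, 1)")
  if (merge_threshold <= 0 || merge_threshold >= 1)
    stop("network_config: merge_threshold must be in (0, 1)")
  structure(list(beta = beta, r2_target = r2_target,
                 merge_threshold = merge_threshold, n_bins = n_bins,
                 candidate_powers = candidate_powers),
            class = "network_config")
}

#' Signed soft-thresholded adjacency from Pearson correlations
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta` — a signed network: perfectly
#' anti-correlated ASVs get adjacency 0, uncorrelated ones `0.5^beta`,
#' perfectly correlated ones 1. The diagonal is set to 1.
#'
#' @param ct A `community_table` (>= 3 samples; run [network_qc()] first so
#'   no ASV has zero variance).
#' @param beta Soft-thresholding power.
#' @return A `network_model`: list with `correlation`, `adjacency`, `beta`;
#'   later stages add `tom`, `diss_tom`, `module_labels`, `eigengenes`,
#'   `kme`.
#' @export
signed_adjacency <- function(ct, beta = 8) {
  v <- if (inherits(ct, "community_table")) ct$values else as.matrix(ct)
  if (nrow(v) < 3) stop("signed_adjacency: need at least 3 samples")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("signed_adjacency: zero-variance ASV(s): ",
         paste(utils::head(colnames(v)[sds == 0], 10), collapse = ", "))
  cc <- stats::cor(v)
  a <- ((1 + cc) / 2)^beta
  diag(a) <- 1
  out <- list(correlation = cc, adjacency = a, beta = beta)
  class(out) <- "network_model"
  out
}

#' Scale-free topology fit index
#'
#' Bins the node connectivities `k_i = sum_{j != i} a_ij` into `n_bins`
#' equal-width bins and regresses `log10(frequency)` on `log10(mean k)`
#' over non-empty bins; the fit index is `-sign(slope) * R^2`, positive
#' when the degree distribution decays as in a scale-free network.
#'
#' @param model A `network_model` (adjacency computed) or adjacency matrix.
#' @param n_bins Number of bins (needs at least `2 * n_bins` ASVs).
#' @return List with `fit_index`, `slope`, `mean_connectivity`,
#'   `degenerate` flag (all connectivities equal).
#' @export
scale_free_fit <- function(model, n_bins = 10L) {
  a <- if (inherits(model, "network_model")) model$adjacency else as.matrix(model)
  if (ncol(a) < 2 * n_bins)
    stop("scale_free_fit: need at least ", 2 * n_bins, " ASVs")
  k <- colSums(a) - diag(a)
  if (diff(range(k)) < 1e-12)
    return(list(fit_index = NA_real_, slope = NA_real_,
                mean_connectivity = mean(k), degenerate = TRUE))
  cuts <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tabulate(cuts, nbins = n_bins)
  mean_k <- tapply(k, cuts, mean)
  ok <- freq > 0 & !is.na(mean_k) & mean_k > 0
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(fit_index = -sign(slope) * r2, slope = slope,
       mean_connectivity = mean(k), degenerate = FALSE)
}

#' Choose the soft-thresholding power
#'
#' Smallest candidate power whose scale-free fit index reaches
#' `r2_target`; if none does, the power with the maximum fit index is
#' returned with a warning. The Pearson correlation matrix is computed once
#' and re-raised for every candidate.
#'
#' @param ct A `community_table`.
#' @param config A [network_config()].
#' @return List with `beta` and `table` (per-power fit index, slope, mean
#'   connectivity).
#' @export
pick_soft_power <- function(ct, config = network_config()) {
  powers <- config$candidate_powers
  if (!length(powers)) stop("pick_soft_power: no candidate powers")
  base <- signed_adjacency(ct, beta = 1)
  sim <- (1 + base$correlation) / 2
  rows <- vector("list", length(powers))
  for (i in seq_along(powers)) {
    a <- sim^powers[i]
    diag(a) <- 1
    f <- scale_free_fit(a, n_bins = config$n_bins)
    rows[[i]] <- data.frame(power = powers[i], fit_index = f$fit_index,
                            slope = f$slope,
                            mean_connectivity = f$mean_connectivity)
  }
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$fit_index) & tab$fit_index >= config$r2_target)
  if (length(hit)) {
    beta <- powers[hit[1]]
  } else {
    beta <- powers[which.max(tab$fit_index)]
    warning("pick_soft_power: no candidate reached r2_target = ",
            config$r2_target, "; returning the best-fitting power ", beta)
  }
  list(beta = beta, table = tab)
}

#' Topological overlap matrix
#'
#' For `i != j`:
#' `tom_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `tom_ii = 1`. Nodes that share many strong neighbors gain overlap beyond
#' their direct adjacency. `diss_tom = 1 - tom` is the clustering input.
#'
#' @param model A `network_model` with adjacency.
#' @return The model with `tom` and `diss_tom` added.
#' @export
tom <- function(model) {
  stopifnot(inherits(model, "network_model"))
  a <- model$adjacency
  a0 <- a; diag(a0) <- 0
  l <- a0 %*% a0            # l_ij = sum_u a_iu a_uj, u != i,j since diag 0
  k <- colSums(a0)
  kmin <- outer(k, k, pmin)
  tt <- (l + a0) / (kmin + 1 - a0)
  diag(tt) <- 1
  model$tom <- tt
  model$diss_tom <- 1 - tt
  model
}

#' Detect co-abundance modules by k-means on the TOM dissimilarity
#'
#' The hybrid module-detection step: rows of `diss_tom` are treated as
#' Euclidean feature vectors and clustered with [kmeans_fit()]. When `k` is
#' `NULL` it is chosen by [choose_k()] over a silhouette/elbow scan of
#' `k_range`. Labels are renumbered by descending module size.
#'
#' @param model A `network_model` with `diss_tom` ([tom()] first).
#' @param k Number of modules, or `NULL` to select automatically.
#' @param seed Optional seed.
#' @param k_range Candidate k for the automatic scan (default 2..10).
#' @param n_restarts k-means restarts.
#' @return Named integer vector of module labels (1 = largest), with
#'   attributes `k` and, for automatic selection, `selection_report`.
#' @export
detect_modules <- function(model, k = NULL, seed = NULL, k_range = 2:10,
                           n_restarts = 25L) {
  stopifnot(inherits(model, "network_model"))
  if (is.null(model$diss_tom)) stop("detect_modules: run tom() first")
  x <- model$diss_tom
  n <- nrow(x)
  report <- NULL
  if (is.null(k)) {
    report <- k_diagnostics(x, k_range, seed = seed, n_restarts = n_restarts)
    k <- as.integer(choose_k(report))
    sol <- attr(report, "solutions")[[as.character(k)]]
  } else {
    if (k >= n) stop("detect_modules: k must be < number of ASVs")
    if (k < 2) stop("detect_modules: k must be >= 2")
    sol <- kmeans_fit(x, k, n_restarts = n_restarts, seed = seed)
  }
  labels <- relabel_by_size(sol$labels)
  names(labels) <- colnames(model$adjacency)
  attr(labels, "k") <- k
  if (!is.null(report)) attr(labels, "selection_report") <- report
  labels
}

# renumber cluster labels so 1 is the largest cluster, ties by first label
relabel_by_size <- function(labels) {
  sizes <- table(labels)
  ord <- names(sizes)[order(-as.vector(sizes), as.integer(names(sizes)))]
  map <- stats::setNames(seq_along(ord), ord)
  as.integer(map[as.character(labels)])
}

#' Module eigengenes
#'
#' Each module is summarized by the first principal component of its
#' standardized member profiles, scaled to unit variance and oriented so
#' the mean correlation with the member profiles is positive. Singleton
#' modules fall back to the standardized profile and are flagged.
#'
#' @param ct A `community_table` restricted to the network's ASVs.
#' @param labels Module labels aligned to `ct$asv_ids`.
#' @return Sample x module matrix (columns `ME1`, `ME2`, ...), attribute
#'   `singleton_modules` listing modules with a single member.
#' @export
module_eigengenes <- function(ct, labels) {
  v <- if (inherits(ct, "community_table")) ct$values else as.matrix(ct)
  if (length(labels) != ncol(v))
    stop("module_eigengenes: labels not aligned to ASVs")
  mods <- sort(unique(labels))
  me <- matrix(NA_real_, nrow(v), length(mods),
               dimnames = list(rownames(v), paste0("ME", mods)))
  singletons <- integer(0)
  for (i in seq_along(mods)) {
    members <- which(labels == mods[i])
    xm <- v[, members, drop = FALSE]
    xm <- scale(xm)
    if (length(members) == 1L) {
      singletons <- c(singletons, mods[i])
      me[, i] <- xm[, 1]
      next
    }
    sv <- svd(xm, nu = 1, nv = 0)
    e <- sv$u[, 1]
    e <- e / stats::sd(e)
    if (mean(stats::cor(e, xm)) < 0) e <- -e
    me[, i] <- e
  }
  attr(me, "singleton_modules") <- singletons
  me
}

#' Module membership (kME) and module-trait statistics
#'
#' `kme[a, m]` is the Pearson correlation of ASV `a`'s profile with module
#' `m`'s eigengene — the ASV's centrality within the module.
#' `module_trait` correlates each eigengene with each trait/covariate
#' column (two-sided p from the t distribution with n - 2 df, no
#' multiple-testing correction; the p-values are reported raw and tagged).
#' `trait_significance` correlates every ASV profile directly with every
#' trait, supporting kME-versus-trait-significance scatter plots.
#'
#' @param ct A `community_table` restricted to the network's ASVs.
#' @param eigengenes Matrix from [module_eigengenes()].
#' @param traits Data frame of numeric per-sample traits/covariates aligned
#'   to samples (constant columns are flagged and get NA correlations).
#' @return List with `kme` (ASV x module), `module_trait` (long data frame:
#'   module, trait, correlation, p_value), `trait_significance`
#'   (ASV x trait), `constant_traits`, `p_adjust_method = "none"`.
#' @export
kme_and_trait_stats <- function(ct, eigengenes, traits) {
  v <- if (inherits(ct, "community_table")) ct$values else as.matrix(ct)
  tr <- as.data.frame(traits)
  num <- vapply(tr, is.numeric, logical(1))
  tr <- tr[, num, drop = FALSE]
  if (nrow(tr) != nrow(v))
    stop("kme_and_trait_stats: traits not aligned to samples")
  n <- nrow(v)
  kme <- stats::cor(v, eigengenes)
  constant <- names(tr)[vapply(tr, function(z) stats::sd(z) == 0, logical(1))]
  tm <- as.matrix(tr)
  mt_cor <- suppressWarnings(stats::cor(eigengenes, tm))
  tstat <- mt_cor * sqrt((n - 2) / pmax(1 - mt_cor^2, 1e-300))
  mt_p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  long <- data.frame(
    module = rep(rownames(mt_cor), times = ncol(mt_cor)),
    trait = rep(colnames(mt_cor), each = nrow(mt_cor)),
    correlation = as.vector(mt_cor),
    p_value = as.vector(mt_p))
  ts <- suppressWarnings(stats::cor(v, tm))
  list(kme = kme, module_trait = long, trait_significance = ts,
       constant_traits = constant, p_adjust_method = "none")
}

#' Merge highly correlated modules
#'
#' Iteratively merges the module pair with the highest eigengene
#' correlation while that correlation exceeds `merge_threshold`,
#' recomputing eigengenes after every merge (ties broken toward the
#' smaller label pair). Merged labels are renumbered by descending size.
#'
#' @param ct A `community_table` restricted to the network's ASVs.
#' @param labels Module labels.
#' @param merge_threshold Eigengene correlation threshold (default 0.7).
#' @return Named merged labels with attributes `eigengenes` (recomputed)
#'   and `merge_trace` (data frame of merges performed).
#' @export
merge_modules <- function(ct, labels, merge_threshold = 0.7) {
  lab <- as.integer(labels)
  trace <- list()
  repeat {
    mods <- sort(unique(lab))
    if (length(mods) < 2) break
    me <- module_eigengenes(ct, lab)
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)
    # deterministic tie-break: smallest (row, col) label pair
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    if (cc[best[1], best[2]] <= merge_threshold) break
    m1 <- mods[min(best)]; m2 <- mods[max(best)]
    trace[[length(trace) + 1L]] <-
      data.frame(from = m2, into = m1, correlation = cc[best[1], best[2]])
    lab[lab == m2] <- m1
  }
  lab <- relabel_by_size(lab)
  names(lab) <- names(labels)
  attr(lab, "eigengenes") <- module_eigengenes(ct, lab)
  attr(lab, "merge_trace") <- if (length(trace)) do.call(rbind, trace) else
    data.frame(from = integer(0), into = integer(0),
               correlation = numeric(0))
  lab
}
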