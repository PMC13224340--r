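#' Pairwise sample distances
#'
#' Euclidean distances, or the Bray-Curtis dissimilarity
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` for non-negative abundance
#' rows. Euclidean on a Hellinger-state table equals the Hellinger distance
#' between the underlying compositions.
#'
#' @param ct A `community_table` (or plain matrix).
#' @param metric `"euclidean"` or `"bray_curtis"`.
#' @return A `distance_matrix`: list with `values` (n x n, zero diagonal,
#'   symmetric), `metric`, `sample_ids`.
#' @export
pairwise_distance <- function(ct, metric = c("euclidean", "bray_curtis")) {
  metric <- match.arg(metric)
  v <- if (inherits(ct, "community_table")) ct$values else as.matrix(ct)
  if (metric == "euclidean") {
    m <- as.matrix(stats::dist(v))
  } else {
    if (any(v < 0)) stop("pairwise_distance: bray_curtis needs non-negative input")
    rs <- rowSums(v)
    denom <- outer(rs, rs, "+")
    if (any(denom == 0))
      stop("pairwise_distance: bray_curtis undefined for a pair of all-zero samples")
    m <- as.matrix(stats::dist(v, method = "manhattan")) / denom
  }
  diag(m) <- 0
  out <- list(values = m, metric = metric, sample_ids = rownames(v))
  class(out) <- "distance_matrix"
  out
}

as_distance_matrix <- function(d) {
  if (inherits(d, "distance_matrix")) return(d)
  m <- as.matrix(d)
  out <- list(values = m, metric = "unknown", sample_ids = rownames(m))
  class(out) <- "distance_matrix"
  out
}

# orient each axis so its largest-|coordinate| sample is positive
orient_axes <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering `B = -1/2 * J %*% D^2 %*% J` with
#' `J = I - 11'/n`, followed by eigendecomposition. Coordinates are
#' eigenvectors scaled by the square root of their (positive) eigenvalues;
#' eigenvalues below `1e-8 * max` are dropped, and negative eigenvalues are
#' discarded without correction (Euclidean-on-Hellinger input yields a
#' positive semi-definite B). Axes are oriented so the largest-magnitude
#' coordinate on each axis is positive.
#'
#' @param d A `distance_matrix` (or square matrix / `dist`).
#' @param n_axes Number of axes requested (default 2). If fewer positive
#'   eigenvalues exist, fewer axes are returned with a warning.
#' @return An `ordination`: list with `coordinates` (n x d), `method`
#'   (`"pcoa"`), `eigenvalues` (all retained, non-increasing),
#'   `variance_explained` (per retained axis, fraction of the positive
#'   eigenvalue total).
#' @export
pcoa <- function(d, n_axes = 2L) {
  d <- as_distance_matrix(d)
  D2 <- d$values^2
  n <- nrow(D2)
  G <- -0.5 * D2
  # double centering without forming J explicitly
  rm_ <- rowMeans(G); gm <- mean(G)
  B <- G - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > 1e-8 * max(e$values)
  if (!any(pos)) stop("pcoa: no positive eigenvalues")
  n_pos <- sum(pos)
  if (n_axes > n_pos) {
    warning("pcoa: only ", n_pos, " positive eigenvalues; returning ",
            n_pos, " axes")
    n_axes <- n_pos
  }
  lam <- e$values[pos]
  coords <- e$vectors[, which(pos)[seq_len(n_axes)], drop = FALSE] %*%
    diag(sqrt(lam[seq_len(n_axes)]), n_axes)
  coords <- orient_axes(coords)
  rownames(coords) <- d$sample_ids
  colnames(coords) <- paste0("axis", seq_len(n_axes))
  out <- list(coordinates = coords, method = "pcoa",
              eigenvalues = lam,
              variance_explained = lam[seq_len(n_axes)] / sum(lam),
              stress = NULL)
  class(out) <- "ordination"
  out
}

# pooled-adjacent-violators monotone fit of y against the order of x
monotone_fit <- function(x, y) {
  ord <- order(x)
  fit <- stats::isoreg(seq_along(ord), y[ord])$yf
  out <- numeric(length(y))
  out[ord] <- fit
  out
}

kruskal_stress1 <- function(dhat, dcur) {
  sqrt(sum((dhat - dcur)^2) / sum(dcur^2))
}

nmds_one_start <- function(delta, x0, max_iter, tol) {
  n <- nrow(x0)
  lt <- lower.tri(delta)
  dl <- delta[lt]
  x <- x0
  trace <- numeric(0)
  stress <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dcur <- as.matrix(stats::dist(x))
    dc <- dcur[lt]
    dhat <- monotone_fit(dl, dc)
    # scale disparities to the current configuration's distance norm
    dhat <- dhat * sqrt(sum(dc^2) / sum(dhat^2))
    new_stress <- kruskal_stress1(dhat, dc)
    trace <- c(trace, new_stress)
    if (is.finite(stress) && stress - new_stress < tol) {
      stress <- min(stress, new_stress)
      converged <- TRUE
      break
    }
    stress <- new_stress
    # Guttman transform with the disparities as target distances
    Dh <- matrix(0, n, n); Dh[lt] <- dhat; Dh <- Dh + t(Dh)
    ratio <- ifelse(dcur > 0, Dh / dcur, 0)
    B <- -ratio
    diag(B) <- rowSums(ratio)
    x <- (B %*% x) / n
    x <- scale(x, center = TRUE, scale = FALSE)
  }
  list(x = x, stress = stress, trace = trace, converged = converged)
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1
#' `sqrt(sum((dhat - d)^2) / sum(d^2))`, alternating pooled-adjacent-
#' violators monotone regression of configuration distances on the
#' dissimilarity order with a Guttman majorization update of the
#' configuration. The best of `n_starts` random initializations plus one
#' PCoA initialization is returned.
#'
#' @param d A `distance_matrix` (n >= 4).
#' @param d_target Embedding dimension (default 2).
#' @param n_starts Random starts in addition to the PCoA start (default 20).
#' @param max_iter Iteration cap per start (default 200).
#' @param seed Optional seed.
#' @param tol Convergence when the stress decrease falls below this
#'   (default 1e-6).
#' @return An `ordination` with `method = "nmds"`, `coordinates`, `stress`,
#'   `converged`, and the per-iteration `stress_trace` of the winning start.
#' @export
nmds <- function(d, d_target = 2L, n_starts = 20L, max_iter = 200L,
                 seed = NULL, tol = 1e-6) {
  d <- as_distance_matrix(d)
  n <- nrow(d$values)
  if (n < 4) stop("nmds: need at least 4 samples")
  if (!is.null(seed)) set.seed(seed)
  starts <- vector("list", n_starts + 1L)
  p0 <- tryCatch(pcoa(d, n_axes = d_target)$coordinates,
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(p0) || ncol(p0) < d_target)
    p0 <- matrix(stats::rnorm(n * d_target), n, d_target)
  starts[[1L]] <- p0
  for (s in seq_len(n_starts))
    starts[[s + 1L]] <- matrix(stats::rnorm(n * d_target), n, d_target)
  best <- NULL
  for (s in starts) {
    fit <- nmds_one_start(d$values, s, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- orient_axes(best$x)
  rownames(coords) <- d$sample_ids
  colnames(coords) <- paste0("axis", seq_len(d_target))
  out <- list(coordinates = coords, method = "nmds",
              eigenvalues = NULL, variance_explained = NULL,
              stress = best$stress, converged = best$converged,
              stress_trace = best$trace)
  class(out) <- "ordination"
  out
}

#' Fit environmental vectors onto an ordination
#'
#' For each covariate, a least-squares fit of the covariate on the
#' ordination axes; `r^2 = 1 - SS_resid / SS_total`. Significance by
#' permuting the covariate values with the add-one estimator
#' `p = (1 + #{permuted r^2 >= observed}) / (1 + n_permutations)`. The
#' direction vector is the unit-length vector of regression coefficients in
#' ordination space.
#'
#' @param ord An `ordination`.
#' @param covariates Data frame of numeric covariates aligned to the
#'   ordination's samples; rows with missing values are dropped per
#'   variable with a warning.
#' @param n_permutations Default 999.
#' @param seed Optional seed.
#' @return Data frame (`envfit_result`) with one row per covariate:
#'   direction components (`dir_axis*`), `r_squared`, `p_value`,
#'   `n_permutations`, `constant` flag.
#' @export
envfit <- function(ord, covariates, n_permutations = 999L, seed = NULL) {
  stopifnot(inherits(ord, "ordination"))
  X <- ord$coordinates
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(X))
    stop("envfit: covariates not aligned to ordination samples")
  if (!is.null(seed)) set.seed(seed)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  res <- vector("list", ncol(covariates))
  for (j in seq_len(ncol(covariates))) {
    y <- covariates[[j]]
    ok <- is.finite(y)
    if (!all(ok))
      warning("envfit: dropping ", sum(!ok), " rows with missing '",
              names(covariates)[j], "'")
    yj <- y[ok]; Xj <- Xc[ok, , drop = FALSE]
    if (stats::sd(yj) == 0) {
      row <- data.frame(variable = names(covariates)[j],
                        r_squared = 0, p_value = 1,
                        n_permutations = n_permutations, constant = TRUE)
      for (a in seq_len(ncol(X))) row[[paste0("dir_axis", a)]] <- NA_real_
      res[[j]] <- row
      next
    }
    qr_x <- qr(cbind(1, Xj))
    r2_of <- function(yy) {
      fit <- qr.fitted(qr_x, yy)
      1 - sum((yy - fit)^2) / sum((yy - mean(yy))^2)
    }
    r2 <- r2_of(yj)
    hits <- 0L
    for (p in seq_len(n_permutations))
      if (r2_of(sample(yj)) >= r2) hits <- hits + 1L
    pval <- (1 + hits) / (1 + n_permutations)
    beta <- qr.coef(qr_x, yj)[-1]
    dir <- beta / sqrt(sum(beta^2))
    row <- data.frame(variable = names(covariates)[j], r_squared = r2,
                      p_value = pval, n_permutations = n_permutations,
                      constant = FALSE)
    for (a in seq_len(ncol(X))) row[[paste0("dir_axis", a)]] <- dir[a]
    res[[j]] <- row
  }
  out <- do.call(rbind, res)
  class(out) <- c("envfit_result", "data.frame")
  out
}
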