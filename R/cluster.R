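#' k-means with k-means++ seeding and multiple restarts
#'
#' Lloyd iterations from k-means++ initial centers, best of `n_restarts` by
#' total within-cluster sum of squares (WSS). Empty clusters are repaired by
#' re-seeding the empty center at the point farthest from its centroid
#' within the largest cluster. Deterministic under `seed`.
#'
#' @param x Numeric matrix (items in rows).
#' @param k Number of clusters (`2 <= k <= nrow(x)`; `k = 1` allowed and
#'   returns the trivial solution).
#' @param n_restarts Number of independent initializations (default 25).
#' @param seed Optional integer seed.
#' @param max_iter Lloyd iteration cap per restart.
#' @return A `cluster_solution`: list with `labels` (1..k, every cluster
#'   non-empty), `k`, `wss`, `centers`, `mean_silhouette` (filled by
#'   [k_diagnostics()]; `NA` here), `seed`, `n_restarts`, `iterations`.
#' @export
kmeans_fit <- function(x, k, n_restarts = 25L, seed = NULL,
                       max_iter = 100L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("kmeans_fit: non-finite features")
  n <- nrow(x)
  if (k > n) stop("kmeans_fit: k (", k, ") exceeds number of items (", n, ")")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd_once(x, k, max_iter)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  out <- list(labels = best$labels, k = k, wss = best$wss,
              centers = best$centers, mean_silhouette = NA_real_,
              seed = seed, n_restarts = n_restarts,
              iterations = best$iterations)
  class(out) <- "cluster_solution"
  out
}

# squared Euclidean distances between rows of x and rows of centers
dist2_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  pmax(d2, 0)
}

# k-means++ seeding: first center uniform, later ones with probability
# proportional to squared distance to the nearest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1L), , drop = FALSE]
  if (k > 1L) {
    for (j in 2:k) {
      d2 <- dist2_to_centers(x, centers)
      nd <- apply(d2, 1, min)
      if (sum(nd) <= 0) idx <- sample.int(n, 1L)
      else idx <- sample.int(n, 1L, prob = nd)
      centers <- rbind(centers, x[idx, , drop = FALSE])
    }
  }
  centers
}

lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- kmeanspp_init(x, k)
  labels <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # repair empty clusters: seed at the farthest point of the largest one
    sizes <- tabulate(new_labels, nbins = k)
    while (any(sizes == 0L)) {
      empty <- which(sizes == 0L)[1L]
      big <- which.max(sizes)
      members <- which(new_labels == big)
      far <- members[which.max(d2[cbind(members, new_labels[members])])]
      new_labels[far] <- empty
      centers[empty, ] <- x[far, ]
      sizes <- tabulate(new_labels, nbins = k)
    }
    if (all(new_labels == labels)) break
    labels <- new_labels
    centers <- rowsum(x, labels) / as.vector(tabulate(labels, nbins = k))
  }
  d2 <- dist2_to_centers(x, centers)
  wss <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, wss = wss, iterations = it)
}

#' WSS and silhouette diagnostics over a range of k
#'
#' For each `k`, fits [kmeans_fit()] (best of restarts) and computes the
#' mean silhouette width `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with
#' Euclidean distances. When every cluster is a single point the silhouette
#' is 0 by convention and the row is flagged.
#'
#' @param x Feature matrix.
#' @param k_range Integer vector of candidate k (within `[2, n - 1]`;
#'   `k = n` is accepted and flagged degenerate).
#' @param seed Optional seed (one stream across the whole scan).
#' @param n_restarts Restarts per k.
#' @param sil_x Optional matrix (same rows as `x`) on which silhouette
#'   widths are computed. Useful when `x` is a smoothed representation
#'   (e.g. per-sample SOM codebook vectors, where many rows are exact
#'   duplicates and silhouette on `x` itself is degenerate): clustering
#'   runs on `x`, separation is judged on the original data.
#' @return A `k_selection_report`: data frame with columns `k`, `wss`,
#'   `mean_silhouette`, `degenerate`; the fitted solutions are attached as
#'   attribute `solutions`.
#' @export
k_diagnostics <- function(x, k_range, seed = NULL, n_restarts = 25L,
                          sil_x = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (any(k_range < 2L) || any(k_range > n))
    stop("k_diagnostics: k_range must lie in [2, n]")
  if (!is.null(seed)) set.seed(seed)
  dx <- stats::dist(if (is.null(sil_x)) x else as.matrix(sil_x))
  rows <- vector("list", length(k_range))
  sols <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    sol <- kmeans_fit(x, k, n_restarts = n_restarts)
    degen <- k == n
    if (degen) {
      sil <- 0
    } else {
      sw <- cluster::silhouette(sol$labels, dx)
      sil <- mean(sw[, "sil_width"])
    }
    sol$mean_silhouette <- sil
    sols[[i]] <- sol
    rows[[i]] <- data.frame(k = k, wss = sol$wss, mean_silhouette = sil,
                            degenerate = degen)
  }
  rep <- do.call(rbind, rows)
  attr(rep, "solutions") <- stats::setNames(sols, k_range)
  class(rep) <- c("k_selection_report", "data.frame")
  rep
}

#' Choose k from WSS-elbow and silhouette diagnostics
#'
#' The elbow k maximizes the perpendicular distance of the (k, WSS) curve to
#' the chord joining its endpoints, with both axes rescaled to \[0, 1\] so
#' the rule is unit-free; the silhouette k maximizes mean silhouette width.
#' If the two agree, that k is returned; otherwise the silhouette k wins
#' (silhouette also accounts for between-cluster separation) and the
#' conflict is recorded in the rule trace.
#'
#' @param report A `k_selection_report` covering at least 3 values of k.
#' @return Chosen k (integer) with attribute `rule_trace` (list: `elbow_k`,
#'   `silhouette_k`, `agreement`, `decision`).
#' @export
choose_k <- function(report) {
  stopifnot(inherits(report, "k_selection_report"))
  if (nrow(report) < 3) stop("choose_k: need at least 3 candidate k values")
  ks <- report$k
  w <- report$wss
  u <- (ks - min(ks)) / diff(range(ks))
  v <- if (diff(range(w)) > 0) (w - min(w)) / diff(range(w)) else rep(0, length(w))
  # distance from (u, v) to the chord from first to last point
  p1 <- c(u[1], v[1]); p2 <- c(u[length(u)], v[length(v)])
  dv <- p2 - p1
  dist_chord <- abs(dv[2] * (u - p1[1]) - dv[1] * (v - p1[2])) /
    sqrt(sum(dv^2))
  elbow_k <- ks[which.max(dist_chord)]
  sil_k <- ks[which.max(report$mean_silhouette)]
  agree <- elbow_k == sil_k
  chosen <- if (agree) elbow_k else sil_k
  attr(chosen, "rule_trace") <- list(
    elbow_k = elbow_k, silhouette_k = sil_k, agreement = agree,
    decision = if (agree) "elbow and silhouette agree"
               else "conflict: silhouette preferred")
  chosen
}
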