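#' Build a hexagonal SOM grid, optionally toroidal
#'
#' Units are laid out in offset hexagonal coordinates: within-row spacing 1,
#' odd rows (0-based) shifted by +0.5, row spacing `sqrt(3)/2`. With
#' `toroidal = TRUE` the map wraps in both directions and the unit-to-unit
#' distance is the minimum planar distance over the nine shifted copies of
#' the map, so every unit sees an identical neighborhood structure. Units
#' are indexed row-major.
#'
#' @param rows,cols Grid dimensions (>= 2 each). For a toroidal hex grid
#'   `rows` must be even for the offset pattern to wrap consistently; odd
#'   `rows` triggers a warning.
#' @param toroidal Wrap the grid edges (default `TRUE`).
#' @return A `som_grid`: list with `rows`, `cols`, `toroidal`, `coords`
#'   (units x 2 planar positions), `unit_distance` (units x units).
#' @export
build_grid <- function(rows, cols, toroidal = TRUE) {
  if (rows < 2 || cols < 2) stop("build_grid: rows and cols must be >= 2")
  if (toroidal && rows %% 2 == 1)
    warning("build_grid: toroidal hex grid with odd rows does not wrap evenly")
  r0 <- rep(seq_len(rows) - 1L, each = cols)
  c0 <- rep(seq_len(cols) - 1L, times = rows)
  coords <- cbind(x = c0 + 0.5 * (r0 %% 2), y = r0 * sqrt(3) / 2)
  n_units <- rows * cols
  if (toroidal) {
    dxs <- c(-cols, 0, cols)
    dys <- c(-rows, 0, rows) * sqrt(3) / 2
    dmat <- matrix(Inf, n_units, n_units)
    for (dx in dxs) for (dy in dys) {
      shifted <- cbind(coords[, 1] + dx, coords[, 2] + dy)
      dd <- outer(rowSums(coords^2), rowSums(shifted^2), "+") -
        2 * tcrossprod(coords, shifted)
      dmat <- pmin(dmat, sqrt(pmax(dd, 0)))
    }
  } else {
    dmat <- as.matrix(stats::dist(coords))
  }
  diag(dmat) <- 0
  dimnames(dmat) <- NULL
  out <- list(rows = rows, cols = cols, toroidal = toroidal,
              coords = coords, unit_distance = dmat)
  class(out) <- "som_grid"
  out
}

#' Train a self-organizing map by online competitive learning
#'
#' Codebook vectors are initialized from data rows sampled without
#' replacement. For each of `rlen * n` presentations, drawn in seeded
#' random order, the best-matching unit (BMU) is found by Euclidean
#' distance and every unit within the current neighborhood radius is moved
#' toward the sample: `w <- w + alpha * (x - w)` (bubble neighborhood; a
#' Gaussian kernel is available via `neighbourhood = "gaussian"`). The
#' learning rate decays linearly from `alpha[1]` to `alpha[2]` over all
#' presentations; the radius decays linearly from the 2/3 quantile of the
#' grid distances to just below the smallest positive grid distance, so
#' training ends with BMU-only updates.
#'
#' @param x A `community_table` (typically Hellinger state) or numeric
#'   matrix, samples in rows.
#' @param grid A `som_grid`.
#' @param alpha Length-2 learning-rate schedule, default `c(0.05, 0.01)`.
#' @param rlen Passes over the data (default 100).
#' @param seed Optional integer seed.
#' @param neighbourhood `"bubble"` (default) or `"gaussian"`.
#' @return A `som_model`: list with `grid`, `codebook` (units x features),
#'   `alpha`, `rlen`, `seed`, `neighbourhood`, `training_loss` (mean
#'   distance of presented samples to their BMU, one entry per pass).
#' @export
train_som <- function(x, grid, alpha = c(0.05, 0.01), rlen = 100L,
                      seed = NULL, neighbourhood = c("bubble", "gaussian")) {
  neighbourhood <- match.arg(neighbourhood)
  stopifnot(inherits(grid, "som_grid"))
  v <- if (inherits(x, "community_table")) x$values else as.matrix(x)
  if (nrow(v) == 0) stop("train_som: empty input")
  n <- nrow(v); p <- ncol(v)
  n_units <- grid$rows * grid$cols
  if (n < n_units)
    warning("train_som: fewer samples (", n, ") than map units (", n_units,
            ")")
  if (!is.null(seed)) set.seed(seed)
  init_idx <- sample.int(n, n_units, replace = n < n_units)
  codebook <- v[init_idx, , drop = FALSE]
  rownames(codebook) <- NULL
  ud <- grid$unit_distance
  pos <- ud[ud > 0]
  r_start <- stats::quantile(pos, 2 / 3, names = FALSE)
  r_end <- 0.99 * min(pos)
  total <- rlen * n
  alphas <- seq(alpha[1], alpha[2], length.out = total)
  radii <- seq(r_start, r_end, length.out = total)
  loss <- numeric(rlen)
  t <- 0L
  for (pass in seq_len(rlen)) {
    ord <- sample.int(n)
    qe <- 0
    for (i in ord) {
      t <- t + 1L
      xi <- v[i, ]
      d2 <- rowSums(codebook^2) - 2 * (codebook %*% xi) + sum(xi^2)
      bmu <- which.min(d2)
      qe <- qe + sqrt(max(d2[bmu], 0))
      if (neighbourhood == "bubble") {
        nb <- which(ud[bmu, ] <= radii[t])
        a <- alphas[t]
        codebook[nb, ] <- codebook[nb, ] +
          a * (matrix(xi, length(nb), p, byrow = TRUE) -
                 codebook[nb, , drop = FALSE])
      } else {
        w <- exp(-(ud[bmu, ]^2) / (2 * max(radii[t], 1e-8)^2))
        a <- alphas[t] * w
        codebook <- codebook + a * (matrix(xi, n_units, p, byrow = TRUE) -
                                      codebook)
      }
    }
    loss[pass] <- qe / n
  }
  out <- list(grid = grid, codebook = codebook, alpha = alpha, rlen = rlen,
              seed = seed, neighbourhood = neighbourhood,
              training_loss = loss)
  class(out) <- "som_model"
  out
}

#' Map samples to their best-matching units
#'
#' @param model A `som_model`.
#' @param x A `community_table` or matrix with the codebook's feature
#'   dimension.
#' @return A `som_mapping`: list with `bmu` (unit index per sample, ties
#'   broken toward the lowest unit index), `quantization_error` (Euclidean
#'   distance to the BMU), `occupancy` (samples per unit, sums to n).
#' @export
map_samples <- function(model, x) {
  stopifnot(inherits(model, "som_model"))
  v <- if (inherits(x, "community_table")) x$values else as.matrix(x)
  if (ncol(v) != ncol(model$codebook))
    stop("map_samples: feature dimension (", ncol(v),
         ") does not match codebook (", ncol(model$codebook), ")")
  cb <- model$codebook
  d2 <- outer(rowSums(v^2), rowSums(cb^2), "+") - 2 * tcrossprod(v, cb)
  d2 <- pmax(d2, 0)
  bmu <- max.col(-d2, ties.method = "first")
  qe <- sqrt(d2[cbind(seq_len(nrow(v)), bmu)])
  out <- list(bmu = bmu, quantization_error = qe,
              occupancy = tabulate(bmu, nbins = nrow(cb)))
  class(out) <- "som_mapping"
  out
}
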