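#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared distances
#' `SS_total = sum_{i<j} d_ij^2 / n` into within-group
#' (`SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`) and between-group
#' parts; `pseudo_F = (SS_between / (k - 1)) / (SS_within / (n - k))`.
#' Significance by permuting group labels with the add-one estimator
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`.
#'
#' @param d A `distance_matrix` (or square matrix / `dist`).
#' @param labels Group labels (>= 2 groups, each with >= 2 members).
#' @param n_permutations Default 999.
#' @param seed Optional seed.
#' @return A `permanova_result`: list with `pseudo_F`, `r_squared`,
#'   `p_value`, `n_permutations`, `df_between`, `df_within`.
#' @export
permanova <- function(d, labels, n_permutations = 999L, seed = NULL) {
  d <- as_distance_matrix(d)
  d2 <- d$values^2
  labels <- as.factor(labels)
  n <- nrow(d2)
  if (length(labels) != n) stop("permanova: labels not aligned to distances")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("permanova: need at least 2 groups")
  if (any(sizes < 2)) stop("permanova: every group needs >= 2 members")
  k <- length(sizes)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- function(lab) {
    s <- 0
    for (g in levels(labels)) {
      idx <- which(lab == g)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_of <- function(lab) {
    ssw <- ss_within(lab)
    ((ss_total - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_of(labels)
  ssw_obs <- ss_within(labels)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (p in seq_len(n_permutations))
    if (f_of(labels[sample.int(n)]) >= f_obs) hits <- hits + 1L
  out <- list(pseudo_F = f_obs,
              r_squared = (ss_total - ssw_obs) / ss_total,
              p_value = (1 + hits) / (1 + n_permutations),
              n_permutations = n_permutations,
              df_between = k - 1, df_within = n - k)
  class(out) <- "permanova_result"
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Wraps [stats::kruskal.test()] (tie-corrected H, chi-square p on k - 1
#' df). All-identical values return H = 0, p = 1.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, >= 2 values each).
#' @return List with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("kruskal_wallis: need at least 2 groups")
  if (any(sizes < 2)) stop("kruskal_wallis: every group needs >= 2 values")
  if (diff(range(values)) == 0)
    return(list(statistic = 0, p_value = 1, df = length(sizes) - 1L))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Pairwise rank-sum tests with p-value adjustment
#'
#' All group pairs are compared with the two-sample Wilcoxon rank-sum
#' (Mann-Whitney) statistic: exact null when the smaller group has at most
#' 8 observations and there are no ties, otherwise the normal approximation
#' with continuity correction. Note: for independent groups of unequal size
#' (clusters of samples) the rank-sum test is the applicable Wilcoxon
#' variant; the paired signed-rank test requires matched observations.
#'
#' @param values Numeric vector.
#' @param groups Group labels (each group >= 2 values).
#' @param adjust Multiplicity correction across pairs: `"holm"` (default),
#'   `"bonferroni"`, `"BH"` or `"none"`.
#' @return Data frame (`pairwise_result`) with columns `group1`, `group2`,
#'   `statistic` (W), `p_value`, `p_adjusted`; attribute `adjust_method`.
#' @export
pairwise_wilcoxon <- function(values, groups, adjust = c("holm",
                                                         "bonferroni",
                                                         "BH", "none")) {
  adjust <- match.arg(adjust)
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) stop("pairwise_wilcoxon: every group needs >= 2 values")
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  rows <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- values[groups == pairs[1, i]]
    b <- values[groups == pairs[2, i]]
    exact <- min(length(a), length(b)) <= 8 &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    rows[[i]] <- data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
                            statistic = unname(wt$statistic),
                            p_value = wt$p.value)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  attr(out, "adjust_method") <- adjust
  class(out) <- c("pairwise_result", "data.frame")
  out
}

#' Pearson correlation with t-based p-value
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df, two-sided. Zero
#' variance in either vector is flagged as undefined.
#'
#' @param x,y Paired numeric vectors (n >= 3 finite pairs).
#' @return List with `r`, `p_value`, `n`, `undefined` flag.
#' @export
correlation_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlation_test: need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n, undefined = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n,
       undefined = FALSE)
}
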