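#' Normalize read counts by 16S copy number
#'
#' Divides each ASV's counts by its estimated 16S rRNA gene copy number, the
#' standard correction for multi-copy amplicon bias, turning read counts
#' into approximate cell-equivalent abundances.
#'
#' @param counts A `community_table` in state `raw`.
#' @param copy_numbers Named positive numeric vector aligned to
#'   `counts$asv_ids` (names required unless exactly aligned).
#' @return A `community_table` in state `copy_corrected`.
#' @export
normalize_copy_number <- function(counts, copy_numbers) {
  stopifnot(inherits(counts, "community_table"))
  if (counts$state != "raw")
    stop("normalize_copy_number: expected a raw counts table, got state '",
         counts$state, "'")
  if (!is.null(names(copy_numbers))) {
    missing <- setdiff(counts$asv_ids, names(copy_numbers))
    if (length(missing))
      stop("normalize_copy_number: no copy number for ASVs: ",
           paste(utils::head(missing, 10), collapse = ", "))
    copy_numbers <- copy_numbers[counts$asv_ids]
  } else if (length(copy_numbers) != length(counts$asv_ids)) {
    stop("normalize_copy_number: unnamed copy_numbers must match ASV count")
  }
  if (any(!is.finite(copy_numbers)) || any(copy_numbers <= 0))
    stop("normalize_copy_number: copy numbers must be positive and finite")
  v <- sweep(counts$values, 2, copy_numbers, "/")
  community_table(v, state = "copy_corrected")
}

#' Remove singleton ASVs
#'
#' A singleton is an ASV whose total count across the whole study equals
#' exactly 1 — almost always a sequencing artifact. Column order of the
#' survivors is preserved. Operates on raw integer counts: singleton status
#' is a read-count concept and is therefore assessed before any
#' normalization.
#'
#' @param counts A `community_table` in state `raw`.
#' @return A `community_table` (raw) without singleton columns; the removed
#'   ASV ids are attached as attribute `removed`.
#' @export
drop_singletons <- function(counts) {
  stopifnot(inherits(counts, "community_table"))
  if (counts$state != "raw")
    stop("drop_singletons: expected a raw counts table")
  tot <- colSums(counts$values)
  single <- tot == 1
  out <- community_table(counts$values[, !single, drop = FALSE], "raw")
  attr(out, "removed") <- counts$asv_ids[single]
  out
}

#' Convert to relative abundance
#'
#' @param ct A `community_table` (any non-relative state).
#' @return A `community_table` in state `relative` (rows sum to 1).
#' @export
relative_abundance <- function(ct) {
  stopifnot(inherits(ct, "community_table"))
  rs <- rowSums(ct$values)
  if (any(rs == 0))
    stop("relative_abundance: zero-total sample(s): ",
         paste(ct$sample_ids[rs == 0], collapse = ", "))
  community_table(ct$values / rs, state = "relative")
}

#' Hellinger transformation
#'
#' Square root of relative abundance: `sqrt(x[s,a] / rowsum[s])`. Euclidean
#' distances between Hellinger-transformed rows equal the Hellinger distance
#' between the raw compositions, which makes the table suitable for
#' Euclidean-assumption methods (PCoA, SOM, k-means).
#'
#' @param ct A `community_table` in state `raw`, `copy_corrected` or
#'   `relative`.
#' @return A `community_table` in state `hellinger` (row sums of squares
#'   equal 1).
#' @export
hellinger <- function(ct) {
  stopifnot(inherits(ct, "community_table"))
  rs <- rowSums(ct$values)
  if (any(rs == 0))
    stop("hellinger: zero-total sample(s): ",
         paste(ct$sample_ids[rs == 0], collapse = ", "))
  community_table(sqrt(ct$values / rs), state = "hellinger")
}

#' Network-specific sample and ASV QC
#'
#' Correlation networks are sensitive to rare, sparse and invariant
#' features, so before network construction we (1) drop zero-variance ASVs,
#' (2) drop samples with more than `max_zero_fraction` zero entries among
#' the retained ASVs, and (3) keep the top `n_keep` ASVs by mean relative
#' abundance.
#'
#' @param ct A `community_table`.
#' @param n_keep Number of most-abundant ASVs to retain.
#' @param max_zero_fraction Samples with a larger fraction of zeros are
#'   dropped (default 0.5).
#' @param var_tol Variance at or below this is treated as zero
#'   (default 1e-12).
#' @return A `community_table`; attribute `qc_report` lists dropped sample
#'   and ASV ids and counts.
#' @export
network_qc <- function(ct, n_keep, max_zero_fraction = 0.5,
                       var_tol = 1e-12) {
  stopifnot(inherits(ct, "community_table"))
  v <- ct$values
  vars <- apply(v, 2, stats::var)
  keep_var <- vars > var_tol
  v1 <- v[, keep_var, drop = FALSE]
  zero_frac <- rowMeans(v1 == 0)
  keep_s <- zero_frac <= max_zero_fraction
  v2 <- v1[keep_s, , drop = FALSE]
  if (n_keep > ncol(v2))
    stop("network_qc: n_keep (", n_keep, ") exceeds surviving ASVs (",
         ncol(v2), ")")
  ab <- if (ct$state == "hellinger") v2^2 else v2   # back to abundance scale
  rel_mean <- colMeans(ab / rowSums(ab))
  keep_a <- order(rel_mean, decreasing = TRUE)[seq_len(n_keep)]
  keep_a <- sort(keep_a)   # preserve original column order
  out <- new_community_table(v2[, keep_a, drop = FALSE], state = ct$state)
  attr(out, "qc_report") <- list(
    n_asvs_zero_variance = sum(!keep_var),
    asvs_zero_variance = ct$asv_ids[!keep_var],
    n_samples_dropped = sum(!keep_s),
    samples_dropped = rownames(v1)[!keep_s],
    n_asvs_kept = n_keep)
  out
}
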