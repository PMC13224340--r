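#' Community abundance table
#'
#' A sample x ASV abundance matrix carrying an explicit transform-state tag so
#' that downstream steps can assert they received the normalization they
#' expect. States form the canonical chain
#' `raw -> copy_corrected -> relative -> hellinger`.
#'
#' @param values Numeric matrix, samples in rows, ASVs in columns. Row and
#'   column names are used as sample and ASV identifiers; defaults are
#'   generated when absent.
#' @param state One of `"raw"`, `"copy_corrected"`, `"relative"`,
#'   `"hellinger"`.
#' @return An object of class `community_table`: a list with elements
#'   `values`, `sample_ids`, `asv_ids`, `state`.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4)
#' ct <- community_table(m)
#' ct$state
#' @export
community_table <- function(values, state = c("raw", "copy_corrected",
                                              "relative", "hellinger")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("community_table: values must be finite")
  if (any(values < 0))
    stop("community_table: negative abundances are not allowed")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("ASV%04d", seq_len(ncol(values)))
  obj <- list(values = values,
              sample_ids = rownames(values),
              asv_ids = colnames(values),
              state = state)
  class(obj) <- "community_table"
  validate_community_table(obj)
  obj
}

#' Validate the state invariants of a community table
#'
#' Checks non-negativity and, for `relative`/`hellinger` tables, the row-sum
#' (resp. row sum-of-squares) normalization to within `tol`.
#'
#' @param ct A `community_table`.
#' @param tol Numeric tolerance on the normalization invariants.
#' @return `ct`, invisibly; errors if an invariant is violated.
#' @export
validate_community_table <- function(ct, tol = 1e-9) {
  stopifnot(inherits(ct, "community_table"))
  v <- ct$values
  if (any(v < 0)) stop("community_table: negative entries")
  nz <- rowSums(v) > 0
  if (ct$state == "relative" && any(abs(rowSums(v[nz, , drop = FALSE]) - 1) > tol))
    stop("community_table: state 'relative' but rows do not sum to 1")
  if (ct$state == "hellinger" &&
      any(abs(rowSums(v[nz, , drop = FALSE]^2) - 1) > tol))
    stop("community_table: state 'hellinger' but row sums of squares != 1")
  invisible(ct)
}

# low-level constructor: no invariant validation; used where a table is a
# column subset of a normalized table (e.g. network QC) so whole-row
# normalization no longer holds
new_community_table <- function(values, state) {
  obj <- list(values = values, sample_ids = rownames(values),
              asv_ids = colnames(values), state = state)
  class(obj) <- "community_table"
  obj
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d ASVs [state: %s]\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$values)

#' Write a community table to TSV
#'
#' Tab-delimited UTF-8 with a header row; sample identifiers occupy the first
#' column (`sample_id`). The transform state is recorded in a `# state:`
#' comment line so round-trips preserve it.
#'
#' @param ct A `community_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_community_tsv <- function(ct, path) {
  stopifnot(inherits(ct, "community_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# state: %s", ct$state), con)
  df <- data.frame(sample_id = ct$sample_ids, ct$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a community table from TSV
#'
#' @param path File written by [write_community_tsv()] (or any TSV with
#'   `sample_id` first column). A missing `# state:` header defaults to raw.
#' @return A `community_table`.
#' @export
read_community_tsv <- function(path) {
  if (!file.exists(path)) stop("read_community_tsv: no such file: ", path)
  first <- readLines(path, n = 1L)
  state <- "raw"
  if (startsWith(first, "# state:"))
    state <- trimws(sub("^# state:", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  community_table(m, state = state)
}

#' Read a BIOM file as a community table
#'
#' Maps the BIOM observation x sample matrix onto the package's sample x ASV
#' orientation. Requires the `biomformat` package.
#'
#' @param path Path to a BIOM (JSON or HDF5) file.
#' @return A `community_table` in state `raw`.
#' @export
read_community_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("read_community_biom requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))
  community_table(m, state = "raw")
}

#' Read/write a simple keyed TSV (metadata, traits, ground truth)
#'
#' @param df Data frame to write; first column is the key.
#' @param path File path.
#' @return `path` invisibly (write) or a data frame (read).
#' @keywords internal
write_keyed_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_keyed_tsv
#' @keywords internal
read_keyed_tsv <- function(path) {
  if (!file.exists(path)) stop("read_keyed_tsv: no such file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
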