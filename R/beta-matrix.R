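#' Compute the beta value from methylated/unmethylated intensities
#'
#' The methylation fraction at a CpG site is computed from fluorescence
#' intensities as `M / (M + U + 100)`, the standard Illumina beta with a
#' stabilising offset of 100 in the denominator. Values always fall in
#' `[0, 1)`.
#'
#' @param M Methylated signal intensity (non-negative, fluorescence units).
#'   Vectorised.
#' @param U Unmethylated signal intensity (non-negative). Recycled against
#'   `M`.
#' @param offset Denominator offset; 100 by convention.
#'
#' @return Numeric vector of methylation fractions in `[0, 1)`.
#'
#' @examples
#' compute_beta(900, 0)    # 0.9
#' compute_beta(100, 100)  # 1/3
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (any(!is.finite(M)) || any(!is.finite(U)))
    stop2("intensities must be finite numbers")
  if (any(M < 0) || any(U < 0))
    stop2("negative intensity: M and U must be >= 0")
  M / (M + U + offset)
}

#' Construct and validate a beta matrix
#'
#' A beta matrix is a plain numeric matrix of methylation fractions with CpG
#' probes as rows and samples as columns; `NA` marks a missing measurement.
#' This constructor enforces the container invariants: unique probe and
#' sample identifiers, and all non-missing values inside `[0, 1]`.
#'
#' @param values Numeric matrix with rownames (probe ids) and colnames
#'   (sample ids).
#'
#' @return The validated matrix (invisibly unchanged).
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop2("beta matrix must be a numeric matrix")
  pid <- rownames(values); sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stop2("beta matrix needs probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(pid)) stop2("duplicate probe ids in beta matrix")
  if (anyDuplicated(sid)) stop2("duplicate sample ids in beta matrix")
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop2("beta values out of range: all non-missing values must lie in [0, 1]")
  values
}

#' Read a beta-value (or detection p-value) matrix from TSV
#'
#' Expects a tab-separated file with probe ids in the first column and a
#' header row of sample ids. Cells equal to `missing` are read as `NA`.
#'
#' @param path File path.
#' @param missing Missing-value marker in the file (default `"NA"`).
#' @param on_invalid What to do with out-of-range values: `"error"` (default)
#'   or `"missing"` (replace with `NA`).
#'
#' @return Numeric matrix, probes x samples, validated as by [beta_matrix()].
#' @export
read_beta_matrix <- function(path, missing = "NA", on_invalid = c("error", "missing")) {
  on_invalid <- match.arg(on_invalid)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = missing,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop2("beta matrix file needs a probe-id column and >= 1 sample")
  pid <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop2("non-numeric cell in beta matrix (not the missing marker)")
  rownames(m) <- pid
  if (on_invalid == "missing") {
    bad <- !is.na(m) & (m < 0 | m > 1)
    m[bad] <- NA_real_
  }
  beta_matrix(m)
}

#' Write a beta matrix to TSV
#'
#' Inverse of [read_beta_matrix()]: probe ids in the first column
#' (`probe_id`), sample ids as header, missing values as `NA`. Values are
#' written with enough digits to round-trip exactly at the chosen precision.
#'
#' @param bm Beta matrix (probes x samples).
#' @param path Output path.
#' @param digits Significant digits written (default 15, bit-faithful for
#'   doubles produced from text at that precision).
#' @export
write_beta_matrix <- function(bm, path, digits = 15) {
  df <- data.frame(probe_id = rownames(bm),
                   apply(bm, 2, function(col) {
                     out <- format_num(col, digits)
                     out[is.na(col)] <- NA_character_
                     out
                   }),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(bm))
  write_tsv_plain(df, path)
}

#' Read a detection p-value matrix
#'
#' Same layout as the beta matrix TSV; values validated to lie in `[0, 1]`.
#'
#' @inheritParams read_beta_matrix
#' @return Numeric matrix of detection p-values.
#' @export
read_detection_p <- function(path, missing = "NA") {
  read_beta_matrix(path, missing = missing, on_invalid = "error")
}
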