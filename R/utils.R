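# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

# Normalize chromosome labels: "chrX" -> "X", "chr1" -> "1"; case-insensitive
# "chr" prefix. Anything else passes through unchanged.
normalize_chromosome <- function(chr) {
  chr <- as.character(chr)
  sub("^[Cc][Hh][Rr]", "", chr)
}

# Deterministic TSV writers: fixed field order, "NA" missing marker, no
# quoting, LF line endings. Byte-identical output for identical input is a
# pipeline contract.
write_tsv_plain <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                    check.names = FALSE, stringsAsFactors = FALSE, ...)
}

# Format numbers for output files: full precision, no scientific drift
# between platforms.
format_num <- function(x, digits = 15) {
  formatC(x, digits = digits, format = "g")
}
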