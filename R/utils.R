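# internal helpers shared across modules

# normalize raw sequence text to the internal DNA alphabet (U -> T, uppercase)
normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# hamming distance between equal-length strings (positions compared bytewise)
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stop_if(length(ra) != length(rb), "hamming: unequal lengths")
  sum(ra != rb)
}

#' Round half away from zero
#'
#' Fixed-precision rounding used for report columns, where exactly-half
#' values move away from zero (2.005 -> 2.01, -2.005 -> -2.01), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# write a data.frame as TSV with header, no quoting
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "", ...)
}
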