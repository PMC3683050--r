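#' Trim a 3' sequencing adapter from reads
#'
#' Removes from each read the longest suffix that matches a prefix of the
#' adapter with overlap of at least `min_overlap` nucleotides and at most
#' `floor(mismatch_rate * overlap)` mismatches. Reads without an admissible
#' match are returned unchanged (a valid outcome for short inserts and
#' adapter-free protocols).
#'
#' @param reads character vector of read sequences (ACGTN).
#' @param adapter adapter sequence; its prefix is searched at read 3' ends.
#' @param min_overlap minimum read-suffix/adapter-prefix overlap.
#' @param mismatch_rate tolerated mismatch fraction of the overlap.
#' @return character vector of trimmed reads.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5, mismatch_rate = 0.1) {
  stop_if(missing(adapter) || is.null(adapter) || !nzchar(adapter),
          "adapter must be a non-empty sequence")
  adapter <- normalize_seq(adapter)
  vapply(normalize_seq(reads), function(r) {
    n <- nchar(r)
    kmax <- min(n, nchar(adapter))
    if (kmax < min_overlap) return(r)
    for (k in kmax:min_overlap) {
      mm <- hamming(substr(r, n - k + 1, n), substr(adapter, 1, k))
      if (mm <= floor(mismatch_rate * k)) return(substr(r, 1, n - k))
    }
    r
  }, character(1), USE.NAMES = FALSE)
}

#' Filter reads by length window
#'
#' The default window keeps miRNA-sized reads: 13 to 30 nt (13 encodes
#' "longer than 12 nt"; sequencers emit reads up to 70+ nt but isomiR
#' grouping only concerns the miRNA-length range).
#'
#' @param reads character vector.
#' @param min_len,max_len inclusive bounds.
#' @return the reads within the window.
#' @export
length_filter <- function(reads, min_len = 13, max_len = 30) {
  stop_if(min_len < 1, "min_len must be >= 1")
  stop_if(min_len > max_len, "min_len exceeds max_len")
  n <- nchar(reads)
  reads[n >= min_len & n <= max_len]
}

#' Collapse reads to unique sequences with counts
#'
#' @param reads character vector of (already trimmed and filtered) reads.
#' @param counts optional per-read multiplicities (for pre-collapsed input).
#' @return data.frame with columns `sequence` and `count`, ordered by
#'   decreasing count then sequence; counts sum to the number of input reads.
#' @export
collapse_reads <- function(reads, counts = NULL) {
  if (length(reads) == 0)
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  if (is.null(counts)) counts <- rep(1L, length(reads))
  tab <- rowsum(as.numeric(counts), group = reads)
  out <- data.frame(sequence = rownames(tab), count = as.integer(tab[, 1]),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$sequence), , drop = FALSE]
}

#' Read, trim, filter and collapse one small-RNA library
#'
#' Accepts FASTQ or FASTA (optionally gzipped; format chosen by file
#' extension unless given). FASTA records whose headers end in
#' `"name_<count>"` are treated as pre-collapsed with that multiplicity.
#' Reads containing N are dropped before filtering, since the grouping
#' tolerances are defined over ACGT only.
#'
#' @param path input file.
#' @param library_id,condition identifiers stored on the result.
#' @param format `"auto"`, `"fastq"` or `"fasta"`.
#' @param adapter optional 3' adapter to trim; `NULL` disables trimming.
#' @param min_overlap,mismatch_rate see [trim_adapter()].
#' @param min_len,max_len see [length_filter()].
#' @return an object of class `mirna_library`: list with `library_id`,
#'   `condition`, `reads` (collapsed data.frame), `total_raw`, `total_kept`.
#' @export
read_library <- function(path, library_id = basename(path),
                         condition = NA_character_,
                         format = c("auto", "fastq", "fasta"),
                         adapter = NULL, min_overlap = 5, mismatch_rate = 0.1,
                         min_len = 13, max_len = 30) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    ext <- tolower(tools::file_ext(base))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  x <- Biostrings::readBStringSet(path, format = format)
  seqs <- normalize_seq(as.character(x))
  counts <- rep(1L, length(seqs))
  if (format == "fasta") {
    ids <- sub("\\s.*$", "", names(x))
    m <- regmatches(ids, regexpr("_[0-9]+$", ids))
    has <- lengths(regmatches(ids, gregexpr("_[0-9]+$", ids))) > 0
    counts[has] <- as.integer(sub("^_", "", m))
  }
  total_raw <- sum(counts)
  if (!is.null(adapter) && nzchar(adapter))
    seqs <- trim_adapter(seqs, adapter, min_overlap, mismatch_rate)
  keep <- !grepl("N", seqs, fixed = TRUE) &
    nchar(seqs) >= min_len & nchar(seqs) <= max_len
  stop_if(min_len > max_len, "min_len exceeds max_len")
  collapsed <- collapse_reads(seqs[keep], counts[keep])
  new_library(library_id, condition, collapsed, total_raw)
}

new_library <- function(library_id, condition, reads, total_raw) {
  structure(list(library_id = library_id, condition = condition,
                 reads = reads, total_raw = as.integer(total_raw),
                 total_kept = as.integer(sum(reads$count))),
            class = "mirna_library")
}

#' @export
print.mirna_library <- function(x, ...) {
  cat("small-RNA library ", x$library_id,
      if (!is.na(x$condition)) paste0(" [", x$condition, "]"), "\n", sep = "")
  cat("  raw reads:  ", x$total_raw, "\n", sep = "")
  cat("  kept reads: ", x$total_kept, " (", nrow(x$reads), " unique)\n",
      sep = "")
  invisible(x)
}

#' Read-length histogram of a library
#'
#' Count-weighted number of reads per length; the miRNA peak of a typical
#' library sits at 22 nt.
#'
#' @param lib a `mirna_library`.
#' @return data.frame with columns `length` and `count`.
#' @export
length_histogram <- function(lib) {
  n <- nchar(lib$reads$sequence)
  tab <- rowsum(lib$reads$count, group = n)
  data.frame(length = as.integer(rownames(tab)), count = as.integer(tab[, 1]))
}
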