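# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by a different route than the
# package internals (explicit padded-character alignment, label
# permutation) so agreement is informative.

# Brute-force read/mature placement: enumerate every (d5, d3) pair
# independently, build the padded alignment as character vectors, count
# mismatches over the overlap, and apply the documented tie-break.
brute_force_match <- function(read, mature, max_mismatch = 2,
                              max_end_offset = 3) {
  lr <- nchar(read)
  lm <- nchar(mature)
  rs <- strsplit(read, "")[[1]]
  ms <- strsplit(mature, "")[[1]]
  best <- NULL
  for (d5 in -max_end_offset:max_end_offset) {
    for (d3 in -max_end_offset:max_end_offset) {
      if (lm + d5 + d3 != lr) next
      # lay both strings on a common axis: mature occupies slots 1..lm,
      # the read occupies slots (1 - d5)..(lm + d3)
      lo <- min(1, 1 - d5)
      hi <- max(lm, lm + d3)
      axis_m <- rep(NA_character_, hi - lo + 1)
      axis_r <- axis_m
      axis_m[(1:lm) - lo + 1] <- ms
      axis_r[((1 - d5):(lm + d3)) - lo + 1] <- rs
      both <- !is.na(axis_m) & !is.na(axis_r)
      if (!any(both)) next
      mm <- sum(axis_m[both] != axis_r[both])
      if (mm > max_mismatch) next
      key <- c(mm, abs(d5) + abs(d3), abs(d5), d5)
      if (is.null(best) || key_lt(key, best$key))
        best <- list(key = key, d5 = d5, d3 = d3, n_mismatch = mm)
    }
  }
  best
}

key_lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# Exact permutation test on the difference of pooled group proportions,
# enumerating all assignments of the 6 libraries to two groups of 3.
permutation_prop_test <- function(x, n, group) {
  stat <- function(g) {
    abs(sum(x[g == 1]) / sum(n[g == 1]) - sum(x[g == 2]) / sum(n[g == 2]))
  }
  obs <- stat(group)
  idx <- utils::combn(length(x), sum(group == 1))
  perm <- apply(idx, 2, function(sel) {
    g <- rep(2, length(x))
    g[sel] <- 1
    stat(g)
  })
  mean(perm >= obs - 1e-15)
}

# mutate one position of a sequence to a different nucleotide
mutate_at <- function(seq, pos, to = NULL) {
  old <- substr(seq, pos, pos)
  if (is.null(to)) to <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(seq, pos, pos) <- to
  seq
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny two-gene reference written to temp FASTA files; returns paths + seqs
write_tiny_reference <- function(dir = withr::local_tempdir(
                                   .local_envir = parent.frame())) {
  hp1 <- paste0("GGA", "TGAGGTAGTAGGTTGTATAGTT", "CTATCAGGCCG",
                "AACTATACAACCTACTACCTCA", "CCT")
  m1 <- "TGAGGTAGTAGGTTGTATAGTT"
  hp2 <- paste0("CATCT", "TACCCTGTAGAACCGAATTTGTG", "GTCTAAGG",
                "CACAAATTCGGTTCTACAGGGTA", "TAATC")
  m2 <- "TACCCTGTAGAACCGAATTTGTG"
  mature <- file.path(dir, "mature.fa")
  hairpin <- file.path(dir, "hairpin.fa")
  writeLines(c(">rno-mir-A", m1, ">rno-mir-B", m2), mature)
  writeLines(c(">rno-hp-A", hp1, ">rno-hp-B", hp2), hairpin)
  list(mature = mature, hairpin = hairpin,
       m = c("rno-mir-A" = m1, "rno-mir-B" = m2),
       hp = c("rno-hp-A" = hp1, "rno-hp-B" = hp2))
}

# hand-built annotation table (one library) for quantification tests
make_ann <- function(sequence, count, mature_id, category, d5 = 0, d3 = 0,
                     n_mismatch = 0, tier = "primary_species") {
  n <- length(sequence)
  tier_col <- rep(tier, length.out = n)
  tier_col[category == "unannotated"] <- NA
  out <- data.frame(sequence = sequence, count = count, mature_id = mature_id,
                    category = category, d5 = rep(d5, length.out = n),
                    d3 = rep(d3, length.out = n),
                    n_mismatch = rep(n_mismatch, length.out = n),
                    tier = tier_col, stringsAsFactors = FALSE)
  class(out) <- c("mirna_annotation", "data.frame")
  out
}
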