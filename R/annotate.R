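#' Grouping tolerance parameters
#'
#' Defaults follow the grouping rule used throughout: up to 2 mismatches
#' within the overlapping sequence and up to 3 added or deleted nucleotides
#' at each of the 5' and 3' ends (a per-end limit).
#'
#' @param max_mismatch maximum internal mismatches over the read/mature
#'   overlap.
#' @param max_end_offset maximum absolute end offset, per end.
#' @return a list of class `grouping_params`.
#' @export
grouping_params <- function(max_mismatch = 2, max_end_offset = 3) {
  stop_if(max_mismatch < 0 || max_end_offset < 0,
          "tolerances must be non-negative")
  structure(list(max_mismatch = as.integer(max_mismatch),
                 max_end_offset = as.integer(max_end_offset)),
            class = "grouping_params")
}

#' Match one read against one canonical mature
#'
#' Considers every ungapped placement of the read on the mature in which the
#' read's 5' end is offset by `d5` and its 3' end by `d3` (sign convention:
#' positive = the read extends beyond the canonical end; read length =
#' mature length + d5 + d3, so d3 is determined by d5). Mismatches are
#' counted only over positions where read and mature overlap; extension
#' nucleotides are not mismatches here (their templated status is decided
#' later against the hairpin). Among admissible placements the one
#' minimizing `(n_mismatch, |d5| + |d3|)` wins; remaining ties prefer the
#' smaller `|d5|`, then the negative `d5`.
#'
#' @param read read sequence (ACGT).
#' @param mature canonical mature sequence (ACGT).
#' @param params a [grouping_params()] list.
#' @return `NULL` when no admissible placement exists, else a list with
#'   `d5`, `d3`, `n_mismatch` and `category` (`"exact_mature"` or
#'   `"grouped"`).
#' @export
match_read <- function(read, mature, params = grouping_params()) {
  lr <- nchar(read)
  lm <- nchar(mature)
  e <- params$max_end_offset
  best <- NULL
  for (d5 in -e:e) {
    d3 <- lr - lm - d5
    if (abs(d3) > e) next
    o_start <- max(1L, 1L - d5)
    o_end <- min(lm, lm + d3)
    if (o_start > o_end) next
    mm <- hamming(substr(read, o_start + d5, o_end + d5),
                  substr(mature, o_start, o_end))
    if (mm > params$max_mismatch) next
    key <- c(mm, abs(d5) + abs(d3), abs(d5), d5)
    if (is.null(best) || placement_lt(key, best$key))
      best <- list(key = key, d5 = d5, d3 = d3, mm = mm)
  }
  if (is.null(best)) return(NULL)
  list(d5 = as.integer(best$d5), d3 = as.integer(best$d3),
       n_mismatch = as.integer(best$mm),
       category = if (best$mm == 0 && best$d5 == 0 && best$d3 == 0)
         "exact_mature" else "grouped")
}

# lexicographic "strictly better" over placement tie-break keys
placement_lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# best (mm, |d5|+|d3|) match of one read across all matures of one tier;
# candidate matures pre-restricted by the length constraint |lr - lm| <= 2e
match_in_tier <- function(read, db, params) {
  e <- params$max_end_offset
  lr <- nchar(read)
  cand <- which(abs(lr - db$matures$length) <= 2L * e)
  best <- NULL
  for (i in cand) {
    m <- match_read(read, db$matures$sequence[i], params)
    if (is.null(m)) next
    key <- c(m$n_mismatch, abs(m$d5) + abs(m$d3))
    if (is.null(best) || placement_lt(key, best$key) ||
        (all(key == best$key) && db$matures$id[i] < best$mature_id)) {
      best <- c(m, list(key = key, mature_id = db$matures$id[i]))
    }
  }
  best
}

#' Annotate a collapsed library against tiered references
#'
#' Each unique read is matched first against the primary-species tier; only
#' reads with no admissible placement there are tested against the
#' other-species tier (candidate novel orthologs). Each read is assigned to
#' at most one mature: best placement across matures with ties broken by
#' fewest mismatches, then smallest total end offset, then lexicographically
#' smallest mature id, making the assignment independent of input order.
#'
#' @param lib a `mirna_library` (or a data.frame with `sequence`, `count`).
#' @param primary `mirna_reference` for the study species.
#' @param other optional `mirna_reference` of other-species matures.
#' @param params a [grouping_params()].
#' @return data.frame of class `mirna_annotation`: one row per unique read
#'   with columns `sequence`, `count`, `mature_id`, `category`
#'   (`exact_mature` / `grouped` / `unannotated`), `d5`, `d3`, `n_mismatch`,
#'   `tier`.
#' @export
annotate_library <- function(lib, primary, other = NULL,
                             params = grouping_params()) {
  reads <- if (inherits(lib, "mirna_library")) lib$reads else lib
  n <- nrow(reads)
  mature_id <- rep(NA_character_, n)
  category <- rep("unannotated", n)
  d5 <- rep(NA_integer_, n)
  d3 <- rep(NA_integer_, n)
  mm <- rep(NA_integer_, n)
  tier <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    hit <- match_in_tier(reads$sequence[i], primary, params)
    this_tier <- "primary_species"
    if (is.null(hit) && !is.null(other)) {
      hit <- match_in_tier(reads$sequence[i], other, params)
      this_tier <- "other_species"
    }
    if (!is.null(hit)) {
      mature_id[i] <- hit$mature_id
      category[i] <- hit$category
      d5[i] <- hit$d5
      d3[i] <- hit$d3
      mm[i] <- hit$n_mismatch
      tier[i] <- this_tier
    }
  }
  out <- data.frame(sequence = reads$sequence, count = reads$count,
                    mature_id = mature_id, category = category,
                    d5 = d5, d3 = d3, n_mismatch = mm, tier = tier,
                    stringsAsFactors = FALSE)
  class(out) <- c("mirna_annotation", "data.frame")
  out
}

#' Per-length annotation tier summary
#'
#' Count-weighted reads per read length in each annotation class
#' (primary-species, other-species/novel-ortholog, unannotated) with
#' fractions summing to 1 per length, the accounting behind a stacked
#' length-distribution barplot.
#'
#' @param ann a `mirna_annotation` (or rbind of several).
#' @return data.frame with columns `length`, `primary_species`,
#'   `other_species`, `unannotated`, and the three `frac_*` columns.
#' @export
annotation_summary <- function(ann) {
  stop_if(nrow(ann) == 0, "no annotation results")
  len <- nchar(ann$sequence)
  cls <- ifelse(ann$category == "unannotated", "unannotated", ann$tier)
  lv <- sort(unique(len))
  out <- data.frame(length = lv)
  for (k in c("primary_species", "other_species", "unannotated")) {
    w <- rowsum(ann$count * (cls == k), group = len)
    out[[k]] <- as.integer(w[match(lv, as.integer(rownames(w))), 1])
  }
  tot <- out$primary_species + out$other_species + out$unannotated
  out$frac_primary <- out$primary_species / tot
  out$frac_other <- out$other_species / tot
  out$frac_unannotated <- out$unannotated / tot
  out
}
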