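#' Classify a grouped read relative to its mature and hairpin
#'
#' Decides, for each extended end, whether the extension nucleotides match
#' the flanking hairpin sequence (templated) or not. On the 3' end the
#' maximal disagreeing suffix of the extension is the non-templated tail
#' (`nta`); a templated nucleotide 3' of a non-templated one counts as
#' non-templated (tails are added post-transcriptionally, so everything
#' beyond the first non-templated position is treated as tail). Internal
#' substitutions are reported in 1-based mature coordinates. The taxonomy
#' code is assembled as: `M` exact; `Sub`/`Sup` for truncation/extension per
#' end (`Sub/Sup` when both occur); `P` when both ends deviate with every
#' extension nucleotide templated (a shifted precursor window); `V` appended
#' when any non-templated or substituted nucleotide exists; `*` inserted
#' after the leading letter for star-strand matures. The code is a derived
#' label; `(d5, d3, templating, subs)` are the ground truth.
#'
#' @param read read sequence.
#' @param mature_id id of the assigned mature.
#' @param d5,d3 signed end offsets from grouping.
#' @param db the `mirna_reference` containing the mature.
#' @return list with `mature_id`, `d5`, `d3`, `five_templated`,
#'   `three_templated` (NA when the mature has no hairpin placement),
#'   `nta`, `internal_subs` (data.frame `position`, `ref`, `alt`), `code`.
#' @export
classify_read <- function(read, mature_id, d5, d3, db) {
  i <- match(mature_id, db$matures$id)
  stop_if(is.na(i), "unknown mature id: ", mature_id)
  mature <- db$matures$sequence[i]
  lm <- nchar(mature)
  lr <- nchar(read)
  stop_if(lr != lm + d5 + d3, "inconsistent grouping offsets for ", mature_id)
  pl <- placement_of(db, mature_id)

  five_templated <- TRUE
  three_templated <- TRUE
  nta <- ""
  if (d5 > 0) {
    if (is.null(pl)) {
      five_templated <- NA
    } else {
      # mature 1-based hairpin position of its first nt is pl$start + 1;
      # extension nt i (i = 1..d5) aligns to hairpin position pl$start - d5 + i
      ok <- vapply(seq_len(d5), function(k) {
        hpos <- pl$start - d5 + k
        hpos >= 1 && substr(pl$hairpin, hpos, hpos) == substr(read, k, k)
      }, logical(1))
      five_templated <- all(ok)
    }
  }
  if (d3 > 0) {
    ext <- substr(read, lr - d3 + 1, lr)
    if (is.null(pl)) {
      three_templated <- NA
      nta <- NA_character_
    } else {
      ok <- vapply(seq_len(d3), function(k) {
        hpos <- pl$end + k
        hpos <= nchar(pl$hairpin) &&
          substr(pl$hairpin, hpos, hpos) == substr(ext, k, k)
      }, logical(1))
      bad <- which(!ok)
      if (length(bad) > 0) nta <- substr(ext, bad[1], d3)
      three_templated <- length(bad) == 0
    }
  }

  o_start <- max(1L, 1L - d5)
  o_end <- min(lm, lm + d3)
  rpos <- (o_start:o_end) + d5
  rv <- strsplit(substr(read, rpos[1], rpos[length(rpos)]), "")[[1]]
  mv <- strsplit(substr(mature, o_start, o_end), "")[[1]]
  diffpos <- which(rv != mv)
  internal_subs <- data.frame(position = o_start - 1L + diffpos,
                              ref = mv[diffpos], alt = rv[diffpos],
                              stringsAsFactors = FALSE)

  has_variant <- nrow(internal_subs) > 0 ||
    (!is.na(nta) && nzchar(nta)) || identical(five_templated, FALSE)
  shifted <- d5 != 0 && d3 != 0 &&
    !identical(five_templated, FALSE) && !identical(three_templated, FALSE) &&
    !is.na(five_templated) && !is.na(three_templated)
  if (d5 == 0 && d3 == 0) {
    code <- "M"
  } else if (shifted && !has_variant) {
    code <- "P"
  } else if (shifted && nrow(internal_subs) > 0 &&
             !(!is.na(nta) && nzchar(nta)) &&
             !identical(five_templated, FALSE)) {
    # shifted window whose only variation is internal substitution(s)
    code <- "PV"
  } else {
    sub_end <- d5 < 0 || d3 < 0
    sup_end <- d5 > 0 || d3 > 0
    part <- if (sub_end && sup_end) "Sub/Sup" else if (sub_end) "Sub" else "Sup"
    code <- paste0("M", part, if (has_variant) "V")
  }
  if (db$matures$is_star[i]) code <- sub("^(.)", "\\1*", code)

  list(mature_id = mature_id, d5 = as.integer(d5), d3 = as.integer(d3),
       five_templated = five_templated, three_templated = three_templated,
       nta = nta, internal_subs = internal_subs, code = code)
}

#' Classify every annotated read of a library
#'
#' Applies [classify_read()] to each annotated row of a `mirna_annotation`,
#' adding the taxonomy columns; unannotated rows receive NA.
#'
#' @param ann a `mirna_annotation` data.frame.
#' @param primary,other the references used during annotation (`other` may
#'   be `NULL` when no other-species tier was searched).
#' @return `ann` with added columns `five_templated`, `three_templated`,
#'   `nta`, `internal_subs` (semicolon-joined `pos:ref>alt`), `code`.
#' @export
classify_annotations <- function(ann, primary, other = NULL) {
  n <- nrow(ann)
  ft <- rep(NA, n)
  tt <- rep(NA, n)
  nta <- rep(NA_character_, n)
  subs <- rep(NA_character_, n)
  code <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (ann$category[i] == "unannotated") next
    db <- if (identical(ann$tier[i], "other_species") && !is.null(other))
      other else primary
    cl <- classify_read(ann$sequence[i], ann$mature_id[i],
                        ann$d5[i], ann$d3[i], db)
    ft[i] <- cl$five_templated
    tt[i] <- cl$three_templated
    nta[i] <- cl$nta
    subs[i] <- if (nrow(cl$internal_subs) == 0) "" else
      paste(sprintf("%d:%s>%s", cl$internal_subs$position,
                    cl$internal_subs$ref, cl$internal_subs$alt),
            collapse = ";")
    code[i] <- cl$code
  }
  ann$five_templated <- ft
  ann$three_templated <- tt
  ann$nta <- nta
  ann$internal_subs <- subs
  ann$code <- code
  ann
}

#' Count-weighted consensus of the reads grouped on one mature
#'
#' Reads are anchored to mature coordinates via their (d5, d3) offsets; at
#' each position of the union span the count-weighted most frequent
#' nucleotide is taken, with ties broken in favour of the canonical
#' (mature, or flanking-hairpin) nucleotide. Positions 5' of the canonical
#' start carry indices <= 0.
#'
#' @param ann annotation rows (with counts) for a single mature.
#' @param db the `mirna_reference`.
#' @return list of class `isomir_consensus`: `mature_id`, `positions`,
#'   `profile` (4 x positions count matrix), `consensus` string,
#'   `canonical` string over the same span (`.` where no template exists).
#' @export
consensus_sequence <- function(ann, db) {
  ann <- ann[ann$category != "unannotated", , drop = FALSE]
  stop_if(nrow(ann) == 0, "no grouped reads to build a consensus from")
  mid <- unique(ann$mature_id)
  stop_if(length(mid) != 1, "reads from several matures: ",
          paste(mid, collapse = ", "))
  mature <- db$matures$sequence[match(mid, db$matures$id)]
  lm <- nchar(mature)
  pl <- placement_of(db, mid)
  lo <- min(1L - ann$d5)
  hi <- max(lm + ann$d3)
  pos <- lo:hi
  nts <- c("A", "C", "G", "T")
  prof <- matrix(0, nrow = 4, ncol = length(pos),
                 dimnames = list(nts, pos))
  for (i in seq_len(nrow(ann))) {
    chars <- strsplit(ann$sequence[i], "")[[1]]
    p <- (1L - ann$d5[i]):(lm + ann$d3[i])
    j <- match(p, pos)
    for (k in seq_along(chars))
      prof[chars[k], j[k]] <- prof[chars[k], j[k]] + ann$count[i]
  }
  template <- vapply(pos, function(p) {
    if (p >= 1 && p <= lm) return(substr(mature, p, p))
    if (!is.null(pl)) {
      hpos <- pl$start + p   # mature pos p sits at hairpin 1-based start + p
      if (hpos >= 1 && hpos <= nchar(pl$hairpin))
        return(substr(pl$hairpin, hpos, hpos))
    }
    "."
  }, character(1))
  cons <- vapply(seq_along(pos), function(j) {
    col <- prof[, j]
    top <- nts[col == max(col)]
    if (template[j] %in% top) template[j] else top[1]
  }, character(1))
  structure(list(mature_id = mid, positions = pos, profile = prof,
                 consensus = paste(cons, collapse = ""),
                 canonical = paste(template, collapse = "")),
            class = "isomir_consensus")
}

#' @export
print.isomir_consensus <- function(x, ...) {
  cat("consensus for ", x$mature_id, " [positions ", min(x$positions), "..",
      max(x$positions), "]\n", sep = "")
  cat("  template:  ", x$canonical, "\n", sep = "")
  cat("  consensus: ", x$consensus, "\n", sep = "")
  invisible(x)
}

#' End-variant distribution by hairpin arm
#'
#' Count-weighted fractions of grouped reads that are canonical, shorter or
#' longer at the 5' and 3' ends, split by the arm (5p/3p) the assigned
#' mature derives from. The three fractions sum to 1 within each
#' (arm, end) cell.
#'
#' @param ann a `mirna_annotation` (classification columns not required).
#' @param db reference used to resolve arms (primary tier).
#' @param weighting `"count"` (per-read, default) or `"unique"` (each unique
#'   sequence weighted once).
#' @return data.frame with columns `arm`, `end`, `canonical`, `shorter`,
#'   `longer`.
#' @export
end_variant_distribution <- function(ann, db, weighting = c("count", "unique")) {
  weighting <- match.arg(weighting)
  ann <- ann[ann$category != "unannotated", , drop = FALSE]
  stop_if(nrow(ann) == 0, "no annotated reads")
  w <- if (weighting == "count") ann$count else rep(1L, nrow(ann))
  arm <- arm_of(db, ann$mature_id)
  out <- expand.grid(arm = c("5p", "3p"), end = c("5p", "3p"),
                     stringsAsFactors = FALSE)
  names(out) <- c("arm", "end")
  cell <- function(a, d) {
    sel <- arm == a
    tot <- sum(w[sel])
    if (tot == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(sum(w[sel & d == 0]), sum(w[sel & d < 0]), sum(w[sel & d > 0])) / tot
  }
  vals <- t(vapply(seq_len(nrow(out)), function(i) {
    d <- if (out$end[i] == "5p") ann$d5 else ann$d3
    cell(out$arm[i], d)
  }, numeric(3)))
  out$canonical <- vals[, 1]
  out$shorter <- vals[, 2]
  out$longer <- vals[, 3]
  out
}

#' Seed region of a miRNA sequence
#'
#' Nucleotides 2-8 (1-based, inclusive), the region dominant in target
#' recognition; 5' isomiRs shift it.
#'
#' @param seq sequence(s) of length >= 8 nt.
#' @return 7-nt seed string(s).
#' @export
seed_of <- function(seq) {
  stop_if(any(nchar(seq) < 8), "sequence shorter than 8 nt has no seed")
  substr(seq, 2, 8)
}

#' Per-position substitution report for one mature
#'
#' For every mature position, the count-weighted fraction of covering reads
#' carrying each non-canonical nucleotide; positions where an alternative
#' reaches `threshold` are flagged as candidate paralog/editing sites.
#'
#' @param ann annotation rows (with counts) for a single mature.
#' @param db the `mirna_reference`.
#' @param threshold flagging fraction (default 0.2).
#' @return data.frame with columns `position`, `ref`, `alt`, `fraction`,
#'   `flagged` (one row per observed alternative; empty when no reads vary).
#' @export
variant_position_report <- function(ann, db, threshold = 0.2) {
  ann <- ann[ann$category != "unannotated", , drop = FALSE]
  stop_if(nrow(ann) == 0, "no grouped reads")
  mid <- unique(ann$mature_id)
  stop_if(length(mid) != 1, "reads from several matures")
  mature <- db$matures$sequence[match(mid, db$matures$id)]
  lm <- nchar(mature)
  nts <- c("A", "C", "G", "T")
  counts <- matrix(0, nrow = 4, ncol = lm, dimnames = list(nts, NULL))
  for (i in seq_len(nrow(ann))) {
    o_start <- max(1L, 1L - ann$d5[i])
    o_end <- min(lm, lm + ann$d3[i])
    chars <- strsplit(substr(ann$sequence[i], o_start + ann$d5[i],
                             o_end + ann$d5[i]), "")[[1]]
    p <- o_start:o_end
    for (k in seq_along(p))
      counts[chars[k], p[k]] <- counts[chars[k], p[k]] + ann$count[i]
  }
  rows <- list()
  for (p in seq_len(lm)) {
    tot <- sum(counts[, p])
    if (tot == 0) next
    ref <- substr(mature, p, p)
    for (a in setdiff(nts, ref)) {
      if (counts[a, p] == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        position = p, ref = ref, alt = a,
        fraction = counts[a, p] / tot, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0)
    data.frame(position = integer(), ref = character(), alt = character(),
               fraction = numeric(), stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  out$flagged <- out$fraction >= threshold
  out
}
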