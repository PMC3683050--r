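#' Load a miRBase-style reference of mature and hairpin sequences
#'
#' Reads a mature-miRNA FASTA and a hairpin (pre-miR) FASTA, normalizes
#' sequences to the DNA alphabet (U to T, uppercase), and places every mature
#' inside its hairpin by exact substring search. Matures found in several
#' hairpins receive one placement per hairpin (multi-gene families such as
#' "mir-138-2//mir-138-1" are one mature with multiple placements); a mature
#' occurring twice within one hairpin is placed at its leftmost occurrence
#' with a warning. Matures with no hairpin hit are retained but flagged
#' unplaced.
#'
#' @param mature_path path to the mature FASTA.
#' @param hairpin_path path to the hairpin FASTA.
#' @param tier annotation tier label, `"primary_species"` (the study species)
#'   or `"other_species"` (candidate novel orthologs).
#' @param star_annotations optional data.frame with columns `mature_id` and
#'   `star_flag` overriding the default star detection from a trailing `*`
#'   in the id.
#' @return an object of class `mirna_reference` with components
#'   `matures` (data.frame: id, species_prefix, sequence, length, is_star,
#'   placed, arm), `hairpins` (named character vector),
#'   `placements` (data.frame: mature_id, hairpin_id, start, end, arm;
#'   0-based half-open coordinates) and `tier`.
#' @export
load_reference <- function(mature_path, hairpin_path,
                           tier = c("primary_species", "other_species"),
                           star_annotations = NULL) {
  tier <- match.arg(tier)
  mat <- read_fasta_named(mature_path)
  hp <- read_fasta_named(hairpin_path)
  stop_if(length(mat) == 0, "empty mature FASTA: ", mature_path)
  stop_if(length(hp) == 0, "empty hairpin FASTA: ", hairpin_path)
  stop_if(anyDuplicated(names(mat)) > 0,
          "duplicate mature id(s): ",
          paste(unique(names(mat)[duplicated(names(mat))]), collapse = ", "))
  if (anyDuplicated(names(hp)) > 0)
    stop("duplicate hairpin id(s) in ", hairpin_path, call. = FALSE)
  bad_len <- nchar(mat) < 15 | nchar(mat) > 30
  stop_if(any(bad_len), "mature sequence length outside [15, 30]: ",
          paste(names(mat)[bad_len], collapse = ", "))
  bad_nt <- grepl("[^ACGT]", mat)
  stop_if(any(bad_nt), "non-ACGT characters after normalization in: ",
          paste(names(mat)[bad_nt], collapse = ", "))

  ref <- build_reference(mat, hp, tier, star_annotations)
  ref
}

# shared constructor used by load_reference and the simulator
build_reference <- function(mat, hp, tier, star_annotations = NULL) {
  is_star <- grepl("\\*$", names(mat))
  if (!is.null(star_annotations)) {
    idx <- match(names(mat), star_annotations$mature_id)
    hit <- !is.na(idx)
    is_star[hit] <- as.logical(star_annotations$star_flag[idx[hit]])
  }
  sp <- ifelse(grepl("^[a-z]{3}-", names(mat)),
               substr(names(mat), 1, 3), NA_character_)

  pl <- vector("list", length(mat))
  for (i in seq_along(mat)) {
    hits <- lapply(seq_along(hp), function(j) {
      occ <- gregexpr(mat[[i]], hp[[j]], fixed = TRUE)[[1]]
      if (occ[1] == -1) return(NULL)
      if (length(occ) > 1)
        warning("mature ", names(mat)[i], " occurs ", length(occ),
                " times in hairpin ", names(hp)[j],
                "; using leftmost occurrence", call. = FALSE)
      data.frame(mature_id = names(mat)[i], hairpin_id = names(hp)[j],
                 start = occ[1] - 1L,
                 end = occ[1] - 1L + nchar(mat[[i]]),
                 stringsAsFactors = FALSE)
    })
    pl[[i]] <- do.call(rbind, hits)
  }
  placements <- do.call(rbind, pl)
  if (is.null(placements))
    placements <- data.frame(mature_id = character(), hairpin_id = character(),
                             start = integer(), end = integer(),
                             stringsAsFactors = FALSE)
  hp_len <- nchar(hp)[placements$hairpin_id]
  placements$arm <- ifelse((placements$start + placements$end) / 2 <
                             hp_len / 2, "5p", "3p")

  first <- match(names(mat), placements$mature_id)
  matures <- data.frame(
    id = names(mat),
    species_prefix = sp,
    sequence = unname(mat),
    length = nchar(unname(mat)),
    is_star = is_star,
    placed = !is.na(first),
    arm = ifelse(is.na(first), "unknown", placements$arm[first]),
    stringsAsFactors = FALSE
  )
  structure(list(matures = matures, hairpins = hp,
                 placements = placements, tier = tier),
            class = "mirna_reference")
}

# FASTA in via Biostrings; BStringSet tolerates U/lowercase before we normalize
read_fasta_named <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- normalize_seq(as.character(x))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Arm of a mature miRNA on its hairpin
#'
#' `"5p"` when the placement midpoint falls in the first half of the hairpin,
#' `"3p"` otherwise, `"unknown"` for matures with no hairpin placement. For
#' matures placed in multiple hairpins the first placement decides.
#'
#' @param db a `mirna_reference`.
#' @param mature_id mature id(s).
#' @return character vector of arm labels.
#' @export
arm_of <- function(db, mature_id) {
  idx <- match(mature_id, db$matures$id)
  stop_if(anyNA(idx), "unknown mature id(s): ",
          paste(mature_id[is.na(idx)], collapse = ", "))
  db$matures$arm[idx]
}

# first placement (with hairpin sequence) for a mature, or NULL if unplaced
placement_of <- function(db, mature_id) {
  i <- match(mature_id, db$placements$mature_id)
  if (is.na(i)) return(NULL)
  p <- db$placements[i, ]
  list(hairpin_id = p$hairpin_id, start = p$start, end = p$end,
       arm = p$arm, hairpin = db$hairpins[[p$hairpin_id]])
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat("miRNA reference (", x$tier, ")\n", sep = "")
  cat("  matures:  ", nrow(x$matures),
      " (", sum(x$matures$is_star), " star, ",
      sum(!x$matures$placed), " unplaced)\n", sep = "")
  cat("  hairpins: ", length(x$hairpins), "\n", sep = "")
  invisible(x)
}

#' Write a reference back to a mature/hairpin FASTA pair
#'
#' @param db a `mirna_reference`.
#' @param mature_path,hairpin_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference_fasta <- function(db, mature_path, hairpin_path) {
  write_fasta(stats::setNames(db$matures$sequence, db$matures$id), mature_path)
  write_fasta(db$hairpins, hairpin_path)
  invisible(c(mature_path, hairpin_path))
}

write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con)
}

#' Summarize a reference as a table
#'
#' One row per placement plus one per unplaced mature: mature id, hairpin id,
#' 0-based half-open coordinates, arm, tier and star status.
#'
#' @param db a `mirna_reference`.
#' @param path optional TSV output path.
#' @return the summary data.frame, invisibly when `path` is given.
#' @export
reference_summary <- function(db, path = NULL) {
  pl <- db$placements
  unplaced <- db$matures[!db$matures$placed, , drop = FALSE]
  out <- rbind(
    data.frame(mature_id = pl$mature_id, hairpin_id = pl$hairpin_id,
               start = pl$start, end = pl$end, arm = pl$arm,
               stringsAsFactors = FALSE),
    if (nrow(unplaced) > 0)
      data.frame(mature_id = unplaced$id, hairpin_id = NA_character_,
                 start = NA_integer_, end = NA_integer_, arm = "unknown",
                 stringsAsFactors = FALSE)
  )
  out$tier <- db$tier
  out$star <- db$matures$is_star[match(out$mature_id, db$matures$id)]
  if (!is.null(path)) {
    write_tsv(out, path)
    return(invisible(out))
  }
  out
}
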