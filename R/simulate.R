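#' Simulation parameters for synthetic small-RNA libraries
#'
#' Defaults emulate the qualitative structure of real cardiac small-RNA
#' libraries: most variability at the 3' end (canonical 3' end only 40% of
#' reads), little at the 5' end (90% canonical), occasional non-templated
#' A/T tails, log-normal abundance across miRNAs, and per-condition
#' abundance gradients for selected miRNAs. All probabilities are
#' repository defaults chosen to match those shapes, not estimates from any
#' particular dataset.
#'
#' @param mature_length simulated mature length (point mass).
#' @param abundance_meanlog,abundance_sdlog log-normal abundance model
#'   across miRNAs.
#' @param star_scale multiplier on star-strand abundance.
#' @param d5_probs named probability vector over 5' end offsets
#'   (names are signed offsets).
#' @param d3_probs named probability vector over templated 3' end offsets.
#' @param nta_prob probability that a read with non-negative templated 3'
#'   offset receives a non-templated tail.
#' @param nta_continuation per-nucleotide tail continuation probability.
#' @param nta_letters sampling weights for tail nucleotides (A-rich, some U).
#' @param internal_subs list of planted substitutions, each a list with
#'   `mature_id`, `position` (1-based on the mature), `alt`, `fraction`.
#' @param error_rate per-nucleotide sequencing substitution rate.
#' @param gradient named numeric vector: per-miRNA abundance multiplier
#'   applied in `gradient_condition`.
#' @param conditions the two condition labels.
#' @param gradient_condition condition receiving the gradient multiplier.
#' @param libraries_per_condition replicate libraries per condition.
#' @param depth reads per library.
#' @param adapter optional 3' adapter appended to every read.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(mature_length = 22,
                       abundance_meanlog = 0, abundance_sdlog = 1.5,
                       star_scale = 0.05,
                       d5_probs = c("-2" = 0.01, "-1" = 0.04, "0" = 0.90,
                                    "1" = 0.04, "2" = 0.01),
                       d3_probs = c("-3" = 0.04, "-2" = 0.09, "-1" = 0.17,
                                    "0" = 0.40, "1" = 0.17, "2" = 0.09,
                                    "3" = 0.04),
                       nta_prob = 0.15, nta_continuation = 0.3,
                       nta_letters = c(A = 0.6, T = 0.4),
                       internal_subs = list(),
                       error_rate = 0,
                       gradient = c(),
                       conditions = c("epicardium", "endocardium"),
                       gradient_condition = "endocardium",
                       libraries_per_condition = 3,
                       depth = 50000,
                       adapter = NULL) {
  stop_if(abs(sum(d5_probs) - 1) > 1e-8, "d5_probs must sum to 1")
  stop_if(abs(sum(d3_probs) - 1) > 1e-8, "d3_probs must sum to 1")
  stop_if(any(c(nta_prob, nta_continuation, error_rate) < 0) ||
            any(c(nta_prob, nta_continuation, error_rate) > 1),
          "probabilities must lie in [0, 1]")
  stop_if(depth <= 0, "depth must be positive")
  structure(list(mature_length = mature_length,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 star_scale = star_scale,
                 d5_probs = d5_probs, d3_probs = d3_probs,
                 nta_prob = nta_prob, nta_continuation = nta_continuation,
                 nta_letters = nta_letters,
                 internal_subs = internal_subs,
                 error_rate = error_rate, gradient = gradient,
                 conditions = conditions,
                 gradient_condition = gradient_condition,
                 libraries_per_condition = libraries_per_condition,
                 depth = depth, adapter = adapter),
            class = "sim_params")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Simulate a miRNA reference
#'
#' Random hairpins with embedded matures: some carry a 5p mature only, some
#' a 3p mature only, some both arms with the minor arm annotated as the star
#' strand. `plant_fixtures = TRUE` additionally plants a gene pair with a
#' 5p mature and a 3p star, and a paralog pair whose matures differ at
#' exactly position 17 (G versus A), mimicking near-identical miRNA family
#' members. Byte-for-byte reproducible under `seed`.
#'
#' @param n_hairpins number of random hairpins.
#' @param hairpin_length hairpin length (nt).
#' @param mature_length mature length (nt); must fit twice in the hairpin
#'   with 3-nt flanks.
#' @param seed RNG seed.
#' @param plant_fixtures add the fixed fixture genes described above.
#' @return a `mirna_reference` (tier `"primary_species"`).
#' @export
simulate_reference <- function(n_hairpins = 20, hairpin_length = 80,
                               mature_length = 22, seed = 1,
                               plant_fixtures = FALSE) {
  stop_if(n_hairpins < 1, "need at least one hairpin")
  stop_if(2 * mature_length + 4 * 3 > hairpin_length,
          "mature too long for hairpin")
  set.seed(seed)
  hp <- character(0)
  mat <- character(0)
  ml <- mature_length
  start5 <- 3L                      # 0-based; 3-nt 5' flank
  start3 <- hairpin_length - 3L - ml
  for (i in seq_len(n_hairpins)) {
    repeat {
      h <- rand_seq(hairpin_length)
      m5 <- substr(h, start5 + 1, start5 + ml)
      m3 <- substr(h, start3 + 1, start3 + ml)
      if (!m5 %in% mat && !m3 %in% mat && m5 != m3) break
    }
    scheme <- sample(c("5p", "3p", "both"), 1, prob = c(0.4, 0.3, 0.3))
    id <- sprintf("sim-mir-%d", i)
    hp[sprintf("sim-hp-%d", i)] <- h
    if (scheme == "5p") {
      mat[id] <- m5
    } else if (scheme == "3p") {
      mat[id] <- m3
    } else {
      major_arm <- sample(c("5p", "3p"), 1)
      mat[id] <- if (major_arm == "5p") m5 else m3
      mat[paste0(id, "*")] <- if (major_arm == "5p") m3 else m5
    }
  }
  if (plant_fixtures) {
    # 5p mature / 3p star gene
    repeat {
      h <- rand_seq(hairpin_length)
      m5 <- substr(h, start5 + 1, start5 + ml)
      m3 <- substr(h, start3 + 1, start3 + ml)
      if (!m5 %in% mat && !m3 %in% mat && m5 != m3) break
    }
    hp["sim-hp-fix486"] <- h
    mat["sim-mir-fix486"] <- m5
    mat["sim-mir-fix486*"] <- m3
    # paralog pair differing only at mature position 17 (G vs A)
    repeat {
      h1 <- rand_seq(hairpin_length)
      m1 <- substr(h1, start5 + 1, start5 + ml)
      substr(m1, 17, 17) <- "G"
      substr(h1, start5 + 17, start5 + 17) <- "G"
      m2 <- m1
      substr(m2, 17, 17) <- "A"
      h2 <- h1
      substr(h2, start5 + 17, start5 + 17) <- "A"
      if (!m1 %in% mat && !m2 %in% mat) break
    }
    hp["sim-hp-fix1a"] <- h1
    hp["sim-hp-fix1b"] <- h2
    mat["sim-mir-fix1a"] <- m1
    mat["sim-mir-fix1b"] <- m2
  }
  build_reference(mat, hp, tier = "primary_species")
}

#' Simulate one small-RNA library with its truth table
#'
#' Reads are drawn miRNA by miRNA from the abundance model (scaled by the
#' condition gradient), then each read applies a sampled 5' offset
#' (templated from the hairpin flank), a templated 3' offset, an optional
#' non-templated tail whose first nucleotide is forced to disagree with the
#' hairpin flank, planted internal substitutions, and per-nucleotide
#' sequencing error; an adapter is appended if configured. Offsets are
#' constrained so every error-free read is recoverable by the default
#' grouping tolerances (total 3' deviation at most 3 per end).
#'
#' @param ref a `mirna_reference` from [simulate_reference()].
#' @param params a [sim_params()].
#' @param condition condition label for this library.
#' @param library_id library id recorded in the truth table.
#' @param seed RNG seed.
#' @param abundance optional named abundance vector (one entry per mature);
#'   drawn from the log-normal model under `seed` when omitted. Supply the
#'   same vector to every library so that only the gradient differs between
#'   conditions.
#' @return list with `reads` (character vector, adapter included if
#'   configured), `library` (a `mirna_library` of the adapter-free reads)
#'   and `truth` (data.frame: sequence, library, condition, mature_id, d5,
#'   d3, nta, subs, has_error).
#' @export
simulate_library <- function(ref, params, condition, library_id,
                             seed = 1, abundance = NULL) {
  stop_if(nrow(ref$matures) == 0, "empty reference")
  set.seed(seed)
  if (is.null(abundance)) abundance <- draw_abundance(ref, params)
  ab <- abundance
  if (condition == params$gradient_condition && length(params$gradient) > 0) {
    g <- params$gradient
    ab[names(g)] <- ab[names(g)] * g
  }
  ids <- ref$matures$id
  n <- params$depth
  mi <- sample(seq_along(ids), n, replace = TRUE, prob = ab[ids])

  # per-mature extended template: 3-nt flanks around the mature (or fewer
  # when the placement sits near a hairpin edge)
  e <- 3L
  tmpl <- flank5 <- integer(length(ids))
  templates <- character(length(ids))
  for (j in seq_along(ids)) {
    pl <- placement_of(ref, ids[j])
    stop_if(is.null(pl), "simulate_library needs placed matures: ", ids[j])
    f5 <- min(e, pl$start)
    f3 <- min(e, nchar(pl$hairpin) - pl$end)
    templates[j] <- substr(pl$hairpin, pl$start - f5 + 1, pl$end + f3)
    flank5[j] <- f5
  }
  lm <- ref$matures$length

  d5 <- as.integer(sample(names(params$d5_probs), n, replace = TRUE,
                          prob = params$d5_probs))
  t3 <- as.integer(sample(names(params$d3_probs), n, replace = TRUE,
                          prob = params$d3_probs))
  # clamp extensions to the available flank; truncations to half the mature
  d5 <- pmax(pmin(d5, flank5[mi]), -(lm[mi] %/% 2L))
  t3 <- pmin(t3, e)

  tail_len <- integer(n)
  tailed <- t3 >= 0 & stats::runif(n) < params$nta_prob
  room <- e - t3
  tail_len[tailed] <- pmin(1L + stats::rgeom(sum(tailed),
                                             1 - params$nta_continuation),
                           room[tailed])

  core <- substr(templates[mi], flank5[mi] + 1L - d5,
                 flank5[mi] + lm[mi] + t3)
  nta <- character(n)
  letters_pool <- names(params$nta_letters)
  for (i in which(tail_len > 0)) {
    tl <- tail_len[i]
    tail_nt <- sample(letters_pool, tl, replace = TRUE,
                      prob = params$nta_letters)
    # first tail nt must disagree with the templated hairpin position so the
    # tail is detectable as non-templated
    hpos <- flank5[mi[i]] + lm[mi[i]] + t3[i] + 1L
    hnt <- substr(templates[mi[i]], hpos, hpos)
    if (nzchar(hnt) && tail_nt[1] == hnt) {
      alt <- setdiff(letters_pool, hnt)
      tail_nt[1] <- if (length(alt) > 0) alt[1] else
        setdiff(c("A", "C", "G", "T"), hnt)[1]
    }
    nta[i] <- paste(tail_nt, collapse = "")
  }
  reads <- paste0(core, nta)
  d3 <- t3 + tail_len

  subs <- character(n)
  for (sp in params$internal_subs) {
    j <- match(sp$mature_id, ids)
    if (is.na(j)) next
    ref_nt <- substr(ref$matures$sequence[j], sp$position, sp$position)
    stop_if(ref_nt == sp$alt, "planted alt equals the canonical nucleotide")
    covered <- mi == j & sp$position >= 1 - d5 &
      sp$position <= lm[j] + pmin(t3, 0L)
    hit <- covered & stats::runif(n) < sp$fraction
    idx <- sp$position + d5[hit]
    substr(reads[hit], idx, idx) <- sp$alt
    lab <- sprintf("%d:%s>%s", sp$position, ref_nt, sp$alt)
    subs[hit] <- ifelse(nzchar(subs[hit]), paste(subs[hit], lab, sep = ";"),
                        lab)
  }

  has_error <- rep(FALSE, n)
  if (params$error_rate > 0) {
    nerr <- stats::rbinom(n, nchar(reads), params$error_rate)
    for (i in which(nerr > 0)) {
      pos <- sample.int(nchar(reads[i]), nerr[i])
      for (p in pos) {
        old <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
      has_error[i] <- TRUE
    }
  }

  truth <- data.frame(sequence = reads, library = library_id,
                      condition = condition,
                      mature_id = ids[mi], d5 = d5, d3 = d3,
                      nta = nta, subs = subs, has_error = has_error,
                      stringsAsFactors = FALSE)
  out_reads <- if (!is.null(params$adapter))
    paste0(reads, normalize_seq(params$adapter)) else reads
  lib <- new_library(library_id, condition, collapse_reads(reads), n)
  list(reads = out_reads, library = lib, truth = truth)
}

# log-normal abundance across matures, stars downscaled
draw_abundance <- function(ref, params) {
  ab <- stats::rlnorm(nrow(ref$matures), params$abundance_meanlog,
                      params$abundance_sdlog)
  ab[ref$matures$is_star] <- ab[ref$matures$is_star] * params$star_scale
  stats::setNames(ab, ref$matures$id)
}

#' Simulate a full two-condition experiment
#'
#' Draws one abundance vector for the whole experiment, then one library per
#' replicate and condition with seeds derived from `seed`, so the only
#' systematic difference between conditions is the configured gradient.
#'
#' @param ref a `mirna_reference`.
#' @param params a [sim_params()].
#' @param seed master seed.
#' @return list with `libraries` (list of `mirna_library`), `reads` (list of
#'   raw read vectors), `truth` (combined truth table), `sample_sheet`
#'   (data.frame: library_id, condition), `abundance`.
#' @export
simulate_experiment <- function(ref, params, seed = 1) {
  set.seed(seed)
  abundance <- draw_abundance(ref, params)
  sheet <- expand.grid(rep = seq_len(params$libraries_per_condition),
                       condition = params$conditions,
                       stringsAsFactors = FALSE)
  sheet$library_id <- sprintf("%s_%d", sheet$condition, sheet$rep)
  libseeds <- sample.int(.Machine$integer.max - 1L, nrow(sheet))
  libs <- reads <- vector("list", nrow(sheet))
  truth <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    sim <- simulate_library(ref, params, sheet$condition[i],
                            sheet$library_id[i], seed = libseeds[i],
                            abundance = abundance)
    libs[[i]] <- sim$library
    reads[[i]] <- sim$reads
    truth[[i]] <- sim$truth
  }
  names(libs) <- names(reads) <- sheet$library_id
  list(libraries = libs, reads = reads, truth = do.call(rbind, truth),
       sample_sheet = sheet[, c("library_id", "condition")],
       abundance = abundance)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the reference FASTA pair, one FASTQ per library (constant high
#' quality; quality is unused downstream), a sample sheet TSV, the truth
#' table TSV, and copies of the in-package printed report tables used by
#' round-trip tests. Two calls with the same seed produce identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param ref optional reference; simulated under `seed` when omitted.
#' @param params a [sim_params()].
#' @param seed master seed.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(out_dir, ref = NULL, params = sim_params(),
                           seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(ref))
    ref <- simulate_reference(seed = seed,
                              mature_length = params$mature_length)
  paths <- c(mature = file.path(out_dir, "mature.fa"),
             hairpin = file.path(out_dir, "hairpin.fa"))
  write_reference_fasta(ref, paths["mature"], paths["hairpin"])
  exp <- simulate_experiment(ref, params, seed = seed)
  for (lid in names(exp$reads)) {
    p <- file.path(out_dir, paste0(lid, ".fastq"))
    write_fastq(exp$reads[[lid]], lid, p)
    paths[lid] <- p
  }
  paths["sample_sheet"] <- file.path(out_dir, "sample_sheet.tsv")
  sheet <- exp$sample_sheet
  sheet$path <- paste0(sheet$library_id, ".fastq")
  write_tsv(sheet[, c("library_id", "path", "condition")],
            paths["sample_sheet"])
  paths["truth"] <- file.path(out_dir, "truth.tsv")
  write_tsv(exp$truth, paths["truth"])
  for (tb in c("table1_exact_mature", "table2_grouped_on_mature",
               "table3_unique_sequence")) {
    src <- system.file("extdata", paste0(tb, ".tsv"), package = "isomiRseq")
    if (nzchar(src)) {
      paths[tb] <- file.path(out_dir, paste0(tb, ".tsv"))
      file.copy(src, paths[tb], overwrite = TRUE)
    }
  }
  invisible(paths)
}

write_fastq <- function(reads, prefix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(k) strrep("I", k), character(1))
  writeLines(paste0("@", prefix, "_", seq_along(reads), "\n", reads,
                    "\n+\n", qual), con)
}
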