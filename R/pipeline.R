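#' Run the profiling pipeline over a set of libraries
#'
#' Orchestrates the full profiling pass: load the tiered references, read
#' and collapse every library listed in the sample sheet, group reads onto
#' matures, classify isomiRs against the hairpins, and aggregate expression
#' at the three feature levels. When `out_dir` is given, writes per-library
#' annotation TSVs, the per-length annotation summary, the end-variant
#' table, and one expression TSV per level.
#'
#' @param mature_fa,hairpin_fa primary-species reference FASTA pair.
#' @param sample_sheet path to a TSV with columns `library_id`, `path`
#'   (FASTQ/FASTA, relative paths resolved against the sheet's directory)
#'   and `condition` — or a data.frame of the same shape.
#' @param out_dir optional output directory for report files.
#' @param other_mature_fa,other_hairpin_fa optional other-species tier.
#' @param params [grouping_params()].
#' @param adapter optional 3' adapter to trim.
#' @param min_len,max_len analysis length window.
#' @param min_raw reportability threshold on raw reads.
#' @param denominator RPMM denominator switch, see [aggregate_expression()].
#' @return object of class `isomir_profile`: list with `reference`,
#'   `other_reference`, `libraries`, `annotations` (classified, one per
#'   library), `summary`, `expression` (list of the three
#'   `expression_table`s), `end_variants`, `conditions`.
#' @export
run_profile <- function(mature_fa, hairpin_fa, sample_sheet, out_dir = NULL,
                        other_mature_fa = NULL, other_hairpin_fa = NULL,
                        params = grouping_params(), adapter = NULL,
                        min_len = 13, max_len = 30, min_raw = 10,
                        denominator = c("annotated", "kept")) {
  denominator <- match.arg(denominator)
  if (is.character(sample_sheet)) {
    sheet_dir <- dirname(sample_sheet)
    sheet <- read_tsv(sample_sheet)
    rel <- !grepl("^/", sheet$path)
    sheet$path[rel] <- file.path(sheet_dir, sheet$path[rel])
  } else {
    sheet <- sample_sheet
  }
  problems <- character(0)
  for (f in c(mature_fa, hairpin_fa, other_mature_fa, other_hairpin_fa,
              sheet$path))
    if (!file.exists(f)) problems <- c(problems, paste("missing file:", f))
  for (col in c("library_id", "path", "condition"))
    if (is.null(sheet[[col]]))
      problems <- c(problems, paste("sample sheet lacks column:", col))
  stop_if(length(problems) > 0, paste(problems, collapse = "\n"))

  primary <- load_reference(mature_fa, hairpin_fa, "primary_species")
  other <- NULL
  if (!is.null(other_mature_fa))
    other <- load_reference(other_mature_fa, other_hairpin_fa,
                            "other_species")

  libs <- anns <- list()
  for (i in seq_len(nrow(sheet))) {
    lid <- sheet$library_id[i]
    libs[[lid]] <- read_library(sheet$path[i], library_id = lid,
                                condition = sheet$condition[i],
                                adapter = adapter,
                                min_len = min_len, max_len = max_len)
    ann <- annotate_library(libs[[lid]], primary, other, params)
    anns[[lid]] <- classify_annotations(ann, primary, other)
  }
  conditions <- stats::setNames(sheet$condition, sheet$library_id)

  expr <- lapply(
    stats::setNames(nm = c("exact_mature", "grouped_on_mature",
                           "unique_sequence")),
    function(lv) aggregate_expression(anns, conditions, level = lv,
                                      min_raw = min_raw,
                                      denominator = denominator))
  # carry type codes onto the unique-sequence feature table
  codemap <- do.call(rbind, lapply(anns, function(a)
    a[a$category != "unannotated", c("sequence", "code")]))
  uf <- expr$unique_sequence$features
  uf$code <- codemap$code[match(uf$feature, codemap$sequence)]
  expr$unique_sequence$features <- uf

  all_ann <- do.call(rbind, anns)
  res <- structure(list(reference = primary, other_reference = other,
                        libraries = libs, annotations = anns,
                        summary = annotation_summary(all_ann),
                        expression = expr,
                        end_variants = end_variant_distribution(
                          all_ann[!is.na(all_ann$tier) &
                                    all_ann$tier == "primary_species", ],
                          primary),
                        conditions = conditions),
                   class = "isomir_profile")
  if (!is.null(out_dir)) write_profile(res, out_dir)
  res
}

write_profile <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (lid in names(res$annotations))
    write_tsv(res$annotations[[lid]],
              file.path(out_dir, paste0("annotation_", lid, ".tsv")))
  write_tsv(res$summary, file.path(out_dir, "annotation_summary.tsv"))
  write_tsv(res$end_variants, file.path(out_dir, "end_variants.tsv"))
  for (lv in names(res$expression)) {
    tab <- res$expression[[lv]]
    cs <- condition_stats(tab)
    raw <- as.data.frame(tab$counts)
    names(raw) <- paste0("raw_", colnames(tab$counts))
    rp <- as.data.frame(tab$rpmm)
    names(rp) <- paste0("rpmm_", colnames(tab$rpmm))
    df <- cbind(tab$features, raw, rp, row.names = NULL)
    for (cc in colnames(cs$mean)) {
      df[[paste0("mean_", cc)]] <- cs$mean[, cc]
      df[[paste0("sem_", cc)]] <- cs$sem[, cc]
    }
    write_tsv(df, file.path(out_dir, paste0("expression_", lv, ".tsv")))
  }
  invisible(out_dir)
}

#' @export
print.isomir_profile <- function(x, ...) {
  cat("isomiR profile: ", length(x$libraries), " libraries, ",
      nrow(x$reference$matures), " primary matures\n", sep = "")
  ann <- do.call(rbind, x$annotations)
  tot <- sum(ann$count)
  annotated <- sum(ann$count[ann$category != "unannotated"])
  cat(sprintf("  reads kept %d, annotated %d (%.1f%%)\n", tot, annotated,
              100 * annotated / tot))
  invisible(x)
}

#' Two-condition differential abundance at all three levels
#'
#' Runs [de_table()] on the exact-mature, grouped-on-mature and
#' unique-sequence tables of a profile, with the level-specific default
#' report filters, optionally writing one TSV per level.
#'
#' @param profile an `isomir_profile` from [run_profile()].
#' @param condition_a,condition_b the two conditions to compare (fold sign
#'   positive when `condition_b` is higher).
#' @param out_dir optional output directory.
#' @param filters optional named list of [de_filters()] overrides per level.
#' @return named list of three `de_table` data.frames.
#' @export
run_de <- function(profile, condition_a, condition_b, out_dir = NULL,
                   filters = list()) {
  for (cc in c(condition_a, condition_b)) {
    n <- sum(profile$conditions == cc)
    stop_if(n < 2, "condition ", cc, " has ", n,
            " libraries; need at least 2 replicates")
  }
  out <- lapply(
    stats::setNames(nm = names(profile$expression)),
    function(lv) de_table(profile$expression[[lv]], condition_a, condition_b,
                          filters[[lv]] %||% de_filters(lv)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (lv in names(out))
      write_tsv(out[[lv]], file.path(out_dir, paste0("de_", lv, ".tsv")))
  }
  out
}
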