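#' Published differential-expression report tables
#'
#' The printed rows of the three transmural differential-abundance report
#' tables (exact mature, grouped on mature, unique sequence), shipped with
#' the package as plain-text fixtures. Each row carries the reported signed
#' endocardial/epicardial fold change and the per-layer mean and SEM RPMM
#' values; the unique-sequence table also carries the literal read sequence
#' and its miRNA/type-code annotation. Used by the fold-change round-trip
#' checks: the signed fold recomputed from the printed layer means must
#' reproduce the printed fold.
#'
#' @param which `"exact_mature"`, `"grouped_on_mature"`,
#'   `"unique_sequence"`, or `"all"` (default) for a named list of the
#'   three.
#' @return a data.frame (or named list of data.frames) with columns
#'   `mir_name`, `fold_change`, `epi_mean`, `epi_sem`, `endo_mean`,
#'   `endo_sem` (plus `sequence` for the unique-sequence table).
#' @export
layer_fold_tables <- function(which = c("all", "exact_mature",
                                        "grouped_on_mature",
                                        "unique_sequence")) {
  which <- match.arg(which)
  one <- function(level) {
    path <- system.file("extdata", paste0(switch(
      level,
      exact_mature = "table1_exact_mature",
      grouped_on_mature = "table2_grouped_on_mature",
      unique_sequence = "table3_unique_sequence"), ".tsv"),
      package = "isomiRseq", mustWork = TRUE)
    read_tsv(path)
  }
  if (which == "all") {
    lv <- c("exact_mature", "grouped_on_mature", "unique_sequence")
    return(stats::setNames(lapply(lv, one), lv))
  }
  one(which)
}
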