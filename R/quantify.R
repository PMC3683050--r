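#' Reads per million mapped
#'
#' @param raw raw count(s).
#' @param total_annotated total annotated reads of the library.
#' @return `raw / total_annotated * 1e6`.
#' @export
rpmm <- function(raw, total_annotated) {
  stop_if(any(total_annotated <= 0), "total_annotated must be positive")
  raw / total_annotated * 1e6
}

#' Abundance thresholds for reporting
#'
#' @param min_raw_reads minimum raw reads (in at least one library) for a
#'   feature to be reportable.
#' @param tiers strictly increasing RPMM cutoffs used by [top_table()].
#' @return list of class `abundance_thresholds`.
#' @export
abundance_thresholds <- function(min_raw_reads = 10,
                                 tiers = c(1000, 10000, 100000)) {
  stop_if(any(diff(tiers) <= 0), "tiers must be strictly increasing")
  structure(list(min_raw_reads = min_raw_reads, tiers = tiers),
            class = "abundance_thresholds")
}

#' Aggregate annotated libraries into an expression table
#'
#' Three aggregation levels: `exact_mature` counts only reads identical to
#' the canonical mature (d5 = d3 = 0, no mismatch), keyed by mature id;
#' `grouped_on_mature` sums every read admitted by the grouping rule per
#' mature; `unique_sequence` keeps each collapsed sequence as its own
#' feature (keyed by the literal sequence). RPMM normalizes each library's
#' counts to its total annotated reads (both tiers by default). Features
#' below `min_raw` raw reads in every library are flagged unreportable but
#' their counts are retained.
#'
#' @param anns named list of `mirna_annotation` data.frames, one per
#'   library (names are library ids).
#' @param conditions named character vector mapping library id to condition.
#' @param level aggregation level.
#' @param min_raw reportability threshold on raw counts.
#' @param denominator `"annotated"` (total annotated reads, default) or
#'   `"kept"` (all length-filtered reads, annotated or not).
#' @return object of class `expression_table`: list with `level`, `counts`
#'   and `rpmm` (feature x library matrices), `features` (data.frame with
#'   `feature`, `mature_id`, for unique level also `sequence`, plus
#'   `reportable`), `conditions`, `totals`.
#' @export
aggregate_expression <- function(anns, conditions,
                                 level = c("grouped_on_mature", "exact_mature",
                                           "unique_sequence"),
                                 min_raw = 10,
                                 denominator = c("annotated", "kept")) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  stop_if(is.null(names(anns)) || any(!nzchar(names(anns))),
          "anns must be a named list of per-library annotations")
  libs <- names(anns)
  stop_if(!all(libs %in% names(conditions)),
          "conditions missing for: ",
          paste(setdiff(libs, names(conditions)), collapse = ", "))

  totals <- vapply(anns, function(a) {
    ann_reads <- a$category != "unannotated"
    if (denominator == "annotated") sum(a$count[ann_reads]) else sum(a$count)
  }, numeric(1))

  per_lib <- lapply(anns, function(a) {
    a <- a[a$category != "unannotated", , drop = FALSE]
    key <- switch(level,
                  exact_mature = ,
                  grouped_on_mature = a$mature_id,
                  unique_sequence = a$sequence)
    w <- a$count
    if (level == "exact_mature") w <- w * (a$category == "exact_mature")
    tab <- rowsum(w, group = key)
    stats::setNames(tab[, 1], rownames(tab))
  })
  feats <- sort(unique(unlist(lapply(per_lib, names))))
  counts <- matrix(0, nrow = length(feats), ncol = length(libs),
                   dimnames = list(feats, libs))
  for (l in libs) counts[names(per_lib[[l]]), l] <- per_lib[[l]]
  rpmm_mat <- sweep(counts, 2, totals, "/") * 1e6

  features <- data.frame(feature = feats, stringsAsFactors = FALSE)
  if (level == "unique_sequence") {
    map <- do.call(rbind, lapply(anns, function(a)
      a[a$category != "unannotated", c("sequence", "mature_id", "category")]))
    features$sequence <- feats
    features$mature_id <- map$mature_id[match(feats, map$sequence)]
  } else {
    features$mature_id <- feats
  }
  features$reportable <- apply(counts, 1, max) >= min_raw

  structure(list(level = level, counts = counts, rpmm = rpmm_mat,
                 features = features,
                 conditions = conditions[libs], totals = totals,
                 min_raw = min_raw, denominator = denominator),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression table [", x$level, "]: ", nrow(x$counts), " features x ",
      ncol(x$counts), " libraries (", sum(x$features$reportable),
      " reportable at >=", x$min_raw, " raw reads)\n", sep = "")
  invisible(x)
}

#' Per-condition mean and SEM of RPMM
#'
#' @param table an `expression_table`.
#' @return list with matrices `mean` and `sem` (feature x condition); SEM is
#'   the standard deviation over replicate libraries divided by sqrt(n).
#' @export
condition_stats <- function(table) {
  conds <- unique(table$conditions)
  mean_m <- sem_m <- matrix(NA_real_, nrow = nrow(table$rpmm),
                            ncol = length(conds),
                            dimnames = list(rownames(table$rpmm), conds))
  for (cc in conds) {
    cols <- names(table$conditions)[table$conditions == cc]
    sub <- table$rpmm[, cols, drop = FALSE]
    mean_m[, cc] <- rowMeans(sub)
    sem_m[, cc] <- apply(sub, 1, stats::sd) / sqrt(ncol(sub))
  }
  list(mean = mean_m, sem = sem_m)
}

#' Features above an RPMM tier
#'
#' Pooled (mean over all libraries) RPMM per feature, reportable features
#' only, restricted to those at or above `tier`.
#'
#' @param table an `expression_table`.
#' @param tier RPMM cutoff (e.g. 1000, 10000, 100000).
#' @return data.frame `feature`, `mean_rpmm`, sorted decreasing.
#' @export
top_table <- function(table, tier = 1000) {
  mu <- rowMeans(table$rpmm)
  keep <- table$features$reportable & mu >= tier
  out <- data.frame(feature = rownames(table$rpmm)[keep],
                    mean_rpmm = mu[keep], stringsAsFactors = FALSE)
  out[order(-out$mean_rpmm), , drop = FALSE]
}

#' Star/mature abundance ratios
#'
#' For each star mature (id ending in `*`) with a non-star counterpart in
#' the reference, the ratio of pooled star RPMM to pooled mature RPMM.
#' Star sequences detected while the major mature strand is not are flagged
#' `mature_undetected` with no finite ratio.
#'
#' @param table an `expression_table` at a mature-keyed level.
#' @param db the `mirna_reference`.
#' @return data.frame `star_id`, `mature_id`, `star_rpmm`, `mature_rpmm`,
#'   `ratio`, `mature_undetected`.
#' @export
star_ratio <- function(table, db) {
  stop_if(table$level == "unique_sequence",
          "star_ratio needs a mature-keyed level")
  stars <- db$matures$id[db$matures$is_star]
  base <- sub("\\*$", "", stars)
  keep <- base %in% db$matures$id
  stars <- stars[keep]
  base <- base[keep]
  mu <- rowMeans(table$rpmm)
  sv <- ifelse(stars %in% names(mu), mu[stars], 0)
  mv <- ifelse(base %in% names(mu), mu[base], 0)
  data.frame(star_id = stars, mature_id = base,
             star_rpmm = unname(sv), mature_rpmm = unname(mv),
             ratio = ifelse(mv > 0, sv / mv, NA_real_),
             mature_undetected = mv == 0 & sv > 0,
             stringsAsFactors = FALSE)
}
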