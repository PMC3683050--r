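#' Signed fold change between two condition means
#'
#' Ratio convention used throughout the reports: with `a` the epicardial
#' (first) mean and `b` the endocardial (second) mean, the fold is
#' `b / a` when that ratio is at least 1 and `-(a / b)` otherwise, so the
#' magnitude is always the larger mean over the smaller and the sign is
#' positive exactly when the second condition is higher. One mean equal to
#' zero yields a signed infinity (the direction is known, the magnitude is
#' not); both zero is an error.
#'
#' @param mean_a,mean_b non-negative condition means (e.g. RPMM).
#' @return signed fold change(s); use [round_half_away()] for the 2-decimal
#'   report convention.
#' @export
fold_change <- function(mean_a, mean_b) {
  stop_if(any(mean_a < 0 | mean_b < 0), "means must be non-negative")
  stop_if(any(mean_a == 0 & mean_b == 0),
          "fold change undefined when both means are zero")
  r <- mean_b / mean_a
  ifelse(r >= 1, r, -1 / r)
}

#' Weighted beta-binomial test for a difference in proportions
#'
#' Baggerly-style test for differential representation of a feature between
#' two groups of count libraries. Each library contributes a proportion
#' `x_i / n_i` (feature count over library total). Within each group a
#' weighted mean proportion is estimated with weights inversely proportional
#' to the sum of the within-library binomial variance and a between-library
#' overdispersion component (estimated iteratively, method-of-moments,
#' floored at zero), so deep libraries dominate only insofar as replicate
#' scatter allows. The statistic is the difference of the two group
#' estimates over the root of their summed variances, referred to a t
#' distribution with (total libraries - 2) degrees of freedom.
#'
#' @param counts_a,counts_b per-library feature counts for each group.
#' @param totals_a,totals_b per-library totals (annotated reads).
#' @return list with `p_value` (two-sided), `statistic`, `df`,
#'   `estimate_a`, `estimate_b` (weighted group proportions).
#' @export
baggerley_test <- function(counts_a, totals_a, counts_b, totals_b) {
  stop_if(length(counts_a) != length(totals_a) ||
            length(counts_b) != length(totals_b),
          "counts and totals lengths differ")
  stop_if(length(counts_a) < 2 || length(counts_b) < 2,
          "need >= 2 libraries per group")
  stop_if(all(totals_a == 0) || all(totals_b == 0),
          "a group has all-zero totals")
  stop_if(any(totals_a <= 0) || any(totals_b <= 0),
          "library totals must be positive")
  ga <- weighted_proportion(counts_a, totals_a)
  gb <- weighted_proportion(counts_b, totals_b)
  df <- length(counts_a) + length(counts_b) - 2
  se <- sqrt(ga$var + gb$var)
  if (se == 0) {
    tstat <- if (ga$p == gb$p) 0 else sign(ga$p - gb$p) * Inf
  } else {
    tstat <- (ga$p - gb$p) / se
  }
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p <- min(max(p, .Machine$double.xmin), 1)
  list(p_value = p, statistic = tstat, df = df,
       estimate_a = ga$p, estimate_b = gb$p)
}

# iterative weighted estimate of a group proportion with between-library
# overdispersion (DerSimonian-Laird-type moment estimator on proportions)
weighted_proportion <- function(x, n) {
  k <- length(x)
  p <- x / n
  phat <- sum(x) / sum(n)
  sig2 <- 0
  for (it in 1:25) {
    vw <- pmax(phat * (1 - phat) / n, 1e-12)
    w <- 1 / (vw + sig2)
    phat_new <- sum(w * p) / sum(w)
    q <- sum(w * (p - phat_new)^2)
    denom <- sum(w) - sum(w^2) / sum(w)
    sig2_new <- if (denom > 0) max(0, (q - (k - 1)) / denom) else 0
    conv <- abs(phat_new - phat) < 1e-12 && abs(sig2_new - sig2) < 1e-18
    phat <- phat_new
    sig2 <- sig2_new
    if (conv) break
  }
  vw <- pmax(phat * (1 - phat) / n, 1e-12)
  w <- 1 / (vw + sig2)
  list(p = sum(w * p) / sum(w), var = 1 / sum(w), tau2 = sig2)
}

#' Report filters for differential tables
#'
#' Level-specific defaults: mature-keyed levels require an absolute fold of
#' at least 1.5 and at least 10 raw reads detected in either condition;
#' the unique-sequence level requires a fold of at least 2 and a condition
#' mean of at least 100 RPMM in either condition.
#'
#' @param level aggregation level of the table to be filtered.
#' @param min_fold minimum absolute fold change.
#' @param min_raw minimum summed raw reads in either condition
#'   (mature levels).
#' @param min_mean_rpmm minimum condition mean RPMM in either condition
#'   (unique level).
#' @return list of class `de_filters`.
#' @export
de_filters <- function(level = c("grouped_on_mature", "exact_mature",
                                 "unique_sequence"),
                       min_fold = NULL, min_raw = NULL, min_mean_rpmm = NULL) {
  level <- match.arg(level)
  if (level == "unique_sequence") {
    f <- list(min_fold = min_fold %||% 2.0, min_raw = NULL,
              min_mean_rpmm = min_mean_rpmm %||% 100)
  } else {
    f <- list(min_fold = min_fold %||% 1.5, min_raw = min_raw %||% 10,
              min_mean_rpmm = NULL)
  }
  stop_if(f$min_fold <= 0, "min_fold must be positive")
  structure(f, class = "de_filters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-condition differential abundance table
#'
#' For every feature of an [aggregate_expression()] table: condition means
#' and SEMs of RPMM, the signed fold change of the means (second condition
#' over first), a Baggerly-style beta-binomial p-value on the raw counts
#' with per-library annotated totals, and Benjamini-Hochberg FDR. The
#' report keeps rows with absolute fold at or above the filter minimum and
#' the level's abundance rule satisfied in at least one condition
#' ("detected in either layer"), sorted by fold change descending. Features
#' with zero counts in both conditions are dropped (their fold is
#' undefined).
#'
#' @param table an `expression_table`.
#' @param condition_a,condition_b the two condition labels (fold sign is
#'   positive when `condition_b` is higher).
#' @param filters a [de_filters()]; defaults follow the table's level.
#' @return data.frame of class `de_table`: `feature` (plus `sequence`,
#'   `mature_id`, `code` columns at unique level when available),
#'   `fold_change` (rounded to 2 decimals, half away from zero; signed
#'   `Inf` when one condition mean is zero), `mean_a`, `sem_a`, `mean_b`,
#'   `sem_b`, `p_value`, `fdr`.
#' @export
de_table <- function(table, condition_a, condition_b,
                     filters = de_filters(table$level)) {
  conds <- table$conditions
  stop_if(!condition_a %in% conds, "condition not present: ", condition_a)
  stop_if(!condition_b %in% conds, "condition not present: ", condition_b)
  libs_a <- names(conds)[conds == condition_a]
  libs_b <- names(conds)[conds == condition_b]
  stop_if(length(libs_a) < 2, "need >= 2 libraries for ", condition_a)
  stop_if(length(libs_b) < 2, "need >= 2 libraries for ", condition_b)

  cs <- condition_stats(table)
  mean_a <- cs$mean[, condition_a]
  mean_b <- cs$mean[, condition_b]
  sem_a <- cs$sem[, condition_a]
  sem_b <- cs$sem[, condition_b]

  testable <- !(mean_a == 0 & mean_b == 0)
  fold <- rep(NA_real_, nrow(table$counts))
  fold[testable] <- fold_change(mean_a[testable], mean_b[testable])

  p <- rep(NA_real_, nrow(table$counts))
  for (i in which(testable)) {
    p[i] <- baggerley_test(table$counts[i, libs_a], table$totals[libs_a],
                           table$counts[i, libs_b],
                           table$totals[libs_b])$p_value
  }
  fdr <- rep(NA_real_, length(p))
  fdr[testable] <- stats::p.adjust(p[testable], method = "BH")

  out <- data.frame(feature = rownames(table$counts),
                    fold_change = round_half_away(fold, 2),
                    mean_a = mean_a, sem_a = sem_a,
                    mean_b = mean_b, sem_b = sem_b,
                    p_value = p, fdr = fdr, stringsAsFactors = FALSE)
  if (table$level == "unique_sequence") {
    idx <- match(out$feature, table$features$feature)
    out$sequence <- table$features$sequence[idx]
    out$mature_id <- table$features$mature_id[idx]
    if (!is.null(table$features$code)) out$code <- table$features$code[idx]
  }

  raw_a <- rowSums(table$counts[, libs_a, drop = FALSE])
  raw_b <- rowSums(table$counts[, libs_b, drop = FALSE])
  detected <- if (!is.null(filters$min_raw)) {
    raw_a >= filters$min_raw | raw_b >= filters$min_raw
  } else {
    mean_a >= filters$min_mean_rpmm | mean_b >= filters$min_mean_rpmm
  }
  keep <- testable & detected & abs(out$fold_change) >= filters$min_fold
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$fold_change), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "condition_a") <- condition_a
  attr(out, "condition_b") <- condition_b
  class(out) <- c("de_table", "data.frame")
  out
}
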