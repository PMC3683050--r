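test_that("signed fold change follows the larger-over-smaller convention", {
  expect_equal(round_half_away(fold_change(4.45, 13.36), 2), 3.00)
  expect_equal(round_half_away(fold_change(39.25, 17.09), 2), -2.30)
  expect_equal(fold_change(5, 5), 1)
  # antisymmetry
  set.seed(2)
  a <- runif(50, 0.1, 100)
  b <- runif(50, 0.1, 100)
  expect_equal(fold_change(a, b), -fold_change(b, a), tolerance = 1e-12)
  # zero handling
  expect_equal(fold_change(0, 3), Inf)
  expect_equal(fold_change(3, 0), -Inf)
  expect_error(fold_change(0, 0), "undefined")
})

test_that("printed report rows round-trip from their printed means", {
  tabs <- layer_fold_tables()
  for (tb in tabs) {
    fold <- round_half_away(fold_change(tb$epi_mean, tb$endo_mean), 2)
    # printed means are themselves rounded, so allow |error| <= 0.03 on the
    # fold across all rows; target rows are checked exactly elsewhere
    expect_true(all(abs(fold - tb$fold_change) <= 0.03))
  }
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_away(2.005, 2), 2.01)
  expect_equal(round_half_away(-2.005, 2), -2.01)
  expect_equal(round_half_away(1.994999, 2), 1.99)
})

test_that("identical proportions give p near 1; strong shifts give small p", {
  n <- c(5e4, 6e4, 5.5e4, 5e4, 6e4, 5.5e4)
  x_same <- round(n * 2e-3)
  p_same <- baggerley_test(x_same[1:3], n[1:3], x_same[4:6], n[4:6])$p_value
  expect_gt(p_same, 0.9)

  # 10x difference at deep totals
  x <- c(round(n[1:3] * 5e-3), round(n[4:6] * 5e-4))
  bt <- baggerley_test(x[1:3], n[1:3], x[4:6], n[4:6])
  expect_lt(bt$p_value, 0.01)
  # permutation oracle on the same counts: the observed split must be the
  # most extreme of all label assignments
  expect_equal(permutation_prop_test(x, n, rep(c(1, 2), each = 3)), 2 / 20)
  expect_error(baggerley_test(1, 10, c(1, 2), c(10, 10)), "2 libraries")
  expect_error(baggerley_test(c(1, 2), c(0, 0), c(1, 2), c(10, 10)), "zero|positive")
})

test_that("null p-values are calibrated and not anticonservative", {
  # beta-binomial null (the declared model): close to uniform
  set.seed(5)
  pv <- replicate(400, {
    n <- round(runif(6, 4e4, 6e4))
    pr <- rbeta(6, 40, 40 / 2e-3 - 40)
    x <- rbinom(6, n, pr)
    baggerley_test(x[1:3], n[1:3], x[4:6], n[4:6])$p_value
  })
  expect_lt(suppressWarnings(ks.test(pv, "punif"))$statistic, 0.1)
  # pure binomial null: overdispersion floor makes the test conservative,
  # never anticonservative
  pv2 <- replicate(400, {
    n <- round(runif(6, 4e4, 6e4))
    x <- rbinom(6, n, 2e-3)
    baggerley_test(x[1:3], n[1:3], x[4:6], n[4:6])$p_value
  })
  expect_lte(mean(pv2 < 0.05), 0.07)
})

test_that("de_table applies level filters and the either-layer rule", {
  m <- "TGAGGTAGTAGGTTGTATAGTT"
  seqs <- c(A = m, B = "TACCCTGTAGAACCGAATTTG", C = "CAGTGCAATGTTAAAAGGGCAT",
            D = "ACGTACGTAAACGTACGTACG")
  mk <- function(counts) make_ann(unname(seqs), as.integer(counts),
                                  paste0("mir-", names(seqs)), "exact_mature")
  # totals ~1e4 per library; mir-A flat, mir-B ~1.4x, mir-C 3x, mir-D scarce
  anns <- list(
    e1 = mk(c(4000, 1000, 100, 4)), e2 = mk(c(4100, 1050, 110, 3)),
    e3 = mk(c(3900, 950, 90, 4)),
    n1 = mk(c(4000, 1400, 300, 8)), n2 = mk(c(4050, 1420, 310, 7)),
    n3 = mk(c(3950, 1380, 290, 9)))
  conds <- c(e1 = "epi", e2 = "epi", e3 = "epi",
             n1 = "endo", n2 = "endo", n3 = "endo")
  tab <- aggregate_expression(anns, conds, "grouped_on_mature")
  de <- de_table(tab, "epi", "endo")
  # flat and sub-1.5-fold features excluded, 3x feature present
  expect_false("mir-A" %in% de$feature)
  expect_false("mir-B" %in% de$feature)
  expect_true("mir-C" %in% de$feature)
  # scarce feature passes the raw threshold via the either-layer sum rule
  expect_true("mir-D" %in% de$feature)
  expect_true(all(abs(de$fold_change) >= 1.5))
  # sorted by fold change descending
  expect_equal(de$fold_change, sort(de$fold_change, decreasing = TRUE))

  # swapping conditions negates folds and keeps p-values
  de_swap <- de_table(tab, "endo", "epi")
  common <- intersect(de$feature, de_swap$feature)
  expect_equal(de_swap$fold_change[match(common, de_swap$feature)],
               -de$fold_change[match(common, de$feature)])
  expect_equal(de_swap$p_value[match(common, de_swap$feature)],
               de$p_value[match(common, de$feature)])

  # raising the raw threshold above mir-D's totals drops it
  de_strict <- de_table(tab, "epi", "endo",
                        de_filters("grouped_on_mature", min_raw = 50))
  expect_false("mir-D" %in% de_strict$feature)
})

test_that("unique-level filter uses fold 2 and 100 mean RPMM in either layer", {
  f <- de_filters("unique_sequence")
  expect_equal(f$min_fold, 2)
  expect_equal(f$min_mean_rpmm, 100)
  seqs <- c("TGAGGTAGTAGGTTGTATAGTT", "TACCCTGTAGAACCGAATTTG",
            "CAGTGCAATGTTAAAAGGGCAT")
  mk <- function(counts) make_ann(seqs, as.integer(counts),
                                  c("mir-A", "mir-B", "mir-C"),
                                  "exact_mature")
  # library total 1e4 -> 99 counts ~ 9900 RPMM; scale so RPMM ~ counts * 100
  anns <- list(e1 = mk(c(9000, 990, 10)), e2 = mk(c(9000, 990, 10)),
               n1 = mk(c(7020, 2960, 20)), n2 = mk(c(7050, 2930, 20)))
  conds <- c(e1 = "epi", e2 = "epi", n1 = "endo", n2 = "endo")
  tab <- aggregate_expression(anns, conds, "unique_sequence", min_raw = 1)
  de <- de_table(tab, "epi", "endo")
  # mir-B sequence ~3x with means >= 100 RPMM: kept
  expect_true(seqs[2] %in% de$feature)
  # mir-C sequence 2x but its best condition mean is 2000 RPMM -> kept;
  # shrink it below 100 RPMM to see it drop
  anns_small <- list(e1 = mk(c(9996, 990, 0)), e2 = mk(c(9996, 990, 0)),
                     n1 = mk(c(9992, 2960, 1)), n2 = mk(c(9992, 2930, 1)))
  tab2 <- aggregate_expression(anns_small, conds, "unique_sequence",
                               min_raw = 1)
  de2 <- de_table(tab2, "epi", "endo")
  expect_false(seqs[3] %in% de2$feature)
})

test_that("a simulated endocardial gradient is recovered with correct sign", {
  ref <- simulate_reference(n_hairpins = 6, seed = 23)
  target <- "sim-mir-1"
  p <- sim_params(depth = 20000, gradient = c("sim-mir-1" = 2.5))
  # fixed uniform abundance so the gradient feature has solid coverage
  ab <- setNames(rep(1, nrow(ref$matures)), ref$matures$id)
  anns <- list()
  conds <- character(0)
  for (i in 1:3) {
    for (cc in c("epicardium", "endocardium")) {
      lid <- paste0(substr(cc, 1, 3), i)
      sim <- simulate_library(ref, p, cc, lid,
                              seed = 100 * i + nchar(cc), abundance = ab)
      anns[[lid]] <- annotate_library(sim$library, ref)
      conds[lid] <- cc
    }
  }
  tab <- aggregate_expression(anns, conds, "grouped_on_mature")
  de <- de_table(tab, "epicardium", "endocardium")
  expect_true(target %in% de$feature)
  row <- de[de$feature == target, ]
  expect_gt(row$fold_change, 1.5)
  expect_lt(row$fold_change, 4)
  expect_lt(row$p_value, 0.05)
})
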