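test_that("classification separates templated extensions from tails", {
  tr <- write_tiny_reference()
  db <- load_reference(tr$mature, tr$hairpin, "primary_species")
  m <- unname(tr$m["rno-mir-A"])           # hairpin context GGA [m] CTA...
  # exact read
  cl <- classify_read(m, "rno-mir-A", 0, 0, db)
  expect_equal(cl$code, "M")
  expect_equal(cl$nta, "")
  expect_equal(nrow(cl$internal_subs), 0)
  # 3' extension by one nt that does not match the hairpin (flank starts "C")
  cl <- classify_read(paste0(m, "A"), "rno-mir-A", 0, 1, db)
  expect_equal(cl$code, "MSupV")
  expect_equal(cl$nta, "A")
  expect_false(cl$three_templated)
  # templated 3' extension ("C" from the hairpin flank)
  cl <- classify_read(paste0(m, "C"), "rno-mir-A", 0, 1, db)
  expect_equal(cl$code, "MSup")
  expect_equal(cl$nta, "")
  expect_true(cl$three_templated)
  # two extra templated 5' nts ("GA" preceding the mature in the hairpin)
  cl <- classify_read(paste0("GA", m), "rno-mir-A", 2, 0, db)
  expect_true(cl$five_templated)
  expect_equal(cl$code, "MSup")
  # shifted precursor window: one off each end, both templated
  shifted <- paste0("A", substr(m, 1, nchar(m) - 1))
  cl <- classify_read(shifted, "rno-mir-A", 1, -1, db)
  expect_equal(cl$code, "P")
  # truncation with internal substitution
  cl <- classify_read(mutate_at(substr(m, 2, nchar(m)), 5), "rno-mir-A",
                      -1, 0, db)
  expect_equal(cl$code, "MSubV")
  expect_equal(cl$internal_subs$position, 6L)  # read pos 5 = mature pos 6
})

test_that("the non-templated tail is the maximal disagreeing suffix", {
  tr <- write_tiny_reference()
  db <- load_reference(tr$mature, tr$hairpin, "primary_species")
  m <- unname(tr$m["rno-mir-A"])   # 3' flank in hairpin: "CTA..."
  # extension CTT: C,T templated, final T disagrees with flank A -> nta "T"
  cl <- classify_read(paste0(m, "CTT"), "rno-mir-A", 0, 3, db)
  expect_equal(cl$nta, "T")
  # extension GTA: G disagrees immediately; the templated-looking TA after
  # it still counts as tail
  cl <- classify_read(paste0(m, "GTA"), "rno-mir-A", 0, 3, db)
  expect_equal(cl$nta, "GTA")
})

test_that("star-strand reads carry the star marker in their code", {
  ref <- simulate_reference(n_hairpins = 3, seed = 7, plant_fixtures = TRUE)
  star <- ref$matures[ref$matures$id == "sim-mir-fix486*", ]
  cl <- classify_read(star$sequence, star$id, 0, 0, ref)
  expect_equal(cl$code, "M*")
  cl <- classify_read(substr(star$sequence, 1, star$length - 1), star$id,
                      0, -1, ref)
  expect_equal(cl$code, "M*Sub")
})

test_that("consensus takes the count-weighted majority with canonical ties", {
  tr <- write_tiny_reference()
  db <- load_reference(tr$mature, tr$hairpin, "primary_species")
  m <- unname(tr$m["rno-mir-A"])
  # single read: consensus equals that read over its span
  ann <- make_ann(m, 4L, "rno-mir-A", "exact_mature")
  cons <- consensus_sequence(ann, db)
  expect_equal(cons$consensus, m)
  # 3:1 majority at one position carries the variant
  v <- mutate_at(m, 10)
  ann <- make_ann(c(v, m), c(3L, 1L), "rno-mir-A",
                  c("grouped", "exact_mature"),
                  n_mismatch = c(1L, 0L))
  cons <- consensus_sequence(ann, db)
  expect_equal(substr(cons$consensus, 10, 10), substr(v, 10, 10))
  # 2:2 tie resolves to the canonical nucleotide
  ann$count <- c(2L, 2L)
  cons <- consensus_sequence(ann, db)
  expect_equal(cons$consensus, m)
  # 5' extension introduces a negative-index column templated from the hairpin
  ext <- paste0("A", m)
  ann <- make_ann(ext, 1L, "rno-mir-A", "grouped", d5 = 1L)
  cons <- consensus_sequence(ann, db)
  expect_equal(min(cons$positions), 0L)
  expect_equal(cons$consensus, ext)
})

test_that("end-variant fractions sum to one and recover simulated rates", {
  # all-exact reads: no variation at either end
  tr <- write_tiny_reference()
  db <- load_reference(tr$mature, tr$hairpin, "primary_species")
  ann <- make_ann(unname(tr$m), c(5L, 5L), names(tr$m), "exact_mature")
  ev <- end_variant_distribution(ann, db)
  cells <- ev[!is.na(ev$canonical), ]
  expect_true(all(cells$canonical == 1))
  expect_true(all(abs(cells$canonical + cells$shorter + cells$longer - 1)
                  < 1e-12))

  # simulation with 30% 3'-shortening recovered within binomial error
  ref <- simulate_reference(n_hairpins = 6, seed = 17)
  p <- sim_params(depth = 8000, d5_probs = c("0" = 1),
                  d3_probs = c("-1" = 0.3, "0" = 0.7), nta_prob = 0)
  sim <- simulate_library(ref, p, "epicardium", "e1", seed = 3)
  ann <- annotate_library(sim$library, ref)
  ev <- end_variant_distribution(ann, db = ref)
  for (a in c("5p", "3p")) {
    cell <- ev[ev$arm == a & ev$end == "3p", ]
    if (is.na(cell$shorter)) next
    expect_lt(abs(cell$shorter - 0.3), 0.03)
    expect_equal(cell$longer, 0)
  }
  # marginal identity: variant share = 1 - canonical share
  expect_equal(ev$shorter + ev$longer, 1 - ev$canonical)
})

test_that("seed extraction returns positions 2-8", {
  expect_identical(seed_of("TACCCTGTAGAACCGAATTTGT"), "ACCCTGT")
  expect_identical(seed_of("ACGTACGT"), "CGTACGT")
  expect_error(seed_of("ACGTACG"), "seed")
})

test_that("variant positions are flagged at the observed frequency", {
  tr <- write_tiny_reference()
  db <- load_reference(tr$mature, tr$hairpin, "primary_species")
  m <- unname(tr$m["rno-mir-A"])
  # no substitutions: nothing flagged
  ann <- make_ann(m, 10L, "rno-mir-A", "exact_mature")
  expect_equal(nrow(variant_position_report(ann, db)), 0)
  # two independent co-occurring variant positions
  v1 <- mutate_at(m, 5, "A")
  v2 <- mutate_at(m, 12, "C")
  stopifnot(substr(m, 5, 5) != "A", substr(m, 12, 12) != "C")
  ann <- make_ann(c(m, v1, v2), c(2L, 6L, 3L), "rno-mir-A",
                  c("exact_mature", "grouped", "grouped"),
                  n_mismatch = c(0L, 1L, 1L))
  rep <- variant_position_report(ann, db, threshold = 0.3)
  expect_equal(rep$position[rep$flagged], c(5L))
  expect_equal(rep$fraction[rep$position == 5], 6 / 11)
  expect_equal(rep$fraction[rep$position == 12], 3 / 11)

  # simulated 77% substitution at position 17 recovered on a one-gene locus
  dir <- withr::local_tempdir()
  set.seed(9)
  m1 <- mutate_at(random_seq(22), 17, "G")
  h1 <- paste0("ACG", m1, random_seq(30))
  writeLines(c(">solo-mir-1", m1), file.path(dir, "m.fa"))
  writeLines(c(">solo-hp-1", h1), file.path(dir, "h.fa"))
  solo <- load_reference(file.path(dir, "m.fa"), file.path(dir, "h.fa"),
                         "primary_species")
  p <- sim_params(depth = 6000, internal_subs = list(
    list(mature_id = "solo-mir-1", position = 17, alt = "A", fraction = 0.77)))
  sim <- simulate_library(solo, p, "epicardium", "e1", seed = 10)
  ann <- annotate_library(sim$library, solo)
  rep <- variant_position_report(ann, solo, threshold = 0.5)
  hit <- rep[rep$position == 17 & rep$alt == "A", ]
  expect_true(hit$flagged)
  expect_lt(abs(hit$fraction - 0.77), 0.03)
})

test_that("classify recovers the simulated truth exactly at zero error", {
  ref <- simulate_reference(n_hairpins = 5, seed = 42)
  p <- sim_params(depth = 4000)
  sim <- simulate_library(ref, p, "epicardium", "e1", seed = 7)
  ann <- classify_annotations(annotate_library(sim$library, ref), ref)
  idx <- match(sim$truth$sequence, ann$sequence)
  expect_true(all(ann$mature_id[idx] == sim$truth$mature_id))
  expect_true(all(ann$d5[idx] == sim$truth$d5))
  expect_true(all(ann$d3[idx] == sim$truth$d3))
  expect_true(all(ann$nta[idx] == sim$truth$nta))
  expect_true(all(ann$internal_subs[idx] == sim$truth$subs))
})
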