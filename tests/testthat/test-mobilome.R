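test_that("absent circles yield zero reads; depth scaling cancels out", {
  g <- small_genome()
  tr <- truth_table(g, planted_circles = data.frame(
    family = c("ZAMx", "GTWx"), count = c(100, 0)),
    mobilome_mt_weight = 50, mobilome_bg_weight = 0)
  m <- simulate_mobilome_library(g, tr, n_reads = 1500, seed = 3)
  expect_false("GTWx" %in% m$reads$origin)
  q1 <- quantify_mobilome(m$alignments, g)
  expect_false("GTWx" %in% q1$family)

  m2 <- simulate_mobilome_library(g, tr, n_reads = 3000, seed = 3)
  q2 <- quantify_mobilome(m2$alignments, g)
  raw1 <- q1$weight[q1$family == "ZAMx"]
  raw2 <- q2$weight[q2$family == "ZAMx"]
  # raw roughly doubles (within multinomial sampling error) ...
  expect_gt(raw2 / raw1, 1.8); expect_lt(raw2 / raw1, 2.2)
  # ... while normalized counts are depth-invariant up to sampling noise
  n1 <- q1$normalized[q1$family == "ZAMx"]
  n2 <- q2$normalized[q2$family == "ZAMx"]
  expect_lt(abs(n2 / n1 - 1), 0.15)
})

test_that("normalization arithmetic and zero-mt handling", {
  counts <- data.table::data.table(family = "ZAMx", weight = 500)
  out <- normalize_mt(counts, 1000)
  expect_equal(out$normalized, 500)
  expect_error(normalize_mt(counts, 0), "normalization")
  expect_warning(truth_table(small_genome(), mobilome_mt_weight = 0),
                 "impossible")
})

test_that("score floor is strict and 1/k down-weighting conserves mass", {
  g <- small_genome()
  rec <- function(qname, rname, score, pos = 10L) data.table::data.table(
    qname = qname, flag = 0L, rname = rname, pos = pos, mapq = 255L,
    cigar = "50M", rnext = NA_character_, pnext = 0L, tlen = 0L,
    seq = strrep("A", 50), score = score)
  aln <- rbind(
    rec("tied", "ZAMx", 0), rec("tied", "GTWx", 0),        # 2-way tie
    rec("floor_ok", "ZAMx", -10),                          # kept (= floor)
    rec("floor_out", "ZAMx", -11),                         # discarded
    rec("second_best", "ZAMx", 0), rec("second_best", "GTWx", -6))
  aln$flag <- aln$flag + 256L * as.integer(duplicated(aln$qname))
  fc <- family_counts(aln, g)
  expect_equal(fc$weight[fc$family == "ZAMx"], 0.5 + 1 + 1)
  expect_equal(fc$weight[fc$family == "GTWx"], 0.5)
  expect_equal(sum(fc$weight), attr(fc, "retained"))
  expect_equal(attr(fc, "dropped"), 1L)  # floor_out lost its only alignment
})

test_that("TE-read assignment matches truth on a simulated library", {
  g <- small_genome()
  tr <- truth_table(g, planted_circles = data.frame(
    family = "ZAMx", count = 500),
    mobilome_mt_weight = 300, mobilome_bg_weight = 500)
  m <- simulate_mobilome_library(g, tr, n_reads = 1300, seed = 9)
  te <- assign_te_reads(m$alignments, g)
  got <- sort(unique(te$qname))
  want <- sort(m$reads$qname[m$reads$origin == "ZAMx"])
  expect_identical(got, want)
  expect_error(assign_te_reads(
    data.table::data.table(qname = "x", flag = 0L, rname = "cA", pos = 1L,
                           mapq = 0L, cigar = "10M", rnext = NA_character_,
                           pnext = 0L, tlen = 0L, seq = strrep("A", 10),
                           score = NA_real_), g),
    "format")
})

test_that("mtDNA normalization recovers planted abundance ratios", {
  g <- small_genome()
  mk <- function(zam, seed) {
    tr <- truth_table(g, planted_circles = data.frame(
      family = c("ZAMx", "CTRLx"), count = c(zam, 200)),
      mobilome_mt_weight = 400, mobilome_bg_weight = 50)
    m <- simulate_mobilome_library(g, tr, n_reads = 6000, seed = seed)
    quantify_mobilome(m$alignments, g)
  }
  qa <- mk(2000, 11)  # condition A: 20x more ZAMx circles than B
  qb <- mk(100, 12)
  cmp <- compare_conditions(qa, qb)
  r <- cmp$fold[cmp$family == "ZAMx"]
  expect_gt(r, 20 * 0.7); expect_lt(r, 20 * 1.4)
  expect_true(cmp$flagged[cmp$family == "ZAMx"])
  # identical inputs: all folds 1, nothing flagged at threshold 2
  cmp0 <- compare_conditions(qa, qa)
  expect_true(all(cmp0$fold == 1))
  expect_false(any(cmp0$flagged))
})

test_that("weight conservation and replicate null calibration", {
  g <- small_genome()
  tr <- truth_table(g, planted_circles = data.frame(
    family = c("ZAMx", "GTWx", "CTRLx"), count = c(300, 300, 300)),
    mobilome_mt_weight = 300, mobilome_bg_weight = 30)
  m <- simulate_mobilome_library(g, tr, n_reads = 4000, seed = 21)
  te <- assign_te_reads(m$alignments, g)
  fc <- family_counts(te, g)
  expect_equal(sum(fc$weight), attr(fc, "retained"), tolerance = 1e-6)
  # two replicate simulations: per-family normalized fold < 2 everywhere
  m2 <- simulate_mobilome_library(g, tr, n_reads = 4000, seed = 22)
  q1 <- quantify_mobilome(m$alignments, g)
  q2 <- quantify_mobilome(m2$alignments, g)
  cmp <- compare_conditions(q1, q2)
  expect_true(all(cmp$fold > 0.5 & cmp$fold < 2))
})
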