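test_that("library_specific: identity, boundaries, symmetry", {
  cfg <- compare_config(window = 20L)
  a <- make_calls("ZAMx", "cA", c(1000, 5000))
  expect_equal(nrow(library_specific(a, a, cfg)$unique_a), 0)
  expect_equal(nrow(library_specific(a, a, cfg)$unique_b), 0)

  b20 <- make_calls("ZAMx", "cA", 1020)
  b21 <- make_calls("ZAMx", "cA", 1021)
  expect_equal(library_specific(a, b20, cfg)$shared_a$breakpoint, 1000L)
  r21 <- library_specific(a, b21, cfg)
  expect_true(1000L %in% r21$unique_a$breakpoint)

  # family-aware: same position, different family, no match
  bf <- make_calls("GTWx", "cA", 1000)
  expect_equal(nrow(library_specific(a, bf, cfg)$shared_a), 0)

  # symmetry under swapping
  set.seed(3)
  x <- make_calls(sample(c("ZAMx", "GTWx"), 30, TRUE), "cA",
                  sample.int(20000L, 30))
  y <- make_calls(sample(c("ZAMx", "GTWx"), 30, TRUE), "cA",
                  sample.int(20000L, 30))
  xy <- library_specific(x, y, cfg)
  yx <- library_specific(y, x, cfg)
  expect_equal(data.table::setorder(xy$unique_a, breakpoint),
               data.table::setorder(yx$unique_b, breakpoint))
  expect_equal(data.table::setorder(xy$unique_b, breakpoint),
               data.table::setorder(yx$unique_a, breakpoint))

  ax <- data.table::copy(a); data.table::setattr(ax, "reference", "dm3")
  bx <- data.table::copy(bf); data.table::setattr(bx, "reference", "dm6")
  expect_error(library_specific(ax, bx, cfg), "mixed")
})

test_that("windowed matching equals the all-pairs oracle on random calls", {
  set.seed(17)
  n <- 100
  mk <- function() make_calls(sample(c("ZAMx", "GTWx", "CTRLx"), n, TRUE),
                              sample(c("cA", "cB"), n, TRUE),
                              sample.int(30000L, n, replace = TRUE))
  a <- mk(); b <- mk()
  cfg <- compare_config(window = 25L)
  got <- library_specific(a, b, cfg)
  want_a <- oracle_matched(a, b, 25L)
  want_b <- oracle_matched(b, a, 25L)
  expect_equal(sort(got$unique_a$breakpoint), sort(a$breakpoint[!want_a]))
  expect_equal(sort(got$unique_b$breakpoint), sort(b$breakpoint[!want_b]))
})

test_that("multi_intersect membership and recounts", {
  base <- make_calls(c("ZAMx", "GTWx"), "cA", c(1000, 8000))
  sets <- lapply(1:12, function(i) data.table::copy(base))
  names(sets) <- paste0("fly", 1:12)
  mi <- multi_intersect(sets)
  expect_equal(nrow(mi), 2)         # 12 identical sets: no unique loci
  expect_true(all(mi$n_sets == 12))

  sets$fly7 <- rbind(sets$fly7, make_calls("ZAMx", "cB", 4000))
  mi2 <- multi_intersect(sets)
  uniq <- mi2[mi2$n_sets == 1]
  expect_equal(nrow(uniq), 1)
  expect_true(uniq$fly7)
  expect_equal(uniq$contig, "cB")

  # recount: per-set membership sums equal per-set call counts (after
  # merging; here no two calls of a set share a locus)
  for (nm in names(sets)) {
    expect_equal(sum(mi2[[nm]]), nrow(sets[[nm]]))
  }
})

test_that("de-novo ratios: trivial cases and undefined propagation", {
  r <- denovo_ratio(c(ZAMx = 5, GTWx = 2), c(ZAMx = 5, GTWx = 2))
  expect_true(all(r$ratio == 1))
  expect_false(any(r$flagged))
  r2 <- denovo_ratio(c(ZAMx = 9), c(ZAMx = 2, GTWx = 0))
  expect_equal(r2$ratio[r2$family == "ZAMx"], 4.5)
  expect_true(r2$flagged[r2$family == "ZAMx"])
  expect_true(is.na(r2$ratio[r2$family == "GTWx"]))  # 0/0 undefined, not 1
  r3 <- denovo_ratio(c(ZAMx = 3), c(ZAMx = 0))
  expect_equal(r3$ratio, Inf)
})

test_that("subsampling: identity at fraction 1, determinism, monotonicity", {
  g <- small_genome()
  ins <- plant_insertions(g, c("ZAMx", "GTWx"), 2, seed = 7,
                          min_gap = 4000L)
  tr <- truth_table(g, planted_insertions = ins, chimera_rate = 0)
  w <- simulate_wgs_library(g, tr, coverage = 15, seed = 8)
  calls_b <- call_insertions(alignment_records(), g$te_library)  # empty B
  full <- call_insertions(w$alignments, g$te_library)
  mapped <- sum(!bitwAnd(w$alignments$flag, 4L) &
                  !bitwAnd(w$alignments$flag, 256L))

  cfg <- compare_config(n_subsamples = 5L)
  s1 <- subsample_matched(w$alignments, calls_b, mapped, g$te_library,
                          cfg, seed = 11)
  expect_equal(s1$fraction, 1)
  # every replicate at fraction 1 equals the full analysis
  full_counts <- table(full$family)
  for (f in names(full_counts)) {
    expect_true(all(s1$replicates[[f]] == full_counts[[f]]))
  }
  s2 <- subsample_matched(w$alignments, calls_b, mapped, g$te_library,
                          cfg, seed = 11)
  expect_identical(s1$mean, s2$mean)
  expect_identical(s1$replicates, s2$replicates)

  # half-depth means lie between 0 and the full-depth count
  s3 <- subsample_matched(w$alignments, calls_b, round(mapped / 2),
                          g$te_library, cfg, seed = 13)
  for (f in names(full_counts)) {
    expect_gte(s3$mean[[f]], 0)
    expect_lte(s3$mean[[f]], full_counts[[f]])
  }
  expect_error(subsample_matched(w$alignments, calls_b, mapped + 1,
                                 g$te_library, cfg, seed = 1),
               "exceeds")
})
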