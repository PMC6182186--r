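mk_rec <- function(qname, flag, rname, pos, cigar, seq,
                   rnext = NA_character_, pnext = 0L) {
  data.table::data.table(
    qname = qname, flag = as.integer(flag), rname = rname,
    pos = as.integer(pos), mapq = 60L, cigar = cigar, rnext = rnext,
    pnext = as.integer(pnext), tlen = 0L, seq = seq, score = 0)
}

test_that("evidence extraction: concordant pairs, CIGAR clips, OEA", {
  # fully mapped concordant pair: no evidence
  pair <- rbind(
    mk_rec("p1", 1 + 64 + 32 + 2, "cA", 100, "100M", strrep("A", 100)),
    mk_rec("p1", 1 + 128 + 16 + 2, "cA", 500, "100M", strrep("A", 100)))
  expect_equal(nrow(extract_evidence(pair)), 0)

  # 100 nt read with a 40 nt right soft clip
  sc <- mk_rec("s1", 1 + 64 + 32 + 2, "cA", 1000, "60M40S",
               paste0(strrep("G", 60), strrep("T", 40)))
  ev <- extract_evidence(sc)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "soft_clip")
  expect_equal(ev$anchor_pos, 1000L + 60L - 1L)
  expect_equal(ev$query_seq, strrep("T", 40))
  expect_equal(ev$clip_side, "right")
  # left clip: anchor just before the first mapped base
  sc2 <- mk_rec("s2", 1 + 64 + 32 + 2, "cA", 2000, "40S60M",
                paste0(strrep("T", 40), strrep("G", 60)))
  ev2 <- extract_evidence(sc2)
  expect_equal(ev2$anchor_pos, 1999L)
  expect_equal(ev2$clip_side, "left")

  # OEA pair: mapped forward anchor + unmapped mate
  oea <- rbind(
    mk_rec("o1", 1 + 64 + 8, "cA", 3000, "100M", strrep("C", 100)),
    mk_rec("o1", 1 + 128 + 4, NA_character_, NA, NA_character_,
           strrep("T", 100)))
  ev3 <- extract_evidence(oea)
  expect_equal(ev3$kind, "oea")
  expect_equal(ev3$anchor_pos, 3000L + 99L)
  expect_equal(ev3$anchor_strand, "+")
  expect_equal(ev3$query_seq, strrep("T", 100))
  expect_warning(extract_evidence(mk_rec("x", 0, "cA", 1, "50M",
                                         strrep("A", 50))),
                 "single-end")
})

test_that("clustering boundaries, chaining, and min_support", {
  mk_ev <- function(pos) data.table::data.table(
    kind = "soft_clip", contig = "cA", anchor_pos = as.integer(pos),
    anchor_strand = "+", query_seq = strrep("A", 30), clip_side = "right",
    qname = paste0("q", seq_along(pos)))
  w <- 100L
  # window boundary: gap of window+1 splits
  cl <- cluster_evidence(mk_ev(c(100, 100 + w + 1L)),
                         cluster_window = w, min_support = 1L)
  expect_equal(length(unique(cl$cluster_id)), 2)
  cl0 <- cluster_evidence(mk_ev(c(100, 100 + w)),
                          cluster_window = w, min_support = 1L)
  expect_equal(length(unique(cl0$cluster_id)), 1)
  # chaining: 100,150,180 with window 100 is one cluster
  cl2 <- cluster_evidence(mk_ev(c(100, 150, 180)), cluster_window = w,
                          min_support = 1L)
  expect_equal(length(unique(cl2$cluster_id)), 1)
  # min_support drops singletons
  cl3 <- cluster_evidence(mk_ev(c(100, 150, 5000)), cluster_window = w,
                          min_support = 2L)
  expect_false(5000 %in% cl3$anchor_pos)
})

test_that("clustering equals brute-force single linkage on random anchors", {
  set.seed(99)
  n <- 200
  ev <- data.table::data.table(
    kind = "oea", contig = sample(c("cA", "cB"), n, TRUE),
    anchor_pos = sample.int(50000L, n, replace = TRUE),
    anchor_strand = "+", query_seq = strrep("A", 30),
    clip_side = NA_character_, qname = paste0("q", 1:n))
  w <- 300L
  got <- cluster_evidence(ev, cluster_window = w, min_support = 1L)
  want <- oracle_single_linkage(got$contig, got$anchor_pos, w)
  # same partition: cluster ids must be a relabeling of the oracle's
  expect_equal(length(unique(got$cluster_id)), length(unique(want)))
  tab <- table(got$cluster_id, want)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("TE-end matching: exact hits, random queries, ties", {
  g <- small_genome()
  lib <- te_end_library(g$te_library, end_len = 600L, effective_cap = 500L)
  # families are 1200-1500 nt: every family contributes 5' and 3' entries
  expect_true(all(table(lib$family) == 2))
  expect_equal(unique(nchar(lib$seq)), 500L)
  mk_cl <- function(seqs, cid = 1L) data.table::data.table(
    kind = "soft_clip", contig = "cA", anchor_pos = 100L,
    anchor_strand = "+", query_seq = seqs, clip_side = "right",
    qname = paste0("q", seq_along(seqs)), cluster_id = cid)

  # exact 30 nt prefix of the ZAMx 5' end: score 30, identity 100%
  q <- substr(g$te_library[["ZAMx"]], 1, 30)
  m <- match_te_ends(mk_cl(q), lib)
  expect_equal(m$family, "ZAMx")
  expect_equal(m$best_score, 30)
  expect_equal(m$identity, 1)
  expect_equal(m$te_end, "5p")
  expect_true(m$assigned)
  # reverse-complement query assigns identically
  m2 <- match_te_ends(mk_cl(revcomp(q)), lib)
  expect_equal(m2$family, "ZAMx")
  expect_true(m2$assigned)

  # random 30-mers: local score against the library stays far below 30
  # and never reaches 90% identity over >= 20 nt (oracle: the exhaustive
  # aligner itself, on sequences provably absent from the library)
  set.seed(7)
  rnd <- vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  }, "")
  rnd <- rnd[!vapply(rnd, function(s) {
    any(grepl(s, lib$seq, fixed = TRUE))
  }, logical(1))]
  mr <- match_te_ends(mk_cl(rnd), lib)
  expect_false(mr$assigned)

  # tie between two families: ambiguous, not assigned
  lib2 <- data.table::copy(lib)
  lib2$seq[lib2$family == "GTWx" & lib2$end == "5p"] <-
    lib$seq[lib$family == "ZAMx" & lib$end == "5p"]
  mt <- match_te_ends(mk_cl(q), lib2)
  expect_true(mt$ambiguous)
  expect_false(mt$assigned)
  expect_error(match_te_ends(mk_cl(q), lib[0]), "empty")
})

test_that("breakpoint definition: mode, majority, OEA inner edge", {
  asg <- data.table::data.table(
    cluster_id = 1L, family = "ZAMx", te_end = "5p", best_score = 30,
    identity = 1, mean_match_score = 30, ambiguous = FALSE, assigned = TRUE)
  mk_ev <- function(pos, kind = "soft_clip", strand = "+") {
    data.table::data.table(
      kind = kind, contig = "cA", anchor_pos = as.integer(pos),
      anchor_strand = strand, query_seq = strrep("A", 30),
      clip_side = ifelse(kind == "soft_clip", "right", NA_character_),
      qname = paste0("q", seq_along(pos)), cluster_id = 1L)
  }
  # all clips at one position
  c1 <- call_breakpoints(mk_ev(rep(10000L, 5)), asg)
  expect_equal(c1$breakpoint, 10000L)
  # majority vote
  c2 <- call_breakpoints(mk_ev(c(9998L, rep(10000L, 4))), asg)
  expect_equal(c2$breakpoint, 10000L)
  expect_equal(c2$support_sc, 5L)
  # OEA-only cluster: midpoint between innermost forward/reverse anchors
  ev3 <- rbind(mk_ev(c(9900L, 9950L), kind = "oea", strand = "+"),
               mk_ev(c(10050L, 10100L), kind = "oea", strand = "-"))
  ev3$qname <- paste0("q", 1:4)
  c3 <- call_breakpoints(ev3, asg)
  expect_equal(c3$breakpoint, 10000L)
  expect_equal(c3$support_oea, 4L)
})

test_that("full caller recovers planted insertions on the small genome", {
  g <- small_genome()
  ins <- plant_insertions(g, c("ZAMx", "GTWx", "CTRLx"), 3, seed = 5,
                          min_gap = 3000L)
  tr <- truth_table(g, planted_insertions = ins, chimera_rate = 0)
  w <- simulate_wgs_library(g, tr, coverage = 25, seed = 6)
  calls <- call_insertions(w$alignments, g$te_library)
  expect_equal(nrow(calls), 3)
  m <- merge(calls, ins, by = c("family", "contig"))
  expect_equal(nrow(m), 3)
  expect_true(all(abs(m$breakpoint - m$pos) <= 20))
})
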