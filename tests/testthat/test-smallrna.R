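test_that("trim_and_select enforces boundaries and strips linkers", {
  cfg <- classifier_config()
  reads <- c(strrep("A", 17), strrep("C", 18), strrep("G", 30),
             strrep("T", 31))
  kept <- trim_and_select(reads, cfg)
  expect_equal(nchar(kept), c(18L, 30L))
  expect_equal(attr(kept, "discarded"), c(too_short = 1L, too_long = 1L))

  with_linker <- paste0(strrep("ACGTA", 5), "TGGAATTCTC")  # 25 nt + linker
  out <- trim_and_select(with_linker, cfg, linker = "TGGAATTCTC")
  expect_equal(nchar(out), 25L)
  expect_equal(as.character(out), strrep("ACGTA", 5))

  expect_warning(trim_and_select(character(0), cfg), "empty")

  # recount: retained mass equals histogram mass on [18,30]
  set.seed(1)
  lens <- sample(15:34, 10000, replace = TRUE)
  reads <- vapply(lens, function(n) strrep("A", n), "")
  kept <- trim_and_select(reads, cfg)
  expect_equal(length(kept), sum(lens >= 18 & lens <= 30))
})

test_that("annotate excludes rRNA/miRNA reads and gets strand logic right", {
  g <- small_genome()
  rr <- g$features[g$features$class == "rRNA"][1]
  zam <- g$te_copies[g$te_copies$family == "ZAMx"][1]
  mk <- function(qname, rname, pos, len, rev) data.table::data.table(
    qname = qname, flag = if (rev) 16L else 0L, rname = rname,
    pos = as.integer(pos), mapq = 255L, cigar = paste0(len, "M"),
    rnext = NA_character_, pnext = 0L, tlen = 0L,
    seq = substr(g$contigs[[rname]], pos, pos + len - 1L), score = 0)
  aln <- rbind(
    mk("in_rrna", rr$contig, rr$start + 10L, 25L, FALSE),
    mk("as_zam", zam$contig, zam$start + 100L, 25L, zam$strand == "+"))
  ann <- annotate(aln, g)
  expect_true(ann$reads[ann$reads$qname == "in_rrna"]$excluded)
  lab <- ann$labels[ann$labels$qname == "as_zam" &
                      ann$labels$category == "TE"]
  expect_equal(lab$label, "ZAMx")
  expect_equal(lab$orientation, "antisense")
  bad <- mk("x", rr$contig, rr$start, 20L, FALSE)
  bad$rname <- "nope"
  expect_error(annotate(bad, g), "reference")
})

test_that("classification size rules and canonical re-assignment", {
  g <- small_genome()
  prof <- data.frame(source_id = "ZAMx",
                     size = c(21L, 22L, 23L, 25L, 30L),
                     strand = "antisense", count = 10)
  sim <- simulate_smallrna_library(g, truth_table(g, smallrna_profile = prof),
                                   seed = 23)
  cl <- classify(annotate(sim$alignments, g), g)
  by_class <- table(cl$candidates$class, cl$candidates$size)
  expect_equal(sum(by_class["siRNA", ]), 10)      # the 21-mers
  expect_equal(unname(by_class["other", "22"]), 10)  # gap size: neither
  expect_equal(sum(by_class["piRNA", ]), 30)      # 23, 25, 30
  # per-class totals equal profile sums over [23,30] and {21}
  expect_equal(sum(cl$candidates$class == "piRNA"),
               sum(prof$count[prof$size >= 23 & prof$size <= 30]))
  expect_equal(sum(cl$candidates$class == "siRNA"),
               sum(prof$count[prof$size == 21]))
})

test_that("count_and_normalize: arithmetic, 1/k conservation, invariance", {
  g <- small_genome()
  prof <- data.frame(
    source_id = rep(c("ZAMx", "GTWx", "cluster1"), each = 2),
    size = rep(c(25L, 26L), 3),
    strand = "antisense", count = c(30, 20, 10, 40, 50, 50))
  sim <- simulate_smallrna_library(g, truth_table(g, smallrna_profile = prof),
                                   seed = 29)
  ann <- annotate(sim$alignments, g)
  cl <- classify(ann, g)
  c1 <- cluster_unique_count(ann)
  expect_equal(c1, 100)  # all cluster1 reads unique at zero divergence
  tab <- count_and_normalize(cl, c1, scale = 1000)
  # trivial arithmetic: raw * scale / c1
  expect_equal(tab$normalized, tab$raw * 1000 / c1)
  # conservation: fractional counts sum to TE-assigned candidate reads
  n_te_cand <- length(unique(
    cl$assignments[cl$assignments$ref_type == "TE"]$qname))
  expect_equal(sum(tab$raw), n_te_cand, tolerance = 1e-6)
  # depth invariance: doubling every profile count leaves normalized as-is
  prof2 <- prof; prof2$count <- prof2$count * 2
  sim2 <- simulate_smallrna_library(
    g, truth_table(g, smallrna_profile = prof2), seed = 29)
  ann2 <- annotate(sim2$alignments, g)
  cl2 <- classify(ann2, g)
  tab2 <- count_and_normalize(cl2, cluster_unique_count(ann2), scale = 1000)
  m <- merge(tab, tab2, by = c("family", "orientation"))
  expect_equal(m$normalized.x, m$normalized.y, tolerance = 1e-9)
  # zero normalizer is an explicit error
  expect_error(count_and_normalize(cl, 0), "normalization")
})

test_that("fractional 1/k split across ex-aequo families conserves mass", {
  # two families sharing identical sequence: every read ties 2 ways
  set.seed(5)
  shared <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  cfg <- small_genome_config()
  cfg$te_families <- c(ZAMx = shared, GTWx = shared, CTRLx = other)
  g <- build_toy_genome(cfg, seed = 42)
  prof <- data.frame(source_id = "ZAMx", size = 25L, strand = "antisense",
                     count = 40)
  sim <- simulate_smallrna_library(g, truth_table(g, smallrna_profile = prof),
                                   seed = 31)
  cl <- classify(annotate(sim$alignments, g), g)
  expect_true(all(cl$assignments[cl$assignments$ref_type == "TE"]$k == 2))
  tab <- count_and_normalize(cl, 100)
  expect_equal(sort(unique(tab$family)), c("GTWx", "ZAMx"))
  expect_equal(tab$raw, c(20, 20))      # +0.5 each per read
  expect_equal(sum(tab$raw), 40, tolerance = 1e-6)
})

test_that("size distribution conserves totals and recovers bimodal peaks", {
  g <- small_genome()
  prof <- data.frame(source_id = "ZAMx",
                     size = c(21L, 21L, 26L, 26L),
                     strand = rep(c("sense", "antisense"), 2),
                     count = c(50, 80, 30, 120))
  sim <- simulate_smallrna_library(g, truth_table(g, smallrna_profile = prof),
                                   seed = 37)
  cl <- classify(annotate(sim$alignments, g), g)
  sd_ <- size_distribution(cl, "ZAMx")
  expect_equal(nrow(sd_), 13)
  expect_equal(sum(sd_$sense) + sum(sd_$antisense), sum(prof$count))
  expect_equal(sd_$antisense[sd_$size == 21], 80)
  expect_equal(sd_$antisense[sd_$size == 26], 120)
  expect_equal(sd_$size[which.max(sd_$antisense)], 26)
  expect_error(size_distribution(cl, "NOPE"), "unknown")
})

test_that("first-nt fractions sum to one and match enforced composition", {
  g <- small_genome()
  prof <- data.frame(source_id = "ZAMx", size = c(21L, 25L),
                     strand = "sense", count = c(1500, 500),
                     p5a = c(0.6, NA))
  sim <- simulate_smallrna_library(g, truth_table(g, smallrna_profile = prof),
                                   seed = 41)
  cl <- classify(annotate(sim$alignments, g), g)
  fb <- first_nt_bias(cl)
  sums <- tapply(fb$fraction, fb$class, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  a21 <- fb$fraction[fb$class == "siRNA" & fb$nt == "A"]
  ci <- qnorm(0.995) * sqrt(0.6 * 0.4 / 1500)
  expect_gt(a21, 0.6 - ci)
  expect_lt(a21, 0.6 + ci)
  empty <- classify(annotate(alignment_records(), g), g)
  expect_error(first_nt_bias(empty), "undefined")
})

test_that("fold changes and Spearman correlation behave", {
  mk <- function(norm) {
    data.table::data.table(family = names(norm), orientation = "antisense",
                           raw = 1, normalized = unname(norm))
  }
  a <- mk(c(ZAMx = 8, GTWx = 2))
  b <- mk(c(ZAMx = 2, GTWx = 2))
  fc0 <- fold_change(a, b, pseudocount = 0)
  expect_equal(fc0[fc0$family == "ZAMx"]$log2fc, 2)
  expect_equal(fc0[fc0$family == "GTWx"]$log2fc, 0)
  # a family absent from one table is zero-filled and flagged
  a2 <- mk(c(ZAMx = 8))
  fc1 <- fold_change(a2, b, pseudocount = 1)
  expect_true(fc1[fc1$family == "GTWx"]$flagged)
  expect_equal(fc1[fc1$family == "GTWx"]$fc, 1 / 3)
  # anti-monotone vectors: rho = -1
  expect_equal(spearman_fc(c(1, 2, 3, 4, 5), c(10, 8, 6, 4, 2)), -1)
})
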