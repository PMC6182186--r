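## Mobilome-seq simulator: reads from rolling-circle-amplified eccDNA
## (sampled from TE consensus sequences proportionally to planted circle
## abundance) plus mitochondrial background (mtDNA is circular and survives
## the linear-DNA removal step, and is the normalization denominator) and a
## small residual linear genomic background. Mates are counted as
## independent reads downstream, so records are emitted single-end.

#' Simulate a mobilome-seq library
#'
#' @param genome a `ToyGenome`.
#' @param truth a `TruthTable`; `planted_circles` gives per-family relative
#'   eccDNA abundance, `mobilome_mt_weight` and `mobilome_bg_weight` the
#'   relative weight of mtDNA and residual linear background reads.
#' @param n_reads total reads drawn (multinomial over circle families,
#'   mtDNA and background).
#' @param read_len read length (default 250 nt).
#' @param seed integer seed.
#' @return list with class `mobilome_sim`: `reads` (qname, origin) and
#'   `alignments`. Circle reads carry one best-score alignment on the
#'   canonical TE contig (rname = family) plus ex-aequo alignments on each
#'   genomic copy; mtDNA and background reads map on the genome.
#' @export
simulate_mobilome_library <- function(genome, truth, n_reads, seed = 1L,
                                      read_len = 250L) {
  stopifnot(inherits(genome, "ToyGenome"), inherits(truth, "TruthTable"))
  circ <- truth$planted_circles
  if (nrow(circ) > 0L && !all(circ$family %in% names(genome$te_library))) {
    stop("planted circle references unknown family", call. = FALSE)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  sources <- data.table::data.table(
    origin = c(circ$family, ".mt", ".bg"),
    w = c(circ$count, truth$mobilome_mt_weight, truth$mobilome_bg_weight)
  )
  sources <- sources[w > 0]
  if (nrow(sources) == 0L) stop("no read sources with positive weight",
                                call. = FALSE)
  counts <- as.vector(stats::rmultinom(1L, n_reads, prob = sources$w))

  recs <- list(); reads <- list(); ridx <- 0L
  for (i in seq_len(nrow(sources))) {
    k <- counts[i]
    if (k == 0L) next
    org <- sources$origin[i]
    qn <- sprintf("mb%07d", ridx + seq_len(k)); ridx <- ridx + k
    if (org == ".mt") {
      ct <- genome$mt_contig
      L <- nchar(genome$contigs[[ct]])
      s <- sample.int(L - read_len + 1L, k, replace = TRUE)
      recs[[length(recs) + 1L]] <- data.table::data.table(
        qname = qn, flag = 0L, rname = ct, pos = s, mapq = 60L,
        cigar = paste0(read_len, "M"), rnext = NA_character_, pnext = 0L,
        tlen = 0L,
        seq = substring(genome$contigs[[ct]], s, s + read_len - 1L),
        score = 0)
    } else if (org == ".bg") {
      # residual linear DNA sampled outside TE copies
      recs[[length(recs) + 1L]] <- background_reads(genome, qn, read_len)
    } else {
      cons <- genome$te_library[[org]]
      L <- nchar(cons)
      if (L < read_len) stop("TE consensus shorter than read length",
                             call. = FALSE)
      s <- sample.int(L - read_len + 1L, k, replace = TRUE)
      rev <- runif(k) < 0.5
      sq <- substring(cons, s, s + read_len - 1L)
      # canonical-TE alignment (the re-mapping reference for counting)
      can <- data.table::data.table(
        qname = qn, flag = ifelse(rev, FLAG_REVERSE, 0L), rname = org,
        pos = s, mapq = 255L, cigar = paste0(read_len, "M"),
        rnext = NA_character_, pnext = 0L, tlen = 0L, seq = sq, score = 0)
      # ex-aequo genomic alignments on each embedded copy
      gen <- smallrna_like_copies(genome, org, s, read_len, qn, sq, rev)
      recs[[length(recs) + 1L]] <- data.table::rbindlist(list(can, gen))
    }
    reads[[length(reads) + 1L]] <- data.table::data.table(qname = qn,
                                                          origin = org)
  }
  aln <- data.table::rbindlist(recs)
  aln[, flag := flag + FLAG_SECONDARY * as.integer(duplicated(qname))]
  aln <- mark_best_alignments(aln)
  structure(list(reads = data.table::rbindlist(reads), alignments = aln),
            class = "mobilome_sim")
}

background_reads <- function(genome, qn, read_len) {
  k <- length(qn)
  cts <- setdiff(names(genome$contigs), genome$mt_contig)
  lens <- vapply(genome$contigs[cts], nchar, 0L)
  out <- data.table::data.table(
    qname = qn, flag = 0L, rname = NA_character_, pos = NA_integer_,
    mapq = 60L, cigar = paste0(read_len, "M"), rnext = NA_character_,
    pnext = 0L, tlen = 0L, seq = NA_character_, score = 0)
  for (i in seq_len(k)) {
    repeat {
      ct <- sample(cts, 1L, prob = lens)
      s <- sample.int(lens[[ct]] - read_len + 1L, 1L)
      hit <- genome$te_copies[contig == ct & s <= end & s + read_len - 1L >= start]
      if (nrow(hit) == 0L) break
    }
    out[i, `:=`(rname = ct, pos = s,
                seq = substring(genome$contigs[[ct]], s, s + read_len - 1L))]
  }
  out
}

# genomic alignments of a consensus-derived read on every embedded copy
smallrna_like_copies <- function(genome, fam, s, read_len, qn, sq, rev) {
  copies <- genome$te_copies[family == fam]
  L <- nchar(genome$te_library[[fam]])
  out <- list()
  for (j in seq_len(nrow(copies))) {
    cp <- copies[j]
    if (cp$strand == "+") {
      gpos <- cp$start + s - 1L
      r <- rev
    } else {
      gpos <- cp$start + (L - (s + read_len - 1L))
      r <- !rev
    }
    fwd <- ifelse(r == rev, sq, revcomp(sq))
    gseq <- substring(genome$contigs[[cp$contig]], gpos,
                      gpos + read_len - 1L)
    mm <- ifelse(gseq == fwd, 0L, hamming(gseq, fwd))
    out[[j]] <- data.table::data.table(
      qname = qn, flag = ifelse(r, FLAG_REVERSE, 0L), rname = cp$contig,
      pos = gpos, mapq = 255L, cigar = paste0(read_len, "M"),
      rnext = NA_character_, pnext = 0L, tlen = 0L, seq = fwd,
      score = -6 * mm)
  }
  data.table::rbindlist(out)
}
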