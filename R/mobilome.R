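## Mobilome-seq (eccDNA) quantification: best-score TE-read assignment,
## canonical-TE re-mapping with a score floor (alignments scoring strictly
## below -10 discarded under the 0-is-perfect convention), ex-aequo 1/k
## down-weighting, and normalization per thousand mtDNA reads.

#' Mobilome quantification configuration
#'
#' @param score_floor alignments with score strictly lower than this are
#'   discarded (default -10; 0 = perfect match, negative penalties).
#' @param norm_per normalization unit (default 1000: reads per thousand
#'   mtDNA reads, the stated unit).
#' @param weighting multi-mapper down-weighting strategy; `"uniform"`
#'   splits 1/k across ex-aequo best assignments. The interface is
#'   swappable: pass a function(k, scores) returning weights summing to 1.
#' @return a `mobilome_config` list.
#' @export
mobilome_config <- function(score_floor = -10, norm_per = 1000,
                            weighting = "uniform") {
  if (score_floor > 0) stop("score_floor must be <= 0 under the 0-is-perfect",
                            " convention", call. = FALSE)
  structure(list(score_floor = score_floor, norm_per = norm_per,
                 weighting = weighting), class = "mobilome_config")
}

#' Select TE reads by best-score location
#'
#' A read is retained iff at least one of its best-score alignments falls
#' either inside a genomic TE copy or on a canonical TE contig.
#'
#' @param alignments alignment records (scores required).
#' @param genome a `ToyGenome` (TE copy intervals; canonical contig names
#'   are the TE library names).
#' @return the subset of `alignments` belonging to retained reads.
#' @export
assign_te_reads <- function(alignments, genome) {
  aln <- data.table::as.data.table(alignments)
  if (any(is.na(aln$score[aln_is_mapped(aln)]))) {
    stop("format error: missing alignment score", call. = FALSE)
  }
  aln <- mark_best_alignments(aln)
  best <- aln[is_best == TRUE]
  canon <- best$rname %in% names(genome$te_library)
  in_copy <- rep(FALSE, nrow(best))
  gen <- which(!canon)
  if (length(gen) > 0L) {
    seqlv <- names(genome$contigs)
    gr <- GenomicRanges::GRanges(
      factor(best$rname[gen], levels = seqlv),
      IRanges::IRanges(best$pos[gen], width = cigar_ref_len(best$cigar[gen])))
    hits <- GenomicRanges::findOverlaps(
      gr, granges_of(genome$te_copies, seqlevels = seqlv))
    in_copy[gen[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  te_qnames <- unique(best$qname[canon | in_copy])
  aln[qname %in% te_qnames]
}

#' Weighted per-family counts from canonical-TE alignments
#'
#' Restricted to canonical-TE alignments (the re-mapping reference),
#' alignments scoring strictly below the floor are discarded; a read with k
#' surviving ex-aequo best-score family assignments contributes 1/k to
#' each. Reads with no surviving alignment are dropped and counted in the
#' `dropped` attribute.
#'
#' @param te_reads alignment records of TE reads (e.g. from
#'   [assign_te_reads()]); only canonical-TE rows are used.
#' @param genome a `ToyGenome` (canonical family names).
#' @param cfg a [mobilome_config()].
#' @return data.table (family, weight) whose weights sum to the number of
#'   retained reads; attributes `retained` and `dropped`.
#' @export
family_counts <- function(te_reads, genome, cfg = mobilome_config()) {
  aln <- data.table::as.data.table(te_reads)
  all_q <- unique(aln$qname)
  can <- aln[rname %in% names(genome$te_library)]
  can <- can[!is.na(score) & score >= cfg$score_floor]
  can <- mark_best_alignments(can)
  can <- can[is_best == TRUE]
  # one assignment per (read, family): ex-aequo locations within the same
  # canonical sequence collapse before down-weighting
  asg <- unique(can[, .(qname, family = rname)])
  asg[, k := .N, by = qname]
  out <- asg[, .(weight = sum(1 / k)), by = family]
  data.table::setattr(out, "retained", length(unique(asg$qname)))
  data.table::setattr(out, "dropped",
                      length(setdiff(all_q, asg$qname)))
  out[]
}

#' Count mtDNA-mapped reads
#'
#' All primary mt-mapped reads count (the normalizer is taken before any
#' score filtering).
#'
#' @param alignments alignment records of the whole library.
#' @param genome a `ToyGenome` (its `mt_contig`).
#' @return integer read count.
#' @export
mt_read_count <- function(alignments, genome) {
  aln <- data.table::as.data.table(alignments)
  nrow(aln[aln_is_mapped(aln) & aln_is_primary(aln) &
             rname == genome$mt_contig])
}

#' Normalize per-family counts by mtDNA reads
#'
#' `normalized = weight * norm_per / mt_reads` (default per thousand mtDNA
#' reads).
#'
#' @param counts [family_counts()] output.
#' @param mt_reads mtDNA read count (> 0).
#' @param cfg a [mobilome_config()].
#' @return the counts table with a `normalized` column.
#' @export
normalize_mt <- function(counts, mt_reads, cfg = mobilome_config()) {
  if (!is.numeric(mt_reads) || mt_reads <= 0) {
    stop("normalization error: mt_reads must be > 0", call. = FALSE)
  }
  out <- data.table::as.data.table(counts)
  out[, normalized := weight * cfg$norm_per / mt_reads]
  out[]
}

#' Compare normalized mobilome counts between two conditions
#'
#' @param norm_a,norm_b [normalize_mt()] outputs for the two conditions.
#' @param fold_threshold families whose fold (a vs b, computed where the
#'   denominator is positive) reaches the threshold are flagged.
#' @return data.table (family, norm_a, norm_b, fold, flagged); families
#'   absent from both are present with zeros and never flagged.
#' @export
compare_conditions <- function(norm_a, norm_b, fold_threshold = 2) {
  a <- data.table::as.data.table(norm_a)[, .(family, norm_a = normalized)]
  b <- data.table::as.data.table(norm_b)[, .(family, norm_b = normalized)]
  m <- merge(a, b, by = "family", all = TRUE)
  m[is.na(norm_a), norm_a := 0]
  m[is.na(norm_b), norm_b := 0]
  m[, fold := data.table::fifelse(norm_b > 0, norm_a / norm_b,
                                  data.table::fifelse(norm_a > 0, Inf,
                                                      NA_real_))]
  m[, flagged := !is.na(fold) & fold >= fold_threshold]
  m[]
}

#' One-call mobilome quantification
#'
#' Convenience wrapper: TE-read assignment, score-floor filtered canonical
#' counting, mtDNA normalization.
#'
#' @param alignments library alignment records.
#' @param genome a `ToyGenome`.
#' @param cfg a [mobilome_config()].
#' @return normalized per-family table (family, weight, normalized).
#' @export
quantify_mobilome <- function(alignments, genome, cfg = mobilome_config()) {
  te <- assign_te_reads(alignments, genome)
  counts <- family_counts(te, genome, cfg)
  normalize_mt(counts, mt_read_count(alignments, genome), cfg)
}
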