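## Small-RNA library simulator: emits 18-30 nt reads drawn from TE family
## consensus sequences and cluster loci according to a truth profile, and
## writes the alignment records directly (no external aligner). A read from
## a family appears once per embedded genomic copy of that family, which is
## exactly how multi-mapping arises in the real libraries.

#' Simulate a small-RNA library with known truth labels
#'
#' Reads are exact substrings of the source sequence (TE family consensus or
#' cluster locus); `antisense` reads are reverse complements. Alignment
#' records are emitted for every genomic embedding of the source, with
#' score 0 for a perfect match and -6 per mismatch (Bowtie2-like
#' end-to-end convention), so best-score and unique-mapper semantics are
#' faithful. The optional profile column `p5a` controls the fraction of
#' reads whose 5' nucleotide is A (drawn per read, Bernoulli), implemented
#' by conditioning the sampled start positions -- reads remain exact
#' substrings.
#'
#' @param genome a `ToyGenome`.
#' @param truth a `TruthTable` whose `smallrna_profile` is non-empty.
#' @param n_reads optional total library size; if `NULL` (default) each
#'   profile row emits exactly `count` reads, otherwise `n_reads` reads are
#'   drawn multinomially with probabilities proportional to `count`.
#' @param seed integer seed.
#' @return list with class `smallrna_sim`: `reads` (qname, seq, size,
#'   source_id, strand, first_nt) and `alignments` (alignment records with
#'   `n_best`/`is_best` columns).
#' @export
simulate_smallrna_library <- function(genome, truth, n_reads = NULL,
                                      seed = 1L) {
  stopifnot(inherits(genome, "ToyGenome"), inherits(truth, "TruthTable"))
  prof <- data.table::copy(truth$smallrna_profile)
  if (nrow(prof) == 0L) stop("smallrna_profile is empty", call. = FALSE)
  if (any(prof$size < 18L | prof$size > 30L)) {
    stop("profile sizes must be within 18-30 nt", call. = FALSE)
  }
  known <- c(names(genome$te_library), genome$clusters$id)
  bad <- setdiff(prof$source_id, known)
  if (length(bad) > 0L) {
    stop("unknown family/cluster in profile: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  if (!is.null(n_reads)) {
    prof[, count := as.vector(stats::rmultinom(1L, n_reads,
                                               prob = prof$count))]
  } else {
    prof[, count := as.integer(round(count))]
  }
  prof <- prof[count > 0L]

  # source sequences and their genomic embeddings
  src_seq <- function(id) {
    if (id %in% names(genome$te_library)) genome$te_library[[id]]
    else cluster_sequence(genome, id)
  }

  reads_list <- list()
  aln_list <- list()
  ridx <- 0L
  for (i in seq_len(nrow(prof))) {
    row <- prof[i]
    cons <- src_seq(row$source_id)
    L <- nchar(cons)
    sz <- row$size
    if (L < sz) stop("source shorter than read size", call. = FALSE)
    base <- strsplit(cons, "", fixed = TRUE)[[1]]
    starts_all <- seq_len(L - sz + 1L)
    # 5' base of a read starting at s: sense = base[s]; antisense =
    # complement of base[s + sz - 1]
    five <- if (row$strand == "sense") {
      base[starts_all]
    } else {
      c(A = "T", C = "G", G = "C", T = "A")[base[starts_all + sz - 1L]]
    }
    if (!is.na(row$p5a)) {
      isA <- five == "A"
      nA <- rbinom(1L, row$count, row$p5a)
      pool_a <- starts_all[isA]
      pool_o <- starts_all[!isA]
      if (length(pool_a) == 0L || length(pool_o) == 0L) {
        stop("cannot enforce 5'-A fraction: degenerate source composition",
             call. = FALSE)
      }
      starts <- c(sample(pool_a, nA, replace = TRUE),
                  sample(pool_o, row$count - nA, replace = TRUE))
      starts <- sample(starts)  # shuffle order
    } else {
      starts <- sample(starts_all, row$count, replace = TRUE)
    }
    rseq <- substring(cons, starts, starts + sz - 1L)
    if (row$strand == "antisense") rseq <- revcomp(rseq)
    qn <- sprintf("sr%07d", ridx + seq_along(starts))
    ridx <- ridx + length(starts)
    reads_list[[i]] <- data.table::data.table(
      qname = qn, seq = rseq, size = sz, source_id = row$source_id,
      strand = row$strand, first_nt = substr(rseq, 1L, 1L)
    )
    aln_list[[i]] <- smallrna_alignments(genome, row$source_id, row$strand,
                                         starts, sz, qn, rseq)
  }
  reads <- data.table::rbindlist(reads_list)
  aln <- data.table::rbindlist(aln_list)
  # primary/secondary flags: first alignment of each read is primary
  aln[, flag := flag + FLAG_SECONDARY * as.integer(duplicated(qname))]
  aln <- mark_best_alignments(aln)
  structure(list(reads = reads, alignments = aln), class = "smallrna_sim")
}

# Alignment records for reads drawn from consensus offsets `starts`
# (1-based, length `sz`) of one source on a given source strand.
smallrna_alignments <- function(genome, source_id, strand, starts, sz,
                                qn, rseq) {
  recs <- list()
  if (source_id %in% names(genome$te_library)) {
    copies <- genome$te_copies[family == source_id]
    L <- nchar(genome$te_library[[source_id]])
    for (j in seq_len(nrow(copies))) {
      cp <- copies[j]
      if (cp$strand == "+") {
        gpos <- cp$start + starts - 1L
        rev <- strand == "antisense"
      } else {
        gpos <- cp$start + (L - (starts + sz - 1L))
        rev <- strand == "sense"
      }
      gseq <- substring(genome$contigs[[cp$contig]], gpos, gpos + sz - 1L)
      fwd_read <- if (rev) revcomp(rseq) else rseq
      mm <- if (identical(gseq, fwd_read)) {
        integer(length(gpos))
      } else {
        hamming(gseq, fwd_read)
      }
      recs[[length(recs) + 1L]] <- data.table::data.table(
        qname = qn, flag = ifelse(rev, FLAG_REVERSE, 0L),
        rname = cp$contig, pos = gpos, mapq = 255L,
        cigar = paste0(sz, "M"), rnext = NA_character_, pnext = 0L,
        tlen = 0L, seq = fwd_read, score = -6 * mm
      )
    }
  } else {
    cl <- genome$clusters[genome$clusters$id == source_id, ]
    rev <- strand == "antisense"
    gpos <- cl$start + starts - 1L
    fwd_read <- if (rev) revcomp(rseq) else rseq
    recs[[1L]] <- data.table::data.table(
      qname = qn, flag = if (rev) FLAG_REVERSE else 0L,
      rname = cl$contig, pos = gpos, mapq = 255L,
      cigar = paste0(sz, "M"), rnext = NA_character_, pnext = 0L,
      tlen = 0L, seq = fwd_read, score = 0
    )
  }
  data.table::rbindlist(recs)
}
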