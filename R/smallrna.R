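## Small-RNA classification and counting: size selection (18-30 nt),
## annotation against clusters / TEs / 3'UTRs with rRNA/miRNA exclusion,
## piRNA (23-30 nt) and siRNA (21 nt) candidate definition, canonical-TE
## re-assignment with fractional multi-mapper counting, cluster-1
## unique-mapper normalization, size distributions, 5' nucleotide bias and
## fold changes.

#' Classifier configuration
#'
#' @param trim_min,trim_max retained read-length window after trimming
#'   (18-30 nt).
#' @param pirna_min,pirna_max piRNA candidate size window (23-30 nt).
#' @param sirna_len siRNA candidate size (21 nt).
#' @param excluded_classes feature classes whose reads are excluded
#'   outright.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(trim_min = 18L, trim_max = 30L,
                              pirna_min = 23L, pirna_max = 30L,
                              sirna_len = 21L,
                              excluded_classes = c("rRNA", "miRNA")) {
  stopifnot(trim_min <= pirna_min, pirna_min <= pirna_max,
            pirna_max <= trim_max,
            sirna_len >= trim_min, sirna_len <= trim_max)
  structure(list(trim_min = trim_min, trim_max = trim_max,
                 pirna_min = pirna_min, pirna_max = pirna_max,
                 sirna_len = sirna_len,
                 excluded_classes = excluded_classes),
            class = "classifier_config")
}

#' Trim 3' linkers and select reads by length
#'
#' @param seqs character vector of raw read sequences.
#' @param cfg a [classifier_config()].
#' @param linker optional 3' linker; the read is cut at its first
#'   occurrence.
#' @return retained sequences, with attribute `discarded`, a named count
#'   vector by reason (`too_short`, `too_long`).
#' @export
trim_and_select <- function(seqs, cfg = classifier_config(), linker = NULL) {
  if (length(seqs) == 0L) {
    warning("empty input read set", call. = FALSE)
    out <- character(0)
    attr(out, "discarded") <- c(too_short = 0L, too_long = 0L)
    return(out)
  }
  if (!is.null(linker)) {
    hit <- regexpr(linker, seqs, fixed = TRUE)
    cut <- hit > 0L
    seqs[cut] <- substr(seqs[cut], 1L, hit[cut] - 1L)
  }
  len <- nchar(seqs)
  keep <- len >= cfg$trim_min & len <= cfg$trim_max
  out <- seqs[keep]
  attr(out, "discarded") <- c(too_short = sum(len < cfg$trim_min),
                              too_long = sum(len > cfg$trim_max))
  out
}

#' Annotate small-RNA alignments against genome features
#'
#' Reads whose best-score alignments touch an excluded feature class
#' (rRNA/miRNA by default) are flagged excluded. Remaining reads are
#' labeled, non-exclusively, with every category their best alignments
#' overlap: piRNA/siRNA clusters, TE copies, and 3'UTRs. Orientation is
#' recorded relative to the annotated feature's strand (clusters are taken
#' as plus-strand loci). A read is a unique mapper iff exactly one
#' best-score genomic alignment exists.
#'
#' @param alignments alignment-record data.table (multi-alignments allowed;
#'   best-score bookkeeping is recomputed).
#' @param genome a `ToyGenome` providing the annotation intervals.
#' @param cfg a [classifier_config()].
#' @return list with class `smallrna_annotated`: `reads` (qname, seq --
#'   as sequenced --, size, first_nt, unique_mapper, excluded) and `labels`
#'   (qname, category, label, orientation).
#' @export
annotate <- function(alignments, genome, cfg = classifier_config()) {
  stopifnot(inherits(genome, "ToyGenome"))
  aln <- mark_best_alignments(data.table::as.data.table(alignments))
  aln <- aln[aln_is_mapped(aln)]
  if (nrow(aln) > 0L && !all(aln$rname %in% names(genome$contigs))) {
    stop("reference error: alignment contigs absent from genome annotation",
         call. = FALSE)
  }
  best <- aln[is_best == TRUE]
  # per-read record, from the primary alignment
  prim <- aln[!duplicated(qname)]
  raw_seq <- ifelse(aln_is_reverse(prim), revcomp(prim$seq), prim$seq)
  reads <- data.table::data.table(
    qname = prim$qname, seq = raw_seq, size = nchar(raw_seq),
    first_nt = substr(raw_seq, 1L, 1L),
    unique_mapper = prim$n_best == 1L, excluded = FALSE
  )

  seqlv <- names(genome$contigs)
  gr_best <- GenomicRanges::GRanges(
    factor(best$rname, levels = seqlv),
    IRanges::IRanges(best$pos, width = cigar_ref_len(best$cigar)),
    strand = ifelse(aln_is_reverse(best), "-", "+"))

  overlap_labels <- function(dt, category, label_col, strand_col = NULL) {
    if (nrow(dt) == 0L) {
      return(data.table::data.table(qname = character(),
                                    category = character(),
                                    label = character(),
                                    orientation = character()))
    }
    gr <- granges_of(dt, strand_col, seqlevels = seqlv)
    hits <- GenomicRanges::findOverlaps(gr_best, gr, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    fstrand <- if (is.null(strand_col)) rep("+", nrow(dt)) else dt[[strand_col]]
    rstrand <- ifelse(aln_is_reverse(best)[qi], "-", "+")
    unique(data.table::data.table(
      qname = best$qname[qi], category = category,
      label = dt[[label_col]][si],
      orientation = ifelse(rstrand == fstrand[si], "sense", "antisense")))
  }

  excl <- genome$features[class %in% cfg$excluded_classes]
  excl_lab <- overlap_labels(excl, "excluded", "class", "strand")
  reads[qname %in% excl_lab$qname, excluded := TRUE]

  labels <- data.table::rbindlist(list(
    overlap_labels(genome$clusters, "cluster", "id"),
    overlap_labels(genome$te_copies, "TE", "family", "strand"),
    overlap_labels(genome$features[class == "3UTR"], "3UTR", "class",
                   "strand")
  ))
  labels <- labels[!(qname %in% excl_lab$qname)]
  structure(list(reads = reads, labels = labels, cfg = cfg),
            class = "smallrna_annotated")
}

#' Classify annotated reads into piRNA and siRNA candidates and re-assign
#' them to canonical references
#'
#' Candidates are the non-excluded reads annotated to a cluster, TE or
#' 3'UTR: piRNA candidates are 23-30 nt, siRNA candidates 21 nt (disjoint
#' by construction). Every candidate is re-matched against the canonical TE
#' sequences and cluster sequences (exact substring on either strand); the
#' per-family counting downstream uses this canonical assignment, not the
#' genomic copy.
#'
#' @param annotated output of [annotate()].
#' @param genome a `ToyGenome` (canonical TE library + cluster sequences).
#' @param cfg a [classifier_config()].
#' @return list with class `smallrna_classified`: `candidates` (qname,
#'   size, first_nt, unique_mapper, class in \{piRNA, siRNA, other\}) and
#'   `assignments` (qname, ref_type in \{TE, cluster\}, ref_id,
#'   orientation, k = number of ex-aequo canonical TE assignments of the
#'   read).
#' @export
classify <- function(annotated, genome, cfg = classifier_config()) {
  stopifnot(inherits(annotated, "smallrna_annotated"))
  keep <- annotated$reads[excluded == FALSE &
                            qname %in% annotated$labels$qname]
  keep[, class := data.table::fifelse(
    size >= cfg$pirna_min & size <= cfg$pirna_max, "piRNA",
    data.table::fifelse(size == cfg$sirna_len, "siRNA", "other"))]

  refs <- c(genome$te_library,
            setNames(lapply(genome$clusters$id, cluster_sequence,
                            genome = genome), genome$clusters$id))
  ref_type <- c(rep("TE", length(genome$te_library)),
                rep("cluster", nrow(genome$clusters)))
  names(ref_type) <- names(refs)

  asg <- match_canonical(keep$seq, refs)
  if (nrow(asg) > 0L) {
    asg <- merge(asg, keep[, .(seq, qname)], by = "seq",
                 allow.cartesian = TRUE)
    asg[, ref_type := ref_type[ref_id]]
    asg[, k := sum(ref_type == "TE"), by = qname]
    asg <- asg[, .(qname, ref_type, ref_id, orientation, k)]
  } else {
    asg <- data.table::data.table(qname = character(), ref_type = character(),
                                  ref_id = character(),
                                  orientation = character(), k = integer())
  }
  structure(list(candidates = keep[, .(qname, size, first_nt,
                                       unique_mapper, class)],
                 assignments = asg, cfg = cfg),
            class = "smallrna_classified")
}

# exact-substring matching of reads against canonical reference sequences;
# forward hit = sense, reverse-complement hit = antisense
match_canonical <- function(seqs, refs) {
  empty <- data.table::data.table(seq = character(), ref_id = character(),
                                  orientation = character())
  useq <- unique(seqs)
  if (length(useq) == 0L) return(empty)
  subject <- Biostrings::DNAStringSet(unlist(refs))
  out <- list()
  # PDict needs constant width: query one width group at a time
  for (wd in unique(nchar(useq))) {
    sw <- useq[nchar(useq) == wd]
    hits_of <- function(patterns) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns))
      Biostrings::vcountPDict(pd, subject) > 0L  # patterns x refs
    }
    fwd <- hits_of(sw)
    rev <- hits_of(revcomp(sw))
    rev <- rev & !fwd  # a palindrome-ish double hit counts once, as sense
    add <- function(m, ori) {
      ij <- which(m, arr.ind = TRUE)
      if (nrow(ij) == 0L) return(NULL)
      data.table::data.table(seq = sw[ij[, 1L]],
                             ref_id = names(refs)[ij[, 2L]],
                             orientation = ori)
    }
    out[[length(out) + 1L]] <- add(fwd, "sense")
    out[[length(out) + 1L]] <- add(rev, "antisense")
  }
  out <- data.table::rbindlist(out)
  if (nrow(out) == 0L) return(empty)
  out
}

#' Count unique mappers of a cluster
#'
#' The cluster-1 flavour of this count (germline piRNA cluster, 42AB-like)
#' is the normalization denominator for all small-RNA tables.
#'
#' @param annotated output of [annotate()].
#' @param cluster_id cluster id (default `"cluster1"`).
#' @return integer count of non-excluded unique-mapper reads overlapping
#'   the cluster.
#' @export
cluster_unique_count <- function(annotated, cluster_id = "cluster1") {
  stopifnot(inherits(annotated, "smallrna_annotated"))
  qn <- annotated$labels[category == "cluster" & label == cluster_id, qname]
  nrow(annotated$reads[qname %in% qn & unique_mapper == TRUE &
                         excluded == FALSE])
}

#' Per-family normalized candidate counts
#'
#' A candidate with k ex-aequo canonical TE assignments contributes 1/k to
#' each family, so fractional counts conserve the number of counted reads.
#' Normalization: `normalized = raw * scale / cluster1_unique_count`.
#'
#' @param classified output of [classify()].
#' @param cluster1_unique_count unique-mapper count of the normalizer
#'   cluster (must be > 0).
#' @param scale normalization scale (default 1e6: counts per million
#'   cluster-1 unique mappers).
#' @param class candidate class to count (`"piRNA"` or `"siRNA"`).
#' @param by_size also stratify by read size.
#' @return data.table (family, orientation[, size], raw, normalized) with
#'   class `annotated_count` and attribute `scale`.
#' @export
count_and_normalize <- function(classified, cluster1_unique_count,
                                scale = 1e6, class = "piRNA",
                                by_size = FALSE) {
  stopifnot(inherits(classified, "smallrna_classified"))
  if (!is.numeric(cluster1_unique_count) || cluster1_unique_count <= 0) {
    stop("normalization error: cluster1_unique_count must be > 0",
         call. = FALSE)
  }
  cls <- class
  cand <- classified$candidates[classified$candidates$class == cls]
  asg <- classified$assignments[ref_type == "TE" & qname %in% cand$qname]
  asg <- merge(asg, cand[, .(qname, size)], by = "qname")
  by_cols <- c("ref_id", "orientation", if (by_size) "size")
  out <- asg[, .(raw = sum(1 / k)), by = by_cols]
  data.table::setnames(out, "ref_id", "family")
  out[, normalized := raw * scale / cluster1_unique_count]
  data.table::setattr(out, "scale", scale)
  data.table::setattr(out, "class",
                      c("annotated_count", class(out)))
  out[]
}

#' Per-size sense/antisense distribution for one family
#'
#' Tabulates all annotated reads canonically assigned to `family` over the
#' 18-30 nt window, fractionally weighted (1/k) for multi-family reads.
#'
#' @param classified output of [classify()].
#' @param family TE family name.
#' @param cfg a [classifier_config()] giving the size window.
#' @return data.table (size 18..30, sense, antisense) covering every size
#'   bin; column sums equal the family's weighted totals.
#' @export
size_distribution <- function(classified, family,
                              cfg = classifier_config()) {
  stopifnot(inherits(classified, "smallrna_classified"))
  asg <- classified$assignments[ref_type == "TE" & ref_id == family]
  if (nrow(asg) == 0L &&
      !(family %in% classified$assignments$ref_id)) {
    stop("unknown family (no reads assigned): ", family, call. = FALSE)
  }
  asg <- merge(asg, classified$candidates[, .(qname, size)], by = "qname")
  sizes <- seq(cfg$trim_min, cfg$trim_max)
  grid <- data.table::CJ(size = sizes, orientation = c("sense", "antisense"))
  tab <- asg[, .(w = sum(1 / k)), by = .(size, orientation)]
  out <- merge(grid, tab, by = c("size", "orientation"), all.x = TRUE)
  out[is.na(w), w := 0]
  data.table::dcast(out, size ~ orientation, value.var = "w")[]
}

#' 5' nucleotide composition of candidates, per class
#'
#' @param classified output of [classify()].
#' @return data.table (class, nt, fraction); fractions sum to 1 within each
#'   class. Errors on an empty candidate set.
#' @export
first_nt_bias <- function(classified) {
  stopifnot(inherits(classified, "smallrna_classified"))
  cand <- classified$candidates[class %in% c("piRNA", "siRNA")]
  if (nrow(cand) == 0L) {
    stop("undefined-fraction error: no candidates", call. = FALSE)
  }
  out <- cand[, {
    tab <- table(factor(first_nt, levels = DNA_ALPHABET))
    list(nt = DNA_ALPHABET, fraction = as.numeric(tab) / sum(tab))
  }, by = class]
  out[]
}

#' Per-family fold changes between two normalized count tables
#'
#' `fc = (normalized_a + pseudocount) / (normalized_b + pseudocount)`.
#' Families present in only one table are treated as zero in the other and
#' flagged.
#'
#' @param table_a,table_b [count_and_normalize()] outputs sharing the same
#'   normalization scheme.
#' @param pseudocount added to both normalized values (default 1; zero-count
#'   families otherwise give infinite fold changes).
#' @param orientation restrict to one orientation (default `"antisense"`,
#'   the figure-level convention); use `NULL` to keep both.
#' @return data.table (family, norm_a, norm_b, fc, log2fc, flagged).
#' @export
fold_change <- function(table_a, table_b, pseudocount = 1,
                        orientation = "antisense") {
  a <- data.table::as.data.table(table_a)
  b <- data.table::as.data.table(table_b)
  if (!is.null(orientation)) {
    ori <- orientation
    a <- a[a$orientation == ori]
    b <- b[b$orientation == ori]
  }
  a <- a[, .(norm_a = sum(normalized)), by = family]
  b <- b[, .(norm_b = sum(normalized)), by = family]
  m <- merge(a, b, by = "family", all = TRUE)
  m[, flagged := is.na(norm_a) | is.na(norm_b)]
  m[is.na(norm_a), norm_a := 0]
  m[is.na(norm_b), norm_b := 0]
  m[, fc := (norm_a + pseudocount) / (norm_b + pseudocount)]
  m[, log2fc := log2(fc)]
  m[]
}

#' Spearman rank correlation between two fold-change vectors
#'
#' @param fc_a,fc_b numeric vectors (matched by position or by the names
#'   attribute when both are named).
#' @return Spearman's rho.
#' @export
spearman_fc <- function(fc_a, fc_b) {
  if (!is.null(names(fc_a)) && !is.null(names(fc_b))) {
    common <- intersect(names(fc_a), names(fc_b))
    fc_a <- fc_a[common]; fc_b <- fc_b[common]
  }
  cor(fc_a, fc_b, method = "spearman")
}
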