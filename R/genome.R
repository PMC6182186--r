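## Toy genome construction: a small reference with embedded TE copies,
## piRNA/siRNA clusters, gene features and a mitochondrial contig, plus the
## canonical TE library the downstream modules count against.

#' Generator settings for a toy genome
#'
#' Builds the configuration list consumed by [build_toy_genome()]. Defaults
#' describe the stated desk-scale world: two 100 kb autosomal contigs plus a
#' mitochondrial contig, three TE families (an ERV-like `ZAMx` with four
#' genomic copies, `GTWx` with three, and a high-load control family `CTRLx`
#' with ten copies), one germline piRNA cluster (`cluster1`, the 42AB-like
#' normalizer), one ovarian siRNA cluster, and a handful of rRNA/miRNA/gene
#' features used by the small-RNA exclusion and annotation rules.
#'
#' @param contig_lengths named integer vector of non-mitochondrial contig
#'   lengths (nt). At least 2 contigs required.
#' @param mt_contig name of the mitochondrial contig.
#' @param mt_length length of the mitochondrial contig (nt).
#' @param te_families named integer vector of TE family consensus lengths, or
#'   a named character vector of explicit consensus sequences. At least 3
#'   families required.
#' @param te_copy_numbers named integer vector of genomic copies per family.
#' @param divergence per-base substitution rate applied independently to each
#'   embedded genomic copy (0 = copies identical to consensus, so oracle
#'   realignment is exact).
#' @param clusters list of cluster descriptors `list(class=, length=)`, named
#'   by cluster id. Must contain an id `cluster1` of class `piRNA` and at
#'   least one `siRNA` cluster.
#' @param features list with counts/lengths of placed features:
#'   `n_rrna`, `rrna_length`, `n_mirna`, `mirna_length`, `n_genes`,
#'   `gene_length`, `utr3_length` (3'UTR carved from the gene end).
#' @return a list of settings with class `toy_genome_config`.
#' @export
toy_genome_config <- function(contig_lengths = c(chr2Lx = 100000L, chr2Rx = 100000L),
                              mt_contig = "chrMx",
                              mt_length = 15000L,
                              te_families = c(ZAMx = 4000L, GTWx = 4000L, CTRLx = 3000L),
                              te_copy_numbers = c(ZAMx = 4L, GTWx = 3L, CTRLx = 10L),
                              divergence = 0,
                              clusters = list(
                                cluster1   = list(class = "piRNA", length = 4000L),
                                sicluster1 = list(class = "siRNA", length = 2000L)
                              ),
                              features = list(
                                n_rrna = 2L, rrna_length = 500L,
                                n_mirna = 3L, mirna_length = 100L,
                                n_genes = 3L, gene_length = 2000L,
                                utr3_length = 300L
                              )) {
  cfg <- list(
    contig_lengths = contig_lengths, mt_contig = mt_contig,
    mt_length = as.integer(mt_length), te_families = te_families,
    te_copy_numbers = te_copy_numbers, divergence = divergence,
    clusters = clusters, features = features
  )
  if (length(contig_lengths) < 2L) {
    stop("config must specify >= 2 non-mitochondrial contigs", call. = FALSE)
  }
  if (length(te_families) < 3L) {
    stop("config must specify >= 3 TE families", call. = FALSE)
  }
  cls <- vapply(clusters, `[[`, "", "class")
  if (!("cluster1" %in% names(clusters)) ||
      clusters[["cluster1"]]$class != "piRNA") {
    stop("a piRNA cluster with id 'cluster1' is required (the normalizer)",
         call. = FALSE)
  }
  if (!any(cls == "siRNA")) {
    stop("at least one siRNA cluster is required", call. = FALSE)
  }
  if (!all(names(te_copy_numbers) %in% names(te_families))) {
    stop("te_copy_numbers names must be TE families", call. = FALSE)
  }
  structure(cfg, class = "toy_genome_config")
}

# place `lengths` non-overlapping intervals on contigs by rejection sampling;
# returns data.table(contig, start, end). Fails with a sizing error when a
# placement cannot be found.
place_intervals <- function(lengths, contig_lengths, occupied = NULL,
                            margin = 50L, max_try = 2000L) {
  occ <- lapply(contig_lengths, function(x) NULL)  # per-contig IRanges
  names(occ) <- names(contig_lengths)
  if (!is.null(occupied)) {
    for (ct in unique(occupied$contig)) {
      occ[[ct]] <- IRanges::IRanges(
        start = occupied$start[occupied$contig == ct],
        end = occupied$end[occupied$contig == ct]
      )
    }
  }
  res <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    placed <- FALSE
    for (try in seq_len(max_try)) {
      ct <- sample(names(contig_lengths), 1L)
      hi <- contig_lengths[[ct]] - len + 1L
      if (hi < 1L) next
      s <- sample.int(hi, 1L)
      cand <- IRanges::IRanges(start = max(1L, s - margin),
                               end = min(contig_lengths[[ct]], s + len - 1L + margin))
      if (is.null(occ[[ct]]) ||
          length(IRanges::findOverlaps(cand, occ[[ct]])) == 0L) {
        ivl <- IRanges::IRanges(start = s, end = s + len - 1L)
        occ[[ct]] <- if (is.null(occ[[ct]])) ivl else c(occ[[ct]], ivl)
        res[[i]] <- data.table::data.table(contig = ct, start = s,
                                           end = s + len - 1L)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("sizing error: contigs too short/crowded to host requested ",
           "features (interval of length ", len, ")", call. = FALSE)
    }
  }
  data.table::rbindlist(res)
}

#' Build a deterministic toy genome with embedded TE copies
#'
#' Generates random background contigs, embeds TE family copies verbatim
#' (optionally with point-mutation divergence), places piRNA/siRNA clusters
#' and gene features at non-overlapping positions, and adds a mitochondrial
#' contig. All coordinates are 1-based closed (the R/Bioconductor
#' convention); BED writers convert on output.
#'
#' @param config a [toy_genome_config()] list.
#' @param seed integer seed; identical seed and config give byte-identical
#'   genomes.
#' @return a `ToyGenome` list with elements `contigs` (named character),
#'   `te_library` (named character, the canonical consensus sequences),
#'   `te_copies`, `clusters`, `features` (data.tables), `mt_contig`,
#'   `config`.
#' @examples
#' g <- build_toy_genome(toy_genome_config(), seed = 1)
#' g$te_copies
#' @export
build_toy_genome <- function(config = toy_genome_config(), seed = 1L) {
  if (!inherits(config, "toy_genome_config")) {
    config <- do.call(toy_genome_config, config)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  # canonical TE library
  tf <- config$te_families
  te_library <- if (is.character(tf)) {
    tf
  } else {
    setNames(vapply(tf, random_dna, ""), names(tf))
  }

  # background contigs
  contigs <- setNames(
    vapply(config$contig_lengths, random_dna, ""),
    names(config$contig_lengths)
  )
  contigs[[config$mt_contig]] <- random_dna(config$mt_length)
  cl <- vapply(contigs, nchar, 0L)
  placeable <- cl[setdiff(names(cl), config$mt_contig)]

  # TE copies
  fams <- rep(names(config$te_copy_numbers), config$te_copy_numbers)
  te_len <- nchar(te_library)[fams]
  te_iv <- place_intervals(te_len, placeable)
  te_copies <- data.table::data.table(
    family = fams, contig = te_iv$contig, start = te_iv$start,
    end = te_iv$end,
    strand = sample(c("+", "-"), length(fams), replace = TRUE)
  )

  # clusters and features, avoiding TE copies
  cl_len <- vapply(config$clusters, function(x) as.integer(x$length), 0L)
  fe <- config$features
  feat_class <- c(rep("rRNA", fe$n_rrna), rep("miRNA", fe$n_mirna),
                  rep("gene", fe$n_genes))
  feat_len <- c(rep(fe$rrna_length, fe$n_rrna),
                rep(fe$mirna_length, fe$n_mirna),
                rep(fe$gene_length, fe$n_genes))
  all_iv <- place_intervals(c(cl_len, feat_len), placeable,
                            occupied = te_copies)
  ncl <- length(cl_len)
  clusters <- data.table::data.table(
    id = names(config$clusters),
    contig = all_iv$contig[seq_len(ncl)],
    start = all_iv$start[seq_len(ncl)],
    end = all_iv$end[seq_len(ncl)],
    class = vapply(config$clusters, `[[`, "", "class")
  )
  fiv <- all_iv[-seq_len(ncl)]
  features <- data.table::data.table(
    class = feat_class, contig = fiv$contig, start = fiv$start,
    end = fiv$end,
    strand = sample(c("+", "-"), length(feat_class), replace = TRUE)
  )
  # carve a 3'UTR out of each gene's downstream end
  genes <- features[class == "gene"]
  if (nrow(genes) > 0L && fe$utr3_length > 0L) {
    utr <- data.table::copy(genes)
    utr[, class := "3UTR"]
    utr[strand == "+", start := end - fe$utr3_length + 1L]
    utr[strand == "-", end := start + fe$utr3_length - 1L]
    features <- data.table::rbindlist(list(features, utr))
  }

  # embed TE copies verbatim (with optional divergence)
  for (i in seq_len(nrow(te_copies))) {
    cp <- te_copies[i]
    s <- te_library[[cp$family]]
    s <- mutate_seq(s, config$divergence)
    if (cp$strand == "-") s <- revcomp(s)
    substr(contigs[[cp$contig]], cp$start, cp$end) <- s
  }

  g <- structure(list(
    contigs = contigs, te_library = te_library, te_copies = te_copies,
    clusters = clusters, features = features,
    mt_contig = config$mt_contig, config = config
  ), class = "ToyGenome")
  validate_toy_genome(g)
  g
}

validate_toy_genome <- function(g) {
  stopifnot(inherits(g, "ToyGenome"))
  cl <- vapply(g$contigs, nchar, 0L)
  chk <- function(dt) {
    all(dt$contig %in% names(cl)) && all(dt$start >= 1L) &&
      all(dt$end <= cl[dt$contig]) && all(dt$start <= dt$end)
  }
  if (!chk(g$te_copies) || !chk(g$clusters) || !chk(g$features)) {
    stop("interval outside contig bounds", call. = FALSE)
  }
  if (!all(g$te_copies$family %in% names(g$te_library))) {
    stop("te_copies reference unknown families", call. = FALSE)
  }
  if (!(g$mt_contig %in% names(g$contigs)) || length(g$mt_contig) != 1L) {
    stop("exactly one mitochondrial contig required", call. = FALSE)
  }
  if (!("cluster1" %in% g$clusters$id)) {
    stop("cluster 'cluster1' (normalizer) missing", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.ToyGenome <- function(x, ...) {
  cat("ToyGenome:", length(x$contigs), "contigs (",
      sum(vapply(x$contigs, nchar, 0L)), "nt ), mt contig:", x$mt_contig, "\n")
  cat("  TE library:", paste(names(x$te_library), collapse = ", "), "\n")
  cat("  TE copies:", nrow(x$te_copies), " clusters:", nrow(x$clusters),
      " features:", nrow(x$features), "\n")
  invisible(x)
}

## ---- derived views ----------------------------------------------------

# GRanges views over annotation tables (1-based closed, as stored)
granges_of <- function(dt, strand_col = NULL, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = if (is.null(seqlevels)) dt$contig
               else factor(dt$contig, levels = seqlevels),
    ranges = IRanges::IRanges(start = dt$start, end = dt$end),
    strand = if (!is.null(strand_col)) dt[[strand_col]] else "*"
  )
}

#' Extract cluster sequence from a toy genome
#' @param genome a `ToyGenome`.
#' @param id cluster id, e.g. `"cluster1"`.
#' @return the cluster's genomic sequence (character).
#' @export
cluster_sequence <- function(genome, id) {
  idx <- which(genome$clusters$id == id)
  if (length(idx) != 1L) stop("unknown cluster id: ", id, call. = FALSE)
  cl <- genome$clusters[idx]
  substr(genome$contigs[[cl$contig]], cl$start, cl$end)
}

## ---- writers ----------------------------------------------------------

#' Write toy genome and TE library to FASTA
#'
#' @param genome a `ToyGenome`.
#' @param genome_path,te_path output FASTA paths (either may be `NULL` to
#'   skip).
#' @return invisibly, the paths written.
#' @export
write_genome_fasta <- function(genome, genome_path = NULL, te_path = NULL) {
  if (!is.null(genome_path)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome$contigs), genome_path)
  }
  if (!is.null(te_path)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome$te_library), te_path)
  }
  invisible(c(genome_path, te_path))
}

#' Write an interval table as BED6
#'
#' Converts from internal 1-based closed to BED's 0-based half-open.
#'
#' @param dt data.table with columns contig, start, end and optionally a
#'   name/strand column.
#' @param path output path.
#' @param name_col column to use as the BED name field.
#' @param strand_col column to use as the BED strand field (`"."` if absent).
#' @return invisibly, `path`.
#' @export
write_bed <- function(dt, path, name_col = NULL, strand_col = NULL) {
  out <- data.table::data.table(
    chrom = dt$contig,
    chromStart = dt$start - 1L,
    chromEnd = dt$end,
    name = if (!is.null(name_col)) dt[[name_col]] else ".",
    score = 0L,
    strand = if (!is.null(strand_col)) dt[[strand_col]] else "."
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
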