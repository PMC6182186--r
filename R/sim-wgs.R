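## Paired-end whole-genome library simulator. Planted insertions are placed
## into a "sample genome"; fragments are drawn uniformly from it and each
## read is classified against the reference block structure: fully inside a
## reference block -> mapped full-length; crossing a reference/TE boundary
## with a sufficient genomic anchor -> soft-clipped; otherwise unmapped.
## Reads falling entirely inside inserted TE sequence are emitted unmapped,
## emulating the unique-mapping filter of the real pipeline (such reads
## multi-map to pre-existing genomic copies and contribute no unique
## anchor); this is what turns junction pairs into one-end-anchored pairs.
##
## Artefactual TE-genome chimeras are modelled as junction *sites*: per
## genomic TE copy, Poisson(chimera_rate) sites per library prep, each with
## a TE-side junction uniform along the TE (no preference for TE ends) and
## fragment depth matching a real junction at the library coverage. Their
## abundance therefore tracks genomic TE load, the false-positive structure
## the de-novo-insertion ratio filter addresses.

#' Simulate a paired-end genomic library with planted insertions and
#' chimeric artifacts
#'
#' @param genome a `ToyGenome`.
#' @param truth a `TruthTable`; `planted_insertions` are embedded in the
#'   sample genome, `chimera_rate` drives artefact junction sites.
#' @param coverage haploid fold coverage (> 0).
#' @param read_len read length (nt).
#' @param insert_mean,insert_sd fragment-size distribution (normal,
#'   rounded); `insert_mean` must be at least `2 * read_len`.
#' @param min_anchor minimum mapped anchor (nt) for a junction-crossing read
#'   to be emitted as a soft-clipped alignment rather than unmapped.
#' @param seed integer seed.
#' @return list with class `wgs_sim`: `alignments` (paired alignment
#'   records with truth columns `truth_label` in
#'   \{real, artifact, NA\}, `truth_family`, `truth_bp`) and
#'   `chimera_sites` (the drawn artefact junctions).
#' @export
simulate_wgs_library <- function(genome, truth, coverage,
                                 read_len = 100L, insert_mean = 500L,
                                 insert_sd = 30L, min_anchor = 20L,
                                 seed = 1L) {
  stopifnot(inherits(genome, "ToyGenome"), inherits(truth, "TruthTable"))
  assert_scalar_num(coverage, "coverage", min = 1e-9)
  if (insert_mean < 2L * read_len) {
    stop("geometry error: insert_mean must be >= 2 * read_len", call. = FALSE)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  contig_names <- setdiff(names(genome$contigs), genome$mt_contig)
  recs <- list()
  pair_idx <- 0L

  for (ct in contig_names) {
    bl <- contig_blocks(genome, truth, ct)
    n_frag <- as.integer(round(
      coverage * bl$sample_len / (2 * read_len)))
    if (n_frag > 0L) {
      out <- sample_fragments(bl, n_frag, read_len, insert_mean, insert_sd,
                              min_anchor, pair_idx)
      pair_idx <- pair_idx + n_frag
      recs[[length(recs) + 1L]] <- out
    }
  }

  # chimeric junction sites
  sites <- draw_chimera_sites(genome, truth, contig_names)
  if (nrow(sites) > 0L) {
    frag_depth <- coverage * insert_mean / (2 * read_len)
    for (i in seq_len(nrow(sites))) {
      st <- sites[i]
      n_frag <- rpois(1L, frag_depth)
      if (n_frag == 0L) next
      out <- chimera_fragments(genome, st, n_frag, read_len, insert_mean,
                               insert_sd, min_anchor, pair_idx)
      pair_idx <- pair_idx + n_frag
      recs[[length(recs) + 1L]] <- out
    }
  }

  aln <- data.table::rbindlist(recs, fill = TRUE)
  aln <- finalize_pairs(aln)
  structure(list(alignments = aln, chimera_sites = sites),
            class = "wgs_sim")
}

# Block structure of one sample contig: alternating reference and inserted
# TE blocks in sample coordinates, with the reference offset of each ref
# block and the insertion breakpoint of each TE block.
contig_blocks <- function(genome, truth, ct) {
  ins <- truth$planted_insertions[contig == ct]
  data.table::setorder(ins, pos)
  ref_seq <- genome$contigs[[ct]]
  L <- nchar(ref_seq)
  s_start <- integer(0); s_end <- integer(0); type <- character(0)
  ref_start <- integer(0); fam <- character(0); bp <- integer(0)
  seq_parts <- character(0)
  cur_ref <- 1L; cur_s <- 1L
  add <- function(env, slen, ty, rs, fm, b, sq) {
    env$s_start <- c(env$s_start, env$cur_s)
    env$s_end <- c(env$s_end, env$cur_s + slen - 1L)
    env$type <- c(env$type, ty); env$ref_start <- c(env$ref_start, rs)
    env$fam <- c(env$fam, fm); env$bp <- c(env$bp, b)
    env$seq_parts <- c(env$seq_parts, sq)
    env$cur_s <- env$cur_s + slen
  }
  env <- environment()
  if (nrow(ins) > 0L) {
    for (i in seq_len(nrow(ins))) {
      p <- ins$pos[i]
      glen <- p - cur_ref + 1L
      add(env, glen, "ref", cur_ref, NA_character_, NA_integer_,
          substr(ref_seq, cur_ref, p))
      te <- genome$te_library[[ins$family[i]]]
      if (runif(1) < 0.5) te <- revcomp(te)
      add(env, nchar(te), "te", NA_integer_, ins$family[i], p, te)
      cur_ref <- p + 1L
    }
  }
  add(env, L - cur_ref + 1L, "ref", cur_ref, NA_character_, NA_integer_,
      substr(ref_seq, cur_ref, L))
  list(contig = ct,
       blocks = data.table::data.table(
         s_start = s_start, s_end = s_end, type = type,
         ref_start = ref_start, fam = fam, bp = bp),
       sample_seq = paste(seq_parts, collapse = ""),
       sample_len = s_end[length(s_end)])
}

# classify one vector of read intervals [a,b] (sample coords, genome-forward
# sequence `fwd`) against a block structure; returns record columns
classify_reads <- function(bl, a, b, fwd, min_anchor) {
  blocks <- bl$blocks
  ia <- findInterval(a, blocks$s_start)
  ib <- findInterval(b, blocks$s_start)
  n <- length(a)
  mapped <- logical(n); pos <- rep(NA_integer_, n)
  cigar <- rep(NA_character_, n)
  lab <- rep(NA_character_, n); labf <- rep(NA_character_, n)
  labp <- rep(NA_integer_, n)

  same <- ia == ib
  inref <- same & blocks$type[ia] == "ref"
  mapped[inref] <- TRUE
  pos[inref] <- blocks$ref_start[ia[inref]] + (a[inref] - blocks$s_start[ia[inref]])
  cigar[inref] <- paste0(b[inref] - a[inref] + 1L, "M")
  inte <- same & blocks$type[ia] == "te"
  lab[inte] <- "real"; labf[inte] <- blocks$fam[ia[inte]]
  labp[inte] <- blocks$bp[ia[inte]]

  junc <- which(ib == ia + 1L)
  for (i in junc) {
    left_ref <- blocks$type[ia[i]] == "ref"
    rl <- b[i] - a[i] + 1L
    if (left_ref) {
      anchor <- blocks$s_end[ia[i]] - a[i] + 1L
      jbp <- blocks$ref_start[ia[i]] + (blocks$s_end[ia[i]] - blocks$s_start[ia[i]])
      tb <- ib[i]
    } else {
      anchor <- b[i] - blocks$s_start[ib[i]] + 1L
      jbp <- blocks$ref_start[ib[i]] - 1L
      tb <- ia[i]
    }
    lab[i] <- "real"; labf[i] <- blocks$fam[tb]; labp[i] <- blocks$bp[tb]
    if (anchor >= min_anchor && anchor < rl) {
      mapped[i] <- TRUE
      if (left_ref) {
        pos[i] <- blocks$ref_start[ia[i]] + (a[i] - blocks$s_start[ia[i]])
        cigar[i] <- paste0(anchor, "M", rl - anchor, "S")
      } else {
        pos[i] <- blocks$ref_start[ib[i]]
        cigar[i] <- paste0(rl - anchor, "S", anchor, "M")
      }
    }
  }
  data.table::data.table(mapped = mapped, pos = pos, cigar = cigar,
                         truth_label = lab, truth_family = labf,
                         truth_bp = labp, seq_fwd = fwd)
}

# draw fragments from one sample contig and emit both mates
sample_fragments <- function(bl, n_frag, read_len, insert_mean, insert_sd,
                             min_anchor, pair_offset) {
  ins_len <- pmax(as.integer(round(rnorm(n_frag, insert_mean, insert_sd))),
                  2L * read_len)
  smax <- bl$sample_len - ins_len + 1L
  s <- 1L + as.integer(floor(runif(n_frag) * pmax(smax, 1L)))
  a1 <- s; b1 <- s + read_len - 1L
  a2 <- s + ins_len - read_len; b2 <- s + ins_len - 1L
  f1 <- substring(bl$sample_seq, a1, b1)
  f2 <- substring(bl$sample_seq, a2, b2)
  r1 <- classify_reads(bl, a1, b1, f1, min_anchor)
  r2 <- classify_reads(bl, a2, b2, f2, min_anchor)
  qn <- sprintf("wg%08d", pair_offset + seq_len(n_frag))
  build_pair_records(qn, bl$contig, r1, r2, rev1 = FALSE, rev2 = TRUE)
}

# chimeric junction sites: (family, contig, ref pos, genome side, TE offset)
draw_chimera_sites <- function(genome, truth, contig_names) {
  rate <- truth$chimera_rate
  copies <- genome$te_copies
  out <- list()
  if (rate > 0 && nrow(copies) > 0L) {
    lens <- vapply(genome$contigs[contig_names], nchar, 0L)
    for (i in seq_len(nrow(copies))) {
      k <- rpois(1L, rate)
      if (k == 0L) next
      ct <- sample(contig_names, k, replace = TRUE,
                   prob = lens[contig_names])
      pos <- vapply(ct, function(x) {
        sample.int(lens[[x]] - 4000L, 1L) + 2000L
      }, 0L)
      out[[length(out) + 1L]] <- data.table::data.table(
        family = copies$family[i], contig = ct, pos = pos,
        genome_side = sample(c("left", "right"), k, replace = TRUE),
        te_strand = sample(c("+", "-"), k, replace = TRUE),
        te_offset = NA_integer_
      )
    }
  }
  if (length(out) == 0L) {
    return(data.table::data.table(family = character(), contig = character(),
                                  pos = integer(), genome_side = character(),
                                  te_strand = character(),
                                  te_offset = integer()))
  }
  sites <- data.table::rbindlist(out)
  # TE-side junction position uniform along the TE (no end preference)
  for (i in seq_len(nrow(sites))) {
    L <- nchar(genome$te_library[[sites$family[i]]])
    sites$te_offset[i] <- sample.int(L, 1L)
  }
  sites[]
}

# fragments spanning one chimeric junction site
chimera_fragments <- function(genome, st, n_frag, read_len, insert_mean,
                              insert_sd, min_anchor, pair_offset) {
  ref_seq <- genome$contigs[[st$contig]]
  te <- genome$te_library[[st$family]]
  if (st$te_strand == "-") te <- revcomp(te)
  Lte <- nchar(te)
  ins_len <- pmax(as.integer(round(rnorm(n_frag, insert_mean, insert_sd))),
                  2L * read_len)
  # genomic part length uniform in [1, ins_len - 1]: junction inside fragment
  g <- 1L + as.integer(floor(runif(n_frag) * (ins_len - 1L)))
  te_need <- ins_len - g
  # TE-side sequence from the junction offset, wrapping circularly if the
  # uniform junction lands too close to the end of the consensus
  te_from <- ((st$te_offset - 1L) %% max(Lte - max(te_need) - 1L, 1L)) + 1L
  te_side <- substring(te, te_from, te_from + te_need - 1L)
  if (st$genome_side == "left") {
    gen_side <- substring(ref_seq, st$pos - g + 1L, st$pos)
    mol <- paste0(gen_side, te_side)
    j0 <- g                               # genomic part is molecule[1..j0]
    mol_ref_start <- st$pos - g + 1L
  } else {
    gen_side <- substring(ref_seq, st$pos + 1L, st$pos + g)
    mol <- paste0(stringrev_safe(te_side), gen_side)
    j0 <- te_need                         # TE part is molecule[1..j0]
    mol_ref_start <- st$pos + 1L - te_need  # ref coord of molecule[1] if it were genomic
  }
  r1 <- classify_chimera_read(1L, read_len, ins_len, j0, st, mol,
                              mol_ref_start, min_anchor)
  r2 <- classify_chimera_read(2L, read_len, ins_len, j0, st, mol,
                              mol_ref_start, min_anchor)
  qn <- sprintf("wg%08d", pair_offset + seq_len(n_frag))
  build_pair_records(qn, st$contig, r1, r2, rev1 = FALSE, rev2 = TRUE)
}

# the TE side placed left of the genome keeps its own 5'->3' orientation in
# the molecule; no reversal needed (orientation already folded into `te`)
stringrev_safe <- function(x) x

classify_chimera_read <- function(mate, read_len, ins_len, j0, st, mol,
                                  mol_ref_start, min_anchor) {
  n <- length(mol)
  a <- if (mate == 1L) rep(1L, n) else ins_len - read_len + 1L
  b <- a + read_len - 1L
  fwd <- substring(mol, a, b)
  mapped <- logical(n); pos <- rep(NA_integer_, n)
  cigar <- rep(NA_character_, n)
  genome_left <- st$genome_side == "left"
  for (i in seq_len(n)) {
    if (genome_left) {
      anchor <- min(j0[i], b[i]) - a[i] + 1L     # genomic prefix inside read
      if (anchor >= read_len) {                  # fully genomic
        mapped[i] <- TRUE
        pos[i] <- st$pos - j0[i] + a[i]
        cigar[i] <- paste0(read_len, "M")
      } else if (anchor >= min_anchor) {         # crosses junction
        mapped[i] <- TRUE
        pos[i] <- st$pos - j0[i] + a[i]
        cigar[i] <- paste0(anchor, "M", read_len - anchor, "S")
      }
    } else {
      anchor <- b[i] - max(j0[i] + 1L, a[i]) + 1L  # genomic suffix inside read
      if (anchor >= read_len) {
        mapped[i] <- TRUE
        pos[i] <- st$pos + 1L + (a[i] - j0[i] - 1L)
        cigar[i] <- paste0(read_len, "M")
      } else if (anchor >= min_anchor) {
        mapped[i] <- TRUE
        pos[i] <- st$pos + 1L
        cigar[i] <- paste0(read_len - anchor, "S", anchor, "M")
      }
    }
  }
  data.table::data.table(mapped = mapped, pos = pos, cigar = cigar,
                         truth_label = "artifact", truth_family = st$family,
                         truth_bp = st$pos, seq_fwd = fwd)
}

# assemble SAM-style paired records from two classified read tables
build_pair_records <- function(qn, contig, r1, r2, rev1, rev2) {
  mk <- function(r, first, rev, other) {
    flag <- FLAG_PAIRED + if (first) FLAG_FIRST else FLAG_SECOND
    flag <- flag + ifelse(r$mapped, ifelse(rev, FLAG_REVERSE, 0L),
                          FLAG_UNMAPPED)
    flag <- flag + ifelse(other$mapped,
                          ifelse(!rev, FLAG_MATE_REVERSE, 0L),
                          FLAG_MATE_UNMAPPED)
    # unmapped records carry the raw read (as sequenced); mapped records the
    # genome-forward sequence, per SAM convention
    sq <- ifelse(r$mapped | !rev, r$seq_fwd, revcomp(r$seq_fwd))
    data.table::data.table(
      qname = qn, flag = flag,
      rname = ifelse(r$mapped, contig, NA_character_),
      pos = r$pos, mapq = ifelse(r$mapped, 60L, 0L), cigar = r$cigar,
      rnext = ifelse(other$mapped, contig, NA_character_),
      pnext = ifelse(other$mapped, other$pos, 0L),
      tlen = 0L, seq = sq, score = ifelse(r$mapped, 0, NA_real_),
      truth_label = r$truth_label, truth_family = r$truth_family,
      truth_bp = r$truth_bp
    )
  }
  data.table::rbindlist(list(mk(r1, TRUE, rev1, r2), mk(r2, FALSE, rev2, r1)))
}

finalize_pairs <- function(aln) {
  both <- aln[, .(proper = all(!has_flag(flag, FLAG_UNMAPPED))), by = qname]
  aln <- merge(aln, both, by = "qname", sort = FALSE)
  aln[proper == TRUE & !has_flag(flag, FLAG_UNMAPPED),
      flag := flag + FLAG_PROPER]
  aln[, proper := NULL]
  aln[]
}
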