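## Ground-truth bookkeeping for the simulators: what was planted, with what
## abundance, so downstream results can be checked against a known answer.

#' Assemble a truth table for the simulators
#'
#' The truth table states the world each simulated library is drawn from:
#' which de novo TE insertions exist, which eccDNA circles are present at
#' what abundance, the small-RNA (family, size, strand) profile, and the
#' chimeric-artifact rate of the genomic library prep.
#'
#' @param genome a `ToyGenome`.
#' @param planted_insertions data.table/data.frame with columns `family`,
#'   `contig`, `pos` (insertion point: the new TE sits between `pos` and
#'   `pos + 1` on the reference). May be `NULL`/empty.
#' @param planted_circles data.table with columns `family`, `count`
#'   (relative circle abundance; read counts are proportional). May be
#'   `NULL`.
#' @param smallrna_profile data.table with columns `source_id` (TE family or
#'   cluster id), `size` (18-30 nt), `strand` (`sense`/`antisense` relative
#'   to the source sequence), `count`, and optionally `p5a` (target fraction
#'   of 5'-A among reads of that row; `NA` = unconstrained).
#' @param chimera_rate expected artefactual TE-genome junction sites per
#'   genomic TE copy per library prep.
#' @param mobilome_mt_weight relative weight of mitochondrial background
#'   reads in the mobilome library (circles and mtDNA both survive the
#'   linear-DNA removal). A value of 0 triggers a warning: mtDNA
#'   normalization becomes impossible.
#' @param mobilome_bg_weight relative weight of residual linear genomic
#'   background reads in the mobilome library.
#' @return a `TruthTable` list.
#' @export
truth_table <- function(genome,
                        planted_insertions = NULL,
                        planted_circles = NULL,
                        smallrna_profile = NULL,
                        chimera_rate = 0,
                        mobilome_mt_weight = 0.3,
                        mobilome_bg_weight = 0.1) {
  stopifnot(inherits(genome, "ToyGenome"))
  pi <- if (is.null(planted_insertions)) {
    data.table::data.table(family = character(), contig = character(),
                           pos = integer())
  } else {
    data.table::as.data.table(planted_insertions)
  }
  pc <- if (is.null(planted_circles)) {
    data.table::data.table(family = character(), count = numeric())
  } else {
    data.table::as.data.table(planted_circles)
  }
  sp <- if (is.null(smallrna_profile)) {
    data.table::data.table(source_id = character(), size = integer(),
                           strand = character(), count = numeric())
  } else {
    data.table::as.data.table(smallrna_profile)
  }
  if (!("p5a" %in% names(sp))) sp[, p5a := NA_real_]

  assert_scalar_num(chimera_rate, "chimera_rate", min = 0)
  if (nrow(pc) > 0 && any(pc$count < 0)) {
    stop("circle counts must be non-negative", call. = FALSE)
  }
  if (nrow(sp) > 0 && any(sp$count < 0)) {
    stop("profile counts must be non-negative", call. = FALSE)
  }
  if (mobilome_mt_weight == 0) {
    warning("mobilome_mt_weight is 0: mtDNA normalization will be impossible",
            call. = FALSE)
  }
  # breakpoints must not fall inside a pre-existing copy of the same family
  if (nrow(pi) > 0L) {
    for (i in seq_len(nrow(pi))) {
      same <- genome$te_copies[family == pi$family[i] & contig == pi$contig[i]]
      if (nrow(same) > 0L &&
          any(pi$pos[i] >= same$start & pi$pos[i] <= same$end)) {
        stop("planted breakpoint inside a pre-existing copy of the same ",
             "family: ", pi$family[i], "@", pi$pos[i], call. = FALSE)
      }
    }
    if (!all(pi$family %in% names(genome$te_library))) {
      stop("planted insertion references unknown family", call. = FALSE)
    }
  }
  structure(list(
    planted_insertions = pi, planted_circles = pc, smallrna_profile = sp,
    chimera_rate = chimera_rate,
    mobilome_mt_weight = mobilome_mt_weight,
    mobilome_bg_weight = mobilome_bg_weight
  ), class = "TruthTable")
}

#' Sample well-separated de novo insertion sites
#'
#' Draws `n` insertion points on non-mitochondrial contigs, outside any
#' pre-existing TE copy and at least `min_gap` nt away from each other and
#' from copy boundaries, so that planted junctions yield distinct evidence
#' clusters.
#'
#' @param genome a `ToyGenome`.
#' @param families character vector recycled to length `n`.
#' @param n number of insertions.
#' @param seed integer seed.
#' @param min_gap minimum pairwise distance (nt).
#' @return data.table(family, contig, pos) suitable for [truth_table()].
#' @export
plant_insertions <- function(genome, families, n, seed = 1L,
                             min_gap = 3000L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  fams <- rep_len(families, n)
  contig_lengths <- vapply(genome$contigs, nchar, 0L)
  contig_lengths <- contig_lengths[setdiff(names(contig_lengths),
                                           genome$mt_contig)]
  picked <- data.table::data.table(family = character(), contig = character(),
                                   pos = integer())
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(5000L)) {
      ct <- sample(names(contig_lengths), 1L)
      p <- sample.int(contig_lengths[[ct]] - 2L * min_gap, 1L) + min_gap
      near_te <- genome$te_copies[contig == ct &
                                    p >= start - min_gap & p <= end + min_gap]
      near_prev <- picked[contig == ct & abs(pos - p) < min_gap]
      if (nrow(near_te) == 0L && nrow(near_prev) == 0L) {
        picked <- data.table::rbindlist(list(
          picked,
          data.table::data.table(family = fams[i], contig = ct, pos = p)))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("sizing error: could not place insertion ", i, call. = FALSE)
  }
  picked[]
}

#' Build a realistic default small-RNA profile
#'
#' Per TE family: antisense piRNAs over 23-30 nt peaking at 25/26 nt, a
#' smaller sense piRNA complement, and 21 nt siRNAs on both strands;
#' plus cluster-derived reads (`cluster1` piRNAs, which provide the unique
#' mappers used for normalization, and siRNA-cluster 21-mers).
#'
#' @param genome a `ToyGenome`.
#' @param scale multiplies all counts.
#' @return profile data.table for [truth_table()].
#' @export
default_smallrna_profile <- function(genome, scale = 1) {
  fams <- names(genome$te_library)
  pirna_shape <- c(`23` = 4, `24` = 8, `25` = 14, `26` = 12, `27` = 6,
                   `28` = 3, `29` = 2, `30` = 1)
  rows <- list()
  for (f in fams) {
    rows[[length(rows) + 1L]] <- data.table::data.table(
      source_id = f, size = as.integer(names(pirna_shape)),
      strand = "antisense", count = pirna_shape * 10)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      source_id = f, size = as.integer(names(pirna_shape)),
      strand = "sense", count = pirna_shape * 3)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      source_id = f, size = 21L, strand = c("sense", "antisense"),
      count = c(60, 60))
  }
  cl <- genome$clusters
  for (i in seq_len(nrow(cl))) {
    if (cl$class[i] == "piRNA") {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        source_id = cl$id[i], size = as.integer(names(pirna_shape)),
        strand = "antisense", count = pirna_shape * 25)
    } else {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        source_id = cl$id[i], size = 21L, strand = c("sense", "antisense"),
        count = c(100, 100))
    }
  }
  out <- data.table::rbindlist(rows)
  out[, count := count * scale]
  out[, p5a := NA_real_]
  out[]
}
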