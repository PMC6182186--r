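## Insertion-set comparison: windowed family-aware matching of calls
## between libraries, multi-set intersection, de-novo-insertion ratios and
## coverage-matched random subsampling.

#' Comparison configuration
#'
#' @param window calls within +/- `window` nt are the same insertion
#'   (default 20, the bedtools-window convention used at genome scale).
#' @param n_subsamples number of coverage-matched subsampling replicates
#'   (default 44).
#' @return a `compare_config` list.
#' @export
compare_config <- function(window = 20L, n_subsamples = 44L) {
  stopifnot(window >= 0L, n_subsamples >= 1L)
  structure(list(window = window, n_subsamples = n_subsamples),
            class = "compare_config")
}

# family-aware windowed matching: for each row of `x`, is there a same-
# family call in `y` within the window?
matched_in <- function(x, y, window) {
  if (nrow(x) == 0L) return(logical(0))
  vapply(seq_len(nrow(x)), function(i) {
    any(y$family == x$family[i] & y$contig == x$contig[i] &
          abs(y$breakpoint - x$breakpoint[i]) <= window)
  }, logical(1))
}

#' Library-specific and shared insertion calls
#'
#' A call in A is shared iff a call of the same family in B lies within
#' +/- `window` of its breakpoint (family-aware matching: same-position
#' calls of different families do not match). Symmetric in A and B.
#'
#' @param calls_a,calls_b `insertion_calls` tables on the same reference.
#' @param cfg a [compare_config()].
#' @return list(unique_a, unique_b, shared_a, shared_b) of call subsets.
#' @export
library_specific <- function(calls_a, calls_b, cfg = compare_config()) {
  a <- data.table::as.data.table(calls_a)
  b <- data.table::as.data.table(calls_b)
  ref_a <- attr(calls_a, "reference"); ref_b <- attr(calls_b, "reference")
  if (!is.null(ref_a) && !is.null(ref_b) && !identical(ref_a, ref_b)) {
    stop("mixed references: ", ref_a, " vs ", ref_b, call. = FALSE)
  }
  in_b <- matched_in(a, b, cfg$window)
  in_a <- matched_in(b, a, cfg$window)
  list(unique_a = a[!in_b], unique_b = b[!in_a],
       shared_a = a[in_b], shared_b = b[in_a])
}

#' Multi-set windowed intersection of insertion calls
#'
#' Pools all call sets, merges same-family breakpoints within the window
#' (single linkage) into loci, and reports per-locus presence across sets.
#' A locus present in exactly one set is a candidate de novo insertion of
#' that library.
#'
#' @param call_sets named list (>= 2) of `insertion_calls` tables.
#' @param cfg a [compare_config()].
#' @return data.table (family, contig, breakpoint = locus representative,
#'   one logical column per set, n_sets).
#' @export
multi_intersect <- function(call_sets, cfg = compare_config()) {
  stopifnot(length(call_sets) >= 2L, !is.null(names(call_sets)))
  pooled <- data.table::rbindlist(
    lapply(names(call_sets), function(nm) {
      dt <- data.table::as.data.table(call_sets[[nm]])
      if (nrow(dt) == 0L) return(NULL)
      dt[, .(family, contig, breakpoint, set_id = nm)]
    }))
  if (nrow(pooled) == 0L) {
    return(data.table::data.table(family = character(), contig = character(),
                                  breakpoint = integer()))
  }
  data.table::setorder(pooled, family, contig, breakpoint)
  grp <- pooled[, {
    new <- c(TRUE, diff(breakpoint) > cfg$window)
    list(idx = .I, sub = cumsum(new))
  }, by = .(family, contig)]
  pooled[grp$idx, locus := paste(family, contig, grp$sub, sep = ":")]
  out <- pooled[, {
    pres <- lapply(names(call_sets), function(nm) any(set_id == nm))
    names(pres) <- names(call_sets)
    c(list(breakpoint = as.integer(round(stats::median(breakpoint)))), pres)
  }, by = .(family, contig, locus)]
  out[, n_sets := rowSums(as.matrix(.SD)), .SDcols = names(call_sets)]
  out[, locus := NULL]
  out[]
}

#' Per-family de-novo-insertion ratio between conditions
#'
#' `ratio = (unique_a + eps) / (unique_b + eps)`. With the default
#' `eps = 0`, a family with both counts zero gets `NA` (undefined, not 1)
#' and a positive numerator over a zero denominator gives `Inf`. Families
#' at or above `flag_threshold` are flagged as candidate transposing
#' families.
#'
#' @param unique_a,unique_b per-family unique-call counts: named numeric
#'   vectors, or tables with `family` and `count`/`N` columns, or
#'   `insertion_calls` tables (counted by family).
#' @param eps pseudocount (documented default 0).
#' @param flag_threshold ratio flag level (default 3).
#' @return data.table (family, unique_a, unique_b, ratio, flagged).
#' @export
denovo_ratio <- function(unique_a, unique_b, eps = 0, flag_threshold = 3) {
  ca <- as_family_counts(unique_a)
  cb <- as_family_counts(unique_b)
  m <- merge(ca, cb, by = "family", all = TRUE,
             suffixes = c("_a", "_b"))
  m[is.na(m)] <- 0
  data.table::setnames(m, c("count_a", "count_b"),
                       c("unique_a", "unique_b"))
  m[, ratio := data.table::fifelse(
    unique_a + eps == 0 & unique_b + eps == 0, NA_real_,
    (unique_a + eps) / (unique_b + eps))]
  m[, flagged := !is.na(ratio) & ratio >= flag_threshold]
  m[]
}

as_family_counts <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    return(data.table::data.table(family = names(x), count = as.numeric(x)))
  }
  dt <- data.table::as.data.table(x)
  if ("count" %in% names(dt)) return(dt[, .(family, count)])
  if ("N" %in% names(dt)) return(dt[, .(family, count = N)])
  dt[, .(count = as.numeric(.N)), by = family]
}

#' Coverage-matched random subsampling of a library
#'
#' Randomly subsamples read pairs from library A (without replacement, at
#' read-pair granularity, so OEA semantics survive) until its mapped read
#' count matches `target_mapped`, reruns the full caller and the
#' library-specific comparison against `calls_b` on every subsample, and
#' returns per-family mean and SD of the unique-to-A counts across the
#' replicates.
#'
#' @param alignments_a paired alignment records of the deeper library.
#' @param calls_b insertion calls of the reference-depth library.
#' @param target_mapped mapped read count to match (<= mapped reads in A).
#' @param te_library canonical TE sequences (or [te_end_library()]).
#' @param cfg a [compare_config()] (`n_subsamples`, matching window).
#' @param seed master seed; each replicate uses an independent derived
#'   seed.
#' @param ... caller parameters forwarded to [call_insertions()].
#' @return list(mean, sd: named per-family vectors; replicates: data.table
#'   replicate x family of unique-to-A counts; fraction).
#' @export
subsample_matched <- function(alignments_a, calls_b, target_mapped,
                              te_library, cfg = compare_config(),
                              seed = 1L, ...) {
  aln <- data.table::as.data.table(alignments_a)
  mapped_total <- sum(aln_is_mapped(aln) & aln_is_primary(aln))
  if (target_mapped > mapped_total) {
    stop("target_mapped exceeds mapped reads available", call. = FALSE)
  }
  pairs <- unique(aln$qname)
  n_sel <- as.integer(round(length(pairs) * target_mapped / mapped_total))
  seeds <- derive_seeds(seed, cfg$n_subsamples)
  fams <- sort(unique(c(
    as.character(data.table::as.data.table(calls_b)$family),
    if (inherits(te_library, "te_end_library")) te_library$family
    else names(te_library))))
  reps <- matrix(0, nrow = cfg$n_subsamples, ncol = length(fams),
                 dimnames = list(NULL, fams))
  for (r in seq_len(cfg$n_subsamples)) {
    old <- local_seed(seeds[r])
    sel <- if (n_sel >= length(pairs)) pairs else sample(pairs, n_sel)
    restore_seed(old)
    sub <- aln[qname %in% sel]
    calls <- call_insertions(sub, te_library, ...)
    uni <- library_specific(calls, calls_b, cfg)$unique_a
    if (nrow(uni) > 0L) {
      tab <- uni[, .N, by = family]
      reps[r, tab$family] <- tab$N
    }
  }
  list(mean = colMeans(reps), sd = apply(reps, 2L, stats::sd),
       replicates = data.table::as.data.table(reps),
       fraction = target_mapped / mapped_total)
}
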