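#' @import data.table
#' @importFrom stats rnorm rpois rbinom runif setNames shapiro.test t.test cor
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", ".I", "qname", "rname", "pos", "flag", "score",
  "n_best", "is_best", "family", "contig", "start", "end", "strand",
  "size", "orientation", "raw", "normalized", "weight", "cluster_id",
  "anchor_pos", "kind", "label", "category", "breakpoint", "support_sc",
  "support_oea", "unique_mapper", "seq", "cigar", "first_nt", "source_id",
  "count", "excluded", "value", "condition", "locus", "set_id", "mapq",
  "mate_mapped", "ref_type", "ref_id", "k", "w", "fc", "log2fc", "flagged",
  "norm_a", "norm_b", "fold", "assigned", "ambiguous", "entry",
  "best_score", "identity", "hit_len", "te_end", "query_seq",
  "anchor_strand", "clip_side", "proper", "p5a", "mate_seq", "unique_a",
  "unique_b", "ratio", "N", "id", "te_offset"
))

## ---- sequence helpers -------------------------------------------------

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. nucleotide composition. Used for toy-genome background and
#' TE family consensus sequences.
#'
#' @param n sequence length in nucleotides.
#' @return a single character string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  # intToUtf8 on sampled code points is much faster than paste(collapse=)
  codes <- utf8ToInt("ACGT")
  intToUtf8(codes[sample.int(4L, n, replace = TRUE)])
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Point-mutate a DNA sequence at a given divergence rate
#'
#' Each position is substituted independently with probability `rate`; the
#' replacement is drawn uniformly from the three other bases.
#'
#' @param seq a single DNA string.
#' @param rate per-base substitution probability.
#' @return the mutated string.
#' @keywords internal
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_ALPHABET, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# vectorised Hamming distance between equal-length string pairs
hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

## ---- seed handling ----------------------------------------------------

# Derive a stream of child seeds (< 2^31) from a master seed without
# disturbing the caller's RNG state more than once.
derive_seeds <- function(master_seed, n) {
  old <- local_seed(master_seed)
  on.exit(restore_seed(old))
  sample.int(.Machine$integer.max - 1L, n)
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

## ---- small assertions -------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("'%s' must be a single number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}
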