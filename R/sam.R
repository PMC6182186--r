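## Alignment-record plumbing. Internally every module works on a plain
## data.table of alignment records with SAM semantics; read/write SAM text
## is provided as the external interface. Flag bits follow the SAM spec.

FLAG_PAIRED <- 1L
FLAG_PROPER <- 2L
FLAG_UNMAPPED <- 4L
FLAG_MATE_UNMAPPED <- 8L
FLAG_REVERSE <- 16L
FLAG_MATE_REVERSE <- 32L
FLAG_FIRST <- 64L
FLAG_SECOND <- 128L
FLAG_SECONDARY <- 256L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Construct an empty alignment-record table
#'
#' The canonical in-memory representation of alignments throughout the
#' package: one row per alignment, SAM-style fields plus an `AS`-like
#' `score` column (0 = perfect, negative penalties, Bowtie2 end-to-end
#' convention).
#'
#' @return a zero-row data.table with the alignment-record columns.
#' @export
alignment_records <- function() {
  data.table::data.table(
    qname = character(), flag = integer(), rname = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    rnext = character(), pnext = integer(), tlen = integer(),
    seq = character(), score = numeric()
  )
}

aln_is_mapped <- function(aln) !has_flag(aln$flag, FLAG_UNMAPPED)
aln_is_reverse <- function(aln) has_flag(aln$flag, FLAG_REVERSE)
aln_is_primary <- function(aln) !has_flag(aln$flag, FLAG_SECONDARY)

## ---- CIGAR ------------------------------------------------------------

# parse CIGAR strings into per-record op/length lists
cigar_ops <- function(cigar) {
  lapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") {
      return(list(op = character(0), len = integer(0)))
    }
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    list(op = op, len = len)
  })
}

# reference-consumed length of an alignment (fast path for pure-match
# cigars, which dominate)
cigar_ref_len <- function(cigar) {
  out <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  out[simple] <- as.integer(sub("M", "", cigar[simple], fixed = TRUE))
  idx <- which(!simple & !is.na(cigar) & cigar != "*")
  if (length(idx) > 0L) {
    m <- gregexpr("[0-9]+(?=[MDN=X])", cigar[idx], perl = TRUE)
    out[idx] <- vapply(regmatches(cigar[idx], m),
                       function(v) sum(as.integer(v)), 0L)
  }
  out
}

# leading/trailing soft-clip lengths (vectorised over records)
cigar_clips <- function(cigar) {
  cigar[is.na(cigar)] <- "*"
  lm <- regmatches(cigar, regexpr("^[0-9]+(?=S)", cigar, perl = TRUE))
  left <- integer(length(cigar))
  left[grepl("^[0-9]+S", cigar)] <- as.integer(lm)
  rm_ <- regmatches(cigar, regexpr("[0-9]+(?=S$)", cigar, perl = TRUE))
  has_r <- grepl("[0-9]+S$", cigar) & !grepl("^[0-9]+S$", cigar)
  right <- integer(length(cigar))
  rmatch <- gregexpr("[0-9]+(?=S$)", cigar, perl = TRUE)
  rv <- regmatches(cigar, rmatch)
  right[has_r] <- vapply(rv[has_r], function(v) as.integer(v[length(v)]), 0L)
  data.table::data.table(left = left, right = right)
}

## ---- best-score bookkeeping -------------------------------------------

# annotate each record with the number of best-score alignments of its read
# and whether the record itself is one of them; unmapped records get NA
mark_best_alignments <- function(aln) {
  aln <- data.table::as.data.table(aln)
  aln[, n_best := NA_integer_]
  aln[, is_best := FALSE]
  mapped <- which(aln_is_mapped(aln))
  if (length(mapped) > 0L) {
    m <- aln[mapped]
    m[, `:=`(is_best = score == max(score), n_best = sum(score == max(score))),
      by = qname]
    aln[mapped, c("n_best", "is_best") := list(m$n_best, m$is_best)]
  }
  aln[]
}

## ---- SAM text I/O -----------------------------------------------------

#' Write alignment records as SAM text
#'
#' @param aln alignment-record data.table (see [alignment_records()]).
#' @param path output path.
#' @param contigs named character vector (or named lengths) used for the
#'   `@SQ` header lines.
#' @return invisibly, `path`.
#' @export
write_sam <- function(aln, path, contigs) {
  lens <- if (is.character(contigs)) nchar(contigs) else contigs
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
  aln <- data.table::as.data.table(aln)
  tag <- ifelse(is.na(aln$score), "",
                sprintf("\tAS:i:%d", as.integer(round(aln$score))))
  body <- paste0(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                         aln$qname, aln$flag,
                         ifelse(is.na(aln$rname), "*", aln$rname),
                         ifelse(is.na(aln$pos), 0L, aln$pos),
                         ifelse(is.na(aln$mapq), 0L, aln$mapq),
                         ifelse(is.na(aln$cigar), "*", aln$cigar),
                         ifelse(is.na(aln$rnext), "*", aln$rnext),
                         ifelse(is.na(aln$pnext), 0L, aln$pnext),
                         ifelse(is.na(aln$tlen), 0L, aln$tlen),
                         aln$seq), tag)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM text into an alignment-record table
#'
#' Parses the mandatory fields plus an `AS:i:` score tag if present
#' (records without one get score `NA`).
#'
#' @param path SAM file path.
#' @return alignment-record data.table.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(alignment_records())
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:11)
  score <- rep(NA_real_, length(lines))
  m <- regmatches(lines, regexpr("AS:i:-?[0-9]+", lines))
  hasm <- grepl("AS:i:", lines, fixed = TRUE)
  score[hasm] <- as.numeric(sub("AS:i:", "", m))
  data.table::data.table(
    qname = f[[1]], flag = as.integer(f[[2]]),
    rname = ifelse(f[[3]] == "*", NA_character_, f[[3]]),
    pos = as.integer(f[[4]]), mapq = as.integer(f[[5]]),
    cigar = ifelse(f[[6]] == "*", NA_character_, f[[6]]),
    rnext = ifelse(f[[7]] == "*", NA_character_, f[[7]]),
    pnext = as.integer(f[[8]]), tlen = as.integer(f[[9]]),
    seq = f[[10]], score = score
  )
}
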