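## De novo TE insertion caller. Evidence = soft-clipped reads (clipped tail
## spans the TE-genome junction) and one-end-anchored (OEA) pairs (unmapped
## mate may be inserted TE sequence). Evidence is clustered by anchor
## position, cluster queries are matched against a library of TE terminal
## segments (600 first/last bases, truncated to the ~500 nt insert-size
## cap) with a local aligner standing in for BLAT, and a second clustering
## step defines the insertion breakpoint.

#' Build a TE-end library from canonical sequences
#'
#' Each family contributes its 5' and 3' terminal segment: the first/last
#' `end_len` bases, truncated to `effective_cap` (the insert-size
#' restriction). Families shorter than `end_len` contribute a single
#' full-length entry.
#'
#' @param te_library named character vector of canonical TE sequences.
#' @param end_len terminal segment length extracted (default 600 nt).
#' @param effective_cap effective length after the insert-size restriction
#'   (default 500 nt).
#' @return data.table (family, end in \{5p, 3p, full\}, seq) with class
#'   `te_end_library`.
#' @export
te_end_library <- function(te_library, end_len = 600L,
                           effective_cap = 500L) {
  keep_len <- min(end_len, effective_cap)
  out <- list()
  for (f in names(te_library)) {
    s <- te_library[[f]]
    L <- nchar(s)
    if (L <= end_len) {
      out[[length(out) + 1L]] <- data.table::data.table(
        family = f, end = "full", seq = substr(s, 1L, min(L, keep_len)))
    } else {
      out[[length(out) + 1L]] <- data.table::data.table(
        family = f, end = c("5p", "3p"),
        seq = c(substr(s, 1L, keep_len), substr(s, L - keep_len + 1L, L)))
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "class", c("te_end_library", class(res)))
  res[]
}

#' Extract soft-clip and OEA evidence from paired alignments
#'
#' Soft-clip evidence comes from primary mapped records with a terminal
#' clip of at least `min_clip` nt; the anchor position is the reference
#' coordinate flanking the clip (right clip: last mapped base; left clip:
#' the base before the first mapped one), so reads from both sides of an
#' insertion point agree on the breakpoint. OEA evidence comes from pairs
#' with exactly one mapped mate; the query is the unmapped mate's sequence
#' and the anchor is the mapped mate's inner edge.
#'
#' @param alignments paired alignment records.
#' @param min_clip minimum clipped-tail length (default 20 nt).
#' @return data.table (kind, contig, anchor_pos, anchor_strand, query_seq,
#'   clip_side, qname).
#' @export
extract_evidence <- function(alignments, min_clip = 20L) {
  aln <- data.table::as.data.table(alignments)
  if (nrow(aln) > 0L && !any(has_flag(aln$flag, FLAG_PAIRED))) {
    warning("single-end input: no OEA evidence possible", call. = FALSE)
  }
  prim <- aln[aln_is_mapped(aln) & aln_is_primary(aln)]
  ev <- list()
  if (nrow(prim) > 0L) {
    clips <- cigar_clips(prim$cigar)
    reflen <- cigar_ref_len(prim$cigar)
    li <- which(clips$left >= min_clip)
    if (length(li) > 0L) {
      ev[[length(ev) + 1L]] <- data.table::data.table(
        kind = "soft_clip", contig = prim$rname[li],
        anchor_pos = prim$pos[li] - 1L,
        anchor_strand = ifelse(aln_is_reverse(prim[li]), "-", "+"),
        query_seq = substr(prim$seq[li], 1L, clips$left[li]),
        clip_side = "left", qname = prim$qname[li])
    }
    ri <- which(clips$right >= min_clip)
    if (length(ri) > 0L) {
      n <- nchar(prim$seq[ri])
      ev[[length(ev) + 1L]] <- data.table::data.table(
        kind = "soft_clip", contig = prim$rname[ri],
        anchor_pos = prim$pos[ri] + reflen[ri] - 1L,
        anchor_strand = ifelse(aln_is_reverse(prim[ri]), "-", "+"),
        query_seq = substr(prim$seq[ri], n - clips$right[ri] + 1L, n),
        clip_side = "right", qname = prim$qname[ri])
    }
    # OEA: mapped primary whose mate is unmapped
    oea_anchor <- prim[has_flag(flag, FLAG_PAIRED) &
                         has_flag(flag, FLAG_MATE_UNMAPPED)]
    if (nrow(oea_anchor) > 0L) {
      unm <- aln[!aln_is_mapped(aln), .(qname, mate_seq = seq)]
      unm <- unm[!duplicated(qname)]
      oea <- merge(oea_anchor, unm, by = "qname", sort = FALSE)
      if (nrow(oea) > 0L) {
        rev <- aln_is_reverse(oea)
        ev[[length(ev) + 1L]] <- data.table::data.table(
          kind = "oea", contig = oea$rname,
          # inner edge of the anchor: end of a forward anchor (insertion
          # expected downstream), start of a reverse anchor (upstream)
          anchor_pos = ifelse(rev, oea$pos,
                              oea$pos + cigar_ref_len(oea$cigar) - 1L),
          anchor_strand = ifelse(rev, "-", "+"),
          query_seq = oea$mate_seq, clip_side = NA_character_,
          qname = oea$qname)
      }
    }
  }
  if (length(ev) == 0L) {
    return(data.table::data.table(
      kind = character(), contig = character(), anchor_pos = integer(),
      anchor_strand = character(), query_seq = character(),
      clip_side = character(), qname = character()))
  }
  out <- data.table::rbindlist(ev)
  out[nchar(query_seq) >= min_clip]
}

#' Single-linkage positional clustering of evidence
#'
#' Consecutive anchors (sorted within contig) at most `cluster_window`
#' apart join one cluster; clusters with fewer than `min_support` evidence
#' records are dropped.
#'
#' @param evidence [extract_evidence()] output.
#' @param cluster_window linkage distance (nt); the default, two insert
#'   sizes, spans the anchor scatter of one insertion.
#' @param min_support minimum evidence records per cluster.
#' @return the evidence table with a `cluster_id` column, filtered to
#'   surviving clusters.
#' @export
cluster_evidence <- function(evidence, cluster_window = 1000L,
                             min_support = 2L) {
  ev <- data.table::as.data.table(evidence)
  if (nrow(ev) == 0L) {
    ev[, cluster_id := integer(0)]
    return(ev)
  }
  data.table::setorder(ev, contig, anchor_pos)
  new_cluster <- c(TRUE, ev$contig[-1L] != ev$contig[-nrow(ev)] |
                     diff(ev$anchor_pos) > cluster_window)
  ev[, cluster_id := cumsum(new_cluster)]
  ev[, if (.N >= min_support) .SD, by = cluster_id]
}

#' Match cluster queries against the TE-end library
#'
#' Every query sequence is locally aligned (match +1, mismatch -1, linear
#' gap -2 -- a BLAT stand-in) against every library entry, on both
#' strands. A cluster is assigned to the family with the highest best
#' score, provided that alignment reaches `min_identity` over at least
#' `min_hit_len` aligned columns; score ties between distinct families
#' mark the cluster ambiguous (excluded from calls).
#'
#' @param clustered [cluster_evidence()] output.
#' @param lib a [te_end_library()].
#' @param min_identity fractional identity threshold (default 0.9).
#' @param min_hit_len minimum alignment length (default 20 nt).
#' @param max_queries per-cluster cap on aligned query sequences (evenly
#'   spaced after sorting by anchor, deterministic); assignment needs only
#'   a handful of junction sequences and the cap keeps desk-scale runtimes
#'   proportional to cluster count, not coverage.
#' @return data.table (cluster_id, family, te_end, best_score,
#'   identity, mean_match_score, ambiguous, assigned).
#' @export
match_te_ends <- function(clustered, lib, min_identity = 0.9,
                          min_hit_len = 20L, max_queries = 16L) {
  if (nrow(lib) == 0L) stop("empty TE-end library", call. = FALSE)
  ev <- data.table::as.data.table(clustered)
  out <- list()
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  for (cid in unique(ev$cluster_id)) {
    q <- ev$query_seq[ev$cluster_id == cid]
    if (length(q) > max_queries) {
      q <- q[unique(as.integer(round(seq(1L, length(q),
                                         length.out = max_queries))))]
    }
    pats <- Biostrings::DNAStringSet(c(q, revcomp(q)))
    nq <- length(q)
    # per (entry, query): best local score over both query strands
    best_by_entry <- matrix(-Inf, nrow = nrow(lib), ncol = nq)
    width_best <- id_best <- matrix(NA_real_, nrow = nrow(lib), ncol = nq)
    for (e in seq_len(nrow(lib))) {
      pa <- Biostrings::pairwiseAlignment(
        pats, Biostrings::DNAString(lib$seq[e]), type = "local",
        substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
      sc <- Biostrings::score(pa)
      pid <- Biostrings::pid(pa) / 100
      wd <- Biostrings::nchar(pa)
      for (j in seq_len(nq)) {
        s2 <- c(sc[j], sc[j + nq])
        k <- which.max(s2)
        if (s2[k] > best_by_entry[e, j]) {
          best_by_entry[e, j] <- s2[k]
          id_best[e, j] <- c(pid[j], pid[j + nq])[k]
          width_best[e, j] <- c(wd[j], wd[j + nq])[k]
        }
      }
    }
    # per family: best single hit and mean of per-query bests
    fam_tab <- data.table::data.table(family = lib$family, end = lib$end,
                                      entry = seq_len(nrow(lib)))
    per_fam <- fam_tab[, {
      sub <- best_by_entry[entry, , drop = FALSE]
      bi <- arrayInd(which.max(sub), dim(sub))
      list(best_score = sub[bi],
           identity = id_best[entry, , drop = FALSE][bi],
           hit_len = width_best[entry, , drop = FALSE][bi],
           te_end = end[bi[1L]],
           mean_match_score = mean(apply(sub, 2L, max)))
    }, by = family]
    data.table::setorder(per_fam, -best_score)
    top <- per_fam[1L]
    ambiguous <- nrow(per_fam) > 1L &&
      isTRUE(all.equal(per_fam$best_score[2L], top$best_score))
    assigned <- !ambiguous && top$identity >= min_identity &&
      top$hit_len >= min_hit_len
    out[[length(out) + 1L]] <- data.table::data.table(
      cluster_id = cid, family = top$family, te_end = top$te_end,
      best_score = top$best_score, identity = top$identity,
      mean_match_score = top$mean_match_score,
      ambiguous = ambiguous, assigned = assigned)
  }
  data.table::rbindlist(out)
}

#' Define insertion breakpoints from assigned clusters
#'
#' Soft-clip evidence defines the breakpoint at the modal clip coordinate;
#' OEA-only clusters use the inner edge of the anchor span. Assigned
#' clusters of the same family whose breakpoints fall within
#' `second_window` merge into one call.
#'
#' @param clustered [cluster_evidence()] output.
#' @param assignments [match_te_ends()] output.
#' @param second_window merge distance for same-family clusters (default
#'   50 nt).
#' @return data.table of calls (family, contig, breakpoint, te_end,
#'   support_sc, support_oea, mean_match_score) with class
#'   `insertion_calls`.
#' @export
call_breakpoints <- function(clustered, assignments, second_window = 50L) {
  ev <- data.table::as.data.table(clustered)
  asg <- data.table::as.data.table(assignments)[assigned == TRUE]
  empty <- data.table::data.table(
    family = character(), contig = character(), breakpoint = integer(),
    te_end = character(), support_sc = integer(), support_oea = integer(),
    mean_match_score = numeric())
  if (nrow(asg) == 0L) {
    data.table::setattr(empty, "class", c("insertion_calls", class(empty)))
    return(empty)
  }
  calls <- list()
  for (i in seq_len(nrow(asg))) {
    a <- asg[i]
    sub <- ev[cluster_id == a$cluster_id]
    sc <- sub[kind == "soft_clip"]
    if (nrow(sc) > 0L) {
      tab <- table(sc$anchor_pos)
      bp <- as.integer(names(tab)[which.max(tab)])
    } else {
      fw <- sub[anchor_strand == "+", anchor_pos]
      rv <- sub[anchor_strand == "-", anchor_pos]
      bp <- if (length(fw) > 0L && length(rv) > 0L) {
        as.integer(round((max(fw) + min(rv)) / 2))
      } else if (length(fw) > 0L) max(fw) else min(rv)
    }
    calls[[i]] <- data.table::data.table(
      family = a$family, contig = sub$contig[1L], breakpoint = bp,
      te_end = a$te_end, support_sc = nrow(sc),
      support_oea = nrow(sub) - nrow(sc),
      mean_match_score = a$mean_match_score)
  }
  calls <- data.table::rbindlist(calls)
  # second clustering: merge same-family calls within second_window
  data.table::setorder(calls, family, contig, breakpoint)
  grp <- calls[, {
    new <- c(TRUE, diff(breakpoint) > second_window)
    list(idx = .I, sub = cumsum(new))
  }, by = .(family, contig)]
  calls[grp$idx, locus := grp$sub]
  merged <- calls[, .(
    breakpoint = breakpoint[which.max(support_sc)],
    te_end = te_end[which.max(support_sc + support_oea)],
    support_sc = sum(support_sc), support_oea = sum(support_oea),
    mean_match_score = mean(mean_match_score)
  ), by = .(family, contig, locus)]
  merged[, locus := NULL]
  data.table::setattr(merged, "class", c("insertion_calls", class(merged)))
  merged[]
}

#' Full insertion-calling pipeline
#'
#' extract evidence, cluster, match against the TE-end library, define
#' breakpoints.
#'
#' @param alignments paired alignment records.
#' @param te_library named canonical TE sequences (or a prebuilt
#'   [te_end_library()]).
#' @param min_clip,cluster_window,min_support,second_window,min_identity,min_hit_len
#'   caller parameters (see the stage functions).
#' @return an `insertion_calls` table.
#' @export
call_insertions <- function(alignments, te_library, min_clip = 20L,
                            cluster_window = 1000L, min_support = 2L,
                            second_window = 50L, min_identity = 0.9,
                            min_hit_len = 20L, max_queries = 16L) {
  lib <- if (inherits(te_library, "te_end_library")) te_library
         else te_end_library(te_library)
  ev <- extract_evidence(alignments, min_clip = min_clip)
  cl <- cluster_evidence(ev, cluster_window = cluster_window,
                         min_support = min_support)
  if (nrow(cl) == 0L) {
    return(call_breakpoints(cl, data.table::data.table(assigned = logical())))
  }
  asg <- match_te_ends(cl, lib, min_identity = min_identity,
                       min_hit_len = min_hit_len, max_queries = max_queries)
  call_breakpoints(cl, asg, second_window = second_window)
}

#' Write insertion calls as a BED-like TSV
#'
#' @param calls an `insertion_calls` table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_calls <- function(calls, path) {
  out <- data.table::data.table(
    chrom = calls$contig, start = calls$breakpoint - 1L,
    end = calls$breakpoint, family = calls$family,
    support_sc = calls$support_sc, support_oea = calls$support_oea,
    score = calls$mean_match_score)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
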