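# Shared fixtures (memoised across test files within one session) and
# independent oracles used by the property-style tests.

.fixture_cache <- local({
  if (!exists(".ervmob_test_cache", envir = globalenv())) {
    assign(".ervmob_test_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  }
  get(".ervmob_test_cache", envir = globalenv())
})

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small genome for unit tests (fast); acceptance tests build the full one
small_genome_config <- function(divergence = 0) {
  toy_genome_config(
    contig_lengths = c(cA = 30000L, cB = 30000L),
    mt_contig = "cM", mt_length = 8000L,
    te_families = c(ZAMx = 1500L, GTWx = 1500L, CTRLx = 1200L),
    te_copy_numbers = c(ZAMx = 2L, GTWx = 2L, CTRLx = 3L),
    divergence = divergence,
    clusters = list(cluster1 = list(class = "piRNA", length = 2000L),
                    sicluster1 = list(class = "siRNA", length = 1000L)),
    features = list(n_rrna = 1L, rrna_length = 300L,
                    n_mirna = 1L, mirna_length = 100L,
                    n_genes = 2L, gene_length = 1000L, utr3_length = 200L)
  )
}

small_genome <- function() {
  memo("small_genome", build_toy_genome(small_genome_config(), seed = 42))
}

# full-size stated world used by the acceptance criteria
accept_genome <- function() {
  memo("accept_genome", build_toy_genome(toy_genome_config(), seed = 1))
}

## ---- oracles ----------------------------------------------------------

# exhaustive realignment of one read against the toy genome (both strands)
oracle_genome_hits <- function(read_seq, genome) {
  out <- list()
  for (ct in names(genome$contigs)) {
    subj <- Biostrings::DNAString(genome$contigs[[ct]])
    fwd <- Biostrings::start(Biostrings::matchPattern(read_seq, subj))
    rev <- Biostrings::start(
      Biostrings::matchPattern(ervmob::revcomp(read_seq), subj))
    if (length(fwd) > 0L) {
      out[[length(out) + 1L]] <- data.frame(contig = ct, pos = fwd,
                                            strand = "+")
    }
    if (length(rev) > 0L) {
      out[[length(out) + 1L]] <- data.frame(contig = ct, pos = rev,
                                            strand = "-")
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      strand = character()))
  }
  do.call(rbind, out)
}

# O(n^2) single-linkage clustering: connected components of the
# within-window adjacency graph, found by BFS (independent of the sorted
# chaining used by the implementation)
oracle_single_linkage <- function(contig, pos, window) {
  n <- length(pos)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(is.na(comp) & contig == contig[v] &
                    abs(pos - pos[v]) <= window)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# all-pairs windowed matching oracle for insertion-call comparison
oracle_matched <- function(a, b, window) {
  vapply(seq_len(nrow(a)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$family[i] == b$family[j] && a$contig[i] == b$contig[j] &&
          abs(a$breakpoint[i] - b$breakpoint[j]) <= window) {
        hit <- TRUE
        break
      }
    }
    hit
  }, logical(1))
}

# minimal hand-built insertion_calls table
make_calls <- function(family, contig, breakpoint) {
  data.table::data.table(
    family = family, contig = contig, breakpoint = as.integer(breakpoint),
    te_end = "5p", support_sc = 5L, support_oea = 5L,
    mean_match_score = 50)
}
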