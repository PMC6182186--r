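Package: ervmob
Title: Endogenous Retrovirus Mobilization Analysis from Small-RNA, Mobilome
    and Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a
    computational pipeline for quantifying endogenous retrovirus (ERV)
    activity after somatic piRNA loss in Drosophila ovaries: classification
    and cluster-1-normalized counting of piRNA (23-30 nt) and siRNA (21 nt)
    candidates from small-RNA alignments; quantification of
    extrachromosomal circular DNA (eccDNA) from mobilome-seq with
    best-score assignment, score-floor filtering, ex-aequo down-weighting
    and mtDNA normalization; de novo transposable-element insertion calling
    from soft-clipped and one-end-anchored paired-end evidence with
    TE-end-library matching; windowed insertion-set comparison,
    de-novo-insertion ratios and coverage-matched subsampling; and
    transposition-rate / Poisson statistics. A synthetic-data module
    generates a toy genome, TE library and all three read-library types
    with known ground truth, so every stage is testable without external
    data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
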