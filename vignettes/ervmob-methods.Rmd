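---
title: "ervmob: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ervmob: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each
module computes, the assumptions behind it, the tunable parameters with
their defaults and rationale, what the synthetic-data generator does and
does not emulate, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The pipeline in one paragraph

Somatic loss of piRNAs derepresses endogenous retroviruses (ERVs) at
several stages of a retroviral cycle, and each stage is read out by a
different sequencing assay. `ervmob` implements the downstream
computations for three assays — small-RNA-seq (piRNA/siRNA
classification and normalized counting), mobilome-seq (eccDNA
quantification), and paired-end genomic sequencing (de novo TE insertion
calling and condition comparison) — plus the transposition-rate and
Poisson arithmetic that connects observed insertion counts to rates per
copy per generation. A synthetic-data module supplies all inputs with
known truth so that every stage is testable offline.

## 2. Coordinates and alignment conventions

Internally all coordinates are **1-based closed**, the R/Bioconductor
(IRanges/GRanges) and SAM convention; BED output converts to 0-based
half-open. This deviates from a 0-based-internal design sketch on
purpose: in R, 1-based intervals are what every interval engine the
package uses (IRanges, GenomicRanges) expects, and carrying a second
convention internally would be a standing source of off-by-one defects.

Alignment scores follow the Bowtie2 end-to-end convention: 0 is a
perfect match, mismatches subtract 6. The mobilome score floor
("discard strictly below −10") is therefore directly meaningful: a read
with two or more mismatches against its best canonical TE is dropped.

The pipeline never shells out to an aligner. The simulators emit
alignment records (data.tables with SAM semantics; `read_sam()` /
`write_sam()` provide the text interface) with correct clip, mate,
strand and score fields, because the alignment step itself is out of
scope and exactness is what makes oracle tests possible.

## 3. The toy genome and what it emulates

`build_toy_genome()` produces: two 100 kb autosomal contigs of uniform
random sequence, a 15 kb mitochondrial contig, and a canonical TE
library of three families embedded as genomic copies — `ZAMx` (4 kb,
4 copies: the "few active copies" regime of a young invasive ERV),
`GTWx` (4 kb, 3 copies) and `CTRLx` (3 kb, 10 copies: a high-load
family, the regime in which chimeric artifacts are most troublesome).
One germline piRNA cluster (`cluster1`, the 42AB-like normalizer), one
ovarian siRNA cluster, and rRNA/miRNA/gene(3′UTR) features complete the
annotation. Copies are embedded verbatim at `divergence = 0` (the
default) so that an exhaustive substring search is an exact oracle for
every emitted read; divergence is configurable upward, in which case
scores carry −6 per mismatch.

Not emulated, deliberately: sequencing error and quality strings
(constant), PCR duplicates, rolling-circle branching artifacts,
repeat-induced mapping ambiguity beyond exact TE copies, and real
*Drosophila* sequence composition. A green test on this world therefore
establishes the *logic* of each computation (classification rules,
weighting, clustering, windows, normalization, ratio behaviour under a
known artifact model) — not robustness to base-call noise or to
reference errors.

## 4. Small-RNA module

Reads are linker-trimmed and length-selected to 18–30 nt. Annotation is
two-stage: reads whose best-score alignments touch rRNA or miRNA are
excluded outright; the rest are labeled **non-exclusively** with every
category they overlap (piRNA/siRNA cluster, TE copy, 3′UTR), because the
downstream counting re-maps candidates to clusters and canonical TEs
separately. piRNA candidates are 23–30 nt, siRNA candidates exactly
21 nt; the sets are disjoint by construction.

Counting uses the **canonical** re-assignment (exact substring match of
the read, on either strand, against the canonical TE sequences), not the
genomic copy: a read with k ex-aequo canonical families contributes 1/k
to each, so per-family fractional counts conserve the number of counted
reads to 1e−6. The multi-mapper rule is uniform 1/k; the small-RNA
literature is not specific here, and 1/k mirrors the explicitly stated
ex-aequo rule of the mobilome assay.

"Unique mapper" means exactly one best-score genomic alignment; ties at
equal score are not unique. Normalization divides by the cluster-1
unique-mapper count and multiplies by a presentation-level scale
(default 1e6, i.e. counts per million cluster-1 unique mappers; only
ratios are ever interpreted). Fold changes default to a pseudocount of 1
(in normalized units) so zero-count families stay finite; Spearman rank
correlation of fold-change vectors is delegated to `stats::cor`.

5′-nucleotide bias is reported per class (21-mers vs 23–30-mers) as four
fractions summing to 1. The simulator can enforce a target 5′-A fraction
per profile row by conditioning sampled start positions on the base at
the 5′ end — reads remain exact genome substrings, so the enforcement is
invisible to the alignment oracle.

## 5. Mobilome module

A read is a TE read iff at least one of its best-score alignments falls
in a genomic TE copy or on a canonical TE. TE reads are then counted
against canonical TEs only: alignments scoring strictly below the floor
(default −10) are discarded, a read's surviving ex-aequo best families
share 1/k each, and per-family weights are normalized **per thousand
mtDNA reads** (the stated unit of the assay — mtDNA is circular,
survives the linear-DNA digestion, and tracks library depth). All
primary mt-mapped reads count toward the normalizer, before any score
filtering; whether the original analysis filtered first is unknowable
from the text, and the choice only rescales both conditions equally.
Mates are counted as independent reads (the simulator emits single-end
250 nt records for this reason); duplicate marking is off, since
rolling-circle amplification makes duplicates uninformative.

The down-weighting strategy is an explicit function slot in
`mobilome_config()` so alternatives (e.g. score-proportional) can be
swapped without touching the counting code.

## 6. Insertion caller

Evidence comes from primary alignments only: terminal soft clips of at
least `min_clip` (20 nt) and OEA pairs (exactly one mapped mate). Anchor
positions are chosen so both junction sides vote for the same
breakpoint: a right clip anchors at its last mapped base, a left clip at
the base before its first mapped base. Clustering is single-linkage on
anchor positions with `cluster_window = 1000` nt (two insert sizes —
wide enough to pool soft clips with their OEA halo, narrow enough that
desk-scale insertions ≥3 kb apart never merge); clusters under
`min_support = 2` are dropped. These internals are not published for the
original caller; the defaults here are logged and configurable.

Cluster queries are matched against a TE-end library: the first/last
600 bases of each canonical TE, truncated to the ~500 nt insert-size
cap (both knobs exposed; the truncation resolves the 600-vs-500 tension
by building 600 then capping). The local aligner is
`Biostrings::pairwiseAlignment(type = "local")` with match +1,
mismatch −1, linear gap −2 — a BLAT stand-in that is exact rather than
heuristic, affordable because entries are ≤600 nt. A cluster is assigned
to the argmax-score family if that alignment reaches 90% identity over
≥20 columns; score ties between families mark the cluster ambiguous and
it is excluded. `max_queries` (16) caps the aligned queries per cluster
(evenly spaced, deterministic): assignment needs a handful of junction
sequences, and the cap keeps runtime proportional to cluster count
rather than coverage.

Breakpoints: modal soft-clip coordinate when clips exist; otherwise the
inner edge(s) of the OEA anchor span. A second, 50 nt single-linkage
pass merges same-family clusters into one call each.

## 7. Comparison, ratios and subsampling

Windowed matching (±20 nt) between call sets is **family-aware**: a
`ZAMx` call never matches a `GTWx` call at the same locus. A
family-agnostic intersection would conflate co-located artifacts of
different families; since the ratio statistic is per-family, matching is
done per family (equivalent to splitting BED files per family before a
window intersection). `multi_intersect()` pools ≥2 call sets, merges
same-family breakpoints within the window and reports per-locus
membership — a locus present in exactly one of the 12 single-fly sets is
that fly's candidate de novo insertion.

The de-novo ratio is `(unique_a + ε)/(unique_b + ε)` with ε = 0 by
default: 0/0 is reported as undefined (`NA`), not 1, and a positive
count over zero is `Inf`; a pseudocount mode exists but is off because
ratios were historically computed where denominators were nonzero.
Families at ratio ≥3 are flagged (the threshold at which the strongest
transposing families separated in the motivating study).

Coverage matching: `subsample_matched()` draws read **pairs** without
replacement (pair granularity preserves OEA semantics) at the fraction
`target_mapped / mapped_reads`, reruns the full caller and comparison
per replicate (default 44) with independent derived seeds, and returns
per-family means and SDs. At fraction 1.0 every replicate reproduces the
full analysis exactly, which is both a correctness check and the
determinism anchor of the test suite.

## 8. The chimera model and what the ratio filter can and cannot do

Chimeric TE–genome fragments are a library-preparation artifact: their
abundance scales with a family's genomic copy number and their TE-side
junction points are uniform along the TE, with no preference for the TE
ends. The simulator models them as junction *sites* — Poisson
(`chimera_rate`) per genomic copy per library prep, each site sampled at
the fragment depth of a real junction at the library's coverage. Two
consequences, both intended:

* only the fraction of sites whose TE-side junction falls near enough to
  a TE end to match the end library produces a call (roughly the
  end-library span over the TE length, ~25–30% for a 4 kb family with
  500 nt capped ends), so false-positive calls per family remain
  proportional to copy number;
* those artefact calls are positionally independent between two library
  preps, so they appear as "library-specific" on both sides in equal
  measure, and the per-family ratio concentrates around 1 — while 5 real
  insertions on one side push a low-copy family's ratio well past 3.
  High-copy families (e.g. `CTRLx` at 10 copies) have proportionally
  more artefact background and are correspondingly harder, mirroring the
  known caveat for high-load elements.

The acceptance suite averages unique counts across 20 seeds before
taking the ratio (the same average-before-compare logic as the 44×
subsampling procedure); per-seed ratios at desk-scale counts would be
dominated by Poisson noise in the 0–5 range, where a ratio is barely
defined.

## 9. Rates and probabilities

`transposition_rate()` implements de novo / (pre-existing ×
generations). The commonly printed formula leaves its final "×"
ambiguous; division is the reading consistent with a *per copy per
generation* rate, and both readings coincide at one generation — the
case actually used for sequencing-based estimates. The literal
multiplication reading is available behind a flag and documented as not
a rate.

In `p_zero()` and `p_at_least_one_among()`, λ is the **per-genome** rate
(active copies × per-copy rate; four active `ZAMx` copies at 1e−6..1e−4
give λ = 4e−6..4e−4). Generations and individuals enter as independent
Poisson thinning: `1 − exp(−g·n·λ)`, which for small arguments equals
g·n·λ to first order — the reason the printed 9.6e−5 is exactly
2·12·4e−6. `load_growth()` and `min_rate_for_fold()` give the replicative
copy-number growth `(1+r)^g` and its inverse: a 10-fold increase within
70 generations requires r ≥ 10^(1/70) − 1 ≈ 0.0334, squarely inside the
observed 1e−2..1e−1 band.

`te_load_foldchange()` replaces proprietary qPCR quantification
internals with the standard efficiency-2 relative ratio: fold = mean
ratio vs baseline, Shapiro normality check, two-tailed Welch t-test with
0.05/0.01/0.001 stars. Zero-variance groups (possible in synthetic
fixtures) short-circuit to p = 1 when means are equal.

## 10. Numerical and degenerate-input policy

* Normalizers of zero (cluster-1 unique mappers, mtDNA reads) are
  explicit errors, never silent division.
* Conservation identities (fractional counts vs counted reads) are held
  to 1e−6; fraction sums to 1 within 1e−9.
* Breakpoint mode ties resolve to the smallest coordinate (stable,
  deterministic); OEA-only breakpoints round half up via `round()`.
* Empty inputs return typed empty tables (or warn, for read sets), so
  pipelines compose without special-casing.
* All randomness flows through explicit seeds; derived seeds come from a
  single `sample.int` stream under the master seed and stay below 2^31.

## 11. Open choices made and logged

* eccDNA junction structure (1-LTR vs 2-LTR circles) is not asserted:
  the simulator samples reads from within the linear consensus (no
  wrap-around junction) and the quantifier counts read abundance only —
  circle-junction split-read analysis is a non-goal.
* Whether an alignment-score floor applied to the insertion analysis in
  the original pipeline is unstated; the caller applies none (its
  evidence comes from the mapped side, which the simulators emit at
  score 0) and exposes identity/length thresholds at the matching stage
  instead.
* The WGS simulator emits reads falling entirely inside inserted TE
  sequence as *unmapped*: in a real library those reads multi-map to
  pre-existing copies and contribute no unique anchor, and modelling
  them as unmapped is what converts junction pairs into OEA pairs
  without simulating the whole multi-mapping resolution machinery.

## 12. Known limitations

Desk scale only: ~10^2 kb genomes, ~10^4–10^5 read pairs, three TE
families. No genotyping of reference insertions, no inserted-sequence
assembly, no target-site-duplication inference, no ping-pong signature
analysis, no differential-expression layer. The chimera model is a
structural stand-in — calibrated to produce the right *dependence*
(abundance ∝ copy number, no end preference, independence between
preps), not the right absolute rate, which varies with the wet protocol.
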