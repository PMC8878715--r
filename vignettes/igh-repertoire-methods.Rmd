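---
title: "Inferring the IGH repertoire from bulk RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the IGH repertoire from bulk RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcellrepseq)
```

## The problem

When human B cells are activated and differentiated into antibody-secreting
plasma cells in vitro, two transcriptome-level questions arise that ordinary
gene-level differential expression does not answer. First, which
immunoglobulin heavy-chain (IGH) variable-region rearrangements are being
expressed — i.e. what does the V(D)J repertoire look like at each time point,
and does the culture skew it? Second, are the expressed heavy chains
somatically mutated (the hallmark of memory-derived B cells) or unmutated
(naive-derived)? Dedicated repertoire sequencing answers these directly, but
the same information is latent in standard bulk paired-end RNA-seq: reads
from IGH transcripts align to the IGH locus, and their sequences carry the
V, D and J germline segment identities plus any somatic hypermutation (SHM).

`bcellrepseq` implements that inference as a tested pipeline:

1. **Extraction** — read pairs where either mate's alignment overlaps the
   IGH locus interval are pulled out of a SAM file, whole (the partner mate
   is rescued even if it aligned elsewhere or not at all).
2. **Trimming** — a fixed 6-nt clip removes random-hexamer priming
   artifacts from the 5' end of each mate.
3. **Annotation** — each mate is aligned locally against every germline
   V, D and J segment; per-pair, the two mate annotations are collapsed
   into a single VDJ call and filtered.
4. **Repertoire statistics** — unique VDJ combination counts, per-sample
   relative frequencies, a paired frequency-shift screen between time
   points, and the unmutated/mutated (UM/M) composition.
5. **Expression summary** — the companion count-matrix side: TMM
   normalization, pseudo-counts, a negative-binomial time-course test with
   Benjamini–Hochberg FDR, |log2FC| ≥ 2 & FDR ≤ 0.05 DE calling, biotype
   classification of the DE set, and Ig-locus overlap annotation.

A first-class synthetic-data generator produces germline references,
rearranged and mutated transcripts, paired reads with SAM placements, and
negative-binomial count matrices with recorded truth, so that every stage is
verifiable without access to any particular sequencing deposit.

## The VDJ annotation model

Each mate is aligned against every germline segment on both strands with a
Smith–Waterman-style local alignment (Biostrings underneath). Scoring
defaults are match +1, mismatch −2, gap open −4, gap extend −1, where a gap
of length L costs |open| + (L−1)|extend|; `N` never matches. The read's
orientation is fixed by the best-scoring hit overall, and hits are ranked
per class by (score, identity, name) — a total order, so annotation is
invariant to the order segments appear in the reference.

A class is **confident** on a mate only when its top score strictly exceeds
the runner-up. Two evidence floors prevent spurious confidence:

* **V/J score floor** (default 20): a local alignment scoring below ~20
  matched bases is indistinguishable from chance on a 100-nt read and is
  not treated as evidence at all. Without this floor, mates that do not
  cover a class routinely acquire a "confident" junk hit, which then
  poisons the pair collapse as a phantom conflict.
* **D evidence floor** (default 8 nt): D segments are only 10–37 nt and
  junctional trimming eats their ends, so a D hit counts only when a
  contiguous exact match of at least 8 nt exists (computed by exact k-mer
  matching, independent of the alignment path). In addition, when a mate
  also shows V and/or J, D hits must lie in the junction window between
  the V end and the J start (±3 nt) in read coordinates — a short exact
  match inside the V or the constant region is not interpretable as a D
  call. This mirrors how dedicated annotators restrict the D search to
  the junction.

**Collapse.** Per pair, each class's gene is the union of the two mates'
confident genes: two different confident genes fail the pair as
`AMBIGUOUS_<class>`; no confident gene in some class fails it as
`INCOMPLETE` (a complete call requires V, D and J — only calls whose three
segments could be confidently determined are counted). Either mate covering
fewer than 40 aligned nt fails the pair as `SHORT_READ`. V identity is
pooled across the mates that cover the call's V gene — 100 × total V
matches / total V aligned columns, gap columns counting as non-matches —
and calls below 95% V identity are filtered out (`LOW_V_IDENTITY`); the
threshold is inclusive, so a call at exactly 95.0 passes. Per-read V
mutation counts are the non-matching aligned V columns of each contributing
mate; mates without V coverage are omitted rather than counted as zero.

**UM/M status.** A call is unmutated (UM) when its pooled V mutation count
is ≤ 0 by default. The 0-mutation convention is the strictest reading of
"unmutated"; the CLL literature's 98%-identity convention corresponds to a
non-zero threshold and is available via `threshold_mutations`. Because bulk
RNA-seq cannot resolve cells, calls (transcript pairs), not cells, are the
counting unit throughout; two reads from the same clone count twice.

**Open choices made here.** Identity is computed over covered (aligned)
columns rather than the full V length, and the 40-nt minimum refers to
aligned coverage rather than raw read length; both are the more
conservative readings for partially covering mates. The hexamer trim is
applied to both mates (configurable).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with defaults fixed at design time:

* Germline segments with realistic IGH lengths (V 250–320, D 10–37,
  J 40–65 nt), laid out on a synthetic contig with a decoy contig for
  extraction tests.
* Rearrangement: uniform junctional trims of 0–5 nt per end and uniform
  N-insertions of 0–10 nt (uniform bases). These are deliberately simple —
  real trim/insert distributions are longer-tailed — chosen to exercise the
  D-calling edge cases (short surviving D remnants).
* SHM as independent per-base substitutions restricted to the V portion,
  since mutation counting is defined on the V region; a 60-nt
  constant-region stub is appended so fragments can originate outside the
  V(D)J region entirely.
* Mixed populations with an exact round-half-even count of mutated
  lineages, the naive/memory mixture being a free parameter (the D0
  mixture of donors is not something the method itself pins down).
* 100×2 paired reads in the FR Illumina convention from fragments of
  250 ± 30 nt (typical short-insert libraries), uniform per-base
  substitution errors only (no indel-error or quality model), and the
  hexamer artifact modeled as replacement of the first 6 nt of each mate —
  which is exactly what motivates the fixed 6-nt trim downstream.
* NB count matrices over 3 time points × 3 replicates with log-normal
  baseline means, a monotone group effect on a chosen fraction of genes
  (half effect at the middle time point), common dispersion, GENCODE-style
  biotype labels, and synthetic coordinates with a configurable subset
  placed inside the packaged GRCh38 Ig locus intervals.

What passing tests on these data do **not** show: robustness to indel
sequencing errors, to allele-level germline variation, to biased segment
usage, to clonal expansion structure, or to the mapping ambiguities of a
real aligner. The simulator is a verification harness for the pipeline's
logic and statistics, not a sequencing emulator.

## The expression summary

TMM normalization is computed by edgeR's reference implementation of the
trimmed-mean-of-M-values procedure (30%/5% trims), and pseudo-counts
rescale each library to the geometric-mean effective size. DE calling uses
|log2FC| ≥ 2 — two-sided, since strong down-regulation is as real as
up-regulation — together with BH FDR ≤ 0.05, both boundaries inclusive.

The time-course test is intentionally a transparent stand-in for
quasi-likelihood machinery: per gene, an NB GLM with group means versus an
intercept-only model, library-size offsets, fixed dispersion, and a
likelihood-ratio statistic against chi-square with 2 df. Dispersion is a
bias-corrected method-of-moments estimate from within-group variation,
shrunk with weight 0.8 toward a pooled abundance-weighted common
dispersion. The pooled target (rather than the median of per-gene
estimates) is a deliberate design choice: with three replicates per group
the per-gene moment estimates are so noisy that their median is biased
low, and using it makes the test anti-conservative; with the pooled
target the null rejection rate at α = 0.05 sits near 0.05–0.08 in the
package's own calibration simulations (2000 genes, 3×3). All-zero genes
get p = 1 by convention.

Biotype classification maps GENCODE-style strings onto five reporting
categories (non-Ig protein coding, Ig-related, ncRNA, pseudogene,
miscellaneous RNA) with an ncRNA breakdown (antisense, lincRNA, other
lncRNA, miRNA, other); the mapping table is an editable tibble, unknown
strings fall through to miscellaneous with a warning, and `IG_*` /
`*_pseudogene` generics are caught by pattern fallbacks. Ig-locus overlap
uses half-open interval intersection against packaged GRCh38 intervals for
IGH (chr14), IGK (chr2) and IGL (chr22), fully overridable.

## Numerical and degenerate-input conventions

* Intervals are 0-based half-open everywhere internally; SAM POS is
  converted on ingest, and unmapped records carry an `NA` position
  sentinel. Abutting intervals do not overlap.
* Ranking tie-breaks are total (score, identity, then name), so results
  are independent of input order; exact ties in the top score make a
  class unconfident by definition.
* Frequency-shift testing uses the closed-form paired t statistic;
  zero-variance combinations get `p = NA` and are flagged on the mean
  shift alone. No multiple-testing correction is applied by default (the
  screen is descriptive), but BH is available.
* `round()` half-even conventions are used for all count rounding.
* Every simulator is a pure function of its arguments and seed (RNG state
  is restored afterwards), so reruns are byte-identical.

## Problem sizes used in the packaged checks

The packaged verification runs use 1000 simulated cells (70% mutated,
SHM rate 0.04, depth 3 pairs/cell) for parameter recovery; 250 cells per
time point for the differentiation trend (true UM fractions 0.8 / 0.3 /
0.15); and 2000-gene, 3×3 matrices for the DE calibration and power
checks. These sizes keep the sampling standard error of the recovered
percentages below about 2 points while keeping a full run in the minutes
range on a single core.

## Known limitations

* The annotator is gene-level only: no allele calling, no CDR3
  translation, no clonal lineage reconstruction, no isotype assignment.
* The 95% V-identity filter interacts with mutated repertoires: a call is
  removed whenever its covered V happens to exceed 5% mismatches, and with
  a true SHM rate of 4% over a typical 100–200 pooled V columns that
  happens to roughly a quarter of mutated calls (a plain binomial tail).
  The packaged recovery run therefore measures a mutated fraction of
  about 62% against a simulated truth of 70% — segment calls themselves
  are essentially always correct, and the per-call mutation counts match
  the planted truth; the bias is a property of the filtering rule, not of
  the implementation, and it shrinks as the SHM rate moves away from the
  identity threshold.
* The NB stand-in test is not a quasi-likelihood F-test; with very few
  replicates its chi-square reference is mildly liberal, which the
  dispersion shrinkage only partly offsets. It is meant for calibration
  and recovery checks on synthetic data, not as a drop-in replacement for
  a production DE engine.
* The frequency-shift screen tests each combination marginally; with
  thousands of combinations its unadjusted flags are descriptive only.
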