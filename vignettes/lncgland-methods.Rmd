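---
title: "Methods and design of the lncgland pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the lncgland pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncgland)
```

## Scope and assumptions

`lncgland` implements the post-alignment half of a two-group lncRNA
study: it assumes reads have already been aligned and assembled, so its
inputs are a transcript annotation (GTF), transcript sequences in sense
orientation (FASTA) and a transcript × sample fragment-count matrix with
an old/young group assignment. Everything upstream — read QC, alignment,
assembly — and everything interpretive is out of scope. All internal
coordinates are 0-based half-open; GTF's 1-based inclusive convention is
converted only at the file boundary, which keeps the gap arithmetic of
the cis-window search free of off-by-one ambiguity.

## lncRNA identification

The classical published pipelines intersect the verdicts of several
external coding-potential classifiers. Those tools (and the database
versions behind them) are moving targets, so this package reproduces the
*consensus architecture* with three self-contained predicates, each a
standard lncRNA heuristic:

* **ORF length** — longest ATG-initiated, stop-terminated ORF over the
  three forward frames, peptide length excluding the stop codon; the
  non-coding call is `orf_len_aa < 100`. Only forward frames are scanned
  because assembled transcripts are already oriented. Codons containing
  N never match ATG or a stop.
* **ORF coverage** — ORF nucleotides (including the stop codon) over
  transcript length; non-coding below 0.5.
* **Hexamer usage** — mean over overlapping 6-mers of
  `log(f_coding / f_noncoding)`, with the two tables trained on labelled
  sequences (by default the generator's training split; users supply
  their own for real data) and smoothed with a pseudocount of 1 over all
  4096 cells; non-coding below 0.

A transcript must be longer than 200 nt (strict) and flagged non-coding
by **all three** predicates. The seven-region Venn counts of the three
single-predicate sets are reported so the contribution of each filter is
visible. The thresholds are pipeline parameters, not reproductions of
any external tool's internal cutoffs, and all are exposed as arguments.

## Quantification and the exact test

FPKM is computed from raw counts and raw library totals; gene-level FPKM
sums the transcripts of each gene, which preserves per-sample totals.

Differential expression follows the conditional exact-test tradition for
negative-binomial counts:

1. **TMM normalization** with the published defaults (30% trim on
   M-values, 5% on A-values, precision weights, reference = the library
   whose 75th-percentile count fraction is closest to the mean); factors
   are rescaled to geometric mean 1. The implementation is validated in
   the test suite against an independent reference implementation within
   5% on random data — small residual differences in trimming
   tie-breaks are expected and harmless, because the factors feed a
   rank-free downstream scaling.
2. **Pseudo-counts**: counts are scaled to the common (geometric-mean)
   effective library size and rounded half-up. This quantile-free
   scaling is simpler than the classical quantile adjustment; its
   correctness is established against an enumeration oracle rather than
   against any other package's output.
3. **Common dispersion** by method of moments: per feature, within-group
   variances are pooled and converted through `var = m + d·m²`; the
   common value is the mean of `max(0, (s² − m)/m²)` over features. With
   4 + 4 samples, tagwise estimates would be unstable, so a common value
   is the deliberate choice; simulation shows the estimator recovers a
   true dispersion of 0.2 within ±0.08 at 2,000 features and stays below
   0.005 on Poisson data.
4. **Exact test**: conditional on a feature's total pseudo-count, the
   group sum follows a beta-binomial-type law with parameters
   `r_g = n_g / d` in which the unknown mean cancels; the two-sided
   p-value sums all splits whose probability does not exceed the
   observed one (with a 1e-10 relative tolerance for floating-point
   ties). Dispersion 0 reduces to the conditional binomial split. The
   test equals a brute-force enumeration oracle to 1e-9 over 1,000
   random cases in the suite.

Fold changes are `log2(mean FPKM old / mean FPKM young)`. The DE call
uses the absolute-value reading — p < 0.05 **and** |log2FC| > 1 — since
down-regulated features are reported as differentially expressed too. A
pseudocount (default 0.01 FPKM) is applied only when a group mean is
exactly zero, and the affected features are recorded in an attribute.
Raw and BH-adjusted p-values are both carried: the DE tables report
both, and the network stage filters on the adjusted value, mirroring the
stricter criterion used for network construction.

## Target prediction

**Cis**: a (lncRNA, gene) pair is linked when both lie on the same
chromosome, their outer spans do not overlap, and the gap between the
spans is in `(0, window]` for a 10 kb or 100 kb window. Distance is the
gap between spans, strand-agnostic, with the window boundary inclusive;
overlap and mere adjacency are excluded ("without overlap"). The
candidate search uses interval overlap machinery; an all-pairs
brute-force scan in the test suite confirms exact agreement.

**Trans**: Pearson correlation of the lncRNA's FPKM profile against
gene-level FPKM across all samples, with edges at |r| strictly greater
than 0.95. The threshold is strict because the criterion is "absolute
value > 0.95"; the window boundary, by contrast, is inclusive because "
within 10 kb" naturally includes 10 kb. Constant profiles have no
defined correlation and are skipped and logged. Trans prediction here is
correlation-only: free-energy RNA–RNA hybridization scoring is a
deliberate non-goal, so trans edges express co-expression, not physical
pairing. With 8 samples the null tail is thin: independent profiles
exceed 0.95 with probability ≈ 3 × 10⁻⁴ (t-transform), which the suite
verifies by simulation.

## Network

Edges are kept only when both endpoints are differentially expressed at
padj < 0.05; nodes are exactly the endpoints of surviving edges, so the
network has no isolated features. Each edge records the sign of its
association (correlation sign for trans, fold-change concordance for
cis) — but sign concordance is *never* used as a filter, because
discordant pairs (an up-regulated lncRNA with a down-regulated cis
target) are biologically meaningful. Exports are SIF (minimal,
Cytoscape-ready) and GraphML with all attributes written at 17
significant digits so a re-import reproduces the network exactly.

## Enrichment

The upper-tail hypergeometric test against user-supplied annotations.
The universe is a mandatory explicit argument — enrichment against an
implicit background is a common source of irreproducibility. The
reporting filter (p < 0.05 and at least 4 DE genes per term) mirrors the
common "more than 3 genes" display convention and is configurable
separately from the test itself.

## qPCR

Technical replicates are averaged (a replicate SD above 0.5 cycles
warns, never rejects); ΔCt subtracts the reference gene per sample; ΔΔCt
centers on the **mean ΔCt of the calibrator group**, the usual reading
of the Livak method for group designs, making the calibrator's geometric
mean RQ exactly 1. The group comparison defaults to an *unpaired*
two-tailed t-test — old and young birds are biologically independent —
with a paired mode behind a flag for genuinely paired designs.
Concordance with RNA-seq compares fold-change direction per gene.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the package is validated under: two 5-Mb chromosomes,
2,000 single-transcript coding genes, 300 lncRNA loci, 4 old vs 4 young
samples, NB counts with dispersion 0.1 around log-normally spread
baseline means (median 100), 10% planted DE at |log2FC| = 2, cis pairs
planted below 10 kb (20), between 10 and 100 kb (20) and beyond 100 kb
(8), 20 trans pairs coupled through a shared per-sample log-normal
factor (σ = 1.5, six negative), one enriched term seeded with 25 DE
genes out of 50, and Ct tables derived from the planted fold changes
with 0.2-cycle noise. Coding transcripts carry a planted ORF of 150–500
aa at 55–85% coverage built from a biased codon pool; non-coding
transcripts are rejection-sampled until their longest ORF is below 100
aa and 50% coverage. Sequence composition differs between the classes
(GC-rich coding vs AT-rich non-coding), which is what gives the hexamer
predicate its signal.

What the generator does **not** emulate — and therefore what passing
tests cannot show about real data: multi-isoform genes, positional
autocorrelation of expression, GC/length biases in counting, batch
effects, outlier libraries, and realistic genome composition. The
planted trans coupling records the *empirical* correlation of each pair
in the truth table rather than assuming the target was reached, so
recovery checks are exact rather than hopeful. `verify_truth()`
re-derives ORFs, gaps, group means, correlations and qPCR fold changes
from the emitted files and fails loudly on any inconsistency, and the
test suite includes a fault-injection case (a shifted exon) to prove the
check bites.

## Problem sizes and determinism

The test suite exercises the full default scale once (2,300 features, a
few seconds) and uses reduced-scale studies (150 genes, 40 lncRNAs) for
multi-seed properties; oracle comparisons run on 1,000 random exact-test
cases, 50 random 500-locus layouts, 500 hypergeometric instances and
1,000 BH vectors. All simulation is seeded; the generator writes
byte-identical files for identical seeds. The full suite completes in
under a minute on one core, and the acceptance script in well under a
minute.

## Known limitations

* Coding-potential thresholds are heuristics; on real data they should
  be tuned against a trusted annotation, and the hexamer tables must be
  trained on species-appropriate sequences.
* The common-dispersion exact test is conservative for features whose
  true dispersion is far from the common value; with designs larger than
  4 + 4, a tagwise shrinkage estimator would be preferable.
* Trans edges are co-expression claims only; at n = 8 even a 0.95
  threshold admits occasional spurious pairs among many thousands of
  candidates, and correlation says nothing about mechanism or direction
  of regulation.
* Gene-level aggregation by summing FPKM is the convention adopted here;
  it is not length-bias-free when isoform usage shifts between groups.
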