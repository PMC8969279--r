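---
title: "Detecting IRE1-dependent decay targets from exon-level RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting IRE1-dependent decay targets from exon-level RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riddseq)
```

## The signal riddseq looks for

Under endoplasmic-reticulum stress the transmembrane sensor IRE1 activates its
endoribonuclease domain. Beyond splicing XBP1 mRNA, it degrades a set of
substrate mRNAs — regulated IRE1-dependent decay (RIDD). Cleavage is
sequence- and structure-specific: a CUGCAG consensus presented in the loop of
an XBP1-like hairpin, with cleavage 3' of the loop guanine (CUG|CAG).

When an in vitro cleavage reaction is read out by poly(A)-selected RNA-seq,
the non-polyadenylated 5' cleavage fragment is lost during library
preparation. A cleaved transcript therefore keeps its read coverage 3' of the
cut but loses it 5' of the cut, in proportion to the fraction of molecules
cleaved. Whole-gene differential expression cannot see this; *differential
exon usage* — each exon bin tested against the rest of its gene — isolates
the within-transcript step. riddseq implements the resulting discovery chain:

1. flatten gene models into disjoint exon bins;
2. test each bin for differential usage (negative-binomial likelihood-ratio
   test), adjust with Benjamini–Hochberg, select candidates at FDR < 0.05 and
   usage fold change < −2;
3. localize the cleavage region as the change-point between the depleted 5'
   bins and the flat 3' bins;
4. scan the change-point window for a CUGCAG consensus inside a stable
   hairpin and call the cleavage coordinate.

A synthetic-data module generates complete experiments with known ground
truth, so every stage is testable without external data.

## The count model and its simulator

`simulate_counts()` draws bin counts as NB(mean, alpha) with variance
`mu + alpha mu^2`. The mock mean of bin *i* of gene *g* in sample *j* is

    s_j * depth * lambda_g * len_i / sum(lambda * len)

library size × gene abundance × a within-gene weight proportional to bin
length. In IRE1-treated samples a bin entirely 5' of a cleavage position is
multiplied by `1 − epsilon` (`epsilon` = cleavage efficiency, the fraction of
molecules cut); a bin containing the position is scaled by its 3' length
fraction plus `(1 − epsilon)` times its 5' fraction; bins 3' of the position
are untouched. `alpha = 0` degenerates to Poisson.

Default parameters and why:

* gene abundances `lambda` ~ log-normal(meanlog 4, sdlog 1) — a realistic
  bulk dynamic range of ~3 orders of magnitude;
* NB dispersion `alpha = 0.05` — typical replicate noise for bulk RNA-seq;
* library sizes log-normal(0, 0.15), normalized to geometric mean 1 —
  moderate depth imbalance;
* 3 treated vs 3 mock replicates, expected depth 10^6 reads per sample over
  200 genes — the replicate structure of the assay the package models, at a
  per-gene coverage comparable to a full-transcriptome experiment;
* cleavage efficiency `epsilon = 0.85` for planted targets; the efficiency
  of the in vitro reaction is not a measured quantity, so this is a
  simulation parameter chosen to represent an efficient reaction, not an
  estimate of any experiment;
* one hairpin per target, planted a few bases (default 15) into the second
  exon. Placing the cut near the 5' end of the transcript mirrors where
  poly(A)-selection depletion is easiest to read, keeps the first bin fully
  depleted, and leaves the cleavage site within ±100 nt of the bin junction
  that the change-point stage reports.

Hairpin planting substitutes bases in place (never inserts), so all
coordinates stay stable; the recorded truth position is the consensus
guanine. What the simulator does **not** emulate: fragment-level read
sampling (FASTQ/BAM), sequencing error, isoform switching, partial 5'
carry-over through poly(A) selection (a config knob, default 0), and
positional coverage bias. Passing the recovery tests therefore demonstrates
the statistical machinery on the stated generative model, not performance on
the full messiness of real libraries.

## The differential exon-usage test

For each unambiguous bin of a multi-bin gene, counts of the bin and of the
rest of its gene (summed over the other bins) are modeled as NB log-linear
with sample and part (bin vs rest) effects; the alternative model adds a
condition-by-part interaction. The statistic `2(l1 − l0)` is referred to
chi-squared with 1 df. With `alpha = 0` and equal size factors the statistic
collapses to the closed-form G-test of independence on the 2×2
part-by-condition total table — a property the test suite asserts to 1e-6.

Dispersions are plug-ins, estimated by method of moments on
size-factor-normalized counts (variance pooled within condition), shrunk
halfway toward the gene-wise mean. Two numerical choices matter and are the
package's own:

* **Part-specific dispersion.** The "rest" part is a sum over the gene's
  other bins, and a sum of k NB(mu, alpha) variables has dispersion of order
  `alpha / k`. Plugging the bin's dispersion into the aggregate overstates
  its variance and makes the test markedly conservative (we measured null
  false-positive rates of 0.6–3% at a nominal 5%). `deu_test()` therefore
  estimates a separate dispersion for the rest counts.
* **Moderated shrinkage target.** With 4 residual df the per-bin estimate has
  a coefficient of variation near 0.7, and noisy plug-ins inflate the LR
  statistic (an underestimated dispersion inflates more than an overestimate
  deflates). The gene-wise shrinkage target is therefore averaged with the
  experiment-wide mean raw dispersion. After both adjustments the measured
  null false-positive rate is about 4–8% across simulation seeds at nominal
  5% — calibrated, with a residual mild anti-conservatism that is a known
  limitation of plug-in dispersion LR tests at three replicates per group.

The usage fold change is the odds ratio of the bin's usage fraction
(IRE1-treated over mock), reported in the signed convention with |fc| ≥ 1, so
"FC < −2" means at least a two-fold usage loss under IRE1. The published
analyses this package generalizes do not define their fold-change formula;
the odds-ratio convention is documented as ours, not asserted as theirs.
Degenerate usages (0 or 1) receive a 0.5 pseudocount on the counts.
Candidate selection uses strict inequalities at both thresholds (a bin at
exactly FC = −2 is excluded) and supports a manual override list for genes
retained on biological grounds despite missing the fold-change cut — such
genes are appended and flagged, mirroring how validation lists are assembled
in practice.

## Change-point localization and XBP1-likeness

The per-gene profile is the per-bin log2 usage fold change ordered 5' to 3'.
Cleavage produces a step; `localize_changepoint()` fits every two-segment
split by least squares and returns the minimizing boundary, ties broken
toward the smallest k. The tie-break encodes the reading that the depleted
run is anchored at the transcript's 5' end under poly(A) selection, so the
5'-most optimal boundary is the cleavage region; this "boundary of
depletion" interpretation (rather than "first depleted bin") is a documented
choice. Exactly one change-point is fitted per gene; targets with two nearby
sites are resolved downstream by grouping stem-loop calls within 200 nt.

A profile is *XBP1-like* — shaped like the known substrate XBP1's — when the
segment-mean drop is at least 1 log2, at least half of the 5'-segment bins
are individually significant, and the 3' segment is flat (|mean| ≤ 0.5
log2). The flatness clause is what distinguishes endonucleolytic cleavage
from whole-transcript downregulation, which depresses every bin and is
rejected for any shift magnitude. Note that usage fractions are
compositional: depleting the 5' bins mechanically inflates 3'-bin usage, so
the 3' segment of a true target sits slightly above zero; the 0.5 log2
allowance absorbs this.

The junction between the last depleted bin and the first flat bin is mapped
to transcript coordinates and padded by ±100 nt (configurable) to form the
window handed to the stem-loop scanner.

## Stem-loop calling

Within a window, every exact CUGCAG occurrence is a candidate; around each,
`fold_hairpin()` exhaustively enumerates hairpins with an unpaired loop of
4–12 nt containing the consensus guanine and a flanking stem of ≥ 4
consecutive pairs (Watson–Crick plus G·U wobble), inside a ±30 nt folding
context. The energy model is deliberately simple and additive — G-C −3,
A-U −2, G·U −1, +0.5 per loop base beyond 4 — rather than a full
nearest-neighbor thermodynamic model: it is deterministic, exactly testable
against brute-force enumeration, and sufficient to rank hairpins; it does
not produce physical free energies, and pseudoknots and multi-branch
structures are out of scope. Because all pair scores are negative, the
optimal stem for a given loop is its maximal outward extension, which the
implementation exploits; the test suite proves equality with the full
enumeration. The reported call's cleavage coordinate is the guanine at
consensus position 3 (CUG|CAG), following the XBP1 literature convention;
the position within the consensus is configurable.

The background specificity of this detector is estimated on
dinucleotide-shuffled window sequences (an Eulerian-walk shuffle preserving
dinucleotide composition): shuffling destroys both the hexamer and the stem,
and the measured consensus-in-hairpin background is well below 20% of
windows, echoing that only a minority of genuine depletion candidates carry
the motif-in-loop.

## Validation statistics

The package also implements the arithmetic used to validate called targets:

* `relative_expression()`: 2^−ΔCt with an endogenous control (shift-invariant
  in Ct by construction);
* `decay_call()`: Welch t-test on replicate ΔCt for inducer-driven decay,
  plus an IRE1-inhibitor (4µ8c) rescue criterion — rescue holds when
  expression under inducer + inhibitor is not significantly below control
  *or* recovers ≥ 75% of control, because partial rescue is the realistic
  outcome. The t-test is run on ΔCt (approximately normal) rather than on
  2^−ΔCt. The test choice is ours; significance marks in validation figures
  rarely name their test.
* `half_life()`: log-linear least squares, `t1/2 = ln 2 / k`, with an
  infinity flag for non-decaying series;
* `fit_median_effect()` / `combination_index()`: the Chou–Talalay
  median-effect equation `fa/fu = (D/Dm)^m` fitted by OLS on the
  log-linearized form, and `CI = d1/Dx1 + d2/Dx2` (mutually exclusive form
  by default, matching common practice; the nonexclusive cross term is a
  flag). A sham single-drug "combination" gives CI = 1 to machine precision,
  and CI < 1 reads as synergy.

## Problem sizes and determinism

The package's own acceptance checks run the full pipeline at 200 genes with
20 planted targets (about 1,300 bins, six samples, depth 10^6), the null
calibration at 500 bins, the flattening oracle on 100 random multi-isoform
loci, and the folding oracle on dozens of ≤ 80 nt windows — sizes chosen so
the whole suite completes in a few minutes on one core while leaving the
statistical assertions well-powered. All randomness flows through explicit
seeds; rerunning any simulation or the pipeline with the same configuration
is bit-identical, which `run_discovery()` additionally guarantees for its
file outputs.

## Known limitations

* Bin-level resolution: the change-point is a bin junction, not a
  nucleotide; nucleotide precision comes only from the consensus match.
* The NB test is mildly anti-conservative (see above) and its p-values rely
  on chi-squared asymptotics at n = 6.
* The energy model ranks hairpins but does not estimate physical stability;
  borderline structures should be checked with a thermodynamic folder.
* Ambiguous bins (shared between genes) are counted but never tested; genes
  whose signal lies entirely in shared exons are invisible.
* The simulator's idealizations listed above mean that measured recovery
  rates are upper bounds relative to real libraries.
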