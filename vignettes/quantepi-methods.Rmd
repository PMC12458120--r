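---
title: "Methods: quantitative differential epigenomics with quantepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative differential epigenomics with quantepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantepi)
```

## The problem

Quantitative ChIP-seq places immunoprecipitation tracks on an absolute
IP-efficiency scale, so the same genomic interval can be compared directly
between a drug-treated and a vehicle-treated culture: the ratio of track
areas over a peak is a physically meaningful response. quantepi implements
the downstream analysis of such experiments — response calling across
biological replicates, shape and chromatin-state characterisation of the
responding peaks, integration of two marks by proximity, and the companion
assays (methylation arrays, arrayed reporter screens) that such studies
use — together with a simulator that plants ground truth for every stage.

All intervals are 0-based half-open on disk (bedGraph/BED native) and held
as `GRanges` in memory; readers and writers do the one-base shift, and the
bedGraph writer emits six decimals so round trips are exact.

## Peak response model

For peak $p$, treatment replicate $t$ and vehicle replicate $v$:

$$\mathrm{log_2FC}(p;t,v)=\log_2\frac{A_t(p)+\epsilon}{A_v(p)+\epsilon},$$

with $A(p)$ the track area (signal × bp; uncovered bases contribute 0) and
$\epsilon$ a pseudocount (default 1 signal·bp) applied to both arms. There
is no established convention for zero-area handling in this setting; the
symmetric pseudocount was chosen because it preserves the arm-swap
antisymmetry of the statistic and the scaling identity
$\mathrm{log_2FC}(c \cdot T, V) = \mathrm{log_2FC}(T, V) + \log_2 c$ in the
small-$\epsilon$ limit, both of which are property-tested.

Each treatment replicate is compared against *every* vehicle replicate (the
full cross of pairings, e.g. DAC1 vs Veh1 and DAC1 vs Veh2); a treatment
replicate's response is the mean over its vehicle pairings, the peak's
overall response is the mean of those per-replicate means, and the variance
gate uses the unbiased variance of the per-replicate means. Variance is
deliberately computed at the biological-replicate level rather than over
raw pairings: the gate is meant to capture disagreement *among replicates*,
and pooling pairings would double-count shared vehicle noise.

Consensus peaks are connected components of any-base-pair overlap across
per-replicate peak sets, kept when they contain peaks from at least
`min_replicates` sets (default: all of them). The consensus interval is the
**union span** of the component. This was a genuinely open choice (union,
intersection, or a reference replicate's interval); union was selected
because it makes downstream widths well defined for every contributing
replicate and never truncates signal, at the cost of slightly widening
peaks whose replicate calls are staggered. Touching-but-not-overlapping
half-open intervals share no base and are *not* merged.

## Differential calling

Calling is pure threshold application with inclusive comparisons
(the thresholds are stated with ≥/≤):

* acetylation-style marks: gain at mean log2FC ≥ 0.585 (that is,
  log2 of a 1.5-fold increase), loss at ≤ −1.0, no variance gate;
* monomethyl-style marks: gain/loss at ± 0.5 **and** replicate variance
  ≤ 1, reflecting the high replicate variability of this mark.

A mean exactly at a threshold is called; a variance exactly at the ceiling
passes. No FDR machinery is attached because the method is a fixed
threshold rule, not a p-value procedure.

## Width mixture

Peak widths for broadly distributed marks show a dense short mode
(~300–400 bp) and a long right tail; a two-component Gaussian mixture on
**log10 width** separates "narrow" from "broad". The log scale was chosen
because widths are strictly positive and right-skewed (the original
analysis does not state its scale). The EM is initialised from the exact
one-dimensional 2-means split of the sorted log-widths, making the fit a
deterministic function of the data — no restarts, no RNG; convergence is
declared at an absolute log-likelihood change below 1e-8 with a variance
floor of 1e-3 on the log10 scale to prevent component collapse. Component 1
is always the smaller-mean (narrow) component, and a posterior of exactly
0.5 resolves to narrow. Fewer than 10 widths, or all-equal widths, raise an
error instructing a single-class fallback rather than returning a
meaningless fit. An independent mixture fitter (mclust, the tool the
original analysis used) serves as a cross-check in the test suite.

## Chromatin-state enrichment

Fold enrichment is base-pair weighted:
$\mathrm{fold}(s) = (\text{peak bp in } s/\text{total peak bp}) \big/
(\text{state bp}/\text{genome bp})$. Peaks spanning several states
contribute to each by exact intersection — no single-assignment — which
treats broad peaks fairly. The 18-state vocabulary condenses to
Promoter/Enhancer/Genic/Repressive via the standard membership list
(`chromhmm_condensation()`), merging adjacent same-category intervals and
conserving coverage exactly.

"Enrichment bias" is each state's fold as a percentage of the *sum of
folds* across defined states, so biases sum to 100 per peak set. Sum of
folds (rather than sum of overlap bp) was adopted as the reading of "total
enrichment"; states absent from the genome have undefined fold and are
excluded from the denominator so they cannot poison the normalization.

## Two-mark integration

Linking is nearest-neighbour within a window (±10 kb for gains, ±20 kb for
losses in the motivating design), measured **edge-to-edge** from the A peak
(centre-to-centre is available as a flag; the window semantics were not
further specified upstream). Overlap means distance 0, and ties between
equidistant partners resolve to the leftmost for determinism.

Linked regions are summarised by the mean second-mark efficiency in a fixed
window around the A-peak midpoint (raw scale; the fixed-window mean was
chosen over nearest-peak signal because it is defined even where the second
mark has no called peak) and clustered with k-means, k = 3, relabelled
low/intermediate/high by ascending centroid. Initial centres are the odd
$(2i-1)/(2k)$ quantiles of the features — deterministic, one centre per
equal-mass slice. A farthest-point sweep was tried first and rejected: when
the top signal tier is absolutely more dispersed than the gap between the
lower tiers, farthest-point seeds two centres inside that tier and k-means
converges to a split of it, merging the lower tiers. Quantile seeding does
not have this failure mode. If all features are identical the assignment is
degenerate and flagged rather than erroring.

Profile matrices mirror the computeMatrix conventions: reference-point mode
tiles $[c - \text{flank}, c + \text{flank})$ around the interval midpoint
(floor division) with fixed bins; scale-regions mode inserts `body_bins`
equal fractions of the region between the flanks, with fractional bin edges
resolved by exact base-pair weighting. Cells are base-pair-weighted mean
signal; bins extending past chromosome bounds are missing and excluded
from the average profile rather than zero-filled, avoiding edge artifacts.
Every cell is property-tested against a per-base brute-force oracle.

Differential-expression input is consumed, never fitted: the filter keeps
genes with |log2FC| ≥ 1 and FDR ≤ 0.01, both inclusive.

## DMR calling

Per-probe deltas are treated-minus-vehicle differences of group mean betas.
The scan reports maximal runs of consecutive same-sign probes (zero deltas
break runs) whose neighbours lie within `max_gap` (default 1,000 bp — array
probes are sparse and an unbounded gap would merge unrelated loci; the
upstream region-calling tool implies but does not print such a bound). A
run is a DMR when it has ≥ 5 probes and |run-mean Δβ| ≥ 0.20. The phrase
"five contiguous CpGs demonstrated a mean difference of 0.20" is ambiguous
between the run-mean and a per-probe requirement; run-mean is the default
and `per_probe = TRUE` gives the stricter reading. Runs separated by a
sign flip are never merged. The scan is verified against a brute-force
enumeration of all maximal sign-consistent sub-runs on chromosomes up to
200 probes.

## Screen hit calling

Scores are background-subtracted luminescence per percent confluency,
floored at zero; wells with non-positive confluency are invalid. Exclusions
before scoring: genes with CPM < 100 in *every* provided expression
condition (a gene expressed in either condition is kept; a gene absent
from the CPM table counts as unexpressed), and wells whose confluency is
more than 1 SD below the mean over valid wells. Z-scores are computed over
the retained wells only — computing them before filtering would let toxic
wells inflate the spread — and a hit requires Z **strictly** greater than
4. The retained Z-scores have mean 0 and SD 1 by construction, which is
asserted in tests.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the emulated study design: 3 biological
replicates per arm, 10% multiplicative replicate noise, narrow peaks
averaging 350 bp with a broad ~2 kb tail (70/30 lognormal mixture sampled
on the log scale), 2-fold gains and 0.4-fold losses on 20% of peaks each,
an 18-state annotation with quiescent chromatin dominating, array betas
with per-sample noise SD 0.02, and an 18,000-gene screen with +8 SD hits,
toxic knockdowns ~2.5 SD below mean confluency, and ~500 unexpressed genes.
Choices the design left open were fixed once at field-plausible values:
background efficiency 0.05 outside peaks, mean chromatin segment 1.5 kb,
probe spacing uniform in 100–800 bp (within the contiguity bound),
Beta(5, 5) baseline methylation, Gaussian null screen scores.

Peaks are rectangles (constant height over width), so planted area ratios
are analytically exact — with zero noise a 2-fold gain has a treatment/
vehicle area ratio of exactly 2, which anchors the exact-identity tests.
Replicate noise is multiplicative lognormal with mean exactly 1, keeping
efficiencies non-negative and making CV = 0 genuinely noiseless. Planted
hits are given at-least-average confluency: hit and toxic are disjoint
truth classes, and under a Gaussian confluency draw ~16% of wells fall
below the 1 SD viability cut, so without this a planted hit could look
toxic by chance and recovery would be bounded away from 1 for reasons
unrelated to hit calling.

Real data differ in ways the simulator does not model: peaks have shaped
summits and shoulders, not rectangles; replicate noise has spatial
correlation; methylation backgrounds are bimodal with probe-type effects;
screens have plate-position artifacts. Passing the planted-truth tests
therefore demonstrates that the *statistics* are implemented correctly
under the stated noise model, not that thresholds are optimal for any
particular real data set.

One sharp consequence of the run-scan DMR definition: with nonzero
per-sample noise, background probes adjacent to a planted run carry small
random-sign deltas, so the maximal same-sign run extends past the planted
boundary with probability ≈ 1/2 per side (diluting the run mean slightly).
Exact-boundary recovery is therefore a zero-noise property, and it is
tested as such; with noise, recovered DMRs still lie on planted runs but
their edges are fuzzy. This mirrors the behaviour of region-growing DMR
callers on real arrays.

## Determinism and numerical choices

Every generator is a pure function of (config, seed): each stage derives
its own stream from the master seed, so adding a stage never perturbs
another. The EM and k-means initialisations are deterministic, `stats::
kmeans` runs from explicit centres, and `run_demo()` re-run with the same
configuration reproduces every output file byte-identically (asserted by
MD5 in the tests). Problem sizes used by the test suite and the acceptance
script — 200 planted peaks, 1,000 mixture widths, 5,000 random peaks for
the enrichment null, 10,000 screen wells, 100 fuzzed profile instances —
were chosen as the smallest sizes at which the planted effects and their
tolerances are statistically meaningful.

## Known limitations

* Peak segmentation (`detect_peaks`) is threshold-and-merge over
  already-scaled tracks; it is a convenience for synthetic data, not a
  replacement for an upstream peak caller.
* The absolute-scaling constant of quantitative ChIP is consumed, never
  computed; tracks must arrive in efficiency units.
* No FDR control anywhere — the implemented procedures are fixed-threshold
  rules by design.
* Proximity linking is a deliberate simplification of regulatory-domain
  gene assignment; it links intervals, not genes to regulatory programs.
* `overlap_enrichment` assumes the annotation tiles the genome when no
  `seqlengths` are available; supply genome sizes when it does not.
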