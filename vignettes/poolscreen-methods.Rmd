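---
title: "Methods: models, parameters and design choices in poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

poolscreen implements the computational chain around a pooled-barcode
cell-line viability screen and the assays that typically accompany one:
dose–response fitting, mutation association, sparse whole-genome copy
number, synergy scoring, expression signatures and PK–PD summaries. This
vignette records the models, their assumptions, the tunable parameters and
the numerical decisions, in enough detail that a maintainer can judge why
each choice was made.

## The screen-processing model

A pooled screen reads out one median fluorescence intensity (MFI) per
barcode per well. Signals are analysed on the log2 scale throughout,
because fluorescence measurement error is predominantly multiplicative.

**Spike-in calibration.** Every well contains ten spike-in control barcodes
at fixed, strictly increasing abundances. Per plate, the reference profile
is the per-barcode median log2(MFI) over negative-control (vehicle) wells.
Per well, a monotone map `g` is fitted through the ten pairs (well spike-in
level → reference level) and applied to the cell barcodes. We use a
shape-preserving monotone cubic Hermite interpolant (`splinefun` method
`"monoH.FC"`), after collapsing tied abscissae and passing the ordinates
through isotonic regression so monotonicity is guaranteed even for noisy
pairs; outside the spike-in range the map continues linearly with the
endpoint derivative. A penalized-spline formulation would need a penalty
order and knot count that have no principled default for ten points; the
monotone interpolant keeps the one property that the downstream analysis
relies on — order preservation — and is exact for affine well distortions.

One consequence worth stating explicitly: calibration aligns wells *to the
plate reference*, which is itself an (unknown) distortion of the true
scale. Pure per-well additive offsets cancel exactly in log-viability
(both treated wells and the negative controls carry the same plate
reference level), so offset-only distortions are recovered exactly. A
per-well *gain* (slope) error, by contrast, leaves the plate-reference
slope in all log-viabilities; that scale indeterminacy is inherent to
spike-in calibration, not an implementation artifact, and is absorbed
downstream by the curve fit. The generator therefore exposes
`well_effect_sd` (offsets, default 0.3 log2 units) and `well_slope_sd`
(gain jitter, default 0.05) separately.

**Quality control.** For each cell line × replicate plate we compute the
error rate of the optimal single-threshold classifier between the line's
positive-control and negative-control calibrated signals: everything below
the threshold is called positive, everything above negative, and the error
is (FP + FN)/n minimized over thresholds. Candidate thresholds are the
midpoints between adjacent distinct pooled values plus ±∞, which covers
every achievable confusion table; with heavy ties this scan coincides with
evaluating both open and closed sides of each observed value. The dynamic
range is DR = μ₋ − μ₊ of the median calibrated control signals. The
defaults mirror the screen's published gates: exclusion when error rate
exceeds 0.05, when DR is below 1.74 log2 units, or when fewer than two
replicates pass — the boundary values themselves pass, because the rules
are strictly "above"/"less than". μ± are computed per cell line × plate;
"normalized log2(MFI)" is taken to be the spike-in-calibrated value.

**Viability and batch correction.** Log-viability is the calibrated
log2(MFI) minus the per-plate, per-line median negative-control value, so
vehicle wells sit at 0 and a halving of signal is −1. Batch effects keyed
to pools/culture conditions are removed with the parametric empirical-Bayes
location–scale adjustment (ComBat, via the sva package) on the cell line ×
condition matrix, with cell lines as samples and conditions (doses) as
features. A single-batch matrix is returned unchanged; if any batch has a
single sample the adjustment falls back to location-only for the whole
matrix, since the scale of a singleton batch is not estimable. Because the
empirical-Bayes step shrinks per-feature batch effects toward a common
prior, a *noisy* injected offset is removed only up to the within-batch
standard error; with noiseless offsets removal is essentially exact.
Replicates are collapsed by the median, and viability fractions are
reported as 2^LV clipped to [0, 1.2] for curve fitting.

## Dose–response

The screen's curve model is the four-parameter logistic
`f(x) = b + (a − b)/(1 + e^{s·log(x/EC50)})` with natural log; the sign
convention is that positive `s` gives viability decreasing with dose (any
log base change is absorbed by `s`). The constraints follow the screen's
published restrictions: a ∈ [0.99, 1.01], b ∈ [0, 1.01], curves not forced
to be decreasing, initialization at a = 1, b = 0.5 (the EC50 is initialized
at the dose whose response is nearest 0.75, a neutral interior guess).

Numerically, the fit proceeds in stages. First an *unconstrained*
Levenberg–Marquardt fit: when its optimum already satisfies the asymptote
boxes — the overwhelmingly common case — it is also the constrained
optimum and is accepted as-is. Only when a bound is violated do we switch
to bounded quasi-Newton (L-BFGS-B) from both the projected free solution
and the standard start, keeping the better. The reason for this staging is
practical: projection-based box handling inside LM can stall on a box face
in the flat direction created by the narrow `a` interval, whereas the free
optimum is found reliably. If everything fails, a robust refit with the
soft-L1 loss `2(√(1+r²)−1)` is reported and flagged
(`robust_fallback_used`). Exactly constant input (zero variance) is
handled as a degenerate flat curve with `s = 0` rather than sent to the
optimizer. The fit is a deterministic function of the data, so permuting
input order changes parameters only at rounding level.

AUC is the mean fitted viability over the tested log10-dose range —
`∫ f(10^u) du / (log10 dmax − log10 dmin)` by adaptive quadrature at
absolute tolerance 1e-9 — so an untreated flat curve scores 1 and lower
values mean greater sensitivity. The integration convention is stated
rather than inherited because screen AUCs are only meaningful relative to
the tested range; the fitted curve (not the raw points) is integrated by
default. IC50 inverts the logistic in closed form,
`EC50 · ((a − 0.5)/(0.5 − b))^{1/s}`, and is reported only when the fitted
curve actually crosses 50% within the dose range.

The exposure–response model is the three-parameter sigmoid
`r(C) = bottom + (1 − bottom)/(1 + (C/EC50)^h)` with the top fixed at 1,
the natural parameterization for vehicle-normalized data; the same staged
optimizer is used, with bottom ∈ [0, 1] and h > 0. Exposure metrics use
the linear trapezoid for AUC; the terminal half-life is ln 2 / k with k
from a log-linear regression on the terminal declining phase, defined as
the longest run of strictly decreasing positive concentrations ending at
the last sample, at least three points (NA otherwise). Kp is the ratio of
tissue to blood AUC. Tumour metrics are percent volume change from
baseline, best response (minimum percent change), and the least-squares
slope of ln V versus time as the per-day exponential growth rate.

## Copy number

Input is a table of fixed-width genomic bins (0-based half-open
coordinates) with GC fraction and read count; the desk-scale default in
the generator is one synthetic chromosome of 2,000 bins of 100 kb at 150
reads per bin, and `paper_scale = TRUE` switches to 20,000 bins, the
resolution of sparse whole-genome sequencing at ~3 million reads. Fixed
bins are a deliberate simplification: mappability-derived variable bins
require a reference genome, and any user-supplied bin table with the same
columns is accepted.

GC correction divides each count by a LOWESS fit of count on GC (span 0.3,
the default robust iterations) rescaled by the genome mean; the floor
`eps = 1e-6 × mean(count)` guards against a degenerate fit near zero. The
overall mean is preserved to well under 0.5% rather than exactly, because
the formula is kept as the plain quotient. Normalization divides by the
genome-wide mean — copy number is *relative* throughout; purity and ploidy
are out of scope.

Segmentation is circular binary segmentation: within each interval the
pair of circular breakpoints maximizing the two-sample t statistic (pooled
variance) between the arc and its complement is found by exhaustive O(m²)
scan (compiled, Rcpp); the split is accepted if its permutation p-value
over within-interval value permutations is ≤ α (default 0.01, 1,000
permutations), and the procedure recurses. Two tie-breaking/efficiency
details: a perfect separation (zero within-variance with distinct means)
scores a large sentinel statistic so noiseless steps are always found; and
the permutation loop terminates early once the p-value can no longer fall
below α, which makes null intervals cheap without changing any decision.
Permutations use R's RNG, so a seed makes segmentation fully
deterministic. Adjacent segments whose means differ by less than
`min_seg_delta` (default 0.1 in linear-ratio units) are merged; the scan
can optionally run on log2 ratios, but linear ratios are the default since
the gain threshold is defined on normalized depth. Segment means are
always reported on the linear scale.

Focal gains require a segment mean ratio strictly above 1.5 *and* physical
extent at most the focality limit (default 20 Mb ≈ 200 bins at 100 kb);
gains longer than that are classed broad. The ratio threshold is the
published gain criterion; the focality limit has no published value, and
20 Mb keeps sub-chromosomal amplicons while excluding arm-level events.
Gene annotation is half-open interval overlap (≥1 bp) via IRanges. Cohort
gain frequencies are compared with the exact two-sided Fisher test — the
sum of hypergeometric probabilities of tables (at fixed margins) whose
point probability does not exceed the observed one, with the customary
(1 + 1e-7) relative slack against floating-point near-ties, matching
`fisher.test`.

## Association, synergy, signatures

Mutation association compares AUC between mutant and wild-type lines per
gene with a Welch t-test (the unequal-variance form is the safer default
when only "t-test" is specified; the pooled form is a flag). Genes need at
least 4 mutant lines; the wild-type floor is 2, the minimum for a variance
estimate. The standard three cohorts — full panel, excluding KRAS-mutant
lines, excluding KRAS- or NRAS-mutant lines — are provided by
`associate_cohorts()`. Raw p-values are the primary readout; a
Benjamini–Hochberg column is appended purely as a convenience and labelled
as such.

Bliss scoring works on the inhibition scale e = 1 − viability with
viability clipped to [0, 1] first, since Bliss independence is defined for
fractional effects; the expectation is eA + eB − eA·eB from the
single-agent margins, excess is observed minus expected (positive =
synergy), replicates are scored individually and averaged afterwards, and
the mean synergy averages all nonzero dose pairs.

z-score signatures standardize a treated sample against the vehicle
controls per gene with the sample (n−1) standard deviation; zero-variance
genes are flagged and excluded rather than given infinite scores. Note the
leave-one-out null of such scores is slightly t-inflated
(var = (1 + 1/n)·(n−1)/(n−3) for n controls), which matters for small
control sets. Consensus across cell lines/drugs uses the Stouffer
combination Σzᵢ/√k over signatures with defined values (simple averaging
is a flag); Stouffer preserves the standard-normal null, which plain
averaging does not.

## What the generators emulate — and what they do not

The synthetic screen reproduces the design of the assay: pools of barcoded
lines on plates (one plate per pool × replicate), an 8-point threefold
dilution in triplicate, ten spike-ins per well, vehicle and lethal control
wells, lognormal MFI noise (additive Gaussian on log2), per-well affine
detection distortions, and batch effects injected on treated
log-viability as additive offsets and scale factors keyed to pools —
exactly the structure the empirical-Bayes corrector assumes. Positive
controls are simulated at viability 0.05 rather than 0 so log-viability
stays finite. The lognormal noise model is an assumption about the
instrument, not an inference; heavy-tailed outliers, barcode crosstalk,
plate-edge effects and pool-composition drift are *not* simulated, so
passing recovery tests demonstrates correctness of the computation, not
robustness to every failure mode of real Luminex data.

The copy-number generator draws Poisson counts around
`mean_depth × copy_ratio × gc_bias`, with a smooth quadratic GC bias; it
does not simulate reads, whole-genome-amplification artifacts, mappability
holes or subclonal mixtures. The dose-matrix generator injects an additive
interaction on the inhibition scale before clipping; the PK generator is a
one-compartment oral model (with the ka = ke limit handled in closed form)
linked to an inhibitory sigmoid.

## Problem sizes and determinism in the test suite

The suite is sized to be thorough yet quick on a single core: parameter
recovery uses 200 simulated lines at noise CV 0.1; segmentation behaviour
uses 200-bin profiles over 100 seeded runs (step localization and null
false-positive rate) plus exhaustive-scan equivalence for up to 12 bins;
the full resistance-genomics cohort (47 samples, focal amplicons implanted
in 7/11 vs 3/36) is run at 150 bins per genome over 20 seeded runs; and
association calibration uses 1,000 label permutations of a 40-line panel.
Every stochastic component takes an explicit seed, and each generator
restores the caller's RNG state, so results are reproducible and
independent of evaluation order.

## Known limitations

* Spike-in calibration cannot recover a per-well gain error beyond the
  plate-reference scale (see above); log-viability is defined up to that
  common factor.
* ComBat-style correction assumes batch effects are location–scale on
  log-viability and shared across lines within a batch; confounding of
  batch with biology (pools *are* sets of lines) is inherent to the design
  and not resolvable by the corrector.
* CBS here tests mean shifts with a permutation null; very short segments
  at low depth trade off against the merge threshold, and p-values are
  granular at 1/(n_perm + 1).
* The exact Fisher test is conservative for small cohorts; no continuity
  or mid-p correction is applied.
* IC50 is undefined (NA) for curves that never cross 50% in range — that
  is a feature of the definition, not a fitting failure.
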