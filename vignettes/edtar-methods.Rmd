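---
title: "Ploidy decomposition, signal amplification and OCRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ploidy decomposition, signal amplification and OCRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edtar)
```

## The problem

DNA image cytometry of brushed (exfoliative) oral epithelial cells
yields, per nucleus, a DNA index (DI): the ratio of the measured DNA
content to the diploid reference, so that DI ≈ 1 marks diploid (2N)
cells, DI ≈ 2 tetraploid (4N) cells, and DI ≥ 2.3 operationally defines
an aneuploid cell. A sample is dominated by diploid cells; the
diagnostically informative aneuploid population is often a few cells in
thousands. The conventional cytology call is purely count-based
("positive" above 5 aneuploid cells, "atypical" at 1–5, "negative" at
0) and gives no graded risk for the large group of atypical
premalignant (oral leukoplakia, OLK) patients.

This package implements a quantitative alternative: each case's DI
distribution is decomposed into diploid / tetraploid / aneuploid
populations, the aneuploid signal is amplified by a fixed re-weighting
rule, the resulting three-Gaussian mixture is reconstructed as a
16-bin density vector over DI ∈ [0, 8], and a radial-kernel SVM maps
that vector to the Oral Cancer Risk Index (OCRI), the calibrated
probability of the carcinoma (OSCC) class.

## Density estimation and peak identification

Each case's DI density is estimated with a Gaussian-kernel KDE on a
fixed grid (step 0.01 DI over `[0, max(8, max DI) + 1]`). The ideal
bandwidth minimises the mean integrated squared error, which depends on
the unknown true density; the implementable proxy used here is the
Sheather–Jones plug-in selector, with Silverman's rule as fallback when
the plug-in fails to converge and a floor of 1e-3 DI for
(near-)degenerate inputs. The chosen bandwidth and selector are stored
on the estimate. The 0.01 grid keeps the resolution well below the
0.5-DI bin width used in reconstruction.

Modes are read off as sign changes of the first derivative after a
light 5-point moving-average smoothing, and retained when their
topographic prominence reaches a configurable fraction of the maximum
height (default 0.5%). No published value exists for how small a peak
still counts; 0.5% is deliberately permissive so that the decision of
what a peak *means* is made downstream by the extraction windows
rather than hidden in the peak finder. The density minimum between two
adjacent retained peaks is their split point (bound); the extreme
peaks extend to the grid edges.

Peak count is non-increasing in bandwidth for this Gaussian-kernel
pipeline, which the test suite checks on a bandwidth ladder.

## Sequential mirror extraction

Populations are removed one at a time, diploid first (the dominant
peak below DI 1.5), then tetraploid (a remaining peak in [1.5, 2.3)).
The extraction assumes the population is symmetric about its centre:

1. The KDE mode converges slowly, so the centre is refined as the
   median of the cells within two provisional standard deviations of
   the mode (clipped to the peak's bounds). Without this refinement a
   mode offset of a few hundredths of a DI makes the mirror
   systematically asymmetric and the extraction unstable.
2. The spread is the half-normal estimate
   `sd = sqrt(mean((x - p)^2))` over the cells at or left of the
   centre within the peak's bounds — the left flank is the side least
   contaminated by higher-ploidy populations.
3. The left flank within 4 sd is claimed outright. Right-flank cells
   are claimed in increasing order while the running count stays
   within the mirrored left-tail count plus an allowance of
   `0.1 m + 0.05 nl` (m = mirrored count at that point, nl = left
   count). The allowance absorbs the mean-zero random-walk noise of
   the count difference; a genuine overlapping population accumulates
   systematic excess past it and is left as residual. Because every
   term scales linearly with the number of cells, and tied values are
   claimed as groups, the claim set is exactly invariant under
   replicating every cell — ratios do not depend on sample size per
   se.

After extraction, residual cells at DI ≥ 2.3 are pooled as the
aneuploid population (its empirical mean, sd, count and maximum DI are
recorded); residual cells below 2.3 are reassigned to the nearest
extracted population by standardised distance, so that population
counts always sum to the case total. Cases whose density has no peak
below DI 1.5 are flagged unanalyzable rather than processed; cases
with fewer than 10 cells skip the KDE entirely and use the fixed
windows [0, 1.5), [1.5, 2.3), [2.3, ∞), where density estimation would
be meaningless.

The diploid window deserves a note: the published threshold table puts
diploid peaks in [0.8, 1.2], yet the worked leukoplakia example calls
a peak at DI 0.798 diploid. We follow the practice rather than the
table: the dominant sub-1.5 peak is diploid, and the printed windows
only label secondary peaks.

## Signal amplification

With population ratios R1 (diploid), R2 (tetraploid), R3 (aneuploid)
constrained to R1 + R2 + R3 = 1:

* **all three observed** — R1:R2 is retained, rescaled so
  R1 + R2 = 0.9; the aneuploid component keeps its observed shape and
  receives R3 = 0.1;
* **diploid + tetraploid** — R1:R2 retained with R1 + R2 = 0.995,
  R3 = 0.005, aneuploid shape fixed at N(2.3, 0.3);
* **diploid only** — R1 ~ Unif[0.75, 0.8], R2 = 0.995 − R1,
  R3 = 0.005, hypothetical tetraploid N(2.0, 0.3) and aneuploid
  N(2.3, 0.3).

The rules do not cover a diploid + aneuploid case with no tetraploid
peak. We treat it as a three-population case (R3 = 0.1, hypothetical
tetraploid N(2.0, 0.3)) and draw the diploid share of the 0.9 budget
from the same uniform rule scaled by 0.9/0.995, which degrades
gracefully into both neighbouring paths. Observed component standard
deviations are floored at 0.05 DI before entering the mixture — an
aneuploid "population" of one cell has sample sd 0, which would
degenerate the bin masses into a point mass.

Two interpretive choices are worth stating. First, hypothetical
components contribute their analytic Gaussian mass directly; the
single stochastic element is the scalar R1 draw, which is seeded and
recorded. Sampling cells from the hypothetical shapes would only add
Monte-Carlo noise to a quantity whose expectation is available in
closed form. Second, when all three populations are observed, the
0.1 left over after R1 + R2 = 0.9 goes entirely to the aneuploid
component — that is the point of the amplification.

Note a consequence of the fixed budgets: *every* case that reaches the
three-population path carries R3 = 0.1, whether its observed aneuploid
population was 0.1% or 10% of cells. What distinguishes a high-risk
case downstream is therefore chiefly the *location and shape* of its
aneuploid component (genuinely aneuploid populations sit well beyond
DI 2.3), not the amplified weight itself.

## Reconstruction

The amplified three-Gaussian mixture is integrated over 16 half-open
intervals [0, 0.5), …, [7.5, 8.0]. Interval probability masses — not
point densities — are used: masses make rows comparable across cases
and sum to (essentially) one. Mass beyond DI 8 is clamped into the
last bin, the negligible mass below 0 into the first, and any bin
under 0.0001 is set to the 0.0001 filler. The bin width is fixed at
0.5 in this version.

## The risk model

Training uses the two pathologically unambiguous classes (normal and
OSCC); leukoplakia cases are score-only. Features are median-centred
and column-scaled with parameters frozen from the training set
(sd floor 1e-8 for constant bins). The RBF width sigma comes from the
median-pairwise-distance heuristic, `sigma = 1/(2 m^2)` with m the
median Euclidean inter-point distance — the published sigma of 0.6456
is a dataset-specific estimate of the same kind, not a constant of the
method. The cost parameter is selected by leave-one-out
cross-validated accuracy over the nine-value grid 2^-2 … 2^6 = 64,
with ties broken toward the smaller (more regularised) cost; whether
the original tuning optimised accuracy or ROC is not stated, and
accuracy is the simpler reading. The final machine is refitted with
Platt-type probability calibration, and OCRI is the calibrated
probability of the OSCC class, in [0, 1], with 0.5 as the reporting
threshold.

The model benchmark runs six families — radial SVM, random forest,
penalized (ridge) logistic regression, a single-hidden-layer neural
network, k-nearest neighbours and a classification tree — under
10-fold cross-validation repeated 5 times (50 resamples), with the
identical fold assignments for every model so that differences
reflect the models, not the resampling. OSCC is the positive class for
sensitivity and specificity (cut at probability 0.5), models are
ranked by median ROC, then sensitivity, then specificity, and the
ranking is descriptive — no hypothesis tests, hence no multiplicity
correction. Within the benchmark the SVM is scored by its decision
values passed through a logistic link (oriented on the training fold)
rather than refitting Platt calibration 50 times; the OCRI model
proper uses full probability calibration.

## The synthetic generator

No patient-level data accompany the method, so the package ships a
generator that emulates the assumed data-generating process: per-case
DI values drawn from a finite Gaussian mixture, with negative draws
rejected and redrawn (DI is a strictly positive ratio; at these
parameter values the rejected mass is negligible, so no truncation
bias is introduced). Three case profiles operationalise the published
qualitative descriptions:

* **normal** — diploid N(1.001, 0.19) at weight 0.9965, a trace
  tetraploid shoulder (0.003) and aneuploid weight 0.0005, keeping the
  expected fraction of cells at DI ≥ 2.3 under 0.1%;
* **olk** — the diploid peak plus secondary components at DI 1.25,
  1.75, 2.22 and 2.74 (the published example locations; weights are
  not published and were fixed once at 0.06 / 0.06 / 0.036 / 0.004 to
  give the intermediate, multi-peak character of premalignant
  lesions);
* **oscc** — diploid 0.80, tetraploid N(1.9, 0.25) at 0.12 and a
  high-DI aneuploid population N(3.4, 0.5) at 0.08, matching the
  published carcinoma example whose aneuploid peaks sit at DI
  3.25–3.99.

The canonical three-population simulation (diploid N(1.001, 0.19),
tetraploid N(2.002, 0.25), aneuploid N(2.300, 0.5) at ratio
0.893 : 0.092 : 0.005) is available as `fig1d_spec()`; the printed
ratio sums to 0.99 and is normalised to mixing proportions. Per-case
cell counts are not published beyond one example of 3,590 cells; the
cohort default draws counts uniformly from 1000–4000. Per-case seeds
are derived deterministically from the cohort seed and recorded in the
manifest, so any single case can be regenerated alone.

What the generator does *not* emulate: measurement artifacts (debris,
cut nuclei, staining drift), the sub-diploid shoulder sometimes seen
in real smears, correlations between cell count and diagnosis, and
any of the 131 non-DI cytologic parameters. Tests passing on this
generator therefore demonstrate the correctness and internal
consistency of the procedure under its own distributional assumptions,
not clinical performance; the published clinical figures (sensitivity
0.939, specificity 0.9444, AUC 0.968 on a 30% holdout) are context,
not a reproduction target, because the underlying cohort is not
available.

## Numerical choices and degenerate inputs

* KDE grid step 0.01 DI; trapezoidal renormalisation to unit integral
  (tolerance 1e-3 in the tests).
* Bandwidth floor 1e-3 DI; zero-variance input warns and floors
  rather than erroring.
* Reconstruction filler 0.0001; feature writers refuse rows below it.
* Observed component sd floor 0.05 DI in amplification.
* Ties in LOOCV cost selection go to the smaller cost; ties in the
  extraction claim are processed per unique value so cell order never
  matters.
* Empty cohorts, single-class training sets, fewer than 10 training
  cases, unanalyzable cases, truncated model archives and version
  mismatches all fail with explicit, classed errors.

## Problem sizes

The shipped experiments are sized for a single CPU: parameter
recovery uses 20 simulations of 4,000 cells; the classifier surrogate
uses 100 normal and 90 OSCC synthetic cases under 10-fold CV × 5
repeats; property suites use cohorts of tens of cases and fuzz sets of
a few thousand vectors. These sizes were chosen so the full
acceptance computation completes in well under a minute while keeping
Monte-Carlo error comfortably inside the stated tolerances.

## Known limitations

* The extraction is geometric, not likelihood-based; no EM mixture
  fit is attempted, by design. Heavily overlapping populations
  (separation ≲ 2 sd) are partially absorbed into the dominant peak.
* The tetraploid window [1.5, 2.3) hard-codes the published
  thresholds; instruments calibrated differently would need them
  exposed.
* The amplified R3 = 0.1 budget makes the feature vector insensitive
  to the observed aneuploid *fraction* whenever three populations are
  detected (see above); risk information then rides on component
  locations.
* OCRI is calibrated within the synthetic (or user-supplied) training
  cohort only; no claim of transportability across laboratories is
  made.
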