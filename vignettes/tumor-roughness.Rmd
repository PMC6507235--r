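---
title: "Methods: boundary roughness scoring of renal masses on CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boundary roughness scoring of renal masses on CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trscore)
```

## The measurement model

The Tumor Roughness Score treats a renal mass's margin irregularity as a
fractal-geometry problem. A perfectly smooth tumor boundary is a
rectifiable curve: covering it with boxes of side $\delta$ needs
$N(\delta) \propto 1/\delta$ boxes, so the slope of $\log N(\delta)$
against $\log(1/\delta)$ — the box-counting dimension, the practical
surrogate of the Hausdorff dimension — is 1. The more convoluted the
boundary, the faster $N(\delta)$ grows as $\delta$ shrinks and the larger
the slope, up to 2 for a set that fills the plane.

Rather than scoring only the mask outline, the pipeline scores the
boundaries of *intensity levels* inside the tumor. Enhancing renal masses
show internal contrast structure (central enhancement washing out toward
the rim), so the level sets of a multilevel thresholding of the ROI trace
both the internal architecture and the outer margin; heterogeneous,
infiltrative masses produce more convoluted level boundaries at every
threshold. Per slice, the score is the mean box dimension over nonempty
levels; the TRS (`R_avg`) is the unweighted mean over slices with a usable
ROI. Both aggregations are plain means because no level or slice is a
priori more informative.

Assumptions worth stating: the mask is trusted (no automatic detection);
slices are scored independently in 2-D (no voxel-level 3-D box counting —
consistent with scoring a thin stack of axial cuts); and intensities are
windowed to $[0, 1]$ before anything else, so thresholds are comparable
across scanners.

## Stage 1 — enhancement

Three canonical operations, in order: a self-guided filter (local linear
model $aI + b$ over $(2r+1)^2$ windows, $a = \mathrm{var}/(\mathrm{var} +
\epsilon)$), unsharp sharpening $I + g\,(I - \mathrm{smooth}(I))$, and a
convex-combination fusion of the original slice with its enhanced version,
followed by range renormalization. Defaults: radius $r = 4$ px,
$\epsilon = 10^{-3}$ (squared gray units; flat-region variance below
$\epsilon$ is smoothed away, edges above it survive), gain $g = 1$, fusion
weights $(0.5, 0.5)$. Whether to fuse the enhanced slice with the original
or with a second, differently enhanced copy was an open design point; the
original-plus-enhanced convex combination was chosen as the simplest form
that preserves a traceable link to the raw data, and `--no-enhance` (or
`trs_config(no_enhance = TRUE)`) ablates the stage entirely. Enhancement
runs only inside the ROI bounding box dilated by 8 px: the background far
from the tumor is irrelevant and renormalizing over it would waste dynamic
range. On noise-free fixtures the stage moves a step edge by less than one
pixel (tested).

## Stage 2 — alpha-trimmed multilevel thresholding

The ROI histogram uses 256 uniform bins over the ROI's own intensity
range. The criterion is the between-class variance
$\sigma^2 = \sum_i P_i(\mu_i - \mu_T)^2$, maximized exhaustively over all
placements of $M - 1$ thresholds on bin boundaries ($M \le 4$; ties break
to the lexicographically smallest vector, so output is deterministic).

Alpha-trimming is applied *globally*: the histogram's cumulative mass is
clipped to $[\alpha, 1 - \alpha]$ (fractionally within boundary bins) and
renormalized before class statistics are formed. An earlier design trimmed
each class's own tails instead, and turned out to be self-defeating: near a
candidate threshold the mass being reassigned between classes lies in the
trimmed-away tails of *both* classes, so the objective develops a plateau
across the inter-mode gap (tilt at rounding level) and the argmax wanders
under impulse noise — the trimmed threshold was *less* stable than the
untrimmed one on every replicate of a salt-and-pepper benchmark. Global
trimming deletes impulse spikes outright (any contamination carrying less
than $\alpha$ mass per tail), keeps a sharp optimum, and has a clean
theoretical property: because the trimmed total variance is fixed,
maximizing between-class variance and minimizing the pooled within-class
variance of the trimmed distribution are exactly the same search. With
$\alpha = 0$ the criterion is exactly classical Otsu (verified to
$10^{-12}$ against an independent implementation).

A linear (unsquared) variant of the criterion,
$\sum_i P_i(\mu_i - \mu_T)$, is exposed behind
`between_class_variance(..., printed_form = TRUE)` for comparison only: it
telescopes to zero identically and is not a usable objective — the squared
form is the one with meaning, and the default.

Defaults: $M = 3$ levels (2 would only reproduce the rim-versus-core
split; 4 fragments small ROIs), $\alpha = 0.1$ (tolerates up to 10%
impulse contamination per tail while discarding little signal), 256 bins.
`M` and $\alpha$ are recorded in every result.

## Stage 3 — box counting

Edges are the 4-connectivity inner boundary of each level region
(parameter-free and deterministic, unlike gradient-threshold edge maps;
pixels beyond the frame count as background). Box sides follow the dyadic
schedule $\delta \in \{2, 4, 8, \dots\}$ up to $\max(16,\ \text{ROI
extent}/4)$, so at least four sizes always enter the fit; the grid is
anchored at the point set's bounding box (whole-pixel translations of the
ROI therefore change nothing) and counts are averaged over four grid
phases (offsets $0, \delta/2$ per axis) to damp grid-phase artifacts.
Counts are kept as reals; the OLS slope of $\log N$ on $\log(1/\delta)$ is
clipped to $[0, 2]$ with a warning if a fit strays outside. Slices with
fewer than 16 ROI pixels are skipped and logged — too few edge points for
a stable fit. $N(\delta)$ monotonicity is asserted on every curve, not
assumed.

Validation anchors the estimator on sets with known dimension: a line
(1), a point (0), the Koch curve ($\log 4/\log 3 \approx 1.2619$, rasterized
at iteration 5 on a 512 px frame, the deepest iteration with features
$\ge 1$ px), the Sierpinski triangle ($\log 3/\log 2 \approx 1.585$,
iteration 6) and a filled square (2). Recovered slopes land within 0.05
(line, point) and 0.10 (the rest) of theory; the residual bias is
finite-size truncation of the scaling range, not estimator error.

## The phantom: what it emulates, and what it does not

The phantom is a thin 3-slice stack containing one bright region on a dark
background. Its boundary is $r(\theta) = R\,(1 + a\,p(\theta))$ with
$p(\theta)$ a random-phase mix of angular harmonics $k = 3 \dots 8$
normalized to peak 1, so the amplitude $a$ *is* the maximal fractional
radial deviation and a single dial orders the family from disk ($a = 0$)
to strongly lobulated ($a = 0.4$). Harmonics below $k = 3$ are excluded —
they translate or elongate the shape without roughening it. Each slice
draws fresh phases, mimicking successive cuts through one lesion; all
randomness flows through a caller-supplied seed, and generation is a pure
function of (spec, seed).

Inside the region the intensity falls off radially,
$I = f - s\,(d/r(\theta))^2$ with shading $s = 0.15$ gray units by
default, emulating contrast washout: this gives the ROI real internal
structure whose level sets are scaled copies of the boundary — the
structure stage 2 is designed to find. Additive Gaussian noise (default
$\sigma = 0.002$ gray units, a good-quality windowed contrast CT; the
noise-robustness benchmarks inject far harsher salt-and-pepper corruption
deliberately) is added after rasterization, so the mask stays exact.
Geometry defaults ($192$ px frame, $R = 60$ px) put the annular levels
several box-sizes apart; on much smaller ROIs the two boundary circles of
a thin annulus merge at coarse $\delta$ and bias slopes upward. The
defaults were calibrated once so that the unperturbed disk reproduces the
smooth-boundary anchor ($R_{avg} \approx 1.05$, within the $1.0 \pm 0.1$
band) and were not revisited.

What the phantom does *not* emulate: CT acquisition physics (beam
hardening, reconstruction kernels, correlated noise), partial-volume
fuzz at the mask edge, non-star-shaped or multifocal lesions, and any
real histology-to-texture relationship. Passing the monotonicity
benchmark (Spearman $\rho \ge 0.9$ between amplitude and TRS across 9
amplitudes × 5 seeds) therefore shows the pipeline orders *geometric*
boundary roughness correctly under mild noise — it does not show that TRS
separates real tumor subtypes; that claim can only come from clinical
data.

## Cohort statistics

The analysis layer mirrors a typical small-cohort workup: one-way ANOVA
with Fisher's LSD post hoc pairwise tests (pooled within-group variance,
deliberately *no* multiplicity correction — that is what LSD is),
two-tailed Pearson correlation of tumor size against TRS, and
multivariable OLS with 95% CIs. Standard model fits go through `lm`,
`anova`, and `cor.test`; the LSD table is computed explicitly and is
cross-checked in the tests against unadjusted pooled-SD pairwise t-tests.
Regressing a categorical subtype on covariates requires a numeric coding;
`subtype_code()` uses the ordered aggressiveness code benign cyst 0,
oncocytoma 1, chromophobe 2, clear cell 3, papillary 4 — the ordering of
the subtypes' mean roughness — and TRS-as-outcome is the statistically
cleaner alternative when the goal is inference about covariates rather
than subtype prediction. `renal_cohort_27()` ships a *synthetic*
subject-level reconstruction of a published 27-patient demographic table
(counts and medians only; continuous values are constant within subtype)
used solely to exercise the summary layer.

Calibration is tested, not assumed: under null simulations the ANOVA,
Pearson and regression tests reject at $0.05 \pm 0.02$; the two-group
ANOVA F equals the squared pooled t to $10^{-9}$; and a known regression
effect (2.6 per TRS unit on the subtype code) is recovered within 2
standard errors in $\ge 90\%$ of replicates.

## Numerical choices and degenerate inputs

* Histogram thresholds live on bin boundaries; a pixel equal to a
  threshold goes to the lower class.
* Empty histogram bins carry zero mass everywhere, so $\sigma^2$ is
  invariant to adding them (tested).
* An ROI with fewer distinct gray values than $M$ raises a typed
  `trs_degenerate_roi` condition; the pipeline skips such slices with a
  warning rather than failing the whole volume.
* A constant box-count curve fits slope 0 with $r^2$ reported as 1 (the
  constant fit is exact).
* Windowing defaults to soft tissue (center 40, width 400 HU) for
  HU-valued volumes and to identity for data already in $[0, 1]$.
* All pipeline stages are deterministic; two runs on identical input and
  configuration produce bit-identical results, including serialized JSON.

## Problem sizes

The shipped validation suite uses 512 px fractal rasters, 1000 random
64-bin histograms for oracle equivalence, 45 phantom runs (9 amplitudes ×
5 seeds) of 192 px × 3 slices for monotonicity, and 500–1000 replicates
per statistical calibration check; the full suite runs in about a minute
on one core. These sizes give the Monte-Carlo bands quoted above
(binomial SE ≈ 0.7% at 1000 replicates) while keeping the suite quick
enough to run on every change.

## Known limitations

* 2-D slice scoring only; a true voxel-based 3-D dimension is out of scope.
* The box-dimension estimate at 4 dyadic sizes carries finite-size bias
  (≈ +0.05 on smooth curves at the default geometry); comparisons are
  meaningful within a fixed configuration, absolute values should not be
  over-interpreted.
* DICOM series are not read directly; convert to NIfTI or PNG slices
  first. Masks must share the stack's grid exactly — there is no
  resampling.
* `M = 4` threshold search is exhaustive and noticeably slower than
  `M ≤ 3` (minutes at 256 bins); it exists for completeness.
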