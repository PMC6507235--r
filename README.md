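# trscore — Tumor Roughness Scoring for Renal Mass CT

Small renal masses are usually found incidentally on CT, and size alone is a
poor guide to how aggressive they are: clear cell and papillary carcinomas
tend to show more irregular, "rough" margins than benign cysts or
oncocytomas. `trscore` quantifies that irregularity. Given a stack of
contrast-enhanced CT slices and a per-slice binary tumor mask, it computes a
**Tumor Roughness Score (TRS)** — a boundary-complexity measure built from
fractal geometry — intended for radiology/urology imaging researchers
studying renal-mass characterization, and for anyone needing a tested,
deterministic box-counting dimension or multilevel-threshold implementation
in R.

## The algorithm

TRS is a three-stage, slice-by-slice pipeline:

1. **Enhancement** — edge-preserving guided filtering (local linear model
   `a·I + b`), unsharp edge enhancement, and convex-combination fusion with
   the original slice, applied inside a dilated bounding box of the ROI.
2. **Multilevel thresholding** — the ROI histogram (256 bins over the ROI
   intensity range) is *alpha-trimmed*: an exact fraction α of the
   probability mass is removed from each tail, discarding impulse noise.
   The `M − 1` thresholds maximize the between-class variance

   σ² = Σᵢ Pᵢ (μᵢ − μ_T)²,  i = 1…M,

   where Pᵢ and μᵢ are class probabilities and means and μ_T the total mean,
   all on the trimmed histogram. The search is exhaustive over bin
   boundaries, ties broken lexicographically; with α = 0 and M = 2 this is
   exactly Otsu's method.
3. **Roughness** — for each intensity level, the 4-connectivity inner
   boundary pixels are box-counted on a dyadic schedule of box sides δ
   (grid anchored at the point set's bounding box, counts averaged over 4
   grid offsets), and the box-counting dimension — the practical surrogate
   for the Hausdorff dimension — is the slope of the OLS fit of log N(δ)
   against log (1/δ). Level slopes are averaged per slice, slice scores are
   averaged into **R_avg**, the TRS.

Smooth, homogeneous masses score near 1 (their level boundaries are smooth
curves); irregular, heterogeneous masses score higher.

The package also provides tumor **phantoms** with a single boundary-
roughness dial (random-phase radial harmonics), classical **fractal
fixtures** (Koch curve, Sierpinski triangle, …) with analytically known
dimension for validating the estimator, and a **cohort statistics** layer
(one-way ANOVA with LSD post hoc tests, Pearson correlation, multivariable
OLS, demographic summary tables).

## Worked example

```r
library(trscore)

# a rough phantom: 3 slices, boundary perturbation amplitude 0.3
ph  <- make_tumor_phantom(phantom_spec(perturb_amplitude = 0.3, seed = 5))
res <- tumor_roughness_score(ph$stack, ph$mask)
res
#> <trs_result> R_avg = 1.0893 over 3 slice(s)
#>  slice    score n_roi n_levels
#>      1 1.063642 11418        3
#>      2 1.068006 11455        3
#>      3 1.136279 11447        3
```

`R_avg = 1.0893` is the mean over the three slice scores; each slice score
is the mean box-dimension of its three intensity-level boundaries. An
unperturbed disk phantom scores ≈ 1.05 (smooth boundary ≈ dimension 1),
and the score rises monotonically with the perturbation amplitude.

The estimator itself can be checked against fixtures with known dimension:

```r
k  <- make_fractal_points(fractal_spec("koch_curve", iterations = 5))
ft <- fit_dimension(box_count(which(k, arr.ind = TRUE), c(2, 4, 8, 16, 32, 64)))
ft$slope          # 1.2014  (theory: log 4 / log 3 = 1.2619)
```

A command-line front end is installed with the package:

```sh
TRS=$(Rscript -e 'cat(system.file("cli/trs.R", package = "trscore"))')
Rscript $TRS phantom  --amplitude 0.3 --seed 5 --out ph
Rscript $TRS score    --images ph/image.nii.gz --mask ph/mask.nii.gz --out result.json
Rscript $TRS validate             # fractal-dimension recovery table
Rscript $TRS stats    --cohort cohort.csv --out report/
```

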