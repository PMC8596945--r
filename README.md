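# escimap

Standardized effect-size maps with exact confidence intervals for fMRI group
analyses — and the equivalence-style inferences they enable.

## Why

A thresholded group-level t map splits the brain into "active" and blank, and
the blank is routinely over-read as evidence of absence. `escimap` computes,
for every voxel, Hedges' *g* (the bias-corrected standardized effect size)
together with its *exact* confidence interval from the artifacts a group
analysis already produces: the t map, the design matrix and the contrast
vector. On top of the maps it implements three interval-based procedures:

* **maps of undecidability** — voxels whose CI upper limit includes or
  exceeds a detected cluster's reference effect, i.e. voxels that *cannot* be
  declared smaller than the detected effect;
* **voxel-wise replication tests** — does the reference sample's effect fall
  inside the replication sample's CI?
* **lateralization tests** — are effects comparable to a cluster's
  75th-percentile effect present in the mirrored contralateral region?

It is aimed at neuroimaging researchers who want to report measurement
uncertainty alongside point estimates, or who need formal inferiority /
equivalence statements ("this region's effect is smaller than that one")
rather than the absence of a star.

## The statistics in one paragraph

For a GLM contrast *c* with design matrix *X*, the voxel t statistic converts
to a standardized effect by the contrast variance scale,
*d<sub>p</sub>* = *t* · √(*c*′(*X*′*X*)⁻*c*), which reduces to
*t*·√(1/n₁ + 1/n₂) (two-sample) and *t*·√(1/n) (one-sample). The point
estimate is Hedges' *g* = *d<sub>p</sub>* · *J* with
*J* = 1 − 3/(4·DoF − 1) and DoF = N − rank(*X*). The CI treats the observed
*t* as the estimate of the noncentrality parameter Δ of a noncentral t
distribution and inverts its CDF: Δ<sub>l</sub> solves
F(t; DoF, Δ) = 1 − α/2, Δ<sub>u</sub> solves F(t; DoF, Δ) = α/2; both limits
are multiplied by the same contrast scale (and are deliberately *not*
bias-corrected, which preserves the exact correspondence between "the
(1−2α) CI excludes 0" and "one-sided p < α"). Default confidence: 0.90, the
conventional equivalence-testing interval.

## Worked example

Scalar route — the group comparison numbers for a two-sample design with
n₁ = 32, n₂ = 35 (DoF 65) and an observed t of 3.4:

```r
library(escimap)
est <- ci_g(t = 3.4, dof = 65, scale = scale_two_sample(32, 35))
print(est)
#> Hedges' g = 0.8220 (d_p = 0.8316), 90% CI [0.4088, 1.2483], dof = 65
inferiority_test(est, 1.2)
#> FALSE
```

The effect estimate is 0.82; the interval excludes 0 (the voxel would be
significant) but reaches 1.25, so the data cannot establish the effect as
smaller than a reference of 1.2 — the voxel would be *undecidable* against
that reference.

Map route, on simulated data with known ground truth (three disk effects of
d = 0.28, 0.50, 0.50 in one slice; group B minus group A):

```r
study  <- simulate_study(n_per_group = 50, seed = 1)
tmap   <- two_sample_tmap(study)
design <- study_design(study)
print(design)
#> design_spec: N = 100, rank = 2, dof = 98, scale = 0.200000

es  <- es_map_from_tmap(tmap, design, confidence = 0.90)
sig <- threshold_tmap(tmap, design, alpha = 0.001)          # p < .001 unc.
ref <- cluster_reference(es, sig$values == 1, kind = "percentile",
                         percentile = 1)                    # peak of cluster
print(ref)
#> cluster_reference: percentile (p = 1) g = 0.9144 at voxel (74, 53, 1)

und <- undecidability_map(es, ref)
print(und)
#> binary_result_map (undecidable): 43/9216 evaluated voxels positive
```

At n = 50 per group, 43 voxels outside the significant cluster cannot be
declared smaller than the detected peak effect (g = 0.91) — blank in the
t map, but not evidence of a smaller effect. Re-running with
`n_per_group = 500` yields an empty undecidability map: with that much data
every sub-reference voxel is decidably smaller.

The same operations are available from a shell via the installed `escimap`
script (`esmap`, `undecide`, `replicate`, `lateralize`, `simulate`, `demo`
subcommands; NIfTI in, NIfTI + JSON sidecar out), e.g.

```sh
escimap esmap -t tmap.nii.gz -X design.tsv -c "1,-1" --confidence 0.90 -o out/
```

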