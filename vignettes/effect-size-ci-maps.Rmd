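---
title: "Effect-size maps with exact confidence intervals: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect-size maps with exact confidence intervals: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escimap)
```

## The problem

Group-level fMRI analyses usually end in a thresholded t map: voxels above a
critical value are "active", everything else is blank. That blank is routinely
over-read as evidence of absence. `escimap` complements significance testing
with *standardized effect sizes and their confidence intervals*, computed
voxel-wise from exactly the artifacts a group analysis already produces — the
t map, the design matrix, and the contrast vector — and uses those intervals
for equivalence-style inference: which voxels can, and which cannot, be
declared smaller than a reference effect.

## The estimator

For a GLM contrast $c$ with design matrix $X$, the t statistic at a voxel
converts to a standardized effect via the *contrast variance scale*

$$ d_p = t \cdot \sqrt{c'(X'X)^- c}, $$

which reduces to $t\sqrt{1/n_1 + 1/n_2}$ for a two-sample comparison and
$t\sqrt{1/n}$ for a one-sample test. $(X'X)^-$ is a pseudoinverse: we use an
SVD with tolerance-based rank determination
(singular values below $\max(\dim X)\cdot\varepsilon\cdot\sigma_{\max}$ are
treated as zero), so over-parameterized designs such as intercept-plus-two-
indicators work, and non-estimable contrasts are rejected rather than
silently projected. Degrees of freedom are $N - \mathrm{rank}(X)$; independent
covariate columns each cost one.

$d_p$ overestimates the population effect $\delta$ in small samples, so the
point estimate is Hedges' $g = d_p \cdot J$ with
$J = 1 - 3/(4\,\mathrm{DoF} - 1)$ by default (the exact
gamma-function form is available via `exact = TRUE`; the two differ by less
than 0.2% for DoF $\ge 5$).

## The confidence interval

The interval is exact, not normal-approximate. The observed $t$ estimates the
noncentrality parameter $\Delta$ of a noncentral t distribution with the
design's DoF; the two-sided $(1-\alpha)$ limits solve

$$ F(t;\,\mathrm{DoF},\,\Delta_l) = 1 - \alpha/2, \qquad
   F(t;\,\mathrm{DoF},\,\Delta_u) = \alpha/2 $$

for the CDF $F$, which is strictly decreasing in $\Delta$. Both limits are
then multiplied by the same contrast scale to land on the effect-size axis.
Two properties follow and are enforced by tests:

* the limits are **not** bias-corrected by $J$ — the noncentral t at the
  correct DoF already yields a valid interval, and shrinking the limits would
  break the next property;
* the $(1-2\alpha)$ interval excludes zero from below exactly when the
  one-sided t test is significant at $\alpha$. Note that this exact pairing
  means a *99.8%* two-sided interval corresponds to one-sided $p < .001$; a
  99.9% interval corresponds to one-sided $p < .0005$. The package always
  exposes the confidence level explicitly so the user chooses the pairing.

Numerically, each limit is found by bracket expansion plus `uniroot`: the
initial bracket $t \pm k\sqrt{\mathrm{DoF}}$ has $k$ doubled until the CDF
target is straddled (an error is raised after 60 doublings), and the returned
root must leave a CDF residual below $10^{-6}$. A brute-force bisection
oracle over the same CDF confirms the limits to 4 decimals across
$t \in [-3, 5]$, DoF $\in \{5, 20, 60, 200\}$ and confidence
$\in \{0.90, 0.95, 0.999\}$. `se_g_approx()` provides the classical
normal-approximation standard error for comparison; nothing in the package
uses it internally.

The default confidence level everywhere is **0.90**, the two-sided interval
whose one-sided tails at 5% match conventional equivalence testing. One-sided
intervals are not offered; one-sided logic is always expressed through the
$(1-2\alpha)$ two-sided interval.

## Map level

`es_map_from_tmap()` lifts the scalar pipeline over every in-mask voxel and is
deterministic given its inputs. Non-finite voxels (outside the mask, or
degenerate) propagate as `NA` and can never become finite downstream; every
output shares the input grid and affine bit-exactly. Voxel indices follow R's
native 1-based convention; world coordinates are obtained from the NIfTI
affine as $A\,(i-1, j-1, k-1, 1)'$, so the I/O boundary remains standard. No
multiplicity correction is applied by default (undecidability results are then
*lower bounds* on the undecidable area); `adjust = "bonferroni"` divides
$\alpha$ by the in-mask voxel count for users who want joint confidence.

Cluster references use the *nearest-rank* convention,
$\mathrm{rank} = \lceil p \cdot n\rceil$: the reference is always the value of
an actual voxel, the median of an even-sized cluster is the lower of the two
middle values, and ties resolve to the first voxel in array order (the chosen
voxel index is reported, so the resolution is auditable).

## The three procedures

**Undecidability.** A voxel is *undecidable* when the upper limit of its CI
includes or exceeds ($\ge$) the cluster reference: the data cannot establish
its effect as smaller than the detected one. The complement is exactly the
inferiority test (`ci_upper < bound`, strict). The reference cluster itself is
excluded from the output by default — those voxels are already decided.
Raising the reference can only remove voxels; widening the interval can only
add them.

**Replication.** A reference effect replicates at a voxel when it falls
inside the replication sample's CI, read as a *closed* interval. Only voxels
with reference $g > 0$ are evaluated (the directional convention of fMRI
contrasts); the output is three-valued: 1 replicated, 0 not, `NA` not
evaluated. Evaluation is brain-wide wherever $g > 0$; stricter masking is
left to the user. The confidence level is an explicit parameter (default
0.90) since replication criteria in the literature also use 95%.

**Lateralization.** The cluster's 75th-percentile voxel (nearest-rank,
configurable) sets the reference; the cluster mask is mirrored across the
midline by index reflection $i \mapsto n+1-i$ along the left–right voxel
axis, inferred from the affine's dominant world-x direction and overridable
(`mirror_axis`) because acquisitions are not always axis-aligned. Mirroring
twice is the identity, and voxel counts are preserved. Clusters that touch or
straddle the midline are rejected. An empty contralateral map supports
lateralization; any flagged voxel speaks against it. The grid is assumed
midline-symmetric; data normalized to a symmetric template satisfy this.

## The simulator

`simulate_study()` emulates the minimal data-generating process the package
needs for validation: per-subject volumes of spatially smoothed Gaussian
white noise, plus hard-edged disk effects added to group B's mean. Design
choices, each made once:

* **Variance renormalization.** Smoothing is separable Gaussian
  (kernel-matrix per axis); afterwards each voxel is divided by its exact
  analytic post-smoothing SD, so the marginal SD equals `noise_sd` everywhere
  including edges. A declared effect $d$ is therefore realized exactly as a
  standardized mean difference of $d$ in expectation — the property every
  recovery and coverage test relies on.
* **Defaults.** `noise_sd = 1`, `smoothing_fwhm = 2` voxels, slice
  `96 x 96`. The grid size is a tractability choice: it leaves the
  standardized effects, their recovery, and all CI behavior untouched (those
  depend only on $n$ and $d$) while keeping repeated-seed validation runs
  fast; it is fully configurable.
* **Determinism.** One integer seed governs the whole study through a fixed
  generation order; regeneration is bit-identical.
* The three-effect demonstration layout places disks of $d = 0.28, 0.50,
  0.50$ (labelled I, II, III) along the mid row at 1/4, 1/2, 3/4 of the
  slice width.

What the simulator deliberately does **not** emulate: temporal
autocorrelation, physiological noise, field inhomogeneity, inter-subject
anatomical variability, or first-level modelling. Passing tests therefore
validate the *statistical machinery* — conversion, bias correction, interval
construction and the decision rules — not robustness to realistic fMRI
artifacts.

`demo_experiment()` runs the full contrast between a large ($n = 500$ per
group) and a small ($n = 50$) study: at $n = 500$ all three effects are
recovered (99.9% CI lower bounds above zero) and the small effect I is
decidably smaller than the detected peak; at $n = 50$ the intervals widen
several-fold and regions of the same true size as the detected effect can
become nonsignificant-yet-undecidable. The undecidability reference is the
peak $g$ within the significant ($p < .001$ one-sided, uncorrected) voxels.
Because the reference is a maximum over many correlated noisy voxels, the
small-sample undecidable-cluster phenomenon at III is seed-dependent; the
demo reports per-region counts so each run documents itself.

## Problem sizes used in validation

Recovery is validated at $n = 500$ per group over 50 seeds (Monte-Carlo SE of
the mean $\approx 0.009$ standardized units); interval coverage with 10,000
two-sample replicates at $n = 50$, $\delta = 0.5$ (binomial SE 0.3
percentage points); the significance correspondence voxel-by-voxel over a
full slice; null calibration with smoothing off, where voxels are
independent and the false-positive rate has an exact binomial reference.

## Known limitations

* `stats::pt(ncp=)` underlies both the inversion and its oracle; its
  documented accuracy (about $10^{-8}$ over this range, degrading for very
  large $|\Delta|$) bounds the agreement achievable, comfortably inside the
  $10^{-6}$ residual tolerance used.
* FWE-corrected cluster *detection* is out of scope: cluster masks are
  inputs. So is first-level modelling, and native binary design formats —
  export the design matrix to delimited text.
* The undecidability and replication procedures inherit the reference-choice
  sensitivity discussed above; the reference specification is always echoed
  in the JSON sidecars so analyses are auditable and preregisterable.
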