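---
title: "Multi-compartment diffusion modeling of optic-nerve injury: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-compartment diffusion modeling of optic-nerve injury: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsir)
```

## The signal model

Diffusion-weighted MRI of a coherent white-matter tract such as the
pre-chiasmatic optic nerve mixes signal from several tissue
environments: water inside and around axons (anisotropic), water
trapped in cells (isotropic and slow), and edema or CSF (isotropic and
fast). Conventional diffusion tensor imaging (DTI) collapses all of
this into a single tensor, so its scalar metrics confound axonal
injury with inflammation and edema.

`dbsir` models the signal of measurement $k$ (direction
$\vec g_k$, b-value $b_k$) as one axially symmetric fiber tensor plus
a non-negative spectrum of isotropic diffusivities:

$$
S_k = S_0\left[\, f\, e^{-b_k\lambda_\perp}
  e^{-b_k(\lambda_\parallel-\lambda_\perp)\cos^2\Phi_k}
  + \sum_i w_i\, e^{-b_k D_i} \right],
$$

where $f$ is the fiber signal-intensity fraction,
$\lambda_\parallel,\lambda_\perp$ are the fiber's axial and radial
diffusivities (µm²/ms), $\Phi_k$ is the angle between $\vec g_k$ and
the fiber axis, and $w_i \ge 0$ are weights on a fixed grid of
isotropic diffusivities $D_i$. b-values are stored in s/mm² and scaled
by $10^{-3}$ inside the exponentials so exponents are dimensionless.

The isotropic spectrum is summarized by two fractions with fixed ADC
cut-offs: *restricted* ($D \le 0.6$ µm²/ms, inclusive; a cellularity /
inflammation marker) and *non-restricted* ($0.6 < D \le 3$ µm²/ms in
vivo, $\le 2$ µm²/ms for fixed ex vivo tissue; an edema / CSF marker).
The spectrum grid runs from 0 to the non-restricted ceiling in steps
of 0.05 µm²/ms, which places a grid point exactly on the 0.6 boundary
so the partition is unambiguous. A single anisotropic component is
assumed throughout: the optic nerve is a coherent bundle, and no
crossing-fiber configurations are modeled.

## Inversion

`fit_dbsi()` inverts the model per voxel in three nested stages:

1. **Orientation.** The principal eigenvector of a weighted log-linear
   DTI fit initializes the fiber axis (antipodally normalized to
   non-negative $z$). In mixed voxels this axis is biased by roughly a
   degree, which is enough to leave a visible residual floor, so the
   refinement stage (below) also optimizes a two-parameter tilt around
   the initial axis. On noise-free phantoms the refined axis is exact
   to millidegrees.
2. **Fiber diffusivities.** A coarse grid over
   $(\lambda_\parallel, \lambda_\perp)$ (default step 0.25 µm²/ms over
   $[0.1, 4] \times [0, 1.5]$, constrained to
   $\lambda_\perp \le \lambda_\parallel$) is followed by Nelder–Mead
   refinement to an absolute residual tolerance of $10^{-4}$. Grid
   ties are broken by lowest residual, then smallest
   $\lambda_\perp$, then smallest $\lambda_\parallel$, so results are
   deterministic. A coarse-plus-refine search was chosen over a dense
   grid: the residual surface is smooth in the diffusivities and a
   dense 0.05-step grid would cost fifty times more inner solves for
   no accuracy gain.
3. **Spectrum weights.** At each candidate, the fiber signature column
   and the isotropic basis $e^{-b_k D_i}$ form a design matrix whose
   non-negative weights are solved by Lawson–Hanson active-set NNLS
   (compiled; validated in the tests against an independent R
   implementation and against exhaustive simplex-grid enumeration).
   Weights are normalized by their sum, so reported fractions are
   signal-intensity fractions summing to 1 by construction.

Two design points deserve justification:

* **Regularization default.** The config exposes an L2 (ridge) penalty
  on the isotropic weights, but the default is 0. The isotropic basis
  columns are highly correlated decaying exponentials; even a small
  ridge prefers smearing weight smoothly across many adjacent
  diffusivities, which pushes mass across the 0.6 µm²/ms boundary and
  biases the restricted fraction by several hundredths — worse than
  the quantity being stabilized. Unregularized active-set solutions
  are sparse vertex solutions and recover delta-like generative
  spectra exactly in the noise-free limit; at SNR 30 their
  ROI-averaged means stay within 0.03 of truth. The penalty remains
  available (`ridge_penalty`) for noisier regimes, and is never
  included in reported residuals.
* **Fiber retention gate.** When $\lambda_\parallel = \lambda_\perp$
  the fiber column duplicates an isotropic basis column, so a
  fiber-free voxel could be "explained" by a degenerate fiber. Each
  voxel is therefore also fit with the isotropic basis alone, and the
  anisotropic component is kept only if it improves the residual norm
  by at least 5% (`fiber_gate`). Pure isotropic voxels then return a
  fiber fraction of exactly 0.

The Gaussian least-squares objective is used even though simulated
noise is Rician; at SNR ≥ 20 this is standard practice. The residual
Rician bias is measurable — at SNR 30 the noisy-fit axial diffusivity
runs high by roughly 0.1–0.15 µm²/ms on sham-like voxels while
fraction estimates stay essentially unbiased — and the tests document
the fraction behavior quantitatively.

## The DTI comparison arm

`fit_dti()` is a two-pass weighted log-linear tensor fit (ordinary LS
on $\log S$, then one reweighting by the squared predicted signal).
Scalars follow the standard conventions: axial diffusivity is the
largest eigenvalue, radial the mean of the other two, MD the
trace/3, and
$FA = \sqrt{3/2 \cdot \sum_i(\lambda_i - \bar\lambda)^2 / \sum_i \lambda_i^2}$.
Negative eigenvalues are not clipped; such voxels are flagged invalid
and excluded from ROI means, preserving their diagnostic value.
On mixed voxels the single-tensor axial diffusivity falls below the
generating fiber's $\lambda_\parallel$ — the "exaggerated decrease"
confound that motivates the multi-compartment model, and a directional
property asserted in the tests. Note that MD computed as trace/3 of
the fitted tensor is on the order of 0.7 µm²/ms for healthy-nerve
compositions; published MD values for this tissue are sometimes
reported under other conventions, so MD is carried as a diagnostic
here rather than a comparison target.

## Acquisition schemes

`make_scheme()` reproduces the two protocol geometries: 25
measurements in vivo (1 reference + 24 weighted, max b = 2,200 s/mm²)
and 99 ex vivo (1 + 98, max b = 3,000 s/mm²). The direction tables of
the original protocols are not published, so weighted directions are
laid out by electrostatic repulsion of antipodal charge pairs on the
sphere (deterministic given a seed; minimum inter-axis angles ≈ 29°
for 24 axes and ≈ 14° for 98). Because the spectrum inversion needs
attenuation sampled at several diffusion weightings, b-values cycle
through four levels (25/50/75/100% of the maximum) across directions.
An experiment assigning a distinct b-value to every direction gave no
better spectrum identifiability, so the simpler four-level design was
kept. Entries with b < 10 s/mm² are treated as b = 0 references to
tolerate real-world `bval` files.

## What the phantom generator emulates

`simulate_cohort()` generates longitudinal sham/TBI cohorts with the
group compositions of the study it emulates: per group and timepoint,
fiber/restricted/non-restricted fractions, fiber diffusivities and
nerve volumes are taken from the published group means
(`study_group_means()`). Printed fraction triplets do not sum to 1
(e.g. day-30 sham: 0.81 + 0.05 + 0.06 = 0.92); the generator
renormalizes them to a unit simplex and records the scaling factor,
since the model's fractions partition the signal by construction. The
generative isotropic spectrum uses two delta components (defaults 0.3
and 1.8 µm²/ms) rather than a continuous spectrum: only binned
fractions are reported for the real tissue, and deltas make recovery
unambiguous.

Animal-to-animal biological variability is modeled by perturbing each
preset parameter once per animal with a coefficient of variation
derived from the published fiber-fraction SDs, attributing half of the
printed variance to the animal level; both eyes (and all timepoints)
of one animal share that draw, which induces the within-mouse
correlation the statistics must cope with. The other half of the
printed variance is left to arise from measurement noise itself —
Rician corruption of each voxel signal,
$\sqrt{(S+\varepsilon_1)^2+\varepsilon_2^2}$ with
$\varepsilon \sim N(0, S_0/\mathrm{SNR})$ — rather than injected as a
second parameter draw. In practice the imaging-noise contribution
after ROI averaging is smaller than the printed measurement half,
because real measurement variance also contains ROI placement and
biological eye asymmetry that are deliberately not modeled. Nerve
cross-sections are single-slice discs whose voxel count matches the
drawn nerve volume at the configured voxel size (the reconstructed
0.0586 × 0.0586 × 1 mm grid by default; 0.14 mm³ → 41 voxels); the
metric ROI is the central third of the disc, the whole-nerve ROI the
full disc, mirroring the two-ROI protocol (small central ROI for map
means, full ROI for nerve and axon volume).

What passing tests on these phantoms do **not** show: robustness to
partial-volume contamination at the nerve boundary, motion or eddy
artifacts, field inhomogeneity, or mis-drawn ROIs — none of which are
generated. Conclusions about real acquisitions rest on the model
structure, not on these tests.

## Problem sizes and statistics

The cohort analyses in `analysis/` and the acceptance checks use
0.1–0.25 mm in-plane voxels instead of the reconstructed 0.0586 mm
grid, giving 2–14 voxels per nerve. This keeps whole-cohort refits in
the tens of seconds while preserving multi-voxel ROI averaging; the
per-voxel model is scale-free, so voxel size only trades ROI-mean
noise against compute.

Group inference uses a fixed-effects two-way ANOVA (group × day, Type
II sums of squares) on per-eye records plus per-day Welch tests. The
mixed model with eyes nested in animals is deliberately out of scope;
because the phantom *does* induce within-animal correlation, the
fixed-effects simplification is visible in the statistics (slightly
anti-conservative group tests), and output headers record it. One
consequence is worth stating plainly: with five animals per group and
half the printed variance at the animal level, the day-30 axial
diffusivity contrast (1.84 vs 1.61 µm²/ms) has a true group-mean
difference of about 2.1 standard errors, so a per-seed Welch test at
α = 0.05 detects it in roughly 45–75% of seeded replications, not
near-certainly. The restricted-fraction contrast (a four-fold change)
is detected essentially always, as is the DTI-exaggeration ordering.

Percent changes are reported with an explicit denominator argument
(`"reference"`, `"comparison"`, `"larger"`) because the published
narrative alternates between normalizing by the sham and by the TBI
mean; the package makes the choice explicit and takes no position on
intent. Report-style integers round halves away from zero
(`report_percent()`), matching how 12.5% appears as 13%.

## Numerical edge cases

* All-zero signals, empty ROIs, empty masks and undersized nerve
  volumes raise immediate, descriptive errors.
* Signals are floored at $10^{-6} \times \max S$ before logs in the
  DTI fit; voxels with non-positive raw signals are flagged rather
  than silently repaired.
* Rank-deficient gradient designs (fewer than 6 independent tensor
  components) are rejected by name.
* All randomness flows through explicit integer seeds;
  reruns with the same configuration are byte-identical, which the
  tests assert on the pipeline's CSV outputs.

## Known limitations

* Single fiber per voxel; crossing fibers are out of scope.
* Orientation refinement is local (a small tilt around the tensor
  axis); it corrects contamination bias but would not rescue a
  grossly wrong initializer, which cannot occur for coherent-tract
  voxels with the default gate.
* The Rician-bias correction is documented, not removed; at SNR well
  below 20 the Gaussian objective becomes inappropriate.
* The fixed-effects ANOVA understates group-level uncertainty when
  within-animal correlation is strong, as noted above.
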