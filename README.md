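# dbsir — diffusion basis spectrum imaging of optic-nerve white matter

Traumatic optic neuropathy (TON) after closed-head injury is often
clinically silent: visual-acuity testing misses it, and conventional
diffusion tensor imaging (DTI) lacks specificity because inflammation,
edema and axonal loss all push its scalar metrics in overlapping
directions. Diffusion basis spectrum imaging (DBSI) addresses this by
decomposing the diffusion-weighted signal of each voxel into an
anisotropic fiber tensor plus a spectrum of isotropic components:

```
S_k = S0 [ f · exp(−b_k λ⊥) · exp(−b_k (λ∥ − λ⊥) cos²Φ_k)  +  Σ_i w_i · exp(−b_k D_i) ]
```

with fiber signal fraction `f` (apparent axonal density), axial/radial
diffusivities `λ∥`, `λ⊥` (axon and myelin integrity), and non-negative
spectrum weights `w_i` over isotropic diffusivities `D_i`, summarized
as a **restricted** fraction (ADC ≤ 0.6 µm²/ms, a cellularity /
inflammation marker) and a **non-restricted** fraction (0.6 < ADC ≤ 3
µm²/ms in vivo, ≤ 2 ex vivo; edema / CSF). Nerve volume × fiber
fraction gives the **axon volume**, an axonal-content marker robust to
nerve swelling.

This package is for imaging scientists who want a tested, reproducible
implementation of that analysis: the exact forward model, per-voxel
inversion (regularizable non-negative least squares nested in a
bounded search over fiber diffusivities, with compiled Lawson–Hanson
NNLS), a DTI comparison fit, a synthetic phantom generator for
longitudinal sham/TBI optic-nerve cohorts with Rician noise, and the
derived study statistics (ROI means, nerve/axon volume, percent
changes, Pearson correlations, two-way ANOVA). NIfTI-1 volumes and
FSL-style `bval`/`bvec` gradient tables are read and written natively.

## Worked example

Simulate one optic-nerve voxel with the day-30 sham and injured-group
tissue compositions, then invert it with both models:

```r
library(dbsir)
sch <- make_scheme("invivo")             # 25 directions, max b = 2,200 s/mm²
for (grp in c("sham", "TBI")) {
  preset <- study_preset("invivo", 30, grp)
  signal <- simulate_voxel(preset, sch, snr = Inf)   # noise-free
  print(fit_dbsi(signal, sch))
  print(fit_dti(signal, sch))
}
```

```
<dbsi_result> fiber 0.880 (AD 1.84 RD 0.14), restricted 0.054, non-restricted 0.065
<dti_result> AD 1.707 RD 0.182 FA 0.884 MD 0.690
<dbsi_result> fiber 0.685 (AD 1.61 RD 0.23), restricted 0.202, non-restricted 0.113
<dti_result> AD 1.225 RD 0.303 FA 0.711 MD 0.610
```

The spectrum inversion recovers the generating compositions exactly
(sham fiber 0.88 at λ∥ 1.84; TBI fiber 0.69 with restricted fraction
0.20 at λ∥ 1.61). The single-tensor fit reports the injured nerve's
axial diffusivity as 1.23 instead of 1.61 µm²/ms — the added
restricted (cellular) signal exaggerates the apparent axonal injury,
which is precisely the confound the multi-compartment model removes.

Derived study quantities follow the same conventions as the narrative
results they emulate:

```r
report_percent(percent_change(0.05, 0.18))   # restricted fraction, day 30
#> 260                                        # +260% vs sham
axon_volume(0.14, 0.81)                      # nerve volume × fiber fraction
#> 0.1134                                    # mm³
```

## Analysis workflow

The `analysis/` scripts run the full study pipeline at desk scale and
write tables under `results/` (image volumes go to `scratch/`):

```sh
Rscript analysis/01_simulate_cohort.R   # longitudinal sham/TBI cohort, SNR 30
Rscript analysis/02_fit_cohort.R        # per-voxel DBSI + DTI fits, ROI tables
Rscript analysis/03_percent_changes.R   # percent-change tables from group means
Rscript analysis/04_group_stats.R       # two-way ANOVA, Welch tests, correlations
```

`run_pipeline()` performs the same simulate → fit → summarize → test
sequence from a single YAML/JSON or list configuration, with every
output stamped by seed and config hash and byte-identical across
reruns.

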