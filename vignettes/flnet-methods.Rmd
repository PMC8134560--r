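---
title: "Task-conditioned functional language networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-conditioned functional language networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flnet)
```

## What the package computes

`flnet` implements a pipeline for analysing block-design task fMRI as a
network at two spatial scales, and for comparing the resulting
architectures between groups of subjects:

1. **Activation mapping.** Each voxel's BOLD series is correlated with
   the expected hemodynamic response (a task boxcar convolved with a
   Gaussian kernel). Voxels pass at a two-sided `p < 0.001` (via the
   `t = r\sqrt{T-2}/\sqrt{1-r^2}` transform), voxels whose temporal SD
   exceeds 8% of their temporal mean are excluded as venous/motion
   artifacts, and the surviving suprathreshold voxels are grouped into
   connected clusters that must exceed a null-calibrated extent
   threshold controlling the family-wise error at 0.05.
2. **Voxel-scale network.** Active voxels are nodes; a binary link joins
   two voxels when the magnitude of the Pearson correlation of their
   series reaches a threshold $\theta$ (default 0.6). Voxels are
   partitioned into fROIs: connected components of active voxels within
   one anatomical label; activation inside excluded labels (visual
   cortex activated by the visual delivery of the task) is discarded.
3. **fROI-scale network.** The link weight between fROIs $i$ and $j$ is
   the number of binarized voxel links crossing between them, normalized
   by the sum of the fROI sizes: $W_{ij} = \sum_{l,m} w_{lm} / (S_i+S_j)$,
   bounded by $S_iS_j/(S_i+S_j)$ with equality iff the cross-connectivity
   is complete bipartite.
4. **Common network.** Per group, links present in at least
   $\lceil\tau N\rceil$ of the $N$ subjects (default $\tau = 1$) are
   retained with weight $W^C_{ij}$ = the mean of $W_{ij}$ over the
   subjects where the link is present, plus its appearance count $f_i$.
   The triangle structure (all three links among pre-SMA, BA(L),
   v-preMA(L)) and the V structure (WA(L)--BA(L) and WA(L)--v-preMA(L))
   are flagged per subject and counted per group, and the five named
   links A = BA--v-preMA, B = pre-SMA--v-preMA, C = pre-SMA--BA,
   D = BA--WA, E = v-preMA--WA are ranked by $W^C$ (ties flagged,
   never silently broken).
5. **k-shell occupancy.** Each subject's voxel network is peeled by the
   standard k-shell decomposition (a node in shell $k$ is in the
   $k$-core but not the $(k{+}1)$-core); shell indices are normalized by
   the subject's $k_{\max}$, nodes are pooled per group regardless of
   subject, split by module (anatomical region), and binned into 15
   normalized-shell bins. Module histograms are compared between groups
   by the sum of squared per-bin differences (SSE).

## The synthetic data model

Real scans are not redistributable at desk scale, so every stage is
exercised against a generative model with known ground truth
(`synthetic_config()`, `simulate_subject()`, `simulate_group()`). A
voxel in region $r$ follows

$$x(t) = \text{baseline} + \beta_r\, s(t) + a_r\, z_r(t) +
  \sum_{n} c_{rn}\, g_{rn}(t) + \varepsilon(t),$$

with $s$ the HRF-convolved boxcar, $z_r$ a latent series shared by the
region, $g_{rn}$ a latent shared by the coupled region pair,
$\varepsilon$ white noise, and background voxels carrying baseline plus
noise only. Two implementation details matter:

* **In-sample orthonormal latents.** The latents are defined as
  unit-variance and mutually independent; we realize those properties
  exactly per draw (Gram–Schmidt against the intercept, the regressor
  and each other, then unit sample variance). Without this, the realized
  second moments of 160-frame latents drift by $O(1/\sqrt{T})$, which is
  the same order as the planted gaps between adjacent couplings: whole
  correlation blocks would wander coherently and no admissible coupling
  ladder would be recoverable. With it, the planted block correlation is
  exact and only per-pair sampling noise remains.
* **One gain factor per subject.** Inter-subject variability is a single
  lognormal factor (SD 0.1 on the log scale) multiplying all betas and
  couplings of that subject. A shared gain changes amplitudes, and only
  marginally the correlations (through the fixed noise floor), so it
  emulates BOLD amplitude variability without scrambling the planted
  link ordering — which independent per-coupling jitter at this series
  length would do.

### The study-conditions cohort

`language_cohort_config()` freezes the emulated study: a
$24\times24\times12$ grid of 4 mm voxels; 8 epochs of 20 s task + 30 s
rest at TR 2.5 s (160 frames); regions pre-SMA (36 voxels), BA(L) (36),
v-preMA(L) (36), WA(L) (20), two peripheral regions (18 each) and an
excluded "Visual" region (32); `baseline = 100`, `noise_sd = 1`,
`beta = 4.03` (a ~4% signal change, so the temporal SD stays well
under the 8% exclusion rule); couplings
$c_A > c_B > c_C \gg c_D > c_E$ = (1.053, 0.975, 0.891, 0.775, 0.714).
V-structure prevalence is planted by *region dropout* (WA not activated
in 2/8 monolingual and 4/8 bilingual-English subjects, 0/8
bilingual-Spanish), matching how variable WA activation manifests in
practice; peripheral regions drop out in 2–3 subjects per group.

The amplitudes were derived from the model's closed form, on the
post-smoothing scale (4 mm FWHM smoothing reduces effective voxel noise
variance to roughly 0.63 of nominal). Three hard constraints shape them:

* **Variance budget.** With additive independent channels, a region's
  correlation shares sum to at most one. BA and v-preMA each carry three
  couplings plus the task share, so the triangle cannot be arbitrarily
  strong; the task share $v \approx 0.48$ of total variance is what
  makes the dense triangle affordable. A consequence worth knowing:
  intra-region pairs share *every* channel, so intra-region correlation
  is automatically $1 - \text{noise share} \approx 0.9$ and every
  planted region is near-clique at $\theta = 0.6$.
* **Weight ceilings.** $W_{ij} \le S_iS_j/(S_i+S_j)$, so region sizes
  must be chosen jointly with couplings: sizes are set so the ceiling is
  maximal for link A and tied within {B, C} and within {D, E}; even at
  edge saturation the planted order can then not invert.
* **Core geometry.** The maximum k-core should be the full triangle, not
  the denser BA--v-preMA pair alone; pre-SMA at 36 voxels contributes
  enough clique degree to sit robustly in the maximum core, while WA's
  weak attachment leaves it at normalized shells around 0.3–0.4.

### Experiment-specific configurations

* `hierarchy_ladder_config(ratio = 1.5)`: a geometric coupling ladder
  with the adjacent ratio fixed at 1.5. A $1.5^4 \approx 5\times$ span
  in coupling SD (a $25\times$ span in variance) cannot sit inside the
  narrow band of correlations that is expressible around
  $\theta = 0.6$ under the variance budget, so recovery experiments with
  this configuration run at $\theta = 0.5$ — consistent with treating
  every threshold-sensitive result as $\theta$-conditional, since the
  correlation threshold of the motivating analyses is not published.
* `wa_contrast_config("strong" | "zero")`: matched configurations for
  the group-difference experiment, differing only in the WA couplings
  (set to the budget maximum, or to zero). Here the task share is raised
  ($\beta \approx 4.25$) so the triangle links saturate: all three core
  modules then occupy the maximum shell in both arms and the SSE between
  matched groups is carried by WA (normalized shell $\approx 0.8$ when
  attached vs $\approx 0.2$ when not). Two details make the manipulation
  clean. First, the arms are simulated with the same group seed — a
  paired design in which "differing only in WA coupling" holds
  realization by realization, not just in distribution. Second, the zero
  arm reallocates each removed coupling share to the private latent of
  the region that carried it, keeping every region's total variance
  matched: simply deleting coupling variance would *raise* the affected
  regions' task-floor correlations (a direct consequence of the
  task-conditioned design) and WA would re-attach through the task.

## Numerical and procedural choices

* **Cluster-extent null.** The null distribution of the maximum cluster
  size is estimated from surrogate statistic maps in which the regressor
  is circularly time-shifted by one shared random offset per surrogate
  against the per-voxel *task-residual* series (the regressor projected
  out). Surrogates computed on the raw series would be re-aligned with
  the task by shifts near multiples of the 50 s epoch — a periodic
  design makes plain circular-shift surrogates unusable — while the
  residual scheme preserves the spatial and temporal autocorrelation of
  the noise, which is what cluster-extent correction is defined
  against. On task-free data the two schemes coincide, and the measured
  any-surviving-cluster rate on 200 null replicates stays within
  [0.02, 0.09] at a nominal 0.05.
* **HRF.** The Gaussian response kernel peaks 5 s after onset with SD
  2.5 s (conventional values; the motivating analyses do not publish
  theirs) and is normalized to unit discrete integral. Both are exposed
  in `analysis_config()`.
* **Detrending** removes a per-voxel linear fit (default on); no further
  frequency filtering is applied.
* **SD filter degenerate input:** voxels with non-positive temporal mean
  have no defined SD/mean ratio; they are excluded and counted.
* **Connectivity** for clustering defaults to the 6-neighborhood
  (faces), the most conservative choice; 18 and 26 are available.
* **Unlabeled activation.** Active voxels on the background anatomical
  label (e.g. smoothing bleed around planted regions) are kept in a
  flagged "unlabeled" fROI rather than silently dropped; excluded-region
  activation is dropped by design.
* **Eq.-3 ambiguity.** The common weight is the mean over the subjects
  where the link is present. At the default $\tau = 1$ (links present
  across all subjects) this equals the mean over all subjects; at
  $\tau < 1$ (the "majority of subjects" reading) it keeps $W^C$ inside
  the range of the contributing weights. Reports always carry $f_i$ so
  the choice is transparent.
* **Histogram normalization.** Occupancy histograms are normalized to
  fractions per (module, group) before SSE; group pools differ in node
  count, so raw counts would make SSE scale-dependent. Raw counts are
  retained in every histogram object and table. Bin edges are half-open
  with the last bin closed; shell-0 (isolated) nodes fall into bin 1 and
  are counted separately. An empty (module, group) pool yields a missing
  histogram, not a zero vector.
* **Ties and missing links** in the hierarchy are flagged, never
  silently ordered.
* **Determinism.** All randomness flows from recorded seeds (subject
  seeds derived from group seeds, surrogate streams from the analysis
  seed); `run_pipeline()` writes a manifest from which
  `rerun_from_manifest()` reproduces every table byte-identically.
  Voxel coordinates in outputs are 0-based grid indices.

## Problem sizes used by the tests

The test-suite experiments run at the cohort's own scale — groups of 8
subjects on the $24\times24\times12$ grid with 160 frames — with 150–500
surrogate maps per activation null, 20 seeded repetitions for the
stochastic recovery claims (hierarchy order, core/periphery occupancy,
paired WA SSE), 200 replicates for family-wise-error calibration, and
$10^4$ voxels for voxel-level calibration. Oracle checks (k-shell
against exhaustive k-core membership; Eq.-2 weights against a
double loop over cross pairs) use 50–100 random graphs of up to 200
nodes.

## What passing tests do and do not show

The generator reproduces the features the analyses consume — planted
contiguous activation with known amplitudes, a controllable inter-region
correlation hierarchy, group-wise structure prevalence, core/periphery
shell geometry — under Gaussian white noise and a single shared gain per
subject. It deliberately omits physiological noise spectra, motion,
spatial inhomogeneity of noise, non-cuboid region shapes and
inter-subject anatomical variability. Passing the recovery experiments
therefore shows the *machinery* is correct and calibrated, not that real
BOLD data would yield the same architectures; on real data the unknown
correlation threshold $\theta$ remains a free analysis choice, and all
threshold-sensitive conclusions should be reported $\theta$-conditional.

## Known limitations

* The cluster-extent null assumes approximate exchangeability of the
  observed and time-shifted residual maps; strong unmodelled temporal
  nonstationarity would violate it.
* `W^C` averages over present subjects only; with $\tau < 1$ and very
  sparse links the mean is computed over few subjects and is noisy.
* The k-shell analysis is binary by construction (the voxel network is
  thresholded); no weighted-core variant is provided.
* Region latents make intra-region correlation uniformly high; real
  fROIs show internal gradients the model does not attempt.
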