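# flnet — task-conditioned functional language networks

`flnet` builds and compares functional brain networks from block-design
task fMRI. It is aimed at analyses of the *functional language network*
(FLN): the set of regions a subject activates during a language task
(phonemic fluency and similar pre-operative clinical paradigms), studied
as a graph at the voxel scale and at the scale of functional regions of
interest (fROIs), with group-level consensus networks and k-core/k-shell
resilience structure.

## The model and statistics at its core

Starting from a 4D BOLD series and a task paradigm:

- **Activation mapping.** Voxel series are cross-correlated with a
  Gaussian-HRF–convolved task boxcar; activation maps are thresholded at
  `p < 0.001` (two-sided, `t = r√(T−2)/√(1−r²)`), voxels whose temporal
  SD exceeds 8% of their temporal mean are excluded, and clusters of
  contiguous suprathreshold voxels must exceed a surrogate-calibrated
  extent threshold controlling the family-wise error rate at 0.05.
- **Voxel network.** Active voxels are linked when `|C_ij| ≥ θ`, where
  `C_ij` is the Pearson correlation of the two BOLD series (default
  `θ = 0.6`; binary links).
- **fROI network.** `W_ij = Σ_{l,m} w_lm / (S_i + S_j)`: the number of
  voxel links crossing between fROIs *i* and *j*, normalized by the sum
  of the fROI sizes.
- **Common network.** Per group of N subjects, links present in
  `≥ ⌈τN⌉` subjects (default τ = 1) are kept with weight
  `W^C = mean(W_ij)` over the subjects carrying the link and frequency
  `f_i`; the triangle (pre-SMA–BA(L)–v-preMA(L)) and V
  (WA(L)–BA(L) + WA(L)–v-preMA(L)) structures are counted, and the five
  named links A–E are ranked by `W^C`.
- **k-shell occupancy.** Each subject's voxel network is decomposed into
  k-shells (iterative pruning); shell indices are normalized by the
  subject's `k_max`, pooled per group, binned into 15 normalized-shell
  bins per module, and module histograms are compared between groups by
  the sum of squared errors (SSE).

A seeded synthetic-data generator (`synthetic_config()`,
`simulate_group()`, and the frozen study configuration
`language_cohort_config()`) produces multi-subject block-design BOLD
volumes with planted active regions, a controllable inter-region
coupling hierarchy and group-wise structure prevalence, so the whole
pipeline is testable end to end with known ground truth. The methods
vignette (`vignettes/flnet-methods.Rmd`) documents the generative model
and every numerical choice.

## Worked example

Simulate one group of eight subjects under the study conditions and run
the full per-subject analysis:

```r
library(flnet)

cohort <- language_cohort_config()
acfg   <- analysis_config(n_null = 200, seed = 1)

grp <- simulate_group(cohort$config, n_subjects = 8, group_seed = 11,
                      group_id = "spanish")
nets <- list(); shells <- list()
for (k in seq_along(grp$subjects)) {
  s <- grp$subjects[[k]]
  set.seed(100 + k)
  res <- subject_network(s$scan, s$labels, acfg)
  nets[[k]]   <- res$region_net
  shells[[k]] <- kshell_decomposition(res$voxel_net)
}

cn <- build_common_network(nets, tau = 1, group = "spanish")
rank_links(cn)
detect_structures(nets, group = "spanish")
```

```
  link   region_i   region_j  W_common f present   tie
1    A      BA(L) v-preMA(L) 17.430556 8    TRUE FALSE
2    B    pre-SMA v-preMA(L) 16.036458 8    TRUE FALSE
3    C    pre-SMA      BA(L) 12.548611 8    TRUE FALSE
4    D      BA(L)      WA(L)  3.808036 8    TRUE FALSE
5    E v-preMA(L)      WA(L)  1.944196 8    TRUE FALSE
<structure_report 'spanish'> triangle 8/8 (100%), V 8/8 (100%)
```

The recovered link hierarchy is the planted order A > B > C > D > E:
all eight subjects carry the fully connected triangle, and in this group
(no planted WA dropout) the V structure appears in 8/8 subjects. The
`W_common` column is the mean size-normalized cross-link weight `W^C`;
`f` counts the subjects carrying the link.

```r
h <- occupancy_histogram(shells, group = "spanish",
                         modules = c("pre-SMA", "BA(L)", "v-preMA(L)", "WA(L)"))
vapply(h$modules, function(m) m$mass[15], numeric(1))   # last-bin occupancy
```

```
   pre-SMA      BA(L) v-preMA(L)      WA(L)
      0.84       0.96       1.00       0.00
```

The three triangle modules concentrate at the maximum shell (`k_max`
core) while Wernicke's area occupies the low and middle shells — the
core/periphery signature the k-shell analysis is designed to expose.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` (three groups of eight scans with planted
WA dropout 6/8, 4/8, 8/8), `02_activation.R`, `03_networks.R`,
`04_common.R` (structure-frequency table and link hierarchy per group),
`05_kshell.R` (occupancy histograms and between-group SSE), and
`06_wa_contrast.R` (the paired strong-vs-zero WA attachment experiment,
where SSE at WA dominates the core modules by orders of magnitude).
Tables land under `results/`, large regenerable intermediates under
`scratch/`.

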