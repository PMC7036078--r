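# pacesim

Simulation and analysis of ventricular activation under right-ventricular
(RV) pacing and left bundle branch block (LBBB).

## The problem

In cardiac resynchronization therapy (CRT) the RV lead is implanted either
at the RV apex (RVAP) or on the mid septum (RVSP). The two stimulation
sites produce different ventricular activation sequences, which matters
because the LV lead is often targeted at the latest-activated LV region:
if RV pacing moves that region, it moves the target. `pacesim` models this
question at desk scale for researchers in cardiac electrophysiology: it
builds an idealized biventricular surface geometry, simulates activation
for intrinsic LBBB and four RV pacing scenarios with a graph-eikonal
conduction model, computes the activation metrics used in
electrocardiographic-imaging (ECGi) studies, and reproduces the paired
cohort statistics such studies report, on synthetic data.

## The model and metrics

Activation spreads on the mesh edge graph; the arrival time at vertex *v*
is the exact multi-source shortest-path solution

t(v) = min over sources s of [ onset(s) + geodesic time from s to v ],

where an edge of length ℓ joining vertices with local conduction
velocities v₁, v₂ costs ℓ / harm(v₁, v₂) (harmonic mean), the RV
endocardial layer is optionally accelerated by a Purkinje-like factor, and
scar regions multiply local velocity by a factor in [0, 1). Each
activation map is summarized by the standard ECGi metrics:

| metric | definition |
|---|---|
| VVtat | max − min activation time, both ventricles (ms) |
| LVtat | max − min activation time, LV incl. septum (ms) |
| VVsync | abs(mean LV time − mean RV time), "ventricular electrical uncoupling" (ms) |
| LVdisp | population SD of LV epicardial times (ms) |
| WFA | orientation of a chosen 30-band isochrone in the LAO-cranial view (deg) |
| terminal segments | AHA 16-segment ids containing the final isochrone band |

Paced maps are compared with LBBB by the Pearson correlation of
VVtat-normalized activation times, the shift of the latest-activated LV
free-wall region, and the WFA rotation. A synthetic paired-cohort
generator (bivariate-normal per-patient draws from published subgroup
summaries, or full simulator runs with noise and scar) feeds a statistical
pipeline with a Kolmogorov-Smirnov normality gate and t / Mann-Whitney U
comparisons. See `vignette("paced-activation-modelling")` for the methods.

## Worked example

```r
library(pacesim)
res <- run_fig5_experiment(run_config())
res$metrics[["LBBB"]]
#> metric_set [LBBB]: VVtat 142.7  VVsync 41.8  LVtat 140.5  LVdisp 30.9 ms; WFA 109.7 deg; final segments {5}
res$comparisons
#>         scenario pearson_r latest_region_shift_mm wfa_delta_deg
#> 1  RVAP_ANTERIOR     0.774                  19.08         -40.6
#> 2       RVAP_MID     0.712                   7.10         -19.7
#> 3 RVAP_POSTERIOR     0.546                  29.31           1.2
#> 4           RVSP     0.787                   5.93          70.3
res$best_match
#> [1] "RVSP"
```

Intrinsic LBBB on the default geometry takes 142.7 ms to activate both
ventricles and terminates in the basal inferolateral AHA segment (5).
Among the paced scenarios, mid-septal pacing correlates best with the LBBB
sequence (r = 0.79 vs 0.55–0.77 for the three apical sites) and moves the
latest-activated LV free-wall region least (5.9 mm vs 7.1–29.3 mm) — septal
pacing is the closer LBBB surrogate, apical pacing redirects activation.

The cohort arm draws a paired 14-patient cohort (9 apical, 5 septal) from
the published subgroup summaries and reports intrinsic vs paced per metric:

```r
run_cohort_experiment(run_config(seed = 11))$report
#>    metric  group  n intrinsic_mean ... paced_mean ...          test p_value
#> 1  vvsync    all 14           40.4           33.9    independent t  0.3831
#> 4  lvdisp    all 14           30.4           34.0    independent t  0.1790
#> 5     wfa    all 14           78.7           51.9    independent t  0.0326
#> ...
```

The numbered scripts under `analysis/` run the two arms end to end
(`01_insilico_scenarios.R`, `02_cohort_report.R`,
`03_replication_and_calibration.R`) and write their tables under
`results/`.

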