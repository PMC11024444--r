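# tlbkit

Analysis toolkit for **thermal liquid biopsy (TLB)**: differential scanning
calorimetry (DSC) thermograms of blood plasma, used to characterize and
differentiate myocardial-injury phenotypes — chronic coronary atherosclerotic
disease (cCAD), acute thrombotic myocardial infarction (TMI) and acute
non-thrombotic myocardial injury (nTMi) — across a longitudinal time course
(baseline T0 through a quiescent follow-up Tfu).

A plasma thermogram is the excess specific heat capacity
C<sub>p</sub><sup>ex</sup>(T) (cal/°C·g) of a dilute plasma sample as it is
scanned in temperature, finalized here on the standard 45–90 °C grid at
0.1 °C resolution. Plasma thermograms show three canonical transitions: a
major transition at 60–66 °C (*Peak 1*), a smaller one at 67–73 °C
(*Peak 2*) and a shoulder at 73–81 °C (*Peak 3*). Acute myocardial injury
depresses Peak 1 and elevates the higher-temperature region; recovery
restores the dominant-Peak-1 quiescent signature.

The package provides:

* **Preprocessing** — buffer-reference subtraction, protein-concentration
  normalization (signal / (scan rate × concentration × cell volume)),
  linear sample-baseline correction anchored on the flat 45–50 and
  85–90 °C flanks, regridding, replicate averaging
  (`read_scan()`, `preprocess_scan()`, …).
* **A 19-metric panel** per thermogram (`compute_panel()`): the three peak
  amplitudes and temperatures; amplitude ratios Peak 1/Peak 2, Peak 1/Peak 3,
  Peak 2/Peak 3; the valley V1.2 between Peaks 1 and 2, its temperature and
  its three peak ratios; the global maximum and its temperature; the
  first-moment temperature T<sub>FM</sub> = Σ T·C<sub>p</sub>(T) / Σ C<sub>p</sub>(T);
  width at half height; and total area.
* **Non-parametric statistics** — per-metric Kruskal–Wallis tests across
  phenotype groups with Holm (or Bonferroni/BH) family adjustment,
  pairwise Wilcoxon tests (exact for small samples), within-patient
  ΔTfu − T0 change panels, pointwise median profiles with 95% quantile
  bands, and mean difference profiles.
* **Unsupervised clustering** — k-means on the full 451-point curves
  (k-means++ initialization, best of many restarts), within-SS/silhouette
  k-selection, and phenotype-purity tables.
* **A seeded synthetic-cohort generator** (`simulate_cohort()`) emulating
  the phenotype signatures and their recovery dynamics — including a TMI
  subtype with a dominant 80 °C peak — so the whole pipeline is testable
  end to end without restricted patient data.

## Worked example

```r
library(tlbkit)

co <- simulate_cohort(n_per_group = c(cCAD = 10, TMI = 16, nTMi = 6),
                      timepoints = c("T0", "Tfu"), seed = 42)
panels <- compute_panels(co)

kw <- kruskal_wallis_panel(panels[panels$timepoint == "T0", ], "phenotype")
head(dplyr::arrange(dplyr::select(kw, -group_summary), p_adjusted), 5)
#>   metric  p_unadjusted p_adjusted
#> 1 peak1     0.00000226  0.0000429
#> 2 r_p1p2    0.00000226  0.0000429
#> 3 r_p1p3    0.00000226  0.0000429
#> 4 r_p2p3    0.00000226  0.0000429
#> 5 r_v12p1   0.00000226  0.0000429
```

At baseline the simulated acute groups differ sharply from the stable cCAD
group in Peak 1 and every ratio involving it — the Holm-adjusted p-values
stay far below 0.05, mirroring the loss of the major transition during an
acute event.

```r
fit <- kmeans_profiles(co, k = 3, seed = 42, timepoint = "T0")
fit
#> Thermogram k-means: k = 3
#>   sizes: 20, 10, 2
#>   within-SS: 3.8318  mean silhouette: 0.550
purity_table(fit, setNames(co$phenotype, co$sample_id))
#>   phenotype cluster  n pct
#> 1 TMI             1 14  70
#> 2 cCAD            1  0   0
#> 3 nTMi            1  6  30
#> 4 TMI             2  0   0
#> 5 cCAD            2 10 100
#> 6 nTMi            2  0   0
#> 7 TMI             3  2 100
#> 8 cCAD            3  0   0
#> 9 nTMi            3  0   0
```

Clustering the raw baseline curves separates the acute samples (cluster 1)
from the stable cCAD samples (cluster 2) and isolates the two 80 °C-subtype
TMI patients in their own small pure cluster (cluster 3) — `2 = round(7/60 × 16)`
patients carry the subtype at this cohort size.

`run_pipeline(config, out_dir)` chains the full analysis (simulation or
file input → censoring → metric panels → the T0 / Tfu / Δ statistical
families → baseline clustering → profile summaries) and writes every stage
as plain CSV/JSON, deterministically for a fixed seed.

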