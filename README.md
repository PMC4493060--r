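# netreconfig

Graph-theoretic analysis of how functional brain networks reconfigure
under increasing task demand, for researchers working with ROI-level
fMRI time series (or any multivariate time series with a node table).

The pipeline mirrors a common within-subject task-fMRI design: each of
*s* subjects is scanned under *c* ordered conditions; per scan, the
N x N Pearson correlation matrix of the ROI time courses is thresholded
edgewise at the Bonferroni-corrected level `alpha / (N(N-1)/2)` into a
binary (or |r|-weighted) network, and the network is summarised by

- **K** — average degree (connection density / wiring cost),
- **Cp, Eloc** — clustering coefficient and local efficiency (segregation),
- **Lp, Eglob** — characteristic path length and global efficiency
  (integration),
- **sigma** — small-worldness `(Cp/Cp_rand)/(Lp/Lp_rand)` against
  degree-preserving Maslov–Sneppen rewired null networks,
- **Dp** — mean Euclidean length of existing edges in mm (wiring cost),
- **Q** — Newman modularity of the best Louvain-found partition,
- **R** — robustness to targeted attack: nodes removed in decreasing
  order of nodal efficiency Enod, `R = (1/N) * sum of the largest-
  component sizes` along the removal sequence,
- **Enod** — per-node efficiency, analysed nodewise.

Group inference is a one-way repeated-measures ANOVA per metric
(F(c-1, (c-1)(s-1)), no sphericity correction), Bonferroni-corrected
post-hoc paired t-tests, and Benjamini–Hochberg FDR across nodes for the
nodal analysis. A factor-model simulator generates complete synthetic
cohorts with condition-graded modular coupling, so the entire pipeline
is testable without access to recordings. See the methods vignette
(`vignettes/network-reconfiguration-methods.Rmd`) for models,
conventions, and limitations.

## Worked example

Simulate a small cohort (8 subjects, 3 conditions, 60 ROIs in 4
modules), run the full pipeline, and inspect the per-metric summary:

```r
library(netreconfig)

cfg <- sim_config(n_subjects = 8, n_rois = 60, n_timepoints = 180,
                  n_modules = 4,
                  lambda_within = c(0.55, 0.65, 0.75),
                  lambda_global = c(0.15, 0.25, 0.35))
report <- run_study(cfg, study_config(n_nulls = 50, n_restarts = 20),
                    seed = 42)
report$summary[, c("metric", "mean_RS", "mean_VSW", "mean_VSD",
                   "F", "df1", "df2", "p")]
#>   metric mean_RS mean_VSW mean_VSD      F df1 df2        p
#> 1     Cp   0.532    0.930    0.971 15.837   2  14 2.54e-04
#> 2     Lp   1.616    1.909    1.953  0.914   2  14 4.23e-01
#> 3   Eloc   0.596    0.962    0.982 11.465   2  14 1.13e-03
#> 4  Eglob   0.151    0.289    0.347 21.949   2  14 4.83e-05
#> 5  sigma   7.507    4.994    4.435  5.329   2  14 1.90e-02
#> 6      K   6.746   12.975   14.363 25.066   2  14 2.36e-05
#> 7     Dp  27.370   27.534   29.227  2.232   2  14 1.44e-01
#> 8      Q   0.720    0.745    0.725  1.429   2  14 2.72e-01
#> 9      R   8.671   13.140   14.269 24.398   2  14 2.74e-05
```

Reading the table: as the planted coupling rises across the three
condition levels, the networks densify (K: 6.7 -> 14.4), become more
clustered and more efficient (Cp, Eloc, Eglob all increase with ANOVA
p < 0.002 on 2 and 14 df), stay small-world throughout (sigma well
above 1), and grow more robust to targeted attack (R: 8.7 -> 14.3).
Post-hoc paired tests localise the global-efficiency effect to the
rest-vs-task contrasts:

```r
subset(report$posthoc, metric == "Eglob",
       select = c(pair, t, p_adj, direction))
#>       pair    t   p_adj direction
#> 10  RS-VSW 5.43 0.00295        up
#> 11  RS-VSD 5.79 0.00201        up
#> 12 VSW-VSD 1.85 0.32054        up

sum(report$nodal$anova$significant)
#> [1] 60   # every node survives FDR under this strong plant
```

`run_study(..., out_dir = "results/")` additionally writes long/summary
metric TSVs, a nodal-results TSV, and a JSON report with the resolved
configuration and seed. Real data enter the same way: a node table TSV
(`roi_id label x y z module`), one series TSV per scan, optional
confound TSVs, assembled into a cohort list and passed via the `cohort`
argument.

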