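---
title: "Methods: task-demand reconfiguration of functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task-demand reconfiguration of functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

When the brain moves from rest into increasingly demanding tasks, its
functional network — the graph whose nodes are regions of interest (ROIs)
and whose edges are strong temporal correlations between regional BOLD
signals — reorganises. `netreconfig` implements a complete within-subject
pipeline for quantifying that reorganisation: per-scan network
construction, a standard set of global and nodal graph parameters,
small-worldness against degree-matched null models, targeted-attack
robustness, and repeated-measures group statistics across ordered task
conditions. Because no public recording accompanies the design it
emulates, the package ships a synthetic cohort generator that plants a
graded, condition-dependent coupling structure, so every stage of the
analysis can be exercised and tested end to end.

# Pipeline and models

## ROI preprocessing

Scans enter as T x N matrices (time points x ROIs, column order fixed by
a node table). The temporal stages, applied in a fixed, logged order, are:

1. **Discard and truncate** — drop `n_discard` leading volumes (scanner
   stabilisation; default 10) and keep `n_keep_timepoints` rows (default
   230) so all conditions contribute equal-length series.
2. **Linear detrend** — subtract each column's least-squares line.
3. **High-pass filter** (optional) — project out the discrete-cosine
   basis functions below the cutoff (default 0.01 Hz). We use DCT
   projection rather than an IIR filter because it is deterministic,
   idempotent, and free of edge effects at T around 230; it is also the
   convention of the major SPM-family toolchains.
4. **Confound regression** (optional) — OLS residualisation against an
   intercept plus supplied nuisance regressors (e.g. six motion
   parameters, white matter, CSF). The global signal is *not* a default
   confound, reflecting the unresolved debate about global-signal
   regression; callers can include it as an ordinary confound column.

Each projection stage is idempotent, which the test suite asserts
directly. Whether filtering should precede or follow nuisance regression
is not fixed by any convention we can anchor to; the order above is a
package decision and is what `preprocess_scan()` applies.

## Network construction

For each scan the full Pearson matrix is computed together with edgewise
two-sided p-values from the t-transform `t = r sqrt((T-2)/(1-r^2))` on
T-2 degrees of freedom. Edges are kept when `p < alpha / (N(N-1)/2)` —
Bonferroni over all unique ROI pairs, i.e. 0.05/12720 for N = 160. Edge
retention is sign-agnostic by default because the thresholding rule is a
pure significance gate; `positive_only = TRUE` is exposed for the common
practice of dropping negative correlations (at Bonferroni stringency
negative edges essentially never survive anyway). Ties at exact equality
are excluded (strict inequality). The weighted variant keeps the same
edge set and carries `|r|` as the weight, so that edge lengths `1/w` are
well defined in path computations; whether a weighted replication should
use `r`, `|r|`, or positive `r` is genuinely open, and `|r|` is our
declared choice.

## Graph parameters

On each binary network we compute average degree K, clustering
coefficient Cp (zero for nodes of degree < 2, averaged over **all** N
nodes so values are comparable across networks), characteristic path
length Lp, local efficiency Eloc, global efficiency Eglob, nodal
efficiency Enod, average Euclidean edge length Dp in mm (a wiring-cost
proxy alongside K), and Newman modularity Q. Conventions for
disconnected graphs matter at Bonferroni sparsity: Lp averages finite
distances only and the unreachable fraction is reported alongside, while
the efficiency family uses 1/Inf = 0. Q is maximised by Louvain-style
greedy optimisation under random node-permutation restarts (default
100), keeping the best partition; the trivial one-community partition
scores exactly 0, so the reported Q is never negative. On graphs small
enough for exhaustive partition search the restarted optimiser attains
the true maximum, which the tests verify. Weighted networks use node
strength for K, Onnela's geometric-mean triangle intensity (weights
rescaled by the maximum) for Cp, shortest paths over lengths `1/w`, and
weighted modularity; with 0/1 weights every weighted metric reduces
exactly to its binary counterpart.

## Null models and small-worldness

Small-worldness is `sigma = (Cp/Cp_rand) / (Lp/Lp_rand)`, with the
random-graph reference obtained by Maslov–Sneppen double-edge swaps: two
edges (a,b), (c,d) become (a,d), (c,b) whenever no loop or duplicate
results, preserving every node's degree exactly. Defaults are 100 nulls
and 10 swap attempts per edge; neither is dictated by the emulated
design, but at these settings the Monte-Carlo error of sigma is far
below between-condition differences. If every null in the ensemble is
triangle-free, `Cp_rand = 0` and `null_ensemble()` raises an
undefined-metric error rather than returning an arbitrary ratio — this
occurs for extremely sparse networks and is discussed under
*Limitations*. For weighted networks the binary support is rewired and
the original weight multiset randomly permuted onto the new edges,
preserving both the degree sequence and the weight distribution.

## Robustness to targeted attack

Nodes are ranked once on the intact network by decreasing Enod (ties by
ascending index) and removed cumulatively; `s_k` is the largest
connected component after k removals. Robustness is
`R = (1/N) sum_{k=0}^{N-1} s_k`, which includes the intact network as
the k = 0 term and is therefore bounded by (N+1)/2 — 80.5 for N = 160,
consistent with group means near 74–78 reported for networks of that
size. The cited literature does not write the AUC normalisation down;
this convention is declared, and the static (not recomputed) ranking
follows the usual reading of "decreasing order of Enod".

## Group statistics

Each metric is tested with a one-way repeated-measures ANOVA
(`F = MS_condition / MS_error`, df = (c-1), (c-1)(s-1); 18 subjects and
3 conditions give F(2, 34)). No sphericity correction is applied, which
matches reporting of plain F(2, 34) in this literature. Significant
metrics receive all-pairs post-hoc paired t-tests, two-tailed,
Bonferroni-corrected over the 3 pairs. Nodal Enod is tested the same way
per node, with Benjamini–Hochberg FDR across the N ANOVA p-values and
Bonferroni-corrected post-hoc tests inside surviving nodes only.
`compare_runs()` reduces a report to 36 outcome labels (9 ANOVA
significance labels + 27 signed post-hoc labels) and scores agreement
between two analysis variants as a percentage; matching "ns" labels
count as consistent, since a non-significant slot carries no direction
to contradict.

# The synthetic cohort

Each ROI signal is a unit-variance factor mixture
`x_i = a g_m(i) + b g + c eps_i` with a module factor per ROI community,
one global factor, private noise, and `c = sqrt(1 - a^2 - b^2)`; all
latent channels are stationary AR(1) with phi = 0.3 (an fMRI-like lag-1
autocorrelation). The implied correlation is `a^2 + b^2` within a module
and `b^2` between modules — positive semi-definite by construction, so no
nearest-PSD repair is ever needed. Task demand is planted by raising the
loadings with condition level (defaults: a = 0.45/0.55/0.65,
b = 0.05/0.15/0.30 for the three levels), and each subject receives one
N(0, 0.05) additive jitter on both loadings, shared across that
subject's conditions to respect the within-subject design. The default
cohort is 18 subjects x 3 conditions x 160 ROIs x 230 time points at
TR = 2 s, with 6 spatially clustered modules (centres separated by at
least twice the 12 mm within-module coordinate SD inside a +/-60 mm
cube).

What the generator does **not** emulate: hemodynamic response shapes,
task-block structure, scanner noise spectra, motion artefacts, and — most
importantly — the empirical density of real functional networks. A
passing pipeline on this plant demonstrates correct recovery of a known
covariance structure through the full analysis chain, not fidelity to
any particular empirical dataset.

## Behaviour of the default plant under the Bonferroni gate

Two structural facts about the default parameters deserve explicit
statement, because they determine which study-level patterns the plant
can and cannot reproduce. At T = 230 the Bonferroni edge gate corresponds
to a critical correlation of about 0.30. The planted within-module
correlation rises from 0.205 (rest) through 0.325 to 0.513, so
within-module edge density — and with it K, Cp, Eloc, and Eglob —
increases sharply and monotonically with level, and subjects with
negative loading jitter have very sparse lowest-level networks. The
planted between-module correlation (0.0025 to 0.09) never approaches the
critical value, so essentially no between-module edges survive at any
level and modularity stays pinned near its 6-module ceiling of about
5/6 instead of falling with demand. Consequently: (i) sparse rest
networks of low-jitter subjects can be triangle-free, where sigma is 0
or undefined, so universal small-worldness across all 54 networks does
not hold under the default plant; (ii) the decreasing-modularity pattern
is not recoverable through the Bonferroni gate at these loadings. Both
are properties of the generator's declared parameters interacting with
the threshold, not of the estimators, whose correctness is pinned by
brute-force oracles on enumerable graphs. The parameters are part of the
package's declared study conditions and are deliberately not adjusted to
manufacture those patterns.

# Numerical choices and degenerate inputs

* Distances come from breadth-first search (binary) or Dijkstra over
  `1/w` (weighted); oracle equivalence against Floyd–Warshall is tested
  on hundreds of random graphs.
* `pearson_matrix()` refuses columns with (near-)zero variance, naming
  the offending ROI; a constant column after detrending falls under the
  same guard.
* `rm_anova()` returns F = 0, p = 1 when the condition sum of squares is
  numerically zero, and F = Inf, p = 0 for a perfectly consistent effect
  with zero error variance; paired tests use the analogous conventions.
* Empty networks make Lp and Dp undefined-metric errors rather than
  silent zeros; pipeline errors carry the subject/condition of the
  offending scan.
* All randomness (simulation, rewiring, modularity restarts, null
  ensembles) flows from one master seed fanned out into named
  per-stage substreams, so any stage can be re-run independently and
  full runs are bit-reproducible.

# Problem sizes used by the shipped checks

The packaged tests run the complete default cohort (54 networks of 160
nodes) for the study-level checks, with 100-null ensembles for the
small-worldness suite and 20 optimiser restarts for the per-scan
modularity in the multi-seed recovery suite; oracle suites use hundreds
of random graphs up to 12 nodes (exhaustive modularity up to 8 nodes);
calibration suites use 500 null ANOVA tables and 200 null nodal
datasets. Pipeline-level unit tests use reduced cohorts (4–12 subjects,
24–48 ROIs) with loadings strong enough that every stage, including the
null ensemble, is well defined at the lowest condition level.

# Known limitations

* The generator's defaults produce much sparser low-demand networks than
  empirical functional networks; see the plant-behaviour section above.
* sigma is a ratio estimator and is unstable on very sparse graphs; the
  package surfaces this as an explicit error rather than extrapolating.
* The Louvain optimiser is a heuristic; its restart scheme is validated
  exhaustively only up to 8 nodes.
* No sphericity correction is offered; with 3 conditions the uncorrected
  F is the convention this pipeline mirrors, but strongly non-spherical
  data would need a different test.
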