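---
title: "Methods: connectome thresholding, global metrics, and clinical-course classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome thresholding, global metrics, and clinical-course classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoms)
```

## The model and its assumptions

The pipeline analyzes subject-level structural connectomes: symmetric,
non-negative `q × q` matrices of streamline counts between gray-matter
parcels (`q = 84` by default), with group labels drawn from HC (healthy
controls) and the four MS clinical courses CIS, RR, SP, PP. Three
assumptions are load-bearing throughout:

* **Undirected, non-negative connectivity.** Streamline counts carry no
  direction and no sign; self-connections are meaningless, so diagonals
  are forced to zero and asymmetries are treated as input errors rather
  than silently symmetrized.
* **Topology over weight.** All metrics except density are computed on the
  binarized graph. The proportional threshold `Υ` keeps the
  `T = ⌊(q² − q)·τ/2⌋` strongest connections, so at a fixed `τ` every
  subject's binary graph has the same edge count (when the support is
  large enough) and group differences express pure topology, not overall
  connectivity strength.
* **Exchangeable subjects within group.** Group comparisons use rank
  statistics and classification uses cross-validation over subjects; no
  covariate structure (age, sex, scanner) is modeled.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `tau` | 0.35 | fraction of possible pairs | binarization threshold; default is the package-wide convention and sits inside the CV plateau the selection procedure identifies on simulated control cohorts |
| `f` | 500,000 | streamlines/subject | tractography emulation depth; in the saturated regime density no longer depends on `f` |
| `q` | 84 | parcels | network size of the standard parcellation |
| grid `C` | `2^{-5}, 2^{-3}, …, 2^{15}` | — | SVM error penalty; powers of two with exponent step 2 spanning the conventional range |
| grid `γ` | `2^{-15}, …, 2^{3}` | — | RBF kernel width on standardized features |
| folds `k` | 10 | — | cross-validation; reduced with a warning when a class is smaller than `k` |
| `stability_tol` | 0.10 | relative | plateau definition in threshold selection (below) |
| `n_restarts` | 10 | — | Louvain restarts in modularity search |

## Threshold selection

Two criteria guide the choice of `τ`: the across-subject coefficient of
variation of the five binarized-graph metrics should be (1) low and
(2) stable in `τ`. The procedure first rejects every `τ` above the
cohort's mean weighted density — beyond that point thresholding retains
the entire support and stops changing the topology, so those values are
uninformative. Among the remaining candidates it returns the smallest `τ`
whose mean CV (averaged over the five metrics) lies within 10% (relative)
of the admissible minimum. Both conventions are package decisions where
the procedure's verbal description leaves freedom: averaging over metrics
(per-metric curves are still reported and plotted), and the 10% plateau
tolerance (an observed plateau CV is an outcome, not a rule, so some
explicit tolerance is needed; 10% is tight enough that the selected `τ`
is never on the steep small-`τ` flank).

## Numerical choices

* **Retained-edge count.** `T = (q² − q)τ/2` is generally non-integer
  (`τ = 0.35`, `q = 84` gives 1220.1); we take the floor, the conservative
  reading of "conserve a fraction τ of the strongest connections" — never
  more than τ. Stated once in `retained_edge_count()` and used everywhere.
* **Ties at the cutoff weight** are broken by ascending `(i, j)` node
  index. This makes thresholding deterministic and, together with
  sorting by descending weight, makes the retained edge sets nested
  (monotone) in `τ` — a property the test suite checks explicitly.
* **Disconnected pairs.** Distances are `Inf`; global efficiency counts
  them as `1/∞ = 0`; CPL excludes them from each node's average (reachable
  nodes only), excludes isolated nodes from the outer mean, and attaches
  the excluded-pair count as an attribute with a warning. This keeps CPL
  finite on the near-complete graphs the pipeline produces while leaving
  the convention auditable. Undefined values (assortativity on
  degree-regular graphs, CPL/modularity on empty graphs) are `NA` plus a
  warning — never silently imputed; only the classifier imputes, with
  training-fold means, and logs how many values it touched.
* **Efficiency denominator.** The inner normalization of global
  efficiency is `q − 1`, matching the CPL formula, so a complete graph has
  `E_g = 1` exactly.
* **Modularity.** `Q` uses the standard Newman–Girvan e-matrix convention
  (cross-module edges contribute half to each module's row, so
  `a_u = k_u/2m`), which agrees with `igraph::modularity` and the brain
  connectivity toolboxes; the package's own `modularity_of_partition()` is
  the single evaluator. The search is exhaustive over all set partitions
  for `q ≤ 8` (at most Bell(8) = 4140 candidates — cheap, and exact, which
  is what lets tests demand agreement with an enumeration oracle at
  1e-10), and seeded multi-restart Louvain beyond. The result is clamped
  below by the trivial single-module partition (`Q = 0`).
* **Mann–Whitney p-values** are exact by enumeration when
  `n₁ + n₂ ≤ 12` with no ties, and use the tie- and continuity-corrected
  normal approximation otherwise. No multiple-testing correction by
  default (each test at its own 5% level, as in the table layout the
  reports mirror); Holm correction is available via `p_adjust`.
* **SVM.** The dual problem is solved by libsvm (via e1071) with
  standardization and imputation re-fitted inside every training fold;
  the extracted dual coefficients are checked against the KKT contract
  `0 ≤ αᵢ ≤ C`, `Σαᵢyᵢ = 0` (tolerance 1e-6). Multi-class tasks use
  one-vs-one voting. The reported triple is the support-weighted average
  of per-class precision/recall/F (per-class rows are kept); each class in
  turn plays "positive", so the choice of positive class is explicit in
  the output rather than implicit. Grid-search ties prefer smaller `C`,
  then smaller `γ`. Folds are stratified by group and seeded.

## What the synthetic generator emulates — and what it does not

`sample_connectome()` plants group structure on *latent pair intensities*,
then allocates `f` streamlines with a single multinomial draw per subject:

* a block structure (4 modules) with within/between connection
  probabilities rescaled to a subject-specific support density
  (`target_density` ± `density_sd`);
* a within/between mean-weight contrast (`weight_contrast`) that
  concentrates the strongest — hence retained — edges inside modules;
* a fixed hub/periphery propensity profile (normal quantiles, interleaved
  across blocks) scaled by `degree_spread`, giving heavy-tailed degrees;
* an assortative tilt (`hub_tilt`): negative values boost hub–periphery
  pairs (the disassortative regime of healthy biological networks),
  positive values boost like-with-like;
* log-normal per-pair jitter (`subject_sigma`) so between-subject CV is
  non-zero and threshold selection has something to measure.

Metrics are *emergent* from these latent dials — no metric value is ever
planted directly — which is what makes direction-recovery a genuine test:
the preset profiles (see `preset_profiles()`) were calibrated once so
that, at the default group sizes (24/12/24/24/17), group mean differences
reproduce the direction pattern expected of MS clinical courses (density
deficit in SP; assortativity rise in SP and PP; modularity below HC in CIS
and above CIS in RR; efficiency deficit and path-length rise in all
patient groups), and then frozen.

The generator does **not** emulate anatomy: no lesion geometry, no
specific tracts, no spatial embedding, no realistic parcel-size
heterogeneity, and no covariate effects. Its absolute metric levels differ
from real tractography cohorts (e.g., transitivity is near the density
baseline because clustering beyond the planted blocks is not modeled).
Passing tests therefore certify the *pipeline* — formulas, procedures,
determinism, statistical behavior under planted effects — not the
biological claims; with real cohorts, the same functions apply unchanged
via `read_cohort_manifest()`.

## Validation problem sizes

The test suite validates metrics against independent brute-force oracles
(triple enumeration, hand-rolled BFS/Floyd–Warshall, exhaustive
partitions) on a few hundred random graphs with `q ≤ 15` (`q ≤ 8` for
modularity), thresholding and nesting on 50 random weighted graphs,
threshold selection on a simulated 24-subject control cohort over the full
20-point `τ` grid, classification on 48-subject two-group cohorts with the
default hyperparameter grid, and direction recovery on 50 simulated
101-subject cohorts. The acceptance script uses the same cohort sizes with
10 cohorts for direction recovery.

## Known limitations

* The Louvain search above `q = 8` is a heuristic; its `Q` is a lower
  bound on the optimum (tests on planted-partition graphs bound the gap).
* CPL on disconnected graphs depends on the stated exclusion convention;
  other toolboxes differ (some use harmonic means or drop the metric).
* Support-weighted averaging of P/R/F is one of several defensible
  multi-class summaries; micro- and macro-averages can be reconstructed
  from the per-class rows.
* With `n` per group near the fold count, cross-validated F-measures are
  noisy and grid-search selection biases the best CV score upward; the
  null-cohort checks quantify this.
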