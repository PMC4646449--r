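---
title: "Scenario-led habitat modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scenario-led habitat modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenhab)
```

# The problem

Land managers and policy makers routinely face questions of the form "if x%
of this land use were converted to that one, what would happen to habitat
suitability for a species of concern?". `scenhab` answers such questions with
a three-part procedure:

1. **Describe the landscape.** A categorical habitat raster (either supplied
   directly, or derived from a multiband image by PCA + unsupervised k-means
   classification and pooling into broad classes) is turned into a predictor
   stack: the proportion of each habitat class within a fixed radius of every
   cell, plus optional covariates such as altitude.
2. **Fit a presence-background suitability model.** Species records in
   upland systems are usually presence-only (e.g. black grouse display-site
   locations), so we estimate a maximum-entropy (maxent) model: a Gibbs
   density over landscape cells whose feature expectations match the
   presence sample, regularised by an L1 penalty whose overall strength is
   selected by AICc.
3. **Simulate scenarios and compare.** Declarative conversion rules ("7% of
   grazed land becomes open-canopy woodland") are realised as stochastically
   grown patches from random starting cells. The fitted model is projected
   onto every simulated landscape, suitability is binarised at thresholds
   taken from the baseline map, and suitable-area proportions are compared
   across scenario ensembles, matched null scenarios, and conversion-extent
   sweeps with Kruskal-Wallis and Mann-Whitney tests.

# The suitability model

The model assigns cell $x$ with feature vector $f(x)$ the probability

$$P(x) = \frac{e^{\lambda \cdot f(x)}}{Z}, \qquad
  Z = \sum_{x \in \text{background}} e^{\lambda \cdot f(x)},$$

and the coefficients minimise the penalised negative log-likelihood

$$\mathrm{NLL}(\lambda) = -\frac{1}{n}\sum_{\text{presences}} \lambda \cdot f(x)
  + \ln \sum_{\text{background}} e^{\lambda \cdot f(x)} - \ln N
  + \beta \sum_j s_j |\lambda_j|,$$

with per-feature penalty scales $s_j = \sqrt{\mathrm{var}_{bg}(f_j)/n}$,
presence count $n$ and background size $N$. This is the standard
presence-background maxent objective; it is convex, so the optimum is unique
and independent of the starting point.

**Features.** Predictors are rescaled to $[0,1]$ by their background range.
Each predictor contributes a linear feature $z$, a quadratic feature $z^2$,
and forward hinge features $\max(0, (z-k)/(1-k))$ with knots $k$ at equally
spaced background quantiles (10 per predictor by default). This matches the
automatic feature choice of reference maxent implementations at moderate
presence sample sizes; product features are omitted by default because they
mainly add interpretive burden at these sample sizes. Features that are
constant over the background are dropped with a warning.

**Optimisation.** Accelerated proximal gradient descent (FISTA) with
backtracking line search and adaptive restart, run until the objective
changes by less than 1e-8 *and* the proximal-gradient optimality map is
below 1e-6. The second condition matters: near a minimiser the accelerated
iterates can take individually tiny steps while still measurably away from
the optimum, and the dual condition is what makes multistart fits agree to
1e-6 in objective (a property the test suite asserts). The fit is
deterministic; no seed is involved.

**Output scales.** `raw` output is the Gibbs density normalised over the
projection grid (it sums to 1); `logistic` output is the usual interpretable
transform $re^H/(1+re^H)$, where $H$ is the entropy of the raw training
distribution, so a cell typical of the training background maps to about
0.5 and the uniform model to exactly 0.5. Thresholds and suitability maps use the logistic scale by
default; the choice is an argument (`type`) everywhere, so raw can be
substituted.

**Model selection.** `select_beta()` fits the model across a grid of
regularisation multipliers (default $\{1,2,3,5,7,9,10,11,13,15,17,19\}$) and
scores each fit with
$\mathrm{AICc} = 2K - 2\ln L + 2K(K+1)/(n-K-1)$, where $\ln L$ is the sum of
log raw predictions at the presences and $K$ counts nonzero coefficients
(the usual convention for L1-regularised maxent). Ties break toward the
larger, more parsimonious $\beta$. When $n \le K+1$ the correction is
undefined and the model is reported as over-parameterised (`Inf`).
`aicc_infer_n()` inverts the identity row-wise, which lets a published
selection table's sample size be recovered from its printed likelihoods —
useful for checking the arithmetic of such tables, and used that way by the
acceptance script.

**Evaluation.** `evaluate_model()` builds a composite set of presence
predictions plus a seeded background sample labelled absent (1000 points by
default), and reports rank-based AUC (ties count one half) and TSS
(sensitivity + specificity − 1) at the threshold maximising
sensitivity + specificity. A presence-only evaluation of this kind is a
relative measure — background points are not true absences — and should be
read accordingly. `cv_maxent()` provides 10-fold cross-validated AUC as a
reporting utility; the deployed model is still fit on all presences.

# Focal predictors

`focal_proportions()` computes, for each class, the fraction of cells of
that class among the available cells inside a **circular** window (Euclidean
distance between cell centres, default radius 2000 m — a conservative
year-round territory radius for black grouse). Two design choices were
genuinely open:

* *Window shape.* Moving-window tools support both square and circular
  windows; a stated radius reads most naturally as a circle, so circular is
  the default and the kernel builder is exposed for anyone preferring
  squares.
* *Edge handling.* Window counts are normalised by the number of in-grid,
  non-nodata cells actually inside the window, so proportions still sum to 1
  at map margins. The alternative (zero-padding) systematically dilutes
  proportions near edges and would bias suitability there.

The implementation counts via FFT convolution and rounds back to integers
(counts of binary indicators are integers, so the rounding removes all
floating-point error); the test suite checks exact agreement with per-cell
brute-force window enumeration.

# Scenario simulation

A scenario is a set of conversion rules plus growth parameters. Execution
semantics, in order of the decisions that had to be made:

* **Targets are computed from the baseline landscape** before any rule runs:
  `round(fraction x baseline source-class cells)` per rule. Later rules may
  not consume cells converted earlier in the same run, so a scenario's rules
  are independent claims on the baseline.
* **Growth:** each rule picks `n_seeds` (default 20) random source-class
  cells which convert immediately; thereafter each sweep visits every
  frontier cell (source cells adjacent to converted cells, 8-neighbour by
  default) and converts it with probability `growth_prob` (default 0.25).
  The probability shapes the patches — lower values give more compact,
  rounder growth — but never changes the final converted area: the sweep
  that overshoots the target has a random surplus subset un-converted, so
  every rule converts exactly its target cell count. If all frontiers
  exhaust before the target is met, a fresh seed is drawn; if the source
  class itself runs out the scenario is infeasible and errors.
* **Null scenarios** (`null_scenario()`) append, for every rule A→B, a
  reciprocal rule B→A whose target equals the original rule's target. Every
  class's net area change is therefore zero by construction while the same
  amount of habitat is moved around, isolating the effect of configuration
  from composition. A change and its exact reverse share one null up to rule
  composition. The reciprocal fraction needs baseline class areas, which is
  why `null_scenario()` takes the grid as an argument.
* **Ensembles:** run $i$ of `run_ensemble()` uses seed `base_seed + i`, so
  single runs are individually reproducible and ensembles are embarrassingly
  parallel in principle.
* **Extent sweeps** rescale all rule fractions so the scenario total equals
  each level (default 5-30% in steps of 5), preserving the internal split
  between rules (a 7:3 split stays 7:3); infeasible levels are skipped with
  a warning.

Whether the original growth process applied its probability per frontier
cell per iteration or per patch, and whether seeds were drawn per rule or
per scenario, are not determinable from the published description; per-cell
and per-rule were chosen because they keep rules independent and the patch
count bounded by `n_seeds`. Both connectivity and the growth probability are
arguments.

# Landscape metrics

`patch_metrics()` reports the four patch-level metrics used for
before/after forestry comparisons: number of patches (NP, connected
components under the configured connectivity, default 8-neighbour to match
the growth engine), total area (TA, km²), mean patch area (MA = TA/NP) and
total edge (TE, km) counted as cell faces between target and non-target
cells. Faces on the map boundary count toward TE by default (the standard
raster perimeter convention; `boundary_edge = FALSE` disables it). An absent
class reports NP = 0, TA = TE = 0 and MA = 0 with an `empty` flag rather
than NA, so ensemble tables stay rectangular.

# Statistical comparison

`compare_scenarios()` reproduces the comparison structure of a
scenario-ensemble analysis: an omnibus Kruskal-Wallis test across scenarios
(tie-corrected H, chi-squared p), all pairwise Mann-Whitney tests (U
reported as the smaller one-sided statistic; exact p for samples of at most
8 without ties, otherwise the normal approximation with tie correction), and
each scenario against its matched null. Cells exactly at a threshold count
as suitable — the comparison direction at equality had to be fixed one way,
and ≥ keeps the all-thresholds-below-minimum case at proportion 1. No
multiple-testing correction is applied by default, mirroring common practice
for these ensemble comparisons; Holm correction is available by flag.

# The synthetic-landscape generator

`synth_habitat()` thresholds a smooth Gaussian latent field (FFT-filtered
white noise at a stated correlation length, plus a weaker rougher component
that prevents classes from forming simple bands) at cumulative-prevalence
ranks. Realised class areas therefore match the prevalence targets exactly
up to rounding, and maps are spatially autocorrelated and deterministic
given the seed. The default preset emulates a six-class upland working
landscape — human-dominated 3%, grazed 35%, moorland 30%, open-canopy
forestry 12%, closed-canopy forestry 15%, water 5% — a plausible mosaic for
an upland study area, with an altitude ramp (46-1078 m) as covariate.
`synth_multiband()` gives each class a distinct spectral signature plus
Gaussian noise to exercise the classification stage, and
`synth_presences()` samples cells without replacement proportional to
$e^{\lambda_{true} \cdot f(x)}$, giving a known ground-truth suitability
surface.

What the generator deliberately does **not** emulate: sensor radiometry and
atmospheric effects, survey effort and detection bias in the presence
records, temporal change, and any real geography. Tests passing on these
fixtures demonstrate that the machinery is correct and self-consistent —
that targets are hit exactly, that a known model is recovered, that
comparisons behave — not that any particular real landscape would yield a
given result.

# Numerical choices and degenerate inputs

* Quantile thresholds use the linear-interpolation definition (R type 7)
  over all non-nodata landscape cells of the baseline prediction.
* The max-sensitivity+specificity threshold searches the distinct predicted
  values at presences and background points; ties resolve to the largest
  (most specific) threshold.
* Constant prediction maps trigger a degenerate-input warning and collapse
  all quantile thresholds to the constant.
* k-means uses Lloyd iterations from k-means++ starts (seeded, `n_init`
  restarts, best within-cluster sum of squares wins); PCA standardises bands
  first (bands have heterogeneous scales) and fixes each component's sign by
  making its largest-magnitude loading positive.
* Rasters are ESRI ASCII grids with a JSON sidecar for legend and CRS;
  altitude or other covariates are expected on the habitat grid's exact
  spec (resample beforehand with nearest-neighbour if needed).
* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state; pipeline stages derive per-stage seeds from one master
  seed with a Lehmer-style mix.

# Problem sizes in the test suite

The packaged tests run the full study design at desk scale: a 100 x 100
six-class landscape (1 km² cells would make it a plausible 100 x 100 km
region; the default 100 m cells make it a 10 x 10 km neighbourhood), five
scenarios x 30 runs x 3 thresholds for the end-to-end check, 200 synthetic
presences for model recovery with a reduced regularisation grid
$\{0.5, 1, 2\}$ and linear features (the ground truth is linear in the
layers, so the recovery check is sharpest there), and brute-force oracle
comparisons on grids of at most 30 x 30 and samples of at most 8. These
sizes were chosen as the smallest at which every claimed property is
non-trivially exercised.

# Known limitations

* Suitability is compositional only: patch shape, fragmentation and edge
  effects influence real populations but enter the model only through the
  focal proportions.
* No demography, dispersal or connectivity: a suitable cell is not an
  occupied cell.
* Presence-only evaluation (AUC/TSS against background points) is relative,
  not absolute.
* Scenarios are single-step: no succession, aging or multi-stage
  transitions.
* No reprojection: all inputs must already share one grid.
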