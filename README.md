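# scenhab

Scenario-led landscape simulation and habitat suitability modelling.

`scenhab` is for ecologists and land-use analysts who need to answer
questions like *"if 10% of the grazed land in this landscape were converted
to moorland and open woodland, how would the area of suitable habitat for
black grouse change?"* — with presence-only species records and a
categorical habitat map as the only inputs.

It combines three pieces into one reproducible pipeline:

* **Habitat description.** A pooled habitat raster — supplied directly, or
  derived from a multiband image by PCA, unsupervised k-means classification
  and class pooling — is converted into focal predictors: the proportion of
  each habitat class within a circular window (default 2 km radius) of every
  cell, plus covariates such as altitude.
* **A presence–background maximum-entropy (maxent) suitability model,**
  implemented in the package as a penalized convex optimisation. For cell
  $x$ with features $f(x)$,

  $$P(x) = \frac{e^{\lambda \cdot f(x)}}{Z}, \qquad
    \hat\lambda = \arg\min_\lambda \Big[ -\tfrac1n \sum_{\text{pres}} \lambda \cdot f(x)
    + \ln \sum_{\text{bg}} e^{\lambda \cdot f(x)} - \ln N
    + \beta \sum_j s_j |\lambda_j| \Big],$$

  with linear, quadratic and hinge features, per-feature penalty scales
  $s_j = \sqrt{\mathrm{var}_{bg}(f_j)/n}$, and the regularisation multiplier
  $\beta$ selected by AICc ($2K - 2\ln L + 2K(K{+}1)/(n{-}K{-}1)$, $K$ =
  nonzero coefficients) over a grid. Evaluation uses presence-background
  AUC and TSS.
* **Scenario simulation.** Declarative conversion rules ("7% of grazed land
  → open-canopy woodland") are realised as stochastic patches grown from 20
  random starting cells with per-sweep conversion probability 0.25, hitting
  each rule's target area exactly. Ensembles (default 30 runs), matched
  null scenarios (same patch dynamics, zero net change per class),
  conversion-extent sweeps (5–30%), patch metrics (NP, TE, TA, MA) and
  Kruskal–Wallis / Mann–Whitney comparisons of suitable-area proportions
  complete the analysis.

Everything is testable offline: `synth_habitat()` / `synth_presences()`
generate spatially autocorrelated six-class landscapes and presences from a
known suitability surface, so the whole pipeline can be exercised end to end
with known ground truth.

## Worked example

Fit a model on a synthetic upland landscape, run two opposing grazing
scenarios, and compare the suitable area they leave behind:

```r
library(scenhab)

land  <- paper_like_landscape(seed = 1)          # 100 x 100 six-class mosaic
stack <- focal_proportions(land$grid, radius = 2000,
                           covariates = list(land$altitude))
pres  <- synth_presences(stack, land$true_lambdas, n = 200, seed = 11)
bg    <- which(!is.na(stack$layers$grazed))

sel <- select_beta(pres$cell, bg, stack, beta_grid = c(0.5, 1, 2),
                   features = feature_spec("linear"))
sel$report
#> # A tibble: 3 × 5
#>    beta log_likelihood n_params  aicc delta_aicc
#>   <dbl>          <dbl>    <int> <dbl>      <dbl>
#> 1   0.5         -1777.        5 3565.       0
#> 2   1           -1779.        4 3567.       2.14
#> 3   2           -1783.        3 3573.       7.97

baseline <- predict(sel$model, stack, type = "logistic")
thr <- suitability_thresholds(baseline, pres$cell, bg)
thr
#> <threshold_set> q1 = 0.2673, median = 0.3417, q3 = 0.4536, max_ss = 0.4151 (sens+spec = 1.358)

ens <- dplyr::bind_rows(
  run_ensemble(land$grid, paper_like_scenarios()$reduced_grazing,
               n_runs = 30, base_seed = 100),
  run_ensemble(land$grid, paper_like_scenarios()$increased_grazing,
               n_runs = 30, base_seed = 200)
)
tidy(ens$summary[[1]])      # per-class bookkeeping of one run
#> # A tibble: 6 × 6
#>   class          code baseline_cells final_cells net_cells net_km2
#>   <chr>         <int>          <int>       <int>     <int>   <dbl>
#> 1 human             1            300         300         0    0
#> 2 grazed            2           3500        3150      -350   -3.5
#> 3 moorland          3           3000        3245       245    2.45
#> 4 open_canopy       4           1200        1305       105    1.05
#> 5 closed_canopy     5           1500        1500         0    0
#> 6 water             6            500         500         0    0

records <- project_ensembles(ens, sel$model, thr, radius = 2000,
                             covariates = list(land$altitude))
compare_scenarios(records, "median",
                  baseline = baseline_proportions(baseline, thr)[["median"]])
#> <scenario_comparison> threshold 'median', baseline proportion 0.5000
#> omnibus Kruskal-Wallis: H = 15.350, df = 1, p = 8.93e-05
#> medians:
#> # A tibble: 2 × 3
#>   scenario          median n_runs
#>   <chr>              <dbl>  <int>
#> 1 increased_grazing  0.502     30
#> 2 reduced_grazing    0.538     30
#> pairwise Mann-Whitney:
#> # A tibble: 1 × 7
#>   scenario_a        scenario_b      statistic value   n_a   n_b   p_value
#>   <chr>             <chr>           <chr>     <dbl> <int> <int>     <dbl>
#> 1 increased_grazing reduced_grazing U           185    30    30 0.0000893
```

Reading the output: the reduced-grazing run converts exactly 10% of grazed
land (350 of 3500 cells: 7% to moorland, 3% to open-canopy woodland) in
every run — only the patch layout varies. At the median threshold the
reduced-grazing ensemble leaves a median 53.8% of the landscape suitable
against a 50.0% baseline, while increased grazing stays at 50.2%; the
rank tests show the two scenario distributions are clearly separated
(U = 185, p < 0.001). `plot_suitable_area(records, ...)` draws the matching
box plots, and `ensemble_patch_metrics()` summarises patch number, area and
edge before and after change.

See `vignettes/scenario-led-habitat-modelling.Rmd` for the full account of
the model, the simulation semantics, parameter defaults and limitations.

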