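#' Project a suitability model onto scenario ensembles
#'
#' For every simulated landscape: recompute focal proportions, project the
#' fitted model, and record the proportion of the study area at or above each
#' threshold. This is the bridge from the simulation engine to the
#' statistical comparison.
#'
#' @param ensembles A tibble of runs ([run_ensemble()] results, possibly
#'   several scenarios bound together; an optional `level` column from
#'   [extent_sweep()] is carried through).
#' @param model A fitted [maxent_fit()] model.
#' @param thresholds A [suitability_thresholds()] set (or any named list of
#'   thresholds).
#' @param radius Focal radius (m) used in training.
#' @param covariates Covariate [continuous_grid()]s used in training.
#' @param type Prediction output fed to the thresholds (default logistic).
#' @param threshold_names Which thresholds to record.
#' @return A tibble of suitable-area records: `scenario`, `run`,
#'   `threshold_name`, `proportion_suitable` (plus `level` if present).
#' @export
project_ensembles <- function(ensembles, model, thresholds, radius = 2000,
                              covariates = list(), type = "logistic",
                              threshold_names = c("q1", "median", "q3")) {
  purrr::map_dfr(seq_len(nrow(ensembles)), function(i) {
    stack <- focal_proportions(ensembles$grid[[i]], radius = radius, covariates = covariates)
    pred <- stats::predict(model, stack, type = type)
    out <- tibble::tibble(
      scenario = ensembles$scenario[i],
      run = ensembles$run[i],
      threshold_name = threshold_names,
      proportion_suitable = vapply(
        threshold_names,
        function(tn) suitable_proportion(pred, thresholds[[tn]]),
        numeric(1)
      )
    )
    if ("level" %in% names(ensembles)) out <- dplyr::mutate(out, level = ensembles$level[i], .before = 1)
    out
  })
}

#' Baseline suitable proportions at each threshold
#'
#' @param prediction Baseline [continuous_grid()] prediction.
#' @param thresholds A [suitability_thresholds()] set.
#' @param threshold_names Thresholds to evaluate.
#' @return Named numeric vector of proportions.
#' @export
baseline_proportions <- function(prediction, thresholds,
                                 threshold_names = c("q1", "median", "q3")) {
  vapply(
    stats::setNames(threshold_names, threshold_names),
    function(tn) suitable_proportion(prediction, thresholds[[tn]]),
    numeric(1)
  )
}

#' Read and write scenario definitions
#'
#' Scenarios serialise as JSON or YAML (by extension):
#' `{name, rules: [{source, dest, fraction}], n_seeds, growth_prob,
#' connectivity}`.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @param scn A [scenario()].
#' @export
read_scenario <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path)
  rules <- purrr::map_dfr(obj$rules, function(r) {
    conversion_rule(r$source, r$dest, as.numeric(r$fraction))
  })
  scenario(obj$name, rules,
    n_seeds = obj$n_seeds %||% 20L,
    growth_prob = obj$growth_prob %||% 0.25,
    connectivity = obj$connectivity %||% 8L
  )
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scn, path) {
  obj <- list(
    name = scn$name,
    rules = purrr::pmap(scn$rules, function(source, dest, fraction) {
      list(source = source, dest = dest, fraction = fraction)
    }),
    n_seeds = scn$n_seeds, growth_prob = scn$growth_prob,
    connectivity = scn$connectivity
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read and write a fitted maxent model as JSON
#'
#' @param path JSON path.
#' @param model A [maxent_fit()] model.
#' @export
write_maxent_model <- function(model, path) {
  fs <- model$feature_spec
  obj <- list(
    feature_classes = fs$classes,
    n_hinge_knots = fs$n_hinge_knots,
    bounds = fs$bounds,
    features = fs$features,
    lambdas = as.list(model$lambdas),
    beta = model$beta,
    s = as.list(model$s),
    log_partition = model$log_partition,
    entropy = model$entropy,
    background_size = model$background_size,
    presence_count = model$presence_count,
    log_likelihood = model$log_likelihood,
    objective = model$objective,
    layer_names = model$layer_names,
    converged = model$converged,
    iterations = model$iterations
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fs <- feature_spec(obj$feature_classes, obj$n_hinge_knots)
  fs$bounds <- tibble::as_tibble(obj$bounds)
  feats <- tibble::as_tibble(obj$features)
  if (!"knot" %in% names(feats)) feats$knot <- NA_real_
  feats$knot <- as.numeric(feats$knot)
  fs$features <- feats
  fs$calibrated <- TRUE
  structure(
    list(
      feature_spec = fs,
      lambdas = unlist(obj$lambdas),
      beta = obj$beta,
      s = unlist(obj$s),
      log_partition = obj$log_partition,
      entropy = obj$entropy,
      background_size = obj$background_size,
      presence_count = obj$presence_count,
      log_likelihood = obj$log_likelihood,
      objective = obj$objective,
      layer_names = obj$layer_names,
      converged = obj$converged,
      iterations = obj$iterations
    ),
    class = "maxent_model"
  )
}

#' Run configuration
#'
#' Bundles paths, model settings, simulation settings and the master seed for
#' a full pipeline run. The master seed fans out deterministically to
#' per-stage seeds via [derive_seed()], so a whole run is reproducible from
#' one integer while stages stay independent.
#'
#' @param raster,altitude,presences,legend,pooling Paths to inputs (any may be
#'   NULL when the corresponding stage is not run or synthetic presets are
#'   used).
#' @param scenarios Paths to scenario JSON/YAML files, or a list of
#'   [scenario()] objects; NULL means the built-in five-scenario preset.
#' @param out_dir Output directory.
#' @param radius Focal radius (m).
#' @param beta_grid Regularisation grid for [select_beta()].
#' @param feature_classes,n_hinge_knots Passed to [feature_spec()].
#' @param background_max Landscapes with at most this many defined cells use
#'   every cell as background; larger ones use a seeded sample of
#'   `background_sample` cells.
#' @param background_sample Background sample size for large landscapes.
#' @param n_runs Runs per scenario ensemble.
#' @param with_null Also run matched null scenarios.
#' @param sweep_levels Extent-sweep levels (percent).
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(raster = NULL, altitude = NULL, presences = NULL,
                       legend = NULL, pooling = NULL, scenarios = NULL,
                       out_dir = ".", radius = 2000,
                       beta_grid = c(1, 2, 3, 5, 7, 9, 10, 11, 13, 15, 17, 19),
                       feature_classes = c("linear", "quadratic", "hinge"),
                       n_hinge_knots = 10L,
                       background_max = 200000L, background_sample = 10000L,
                       n_runs = 30L, with_null = TRUE,
                       sweep_levels = c(5, 10, 15, 20, 25, 30),
                       seed = 1L) {
  structure(
    list(
      raster = raster, altitude = altitude, presences = presences,
      legend = legend, pooling = pooling, scenarios = scenarios,
      out_dir = out_dir, radius = radius, beta_grid = beta_grid,
      feature_classes = feature_classes, n_hinge_knots = n_hinge_knots,
      background_max = background_max, background_sample = background_sample,
      n_runs = n_runs, with_null = with_null, sweep_levels = sweep_levels,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML config path; fields mirror the `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")),
      class = "scenhab_error_config"
    )
  }
  do.call(run_config, obj)
}

#' Derive a stage seed from the master seed
#'
#' Lehmer-style mixing keeps derived seeds inside 32-bit integer range while
#' giving distinct, reproducible streams per stage.
#'
#' @param master Master integer seed.
#' @param k Stage index (any small integer).
#' @return An integer seed.
#' @export
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + k * 7919 + 12345) %% 2147483647)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Write a pipeline artifact CSV with provenance header
#'
#' Prepends a comment line recording the package version, master seed and a
#' config digest, then the CSV body (read back with `comment = "#"`).
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config The [run_config()] in force.
#' @export
write_artifact_csv <- function(df, path, config) {
  header <- sprintf(
    "# scenhab %s seed=%d config=%d",
    as.character(utils::packageVersion("scenhab")),
    config$seed, config_hash(config)
  )
  writeLines(header, path)
  suppressWarnings(readr::write_csv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

resolve_scenarios <- function(config) {
  if (is.null(config$scenarios)) {
    return(paper_like_scenarios())
  }
  if (is.character(config$scenarios)) {
    scns <- lapply(config$scenarios, read_scenario)
    names(scns) <- vapply(scns, function(s) s$name, character(1))
    return(scns)
  }
  scns <- config$scenarios
  names(scns) <- vapply(scns, function(s) s$name, character(1))
  scns
}

choose_background <- function(stack, config) {
  cells <- stack_defined_cells(stack)
  if (length(cells) <= config$background_max) {
    return(cells)
  }
  withr::with_seed(
    derive_seed(config$seed, 2L),
    sample(cells, config$background_sample)
  )
}

#' Pipeline stage: classify a multiband image into pooled habitat classes
#'
#' PCA reduction, k-means clustering and class pooling in one step, writing
#' the pooled habitat grid to `out_dir/habitat.asc`.
#'
#' @param image A [multiband_image()] (or NULL to read band paths from
#'   `config$raster`, a vector of `.asc` files).
#' @param config A [run_config()].
#' @param n_components,k Classification settings.
#' @return The pooled [habitat_grid()], invisibly; logs explained variance
#'   and class areas.
#' @export
pipeline_classify <- function(config, image = NULL, n_components = 3L, k = 18L) {
  if (is.null(image)) {
    if (is.null(config$raster)) {
      rlang::abort("no image and no raster paths in config", class = "scenhab_error_config")
    }
    grids <- lapply(config$raster, read_continuous_grid)
    image <- multiband_image(
      stats::setNames(lapply(grids, `[[`, "values"), vapply(grids, `[[`, "", "name")),
      grids[[1]]$spec
    )
  }
  if (is.null(config$pooling)) {
    rlang::abort("config$pooling (pooling map JSON) is required", class = "scenhab_error_config")
  }
  pooling <- if (is.character(config$pooling)) read_pooling_map(config$pooling) else config$pooling
  scores <- pca_reduce(image, n_components)
  message(sprintf(
    "explained variance: %s",
    paste(sprintf("%.1f%%", 100 * attr(scores, "explained_variance")[1:n_components]),
      collapse = ", "
    )
  ))
  raw <- kmeans_classify(scores, k = k, seed = derive_seed(config$seed, 1L))
  pooled <- pool_classes(raw, pooling)
  areas <- class_areas(pooled)
  message(paste(sprintf("%s: %d cells", areas$class, areas$cells), collapse = "; "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_habitat_grid(pooled, file.path(config$out_dir, "habitat.asc"))
  invisible(pooled)
}

#' Pipeline stage: fit the suitability model
#'
#' Builds focal predictors, selects the regularisation multiplier by AICc and
#' writes `model.json` plus a `fit_report.csv` mirroring a model-selection
#' table (beta, log-likelihood, parameter count, AICc, delta AICc).
#'
#' @param config A [run_config()].
#' @param grid,altitude,presence_points Objects overriding the config paths.
#' @return List with `model`, `report`, `stack`, `background`, `presence_cells`.
#' @export
pipeline_fit <- function(config, grid = NULL, altitude = NULL, presence_points = NULL) {
  if (is.null(grid)) grid <- read_habitat_grid(config$raster, legend = NULL)
  covs <- list()
  if (!is.null(altitude)) {
    covs <- list(altitude)
  } else if (!is.null(config$altitude)) {
    covs <- list(read_continuous_grid(config$altitude, name = "altitude"))
  }
  if (is.null(presence_points)) presence_points <- read_presences(config$presences)
  stack <- focal_proportions(grid, radius = config$radius, covariates = covs)
  pres <- presence_cells(stack$spec, presence_points)
  bg <- choose_background(stack, config)
  sel <- select_beta(pres, bg, stack,
    beta_grid = config$beta_grid,
    features = feature_spec(config$feature_classes, config$n_hinge_knots)
  )
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_maxent_model(sel$model, file.path(config$out_dir, "model.json"))
  write_artifact_csv(sel$report, file.path(config$out_dir, "fit_report.csv"), config)
  invisible(list(
    model = sel$model, report = sel$report, stack = stack,
    background = bg, presence_cells = pres
  ))
}

#' Pipeline stage: simulate scenarios and record suitable-area proportions
#'
#' Runs every configured scenario (and its matched null when
#' `config$with_null`), projects the model onto each simulated landscape and
#' writes `records.csv` (per-run suitable proportions per threshold) and
#' `summaries.csv` (per-run per-class net changes).
#'
#' @param config A [run_config()].
#' @param fit The [pipeline_fit()] result (model + stack); refitted from
#'   config paths when NULL.
#' @param grid Baseline [habitat_grid()]; read from config when NULL.
#' @param covariates Covariate grids used in training.
#' @return List with `records`, `summaries`, `thresholds`, `baseline`
#'   (named baseline proportions), invisibly.
#' @export
pipeline_simulate <- function(config, fit = NULL, grid = NULL, covariates = list()) {
  if (is.null(grid)) grid <- read_habitat_grid(config$raster, legend = NULL)
  if (is.null(fit)) fit <- pipeline_fit(config, grid = grid)
  baseline_pred <- stats::predict(fit$model, fit$stack, type = "logistic")
  thr <- suitability_thresholds(baseline_pred, fit$presence_cells, fit$background)
  baseline <- baseline_proportions(baseline_pred, thr)
  scns <- resolve_scenarios(config)
  ensembles <- purrr::imap_dfr(scns, function(scn, nm) {
    base_seed <- derive_seed(config$seed, 10L + match(nm, names(scns)))
    ens <- run_ensemble(grid, scn, n_runs = config$n_runs, base_seed = base_seed)
    if (config$with_null) {
      nul <- null_scenario(scn, grid)
      ens <- dplyr::bind_rows(
        ens,
        run_ensemble(grid, nul, n_runs = config$n_runs, base_seed = base_seed + 500L)
      )
    }
    ens
  })
  records <- project_ensembles(ensembles, fit$model, thr,
    radius = config$radius, covariates = covariates
  )
  summaries <- purrr::map_dfr(seq_len(nrow(ensembles)), function(i) {
    dplyr::mutate(ensembles$summary[[i]]$classes,
      scenario = ensembles$scenario[i], run = ensembles$run[i], .before = 1
    )
  })
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_artifact_csv(records, file.path(config$out_dir, "records.csv"), config)
  write_artifact_csv(summaries, file.path(config$out_dir, "summaries.csv"), config)
  invisible(list(
    records = records, summaries = summaries,
    thresholds = thr, baseline = baseline
  ))
}

#' Pipeline stage: compare scenario ensembles
#'
#' @param config A [run_config()].
#' @param records Records tibble (read from `out_dir/records.csv` when NULL).
#' @param baseline Optional named baseline proportions.
#' @return Named list of [compare_scenarios()] results, one per threshold
#'   present in the records; writes `comparison_<threshold>.csv` tables.
#' @export
pipeline_report <- function(config, records = NULL, baseline = NULL) {
  if (is.null(records)) {
    records <- readr::read_csv(file.path(config$out_dir, "records.csv"),
      comment = "#", show_col_types = FALSE
    )
  }
  out <- list()
  for (tn in unique(records$threshold_name)) {
    cmp <- compare_scenarios(records, tn,
      baseline = if (!is.null(baseline)) unname(baseline[tn]) else NULL
    )
    write_artifact_csv(
      cmp$pairwise,
      file.path(config$out_dir, sprintf("comparison_%s.csv", tn)), config
    )
    out[[tn]] <- cmp
  }
  invisible(out)
}
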