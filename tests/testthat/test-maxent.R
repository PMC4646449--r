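# Small training fixture: 100-cell landscape, 3 classes, focal predictors.
make_maxent_fixture <- function(seed = 1, n_pres = 40, n = 10) {
  g <- make_test_grid(n = n, k = 3, seed = seed)
  stack <- focal_proportions(g, radius = 60)
  bg <- seq_len(n * n)
  pres <- synth_presences(stack, c(class_1 = 3, class_2 = -2), n_pres, seed = seed + 1)
  list(stack = stack, bg = bg, pres = pres$cell)
}

test_that("feature expansion matches hand-computed values", {
  P <- cbind(p = c(0, 1, 2, 3, 4))
  fs <- calibrate_features(P, feature_spec(c("linear", "quadratic", "hinge"), n_hinge_knots = 2))
  FF <- build_features(P, fs)
  z <- c(0, 0.25, 0.5, 0.75, 1)
  expect_equal(unname(FF[, "p"]), z) # min -> 0, max -> 1
  expect_equal(unname(FF[, "p^2"]), z^2) # midpoint -> 0.25
  # knots at the 1/3 and 2/3 background quantiles of z = 1/3, 2/3;
  # hinge value max(0, (z - k) / (1 - k)) computed by hand:
  expect_equal(fs$features$knot[fs$features$type == "hinge"], c(1 / 3, 2 / 3))
  h1 <- unname(FF[, 3])
  h2 <- unname(FF[, 4])
  expect_equal(h1, c(0, 0, 0.25, 0.625, 1), tolerance = 1e-12)
  expect_equal(h2, c(0, 0, 0, 0.25, 1), tolerance = 1e-12)
})

test_that("constant predictors are dropped with a warning", {
  P <- cbind(a = c(0, 1, 2), b = c(5, 5, 5))
  expect_warning(fs <- calibrate_features(P, feature_spec("linear")), "constant")
  expect_equal(fs$bounds$predictor, "a")
})

test_that("a fully penalised fit is the uniform model", {
  fx <- make_maxent_fixture()
  fit <- maxent_fit(fx$pres, fx$bg, fx$stack, beta = 1e6, features = feature_spec("linear"))
  expect_true(all(fit$lambdas == 0))
  pred <- predict(fit, fx$stack, type = "raw")
  expect_true(all(abs(pred$values - 1 / length(fx$bg)) < 1e-12))
  # logistic output of the uniform model is constant
  lg <- predict(fit, fx$stack, type = "logistic")
  expect_lt(diff(range(lg$values)), 1e-12)
})

test_that("fit matches a 1-D grid-search oracle of the same objective", {
  # one binary predictor: background half 0 half 1, presences all at 1
  spec <- grid_spec(2, 2, 30)
  stack <- focal_stack(list(p = matrix(c(0, 0, 1, 1), 2, 2)), spec, radius = 30)
  bg <- 1:4
  pres <- c(4L, 4L, 3L, 3L, 4L)
  beta <- 0.5
  fit <- maxent_fit(pres, bg, stack, beta = beta, features = feature_spec("linear"))
  f_bg <- c(0, 0, 1, 1)
  s <- sqrt(stats::var(f_bg) / length(pres))
  objective <- function(l) {
    -l + log(sum(exp(l * f_bg))) - log(4) + beta * s * abs(l)
  }
  grid <- seq(-2, 8, by = 1e-4)
  oracle <- grid[which.min(vapply(grid, objective, numeric(1)))]
  expect_equal(unname(fit$lambdas), oracle, tolerance = 1e-4)
})

test_that("the penalised objective is convex: multistart fits agree", {
  fx <- make_maxent_fixture(seed = 3)
  f0 <- maxent_fit(fx$pres, fx$bg, fx$stack, beta = 1)
  withr::with_seed(1, {
    for (trial in 1:3) {
      f1 <- maxent_fit(fx$pres, fx$bg, fx$stack,
        beta = 1,
        init = stats::rnorm(length(f0$lambdas))
      )
      expect_equal(f1$objective, f0$objective, tolerance = 1e-6)
    }
  })
})

test_that("raw predictions over the training background sum to 1", {
  for (seed in c(2, 7)) {
    fx <- make_maxent_fixture(seed = seed)
    fit <- maxent_fit(fx$pres, fx$bg, fx$stack, beta = 2)
    pred <- predict(fit, fx$stack, type = "raw")
    expect_equal(sum(pred$values[fx$bg]), 1, tolerance = 1e-6)
  }
})

test_that("increasing beta weakly shrinks the weighted L1 norm", {
  fx <- make_maxent_fixture(seed = 5)
  norms <- vapply(c(1, 2, 3, 5, 7, 9, 10, 11, 13, 15, 17, 19), function(b) {
    fit <- maxent_fit(fx$pres, fx$bg, fx$stack, beta = b, features = feature_spec("linear"))
    sum(fit$s * abs(fit$lambdas))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("prediction responds monotonically to a positively weighted predictor", {
  fx <- make_maxent_fixture(seed = 4)
  fit <- maxent_fit(fx$pres, fx$bg, fx$stack, beta = 1, features = feature_spec("linear"))
  j <- which(fit$lambdas > 0)[1]
  skip_if(is.na(j), "no positive coefficient in fixture fit")
  layer <- fit$feature_spec$features$predictor[j]
  pred0 <- predict(fit, fx$stack, type = "raw")
  cell <- fx$bg[17]
  stack2 <- fx$stack
  stack2$layers[[layer]][cell] <- stack2$layers[[layer]][cell] + 0.05
  pred1 <- predict(fit, stack2, type = "raw")
  # relative rank of the perturbed cell never decreases
  expect_gte(
    pred1$values[cell] / max(pred1$values, na.rm = TRUE),
    pred0$values[cell] / max(pred0$values, na.rm = TRUE) - 1e-12
  )
})

test_that("AICc reproduces the published selection-table arithmetic", {
  # sample size recovered by inverting the identity on three table rows
  n <- aicc_infer_n(
    log_likelihood = c(-946.569, -953.742, -958.848),
    n_params = c(37, 19, 16),
    aicc_values = c(2052.35, 1960.39, 1959.77)
  )
  expect_identical(n, 71L)
  expect_equal(aicc(-958.653, 10, n), 1940.97, tolerance = 0.01)
  expect_equal(aicc(-953.742, 19, n), 1960.39, tolerance = 0.01)
  expect_equal(aicc(-953.742, 19, n) - aicc(-958.653, 10, n), 19.41, tolerance = 0.01)
  expect_equal(aicc(0, 0, 50), 0)
  expect_warning(res <- aicc(-10, 10, 11), "AICc undefined")
  expect_identical(res, Inf)
})

test_that("select_beta returns a consistent, sorted report and sane winner", {
  fx <- make_maxent_fixture(seed = 6)
  sel <- select_beta(fx$pres, fx$bg, fx$stack,
    beta_grid = c(4, 1, 2),
    features = feature_spec("linear")
  )
  expect_equal(sel$report$beta, c(1, 2, 4)) # sorted by beta
  expect_equal(min(sel$report$delta_aicc), 0)
  # AICc column equals aicc() applied row-wise to its own lnL/K columns
  recomputed <- mapply(
    function(l, k) suppressWarnings(aicc(l, k, length(fx$pres))),
    sel$report$log_likelihood, sel$report$n_params
  )
  expect_equal(sel$report$aicc, unname(recomputed))
  # winner attains the minimum AICc (ties resolved toward larger beta)
  winner_aicc <- sel$report$aicc[sel$report$beta == sel$model$beta]
  expect_equal(winner_aicc, min(sel$report$aicc), tolerance = 1e-9)
  # a grid of one huge beta selects the uniform model
  sel0 <- select_beta(fx$pres, fx$bg, fx$stack,
    beta_grid = 1e6,
    features = feature_spec("linear")
  )
  expect_true(all(sel0$model$lambdas == 0))
})

test_that("quantile thresholds and max sens+spec behave on worked cases", {
  spec <- grid_spec(2, 5, 30)
  pred <- continuous_grid(matrix(seq(0.1, 1.0, by = 0.1), 2, 5), spec)
  thr <- suitability_thresholds(pred, presences = c(9L, 10L), background = c(1L, 2L))
  expect_equal(thr$median, 0.55) # linear-interpolation quantile of 0.1..1.0
  expect_equal(thr$q1, 0.325)
  expect_equal(thr$q3, 0.775)
  # perfect separation: sens + spec = 2
  expect_equal(thr$max_ss_value, 2)
  expect_true(thr$max_ss > 0.2 && thr$max_ss <= 0.9)

  const <- continuous_grid(matrix(0.5, 2, 5), spec)
  expect_warning(
    thrc <- suitability_thresholds(const, presences = 1L, background = 2L),
    "degenerate"
  )
  expect_equal(c(thrc$q1, thrc$median, thrc$q3), rep(0.5, 3))
})

test_that("AUC and TSS match pair-counting on worked examples", {
  spec <- grid_spec(2, 3, 30)
  pred <- continuous_grid(matrix(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.1), 2, 3), spec)
  # presences {0.9, 0.8, 0.4} vs background {0.7, 0.3, 0.1}: 8 of 9 pairs concordant
  ev <- evaluate_model(pred, presences = 1:3, background = 4:6)
  expect_equal(ev$auc, 8 / 9)
  # perfect separation
  ev2 <- evaluate_model(pred, presences = 1:2, background = 5:6)
  expect_equal(ev2$auc, 1)
  expect_equal(ev2$tss, 1)
  # constant predictions are uninformative
  const <- continuous_grid(matrix(0.5, 2, 3), spec)
  ev3 <- evaluate_model(const, presences = 1:2, background = 5:6)
  expect_equal(ev3$auc, 0.5)
  # complement symmetry: AUC(pred) = 1 - AUC(-pred)
  neg <- continuous_grid(-pred$values, spec)
  ev4 <- evaluate_model(neg, presences = 1:3, background = 4:6)
  expect_equal(ev4$auc, 1 - ev$auc)
})

test_that("models round-trip through JSON and keep predicting identically", {
  fx <- make_maxent_fixture(seed = 8)
  fit <- maxent_fit(fx$pres, fx$bg, fx$stack, beta = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_model(fit, path)
  fit2 <- read_maxent_model(path)
  p1 <- predict(fit, fx$stack, type = "logistic")
  p2 <- predict(fit2, fx$stack, type = "logistic")
  expect_equal(p2$values, p1$values, tolerance = 1e-10)
  expect_equal(glance(fit2)$aicc, glance(fit)$aicc, tolerance = 1e-8)
})

test_that("tidy and glance summarise a fit coherently", {
  fx <- make_maxent_fixture(seed = 9)
  fit <- maxent_fit(fx$pres, fx$bg, fx$stack, beta = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), length(fit$lambdas))
  expect_true(all(c("feature", "predictor", "type", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_params, sum(td$estimate != 0))
  expect_equal(gl$background_size, length(fx$bg))
})
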