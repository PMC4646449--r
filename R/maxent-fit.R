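#' Fit a presence-background maximum-entropy suitability model
#'
#' Estimates a Gibbs distribution over landscape cells,
#' `P(x) = exp(lambda . f(x)) / Z`, whose features match the presence sample
#' as closely as an L1 penalty allows. Coefficients minimise the penalized
#' negative log-likelihood
#' \deqn{-(1/n) \sum_{presence} \lambda f(x) + \ln \sum_{background}
#'   e^{\lambda f(x)} - \ln N + \beta \sum_j s_j |\lambda_j|,}
#' with per-feature penalty scales `s_j = sqrt(var_bg(f_j) / n)`. The
#' objective is convex; it is minimised by accelerated proximal gradient
#' descent (FISTA with backtracking and restart) to an objective-change
#' tolerance of 1e-8, which is deterministic: no seed is involved.
#'
#' @param presences Integer vector of presence cell indices (column-major
#'   linear indices into the stack's grid), at least 5.
#' @param background Integer vector of background cell indices, normally the
#'   whole landscape or a large representative sample of it.
#' @param stack A [focal_stack()] of predictor layers.
#' @param beta Regularisation multiplier (> 0): scales the L1 penalty.
#' @param features A [feature_spec()]; calibrated here against the background.
#' @param tol Convergence tolerance on the objective change.
#' @param max_iter Iteration cap.
#' @param init Optional starting coefficient vector (defaults to all zero);
#'   the objective is convex, so any start reaches the same optimum.
#' @return An object of class `maxent_model`: feature spec with bounds and
#'   knots, coefficients (`lambdas`), `beta`, penalty scales `s`, training
#'   log-partition `log_partition`, training-distribution entropy `entropy`,
#'   `background_size`, `presence_count`, per-presence log-likelihood sum
#'   `log_likelihood`, convergence info.
#' @export
maxent_fit <- function(presences, background, stack, beta = 1,
                       features = feature_spec(), tol = 1e-8, max_iter = 20000L,
                       init = NULL) {
  if (length(presences) < 5) {
    rlang::abort("need at least 5 presences", class = "scenhab_error_parameter")
  }
  if (beta <= 0) rlang::abort("beta must be > 0", class = "scenhab_error_parameter")
  P_bg <- stack_matrix(stack, background)
  P_pr <- stack_matrix(stack, presences)
  if (anyNA(P_bg) || anyNA(P_pr)) {
    rlang::abort("predictors must be defined at all presence and background cells",
      class = "scenhab_error_parameter"
    )
  }
  fspec <- calibrate_features(P_bg, features)
  F_bg <- build_features(P_bg, fspec)
  F_pr <- build_features(P_pr, fspec)
  n <- length(presences)
  N <- length(background)
  s <- sqrt(apply(F_bg, 2, stats::var) / n)

  a <- colMeans(F_pr) # presence feature means
  lse <- function(eta) {
    m <- max(eta)
    m + log(sum(exp(eta - m)))
  }
  smooth_val <- function(lam) {
    eta <- drop(F_bg %*% lam)
    -sum(a * lam) + lse(eta) - log(N)
  }
  smooth_grad <- function(lam) {
    eta <- drop(F_bg %*% lam)
    q <- exp(eta - lse(eta))
    drop(crossprod(F_bg, q)) - a
  }
  penalty <- function(lam) beta * sum(s * abs(lam))
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

  J <- ncol(F_bg)
  lam <- if (is.null(init)) numeric(J) else rep_len(init, J)
  y <- lam
  tprev <- 1
  L <- 1
  obj <- smooth_val(lam) + penalty(lam)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    gy <- smooth_val(y)
    grad <- smooth_grad(y)
    repeat {
      cand <- soft(y - grad / L, beta * s / L)
      d <- cand - y
      if (smooth_val(cand) <= gy + sum(grad * d) + L / 2 * sum(d^2) + 1e-12) break
      L <- L * 2
      if (L > 1e14) {
        rlang::abort("non-finite objective in maxent fit", class = "scenhab_error_numeric")
      }
    }
    new_obj <- smooth_val(cand) + penalty(cand)
    if (!is.finite(new_obj)) {
      rlang::abort("non-finite objective in maxent fit", class = "scenhab_error_numeric")
    }
    if (new_obj > obj) { # restart acceleration from the last accepted point
      y <- lam
      tprev <- 1
      next
    }
    tcur <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    y <- cand + ((tprev - 1) / tcur) * (cand - lam)
    delta <- obj - new_obj
    lam <- cand
    obj <- new_obj
    tprev <- tcur
    L <- max(L / 2, 1e-6)
    if (delta < tol) {
      # a small step alone can be a stalled accelerated iterate; also require
      # the prox-gradient optimality map to vanish before declaring converged
      gmap <- max(abs(lam - soft(lam - smooth_grad(lam), beta * s)))
      if (gmap < 1e-6) {
        converged <- TRUE
        break
      }
      y <- lam
      tprev <- 1
    }
  }

  eta_bg <- drop(F_bg %*% lam)
  lnZ <- lse(eta_bg)
  q <- exp(eta_bg - lnZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  lnL <- sum(drop(F_pr %*% lam) - lnZ)

  structure(
    list(
      feature_spec = fspec, lambdas = stats::setNames(lam, colnames(F_bg)),
      beta = beta, s = stats::setNames(s, colnames(F_bg)),
      log_partition = lnZ, entropy = H,
      background_size = N, presence_count = n,
      log_likelihood = lnL, objective = obj,
      layer_names = names(stack$layers),
      converged = converged, iterations = iters
    ),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> beta = %g, %d/%d nonzero features, lnL = %.3f (n = %d, N = %d)\n",
    x$beta, sum(x$lambdas != 0), length(x$lambdas), x$log_likelihood,
    x$presence_count, x$background_size
  ))
  invisible(x)
}

#' Project a maxent model onto a landscape
#'
#' `raw` output is the Gibbs density normalised over the projection grid's
#' defined cells (it sums to 1 over them; on the training landscape this is
#' the training normalisation). `logistic` output is the standard
#' interpretable transform `r e^H / (1 + r e^H)` with `H` the entropy of the
#' raw training distribution, so a cell typical of the training background
#' maps to about 0.5 and the uniform model maps to exactly 0.5.
#'
#' @param object A fitted [maxent_fit()] model.
#' @param stack A [focal_stack()] with the same layer set used in training.
#' @param type `"logistic"` (default) or `"raw"`.
#' @param ... Unused.
#' @return A [continuous_grid()] of suitability values in `[0, 1]`.
#' @export
predict.maxent_model <- function(object, stack, type = c("logistic", "raw"), ...) {
  type <- match.arg(type)
  if (!identical(names(stack$layers), object$layer_names)) {
    rlang::abort("stack layers do not match the training layer set",
      class = "scenhab_error_schema"
    )
  }
  cells <- stack_defined_cells(stack)
  P <- stack_matrix(stack, cells)
  FF <- build_features(P, object$feature_spec)
  eta <- drop(FF %*% object$lambdas)
  m <- max(eta)
  lnZ <- m + log(sum(exp(eta - m)))
  raw <- exp(eta - lnZ)
  vals <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
  if (type == "raw") {
    vals[cells] <- raw
  } else {
    odds <- raw * exp(object$entropy)
    vals[cells] <- odds / (1 + odds)
  }
  continuous_grid(vals, stack$spec, name = paste0("suitability_", type))
}

#' Sample-size-corrected Akaike information criterion
#'
#' `AICc = 2K - 2 lnL + 2K(K+1) / (n - K - 1)`, where `lnL` is the sum over
#' presences of the log of the raw (background-normalised) prediction and `K`
#' counts nonzero coefficients. When `n <= K + 1` the correction is undefined
#' and `Inf` is returned with a warning (the model is over-parameterised for
#' the sample).
#'
#' @param log_likelihood Presence log-likelihood sum (lnL).
#' @param n_params Number of nonzero coefficients (K).
#' @param n_presences Presence sample size (n).
#' @return AICc value.
#' @export
aicc <- function(log_likelihood, n_params, n_presences) {
  if (n_presences <= n_params + 1) {
    rlang::warn("n <= K + 1: AICc undefined, returning Inf (over-parameterised model)")
    return(Inf)
  }
  2 * n_params - 2 * log_likelihood +
    2 * n_params * (n_params + 1) / (n_presences - n_params - 1)
}

#' Infer the presence sample size behind a published AICc table
#'
#' Inverts the AICc identity row-wise: given `lnL`, `K` and the printed AICc,
#' `n = 2K(K+1) / (AICc - 2K + 2 lnL) + K + 1`. Each row yields an estimate;
#' the rounded estimates must agree, and the consensus integer is returned.
#' Useful when a selection table prints likelihoods and AICc but not the
#' sample size itself.
#'
#' @param log_likelihood,n_params,aicc_values Equal-length vectors of table
#'   rows.
#' @param tol Allowed deviation of each row's continuous estimate from the
#'   consensus integer (printed tables are rounded; default 0.1).
#' @return The inferred integer sample size.
#' @export
aicc_infer_n <- function(log_likelihood, n_params, aicc_values, tol = 0.1) {
  denom <- aicc_values - 2 * n_params + 2 * log_likelihood
  if (any(denom <= 0)) {
    rlang::abort("AICc rows inconsistent with a finite sample size",
      class = "scenhab_error_parameter"
    )
  }
  n_est <- 2 * n_params * (n_params + 1) / denom + n_params + 1
  n <- round(stats::median(n_est))
  if (any(abs(n_est - n) > tol)) {
    rlang::abort(sprintf(
      "rows disagree on n (estimates: %s)", paste(round(n_est, 3), collapse = ", ")
    ), class = "scenhab_error_parameter")
  }
  as.integer(n)
}

#' Select the regularisation multiplier by AICc
#'
#' Fits one model per candidate `beta`, scores each by AICc (likelihood from
#' raw predictions at presences, K = nonzero coefficients) and returns the
#' minimum-AICc model together with a selection report. Ties are broken
#' toward the larger, more parsimonious `beta`.
#'
#' @inheritParams maxent_fit
#' @param beta_grid Candidate multipliers; the default grid spans 1-19.
#' @return A list with `model` (the winning [maxent_fit()] object) and
#'   `report` (tibble sorted by `beta`: `beta`, `log_likelihood`, `n_params`,
#'   `aicc`, `delta_aicc`).
#' @export
select_beta <- function(presences, background, stack,
                        beta_grid = c(1, 2, 3, 5, 7, 9, 10, 11, 13, 15, 17, 19),
                        features = feature_spec(), tol = 1e-8, max_iter = 20000L) {
  if (length(beta_grid) == 0) {
    rlang::abort("beta_grid must be nonempty", class = "scenhab_error_parameter")
  }
  beta_grid <- sort(beta_grid)
  fits <- lapply(beta_grid, function(b) {
    maxent_fit(presences, background, stack,
      beta = b, features = features,
      tol = tol, max_iter = max_iter
    )
  })
  n <- length(presences)
  report <- purrr::map2_dfr(fits, beta_grid, function(fit, b) {
    K <- sum(fit$lambdas != 0)
    tibble::tibble(
      beta = b, log_likelihood = fit$log_likelihood, n_params = K,
      aicc = suppressWarnings(aicc(fit$log_likelihood, K, n))
    )
  })
  if (all(!is.finite(report$aicc))) {
    rlang::abort("all candidate models are over-parameterised for the sample",
      class = "scenhab_error_selection"
    )
  }
  report$delta_aicc <- report$aicc - min(report$aicc)
  # min AICc; ties toward larger beta
  best_idx <- max(which(report$aicc <= min(report$aicc) + 1e-9))
  list(model = fits[[best_idx]], report = report)
}
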