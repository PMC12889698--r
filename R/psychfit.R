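#' Time-dependent psychometric switch probability
#'
#' Probability of reporting a direction switch as a function of signed
#' test-stimulus viewing time:
#' \deqn{p = \lambda + \frac{1 - 2\lambda}{1 + e^{-\beta_{slope}(x_1 -
#'   (\beta_{ss} x_2 + \beta_{rl} x_3))}}}
#' where `x1` is viewing time in ms, positive on switch and negative on
#' non-switch trials; `x2` the switch indicator; `x3` the right/left
#' indicator; and the lapse rate `lambda` compresses the range to
#' `[lambda, 1 - lambda]`. Bias terms act on the x-intercept.
#'
#' @param params Named list (or vector) with elements `lapse`, `beta_slope`,
#'   `beta_ss`, `beta_rl` (and `beta_tw` for the trial-wise variant).
#' @param cov Data frame of trial covariates with columns `x1`, `x2`, `x3`
#'   (and `x4` for the trial-wise variant).
#' @return Numeric vector of switch-report probabilities.
#' @seealso [predict_switch_prob_trialwise()], [fit_psychometric()]
#' @export
predict_switch_prob <- function(params, cov) {
  p <- as.list(params)
  arg <- p$beta_slope * (cov$x1 - (p$beta_ss * cov$x2 + p$beta_rl * cov$x3))
  p$lapse + (1 - 2 * p$lapse) / (1 + exp(-arg))
}

#' Trial-wise-modulated psychometric switch probability
#'
#' Extends [predict_switch_prob()] with a trial-wise modulator `x4`
#' (normalized firing rate or evoked-pupil residual) whose influence is
#' scaled by `beta_tw`:
#' \deqn{p = \lambda + \frac{1 - 2\lambda}{1 +
#'   e^{-\beta_{slope}\beta_{tw}(x_1 x_4 - (\beta_{ss} x_2 + \beta_{rl} x_3))}}}
#' With `beta_tw = 1` and `x4 = 1` this reduces exactly to the base model.
#'
#' @inheritParams predict_switch_prob
#' @return Numeric vector of switch-report probabilities.
#' @export
predict_switch_prob_trialwise <- function(params, cov) {
  p <- as.list(params)
  arg <- p$beta_slope * p$beta_tw *
    (cov$x1 * cov$x4 - (p$beta_ss * cov$x2 + p$beta_rl * cov$x3))
  p$lapse + (1 - 2 * p$lapse) / (1 + exp(-arg))
}

#' Tjur's coefficient of discrimination
#'
#' Mean predicted probability on trials with outcome 1 minus the mean on
#' trials with outcome 0.
#'
#' @param predicted Vector of predicted probabilities.
#' @param outcomes Binary outcome vector of the same length.
#' @return A value in `[-1, 1]`, or `NA` with a warning if only one outcome
#'   class is present.
#' @export
tjur_r2 <- function(predicted, outcomes) {
  stopifnot(length(predicted) == length(outcomes))
  y <- as.integer(outcomes)
  if (length(unique(y)) < 2L) {
    warning("tjur_r2 undefined: only one outcome class present")
    return(NA_real_)
  }
  mean(predicted[y == 1]) - mean(predicted[y == 0])
}

psych_bounds <- function(variant) {
  lower <- c(lapse = 0, beta_slope = 0, beta_ss = -2000, beta_rl = -2000)
  upper <- c(lapse = 0.45, beta_slope = 0.05, beta_ss = 2000, beta_rl = 2000)
  if (variant == "eq3") {
    lower <- c(lower, beta_tw = -20)
    upper <- c(upper, beta_tw = 20)
  }
  list(lower = lower, upper = upper)
}

# fitted trial-wise model: the modulator scales the effective slope,
# arg = beta_slope * (x1 * (1 + beta_tw * x4) - (beta_ss x2 + beta_rl x3)),
# so beta_tw = 0 (or a constant x4 after standardization) reduces exactly to
# the base model and beta_tw measures how much the slope covaries with x4
predict_slope_modulated <- function(params, cov) {
  p <- as.list(params)
  arg <- p$beta_slope * (cov$x1 * (1 + p$beta_tw * cov$x4) -
                           (p$beta_ss * cov$x2 + p$beta_rl * cov$x3))
  p$lapse + (1 - 2 * p$lapse) / (1 + exp(-arg))
}

psych_negloglik <- function(theta, cov, y, variant) {
  params <- as.list(theta)
  p <- if (variant == "eq1") predict_switch_prob(params, cov)
       else predict_slope_modulated(params, cov)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log1p(-p))
}

#' Fit the time-dependent psychometric function
#'
#' Maximum-likelihood fit of the lapse-logistic choice model by bounded
#' quasi-Newton optimization (L-BFGS-B) from multiple random starts. The
#' lapse rate is bounded in `[0, 0.45]` and the slope in `[0, 0.05]` 1/ms.
#'
#' For the trial-wise variant (`"eq3"`), `x4` is z-scored before fitting and
#' the effective slope is modeled as `beta_slope * (1 + beta_tw * x4)` (the
#' bias terms are not modulated), so `beta_tw` quantifies how much the
#' psychometric slope covaries with the trial-wise signal and the model
#' reduces exactly to the base variant when `beta_tw = 0` or `x4` is
#' constant. See [predict_switch_prob_trialwise()] for the alternative
#' product parameterization of the same covariates, which does not nest the
#' base model once `x4` is standardized.
#'
#' @param trials Data frame with columns `x1` (signed viewing time, ms),
#'   `x2` (switch indicator), `x3` (right indicator), `y` (reported switch),
#'   and `x4` for the `"eq3"` variant. See [trial_covariates()].
#' @param variant `"eq1"` (base model) or `"eq3"` (trial-wise modulator).
#' @param n_starts Number of optimizer starts (first start is deterministic,
#'   the rest are random within bounds).
#' @param condition Optional label stored with the fit.
#' @return An object of class `psychfit` with components `params`,
#'   `log_likelihood`, `tjur_r2`, `n_trials`, `converged`, `boundary`,
#'   `variant`, `condition`, `fitted`, and `data`; supports `coef`,
#'   `logLik`, `predict`, `residuals`, `simulate`, `summary`, and `plot`.
#' @examples
#' set.seed(1)
#' tr <- simulate_psychometric_trials(
#'   list(lapse = 0.05, beta_slope = 0.012, beta_ss = 150, beta_rl = 20), 500)
#' fit <- fit_psychometric(tr, n_starts = 3)
#' coef(fit)
#' @export
fit_psychometric <- function(trials, variant = c("eq1", "eq3"),
                             n_starts = 10, condition = NA_character_) {
  variant <- match.arg(variant)
  needed <- c("x1", "x2", "x3", "y", if (variant == "eq3") "x4")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols))
    stop("trials is missing columns: ", paste(missing_cols, collapse = ", "))
  if (variant == "eq3") trials <- trials[is.finite(trials$x4), , drop = FALSE]
  if (nrow(trials) < 20L)
    stop("need at least 20 trials to fit the psychometric function")
  y <- as.integer(trials$y)
  if (length(unique(y)) < 2L)
    stop("cannot fit: all trials have the same outcome class")

  x4_scale <- NULL
  if (variant == "eq3") {
    s <- stats::sd(trials$x4)
    if (is.finite(s) && s > 1e-8) {
      x4_scale <- c(center = mean(trials$x4), scale = s)
      trials$x4 <- (trials$x4 - x4_scale["center"]) / x4_scale["scale"]
    } else {
      # constant modulator carries no trial-wise information: the
      # standardized covariate is defined as 0, reducing to the base model
      trials$x4 <- 0
    }
  }

  b <- psych_bounds(variant)
  start0 <- c(lapse = 0.05, beta_slope = 0.005, beta_ss = 0, beta_rl = 0,
              if (variant == "eq3") c(beta_tw = 0))
  names(start0) <- names(b$lower)
  # parameters span several orders of magnitude (1/ms slope vs ms biases);
  # without scaling, finite-difference steps are far too coarse for the slope
  parscale <- c(lapse = 0.05, beta_slope = 0.005, beta_ss = 100,
                beta_rl = 100, if (variant == "eq3") c(beta_tw = 0.5))
  names(parscale) <- names(b$lower)

  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    start <- if (s == 1L) start0 else {
      st <- c(lapse = stats::runif(1, 0, 0.2),
              beta_slope = stats::runif(1, 1e-4, 0.03),
              beta_ss = stats::runif(1, -300, 300),
              beta_rl = stats::runif(1, -300, 300),
              if (variant == "eq3") c(beta_tw = stats::runif(1, -1, 1)))
      names(st) <- names(b$lower)
      st
    }
    res <- tryCatch(
      stats::optim(start, psych_negloglik, cov = trials, y = y,
                   variant = variant, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = 500, parscale = parscale)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")

  theta <- best$par
  tol <- 1e-8
  at_bound <- theta <= b$lower + tol | theta >= b$upper - tol
  # bias bounds are nuisance limits; only lapse/slope/tw bounds are reported
  boundary <- any(at_bound[!names(theta) %in% c("beta_ss", "beta_rl")])

  params <- as.list(theta)
  fitted <- if (variant == "eq1") predict_switch_prob(params, trials)
            else predict_slope_modulated(params, trials)

  structure(
    list(
      params = params,
      log_likelihood = -best$value,
      tjur_r2 = tjur_r2(fitted, y),
      n_trials = nrow(trials),
      converged = best$convergence == 0L,
      boundary = boundary,
      variant = variant,
      condition = condition,
      x4_scale = x4_scale,
      fitted = fitted,
      data = trials
    ),
    class = "psychfit"
  )
}

#' @export
coef.psychfit <- function(object, ...) unlist(object$params)

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$params), nobs = object$n_trials,
            class = "logLik")
}

#' Predict switch-report probabilities from a fitted psychometric model
#'
#' @param object A `psychfit` object.
#' @param newdata Optional data frame of covariates (`x1`, `x2`, `x3`, and
#'   `x4` for the trial-wise variant, on the original scale); defaults to the
#'   training data.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (object$variant == "eq3" && !is.null(object$x4_scale)) {
    newdata$x4 <- (newdata$x4 - object$x4_scale["center"]) /
      object$x4_scale["scale"]
  }
  if (object$variant == "eq1") predict_switch_prob(object$params, newdata)
  else predict_slope_modulated(object$params, newdata)
}

#' @export
residuals.psychfit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- as.integer(object$data$y) - object$fitted
  if (type == "pearson")
    r <- r / sqrt(object$fitted * (1 - object$fitted))
  r
}

#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_trials
  out <- as.data.frame(
    replicate(nsim, stats::rbinom(n, 1L, object$fitted))
  )
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.psychfit <- function(x, ...) {
  cat(sprintf("Psychometric fit (%s%s), %d trials\n", x$variant,
              if (!is.na(x$condition)) paste0(", ", x$condition) else "",
              x$n_trials))
  print(round(unlist(x$params), 5))
  cat(sprintf("logLik %.2f | Tjur R2 %.3f | converged: %s%s\n",
              x$log_likelihood, x$tjur_r2, x$converged,
              if (x$boundary) " | at parameter bound" else ""))
  invisible(x)
}

#' @export
summary.psychfit <- function(object, ...) {
  out <- list(
    coefficients = unlist(object$params),
    log_likelihood = object$log_likelihood,
    tjur_r2 = object$tjur_r2,
    n_trials = object$n_trials,
    converged = object$converged,
    boundary = object$boundary,
    variant = object$variant,
    condition = object$condition
  )
  class(out) <- "summary.psychfit"
  out
}

#' @export
print.summary.psychfit <- function(x, ...) {
  cat(sprintf("Time-dependent psychometric function (variant %s)\n", x$variant))
  if (!is.na(x$condition)) cat("Condition:", x$condition, "\n")
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 5))
  cat(sprintf("\nn = %d, logLik = %.2f, Tjur pseudo-R2 = %.3f\n",
              x$n_trials, x$log_likelihood, x$tjur_r2))
  if (!x$converged) cat("Warning: optimizer did not converge\n")
  if (x$boundary) cat("Note: solution lies on a parameter bound\n")
  invisible(x)
}

#' Plot a fitted psychometric function
#'
#' Plots the observed proportion of switch reports in signed-duration bins
#' together with the fitted curve (evaluated at `x2` implied by the sign of
#' `x1` and the modal `x3`).
#'
#' @param x A `psychfit` object.
#' @param n_bins Number of signed-duration bins for the observed proportions.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the binned proportions.
#' @export
plot.psychfit <- function(x, n_bins = 12, ...) {
  d <- x$data
  edges <- seq(min(d$x1), max(d$x1), length.out = n_bins + 1L)
  bin <- cut(d$x1, edges, include.lowest = TRUE)
  obs <- tapply(as.integer(d$y), bin, mean)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  x3_mode <- as.numeric(names(which.max(table(d$x3))))
  grid <- seq(min(d$x1), max(d$x1), length.out = 200)
  nd <- data.frame(x1 = grid, x2 = as.integer(grid > 0), x3 = x3_mode)
  if (x$variant == "eq3") nd$x4 <- 1
  graphics::plot(mid, obs, ylim = c(0, 1),
                 xlab = "signed viewing time (ms)",
                 ylab = "P(report switch)", pch = 16, ...)
  graphics::lines(grid, predict(x, nd), col = "steelblue", lwd = 2)
  invisible(data.frame(mid = mid, prop = as.numeric(obs)))
}

#' Build psychometric covariates from a simulated trials table
#'
#' Maps the trials table written by [generate_session()] to the covariates
#' of the psychometric model: `x1` is the test duration signed by trial type
#' (positive on switch trials), `x2` the switch indicator, `x3` the
#' rightward-test indicator, and `y` the reported-switch outcome.
#'
#' @param trials Trials data frame with columns `test_duration_ms`,
#'   `is_switch`, `test_direction`, `reported_switch` (plus any extra
#'   columns, which are carried through).
#' @return Data frame with `x1`, `x2`, `x3`, `y` and the original columns.
#' @export
trial_covariates <- function(trials) {
  stopifnot(all(c("test_duration_ms", "is_switch", "test_direction",
                  "reported_switch") %in% names(trials)))
  trials$x1 <- trials$test_duration_ms * ifelse(trials$is_switch, 1, -1)
  trials$x2 <- as.integer(trials$is_switch)
  trials$x3 <- as.integer(trials$test_direction == "right")
  trials$y <- as.integer(trials$reported_switch)
  trials
}

#' Simulate trials directly from psychometric parameters
#'
#' Draws covariates matching the task design (durations from the truncated
#' exponential, equal switch/non-switch and right/left probabilities) and
#' Bernoulli outcomes from the model, for parameter-recovery studies.
#'
#' @param params Named list of psychometric parameters (see
#'   [predict_switch_prob()]; include `beta_tw` and supply `x4` draws via
#'   `x4_sd` for the trial-wise variant).
#' @param n Number of trials.
#' @param config A [task_config()] used for the duration distribution.
#' @param variant `"eq1"` or `"eq3"`.
#' @param x4_sd SD of the standard-normal trial-wise modulator (eq3 only).
#' @return Covariate data frame with outcome column `y`.
#' @export
simulate_psychometric_trials <- function(params, n, config = task_config(),
                                         variant = c("eq1", "eq3"),
                                         x4_sd = 1) {
  variant <- match.arg(variant)
  dur <- draw_test_duration(config, n)
  x2 <- stats::rbinom(n, 1L, 0.5)
  cov <- data.frame(
    x1 = dur * ifelse(x2 == 1L, 1, -1),
    x2 = x2,
    x3 = stats::rbinom(n, 1L, 0.5)
  )
  if (variant == "eq3") cov$x4 <- stats::rnorm(n, 0, x4_sd)
  p <- if (variant == "eq1") predict_switch_prob(params, cov)
       else predict_switch_prob_trialwise(params, cov)
  cov$y <- stats::rbinom(n, 1L, p)
  cov
}

#' Per-session pseudo-R-squared from separate condition fits
#'
#' Fits the psychometric model separately to LSF and HSF trials and returns
#' the mean of the two Tjur pseudo-R-squared values (the per-session fit
#' summary used throughout).
#'
#' @param trials Covariate data frame including a `condition` column.
#' @param variant Model variant passed to [fit_psychometric()].
#' @param n_starts Optimizer starts per condition fit.
#' @return List with `r2` (mean across conditions) and the per-condition
#'   `fits`.
#' @export
fit_by_condition <- function(trials, variant = "eq1", n_starts = 10) {
  stopifnot("condition" %in% names(trials))
  conds <- intersect(c("LSF", "HSF"), unique(trials$condition))
  fits <- lapply(conds, function(cc) {
    fit_psychometric(trials[trials$condition == cc, , drop = FALSE],
                     variant = variant, n_starts = n_starts, condition = cc)
  })
  names(fits) <- conds
  list(r2 = mean(vapply(fits, function(f) f$tjur_r2, numeric(1))),
       fits = fits)
}

#' Shuffled-null distribution of the session pseudo-R-squared
#'
#' Breaks the association between test-stimulus durations and switch /
#' non-switch trial types by permuting `|x1|` across the session's trials
#' (keeping `x2`, `x3`, `y`, and condition labels fixed and re-signing the
#' permuted durations by trial type), refits both condition models per
#' iteration, and records the mean Tjur pseudo-R-squared.
#'
#' @param trials Covariate data frame including `condition`.
#' @param variant Model variant.
#' @param n_iter Number of shuffle iterations.
#' @param n_starts Optimizer starts per fit (null refits are cheap, so a
#'   small number is typical here).
#' @return Numeric vector of length `n_iter` (iterations whose fits failed
#'   are `NA`, with a warning).
#' @export
shuffled_null_r2 <- function(trials, variant = "eq1", n_iter = 100,
                             n_starts = 2) {
  out <- numeric(n_iter)
  n_fail <- 0L
  for (i in seq_len(n_iter)) {
    sh <- trials
    perm <- sample.int(nrow(sh))
    sh$x1 <- abs(sh$x1)[perm] * ifelse(sh$x2 == 1L, 1, -1)
    out[i] <- tryCatch(
      fit_by_condition(sh, variant = variant, n_starts = n_starts)$r2,
      error = function(e) {
        n_fail <<- n_fail + 1L
        NA_real_
      }
    )
  }
  if (n_fail > 0L)
    warning(sprintf("%d of %d null iterations failed and were skipped",
                    n_fail, n_iter))
  out
}

#' Choice accuracy in viewing-duration bins
#'
#' Bins trials by test-stimulus duration (half-open bins `[low, high)`) and
#' tabulates the proportion of correct choices per bin.
#'
#' @param trials Data frame with `test_duration_ms` (or signed `x1`) and
#'   `correct`; `is_switch` is required when `switch_only = TRUE`.
#' @param bin_edges Ordered numeric vector of bin edges (ms).
#' @param switch_only Restrict to switch trials.
#' @return Data frame with `bin_low`, `bin_high`, `n`, `prop_correct`
#'   (`NA` for empty bins).
#' @export
accuracy_by_duration <- function(trials, bin_edges, switch_only = FALSE) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  if (switch_only) trials <- trials[as.logical(trials$is_switch), , drop = FALSE]
  dur <- if ("test_duration_ms" %in% names(trials)) trials$test_duration_ms
         else abs(trials$x1)
  correct <- as.logical(trials$correct)
  n_bin <- length(bin_edges) - 1L
  out <- data.frame(bin_low = bin_edges[-length(bin_edges)],
                    bin_high = bin_edges[-1],
                    n = integer(n_bin), prop_correct = NA_real_)
  for (i in seq_len(n_bin)) {
    sel <- dur >= out$bin_low[i] & dur < out$bin_high[i]
    out$n[i] <- sum(sel)
    if (out$n[i] > 0L) out$prop_correct[i] <- mean(correct[sel])
  }
  out
}

#' Running average of a choice sequence
#'
#' Centered moving mean with edge truncation (the window shrinks near the
#' ends of the sequence).
#'
#' @param y Numeric or logical outcome sequence.
#' @param window Odd window length (trials).
#' @return Numeric vector the same length as `y`.
#' @export
running_choice_average <- function(y, window = 5) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be odd and >= 1")
  y <- as.numeric(y)
  n <- length(y)
  h <- (window - 1L) / 2L
  vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}
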