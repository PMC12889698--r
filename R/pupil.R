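#' Five-step pupil preprocessing pipeline
#'
#' Applies, in order: (1) linear interpolation of missing samples, (2) a
#' first-order 5 Hz low-pass Butterworth filter (causal, single forward
#' pass), (3) removal and linear interpolation of samples exceeding +/- 2
#' session SDs from the session mean (statistics computed once on the
#' concatenated post-filter samples), (4) subtraction of the
#' session-averaged response time course (per-sample mean across trials,
#' all conditions), and (5) z-scoring against the mean and SD of the
#' session's concatenated samples. Traces that are entirely missing, have
#' fewer than two valid samples, or have (numerically) zero variance are
#' excluded with a message.
#'
#' @param session A `pupil_session` from [simulate_pupil()] (or an
#'   equivalently structured list).
#' @param steps Integer subset of `1:5`, the steps to apply (in order).
#' @param outlier_sd Outlier threshold in session SDs.
#' @param cutoff_hz Low-pass cutoff frequency (Hz).
#' @return An object of class `clean_pupil`: list with `samples` (kept
#'   trials x samples, `NA`-padded past each trial's end), `kept` (original
#'   trial indices), `lengths`, `t0`, `fs`, `conditions`, `steps_applied`,
#'   `session_mean`, `session_sd` (the z-scoring scale, for mapping
#'   coefficients back to input units).
#' @export
preprocess_pupil <- function(session, steps = 1:5, outlier_sd = 2,
                             cutoff_hz = 5) {
  stopifnot(all(steps %in% 1:5))
  x <- session$samples
  lens <- session$lengths
  n <- nrow(x)
  fs <- session$fs

  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    tr <- x[i, seq_len(lens[i])]
    if (sum(is.finite(tr)) < 2L) keep[i] <- FALSE
  }
  if (any(!keep))
    message(sprintf("preprocess_pupil: excluded %d trace(s) with < 2 valid samples",
                    sum(!keep)))

  interp_na <- function(tr) {
    if (!anyNA(tr)) return(tr)
    idx <- seq_along(tr)
    ok <- is.finite(tr)
    stats::approx(idx[ok], tr[ok], xout = idx, rule = 2)$y
  }

  # step 1: linear interpolation of missing values
  if (1 %in% steps) {
    for (i in which(keep)) {
      tr <- x[i, seq_len(lens[i])]
      x[i, seq_len(lens[i])] <- interp_na(tr)
    }
  }

  # step 2: first-order low-pass Butterworth, forward pass only;
  # the first sample is subtracted before filtering to avoid a step
  # transient from the filter's zero initial state
  if (2 %in% steps) {
    bf <- signal::butter(1, cutoff_hz / (fs / 2), type = "low")
    for (i in which(keep)) {
      tr <- x[i, seq_len(lens[i])]
      x[i, seq_len(lens[i])] <-
        as.numeric(signal::filter(bf, tr - tr[1])) + tr[1]
    }
  }

  # step 3: +/- outlier_sd rejection against session statistics, single pass
  if (3 %in% steps) {
    all_samp <- unlist(lapply(which(keep), function(i) x[i, seq_len(lens[i])]))
    mu <- mean(all_samp, na.rm = TRUE)
    sdv <- stats::sd(all_samp, na.rm = TRUE)
    for (i in which(keep)) {
      tr <- x[i, seq_len(lens[i])]
      out <- is.finite(tr) & abs(tr - mu) > outlier_sd * sdv
      if (any(out)) {
        tr[out] <- NA_real_
        x[i, seq_len(lens[i])] <- interp_na(tr)
      }
    }
  }

  # zero-variance traces cannot survive z-scoring
  if (5 %in% steps) {
    for (i in which(keep)) {
      if (stats::sd(x[i, seq_len(lens[i])], na.rm = TRUE) < 1e-10) {
        keep[i] <- FALSE
        message(sprintf("preprocess_pupil: excluded constant trace %d", i))
      }
    }
  }
  if (!any(keep)) stop("no traces left after preprocessing exclusions")

  # step 4: subtract the session-averaged time course
  if (4 %in% steps) {
    avg <- colMeans(x[keep, , drop = FALSE], na.rm = TRUE)
    for (i in which(keep)) {
      sel <- seq_len(lens[i])
      x[i, sel] <- x[i, sel] - avg[sel]
    }
  }

  # step 5: z-score against the concatenated session samples
  session_mean <- NA_real_
  session_sd <- NA_real_
  if (5 %in% steps) {
    all_samp <- unlist(lapply(which(keep), function(i) x[i, seq_len(lens[i])]))
    session_mean <- mean(all_samp, na.rm = TRUE)
    session_sd <- stats::sd(all_samp, na.rm = TRUE)
    if (!is.finite(session_sd) || session_sd < 1e-10)
      stop("zero variance across the session at the z-scoring step")
    for (i in which(keep)) {
      sel <- seq_len(lens[i])
      x[i, sel] <- (x[i, sel] - session_mean) / session_sd
    }
  }

  structure(
    list(samples = x[keep, , drop = FALSE],
         kept = which(keep),
         lengths = lens[keep],
         t0 = session$t0, fs = fs,
         conditions = session$conditions[keep],
         steps_applied = sort(steps),
         session_mean = session_mean, session_sd = session_sd),
    class = "clean_pupil"
  )
}

#' @export
print.clean_pupil <- function(x, ...) {
  cat(sprintf("clean_pupil: %d traces, steps applied: %s\n",
              nrow(x$samples), paste(x$steps_applied, collapse = ",")))
  invisible(x)
}

# column indices for a time window (ms relative to adapting onset)
pupil_window_idx <- function(clean, window) {
  ms_per_sample <- 1000 / clean$fs
  i0 <- clean$t0 + round(window[1] / ms_per_sample)
  i1 <- clean$t0 + round(window[2] / ms_per_sample) - 1L
  i0:i1
}

#' Baseline pupil diameter
#'
#' Mean pupil diameter per trial over the 100 ms window immediately
#' preceding motion-stimulus onset.
#'
#' @param clean A `clean_pupil` object.
#' @param window Length-2 numeric window (ms relative to adapting onset);
#'   must lie inside every trace.
#' @return Numeric vector, one value per kept trial.
#' @export
baseline_pupil <- function(clean, window = c(-100, 0)) {
  idx <- pupil_window_idx(clean, window)
  if (min(idx) < 1L || max(idx) > ncol(clean$samples))
    stop("baseline window lies outside the traces")
  rowMeans(clean$samples[, idx, drop = FALSE], na.rm = TRUE)
}

#' Sliding-window regression of pupil diameter on baseline and context
#'
#' For each 100 ms window (10 ms steps) of the adapting epoch, regresses the
#' windowed mean pupil diameter across trials on an intercept, the trial's
#' baseline pupil diameter, and the context-stability indicator
#' (1 = LSF, 0 = HSF) by ordinary least squares. `beta_cxt` estimates the
#' LSF - HSF difference in evoked diameter while controlling for baseline;
#' per-window two-sided p-values for `beta_cxt` are reported uncorrected.
#'
#' @param clean A `clean_pupil` object.
#' @param baselines Per-trial baseline values (defaults to
#'   [baseline_pupil()]).
#' @param conditions Per-trial condition labels (defaults to those stored in
#'   `clean`).
#' @param window_ms,step_ms Window length and step (ms).
#' @param t_range Range of window centers (ms relative to adapting onset).
#' @return An object of class `window_regression`: data frame with
#'   `time_ms`, `beta0`, `beta_baseline`, `beta_cxt`, `p_cxt`, `n`. Windows
#'   with a rank-deficient design (e.g. a single condition) are `NA`.
#' @export
sliding_regression <- function(clean, baselines = NULL, conditions = NULL,
                               window_ms = 100, step_ms = 10,
                               t_range = c(0, 2400)) {
  if (is.null(baselines)) baselines <- baseline_pupil(clean)
  if (is.null(conditions)) conditions <- clean$conditions
  n <- nrow(clean$samples)
  stopifnot(length(baselines) == n, length(conditions) == n)
  if (length(unique(conditions)) < 2L || min(table(conditions)) < 3L)
    warning("sliding_regression: fewer than 3 trials in a condition; windows will be undefined")

  centers <- seq(t_range[1], t_range[2], by = step_ms)
  half <- window_ms / 2
  X <- cbind(1, baselines, as.integer(conditions == "LSF"))
  qx <- qr(X)
  out <- data.frame(time_ms = centers, beta0 = NA_real_,
                    beta_baseline = NA_real_, beta_cxt = NA_real_,
                    p_cxt = NA_real_, n = n)
  rank_ok <- qx$rank == 3L
  if (rank_ok) xtx_inv_33 <- chol2inv(qr.R(qx))[3, 3]
  ms_per_sample <- 1000 / clean$fs
  for (j in seq_along(centers)) {
    idx <- pupil_window_idx(clean, centers[j] + c(-half, half))
    if (min(idx) < 1L || max(idx) > ncol(clean$samples)) next
    y <- rowMeans(clean$samples[, idx, drop = FALSE], na.rm = TRUE)
    if (!rank_ok || anyNA(y)) next
    beta <- qr.coef(qx, y)
    res <- y - X %*% beta
    df <- n - 3L
    sigma2 <- sum(res^2) / df
    se <- sqrt(sigma2 * xtx_inv_33)
    out$beta0[j] <- beta[1]
    out$beta_baseline[j] <- beta[2]
    out$beta_cxt[j] <- beta[3]
    out$p_cxt[j] <- if (se > 0) 2 * stats::pt(-abs(beta[3] / se), df) else NA
  }
  class(out) <- c("window_regression", "data.frame")
  out
}

#' Evoked-pupil residual covariate
#'
#' Residualizes each trial's pre-test pupil diameter (mean over the 500 ms
#' preceding test onset) against the trial's whole-trace average diameter
#' and baseline diameter, by a single per-session OLS fit. The residuals are
#' the trial-wise evoked-pupil covariate of the modulated psychometric
#' model.
#'
#' @param pretest Per-trial mean pupil over the pre-test window.
#' @param trace_avg Per-trial whole-trace average pupil.
#' @param baseline Per-trial baseline pupil.
#' @return Numeric vector of residuals (sum to 0 across trials).
#' @export
evoked_residual <- function(pretest, trace_avg, baseline) {
  n <- length(pretest)
  stopifnot(length(trace_avg) == n, length(baseline) == n)
  if (n < 3L) stop("evoked_residual needs at least 3 trials")
  X <- cbind(1, trace_avg, baseline)
  if (qr(X)$rank < 3L)
    stop("evoked_residual: rank-deficient design (collinear regressors)")
  as.numeric(stats::lm.fit(X, pretest)$residuals)
}

#' Per-trial pupil covariates for a session
#'
#' Convenience wrapper computing, from a cleaned session, the baseline,
#' pre-test mean, whole-trace average, and evoked residual per trial.
#'
#' @param clean A `clean_pupil` object.
#' @param pretest_window Pre-test window (ms relative to adapting onset).
#' @param baseline_window Baseline window (ms relative to adapting onset).
#' @return Data frame with `trial` (original trial index), `baseline`,
#'   `pretest`, `trace_avg`, `evoked_resid`.
#' @export
pupil_trialwise <- function(clean, pretest_window = c(1900, 2400),
                            baseline_window = c(-100, 0)) {
  idx <- pupil_window_idx(clean, pretest_window)
  pretest <- rowMeans(clean$samples[, idx, drop = FALSE], na.rm = TRUE)
  trace_avg <- vapply(seq_len(nrow(clean$samples)), function(i) {
    mean(clean$samples[i, seq_len(clean$lengths[i])], na.rm = TRUE)
  }, numeric(1))
  baseline <- baseline_pupil(clean, baseline_window)
  data.frame(
    trial = clean$kept,
    baseline = baseline,
    pretest = pretest,
    trace_avg = trace_avg,
    evoked_resid = evoked_residual(pretest, trace_avg, baseline)
  )
}
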