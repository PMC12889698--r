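#' Sliding-window firing rates
#'
#' Converts per-trial spike-time vectors into a trial-by-time firing-rate
#' matrix on a sliding-window grid (100 ms windows advanced in 10 ms steps
#' by default). Rates are indexed by window center; each window counts
#' spikes in the half-open interval `[t - w/2, t + w/2)` and divides by the
#' window length. Windows that are not fully contained in a trial's valid
#' observation range are `NA`; trials whose valid range is shorter than one
#' window are excluded (all-`NA` row) with a message.
#'
#' @param spikes List of numeric spike-time vectors (ms), one per trial,
#'   already aligned to the requested event.
#' @param t_range Length-2 numeric: range of window centers (ms).
#' @param alignment Label for the alignment event (`"adapt_onset"` or
#'   `"test_onset"`), stored as metadata.
#' @param window_ms,step_ms Window length and step (ms).
#' @param valid_ranges Optional list (or 2-column matrix) of per-trial valid
#'   observation ranges (ms); defaults to unrestricted.
#' @return An object of class `rate_series`: list with `time_grid`, `rates`
#'   (trials x windows, spikes/s), `alignment`, `window_ms`, `step_ms`,
#'   `baseline_per_trial`, `norm_factor`, `is_normalized`.
#' @export
estimate_rates <- function(spikes, t_range, alignment = "adapt_onset",
                           window_ms = 100, step_ms = 10,
                           valid_ranges = NULL) {
  stopifnot(is.list(spikes), length(t_range) == 2L, window_ms > 0,
            step_ms > 0)
  centers <- seq(t_range[1], t_range[2], by = step_ms)
  half <- window_ms / 2
  n <- length(spikes)
  rates <- matrix(NA_real_, n, length(centers))
  excluded <- integer(0)
  for (i in seq_len(n)) {
    vr <- if (is.null(valid_ranges)) c(-Inf, Inf)
          else if (is.matrix(valid_ranges)) valid_ranges[i, ]
          else valid_ranges[[i]]
    if (diff(vr) < window_ms) { excluded <- c(excluded, i); next }
    ok <- centers - half >= vr[1] & centers + half <= vr[2]
    s <- spikes[[i]]
    if (!all(is.finite(s))) stop("spike times must be finite")
    cnt <- vapply(centers[ok], function(tc) {
      sum(s >= tc - half & s < tc + half)
    }, numeric(1))
    rates[i, ok] <- cnt / (window_ms / 1000)
  }
  if (length(excluded))
    message(sprintf("estimate_rates: excluded %d trial(s) shorter than one window",
                    length(excluded)))
  structure(
    list(time_grid = centers, rates = rates, alignment = alignment,
         window_ms = window_ms, step_ms = step_ms,
         baseline_per_trial = NULL, norm_factor = NULL,
         is_normalized = FALSE, excluded_trials = excluded),
    class = "rate_series"
  )
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("rate_series: %d trials x %d windows (%g ms / %g ms), aligned to %s%s\n",
              nrow(x$rates), length(x$time_grid), x$window_ms, x$step_ms,
              x$alignment,
              if (x$is_normalized) ", baseline-subtracted & normalized" else ""))
  invisible(x)
}

# trial-averaged trace (NA-aware)
mean_trace <- function(series) colMeans(series$rates, na.rm = TRUE)

# mean of the trial-averaged trace over window centers in [lo, hi)
epoch_mean <- function(series, window) {
  sel <- series$time_grid >= window[1] & series$time_grid < window[2]
  mean(mean_trace(series)[sel], na.rm = TRUE)
}

# per-trial epoch means
epoch_mean_per_trial <- function(series, window) {
  sel <- series$time_grid >= window[1] & series$time_grid < window[2]
  rowMeans(series$rates[, sel, drop = FALSE], na.rm = TRUE)
}

#' Baseline-subtract and normalize a rate series
#'
#' Subtracts, trial by trial, the firing rate in the 100 ms window
#' immediately preceding adapting-stimulus onset, then divides by the
#' maximum of the trial-averaged baseline-subtracted trace over the adapting
#' epoch. To keep conditions comparable, the normalization factor can be
#' supplied (e.g. the maximum across both conditions, see
#' [normalization_factor()]); when computed internally it is the maximum
#' over `norm_epoch`. A non-positive factor flags the unit and leaves the
#' series unnormalized.
#'
#' @param series A `rate_series` aligned to adapting onset (or any series
#'   sharing the trials of such a series, with `baseline` supplied).
#' @param baseline_window Length-2 numeric, baseline window (ms relative to
#'   adapting onset); must precede onset.
#' @param norm_epoch Length-2 numeric, epoch over which the normalization
#'   maximum is taken.
#' @param norm_factor Optional externally computed normalization factor
#'   (spikes/s).
#' @param baseline Optional per-trial baseline rates (spikes/s), e.g. taken
#'   from the adapt-aligned series when normalizing a test-aligned one.
#' @return A `rate_series` with baseline removed, `norm_factor` recorded,
#'   and `is_normalized` set (or `flagged = TRUE` when the factor is not
#'   positive).
#' @export
baseline_subtract_normalize <- function(series,
                                        baseline_window = c(-100, 0),
                                        norm_epoch = c(0, 2400),
                                        norm_factor = NULL,
                                        baseline = NULL) {
  stopifnot(inherits(series, "rate_series"))
  if (baseline_window[2] > 0)
    stop("baseline window must precede adapting-stimulus onset")
  if (is.null(baseline)) {
    half <- series$window_ms / 2
    sel <- series$time_grid - half >= baseline_window[1] &
      series$time_grid + half <= baseline_window[2]
    if (!any(sel))
      stop("no rate window fully inside the baseline window; supply `baseline`")
    baseline <- rowMeans(series$rates[, sel, drop = FALSE], na.rm = TRUE)
  }
  out <- series
  out$rates <- series$rates - baseline
  out$baseline_per_trial <- baseline
  if (is.null(norm_factor)) {
    sel <- series$time_grid >= norm_epoch[1] & series$time_grid < norm_epoch[2]
    norm_factor <- max(mean_trace(out)[sel], na.rm = TRUE)
  }
  out$norm_factor <- norm_factor
  if (!is.finite(norm_factor) || norm_factor <= 0) {
    out$flagged <- TRUE
    warning("non-positive normalization factor; unit flagged, series left unnormalized")
    return(out)
  }
  out$rates <- out$rates / norm_factor
  out$is_normalized <- TRUE
  out
}

#' Shared normalization factor across conditions
#'
#' Maximum, across the supplied (baseline-subtracted) adapt-aligned series,
#' of each condition's trial-averaged trace over the adapting epoch. Using
#' the cross-condition maximum for both conditions keeps their normalized
#' responses comparable.
#'
#' @param series_list List of `rate_series` (one per condition), already
#'   baseline-subtracted or raw with `baseline` handled by the caller.
#' @param norm_epoch Epoch over which the maximum is taken (ms).
#' @return A single normalization factor (spikes/s).
#' @export
normalization_factor <- function(series_list, norm_epoch = c(0, 2400)) {
  max(vapply(series_list, function(s) {
    sel <- s$time_grid >= norm_epoch[1] & s$time_grid < norm_epoch[2]
    max(mean_trace(s)[sel], na.rm = TRUE)
  }, numeric(1)))
}

#' Direction selectivity of a unit
#'
#' Mean difference between trial-averaged responses to preferred and null
#' motion over the early adapting epoch (100-500 ms after adapting onset by
#' default, the stimulus period shared by both conditions allowing for
#' response delay).
#'
#' @param series_pref,series_null `rate_series` objects aligned to adapting
#'   onset, for preferred-initial and null-initial trials.
#' @param window Length-2 numeric window (ms).
#' @return Selectivity in the units of the input series (spikes/s, or
#'   normalized rate).
#' @export
direction_selectivity <- function(series_pref, series_null,
                                  window = c(100, 500)) {
  stopifnot(identical(series_pref$time_grid, series_null$time_grid))
  sel <- series_pref$time_grid >= window[1] & series_pref$time_grid < window[2]
  mean(mean_trace(series_pref)[sel] - mean_trace(series_null)[sel],
       na.rm = TRUE)
}

#' Area under the ROC curve for preferred versus null responses
#'
#' Probability that a randomly drawn preferred-trial value exceeds a
#' randomly drawn null-trial value, with ties counted one half (the
#' normalized rank-sum statistic).
#'
#' @param pref_samples,null_samples Numeric response samples.
#' @return Value in `[0, 1]`, or `NA` with a warning if either side is
#'   empty after removing `NA`s.
#' @export
roc_area <- function(pref_samples, null_samples) {
  x <- pref_samples[is.finite(pref_samples)]
  y <- null_samples[is.finite(null_samples)]
  if (length(x) == 0L || length(y) == 0L) {
    warning("roc_area undefined: empty sample")
    return(NA_real_)
  }
  r <- rank(c(x, y))  # midranks handle ties as 1/2
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}

#' Sliding ROC discriminability over time
#'
#' Applies [roc_area()] per window column of a pair of rate series sharing a
#' time grid.
#'
#' @param series_pref,series_null `rate_series` objects on the same grid.
#' @return An object of class `roc_series`: data frame with `time_ms`,
#'   `auc`, `n_pref`, `n_null`.
#' @export
sliding_roc <- function(series_pref, series_null) {
  stopifnot(identical(series_pref$time_grid, series_null$time_grid))
  grid <- series_pref$time_grid
  out <- data.frame(time_ms = grid, auc = NA_real_,
                    n_pref = 0L, n_null = 0L)
  for (j in seq_along(grid)) {
    p <- series_pref$rates[, j]
    q <- series_null$rates[, j]
    p <- p[is.finite(p)]; q <- q[is.finite(q)]
    out$n_pref[j] <- length(p); out$n_null[j] <- length(q)
    if (length(p) && length(q))
      out$auc[j] <- roc_area(p, q)
  }
  class(out) <- c("roc_series", "data.frame")
  out
}

#' Cohen's d between two response samples
#'
#' Two-sample pooled-SD form: `(mean(x) - mean(y)) / s_pooled`.
#'
#' @param x,y Numeric samples (at least 2 values each).
#' @return Cohen's d, or `NA` with a warning if the pooled SD is zero.
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("cohens_d needs at least 2 finite values per sample")
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  if (sp == 0) {
    warning("cohens_d undefined: zero pooled SD")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sp
}

#' Effect size of repeated preferred-motion presentations
#'
#' For each presentation window, computes Cohen's d of per-trial responses
#' relative to the first (adapting-stimulus onset) presentation.
#'
#' @param series A `rate_series` (typically baseline-subtracted and
#'   normalized, adapt-aligned).
#' @param presentation_windows List of length-2 numeric windows (ms), one
#'   per preferred presentation, in presentation order; response-latency
#'   offsets should already be applied.
#' @return Numeric vector of Cohen's d values, one per presentation (the
#'   first is 0 by construction).
#' @export
presentation_effect_size <- function(series, presentation_windows) {
  stopifnot(inherits(series, "rate_series"), length(presentation_windows) >= 1)
  samples <- lapply(presentation_windows, function(w)
    epoch_mean_per_trial(series, w))
  ref <- samples[[1]]
  vapply(samples, function(s) {
    if (identical(s, ref)) 0 else cohens_d(s, ref)
  }, numeric(1))
}

#' Classify a unit as adapting or facilitating
#'
#' Threshold method: compares mean normalized activity between the first
#' preferred-motion presentation (200-400 ms after adapting onset) and
#' preferred motion during the test stimulus (50-500 ms after test onset),
#' separately for LSF and HSF; the unit is `adapting` if the response
#' decreased by more than the threshold (2.5% of the normalized maximum)
#' under both conditions, `facilitating` if it increased by more than the
#' threshold under both, otherwise `unclassified`.
#'
#' Slope method: fits a line to per-presentation peak preferred responses
#' per condition and classifies by the common sign when both slopes differ
#' significantly from zero (p < 0.05); conflicting or non-significant slopes
#' give `unclassified`.
#'
#' @param adapt_series Named list (`LSF`, `HSF`) of normalized adapt-aligned
#'   `rate_series` restricted to trials whose first adapting segment is the
#'   preferred direction.
#' @param test_series Named list (`LSF`, `HSF`) of normalized test-aligned
#'   `rate_series` restricted to preferred-direction test trials.
#' @param method `"threshold_2p5"` or `"slope_fit"`.
#' @param threshold Response-change criterion (fraction of normalized max).
#' @param first_window,test_window Comparison windows (ms).
#' @param peaks For the slope method: named list (`LSF`, `HSF`) of
#'   per-presentation peak response vectors (see [presentation_peaks()]).
#' @return An object of class `unit_classification`: list with `label`,
#'   `delta_fraction_lsf`, `delta_fraction_hsf`, `method` (and `slopes`,
#'   `p_values` for the slope method).
#' @export
classify_unit <- function(adapt_series = NULL, test_series = NULL,
                          method = c("threshold_2p5", "slope_fit"),
                          threshold = 0.025,
                          first_window = c(200, 400),
                          test_window = c(50, 500),
                          peaks = NULL) {
  method <- match.arg(method)
  if (method == "threshold_2p5") {
    stopifnot(all(c("LSF", "HSF") %in% names(adapt_series)),
              all(c("LSF", "HSF") %in% names(test_series)))
    delta <- vapply(c("LSF", "HSF"), function(cc) {
      epoch_mean(test_series[[cc]], test_window) -
        epoch_mean(adapt_series[[cc]], first_window)
    }, numeric(1))
    label <- if (all(delta < -threshold)) "adapting"
             else if (all(delta > threshold)) "facilitating"
             else "unclassified"
    res <- list(label = label, delta_fraction_lsf = delta[["LSF"]],
                delta_fraction_hsf = delta[["HSF"]], method = method)
  } else {
    stopifnot(all(c("LSF", "HSF") %in% names(peaks)))
    fits <- lapply(peaks, function(p) {
      if (length(p) < 3L) return(c(slope = NA_real_, p = NA_real_))
      sm <- summary(stats::lm(p ~ seq_along(p)))$coefficients
      c(slope = sm[2, 1], p = sm[2, 4])
    })
    slopes <- vapply(fits, `[[`, numeric(1), "slope")
    pvals <- vapply(fits, `[[`, numeric(1), "p")
    sig <- is.finite(pvals) & pvals < 0.05
    label <- if (all(sig) && all(slopes < 0)) "adapting"
             else if (all(sig) && all(slopes > 0)) "facilitating"
             else "unclassified"
    res <- list(label = label,
                delta_fraction_lsf = NA_real_,
                delta_fraction_hsf = NA_real_,
                method = method, slopes = slopes, p_values = pvals)
  }
  class(res) <- "unit_classification"
  res
}

#' @export
print.unit_classification <- function(x, ...) {
  cat(sprintf("unit classification (%s): %s\n", x$method, x$label))
  invisible(x)
}

#' Per-presentation peak responses
#'
#' Maximum of the trial-averaged trace within each preferred-segment window
#' (latency offset applied), used by the slope-based classifier.
#'
#' @param series Adapt-aligned (optionally extended to the test epoch)
#'   `rate_series`.
#' @param segments Data frame with `start_ms`, `end_ms` for the preferred
#'   presentations, in order.
#' @param latency_ms Response latency offset (ms).
#' @return Numeric vector of per-presentation peaks.
#' @export
presentation_peaks <- function(series, segments, latency_ms = 50) {
  tr <- mean_trace(series)
  vapply(seq_len(nrow(segments)), function(i) {
    sel <- series$time_grid >= segments$start_ms[i] + latency_ms &
      series$time_grid < segments$end_ms[i] + latency_ms
    if (!any(sel)) return(NA_real_)
    max(tr[sel], na.rm = TRUE)
  }, numeric(1))
}

#' Single-exponential fit to three binned responses
#'
#' Fits `v(t) = a + b * exp(-t / tau)` through three (time, value) points
#' (an exact interpolation when the points are consistent with a positive
#' time constant). Flat or non-monotone triples, or triples requiring a
#' non-positive tau, are flagged non-convergent.
#'
#' @param times Three bin-center times (ms); defaults correspond to response
#'   bins 200-330, 340-470, and 480-600 ms after test onset.
#' @param values Three response values.
#' @return An object of class `exp_fit`: list with `a`, `b`, `tau`,
#'   `bin_centers`, `converged`.
#' @export
fit_exponential_tau <- function(values, times = c(265, 405, 540)) {
  stopifnot(length(values) == 3L, length(times) == 3L)
  if (anyDuplicated(times)) stop("bin times must be distinct")
  o <- order(times)
  t <- times[o]; v <- values[o]
  d1 <- v[1] - v[2]; d2 <- v[2] - v[3]
  bad <- function() {
    structure(list(a = NA_real_, b = NA_real_, tau = NA_real_,
                   bin_centers = t, converged = FALSE), class = "exp_fit")
  }
  # flat (b ~ 0) or non-monotone data admit no positive tau
  if (abs(d1) < 1e-12 && abs(d2) < 1e-12) return(bad())
  if (d1 * d2 <= 0) return(bad())
  target <- d1 / d2
  g <- function(log_tau) {
    tau <- exp(log_tau)
    e <- exp(-t / tau)
    (e[1] - e[2]) / (e[2] - e[3]) - target
  }
  lo <- log(1); hi <- log(1e6)
  if (g(lo) * g(hi) > 0) return(bad())
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-12)
  tau <- exp(root$root)
  e <- exp(-t / tau)
  b <- d1 / (e[1] - e[2])
  a <- v[1] - b * e[1]
  structure(list(a = a, b = b, tau = tau, bin_centers = t, converged = TRUE),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("exponential fit: a = %.4g, b = %.4g, tau = %.1f ms\n",
                x$a, x$b, x$tau))
  else cat("exponential fit: not convergent (flat or inconsistent data)\n")
  invisible(x)
}

#' LSF minus HSF condition difference
#'
#' Elementwise LSF - HSF difference of matched per-unit (or per-session)
#' metrics; names are matched when present and mismatches are rejected.
#'
#' @param metric_lsf,metric_hsf Numeric vectors (optionally named).
#' @return Numeric vector of differences, named like the inputs.
#' @export
condition_difference <- function(metric_lsf, metric_hsf) {
  if (!is.null(names(metric_lsf)) && !is.null(names(metric_hsf))) {
    if (!setequal(names(metric_lsf), names(metric_hsf)))
      stop("unmatched identifiers between conditions")
    metric_hsf <- metric_hsf[names(metric_lsf)]
  } else if (length(metric_lsf) != length(metric_hsf)) {
    stop("condition metrics must have equal length")
  }
  metric_lsf - metric_hsf
}

#' Trial-wise firing rate during the test stimulus
#'
#' Mean rate in the test window with a fixed response delay, per trial: the
#' trial-wise neural covariate of the modulated psychometric model.
#'
#' @param spikes List of spike-time vectors aligned to adapting onset.
#' @param schedules List of matching `stim_schedule`s.
#' @param delay_ms Response delay (ms).
#' @return Numeric vector of rates (spikes/s), one per trial.
#' @export
test_epoch_rate <- function(spikes, schedules, delay_ms = 50) {
  stopifnot(length(spikes) == length(schedules))
  vapply(seq_along(spikes), function(i) {
    sch <- schedules[[i]]
    a <- sch$test_onset_ms + delay_ms
    b <- sch$test_onset_ms + sch$test_duration_ms + delay_ms
    sum(spikes[[i]] >= a & spikes[[i]] < b) / (b - a) * 1000
  }, numeric(1))
}
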