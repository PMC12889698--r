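#' Parameters of the synthetic pupil generator
#'
#' Describes per-trial pupil traces (arbitrary units, sampled at 1000 Hz)
#' built from: a tonic baseline that follows an AR(1) process across trials;
#' a stereotyped luminance constriction at stimulus onset (gamma-shaped
#' impulse response); a context-dependent evoked component whose amplitude
#' ramps up over the adapting epoch and saturates before test onset; white
#' measurement noise; and blink gaps marked as missing. The evoked amplitude
#' is reduced in proportion to the trial's baseline
#' (`baseline_evoked_coupling`), emulating the inverse relation between
#' baseline and evoked diameter.
#'
#' @param sample_rate_hz Sampling rate (Hz).
#' @param baseline_ar_coef AR(1) coefficient of the across-trial baseline.
#' @param baseline_noise_sd Innovation SD of the baseline process (a.u.).
#' @param constriction_amp Peak amplitude of the onset constriction (a.u.).
#' @param evoked_amp_lsf,evoked_amp_hsf Saturating evoked amplitude per
#'   condition (a.u.).
#' @param evoked_ramp Ramp rate of the evoked component (fraction of the
#'   saturating amplitude per ms; the default saturates at 1800 ms, before
#'   test onset).
#' @param kernel_shape Length-2 `(shape, scale-ms)` of the gamma-form
#'   constriction impulse response.
#' @param blink_rate Blink events per second.
#' @param blink_duration_ms Length-2 range of blink-gap durations (ms).
#' @param measurement_noise_sd White-noise SD (a.u.).
#' @param arousal_center_ms,arousal_width_ms Center and SD (ms, relative to
#'   adapting onset) of the Gaussian time course with which the optional
#'   per-trial latent arousal signal is expressed: an anticipatory
#'   component peaking at test onset, distinct from the slow
#'   condition-evoked ramp.
#' @param baseline_evoked_coupling Strength of the inverse baseline-to-evoked
#'   relation (a.u. of evoked amplitude per a.u. of baseline).
#' @param pre_onset_ms Pre-stimulus time included in each trace (ms).
#' @return An object of class `pupil_params`.
#' @export
pupil_params <- function(sample_rate_hz = 1000,
                         baseline_ar_coef = 0.5,
                         baseline_noise_sd = 0.2,
                         constriction_amp = 0.5,
                         evoked_amp_lsf = 0.6,
                         evoked_amp_hsf = 0.4,
                         evoked_ramp = 1 / 1800,
                         kernel_shape = c(2, 150),
                         blink_rate = 0.1,
                         blink_duration_ms = c(100, 300),
                         measurement_noise_sd = 0.15,
                         baseline_evoked_coupling = 1.5,
                         arousal_center_ms = 2400,
                         arousal_width_ms = 300,
                         pre_onset_ms = 500) {
  stopifnot(sample_rate_hz > 0, blink_rate >= 0,
            length(kernel_shape) == 2L, all(kernel_shape > 0),
            length(blink_duration_ms) == 2L,
            diff(blink_duration_ms) >= 0)
  structure(as.list(environment()), class = "pupil_params")
}

#' Simulate per-trial pupil traces for a session
#'
#' Generates one trace per schedule (aligned to adapting-stimulus onset,
#' spanning `pre_onset_ms` before onset through the end of the test epoch),
#' with the components described in [pupil_params()]. Blink gaps are
#' returned as `NA` samples flagged in the missing mask.
#'
#' @param schedules List of `stim_schedule`s, one per trial, in session
#'   order.
#' @param params A [pupil_params()] object.
#' @param arousal Optional per-trial additive evoked amplitude (a.u.), e.g.
#'   a latent arousal signal shared with the behavior generator.
#' @return An object of class `pupil_session`: list with `samples`
#'   (trials x samples matrix, `NA`-padded past each trial's end and `NA`
#'   inside blink gaps), `missing` (logical matrix of blink gaps), `t0`
#'   (column index of the adapting-onset sample), `fs`, `conditions`, and
#'   `baseline_true` (the generated tonic baselines).
#' @export
simulate_pupil <- function(schedules, params = pupil_params(),
                           arousal = NULL) {
  n <- length(schedules)
  stopifnot(n >= 1)
  if (is.null(arousal)) arousal <- numeric(n)
  stopifnot(length(arousal) == n)
  fs <- params$sample_rate_hz
  ms_per_sample <- 1000 / fs
  pre <- round(params$pre_onset_ms / ms_per_sample)

  lens <- vapply(schedules, function(s) {
    pre + round((s$test_onset_ms + s$test_duration_ms) / ms_per_sample)
  }, numeric(1))
  width <- max(lens)
  samples <- matrix(NA_real_, n, width)
  miss <- matrix(FALSE, n, width)

  # stationary start for the across-trial AR(1) baseline
  sd_stat <- params$baseline_noise_sd /
    sqrt(max(1 - params$baseline_ar_coef^2, 1e-8))
  b <- stats::rnorm(1, 0, sd_stat)
  baselines <- numeric(n)

  shape <- params$kernel_shape[1]
  scale <- params$kernel_shape[2]
  peak_t <- (shape - 1) * scale  # mode of the gamma density
  kpeak <- stats::dgamma(max(peak_t, 1e-6), shape, scale = scale)

  for (i in seq_len(n)) {
    sch <- schedules[[i]]
    len <- lens[i]
    t_ms <- (seq_len(len) - pre - 1) * ms_per_sample  # rel. adapting onset
    ramp <- pmin(pmax(params$evoked_ramp * t_ms, 0), 1)
    amp_cond <- if (sch$condition == "LSF") params$evoked_amp_lsf
                else params$evoked_amp_hsf
    amp <- amp_cond - params$baseline_evoked_coupling * b
    anticip <- arousal[i] *
      exp(-0.5 * ((t_ms - params$arousal_center_ms) /
                    params$arousal_width_ms)^2)
    constr <- ifelse(t_ms >= 0,
                     -params$constriction_amp *
                       stats::dgamma(pmax(t_ms, 1e-6), shape, scale = scale) /
                       kpeak,
                     0)
    trace <- b + amp * ramp + anticip + constr +
      stats::rnorm(len, 0, params$measurement_noise_sd)

    if (params$blink_rate > 0) {
      n_blinks <- stats::rpois(1, params$blink_rate * len * ms_per_sample / 1000)
      if (n_blinks > 0) {
        for (bs in stats::runif(n_blinks, 0, len * ms_per_sample)) {
          bd <- stats::runif(1, params$blink_duration_ms[1],
                             params$blink_duration_ms[2])
          idx <- which(t_ms + params$pre_onset_ms >= bs &
                         t_ms + params$pre_onset_ms < bs + bd)
          if (length(idx)) {
            trace[idx] <- NA_real_
            miss[i, idx] <- TRUE
          }
        }
      }
    }
    samples[i, seq_len(len)] <- trace
    baselines[i] <- b
    b <- params$baseline_ar_coef * b +
      stats::rnorm(1, 0, params$baseline_noise_sd)
  }

  structure(
    list(samples = samples, missing = miss, lengths = as.integer(lens),
         t0 = pre + 1L, fs = fs,
         conditions = vapply(schedules, `[[`, character(1), "condition"),
         baseline_true = baselines),
    class = "pupil_session"
  )
}

#' @export
print.pupil_session <- function(x, ...) {
  cat(sprintf("pupil_session: %d trials x %d samples at %g Hz (onset at sample %d), %.2f%% missing\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$t0,
              100 * mean(x$missing[!is.na(x$samples) | x$missing])))
  invisible(x)
}
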