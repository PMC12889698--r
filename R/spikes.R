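#' Parameters of a simulated direction-tuned unit
#'
#' Describes an MT-like unit whose firing follows an inhomogeneous Poisson
#' process: `base_rate` throughout, plus `pref_gain` (scaled by a
#' presentation-dependent adaptation gain) during preferred-direction
#' stimulus segments and `null_gain` during null-direction segments, both
#' shifted by a response latency. The adaptation gain starts at 1 and is
#' multiplied by `(1 - adapt_step)` after every preferred presentation, with
#' the step set by the context-stability condition; positive steps give an
#' adapting profile, negative steps a facilitating one.
#'
#' @param base_rate Background rate (spikes/s).
#' @param pref_gain Added rate during preferred segments at gain 1 (spikes/s).
#' @param null_gain Added rate during null segments (spikes/s; typically
#'   negative, i.e. suppression below baseline).
#' @param latency_ms Response latency (ms).
#' @param adapt_step_lsf,adapt_step_hsf Fractional gain change per preferred
#'   presentation in each condition (`|step| < 1`).
#' @param profile `"adapting"` (steps > 0) or `"facilitating"` (steps < 0);
#'   checked against the signs of the steps.
#' @param pref_direction The unit's preferred direction, `"right"` or
#'   `"left"`.
#' @return An object of class `unit_params`.
#' @export
unit_params <- function(base_rate = 10, pref_gain = 40, null_gain = -5,
                        latency_ms = 50,
                        adapt_step_lsf = 0.05, adapt_step_hsf = 0.15,
                        profile = c("adapting", "facilitating"),
                        pref_direction = "right") {
  profile <- match.arg(profile)
  stopifnot(base_rate >= 0, abs(adapt_step_lsf) < 1, abs(adapt_step_hsf) < 1,
            pref_direction %in% c("right", "left"))
  steps <- c(adapt_step_lsf, adapt_step_hsf)
  if (profile == "adapting" && any(steps < 0))
    stop("adapting profile requires adapt steps >= 0")
  if (profile == "facilitating" && any(steps > 0))
    stop("facilitating profile requires adapt steps <= 0")
  structure(
    list(base_rate = base_rate, pref_gain = pref_gain, null_gain = null_gain,
         latency_ms = latency_ms, adapt_step_lsf = adapt_step_lsf,
         adapt_step_hsf = adapt_step_hsf, profile = profile,
         pref_direction = pref_direction),
    class = "unit_params"
  )
}

#' Simulate a spike train for one trial
#'
#' Inhomogeneous Poisson spike generation over a piecewise-constant rate
#' built from the stimulus schedule: stimulus-driven rate changes are shifted
#' by the unit's latency, and the preferred-segment gain is updated
#' multiplicatively after each preferred presentation (the test segment
#' counts as a presentation and uses the gain reached by the end of the
#' adapting epoch). Negative instantaneous rates are clipped at zero and
#' flagged via the `"clipped"` attribute.
#'
#' @param schedule A `stim_schedule`.
#' @param params A [unit_params()] object.
#' @param t_pre_ms Pre-adapting-onset background time to simulate (ms).
#' @param test_gain_scale Extra multiplier on the test-segment preferred
#'   gain (used to inject trial-wise gain fluctuations).
#' @return Sorted numeric vector of spike times (ms, aligned to adapting
#'   onset) with attributes `gain_sequence` (per-presentation gains) and
#'   `clipped`.
#' @export
simulate_spike_train <- function(schedule, params, t_pre_ms = 300,
                                 test_gain_scale = 1) {
  stopifnot(inherits(schedule, "stim_schedule"),
            inherits(params, "unit_params"))
  step <- if (schedule$condition == "LSF") params$adapt_step_lsf
          else params$adapt_step_hsf
  lat <- params$latency_ms

  seg <- schedule$segments
  seg <- rbind(seg, data.frame(
    start_ms = schedule$test_onset_ms,
    end_ms = schedule$test_onset_ms + schedule$test_duration_ms,
    direction = schedule$test_direction
  ))
  is_pref <- seg$direction == params$pref_direction

  gain <- 1
  gains <- numeric(0)
  pieces <- data.frame(start = numeric(0), end = numeric(0), rate = numeric(0))
  for (i in seq_len(nrow(seg))) {
    extra <- if (is_pref[i]) {
      g <- gain * if (i == nrow(seg)) test_gain_scale else 1
      gains <- c(gains, g)
      gain <- gain * (1 - step)
      g * params$pref_gain
    } else {
      params$null_gain
    }
    pieces <- rbind(pieces, data.frame(
      start = seg$start_ms[i] + lat, end = seg$end_ms[i] + lat,
      rate = params$base_rate + extra))
  }

  t_end <- schedule$test_onset_ms + schedule$test_duration_ms + lat
  # background pieces: before the first stimulus response and after offset
  edges <- sort(unique(c(-t_pre_ms, pieces$start, pieces$end, t_end)))
  rate_at <- function(t) {
    r <- params$base_rate
    hit <- pieces$start <= t & t < pieces$end
    if (any(hit)) r <- pieces$rate[which(hit)[1]]
    r
  }
  clipped <- FALSE
  spikes <- numeric(0)
  for (i in seq_len(length(edges) - 1L)) {
    a <- edges[i]; b <- edges[i + 1L]
    r <- rate_at(a)
    if (r < 0) { r <- 0; clipped <- TRUE }
    n <- stats::rpois(1L, r * (b - a) / 1000)
    if (n > 0L) spikes <- c(spikes, stats::runif(n, a, b))
  }
  structure(sort(spikes), gain_sequence = gains, clipped = clipped)
}
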