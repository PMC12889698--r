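#' Leaky-accumulator parameters
#'
#' Parameters of the linear leaky evidence accumulator used to generate
#' choices: dA = (-k A + drift_gain * coherence * d(t)) dt + noise dW, where
#' d(t) is +1 for rightward and -1 for leftward motion and the leak k is set
#' by the context-stability condition. A larger leak discounts older evidence
#' faster and produces a shallower time-dependent psychometric slope.
#'
#' @param leak_lsf,leak_hsf Leak rates (1/ms) for the LSF and HSF conditions.
#' @param drift_gain Evidence units per ms per unit coherence.
#' @param noise_sd Diffusion coefficient (evidence units per sqrt(ms)).
#' @param adapt_atten_lsf,adapt_atten_hsf Initial fractional attenuation of
#'   the test-epoch drift gain in each condition (0 = none), emulating
#'   adaptation-attenuated evidence encoding that recovers during the test
#'   epoch. This recovering attenuation - stronger after the unstable (HSF)
#'   adaptor - is what slows the approach to asymptotic accuracy and yields
#'   the shallower fitted psychometric slope at HSF; a larger leak alone
#'   only lowers the long-duration asymptote. Set both to 0 for a pure-leak
#'   context effect.
#' @param recovery_tau_ms Time constant of the exponential recovery of the
#'   attenuated gain during the test epoch (ms).
#' @param lapse_prob Probability of flipping the choice irrespective of the
#'   accumulator state.
#' @return An object of class `accumulator_params`.
#' @export
accumulator_params <- function(leak_lsf = 0.002, leak_hsf = 0.003,
                               drift_gain = 0.01, noise_sd = 0.12,
                               adapt_atten_lsf = 0.1,
                               adapt_atten_hsf = 0.85,
                               recovery_tau_ms = 800,
                               lapse_prob = 0.05) {
  stopifnot(leak_lsf >= 0, leak_hsf >= 0, noise_sd >= 0,
            adapt_atten_lsf >= 0, adapt_atten_lsf < 1,
            adapt_atten_hsf >= 0, adapt_atten_hsf < 1,
            recovery_tau_ms > 0)
  if (lapse_prob < 0 || lapse_prob > 0.5)
    stop("lapse_prob must be in [0, 0.5]")
  structure(
    list(leak_lsf = leak_lsf, leak_hsf = leak_hsf, drift_gain = drift_gain,
         noise_sd = noise_sd, adapt_atten_lsf = adapt_atten_lsf,
         adapt_atten_hsf = adapt_atten_hsf,
         recovery_tau_ms = recovery_tau_ms, lapse_prob = lapse_prob),
    class = "accumulator_params"
  )
}

# signed evidence (+1 right, -1 left) on a time grid covering [t0, t1)
schedule_evidence <- function(schedule, times, coherence_adapt,
                              coherence_test) {
  ev <- numeric(length(times))
  seg <- schedule$segments
  for (i in seq_len(nrow(seg))) {
    in_seg <- times >= seg$start_ms[i] & times < seg$end_ms[i]
    ev[in_seg] <- coherence_adapt * if (seg$direction[i] == "right") 1 else -1
  }
  t_on <- schedule$test_onset_ms
  in_test <- times >= t_on & times < t_on + schedule$test_duration_ms
  ev[in_test] <- coherence_test * if (schedule$test_direction == "right") 1 else -1
  ev
}

#' Simulate one choice from the leaky accumulator
#'
#' Euler-integrates the leaky accumulator over the test epoch (optionally
#' also the adapting epoch, with no reset at test onset) and reports the
#' sign of the terminal state as the choice, flipped with probability
#' `lapse_prob`.
#'
#' @param schedule A `stim_schedule` from [generate_schedule()].
#' @param params An [accumulator_params()] object.
#' @param config A [task_config()] supplying the coherences.
#' @param dt_ms Euler step (ms); must be positive.
#' @param include_adapt If `TRUE`, integration starts at adapting onset so
#'   adapting-epoch evidence carries into the test epoch; default `FALSE`
#'   (test-epoch-only integration).
#' @param drift_scale Trial-wise multiplier on `drift_gain` (used to couple
#'   behavior to simulated neural gain or arousal).
#' @return List with `choice` ("right"/"left"), `correct`,
#'   `reported_switch` (choice differs from the final adapting direction),
#'   and `terminal_A`.
#' @export
simulate_choice <- function(schedule, params, config = task_config(),
                            dt_ms = 1, include_adapt = FALSE,
                            drift_scale = 1) {
  stopifnot(inherits(schedule, "stim_schedule"),
            inherits(params, "accumulator_params"))
  if (dt_ms <= 0) stop("dt_ms must be positive")

  k <- if (schedule$condition == "LSF") params$leak_lsf else params$leak_hsf
  a0 <- if (schedule$condition == "LSF") params$adapt_atten_lsf
        else params$adapt_atten_hsf
  t0 <- if (include_adapt) 0 else schedule$test_onset_ms
  t1 <- schedule$test_onset_ms + schedule$test_duration_ms
  times <- seq(t0, t1 - dt_ms / 2, by = dt_ms)
  ev <- schedule_evidence(schedule, times, config$adapt_coherence,
                          config$test_coherence)

  # adaptation-attenuated gain recovering over the test epoch
  gain_t <- 1 - a0 * exp(-pmax(times - schedule$test_onset_ms, 0) /
                           params$recovery_tau_ms)
  drift <- params$drift_gain * gain_t * drift_scale * ev * dt_ms
  noise <- if (params$noise_sd > 0) {
    stats::rnorm(length(times), 0, params$noise_sd * sqrt(dt_ms))
  } else {
    numeric(length(times))
  }
  A <- 0
  decay <- 1 - k * dt_ms
  for (i in seq_along(times)) {
    A <- A * decay + drift[i] + noise[i]
  }

  choice <- if (A > 0) "right" else if (A < 0) "left" else
    sample(c("right", "left"), 1L)
  if (params$lapse_prob > 0 && stats::runif(1) < params$lapse_prob)
    choice <- opposite_direction(choice)

  last_adapt_dir <- schedule$segments$direction[nrow(schedule$segments)]
  list(
    choice = choice,
    correct = choice == schedule$test_direction,
    reported_switch = choice != last_adapt_dir,
    terminal_A = A
  )
}
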