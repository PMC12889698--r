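#' Task configuration for the switching-adaptor motion task
#'
#' Builds and validates the parameters of the two-epoch random-dot motion
#' task: a 2400 ms adapting epoch in which motion direction reverses at a low
#' (LSF; 1 switch at 1200 ms) or high (HSF; 5 switches, every 400 ms)
#' frequency, followed by a test epoch whose duration is drawn from a
#' truncated exponential distribution. Both conditions give 1200 ms of
#' exposure to each adapting direction; the test direction differs from the
#' final adapting direction with probability `epoch_switch_prob`.
#'
#' @param adapt_duration_ms Duration of the adapting epoch (ms).
#' @param lsf_switch_times_ms Switch times within the adapting epoch for the
#'   low switch-frequency condition (ms after adapting onset).
#' @param hsf_switch_period_ms Period of direction switches for the high
#'   switch-frequency condition (ms); switches occur at every multiple of
#'   this period strictly inside the adapting epoch.
#' @param test_duration_mean_ms Mean of the pre-truncation exponential
#'   distribution of test durations (ms).
#' @param test_duration_bounds_ms Length-2 numeric, truncation bounds (ms).
#' @param epoch_switch_prob Probability that the test direction differs from
#'   the final adapting direction.
#' @param adapt_coherence Motion coherence of the adapting stimulus (fraction).
#' @param test_coherence Motion coherence of the test stimulus (fraction).
#' @param block_structure `"blocked"` (conditions in two contiguous runs) or
#'   `"interleaved"`.
#' @param seed Optional integer seed recorded with the configuration and used
#'   by [generate_session()].
#' @return An object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' cfg$adapt_duration_ms
#' @export
task_config <- function(adapt_duration_ms = 2400,
                        lsf_switch_times_ms = 1200,
                        hsf_switch_period_ms = 400,
                        test_duration_mean_ms = 500,
                        test_duration_bounds_ms = c(100, 1200),
                        epoch_switch_prob = 0.5,
                        adapt_coherence = 0.70,
                        test_coherence = 0.55,
                        block_structure = c("blocked", "interleaved"),
                        seed = NULL) {
  block_structure <- match.arg(block_structure)
  stopifnot(
    is.numeric(adapt_duration_ms), length(adapt_duration_ms) == 1L,
    adapt_duration_ms > 0,
    is.numeric(lsf_switch_times_ms), length(lsf_switch_times_ms) >= 1L,
    is.numeric(hsf_switch_period_ms), hsf_switch_period_ms > 0,
    length(test_duration_bounds_ms) == 2L,
    is.numeric(test_duration_mean_ms), test_duration_mean_ms > 0
  )
  if (any(lsf_switch_times_ms <= 0 | lsf_switch_times_ms >= adapt_duration_ms))
    stop("lsf_switch_times_ms must lie strictly inside (0, adapt_duration_ms)")
  if (diff(test_duration_bounds_ms) < 0)
    stop("test_duration_bounds_ms must be ordered (low, high)")
  if (epoch_switch_prob < 0 || epoch_switch_prob > 1)
    stop("epoch_switch_prob must be in [0, 1]")
  if (adapt_coherence < 0 || adapt_coherence > 1 ||
      test_coherence < 0 || test_coherence > 1)
    stop("coherences are fractions in [0, 1]")
  structure(
    list(
      adapt_duration_ms = adapt_duration_ms,
      lsf_switch_times_ms = sort(lsf_switch_times_ms),
      hsf_switch_period_ms = hsf_switch_period_ms,
      test_duration_mean_ms = test_duration_mean_ms,
      test_duration_bounds_ms = as.numeric(test_duration_bounds_ms),
      epoch_switch_prob = epoch_switch_prob,
      adapt_coherence = adapt_coherence,
      test_coherence = test_coherence,
      block_structure = block_structure,
      seed = seed
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("Switching-adaptor task configuration\n")
  cat(sprintf("  adapting epoch : %g ms (coherence %.2f)\n",
              x$adapt_duration_ms, x$adapt_coherence))
  cat(sprintf("  LSF switches   : %s ms\n",
              paste(x$lsf_switch_times_ms, collapse = ", ")))
  cat(sprintf("  HSF switches   : every %g ms\n", x$hsf_switch_period_ms))
  cat(sprintf("  test epoch     : exp(mean %g) truncated to [%g, %g] ms (coherence %.2f)\n",
              x$test_duration_mean_ms, x$test_duration_bounds_ms[1],
              x$test_duration_bounds_ms[2], x$test_coherence))
  cat(sprintf("  P(epoch switch): %g, %s blocks\n",
              x$epoch_switch_prob, x$block_structure))
  invisible(x)
}

opposite_direction <- function(direction) {
  ifelse(direction == "right", "left", "right")
}

#' Draw test-stimulus durations
#'
#' Samples durations from an exponential distribution with mean
#' `test_duration_mean_ms`, restricted to `test_duration_bounds_ms` (the
#' doubly truncated exponential). Collapsed bounds return the bound.
#'
#' @param config A [task_config()].
#' @param n Number of draws.
#' @return Numeric vector of durations in ms, all within the bounds.
#' @export
draw_test_duration <- function(config, n = 1L) {
  stopifnot(inherits(config, "task_config"), n >= 0)
  a <- config$test_duration_bounds_ms[1]
  b <- config$test_duration_bounds_ms[2]
  m <- config$test_duration_mean_ms
  if (b - a <= .Machine$double.eps * max(1, a)) return(rep(a, n))
  # inverse CDF of the exponential conditioned on [a, b]
  u <- stats::runif(n)
  fa <- exp(-a / m)
  fb <- exp(-b / m)
  -m * log(fa - u * (fa - fb))
}

#' Generate one stimulus schedule
#'
#' Lays out the alternating-direction adapting segments for the requested
#' context-stability condition, then appends a test segment whose direction
#' flips from the final adapting direction with probability
#' `epoch_switch_prob` and whose duration is drawn by [draw_test_duration()].
#'
#' @param condition `"LSF"` or `"HSF"`.
#' @param initial_direction `"right"` or `"left"`, direction of the first
#'   adapting segment.
#' @param config A [task_config()].
#' @return An object of class `stim_schedule`: a list with `condition`,
#'   `segments` (data.frame `start_ms`, `end_ms`, `direction`; contiguous,
#'   alternating, spanning exactly the adapting epoch), `test_onset_ms`,
#'   `test_duration_ms`, `test_direction`, and `is_switch_trial`.
#' @examples
#' set.seed(1)
#' sched <- generate_schedule("HSF", "right", task_config())
#' sched$segments
#' @export
generate_schedule <- function(condition, initial_direction = "right",
                              config = task_config()) {
  if (!condition %in% c("LSF", "HSF"))
    stop("condition must be 'LSF' or 'HSF'")
  if (!initial_direction %in% c("right", "left"))
    stop("initial_direction must be 'right' or 'left'")
  stopifnot(inherits(config, "task_config"))

  dur <- config$adapt_duration_ms
  switch_times <- if (condition == "LSF") {
    config$lsf_switch_times_ms
  } else {
    p <- config$hsf_switch_period_ms
    n_sw <- ceiling(dur / p) - 1L  # switches strictly inside (0, dur)
    p * seq_len(n_sw)
  }
  edges <- c(0, switch_times, dur)
  n_seg <- length(edges) - 1L
  dirs <- rep(c(initial_direction, opposite_direction(initial_direction)),
              length.out = n_seg)
  segments <- data.frame(
    start_ms = edges[-length(edges)],
    end_ms = edges[-1],
    direction = dirs,
    stringsAsFactors = FALSE
  )

  last_dir <- dirs[n_seg]
  is_switch <- stats::runif(1) < config$epoch_switch_prob
  test_dir <- if (is_switch) opposite_direction(last_dir) else last_dir

  structure(
    list(
      condition = condition,
      segments = segments,
      test_onset_ms = dur,
      test_duration_ms = draw_test_duration(config, 1L),
      test_direction = test_dir,
      is_switch_trial = is_switch
    ),
    class = "stim_schedule"
  )
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("%s schedule: %d adapting segments over %g ms, test %s for %.0f ms (%s trial)\n",
              x$condition, nrow(x$segments), x$test_onset_ms,
              x$test_direction, x$test_duration_ms,
              if (x$is_switch_trial) "switch" else "non-switch"))
  invisible(x)
}

# per-direction exposure during the adapting epoch, in ms
adapting_exposure <- function(schedule) {
  seg <- schedule$segments
  vapply(c(right = "right", left = "left"), function(d) {
    sum(seg$end_ms[seg$direction == d] - seg$start_ms[seg$direction == d])
  }, numeric(1))
}
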