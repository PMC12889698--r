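sine_session <- function(freq_hz, n_sec = 8, fs = 1000, amp = 1) {
  n <- n_sec * fs
  tr <- amp * sin(2 * pi * freq_hz * (0:(n - 1)) / fs)
  list(samples = matrix(tr, 1), missing = matrix(FALSE, 1, n),
       lengths = n, t0 = 1L, fs = fs, conditions = "LSF")
}

test_that("low-pass filter has unit DC gain and the analytic rolloff", {
  # DC: a constant trace passes unchanged through the filtering step
  flat <- sine_session(1); flat$samples[] <- 3
  out <- preprocess_pupil(flat, steps = 2)
  expect_equal(as.numeric(out$samples), rep(3, 8000), tolerance = 1e-10)

  gain_at <- function(f) {
    s <- sine_session(f)
    o <- preprocess_pupil(s, steps = 2)
    # steady-state amplitude from the second half of the trace
    tail_in <- s$samples[1, 4001:8000]
    tail_out <- o$samples[1, 4001:8000]
    sd(tail_out) / sd(tail_in)
  }
  # first-order Butterworth, 5 Hz cutoff: |H(f)| = 1/sqrt(1 + (f/5)^2)
  expect_equal(gain_at(5), 1 / sqrt(2), tolerance = 0.02)
  expect_equal(gain_at(10), 1 / sqrt(5), tolerance = 0.05)
})

test_that("interpolation and outlier steps are identity on clean traces", {
  set.seed(1)
  n <- 3000
  tr <- sin(2 * pi * (0:(n - 1)) / n)  # smooth, no outliers, no gaps
  sess <- list(samples = matrix(rep(tr, 2), 2, byrow = TRUE),
               missing = matrix(FALSE, 2, n), lengths = c(n, n),
               t0 = 1L, fs = 1000, conditions = c("LSF", "HSF"))
  out <- preprocess_pupil(sess, steps = c(1, 3))
  expect_equal(out$samples, sess$samples, tolerance = 1e-12)
  # idempotence: re-application changes nothing
  out2 <- preprocess_pupil(out, steps = c(1, 3))
  expect_equal(out2$samples, out$samples, tolerance = 1e-12)
})

test_that("missing samples are linearly interpolated", {
  tr <- c(0, 1, NA, NA, 4, 5)
  sess <- list(samples = matrix(tr, 1), missing = matrix(is.na(tr), 1),
               lengths = 6L, t0 = 1L, fs = 1000, conditions = "LSF")
  out <- preprocess_pupil(sess, steps = 1)
  expect_equal(as.numeric(out$samples), 0:5)
})

test_that("outliers beyond 2 session SDs are removed and interpolated", {
  set.seed(2)
  base <- rnorm(2000, 0, 1)
  base[1000] <- 50  # gross outlier
  sess <- list(samples = matrix(base, 1), missing = matrix(FALSE, 1, 2000),
               lengths = 2000L, t0 = 1L, fs = 1000, conditions = "LSF")
  out <- preprocess_pupil(sess, steps = 3)
  expect_lt(abs(out$samples[1, 1000]), 4)
  expect_equal(out$samples[1, 1000],
               mean(out$samples[1, c(999, 1001)]))
})

test_that("z-scoring yields unit session statistics; degenerate traces drop", {
  set.seed(3)
  sess <- list(samples = matrix(rnorm(4 * 1500, 5, 2), 4),
               missing = matrix(FALSE, 4, 1500), lengths = rep(1500L, 4),
               t0 = 1L, fs = 1000, conditions = rep(c("LSF", "HSF"), 2))
  out <- preprocess_pupil(sess, steps = 5)
  all_samp <- as.numeric(out$samples)
  expect_equal(mean(all_samp), 0, tolerance = 1e-10)
  expect_equal(sd(all_samp), 1, tolerance = 1e-3)

  sess$samples[2, ] <- 7  # constant trace cannot be z-scored
  expect_message(out2 <- preprocess_pupil(sess, steps = 5), "constant trace")
  expect_equal(out2$kept, c(1L, 3L, 4L))
})

test_that("baseline pupil is the pre-onset window mean", {
  m <- matrix(2.5, 3, 400)
  cl <- make_clean_pupil(m, t0 = 201L)
  expect_equal(baseline_pupil(cl), rep(2.5, 3))

  # linear ramp: the window mean is (numerically) the midpoint value
  ramp <- matrix(seq(0, 1, length.out = 400), 1, 400, byrow = TRUE)
  clr <- make_clean_pupil(ramp, t0 = 201L)
  idx <- 101:200  # the [-100, 0) window
  expect_equal(baseline_pupil(clr), mean(ramp[1, idx]))
  expect_equal(baseline_pupil(clr), ramp[1, 150], tolerance = 0.01)

  expect_error(baseline_pupil(make_clean_pupil(m, t0 = 50L)), "outside")
})

test_that("noiseless sliding regression recovers coefficients exactly", {
  set.seed(4)
  n <- 30
  baselines <- rnorm(n)
  conds <- rep(c("LSF", "HSF"), length.out = n)
  y <- 2 + 0.5 * baselines + 1.0 * (conds == "LSF")
  width <- 700
  samples <- matrix(y, n, width)  # constant in time per trial
  cl <- make_clean_pupil(samples, t0 = 101L, conditions = conds)
  reg <- sliding_regression(cl, baselines = baselines, conditions = conds,
                            t_range = c(50, 500))
  expect_s3_class(reg, "window_regression")
  expect_equal(reg$beta0, rep(2, nrow(reg)), tolerance = 1e-10)
  expect_equal(reg$beta_baseline, rep(0.5, nrow(reg)), tolerance = 1e-10)
  expect_equal(reg$beta_cxt, rep(1.0, nrow(reg)), tolerance = 1e-10)

  # single-condition designs are rank deficient: windows undefined
  expect_warning(
    reg2 <- sliding_regression(cl, baselines = baselines,
                               conditions = rep("LSF", n),
                               t_range = c(50, 500)),
    "fewer than 3"
  )
  expect_true(all(is.na(reg2$beta_cxt)))
})

test_that("evoked residuals are OLS residuals of the pre-test window", {
  set.seed(5)
  n <- 40
  avg <- rnorm(n); base <- rnorm(n)
  # exactly linear in the two regressors: residuals vanish
  pre <- 1.5 + 2 * avg - 0.7 * base
  expect_equal(evoked_residual(pre, avg, base), rep(0, n), tolerance = 1e-10)

  pre2 <- pre + rnorm(n)
  r <- evoked_residual(pre2, avg, base)
  expect_equal(sum(r), 0, tolerance = 1e-10)
  expect_error(evoked_residual(pre2, avg, avg), "rank-deficient")
  expect_error(evoked_residual(pre2[1:2], avg[1:2], base[1:2]), "3 trials")
})

test_that("generator-to-analysis pupil pipeline recovers structure", {
  set.seed(6)
  conds <- rep(c("LSF", "HSF"), each = 40)
  sch <- lapply(seq_along(conds), function(i)
    generate_schedule(conds[i], c("right", "left")[1 + i %% 2]))
  pp <- pupil_params()
  ps <- simulate_pupil(sch, pp)
  expect_equal(nrow(ps$samples), 80)
  expect_true(any(ps$missing))

  # blink-free generator leaves the missing mask empty
  ps0 <- simulate_pupil(sch, pupil_params(blink_rate = 0))
  expect_false(any(ps0$missing))

  # zero-amplitude, zero-noise generator gives flat traces at the baseline
  flat <- pupil_params(constriction_amp = 0, evoked_amp_lsf = 0,
                       evoked_amp_hsf = 0, baseline_evoked_coupling = 0,
                       measurement_noise_sd = 0, blink_rate = 0)
  psf <- simulate_pupil(sch[1:3], flat)
  for (i in 1:3) {
    v <- psf$samples[i, seq_len(psf$lengths[i])]
    expect_equal(v, rep(psf$baseline_true[i], length(v)), tolerance = 1e-12)
  }

  cl <- preprocess_pupil(ps)
  reg <- sliding_regression(cl)
  sel <- reg$time_ms >= 1900 & reg$time_ms <= 2400
  # evoked LSF > HSF amplitude appears as positive pre-test beta_cxt,
  # and the imposed inverse baseline-evoked relation as negative
  # beta_baseline
  expect_gt(mean(reg$beta_cxt[sel]), 0)
  expect_lt(mean(reg$beta_baseline[sel]), 0)

  tw <- pupil_trialwise(cl)
  expect_equal(sum(tw$evoked_resid), 0, tolerance = 1e-8)
})
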