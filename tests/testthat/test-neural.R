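test_that("sliding-window rates count spikes in half-open windows", {
  # direct count oracle: spikes {10, 20, 120}, window centered at 60 ms
  rs <- estimate_rates(list(c(10, 20, 120)), t_range = c(60, 60))
  expect_equal(as.numeric(rs$rates), 20)

  # empty train gives all-zero rates
  rs0 <- estimate_rates(list(numeric(0)), t_range = c(0, 500))
  expect_true(all(rs0$rates == 0))

  # regular 100 Hz train: every interior window holds 10 spikes
  reg <- seq(5, 995, by = 10)
  rs1 <- estimate_rates(list(reg), t_range = c(100, 900))
  expect_true(all(rs1$rates == 100))

  # non-overlapping cover recovers the total spike count
  set.seed(1)
  sp <- sort(runif(200, 0, 1000))
  rs2 <- estimate_rates(list(sp), t_range = c(50, 950), step_ms = 100)
  expect_equal(sum(rs2$rates) * 0.1, 200)

  # trials shorter than one window are excluded with a message
  expect_message(
    rs3 <- estimate_rates(list(c(1, 2), c(100, 200)), t_range = c(0, 300),
                          valid_ranges = list(c(0, 50), c(0, 400))),
    "excluded"
  )
  expect_true(all(is.na(rs3$rates[1, ])))
})

test_that("baseline subtraction and normalization follow the hand oracle", {
  # baseline 5 sp/s before onset, 25 sp/s adapting peak, 15 sp/s test
  grid <- seq(-150, 2400, by = 10)
  tr <- ifelse(grid < 0, 5, ifelse(grid < 2000, 25, 15))
  rs <- make_const_series(c(1, 1))
  rs$rates <- rbind(tr, tr)
  out <- baseline_subtract_normalize(rs)
  expect_equal(out$norm_factor, 20)
  expect_true(out$is_normalized)
  sel <- out$time_grid >= 2100 & out$time_grid < 2400
  expect_true(all(abs(out$rates[, sel] - 0.5) < 1e-10))

  # doubling all rates leaves the normalized trace unchanged
  rs2 <- rs; rs2$rates <- rs$rates * 2
  out2 <- baseline_subtract_normalize(rs2)
  expect_equal(out2$rates, out$rates)

  # a constant-rate unit has no adapting response and is flagged
  flat <- make_const_series(c(10, 10))
  expect_warning(outf <- baseline_subtract_normalize(flat), "flagged")
  expect_false(outf$is_normalized)
  expect_true(outf$flagged)
})

test_that("direction selectivity is a windowed preferred-null contrast", {
  a <- make_const_series(c(30, 30)); b <- make_const_series(c(10, 10))
  expect_equal(direction_selectivity(a, b), 20)
  expect_equal(direction_selectivity(a, a), 0)
  expect_equal(direction_selectivity(b, a), -direction_selectivity(a, b))
})

test_that("ROC area equals the all-pairs proportion with half ties", {
  expect_equal(roc_area(c(3, 5), c(1, 4)), 0.75)
  expect_equal(roc_area(rep(2, 5), rep(2, 7)), 0.5)
  expect_equal(roc_area(6:10, 1:5), 1)
  expect_warning(r <- roc_area(numeric(0), 1:3), "empty")
  expect_true(is.na(r))

  set.seed(2)
  for (i in 1:30) {
    x <- sample(0:6, sample(2:10, 1), replace = TRUE)
    y <- sample(0:6, sample(2:10, 1), replace = TRUE)
    expect_equal(roc_area(x, y), roc_brute(x, y), tolerance = 1e-12)
    # complement symmetry and monotone-transform invariance
    expect_equal(roc_area(x, y), 1 - roc_area(y, x), tolerance = 1e-12)
    expect_equal(roc_area(exp(x), exp(y)), roc_area(x, y), tolerance = 1e-12)
  }

  # independent cross-check against the rank-sum statistic
  set.seed(3)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  w <- wilcox.test(x, y, exact = FALSE)$statistic
  expect_equal(roc_area(x, y), unname(w) / (40 * 35), tolerance = 1e-12)
})

test_that("sliding ROC mirrors the per-window statistic", {
  set.seed(4)
  p <- make_const_series(rnorm(8, 20, 3), t_range = c(0, 100))
  q <- make_const_series(rnorm(6, 10, 3), t_range = c(0, 100))
  out <- sliding_roc(p, q)
  expect_s3_class(out, "roc_series")
  expect_equal(out$auc[1], roc_area(p$rates[, 1], q$rates[, 1]))
  expect_true(all(out$n_pref == 8 & out$n_null == 6))
})

test_that("Cohen's d uses the pooled two-sample form", {
  expect_equal(cohens_d(c(2, 4), c(0, 2)), sqrt(2))
  expect_equal(cohens_d(c(0, 2), c(2, 4)), -sqrt(2))
  expect_warning(d <- cohens_d(c(1, 1), c(1, 1)), "zero pooled")
  expect_true(is.na(d))

  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 1)
    expect_equal(cohens_d(x, y), cohens_d_brute(x, y), tolerance = 1e-12)
  }

  # per-presentation effect sizes: the first presentation is the reference
  rs <- make_const_series(c(1, 1, 1), t_range = c(0, 1000))
  set.seed(6)
  rs$rates <- matrix(rnorm(3 * length(rs$time_grid), 20), nrow = 3)
  d <- presentation_effect_size(rs, list(c(0, 400), c(400, 800)))
  expect_equal(d[1], 0)
  s1 <- epoch_mean_per_trial(rs, c(0, 400))
  s2 <- epoch_mean_per_trial(rs, c(400, 800))
  expect_equal(d[2], cohens_d_brute(s2, s1))
})

test_that("single-exponential interpolation inverts forward generation", {
  t3 <- c(265, 405, 540)
  v <- 0.2 + 0.5 * exp(-t3 / 150)
  fit <- fit_exponential_tau(v)
  expect_true(fit$converged)
  expect_equal(fit$a, 0.2, tolerance = 1e-6)
  expect_equal(fit$b, 0.5, tolerance = 1e-6)
  expect_equal(fit$tau, 150, tolerance = 1e-4)

  # shifting all values by a constant shifts only the offset
  fit2 <- fit_exponential_tau(v + 0.3)
  expect_equal(fit2$a, 0.5, tolerance = 1e-6)
  expect_equal(fit2$tau, fit$tau, tolerance = 1e-6)

  # flat and non-monotone triples are flagged
  expect_false(fit_exponential_tau(rep(0.4, 3))$converged)
  expect_false(fit_exponential_tau(c(0.2, 0.6, 0.3))$converged)
  expect_error(fit_exponential_tau(v, times = c(100, 100, 300)), "distinct")
})

test_that("condition differences subtract matched metrics", {
  expect_equal(condition_difference(0.6, 0.4), 0.2)
  a <- c(u1 = 1, u2 = 2); b <- c(u2 = 5, u1 = 1)
  expect_equal(condition_difference(a, b), c(u1 = 0, u2 = -3))
  expect_equal(condition_difference(b, a)[names(a)],
               -condition_difference(a, b))
  expect_error(condition_difference(a, c(u3 = 1, u1 = 1)), "unmatched")
})

test_that("threshold classification applies the joint 2.5% criterion", {
  series_at <- function(level, t_range) {
    s <- make_const_series(rep(level, 4), t_range = t_range)
    s
  }
  mk <- function(first, test) {
    list(adapt = list(LSF = series_at(first[1], c(0, 600)),
                      HSF = series_at(first[2], c(0, 600))),
         test = list(LSF = series_at(test[1], c(0, 600)),
                     HSF = series_at(test[2], c(0, 600))))
  }
  x <- mk(c(0.5, 0.5), c(0.40, 0.42))   # deltas -0.10, -0.08
  expect_equal(classify_unit(x$adapt, x$test)$label, "adapting")
  x <- mk(c(0.5, 0.5), c(0.51, 0.51))   # deltas +0.01, +0.01
  expect_equal(classify_unit(x$adapt, x$test)$label, "unclassified")
  x <- mk(c(0.5, 0.5), c(0.58, 0.56))   # both above +0.025
  expect_equal(classify_unit(x$adapt, x$test)$label, "facilitating")
  x <- mk(c(0.5, 0.5), c(0.40, 0.58))   # conflicting signs
  expect_equal(classify_unit(x$adapt, x$test)$label, "unclassified")
})

test_that("slope-based classification tracks per-presentation peaks", {
  set.seed(7)
  decays <- lapply(c(LSF = 1, HSF = 1), function(i)
    0.9^(0:5) + rnorm(6, 0, 0.005))
  cls <- classify_unit(method = "slope_fit", peaks = decays)
  expect_equal(cls$label, "adapting")
  flat <- lapply(c(LSF = 1, HSF = 1), function(i) rnorm(6, 0.5, 0.1))
  expect_equal(classify_unit(method = "slope_fit", peaks = flat)$label,
               "unclassified")
})

test_that("trial-wise test rate counts spikes in the delayed test window", {
  set.seed(8)
  sch <- generate_schedule("LSF", "right")
  sch$test_duration_ms <- 400
  # 5 spikes inside [2450, 2850), others outside
  sp <- c(100, 2440, 2500, 2600, 2700, 2800, 2849.9, 2860)
  expect_equal(test_epoch_rate(list(sp), list(sch)), 5 / 0.4)
})
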