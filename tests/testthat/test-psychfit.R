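test_that("switch-probability predictors match scalar oracles", {
  # argument zero gives 0.5 for any lapse
  for (lam in c(0, 0.1, 0.4)) {
    p <- list(lapse = lam, beta_slope = 0.01, beta_ss = 100, beta_rl = 50)
    cov <- data.frame(x1 = 100 + 50, x2 = 1, x3 = 1,
                      check.names = FALSE)
    cov$x1 <- p$beta_ss * cov$x2 + p$beta_rl * cov$x3
    expect_equal(predict_switch_prob(p, cov), 0.5)
  }
  # zero slope gives 0.5 everywhere
  p0 <- list(lapse = 0.2, beta_slope = 0, beta_ss = 0, beta_rl = 0)
  cov <- data.frame(x1 = c(-900, 150, 1200), x2 = c(0, 1, 1), x3 = 0)
  expect_equal(predict_switch_prob(p0, cov), rep(0.5, 3))
  # direct scalar evaluation
  p1 <- list(lapse = 0.05, beta_slope = 0.01, beta_ss = 100, beta_rl = 0)
  cov1 <- data.frame(x1 = 300, x2 = 1, x3 = 0)
  expect_equal(predict_switch_prob(p1, cov1), 0.05 + 0.9 / (1 + exp(-2)))
})

test_that("trial-wise predictor reduces, rescales, and evaluates correctly", {
  p <- list(lapse = 0.07, beta_slope = 0.012, beta_ss = 120, beta_rl = -30,
            beta_tw = 1)
  cov <- data.frame(x1 = c(-400, 250, 800), x2 = c(0, 1, 1), x3 = c(1, 0, 1),
                    x4 = 1)
  expect_equal(predict_switch_prob_trialwise(p, cov),
               predict_switch_prob(p, cov))

  # scale degeneracy of the product form (no biases)
  pa <- list(lapse = 0, beta_slope = 0.01, beta_ss = 0, beta_rl = 0,
             beta_tw = 2)
  pb <- pa; pb$beta_tw <- 1
  ca <- data.frame(x1 = c(100, -700), x2 = c(1, 0), x3 = 0, x4 = 0.5)
  cb <- ca; cb$x4 <- 1
  expect_equal(predict_switch_prob_trialwise(pa, ca),
               predict_switch_prob_trialwise(pb, cb))

  # direct scalar evaluation
  pc <- list(lapse = 0, beta_slope = 0.01, beta_ss = 0, beta_rl = 0,
             beta_tw = 2)
  cc <- data.frame(x1 = 100, x2 = 1, x3 = 0, x4 = 0.5)
  expect_equal(predict_switch_prob_trialwise(pc, cc), 1 / (1 + exp(-1)))
})

test_that("predicted probabilities are monotone in viewing time and bounded", {
  set.seed(1)
  for (i in 1:20) {
    # moderate slopes keep the logistic away from floating-point saturation
    p <- list(lapse = runif(1, 0, 0.4), beta_slope = runif(1, 1e-4, 0.01),
              beta_ss = runif(1, -100, 100), beta_rl = runif(1, -100, 100))
    x1 <- sort(runif(50, -300, 300))
    cov <- data.frame(x1 = x1, x2 = 1, x3 = 1)
    pr <- predict_switch_prob(p, cov)
    expect_true(all(diff(pr) > 0))
    expect_true(all(pr > p$lapse & pr < 1 - p$lapse))
  }
  # at extreme arguments the probabilities saturate at the lapse limits
  pe <- list(lapse = 0.1, beta_slope = 0.05, beta_ss = 0, beta_rl = 0)
  pre <- predict_switch_prob(pe, data.frame(x1 = c(-1200, 1200), x2 = 1,
                                            x3 = 0))
  expect_equal(pre, c(0.1, 0.9), tolerance = 1e-8)
})

test_that("Tjur's coefficient matches its definition and symmetries", {
  expect_equal(tjur_r2(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0)
  y <- c(1, 1, 0, 0)
  expect_equal(tjur_r2(y, y), 1)
  expect_equal(tjur_r2(c(0.8, 0.6, 0.3, 0.1), c(1, 1, 0, 0)), 0.5)

  set.seed(2)
  p <- runif(30); yy <- rbinom(30, 1, 0.5)
  o <- sample(30)
  expect_equal(tjur_r2(p, yy), tjur_r2(p[o], yy[o]))           # reordering
  expect_equal(tjur_r2(p, yy), tjur_r2(1 - p, 1 - yy))          # label flip
  expect_warning(r <- tjur_r2(p, rep(1, 30)), "one outcome")
  expect_true(is.na(r))
})

test_that("maximum-likelihood fitting recovers, flags bounds, and refuses bad input", {
  truth <- list(lapse = 0.05, beta_slope = 0.012, beta_ss = 150, beta_rl = 20)
  set.seed(3)
  tr <- simulate_psychometric_trials(truth, 2000)
  fit <- fit_psychometric(tr, n_starts = 5)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$beta_slope - truth$beta_slope) / truth$beta_slope,
            0.3)
  expect_lt(abs(fit$params$lapse - truth$lapse), 0.03)
  # the fit never falls below the likelihood of the generating parameters
  ll_true <- sum(dbinom(tr$y, 1, predict_switch_prob(truth, tr), log = TRUE))
  expect_gte(fit$log_likelihood, ll_true - 1e-6)

  # ground truth beyond the slope bound comes back at the bound, flagged
  steep <- list(lapse = 0.02, beta_slope = 0.2, beta_ss = 0, beta_rl = 0)
  set.seed(4)
  tr2 <- simulate_psychometric_trials(steep, 800)
  fit2 <- fit_psychometric(tr2, n_starts = 5)
  expect_equal(fit2$params$beta_slope, 0.05)
  expect_true(fit2$boundary)

  one_class <- data.frame(x1 = seq(100, 1200, length.out = 30), x2 = 1,
                          x3 = 0, y = 1)
  expect_error(fit_psychometric(one_class), "same outcome")
  expect_error(fit_psychometric(tr[1:10, ]), "at least 20")
})

test_that("refits from different random starts agree to 1e-6 in log-likelihood", {
  set.seed(5)
  tr <- simulate_psychometric_trials(
    list(lapse = 0.1, beta_slope = 0.008, beta_ss = 100, beta_rl = 0), 600)
  set.seed(100); f1 <- fit_psychometric(tr, n_starts = 10)
  set.seed(200); f2 <- fit_psychometric(tr, n_starts = 10)
  expect_lt(abs(f1$log_likelihood - f2$log_likelihood), 1e-6)
})

test_that("psychfit methods are coherent", {
  set.seed(6)
  tr <- simulate_psychometric_trials(
    list(lapse = 0.05, beta_slope = 0.01, beta_ss = 100, beta_rl = 0), 400)
  fit <- fit_psychometric(tr, n_starts = 3)
  expect_s3_class(fit, "psychfit")
  expect_named(coef(fit), c("lapse", "beta_slope", "beta_ss", "beta_rl"))
  expect_equal(as.numeric(logLik(fit)), fit$log_likelihood)
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, tr), fit$fitted)
  expect_equal(residuals(fit), tr$y - fit$fitted)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(400L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  expect_output(print(summary(fit)), "Tjur pseudo-R2")
  pdf(NULL); on.exit(dev.off())
  binned <- plot(fit)
  expect_true(all(binned$prop >= 0 & binned$prop <= 1, na.rm = TRUE))
})

test_that("trial-wise variant nests the base model", {
  set.seed(7)
  tr <- simulate_psychometric_trials(
    list(lapse = 0.05, beta_slope = 0.01, beta_ss = 100, beta_rl = 0), 500)
  tr$x4 <- 1  # constant modulator carries no information
  f1 <- fit_psychometric(tr, "eq1", n_starts = 4)
  f3 <- fit_psychometric(tr, "eq3", n_starts = 4)
  expect_equal(f3$tjur_r2, f1$tjur_r2, tolerance = 1e-4)
  expect_gte(f3$log_likelihood, f1$log_likelihood - 1e-4)
})

test_that("running choice average is a truncated centered mean", {
  expect_equal(running_choice_average(c(0, 0, 1, 1, 1), 3),
               c(0, 1 / 3, 2 / 3, 1, 1))
  y <- rbinom(20, 1, 0.5)
  expect_equal(running_choice_average(y, 1), as.numeric(y))
  expect_equal(running_choice_average(rep(1, 10), 5), rep(1, 10))
  expect_error(running_choice_average(y, 4), "odd")
})

test_that("duration-binned accuracy uses half-open bins", {
  tr <- data.frame(test_duration_ms = c(400, 700, 450, 500),
                   correct = c(TRUE, TRUE, TRUE, FALSE),
                   is_switch = c(TRUE, TRUE, FALSE, TRUE))
  out <- accuracy_by_duration(tr, c(375, 600))
  expect_equal(out$n, 3L)
  expect_equal(out$prop_correct, 2 / 3)

  # the 700 ms trial falls outside [375, 600)
  out2 <- accuracy_by_duration(tr[1:2, ], c(375, 600))
  expect_equal(out2$n, 1L)
  expect_equal(out2$prop_correct, 1)

  all_correct <- data.frame(test_duration_ms = c(150, 250, 800),
                            correct = TRUE, is_switch = TRUE)
  out3 <- accuracy_by_duration(all_correct, c(100, 300, 1200))
  expect_equal(out3$prop_correct, c(1, 1))

  out4 <- accuracy_by_duration(tr, c(1000, 1200))
  expect_equal(out4$n, 0L)
  expect_true(is.na(out4$prop_correct))

  out5 <- accuracy_by_duration(tr, c(375, 600), switch_only = TRUE)
  expect_equal(out5$n, 2L)
  expect_error(accuracy_by_duration(tr, c(600, 375)), "increasing")
})

test_that("shuffled null keeps lengths and degrades structured fits", {
  set.seed(8)
  sess <- generate_session(n_trials = 400, units = list(), pupil = NULL,
                           seed = 88)
  cov <- trial_covariates(sess$trials)
  nul <- shuffled_null_r2(cov, n_iter = 5, n_starts = 2)
  expect_length(nul, 5)
  expect_true(all(is.finite(nul)))
  emp <- fit_by_condition(cov, n_starts = 5)$r2
  expect_gt(emp, min(nul))
})
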