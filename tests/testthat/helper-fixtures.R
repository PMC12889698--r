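# shared helpers for building small in-code fixtures

# rate_series with given constant per-trial rates over a time grid
make_const_series <- function(rates_per_trial, t_range = c(-150, 2400),
                              step = 10) {
  grid <- seq(t_range[1], t_range[2], by = step)
  structure(
    list(time_grid = grid,
         rates = matrix(rep(rates_per_trial, each = length(grid)),
                        nrow = length(rates_per_trial), byrow = TRUE),
         alignment = "adapt_onset", window_ms = 100, step_ms = step,
         baseline_per_trial = NULL, norm_factor = NULL,
         is_normalized = FALSE),
    class = "rate_series"
  )
}

# minimal clean_pupil object from a samples matrix (already "clean")
make_clean_pupil <- function(samples, t0 = 101L, fs = 1000,
                             conditions = NULL) {
  structure(
    list(samples = samples, kept = seq_len(nrow(samples)),
         lengths = rep(ncol(samples), nrow(samples)),
         t0 = t0, fs = fs,
         conditions = conditions %||% rep("LSF", nrow(samples)),
         steps_applied = integer(0),
         session_mean = 0, session_sd = 1),
    class = "clean_pupil"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force ROC area over all ordered pairs, ties counted one half
roc_brute <- function(x, y) {
  s <- 0
  for (xi in x) for (yi in y) s <- s + (xi > yi) + 0.5 * (xi == yi)
  s / (length(x) * length(y))
}

# brute-force two-sample pooled-SD Cohen's d
cohens_d_brute <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2)
}

# units used in the synthetic-unit recovery studies
random_strong_unit <- function(step_lsf, step_hsf, profile = "adapting") {
  unit_params(base_rate = runif(1, 10, 20), pref_gain = runif(1, 40, 80),
              adapt_step_lsf = step_lsf, adapt_step_hsf = step_hsf,
              profile = profile)
}
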