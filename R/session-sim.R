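#' Simulate a complete experimental session
#'
#' Generates trials for both context-stability conditions (blocked or
#' interleaved per the task configuration), with counterbalanced initial
#' directions within each condition, choices from the leaky accumulator,
#' spike trains for each supplied unit, and pupil traces. Optional latent
#' per-trial signals couple behavior to the simulated neural gain
#' (`neural_coupling`) and/or to a latent arousal signal expressed in the
#' evoked pupil (`pupil_coupling`), for ground-truth dissociation studies.
#' All ground-truth parameters and the seed are stored with the outputs.
#'
#' @param config A [task_config()].
#' @param behavior An [accumulator_params()] object.
#' @param units List of [unit_params()] objects (may be empty for a
#'   behavior-only session).
#' @param pupil A [pupil_params()] object, or `NULL` to skip pupil traces.
#' @param n_trials Total number of trials (split equally across conditions;
#'   must be at least 2).
#' @param seed Optional integer seed (defaults to `config$seed`); all
#'   randomness in the session flows from it.
#' @param session_id Identifier stored in the trials table.
#' @param neural_coupling SD of the latent gain signal's effect: a per-trial
#'   standard-normal draw scales both the accumulator drift and the units'
#'   test-epoch response gain by `1 + neural_coupling * z`.
#' @param pupil_coupling Effect of the latent arousal draw on the
#'   accumulator drift (`1 + pupil_coupling * z`).
#' @param arousal_amp Amplitude (a.u.) with which the latent arousal draw is
#'   expressed in the evoked pupil component.
#' @param include_adapt Passed to [simulate_choice()].
#' @return An object of class `sim_session`: list with `trials` (data
#'   frame), `schedules`, `spikes` (data frame `unit_id`, `trial_index`,
#'   `spike_time_ms`), `spike_trains` (list per unit of per-trial vectors),
#'   `pupil` (a `pupil_session` or `NULL`), and `ground_truth`.
#' @examples
#' sess <- generate_session(n_trials = 20, seed = 1)
#' head(sess$trials)
#' @export
generate_session <- function(config = task_config(),
                             behavior = accumulator_params(),
                             units = list(),
                             pupil = pupil_params(),
                             n_trials = 200,
                             seed = NULL,
                             session_id = "S1",
                             neural_coupling = 0,
                             pupil_coupling = 0,
                             arousal_amp = 0.3,
                             include_adapt = FALSE) {
  if (n_trials < 2) stop("n_trials must be at least 2")
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)

  n_lsf <- floor(n_trials / 2)
  conditions <- if (config$block_structure == "blocked") {
    c(rep("LSF", n_lsf), rep("HSF", n_trials - n_lsf))
  } else {
    sample(c(rep("LSF", n_lsf), rep("HSF", n_trials - n_lsf)))
  }
  # counterbalanced initial directions within condition
  init_dir <- character(n_trials)
  for (cc in unique(conditions)) {
    idx <- which(conditions == cc)
    dirs <- rep_len(c("right", "left"), length(idx))
    init_dir[idx] <- sample(dirs)
  }

  z_gain <- stats::rnorm(n_trials)
  z_arousal <- stats::rnorm(n_trials)
  drift_scale <- pmax(0.05, 1 + neural_coupling * z_gain +
                        pupil_coupling * z_arousal)
  gain_scale <- pmax(0.05, 1 + neural_coupling * z_gain)

  schedules <- vector("list", n_trials)
  rows <- vector("list", n_trials)
  spike_trains <- lapply(seq_along(units), function(u) vector("list", n_trials))

  for (i in seq_len(n_trials)) {
    sch <- generate_schedule(conditions[i], init_dir[i], config)
    schedules[[i]] <- sch
    ch <- simulate_choice(sch, behavior, config,
                          include_adapt = include_adapt,
                          drift_scale = drift_scale[i])
    rows[[i]] <- data.frame(
      session_id = session_id, trial_index = i,
      condition = conditions[i], is_switch = sch$is_switch_trial,
      test_duration_ms = sch$test_duration_ms,
      initial_direction = init_dir[i],
      test_direction = sch$test_direction,
      choice = ch$choice, correct = ch$correct,
      reported_switch = ch$reported_switch,
      stringsAsFactors = FALSE
    )
    for (u in seq_along(units)) {
      spike_trains[[u]][[i]] <-
        simulate_spike_train(sch, units[[u]],
                             test_gain_scale = gain_scale[i])
    }
  }
  trials <- do.call(rbind, rows)

  pupil_data <- NULL
  if (!is.null(pupil)) {
    pupil_data <- simulate_pupil(schedules, pupil,
                                 arousal = arousal_amp * z_arousal)
    # fixation-acquisition time covaries with the tonic pupil baseline
    trials$fixation_acquire_ms <-
      pmax(100, 300 + 200 * pupil_data$baseline_true +
             stats::rnorm(n_trials, 0, 50))
  } else {
    trials$fixation_acquire_ms <- NA_real_
  }

  spikes <- if (length(units)) {
    do.call(rbind, lapply(seq_along(units), function(u) {
      do.call(rbind, lapply(seq_len(n_trials), function(i) {
        st <- spike_trains[[u]][[i]]
        if (!length(st)) return(NULL)
        data.frame(unit_id = paste0("u", u), trial_index = i,
                   spike_time_ms = as.numeric(st))
      }))
    }))
  } else {
    data.frame(unit_id = character(0), trial_index = integer(0),
               spike_time_ms = numeric(0))
  }

  structure(
    list(trials = trials, schedules = schedules, spikes = spikes,
         spike_trains = spike_trains, pupil = pupil_data,
         ground_truth = list(config = config, behavior = behavior,
                             units = units, pupil = pupil, seed = seed,
                             neural_coupling = neural_coupling,
                             pupil_coupling = pupil_coupling,
                             arousal_amp = arousal_amp,
                             z_gain = z_gain, z_arousal = z_arousal)),
    class = "sim_session"
  )
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("sim_session %s: %d trials (%d LSF / %d HSF), %d unit(s), pupil: %s\n",
              x$trials$session_id[1], nrow(x$trials),
              sum(x$trials$condition == "LSF"),
              sum(x$trials$condition == "HSF"),
              length(x$ground_truth$units),
              if (is.null(x$pupil)) "no" else "yes"))
  invisible(x)
}

#' Write session data to plain-text files
#'
#' Writes the trials table, long-format spikes table, pupil sample and
#' missing-mask matrices (CSV), and a ground-truth YAML sidecar.
#'
#' @param session A `sim_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             spikes = file.path(dir, "spikes.csv"),
             pupil = file.path(dir, "pupil.csv"),
             mask = file.path(dir, "pupil_mask.csv"),
             truth = file.path(dir, "ground_truth.yaml"))
  utils::write.csv(session$trials, paths["trials"], row.names = FALSE)
  utils::write.csv(session$spikes, paths["spikes"], row.names = FALSE)
  if (!is.null(session$pupil)) {
    utils::write.csv(session$pupil$samples, paths["pupil"], row.names = FALSE)
    utils::write.csv(session$pupil$missing, paths["mask"], row.names = FALSE)
  }
  gt <- session$ground_truth
  gt$z_gain <- NULL; gt$z_arousal <- NULL
  gt <- rapply(gt, unclass, how = "replace")
  yaml::write_yaml(gt, paths["truth"])
  invisible(paths)
}

#' Read a trials table written by [write_session()]
#'
#' @param path Path to `trials.csv`.
#' @return Trials data frame.
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
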