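# Canned experiment protocols ----------------------------------------------
#
# The two study designs the package is built around, wrapped end to end so
# that a single seed reproduces the whole experiment: generation, training,
# noise calibration, trials, and (for the injury sweeps) the deterioration
# fit.

#' Healthy face-recognition experiment on correlated memories
#'
#' Generates a family of correlated grayscale patterns, trains a covariance
#' Hopfield network on them, calibrates the dynamic-noise amplitude so the
#' healthy network recalls noisy cues correctly about `target_correct` of
#' the time, and then measures outcome fractions over `n_trials` fresh
#' recall trials at `cue_noise` corruption.
#'
#' @param n_neurons,n_memories,n_levels,target_overlap memory-family
#'   parameters (defaults: 1,080 neurons, 3 memories, 8 gray levels, 65%
#'   pairwise overlap).
#' @param cue_noise cue corruption fraction (default 0.2).
#' @param n_trials number of measurement trials, cycling over the memories.
#' @param target_correct healthy correct-recall operating point used by the
#'   noise calibration (default 0.9).
#' @param calibration_trials pilot trials per calibration candidate.
#' @param max_sweeps sweep budget per trial.
#' @param seed master seed (mandatory); all stages derive their own seeds
#'   from it.
#' @return A list: `frac_correct`, `frac_none`, `frac_confused`, the
#'   calibrated `noise_sigma`, the calibration `table`, the trial table, the
#'   `memories` and the trained `network`.
#' @export
face_recognition_experiment <- function(n_neurons = 1080, n_memories = 3,
                                        n_levels = 8, target_overlap = 0.65,
                                        cue_noise = 0.2, n_trials = 102,
                                        target_correct = 0.9,
                                        calibration_trials = 100,
                                        max_sweeps = 100, seed) {
  if (missing(seed)) stop("`seed` is required (reproducibility is mandatory)")
  ms <- generate_correlated_family(n_neurons, n_memories, n_levels,
                                   target_overlap, seed = derive_seed(seed, 1L))
  net <- hebbian_train(ms, center = TRUE)
  cal <- calibrate_noise_sigma(net, ms, noise_level = cue_noise,
                               target = target_correct,
                               n_trials = calibration_trials,
                               max_sweeps = max_sweeps,
                               seed = derive_seed(seed, 2L))
  set.seed(derive_seed(seed, 3L))
  cues <- rep_len(seq_len(n_memories), n_trials)
  trials <- do.call(rbind, lapply(cues, function(cue)
    run_trial(net, ms, cue, cue_noise, NULL, cal$noise_sigma,
              max_sweeps = max_sweeps)))
  list(frac_correct = mean(trials$outcome == "correct"),
       frac_none = mean(trials$outcome == "none"),
       frac_confused = mean(trials$outcome == "confused"),
       noise_sigma = cal$noise_sigma, calibration = cal$table,
       trials = trials, memories = ms, network = net)
}

#' Injury-sweep deterioration experiment on random memories
#'
#' Stores a set of random binary memories at the capacity limit, fixes the
#' cue noise, calibrates the dynamic-noise amplitude against the healthy
#' network (unless one is supplied), sweeps the injury level under the given
#' FAS pie-chart, normalizes recognition scores by the healthy baseline,
#' and fits the deterioration law R(p) = A - B * exp(p).
#'
#' @param dist a `fas_distribution` pie-chart.
#' @param n_neurons,n_memories,n_levels,active_fraction memory-set
#'   parameters (defaults: the 900-neuron binary network storing 126
#'   memories, i.e. 0.14 N).
#' @param cue_noise fixed cue corruption of all trials (default 0.1).
#' @param injury_levels injury grid; must contain 0 (default 0 to 0.5 in
#'   steps of 0.05).
#' @param replicates injury re-drawings per grid point.
#' @param n_cues memory subsample cued per replicate.
#' @param noise_sigma dynamic-noise amplitude; `NULL` (default) calibrates
#'   it to the `target_correct` healthy operating point at `cue_noise`.
#' @param target_correct calibration target (default 0.9).
#' @param max_sweeps sweep budget per trial.
#' @param seed master seed (mandatory).
#' @return A list: the deterioration `fit`, the `aggregated` cell table, the
#'   raw `sweep`, the `noise_sigma` used, and the `memories`.
#' @export
deterioration_experiment <- function(dist, n_neurons = 900, n_memories = 126,
                                     n_levels = 2, active_fraction = 0.5,
                                     cue_noise = 0.1,
                                     injury_levels = seq(0, 0.5, by = 0.05),
                                     replicates = 3, n_cues = 25,
                                     noise_sigma = NULL, target_correct = 0.9,
                                     max_sweeps = 100, seed) {
  if (missing(seed)) stop("`seed` is required (reproducibility is mandatory)")
  ms <- generate_random_memories(n_neurons, n_memories, n_levels,
                                 active_fraction, seed = derive_seed(seed, 1L))
  if (is.null(noise_sigma)) {
    net <- hebbian_train(ms)
    noise_sigma <- calibrate_noise_sigma(net, ms, noise_level = cue_noise,
                                         target = target_correct,
                                         n_trials = 30,
                                         max_sweeps = max_sweeps,
                                         seed = derive_seed(seed, 2L))$noise_sigma
  }
  sw <- run_sweep(ms, dist, noise_levels = cue_noise,
                  injury_levels = injury_levels, replicates = replicates,
                  n_cues = n_cues, noise_sigma = noise_sigma,
                  max_sweeps = max_sweeps, seed = derive_seed(seed, 3L))
  agg <- aggregate_sweep(sw)
  list(fit = fit_deterioration(agg), aggregated = agg, sweep = sw,
       noise_sigma = noise_sigma, memories = ms)
}
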