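# Operating-point calibrations ---------------------------------------------
#
# Two quantities the recall experiments need but that are not physical
# constants: the dynamic noise amplitude, and the fixed cue-noise level of
# the deterioration sweeps.  Both are calibrated against the *healthy*
# network's performance, anchoring the simulations at the healthy ~90%
# correct-recall operating point before any injury is introduced.

#' Calibrate the dynamic noise amplitude
#'
#' Searches a grid of `noise_sigma` values (coarse pass, then one refinement
#' around the best candidate) for the amplitude at which the healthy network
#' recalls noisy cues correctly with probability closest to `target`.
#' Pilot trials cycle over all memories.
#'
#' @param net a trained `hopfield_network`.
#' @param memories its `memory_set`.
#' @param noise_level cue corruption of the pilot trials (default 0.2).
#' @param target desired correct-recall fraction (default 0.9).
#' @param sigmas coarse grid of candidate amplitudes; roughly log-spaced,
#'   since recall degrades very sharply once perturbations reach the
#'   inter-level spacing over a full trajectory.
#' @param n_trials pilot trials per candidate (default 40).
#' @param seed integer seed (mandatory).
#' @inheritParams run_trial
#' @return A list with `noise_sigma` (the calibrated amplitude) and `table`
#'   (a `data.frame` of candidate amplitudes and pilot correct fractions).
#' @export
calibrate_noise_sigma <- function(net, memories, noise_level = 0.2,
                                  target = 0.9,
                                  sigmas = c(0.002, 0.005, 0.01, 0.02,
                                             0.05, 0.1, 0.2),
                                  n_trials = 40, theta = 0.75, delta = 0.10,
                                  max_sweeps = 100, seed) {
  if (missing(seed)) stop("`seed` is required (reproducibility is mandatory)")
  pilot <- function(sig, tag) {
    set.seed(derive_seed(seed, tag))
    cues <- rep_len(seq_len(n_memories(memories)), n_trials)
    out <- vapply(cues, function(cue)
      run_trial(net, memories, cue, noise_level, NULL, sig,
                theta, delta, max_sweeps)$outcome == "correct", logical(1))
    mean(out)
  }
  sigmas <- sort(sigmas)
  frac <- vapply(seq_along(sigmas), function(i) pilot(sigmas[i], i), numeric(1))
  # bracket the target crossing (performance decreases with amplitude) and
  # bisect on the log scale; the response can be steep, so nearest-grid
  # selection alone is not enough
  above <- which(frac >= target)
  lo <- if (length(above)) sigmas[max(above)] else sigmas[1] / 4
  hi_candidates <- sigmas[sigmas > lo]
  hi <- if (length(hi_candidates)) min(hi_candidates) else sigmas[length(sigmas)] * 4
  tab <- data.frame(noise_sigma = sigmas, frac_correct = frac)
  for (step in 1:4) {
    mid <- sqrt(lo * hi)
    fmid <- pilot(mid, 1000L + step)
    tab <- rbind(tab, data.frame(noise_sigma = mid, frac_correct = fmid))
    if (fmid >= target) lo <- mid else hi <- mid
  }
  tab <- tab[order(tab$noise_sigma), ]
  # pool all pilots through a decreasing isotonic fit, then interpolate the
  # target crossing on the log-amplitude scale; pooling resists the
  # sampling noise of any single pilot
  iso <- -stats::isoreg(seq_len(nrow(tab)), -tab$frac_correct)$yf
  if (all(iso >= target)) {
    sel <- tab$noise_sigma[nrow(tab)]
  } else if (all(iso < target)) {
    sel <- tab$noise_sigma[1]
  } else {
    k <- max(which(iso >= target))
    drop_ <- iso[k] - iso[k + 1]
    t_ <- if (drop_ > 0) (iso[k] - target) / drop_ else 0.5
    sel <- exp((1 - t_) * log(tab$noise_sigma[k]) +
               t_ * log(tab$noise_sigma[k + 1]))
  }
  list(noise_sigma = sel, table = tab)
}

#' Calibrate the fixed cue-noise level of a deterioration sweep
#'
#' The deterioration law is fitted at a fixed cue-noise level; this picks
#' the largest level on the candidate grid at which the *healthy* network
#' still recalls at least `target` of cued memories, i.e. the hardest
#' denoising task the intact network handles reliably.  Falls back to the
#' smallest candidate when none qualifies.
#'
#' @inheritParams calibrate_noise_sigma
#' @param noise_levels candidate cue-noise grid (ascending).
#' @param noise_sigma dynamic noise amplitude used in the pilot trials.
#' @return A list with `noise_level` and the pilot `table`.
#' @export
calibrate_cue_noise <- function(net, memories,
                                noise_levels = seq(0.02, 0.2, by = 0.02),
                                target = 0.9, noise_sigma = 0.1,
                                n_trials = 30, theta = 0.75, delta = 0.10,
                                max_sweeps = 100, seed) {
  if (missing(seed)) stop("`seed` is required (reproducibility is mandatory)")
  noise_levels <- sort(noise_levels)
  frac <- vapply(seq_along(noise_levels), function(i) {
    set.seed(derive_seed(seed, i))
    cues <- rep_len(seq_len(n_memories(memories)), n_trials)
    mean(vapply(cues, function(cue)
      run_trial(net, memories, cue, noise_levels[i], NULL, noise_sigma,
                theta, delta, max_sweeps)$outcome == "correct", logical(1)))
  }, numeric(1))
  ok <- which(frac >= target)
  sel <- if (length(ok)) noise_levels[max(ok)] else noise_levels[1]
  list(noise_level = sel,
       table = data.frame(noise_level = noise_levels, frac_correct = frac))
}
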