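# Recall trials, outcome classification, recognition score, grid sweeps ----

#' Classify a final network state against the stored memories
#'
#' The classification is *significant* iff the best overlap reaches `theta`
#' and beats the runner-up by at least `delta`.  A significant match to the
#' cued memory is `correct`; a significant match to any other memory is
#' `confused` (wrong-convergence); anything else is `none`
#' (non-convergence in recognition terms).
#'
#' @param levels integer level vector of the final state.
#' @param memories the stored `memory_set`.
#' @param theta minimum overlap for a significant classification (default 0.75).
#' @param delta minimum margin over the second-best overlap (default 0.10).
#' @param cued index of the cued memory, or `NULL` when only the best match
#'   is wanted.
#' @return A list: `best_match` (index or `NA`), `outcome` (`"correct"`,
#'   `"confused"`, `"none"`, or `NA` without a cue), `overlaps`,
#'   `best_overlap`, `margin`, `significant`.
#' @export
classify_state <- function(levels, memories, theta = 0.75, delta = 0.10,
                           cued = NULL) {
  if (!inherits(memories, "memory_set")) stop("`memories` must be a memory_set")
  if (!(theta > 0 && theta < 1)) stop("`theta` must lie in (0, 1)")
  if (delta < 0) stop("`delta` must be >= 0")
  lv <- as.integer(levels)
  if (length(lv) != ncol(memories$levels)) stop("state length does not match memories")
  ov <- rowMeans(memories$levels == matrix(lv, nrow(memories$levels),
                                           length(lv), byrow = TRUE))
  best <- which.max(ov)                      # ties resolve to the lower index
  second <- if (length(ov) > 1L) max(ov[-best]) else -Inf
  significant <- ov[best] >= theta && (ov[best] - second) >= delta
  outcome <- NA_character_
  if (!is.null(cued)) {
    outcome <- if (!significant) "none"
               else if (best == cued) "correct" else "confused"
  }
  list(best_match = if (significant) best else NA_integer_,
       outcome = outcome, overlaps = ov, best_overlap = unname(ov[best]),
       margin = unname(ov[best] - second), significant = significant)
}

#' Run one recall trial
#'
#' Corrupts the cued memory with exact-count cue noise, runs the recall
#' dynamics to convergence under the given injury, and classifies the final
#' state.  Randomness is drawn from the current RNG stream; seed with
#' `set.seed()` (or use [run_sweep()], which derives per-trial seeds).
#'
#' @param net a trained `hopfield_network`.
#' @param memories the stored `memory_set`.
#' @param cue_index which memory to cue.
#' @param noise_level cue corruption fraction in \[0, 1\].
#' @param assignment optional `fas_assignment` (`NULL` = healthy).
#' @param noise_sigma dynamic field-noise standard deviation.
#' @param theta,delta classification thresholds, see [classify_state()].
#' @param max_sweeps sweep budget for [run_to_convergence()].
#' @param filter a [filter_spec()].
#' @return A one-row `data.frame`: `cued`, `best_match`, `outcome`,
#'   `overlap_correct`, `overlap_best`, `converged`, `sweeps`.
#' @export
run_trial <- function(net, memories, cue_index, noise_level,
                      assignment = NULL, noise_sigma = 0.1,
                      theta = 0.75, delta = 0.10, max_sweeps = 100,
                      filter = filter_spec()) {
  cue_index <- as.integer(cue_index)
  if (cue_index < 1L || cue_index > n_memories(memories))
    stop("`cue_index` out of range")
  cue <- add_cue_noise(get_pattern(memories, cue_index), noise_level)
  res <- run_to_convergence(net, cue, noise_sigma = noise_sigma,
                            assignment = assignment, max_sweeps = max_sweeps,
                            filter = filter)
  cl <- classify_state(res$levels, memories, theta, delta, cued = cue_index)
  data.frame(cued = cue_index,
             best_match = cl$best_match,
             outcome = cl$outcome,
             overlap_correct = unname(cl$overlaps[cue_index]),
             overlap_best = cl$best_overlap,
             converged = res$converged,
             sweeps = res$sweeps)
}

#' Recognition score of a set of trials
#'
#' Each trial contributes its final overlap with the cued memory when
#' correct, zero when non-convergent, and *minus* its overlap with the
#' wrongly matched memory when confused, so confusion is penalised more
#' than mere non-convergence.  The raw mean score is returned as is, or,
#' when a healthy-network `baseline` is supplied, normalized by it and
#' clamped to \[0, 1\].
#'
#' @param outcomes a `data.frame` of trial rows as produced by [run_trial()].
#' @param baseline raw score of the healthy network at the same cue-noise
#'   level, or `NULL` for the unnormalized score.
#' @return A scalar score.
#' @export
recognition_score <- function(outcomes, baseline = NULL) {
  if (!is.data.frame(outcomes) || nrow(outcomes) < 1L)
    stop("`outcomes` must contain at least one trial")
  s <- ifelse(outcomes$outcome == "correct", outcomes$overlap_correct,
              ifelse(outcomes$outcome == "confused", -outcomes$overlap_best, 0))
  r <- mean(s)
  if (is.null(baseline)) return(r)
  if (!is.numeric(baseline) || baseline <= 0) stop("`baseline` must be > 0")
  min(max(r / baseline, 0), 1)
}

summarise_cell <- function(outcomes) {
  data.frame(n_trials = nrow(outcomes),
             frac_correct = mean(outcomes$outcome == "correct"),
             frac_none = mean(outcomes$outcome == "none"),
             frac_confused = mean(outcomes$outcome == "confused"),
             mean_accuracy = mean(outcomes$overlap_correct),
             frac_converged = mean(outcomes$converged),
             raw_score = recognition_score(outcomes))
}

#' Sweep a noise-by-injury grid of recall experiments
#'
#' For every grid cell and replicate a fresh injury assignment is drawn and
#' a block of recall trials is run: one per stored memory when
#' `n_cues = NULL`, otherwise over a random subsample of `n_cues` memories.
#' Per-cell, per-replicate seeds are derived deterministically from the
#' master seed, so cells are independent and the whole sweep is reproducible
#' bit for bit.
#'
#' @param memories the `memory_set` to store and recall.
#' @param dist a `fas_distribution` pie-chart (ignored at injury 0).
#' @param noise_levels,injury_levels numeric grids of cue-noise and injury
#'   levels.
#' @param replicates injury re-drawings per cell (>= 1).
#' @param n_cues memory subsample size per replicate, or `NULL` to cue every
#'   memory once.
#' @param center train with the covariance rule (see [hebbian_train()]);
#'   use for correlated memory families.
#' @param seed master integer seed (mandatory).
#' @inheritParams run_trial
#' @return A `recognition_sweep`: a `data.frame` with one row per
#'   (noise, injury, replicate) holding outcome fractions, mean accuracy and
#'   the raw recognition score, plus a `config` attribute.
#' @export
run_sweep <- function(memories, dist = NULL, noise_levels, injury_levels,
                      replicates = 1, n_cues = NULL, noise_sigma = 0.1,
                      theta = 0.75, delta = 0.10, max_sweeps = 100,
                      filter = filter_spec(), center = FALSE, seed) {
  if (missing(seed)) stop("`seed` is required (reproducibility is mandatory)")
  if (length(noise_levels) < 1L || length(injury_levels) < 1L)
    stop("grids must be non-empty")
  if (replicates < 1L) stop("`replicates` must be >= 1")
  if (any(injury_levels > 0) && is.null(dist))
    stop("`dist` is required when the grid contains nonzero injury levels")
  net <- hebbian_train(memories, center = center)
  m <- n_memories(memories)
  grid <- expand.grid(noise = noise_levels, injury = injury_levels,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (ci in seq_len(nrow(grid))) {
    for (rep_i in seq_len(replicates)) {
      set.seed(derive_seed(seed, ci, rep_i))
      p <- grid$injury[ci]
      assignment <- if (p > 0) {
        sample_assignment(net$n_neurons, p, dist, seed = derive_seed(seed, ci, rep_i, 7L))
      } else NULL
      cues <- if (is.null(n_cues)) seq_len(m) else sample.int(m, min(n_cues, m))
      trials <- lapply(cues, function(cue)
        run_trial(net, memories, cue, grid$noise[ci], assignment,
                  noise_sigma, theta, delta, max_sweeps, filter))
      cell <- summarise_cell(do.call(rbind, trials))
      k <- k + 1L
      rows[[k]] <- cbind(data.frame(noise = grid$noise[ci],
                                    injury = p, replicate = rep_i), cell)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(
    n_neurons = n_neurons(memories), n_memories = m,
    n_levels = memories$n_levels,
    dist = if (is.null(dist)) NULL else dist$probs,
    dist_label = if (is.null(dist)) NULL else dist$label,
    replicates = replicates, n_cues = n_cues, noise_sigma = noise_sigma,
    theta = theta, delta = delta, max_sweeps = max_sweeps,
    center = center, seed = seed)
  class(out) <- c("recognition_sweep", "data.frame")
  out
}

#' Aggregate a sweep and normalize by the healthy baseline
#'
#' Replicates are averaged within each (noise, injury) cell; the normalized
#' recognition score R of a cell is its mean raw score divided by the mean
#' raw score of the healthy (injury = 0) cell at the same noise level,
#' clamped to \[0, 1\].  The injury grid must therefore contain 0.
#'
#' @param x a `recognition_sweep`.
#' @return A `data.frame` with one row per cell: outcome fractions,
#'   `raw_score`, the healthy `baseline`, and the normalized score `R`.
#' @export
aggregate_sweep <- function(x) {
  if (!inherits(x, "recognition_sweep")) stop("`x` must be a recognition_sweep")
  agg <- aggregate(cbind(frac_correct, frac_none, frac_confused,
                         mean_accuracy, raw_score) ~ noise + injury,
                   data = as.data.frame(x), FUN = mean)
  agg <- agg[order(agg$noise, agg$injury), ]
  base <- agg[agg$injury == 0, c("noise", "raw_score")]
  if (nrow(base) == 0L)
    stop("injury grid must contain 0 (the healthy baseline) for normalization")
  names(base)[2] <- "baseline"
  agg <- merge(agg, base, by = "noise", sort = FALSE)
  if (any(agg$baseline <= 0))
    stop("healthy baseline score is not positive; cannot normalize")
  agg$R <- pmin(pmax(agg$raw_score / agg$baseline, 0), 1)
  agg[order(agg$noise, agg$injury), ]
}

#' Heatmap matrix of a sweep quantity
#'
#' Rows are noise levels (increasing downward), columns injury levels
#' (increasing rightward), so strong recognition sits in the upper-left
#' corner and degraded recognition in the lower-right.
#'
#' @param x an aggregated sweep (from [aggregate_sweep()]).
#' @param value which column to pivot (default `"R"`).
#' @return A numeric matrix with named dimensions.
#' @export
sweep_heatmap <- function(x, value = "R") {
  noise <- sort(unique(x$noise)); injury <- sort(unique(x$injury))
  m <- matrix(NA_real_, length(noise), length(injury),
              dimnames = list(noise = format(noise), injury = format(injury)))
  for (i in seq_len(nrow(x)))
    m[match(x$noise[i], noise), match(x$injury[i], injury)] <- x[[value]][i]
  m
}
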