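# Memory patterns and pattern generators ----------------------------------
#
# A pattern is a length-N vector of discrete activity levels 0, ..., q-1,
# the multi-state generalisation of the binary Hopfield unit: q grayscale
# activity states let one network node encode one image pixel with shades
# of grey.  Levels are embedded affinely into [-1, 1] for the network
# arithmetic (see level_values()).

#' Construct a single memory pattern
#'
#' @param levels integer vector of activity levels, each in `0:(n_levels-1)`.
#' @param n_levels number of discrete activity states q (>= 2).
#' @return An object of class `memory_pattern`: the integer level vector with
#'   an `n_levels` attribute.
#' @export
memory_pattern <- function(levels, n_levels) {
  n_levels <- as.integer(n_levels)
  if (length(n_levels) != 1L || is.na(n_levels) || n_levels < 2L)
    stop("`n_levels` must be a single integer >= 2")
  lv <- as.integer(levels)
  if (length(lv) < 1L)
    stop("a memory pattern must contain at least one neuron")
  if (anyNA(lv) || any(lv < 0L) || any(lv >= n_levels))
    stop("all levels must be integers in [0, n_levels - 1]")
  structure(lv, n_levels = n_levels, class = "memory_pattern")
}

#' @export
print.memory_pattern <- function(x, ...) {
  cat(sprintf("<memory_pattern> N = %d neurons, q = %d activity states\n",
              length(x), attr(x, "n_levels")))
  invisible(x)
}

#' Construct a set of stored memories
#'
#' @param levels integer matrix, one row per memory, entries in
#'   `0:(n_levels-1)`.
#' @param n_levels number of discrete activity states q shared by all
#'   patterns.
#' @param labels optional character labels, one per memory.
#' @return An object of class `memory_set` with elements `levels`
#'   (M x N integer matrix), `n_levels`, and `labels`.
#' @export
memory_set <- function(levels, n_levels, labels = NULL) {
  if (!is.matrix(levels)) stop("`levels` must be a matrix (one row per memory)")
  storage.mode(levels) <- "integer"
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("`n_levels` must be >= 2")
  if (nrow(levels) < 1L) stop("a memory set needs at least one pattern (M >= 1)")
  if (anyNA(levels) || any(levels < 0L) || any(levels >= n_levels))
    stop("all levels must be integers in [0, n_levels - 1]")
  if (is.null(labels)) labels <- paste0("m", seq_len(nrow(levels)))
  if (length(labels) != nrow(levels)) stop("one label per pattern required")
  structure(list(levels = levels, n_levels = n_levels,
                 labels = as.character(labels)),
            class = "memory_set")
}

#' @export
print.memory_set <- function(x, ...) {
  cat(sprintf("<memory_set> M = %d memories, N = %d neurons, q = %d levels\n",
              nrow(x$levels), ncol(x$levels), x$n_levels))
  invisible(x)
}

#' Extract one pattern from a memory set
#'
#' @param x a `memory_set`.
#' @param i pattern index.
#' @return A `memory_pattern`.
#' @export
get_pattern <- function(x, i) {
  stopifnot(inherits(x, "memory_set"))
  i <- as.integer(i)
  if (i < 1L || i > nrow(x$levels)) stop("pattern index out of range")
  memory_pattern(x$levels[i, ], x$n_levels)
}

#' Number of neurons / memories in a memory set
#' @param x a `memory_set`.
#' @return An integer.
#' @export
n_neurons <- function(x) ncol(x$levels)

#' @rdname n_neurons
#' @export
n_memories <- function(x) nrow(x$levels)

#' Generate sparse, uncorrelated random memories
#'
#' Each pattern sets a fixed number `round(active_fraction * n_neurons)` of
#' randomly chosen neurons to a uniformly random nonzero level and leaves the
#' rest silent (level 0).  With `n_levels = 2` and `active_fraction = 0.5`
#' this is the classical dense bipolar ensemble whose storage capacity is
#' about 0.14 N memories.
#'
#' @param n_neurons network size N.
#' @param n_memories number of patterns M.  A warning is issued above the
#'   0.14 N capacity estimate; more than twice that is an error.
#' @param n_levels number of activity states q (default 2).
#' @param active_fraction fraction of neurons active per pattern, in (0, 1].
#' @param seed integer seed; mandatory, reproducibility is part of the
#'   contract.
#' @return A `memory_set`; the generator call is recorded in its
#'   `generator` attribute.
#' @seealso [expected_overlap_random()] for the closed-form expected
#'   pairwise overlap of this ensemble.
#' @export
generate_random_memories <- function(n_neurons, n_memories, n_levels = 2,
                                     active_fraction = 0.5, seed) {
  if (missing(seed)) stop("`seed` is required (reproducibility is mandatory)")
  n_neurons <- as.integer(n_neurons); n_memories <- as.integer(n_memories)
  if (n_neurons < 1L || n_memories < 1L)
    stop("`n_neurons` and `n_memories` must be positive")
  if (!(active_fraction > 0 && active_fraction <= 1))
    stop("`active_fraction` must lie in (0, 1]")
  cap <- 0.14 * n_neurons
  if (n_memories > 2 * ceiling(cap))
    stop(sprintf("n_memories = %d exceeds twice the ~0.14 N capacity of N = %d",
                 n_memories, n_neurons))
  if (n_memories > cap)
    warning(sprintf("n_memories = %d exceeds the ~0.14 N capacity estimate (%.0f)",
                    n_memories, cap))
  q <- as.integer(n_levels)
  if (q < 2L) stop("`n_levels` must be >= 2")
  set.seed(seed)
  n_active <- round(active_fraction * n_neurons)
  lv <- matrix(0L, n_memories, n_neurons)
  for (m in seq_len(n_memories)) {
    pos <- sample.int(n_neurons, n_active)
    lv[m, pos] <- if (q == 2L) 1L else sample.int(q - 1L, n_active, replace = TRUE)
  }
  ms <- memory_set(lv, q)
  attr(ms, "generator") <- list(type = "random", n_neurons = n_neurons,
                                n_memories = n_memories, n_levels = q,
                                active_fraction = active_fraction, seed = seed)
  ms
}

#' Expected pairwise overlap of the random-memory ensemble
#'
#' Two independent patterns with active fraction `a` and q levels agree at a
#' position with probability (1-a)^2 + a^2/(q-1): both silent, or both active
#' at the same of the q-1 nonzero levels.
#'
#' @param active_fraction active fraction a.
#' @param n_levels number of activity states q.
#' @return Expected fraction of positions with identical level.
#' @export
expected_overlap_random <- function(active_fraction, n_levels) {
  a <- active_fraction
  (1 - a)^2 + a^2 / (n_levels - 1)
}

#' Generate a correlated memory family
#'
#' Emulates a set of highly similar memories (such as faces sharing global
#' structure): a template pattern is drawn, a shared fraction c of positions
#' is copied into every family member, and the remaining positions are
#' i.i.d. uniform over the q levels.  The expected pairwise overlap is then
#' c + (1 - c)/q, and c is solved from the requested `target_overlap`.
#'
#' @param n_neurons network size N.
#' @param n_memories family size M.
#' @param n_levels number of activity states q (default 8).
#' @param target_overlap desired expected pairwise overlap, in (1/q, 1).
#' @param seed integer seed (mandatory).
#' @return A `memory_set` with a `generator` attribute.
#' @export
generate_correlated_family <- function(n_neurons, n_memories, n_levels = 8,
                                       target_overlap = 0.65, seed) {
  if (missing(seed)) stop("`seed` is required (reproducibility is mandatory)")
  n_neurons <- as.integer(n_neurons); n_memories <- as.integer(n_memories)
  if (n_neurons < 1L || n_memories < 1L)
    stop("`n_neurons` and `n_memories` must be positive")
  q <- as.integer(n_levels)
  if (q < 2L) stop("`n_levels` must be >= 2")
  if (!(target_overlap > 1 / q && target_overlap < 1))
    stop(sprintf("`target_overlap` must lie in (1/q, 1) = (%.3f, 1) for q = %d",
                 1 / q, q))
  copy_frac <- (target_overlap - 1 / q) / (1 - 1 / q)
  set.seed(seed)
  template <- sample.int(q, n_neurons, replace = TRUE) - 1L
  shared <- sample.int(n_neurons, round(copy_frac * n_neurons))
  lv <- matrix(0L, n_memories, n_neurons)
  for (m in seq_len(n_memories)) {
    row <- sample.int(q, n_neurons, replace = TRUE) - 1L
    row[shared] <- template[shared]
    lv[m, ] <- row
  }
  ms <- memory_set(lv, q)
  attr(ms, "generator") <- list(type = "correlated", n_neurons = n_neurons,
                                n_memories = n_memories, n_levels = q,
                                target_overlap = target_overlap,
                                copy_fraction = copy_frac, seed = seed)
  ms
}

#' Quantize a grayscale image into a memory pattern
#'
#' Pixels are flattened row-major and quantized to
#' `floor(intensity * q / 256)`, clamped to q - 1.
#'
#' @param pixels numeric matrix of grayscale intensities in \[0, 255\].
#' @param n_levels number of activity states q (>= 2).
#' @return A `memory_pattern` of length `nrow(pixels) * ncol(pixels)`, with
#'   the original image dimensions in its `image_dim` attribute.
#' @export
encode_image <- function(pixels, n_levels) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  q <- as.integer(n_levels)
  if (q < 2L) stop("`n_levels` must be >= 2")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stop("pixel intensities must lie in [0, 255]")
  lv <- pmin(floor(pixels * q / 256), q - 1L)
  # t(): R matrices are column-major, the pattern is defined row-major
  p <- memory_pattern(as.integer(t(lv)), q)
  attr(p, "image_dim") <- dim(pixels)
  p
}

#' Corrupt a pattern with exact-count cue noise
#'
#' Exactly `round(noise_level * N)` positions, chosen without replacement,
#' are reassigned a uniformly random level *different* from their current
#' one, so the overlap with the original is 1 - noise_level by construction.
#'
#' @param pattern a `memory_pattern`.
#' @param noise_level fraction of positions to corrupt, in \[0, 1\].
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so trial drivers can manage seeding themselves).
#' @return A corrupted `memory_pattern`.
#' @export
add_cue_noise <- function(pattern, noise_level, seed = NULL) {
  if (!inherits(pattern, "memory_pattern"))
    stop("`pattern` must be a memory_pattern")
  if (!is.numeric(noise_level) || length(noise_level) != 1L ||
      is.na(noise_level) || noise_level < 0 || noise_level > 1)
    stop("`noise_level` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  q <- attr(pattern, "n_levels")
  n <- length(pattern)
  k <- round(noise_level * n)
  if (k == 0L) return(pattern)
  out <- unclass(pattern)
  pos <- sample.int(n, k)
  # adding a uniform nonzero shift mod q is a uniform draw over the other levels
  out[pos] <- (out[pos] + sample.int(q - 1L, k, replace = TRUE)) %% q
  attributes(out) <- attributes(pattern)
  out
}

#' Overlap between two level vectors
#'
#' Overlap is 1 minus the normalized Hamming distance: the fraction of
#' positions at which the two patterns have identical activity level.
#'
#' @param x,y integer level vectors (or `memory_pattern`s) of equal length.
#' @return A fraction in \[0, 1\].
#' @export
overlap <- function(x, y) {
  if (length(x) != length(y)) stop("patterns must have equal length")
  mean(unclass(x) == unclass(y))
}

#' Pairwise overlap matrix of a memory set
#'
#' @param x a `memory_set` (or an integer level matrix, one row per pattern).
#' @return A symmetric M x M matrix of overlaps with unit diagonal.
#' @export
pairwise_overlap <- function(x) {
  lv <- if (inherits(x, "memory_set")) x$levels else x
  labs <- if (inherits(x, "memory_set")) x$labels else NULL
  q <- max(lv) + 1L
  n <- ncol(lv)
  ov <- matrix(0, nrow(lv), nrow(lv))
  for (l in seq_len(q) - 1L) {
    ind <- (lv == l) * 1
    ov <- ov + tcrossprod(ind)
  }
  ov <- ov / n
  dimnames(ov) <- list(labs, labs)
  ov
}

#' Mean off-diagonal pairwise overlap
#' @param x a `memory_set`.
#' @return The mean overlap over all distinct pattern pairs.
#' @export
mean_pairwise_overlap <- function(x) {
  ov <- pairwise_overlap(x)
  if (nrow(ov) < 2L) return(NA_real_)
  mean(ov[upper.tri(ov)])
}
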