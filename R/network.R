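# Multi-state Hopfield network: Hebbian training and recall dynamics ------

#' Bipolar embedding of activity levels
#'
#' Levels 0, ..., q-1 are mapped affinely onto q equally spaced values in
#' \[-1, 1\]; for q = 2 this is the classical bipolar -1/+1 coding.
#'
#' @param n_levels number of activity states q.
#' @return Numeric vector of length q.
#' @export
level_values <- function(n_levels) seq(-1, 1, length.out = n_levels)

#' Train a Hopfield network with the Hebbian outer-product rule
#'
#' The coupling matrix is \eqn{w_{ij} = \sum_\mu v^\mu_i v^\mu_j / (N
#' \bar{v^2})} for i != j and 0 on the diagonal, where \eqn{v^\mu} is the
#' bipolar embedding of stored pattern \eqn{\mu} and \eqn{\bar{v^2}} the
#' mean squared embedded activity over the training set.  The activity
#' normalisation makes the local field at a stored pattern reproduce the
#' pattern itself (h ~ v) for any number of activity states; for q = 2
#' bipolar patterns \eqn{\bar{v^2} = 1} and the rule reduces to the
#' classical outer product whose storage capacity is about 0.14 N.
#'
#' With `center = TRUE` the network is trained for *correlated* memory
#' families (use it for the grayscale face-like tasks): each neuron's mean
#' activity over the training set, \eqn{\bar v_i}, is subtracted, the
#' couplings are the projection (pseudo-inverse) operator onto the span of
#' the deviation patterns, and the recall field becomes
#' \eqn{h_i = \bar v_i + \sum_j w_{ij} (v_j - \bar v_j)}.  A shared template
#' would swamp plain outer-product couplings and destroy the stored fixed
#' points, and with few memories the deviation norms vary enough that
#' outer-product gains per pattern drift from 1; the projection operator
#' gives every stored pattern unit gain exactly, whatever its norm.
#' Requires M >= 2.
#'
#' @param memories a `memory_set`.
#' @param center use the covariance (mean-centered) rule; default `FALSE`,
#'   the classical rule.
#' @return An object of class `hopfield_network` with elements `weights`
#'   (N x N symmetric, zero diagonal), `n_neurons`, `n_levels`,
#'   `level_values`, and `center` (per-neuron reference activity; all zero
#'   for the classical rule).
#' @export
hebbian_train <- function(memories, center = FALSE) {
  if (!inherits(memories, "memory_set")) stop("`memories` must be a memory_set")
  vals <- level_values(memories$n_levels)
  v <- matrix(vals[memories$levels + 1L], nrow(memories$levels))
  if (center && nrow(v) < 2L)
    stop("the covariance rule needs at least two memories")
  cbar <- if (center) colMeans(v) else numeric(ncol(v))
  d <- sweep(v, 2L, cbar)
  msq <- mean(d^2)
  if (msq == 0) stop("degenerate memory set: no activity variation to encode")
  if (center) {
    # projection onto the span of the deviation patterns: W d_mu = d_mu for
    # every stored pattern (the Gram matrix is rank M-1 because centering
    # makes the deviations sum to zero, hence the pseudo-inverse)
    g <- tcrossprod(d)
    eg <- eigen(g, symmetric = TRUE)
    keep <- eg$values > max(eg$values) * 1e-10
    ginv <- eg$vectors[, keep, drop = FALSE] %*%
      (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
    w <- crossprod(d, ginv %*% d)
    w <- (w + t(w)) / 2  # exact symmetry (the sweep kernel relies on it)
  } else {
    w <- crossprod(d) / (ncol(v) * msq)
  }
  diag(w) <- 0
  structure(list(weights = w, n_neurons = ncol(v),
                 n_levels = memories$n_levels, level_values = vals,
                 center = cbar),
            class = "hopfield_network")
}

#' @export
print.hopfield_network <- function(x, ...) {
  cat(sprintf("<hopfield_network> N = %d neurons, q = %d activity states\n",
              x$n_neurons, x$n_levels))
  invisible(x)
}

as_values <- function(net, levels) net$level_values[as.integer(levels) + 1L]

check_state <- function(net, levels) {
  if (length(levels) != net$n_neurons) stop("state length does not match network size")
  if (any(levels < 0L) || any(levels >= net$n_levels)) stop("state levels out of range")
  invisible(TRUE)
}

regime_vector <- function(net, assignment) {
  if (is.null(assignment)) return(integer(net$n_neurons))
  if (!inherits(assignment, "fas_assignment")) stop("`assignment` must be a fas_assignment")
  if (length(assignment$regime) != net$n_neurons)
    stop("injury assignment length does not match network size")
  assignment$regime
}

#' Local field at every neuron
#'
#' \eqn{h_i = \bar v_i + \sum_j w_{ij} \tilde v_j}, where \eqn{\tilde v_j}
#' is the injury-transformed effective output of neuron j (its transmitted
#' signal, measured from the network's reference activity \eqn{\bar v};
#' equal to the signal itself when the network is healthy; see
#' [effective_output()]).  For classically trained networks \eqn{\bar v = 0}
#' and this is the textbook Hopfield field.
#'
#' @param net a `hopfield_network`.
#' @param levels integer state vector (levels in `0:(q-1)`).
#' @param assignment optional `fas_assignment`; `NULL` means healthy.
#' @param filter a [filter_spec()] with the filtering-regime parameters.
#' @return Numeric vector of length N.
#' @export
local_field <- function(net, levels, assignment = NULL, filter = filter_spec()) {
  check_state(net, levels)
  v <- as_values(net, levels) - net$center
  e <- if (is.null(assignment)) v else effective_output(v, assignment, filter)
  drop(net$weights %*% e) + net$center
}

#' One asynchronous update sweep
#'
#' Neurons are visited in a fresh random permutation; each computes its local
#' field from the current (partially updated) effective outputs, adds a
#' Gaussian perturbation of standard deviation `noise_sigma`, clamps the
#' result to \[-1, 1\], and adopts the nearest activity level (ties broken
#' toward the lower level index).  Blocked neurons are frozen and skipped.
#'
#' @inheritParams local_field
#' @param noise_sigma standard deviation of the per-update Gaussian field
#'   perturbation (the Brownian-noise proxy for stochastic fluctuations).
#' @return The updated integer level vector.
#' @export
update_sweep <- function(net, levels, noise_sigma = 0, assignment = NULL,
                         filter = filter_spec()) {
  check_state(net, levels)
  res <- cpp_run_dynamics(net$weights, as.integer(levels), net$level_values,
                          net$center, noise_sigma,
                          regime_vector(net, assignment),
                          filter$theta, filter$kappa,
                          max_sweeps = 1L, single_sweep = TRUE)
  res$levels
}

#' Run recall dynamics to convergence
#'
#' Repeats asynchronous sweeps until convergence or `max_sweeps`.  With
#' `noise_sigma = 0` a single change-free sweep declares convergence; with
#' dynamic noise two consecutive change-free sweeps are required.
#'
#' @inheritParams update_sweep
#' @param max_sweeps maximum number of full sweeps (>= 1), default 100.
#' @return A list with `levels` (final integer state), `converged` (logical),
#'   and `sweeps` (number of sweeps used).
#' @export
run_to_convergence <- function(net, levels, noise_sigma = 0.1,
                               assignment = NULL, max_sweeps = 100,
                               filter = filter_spec()) {
  if (!is.numeric(max_sweeps) || max_sweeps < 1) stop("`max_sweeps` must be >= 1")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  check_state(net, levels)
  cpp_run_dynamics(net$weights, as.integer(levels), net$level_values,
                   net$center, noise_sigma, regime_vector(net, assignment),
                   filter$theta, filter$kappa,
                   max_sweeps = as.integer(max_sweeps), single_sweep = FALSE)
}

#' Hopfield energy of a network state
#'
#' \eqn{E = -\tfrac12 \sum_{i \ne j} w_{ij} d_i d_j - \sum_i \bar v_i d_i}
#' with \eqn{d = v - \bar v}; for classically trained networks
#' (\eqn{\bar v = 0}) this is the textbook
#' \eqn{-\tfrac12 \sum_{i \ne j} w_{ij} v_i v_j}.  For q = 2 the
#' asynchronous noiseless healthy dynamics never increase E (Lyapunov
#' property of the sign rule with symmetric zero-diagonal couplings).
#'
#' @inheritParams local_field
#' @return A scalar energy.
#' @export
energy <- function(net, levels) {
  check_state(net, levels)
  d <- as_values(net, levels) - net$center
  -0.5 * drop(crossprod(d, net$weights %*% d)) - sum(net$center * d)
}
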