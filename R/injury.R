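# Focal axonal swelling (FAS) injury model ---------------------------------
#
# Each injured neuron carries a swelling on its axon that distorts the spike
# train it transmits.  Four impaired-response regimes are distinguished:
# unimpaired transmission, rate filtering, spike reflection (rate halving)
# and blockage (no signal passes).  A "pie-chart" gives the mixture of
# regimes among injured neurons; the injury level p is the fraction of
# neurons carrying a swelling at all.
#
# Regime codes used throughout: 0 = uninjured, 1 = transmission,
# 2 = filtering, 3 = reflection, 4 = blockage.

FAS_REGIMES <- c("uninjured", "transmission", "filtering", "reflection", "blockage")

#' Pie-chart of FAS regimes among injured neurons
#'
#' @param transmission,filtering,reflection,blockage regime probabilities;
#'   must be non-negative and sum to 1 (tolerance 1e-9).
#' @param label optional name for the mixture (e.g. `"f60b40"`).
#' @return An object of class `fas_distribution`.
#' @export
fas_distribution <- function(transmission = 0, filtering = 0, reflection = 0,
                             blockage = 0, label = NULL) {
  p <- c(transmission = transmission, filtering = filtering,
         reflection = reflection, blockage = blockage)
  if (any(!is.finite(p)) || any(p < 0))
    stop("regime probabilities must be finite and non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("regime probabilities must sum to 1 (tolerance 1e-9)")
  structure(list(probs = p, label = label), class = "fas_distribution")
}

#' @export
print.fas_distribution <- function(x, ...) {
  cat(sprintf("<fas_distribution>%s transmission %.2f | filtering %.2f | reflection %.2f | blockage %.2f\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$probs[1], x$probs[2], x$probs[3], x$probs[4]))
  invisible(x)
}

#' Shipped filtering/blockage mixtures
#'
#' The three filtering/blockage mixtures used for the random-pattern
#' deterioration sweeps (f = filtering share, b = blockage share, with
#' transmission = reflection = 0), plus the pure-blockage mixture that
#' reproduces classical binary lesion studies.
#'
#' @return A named list of `fas_distribution` objects.
#' @export
fas_presets <- function() {
  list(
    f60b40 = fas_distribution(filtering = 0.6, blockage = 0.4, label = "f60b40"),
    f40b60 = fas_distribution(filtering = 0.4, blockage = 0.6, label = "f40b60"),
    f20b80 = fas_distribution(filtering = 0.2, blockage = 0.8, label = "f20b80"),
    blockage_only = fas_distribution(blockage = 1, label = "blockage_only")
  )
}

#' Parameters of the filtering regime
#'
#' Filtering attenuates high firing rates (spike pile-up inside the
#' swelling): rates at or below the knee `theta` pass unchanged, rates above
#' it are compressed with slope `kappa`, i.e.
#' `r_out = theta + kappa * (r - theta)` for `r > theta`.  The map is
#' monotone non-decreasing and never increases a rate.
#'
#' @param theta knee of the piecewise-linear soft cap, in \[0, 1\] (default 0.5).
#' @param kappa compression slope above the knee, in \[0, 1\] (default 0.25).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(theta = 0.5, kappa = 0.25) {
  if (!is.numeric(theta) || theta < 0 || theta > 1) stop("`theta` must lie in [0, 1]")
  if (!is.numeric(kappa) || kappa < 0 || kappa > 1) stop("`kappa` must lie in [0, 1]")
  structure(list(theta = theta, kappa = kappa), class = "filter_spec")
}

#' Draw a per-neuron injury assignment
#'
#' Exactly `round(injury_level * n_neurons)` neurons, chosen uniformly
#' without replacement, are injured; each injured neuron's regime is drawn
#' independently from the pie-chart.  The remaining neurons are uninjured.
#'
#' @param n_neurons network size N.
#' @param injury_level fraction p of injured neurons, in \[0, 1\].
#' @param dist a `fas_distribution`.
#' @param seed integer seed (mandatory).
#' @return An object of class `fas_assignment` with elements `regime`
#'   (integer vector over 0:4), `injury_level`, `distribution`, `seed`.
#' @export
sample_assignment <- function(n_neurons, injury_level, dist, seed) {
  if (missing(seed)) stop("`seed` is required (reproducibility is mandatory)")
  if (!inherits(dist, "fas_distribution")) stop("`dist` must be a fas_distribution")
  if (!is.numeric(injury_level) || length(injury_level) != 1L ||
      is.na(injury_level) || injury_level < 0 || injury_level > 1)
    stop("`injury_level` must lie in [0, 1]")
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 1L) stop("`n_neurons` must be positive")
  set.seed(seed)
  regime <- integer(n_neurons)
  k <- round(injury_level * n_neurons)
  if (k > 0L) {
    injured <- sample.int(n_neurons, k)
    regime[injured] <- sample.int(4L, k, replace = TRUE, prob = dist$probs)
  }
  structure(list(regime = regime, injury_level = injury_level,
                 distribution = dist, seed = seed),
            class = "fas_assignment")
}

#' @export
print.fas_assignment <- function(x, ...) {
  tab <- table(factor(x$regime, levels = 0:4, labels = FAS_REGIMES))
  cat(sprintf("<fas_assignment> N = %d, injury level p = %.3f\n",
              length(x$regime), x$injury_level))
  print(tab)
  invisible(x)
}

#' FAS transfer function on firing rates
#'
#' Maps a pre-injury firing rate in \[0, 1\] to the post-injury effective
#' rate: uninjured and transmission pass unchanged, reflection halves the
#' rate (the reflected spike annihilates an oncoming one), blockage zeroes
#' it, and filtering applies the soft cap of [filter_spec()].  With
#' `stochastic = TRUE` the filtering cap is applied with probability equal
#' to the rate itself (higher rates are more likely to be attenuated by
#' pile-up) and the rate passes unchanged otherwise; the deterministic map
#' is the default used by the recall dynamics.
#'
#' @param value firing rate(s) in \[0, 1\].
#' @param regime integer regime code(s) in 0:4 (recycled against `value`).
#' @param filter a [filter_spec()].
#' @param stochastic use the stochastic filtering variant (draws from the
#'   current RNG stream).
#' @return Effective firing rate(s) in \[0, 1\].
#' @export
fas_transfer <- function(value, regime, filter = filter_spec(),
                         stochastic = FALSE) {
  if (any(!is.finite(value)) || any(value < 0) || any(value > 1))
    stop("firing rates must lie in [0, 1]")
  regime <- as.integer(regime)
  if (any(is.na(regime)) || any(regime < 0L) || any(regime > 4L))
    stop("unknown injury regime (codes 0:4 expected)")
  n <- max(length(value), length(regime))
  value <- rep_len(value, n); regime <- rep_len(regime, n)
  out <- value
  f <- regime == 2L
  if (any(f)) {
    capped <- ifelse(value[f] <= filter$theta, value[f],
                     filter$theta + filter$kappa * (value[f] - filter$theta))
    if (stochastic) {
      apply_cap <- stats::runif(sum(f)) < value[f]
      out[f] <- ifelse(apply_cap, capped, value[f])
    } else {
      out[f] <- capped
    }
  }
  out[regime == 3L] <- 0.5 * value[regime == 3L]
  out[regime == 4L] <- 0
  out
}

#' Injury-transformed effective outputs
#'
#' Applies the FAS transfer function of each neuron's regime to the
#' *magnitude* of its transmitted bipolar signal, preserving the sign:
#' filtering soft-caps strong signals, reflection halves the signal, and
#' blocked neurons transmit nothing at all — their effective output is 0 in
#' field space (absence of signal, equivalent to removing the neuron's
#' outgoing couplings).  Because a blocked neuron's effective firing rate
#' *is* its state, the recall dynamics additionally silence blocked neurons
#' (force them to the lowest activity level) and freeze them there, so they
#' neither influence nor adapt to the collective dynamics.  This keeps the
#' severity ordering of the regimes: transmission, then filtering, then
#' reflection, then blockage as the most severe.
#'
#' @param values numeric vector of bipolar neuron values in \[-1, 1\].
#' @param assignment a `fas_assignment`.
#' @param filter a [filter_spec()].
#' @return Numeric vector of effective outputs feeding the local fields.
#' @export
effective_output <- function(values, assignment, filter = filter_spec()) {
  if (!inherits(assignment, "fas_assignment"))
    stop("`assignment` must be a fas_assignment")
  reg <- assignment$regime
  if (length(values) != length(reg))
    stop("state and injury assignment must have equal length")
  out <- values
  f <- reg == 2L
  if (any(f)) {
    m <- abs(values[f])
    mt <- ifelse(m <= filter$theta, m, filter$theta + filter$kappa * (m - filter$theta))
    out[f] <- sign(values[f]) * mt
  }
  out[reg == 3L] <- 0.5 * values[reg == 3L]
  out[reg == 4L] <- 0
  out
}

#' Read a FAS pie-chart from YAML or JSON
#'
#' The file must provide the keys `transmission`, `filtering`, `reflection`,
#' `blockage` (missing keys default to 0); values are normalized to sum to 1.
#' A warning is issued when the blockage share is 0.5 or more, since in all
#' experimentally derived mixtures fewer than half of injured neurons are in
#' the blocking regime.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `fas_distribution`.
#' @export
read_fas_distribution <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path),
                stop("unsupported pie-chart format: ", ext))
  keys <- c("transmission", "filtering", "reflection", "blockage")
  unknown <- setdiff(setdiff(names(raw), keys), "label")
  if (length(unknown))
    stop("unknown pie-chart keys: ", paste(unknown, collapse = ", "))
  p <- vapply(keys, function(k) as.numeric(raw[[k]] %||% 0), numeric(1))
  if (any(p < 0) || sum(p) <= 0) stop("pie-chart fractions must be non-negative and not all zero")
  p <- p / sum(p)
  if (p[["blockage"]] >= 0.5)
    warning("blockage share >= 0.5: experimentally derived FAS mixtures have < 50% blockage")
  fas_distribution(p[1], p[2], p[3], p[4], label = raw$label %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
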