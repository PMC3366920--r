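#' First-order Boltzmann curve
#'
#' Activation curves rise with voltage,
#' 1 / (1 + exp(-(v - v_half) / slope)); inactivation (availability)
#' curves fall, 1 / (1 + exp((v - v_half) / slope)). Exponents are
#' clamped at +/-700 so extreme voltages stay numerically finite.
#'
#' @param v Membrane potential(s), mV.
#' @param v_half Midpoint, mV.
#' @param slope Slope factor, mV per e-fold (> 0).
#' @param direction `"inactivation"` (decreasing) or `"activation"`.
#' @return Values in (0, 1), same length as `v`.
#' @examples
#' boltzmann(-80, -72.4, 3.7)             # availability at -80 mV
#' boltzmann(-20, -26.5, 17.9, "activation")
#' @export
boltzmann <- function(v, v_half, slope,
                      direction = c("inactivation", "activation")) {
  direction <- match.arg(direction)
  if (slope <= 0) stop("`slope` must be > 0")
  z <- (v - v_half) / slope
  if (direction == "activation") z <- -z
  z <- pmin(pmax(z, -700), 700)
  1 / (1 + exp(z))
}

#' Per-subunit midpoint shift from homomeric endpoints
#'
#' Assuming each DPP6K subunit contributes an equal energetic shift to
#' the steady-state inactivation midpoint, the per-subunit shift is the
#' difference between the all-DPP6K and all-DPP6a midpoints divided by
#' the number of DPP6 sites per channel.
#'
#' @param v_half_all_a Midpoint with all-DPP6a channels, mV.
#' @param v_half_all_K Midpoint with all-DPP6K channels, mV.
#' @param n_sites DPP6 sites per channel (> 0).
#' @return Shift per DPP6K subunit, mV (negative = hyperpolarizing).
#' @examples
#' per_subunit_shift(-63.3, -72.4, 4)  # about -2.3 mV
#' @export
per_subunit_shift <- function(v_half_all_a, v_half_all_K, n_sites) {
  if (!is.numeric(n_sites) || length(n_sites) != 1 || n_sites <= 0) {
    stop("`n_sites` must be a positive integer")
  }
  (v_half_all_K - v_half_all_a) / n_sites
}

#' Shift-model description of mixed-channel availability
#'
#' @param base_v_half,base_slope Boltzmann parameters of the all-DPP6a
#'   availability curve (mV; mV per e-fold).
#' @param delta_v_per_K Midpoint shift per incorporated DPP6K subunit,
#'   mV (default -2.3).
#' @return Object of class `shift_model`.
#' @export
shift_model <- function(base_v_half = -63.3, base_slope = 4.3,
                        delta_v_per_K = -2.3) {
  if (base_slope <= 0) stop("`base_slope` must be > 0")
  structure(list(base_v_half = base_v_half, base_slope = base_slope,
                 delta_v_per_K = delta_v_per_K),
            class = "shift_model")
}

#' Availability curve of a binomial mixture of shifted Boltzmanns
#'
#' Each subunit composition contributes the base availability curve
#' shifted by `n_K * delta_v_per_K` mV; the population curve is the
#' assembly-probability-weighted sum.
#'
#' @param dist Assembly distribution from [assembly_distribution()] (or
#'   any tibble with columns `n_K`, `prob`).
#' @param model A [shift_model()].
#' @param v_grid Voltages, mV.
#' @return Tibble with columns `v` and `availability`.
#' @export
mixed_ssi_curve <- function(dist, model, v_grid) {
  stopifnot(inherits(model, "shift_model"))
  if (length(v_grid) == 0) stop("`v_grid` must be non-empty")
  if (abs(sum(dist$prob) - 1) > 1e-9) stop("`dist$prob` must sum to 1")
  avail <- rep(0, length(v_grid))
  for (k in seq_len(nrow(dist))) {
    avail <- avail + dist$prob[k] *
      boltzmann(v_grid, model$base_v_half + dist$n_K[k] * model$delta_v_per_K,
                model$base_slope, "inactivation")
  }
  tibble::tibble(v = v_grid, availability = avail)
}

#' Refit a single Boltzmann to a summed availability curve
#'
#' Least-squares fit of a first-order Boltzmann (fixed unit maximum) to
#' availability data, as applied to the binomially summed mixture
#' curves.
#'
#' @param v Voltages, mV (>= 4 points spanning the transition).
#' @param availability Availability values.
#' @param direction Passed to [boltzmann()].
#' @return Object of class `boltzmann_fit` with `v_half`, `slope`,
#'   `direction`, `rss`, `converged`, `n_iter`, and the data.
#' @export
refit_single_boltzmann <- function(v, availability,
                                   direction = "inactivation") {
  fit_boltzmann_curve(tibble::tibble(v = v, y = availability),
                      v_col = "v", y_col = "y", direction = direction)
}

#' Linear regression of fitted midpoints on DPP6K mole fraction
#'
#' Ordinary least squares line through (mole fraction, fitted midpoint)
#' points; under the per-subunit shift model the relation is linear with
#' slope `n_sites * delta_v_per_K`.
#'
#' @param data Data frame with the regression variables.
#' @param x_col,y_col Column names (defaults `x_K`, `v_half`).
#' @return One-row tibble: `slope` (mV per unit mole fraction),
#'   `intercept` (mV), `r_squared`.
#' @export
midpoint_regression <- function(data, x_col = "x_K", y_col = "v_half") {
  x <- data[[x_col]]; y <- data[[y_col]]
  if (length(unique(x)) < 2) {
    stop("need >= 2 distinct mole-fraction values for a regression")
  }
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 1 else summary(fit)$r.squared
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2)
}
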