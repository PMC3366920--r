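# Report-level conveniences: stoichiometry prediction tables, the SSI
# mixture experiment, and a self-contained reproduction report of the
# model's headline predictions.

#' Stoichiometry prediction table
#'
#' For each DPP6a/DPP6K composition (all compositions of the model's
#' site count by default), reports the predicted fast inactivation time
#' constant, the fast component's amplitude in the open-state
#' relaxation, and the equilibrium open/inactivated occupancies.
#'
#' @param spec A [model_spec()] or preset name (`"model1-4"`, ...).
#' @param compositions Optional data frame with columns `n_a`, `n_K`.
#' @return Tibble with one row per composition: `n_a`, `n_K`,
#'   `tau_fast_ms` (rounded to 0.1 ms, the reporting precision),
#'   `fast_amplitude`, `p_open_eq`, `p_inactivated_eq`.
#' @examples
#' stoich_predict("model1-4")
#' @export
stoich_predict <- function(spec, compositions = NULL) {
  if (is.character(spec)) spec <- model_preset(spec)
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(compositions)) {
    compositions <- tibble::tibble(n_a = 0:spec$n_sites,
                                   n_K = spec$n_sites - 0:spec$n_sites)
  }
  purrr::map_dfr(seq_len(nrow(compositions)), function(i) {
    n_a <- compositions$n_a[i]; n_K <- compositions$n_K[i]
    sch <- build_inactivation_scheme(n_a, n_K, spec)
    if (length(sch$states) == 1) {
      return(tibble::tibble(n_a = n_a, n_K = n_K, tau_fast_ms = NA_real_,
                            fast_amplitude = NA_real_, p_open_eq = 1,
                            p_inactivated_eq = 0))
    }
    sp <- relaxation_spectrum(sch)
    eq <- equilibrium_occupancy(sch)
    fast <- which.min(sp$components$tau)
    tibble::tibble(
      n_a = n_a, n_K = n_K,
      tau_fast_ms = round(sp$components$tau[fast] * 1000, 1),
      fast_amplitude = sp$components$amplitude[fast],
      p_open_eq = eq[["O"]], p_inactivated_eq = 1 - eq[["O"]])
  })
}

#' Steady-state-inactivation mixture experiment
#'
#' For each DPP6K mole fraction, builds the binomial assembly
#' distribution, sums the per-composition shifted Boltzmann curves,
#' refits a single Boltzmann, and regresses the fitted midpoints on
#' mole fraction.
#'
#' @param model A [shift_model()] (defaults to the all-DPP6a base curve
#'   with a -2.3 mV shift per DPP6K subunit).
#' @param mole_fractions_K DPP6K mole fractions to evaluate.
#' @param n_sites DPP6 sites per channel.
#' @param bias_a DPP6a assembly bias (see [assembly_distribution()]).
#' @param v_grid Refit voltage grid, mV (default -110 to -30 in 2 mV
#'   steps, spanning all reported midpoints).
#' @return List with `table` (tibble: `x_K`, `v_half`, `slope`, `rss`)
#'   and `regression` (see [midpoint_regression()]).
#' @examples
#' ssi_mix(mole_fractions_K = c(0, 0.5, 1))
#' @export
ssi_mix <- function(model = shift_model(),
                    mole_fractions_K = seq(0, 1, 0.25), n_sites = 4,
                    bias_a = 1, v_grid = seq(-110, -30, by = 2)) {
  stopifnot(inherits(model, "shift_model"))
  tab <- purrr::map_dfr(mole_fractions_K, function(x_K) {
    dist <- assembly_distribution(1 - x_K, n_sites, bias_a)
    curve <- mixed_ssi_curve(dist, model, v_grid)
    fit <- refit_single_boltzmann(curve$v, curve$availability)
    tibble::tibble(x_K = x_K, v_half = fit$v_half, slope = fit$slope,
                   rss = fit$rss)
  })
  list(table = tab, regression = midpoint_regression(tab))
}

#' Reproduce the model's headline predictions
#'
#' Recomputes, from the published rate constants and midpoints, the
#' quantities the kinetic and shift models predict: the four fast time
#' constants for channels with one DPP6a subunit, the rate-constant
#' derivations from (tau, f) pairs, the model self-consistency checks,
#' and the per-subunit SSI shift. Each row carries the computed value,
#' the printed value, and a pass flag at the stated precision.
#'
#' @return Tibble with columns `id`, `quantity`, `computed`, `printed`,
#'   `tolerance`, `pass`.
#' @export
reproduce_report <- function() {
  ms <- function(x) x * 1000
  row <- function(id, quantity, computed, printed, tolerance) {
    tibble::tibble(id = id, quantity = quantity, computed = computed,
                   printed = printed, tolerance = tolerance,
                   pass = abs(computed - printed) <= tolerance)
  }
  r_a <- rates_from_fast_fit(0.006, 0.71)
  r_int <- rates_from_fast_fit(0.035, 0.74)
  eq1 <- equilibrium_occupancy(
    build_inactivation_scheme(4, 0, model_spec("model1", 4)))
  dplyr::bind_rows(
    row("t1", "Model #1 fast tau, 1 DPP6a of 4 sites (ms)",
        round(ms(predicted_fast_tau(1, 3, model_spec("model1", 4))), 1),
        11.6, 0.05),
    row("t2", "Model #1 fast tau, 1 DPP6a of 2 sites (ms)",
        round(ms(predicted_fast_tau(1, 1, model_spec("model1", 2))), 1),
        8.7, 0.05),
    row("t3", "Model #2 fast tau, 1 DPP6a of 4 sites (ms)",
        round(ms(predicted_fast_tau(1, 3, model_spec("model2", 4))), 1),
        11.6, 0.05),
    row("t4", "Model #2 fast tau, 1 DPP6a of 2 sites (ms)",
        round(ms(predicted_fast_tau(1, 1, model_spec("model2", 2))), 2),
        8.75, 0.005),
    row("t5", "Per-subunit N-type ON-rate, 4 sites (s^-1)",
        round(r_a$k_on / 4), 30, 0.5),
    row("t6", "Channel-level N-type OFF-rate (s^-1)",
        round(r_a$k_off), 48, 0.5),
    row("t7", "Intrinsic ON-rate (s^-1)", round(r_int$k_on), 21, 0.5),
    row("t8", "SSI shift per DPP6K subunit (mV)",
        round(per_subunit_shift(-63.3, -72.4, 4), 1), -2.3, 0.05),
    row("t9", "Model #2 fast tau, 4 DPP6a (ms)",
        round(ms(predicted_fast_tau(4, 0, model_spec("model2", 4))), 1),
        6.0, 0.05),
    row("t10", "Model #2 tau, 0 DPP6a (ms)",
        round(ms(predicted_fast_tau(0, 4, model_spec("model2", 4)))),
        35, 0.5),
    row("t11", "Model #1 all-DPP6a equilibrium inactivated fraction",
        round(1 - eq1[["O"]], 2), 0.71, 0.005))
}
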