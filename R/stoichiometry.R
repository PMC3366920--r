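#' Kinetic model specification for mixed DPP6a/DPP6K channels
#'
#' Two stoichiometry models describe how DPP6 subunit composition sets
#' inactivation kinetics of the Kv4.2+KChIP3a channel:
#' \describe{
#'   \item{model1 (full proportionate ON-rate)}{both the DPP6a-mediated
#'     (N-type) and DPP6K-mediated ON-rates scale with the respective
#'     subunit counts; OFF-rates are channel-level constants.}
#'   \item{model2 (DPP6a-only proportionate ON-rate)}{only the N-type
#'     ON-rate scales with the DPP6a count; a composition-independent
#'     intrinsic inactivation branch is always present.}
#' }
#' Default rate constants are the published per-subunit/channel values,
#' keyed by model and DPP6 site count:
#' model1/4 sites (30, 48, 5.8, 7.5), model1/2 sites (60, 48, 11.6, 7.5),
#' model2/4 sites (25, 52, 21, 7.5), model2/2 sites (50, 52, 21, 7.5),
#' all in s^-1.
#'
#' @param model_id `"model1"` or `"model2"`.
#' @param n_sites Number of DPP6 positions per channel, 2 or 4.
#' @param k_a_on Per-subunit N-type ON-rate (s^-1).
#' @param k_a_off Channel-level N-type OFF-rate (s^-1).
#' @param k_x_on For model1 the per-subunit DPP6K ON-rate; for model2 the
#'   channel-level intrinsic ON-rate (s^-1).
#' @param k_x_off Channel-level OFF-rate of the second branch (s^-1).
#' @return Object of class `model_spec`.
#' @examples
#' model_spec("model1", 4)
#' model_spec("model2", 2)
#' @export
model_spec <- function(model_id = c("model1", "model2"), n_sites = 4,
                       k_a_on = NULL, k_a_off = NULL,
                       k_x_on = NULL, k_x_off = NULL) {
  model_id <- match.arg(model_id)
  if (!n_sites %in% c(2, 4)) stop("`n_sites` must be 2 or 4")
  defaults <- list(
    `model1.4` = c(30, 48, 5.8, 7.5),
    `model1.2` = c(60, 48, 11.6, 7.5),
    `model2.4` = c(25, 52, 21, 7.5),
    `model2.2` = c(50, 52, 21, 7.5))
  d <- defaults[[paste(model_id, n_sites, sep = ".")]]
  rates <- c(k_a_on %||% d[1], k_a_off %||% d[2],
             k_x_on %||% d[3], k_x_off %||% d[4])
  if (any(rates < 0)) stop("all rates must be >= 0")
  structure(
    list(model_id = model_id, n_sites = as.integer(n_sites),
         k_a_on = rates[1], k_a_off = rates[2],
         k_x_on = rates[3], k_x_off = rates[4]),
    class = "model_spec")
}

#' Look up a model preset by name
#'
#' Preset names are `"model1-4"`, `"model1-2"`, `"model2-4"`,
#' `"model2-2"` (model, then DPP6 sites per channel).
#'
#' @param name Preset string.
#' @return A [model_spec()].
#' @export
model_preset <- function(name) {
  m <- regmatches(name, regexec("^(model[12])-([24])$", name))[[1]]
  if (length(m) == 0) {
    stop("unknown model preset '", name,
         "'; use model1-4, model1-2, model2-4 or model2-2")
  }
  model_spec(m[2], as.integer(m[3]))
}

#' @export
print.model_spec <- function(x, ...) {
  second <- if (x$model_id == "model1") "DPP6K (per subunit)" else "intrinsic (channel)"
  cat("<model_spec> ", x$model_id, ", ", x$n_sites, " DPP6 sites\n",
      "  N-type: on ", x$k_a_on, " s^-1/subunit, off ", x$k_a_off, " s^-1\n",
      "  ", second, ": on ", x$k_x_on, " s^-1, off ", x$k_x_off, " s^-1\n",
      sep = "")
  invisible(x)
}

#' Binomial assembly distribution over DPP6 subunit compositions
#'
#' Channels assemble DPP6a and DPP6K subunits independently at
#' `n_sites` positions, so the number of DPP6a subunits per channel is
#' binomial in the DPP6a mole fraction. An optional bias factor
#' over-weights DPP6a-containing assembly:
#' P(n_a) is proportional to C(n_sites, n_a) (bias_a x_a)^n_a
#' (1 - x_a)^(n_sites - n_a), renormalized. `bias_a = 1` is the exact
#' binomial; `bias_a = 2` reproduces the scenario in which
#' DPP6a-containing channels are over-represented about two-fold in
#' recordings.
#'
#' @param x_a DPP6a mole fraction in \[0, 1\].
#' @param n_sites Number of DPP6 positions (2 or 4).
#' @param bias_a Non-negative over-representation factor (default 1).
#' @return Tibble with columns `n_a`, `n_K`, `prob`; attribute `bias_a`.
#' @examples
#' assembly_distribution(0.1, 4)
#' @export
assembly_distribution <- function(x_a, n_sites = 4, bias_a = 1) {
  if (!is.numeric(x_a) || length(x_a) != 1 || x_a < 0 || x_a > 1) {
    stop("`x_a` must be a single mole fraction in [0, 1]")
  }
  if (bias_a < 0) stop("`bias_a` must be >= 0")
  n_a <- 0:n_sites
  w <- choose(n_sites, n_a) * (bias_a * x_a)^n_a * (1 - x_a)^(n_sites - n_a)
  if (sum(w) == 0) {          # x_a = 1 with bias 0, or similar corner
    w <- as.numeric(n_a == n_sites * (x_a == 1))
  }
  out <- tibble::tibble(n_a = n_a, n_K = n_sites - n_a, prob = w / sum(w))
  attr(out, "bias_a") <- bias_a
  attr(out, "n_sites") <- as.integer(n_sites)
  out
}

#' Build the inactivation gating scheme for one subunit composition
#'
#' Produces the star scheme centred on the open state O.
#' Under model1: O -> I_a at n_a * k_a_on, I_a -> O at k_a_off;
#' O -> I_K at n_K * k_K_on, I_K -> O at k_K_off.
#' Under model2: the N-type branch is as above while the intrinsic
#' branch O <-> I_int runs at composition-independent channel-level
#' rates. Branches whose ON-rate is zero are omitted.
#'
#' @param n_a,n_K DPP6a and DPP6K subunit counts; must sum to
#'   `spec$n_sites`.
#' @param spec A [model_spec()].
#' @return A [gating_scheme()].
#' @examples
#' build_inactivation_scheme(1, 3, model_spec("model1", 4))
#' @export
build_inactivation_scheme <- function(n_a, n_K, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (n_a < 0 || n_K < 0 || n_a + n_K != spec$n_sites) {
    stop("composition (", n_a, "a, ", n_K, "K) does not fill ",
         spec$n_sites, " DPP6 sites")
  }
  states <- "O"; conducting <- 1
  from <- character(); to <- character(); rate <- numeric()
  if (n_a > 0 && spec$k_a_on > 0) {
    states <- c(states, "Ia"); conducting <- c(conducting, 0)
    from <- c(from, "O", "Ia"); to <- c(to, "Ia", "O")
    rate <- c(rate, n_a * spec$k_a_on, spec$k_a_off)
  }
  second_on <- if (spec$model_id == "model1") n_K * spec$k_x_on else spec$k_x_on
  second_label <- if (spec$model_id == "model1") "IK" else "Iint"
  if (second_on > 0) {
    states <- c(states, second_label); conducting <- c(conducting, 0)
    from <- c(from, "O", second_label); to <- c(to, second_label, "O")
    rate <- c(rate, second_on, spec$k_x_off)
  }
  gating_scheme(states, conducting,
                tibble::tibble(from = from, to = to, rate = rate))
}

#' Predicted fast inactivation time constant for a composition
#'
#' Builds the composition's scheme, starts all-open, and returns the
#' fastest relaxation time constant of the open-state observable
#' (reciprocal of the largest-magnitude nonzero generator eigenvalue).
#'
#' @inheritParams build_inactivation_scheme
#' @return Fast time constant in seconds (`NA` if the scheme has no
#'   inactivated state).
#' @examples
#' predicted_fast_tau(1, 3, model_spec("model1", 4)) * 1000  # 11.6 ms
#' @export
predicted_fast_tau <- function(n_a, n_K, spec) {
  sch <- build_inactivation_scheme(n_a, n_K, spec)
  if (length(sch$states) == 1) return(NA_real_)
  fast_tau(relaxation_spectrum(sch))
}

#' Population-average open-probability decay for an expression mix
#'
#' Weights each subunit composition's open-probability trajectory by its
#' assembly probability. With `segregated = TRUE` the subunits are
#' assumed not to co-assemble: the population is a mixture of the two
#' pure compositions with weights `x_a` and `1 - x_a` (the "no
#' co-assembly" prediction).
#'
#' @param x_a DPP6a mole fraction.
#' @param spec A [model_spec()].
#' @param times Times in seconds (strictly increasing, >= 0).
#' @param bias_a Assembly bias factor (see [assembly_distribution()]).
#' @param segregated If `TRUE`, use the segregated two-population mix.
#' @return Tibble with columns `time` (s) and `p_open`.
#' @export
population_decay <- function(x_a, spec, times, bias_a = 1,
                             segregated = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (segregated) {
    dist <- tibble::tibble(n_a = c(spec$n_sites, 0L),
                           n_K = c(0L, spec$n_sites),
                           prob = c(x_a, 1 - x_a))
  } else {
    dist <- assembly_distribution(x_a, spec$n_sites, bias_a)
  }
  dist <- dist[dist$prob >= 1e-9, , drop = FALSE]
  dist$prob <- dist$prob / sum(dist$prob)
  p_open <- rep(0, length(times))
  for (k in seq_len(nrow(dist))) {
    sch <- build_inactivation_scheme(dist$n_a[k], dist$n_K[k], spec)
    if (length(sch$states) == 1) {
      p_open <- p_open + dist$prob[k]
    } else {
      occ <- simulate_occupancy(sch, times = times)
      p_open <- p_open + dist$prob[k] * occ$O
    }
  }
  tibble::tibble(time = times, p_open = p_open)
}

#' Population fast-inactivation weight for an expression mix
#'
#' The percentage of population inactivation attributed to the fast
#' N-type (DPP6a-mediated) component, under two conventions:
#' \describe{
#'   \item{`"biexp"`}{fit the population-average decay with two
#'     exponentials plus offset and report the fast component's relative
#'     weight W-1 (% of the t = 0 signal).}
#'   \item{`"equilibrium"`}{the population-weighted equilibrium fraction
#'     of inactivated channels that reside in N-type inactivated (I_a)
#'     states, as a percentage.}
#' }
#'
#' @inheritParams population_decay
#' @param convention `"biexp"`, `"equilibrium"`, or `"both"`.
#' @param duration Decay length simulated for the biexp convention,
#'   seconds.
#' @return Tibble with columns `convention` and `percent`.
#' @export
population_fast_weight <- function(x_a, spec, bias_a = 1,
                                   convention = c("both", "biexp",
                                                  "equilibrium"),
                                   duration = 1) {
  convention <- match.arg(convention)
  stopifnot(inherits(spec, "model_spec"))
  out <- list()
  if (convention %in% c("both", "equilibrium")) {
    dist <- assembly_distribution(x_a, spec$n_sites, bias_a)
    dist <- dist[dist$prob >= 1e-9, , drop = FALSE]
    p_ia <- 0; p_inact <- 0
    for (k in seq_len(nrow(dist))) {
      sch <- build_inactivation_scheme(dist$n_a[k], dist$n_K[k], spec)
      if (length(sch$states) == 1) next
      eq <- equilibrium_occupancy(sch)
      p_ia <- p_ia + dist$prob[k] * sum(eq[names(eq) == "Ia"])
      p_inact <- p_inact + dist$prob[k] * (1 - eq[["O"]])
    }
    pct <- if (p_inact > 0) 100 * p_ia / p_inact else 0
    out$equilibrium <- pct
  }
  if (convention %in% c("both", "biexp")) {
    times <- seq(0, duration, length.out = 2000)
    dec <- population_decay(x_a, spec, times, bias_a)
    df <- tibble::tibble(time_ms = dec$time * 1000, current = dec$p_open)
    fit <- fit_exp_decay(df, n_components = 2, with_offset = TRUE)
    out$biexp <- fit$weights_pct[1]
  }
  tibble::tibble(convention = names(out),
                 percent = as.numeric(unlist(out)))
}
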