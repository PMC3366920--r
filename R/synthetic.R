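# Seeded synthetic voltage-clamp data with the statistical structure the
# analysis pipeline assumes: bi-exponential decaying outward currents
# with a steady component, two-pulse recovery experiments, and
# steady-state-inactivation prepulse families following Boltzmann
# availability, all with additive Gaussian noise.

# Published fixture parameter sets for Kv4.2 channel complexes
# (oocyte ternary complexes and the native cerebellar granule-cell
# current "CG"). Decay taus in ms, weights in % of the peak signal;
# recovery taus in ms with relative weights in %; Boltzmann midpoints
# in mV with slopes in mV per e-fold. A transcription copy lives in
# inst/extdata/fixture_presets.tsv and is checked by the test suite.
preset_table <- function() {
  tibble::tribble(
    ~preset,            ~decay_tau1, ~decay_tau2, ~decay_w1, ~decay_w2, ~decay_wss,
                        ~rec_tau1, ~rec_tau2, ~rec_w1, ~rec_w2,
                        ~act_v_half, ~act_slope, ~ssi_v_half, ~ssi_slope,
    "CG",               11,   120, 72, 25,  3,    8,   68,  80, 20,  -25,   19,   -76,   8.4,
    "K3a+DPP6a",         6.0, 461, 71, 22,  7,   15.3, NA, 100, NA,  -26.5, 17.9, -63.3, 4.3,
    "K3a+DPP6S",        39.4, 177, 63, 30,  7,   24.4, NA, 100, NA,  -25.7, 19.8, -64.9, 4.7,
    "K3a+DPP6K",        35.0, 189, 74, 21,  4,   43,  265,  29, 72,  -20.1, 18.9, -72.4, 3.7,
    "K3a+noDPP6",       42.2, 192, 24, 69,  6,   76.7, NA, 100, NA,  -17.4, 20.4, -61.2, 3.6,
    "K3a+DPP6K_dN16",   70.1, 156, 40, 51,  9,   32.5, NA, 100, NA,  -15.8, 18.2, -60.2, 3.4,
    "K3a+aK_1to1",       7.4, 131, 69, 15, 16,   11.0, 199, 91,  9,  -25.6, 18.3, -66.0, 4.5,
    "K3a+aK_1to2",       6.9, 107, 70, 16, 13,   10.6, 156, 88, 12,  -25.6, 16.4, -68.8, 4.5,
    "K3a+aK_1to3",       8.5, 122, 65, 25, 10,   14.5, 207, 79, 21,  -22.9, 17.2, -69.6, 4.5,
    "K4bL+aK_1to2",      5.1,  67, 71, 16, 12,   14.3, 145, 63, 37,  -30.9, 12.1, -70.6, 4.5)
}

#' Published fixture parameter sets for the synthetic generator
#'
#' One row per channel-complex fixture (the native granule-cell current
#' `"CG"` plus oocyte-expressed complexes; `aK_1toN` denotes
#' DPP6a:DPP6K cRNA ratios). Columns hold the bi-exponential decay
#' parameters (tau in ms, weights in %), recovery parameters, and
#' activation/availability Boltzmann parameters (mV).
#'
#' @return A tibble of fixture presets.
#' @export
fixture_presets <- function() preset_table()

#' Generator parameter bundle
#'
#' @param preset Name of a fixture preset (see [fixture_presets()]), or
#'   `NULL` to pass parameters explicitly.
#' @param decay List with `taus` (ms), `weights` (%), `w_ss` (%),
#'   `peak`.
#' @param recovery List with `taus` (ms) and `weights` (fractions or
#'   percentages; normalized to sum to 1).
#' @param activation,ssi Lists with `v_half` and `slope` (mV).
#' @param noise_sd Noise standard deviation as a fraction of peak.
#' @param sampling_khz Sampling rate, kHz.
#' @param seed Integer seed for the noise stream.
#' @return Object of class `generator_params`.
#' @export
generator_params <- function(preset = NULL, decay = NULL, recovery = NULL,
                             activation = NULL, ssi = NULL,
                             noise_sd = 0, sampling_khz = 10, seed = 1) {
  if (!is.null(preset)) {
    tab <- preset_table()
    row <- tab[tab$preset == preset, ]
    if (nrow(row) != 1) {
      stop("unknown preset '", preset, "'; see fixture_presets()")
    }
    decay <- decay %||% list(taus = c(row$decay_tau1, row$decay_tau2),
                             weights = c(row$decay_w1, row$decay_w2),
                             w_ss = row$decay_wss, peak = 1)
    rec_taus <- c(row$rec_tau1, row$rec_tau2)
    rec_w <- c(row$rec_w1, row$rec_w2)
    keep <- !is.na(rec_taus)
    recovery <- recovery %||% list(taus = rec_taus[keep],
                                   weights = rec_w[keep] /
                                     sum(rec_w[keep]))
    activation <- activation %||% list(v_half = row$act_v_half,
                                       slope = row$act_slope)
    ssi <- ssi %||% list(v_half = row$ssi_v_half, slope = row$ssi_slope)
  }
  stopifnot(!is.null(decay), !is.null(recovery))
  decay$peak <- decay$peak %||% 1
  recovery$weights <- recovery$weights / sum(recovery$weights)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(preset = preset, decay = decay, recovery = recovery,
                 activation = activation, ssi = ssi,
                 noise_sd = noise_sd, sampling_khz = sampling_khz,
                 seed = as.integer(seed)),
            class = "generator_params")
}

as_generator_params <- function(x, ...) {
  if (inherits(x, "generator_params")) x else generator_params(x, ...)
}

decay_model_value <- function(decay, t_ms) {
  decay$peak * (Reduce(`+`, lapply(seq_along(decay$taus), function(i)
    decay$weights[i] / 100 * exp(-t_ms / decay$taus[i]))) +
      decay$w_ss / 100)
}

seeded_noise <- function(n, sd, seed) {
  if (sd == 0) return(rep(0, n))
  withr::with_seed(seed, stats::rnorm(n, 0, sd))
}

#' Generate a decaying outward-current trace
#'
#' y(t) = peak (sum_i W_i/100 exp(-t/tau_i) + W_ss/100) plus additive
#' Gaussian noise with standard deviation `noise_sd * peak`,
#' reproducible per seed.
#'
#' @param params A [generator_params()] or preset name.
#' @param duration_ms Trace length, ms. If shorter than 5x the slowest
#'   tau a warning note is stored in the trace metadata.
#' @param noise_sd,seed,sampling_khz Optional overrides of the bundle.
#' @return A [current_trace()].
#' @examples
#' gen_decay_trace("K3a+DPP6a", duration_ms = 1000, noise_sd = 0)
#' @export
gen_decay_trace <- function(params, duration_ms = 1000, noise_sd = NULL,
                            seed = NULL, sampling_khz = NULL) {
  p <- as_generator_params(params)
  noise_sd <- noise_sd %||% p$noise_sd
  seed <- seed %||% p$seed
  khz <- sampling_khz %||% p$sampling_khz
  dt <- 1 / khz
  t <- seq(0, duration_ms, by = dt)
  y <- decay_model_value(p$decay, t) +
    seeded_noise(length(t), noise_sd * p$decay$peak, seed)
  meta <- list(preset = p$preset, seed = seed, noise_sd = noise_sd)
  if (duration_ms < 5 * max(p$decay$taus)) {
    meta$warning <- "duration shorter than 5x the slowest decay tau"
  }
  current_trace(y, dt, "norm", metadata = meta)
}

#' Generate a two-pulse recovery-from-inactivation dataset
#'
#' A long conditioning pulse maximally inactivates the channels; after
#' each recovery interval at a hyperpolarized potential a test pulse
#' probes availability. The second-pulse current is the first-pulse
#' model scaled so that the measured fractional recovery equals
#' R(t) = 1 - sum_i w_i exp(-t/tau_i) exactly in the noiseless case.
#'
#' @param params A [generator_params()] or preset name.
#' @param intervals_ms Recovery intervals, ms (>= 0).
#' @param pulse1_ms,pulse2_ms Pulse durations, ms.
#' @inheritParams gen_decay_trace
#' @return Tibble of class `recovery_dataset` with columns
#'   `interval_ms`, `pulse1`, `pulse2` (list columns of traces).
#' @export
gen_recovery_dataset <- function(params, intervals_ms,
                                 pulse1_ms = 1000, pulse2_ms = 250,
                                 noise_sd = NULL, seed = NULL,
                                 sampling_khz = NULL) {
  p <- as_generator_params(params)
  if (any(intervals_ms < 0)) stop("recovery intervals must be >= 0")
  noise_sd <- noise_sd %||% p$noise_sd
  seed <- seed %||% p$seed
  khz <- sampling_khz %||% p$sampling_khz
  dt <- 1 / khz
  t1 <- seq(0, pulse1_ms, by = dt)
  t2 <- seq(0, pulse2_ms, by = dt)
  model1 <- decay_model_value(p$decay, t1)
  model2 <- decay_model_value(p$decay, t2)
  res1 <- model1[length(model1)]
  rec <- function(i) 1 - sum(p$recovery$weights * exp(-i / p$recovery$taus))
  rows <- purrr::map(seq_along(intervals_ms), function(k) {
    R <- rec(intervals_ms[k])
    y1 <- model1 + seeded_noise(length(t1), noise_sd * p$decay$peak,
                                seed + 2L * k)
    y2 <- res1 + R * (model2 - res1) +
      seeded_noise(length(t2), noise_sd * p$decay$peak, seed + 2L * k + 1L)
    meta <- list(preset = p$preset, interval_ms = intervals_ms[k],
                 seed = seed)
    tibble::tibble(interval_ms = intervals_ms[k],
                   pulse1 = list(current_trace(y1, dt, "norm",
                                               metadata = meta)),
                   pulse2 = list(current_trace(y2, dt, "norm",
                                               metadata = meta)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recovery_dataset", class(out))
  out
}

#' Measure fractional recovery across a recovery dataset
#'
#' @param dataset A [gen_recovery_dataset()] result (or any tibble with
#'   `interval_ms`, `pulse1`, `pulse2` columns).
#' @param ... Passed to [fractional_recovery()].
#' @return Tibble with columns `interval_ms`, `recovery`.
#' @export
recovery_points <- function(dataset, ...) {
  tibble::tibble(
    interval_ms = dataset$interval_ms,
    recovery = purrr::map2_dbl(dataset$pulse1, dataset$pulse2,
                               fractional_recovery, ...))
}

#' Generate a steady-state-inactivation prepulse family
#'
#' Each sweep's test-pulse current is the decay model scaled by the
#' Boltzmann availability at its prepulse voltage, plus noise.
#'
#' @param params A [generator_params()] or preset name (must carry
#'   `ssi` Boltzmann parameters).
#' @param prepulse_mV Prepulse voltages, mV (>= 2 values).
#' @param test_ms Test-pulse duration, ms.
#' @inheritParams gen_decay_trace
#' @return A [sweep_set()] varied by `prepulse_mV`.
#' @export
gen_ssi_dataset <- function(params, prepulse_mV, test_ms = 250,
                            noise_sd = NULL, seed = NULL,
                            sampling_khz = NULL) {
  p <- as_generator_params(params)
  if (length(prepulse_mV) < 2) stop("need at least 2 prepulse voltages")
  if (is.null(p$ssi)) stop("generator params carry no SSI Boltzmann")
  noise_sd <- noise_sd %||% p$noise_sd
  seed <- seed %||% p$seed
  khz <- sampling_khz %||% p$sampling_khz
  dt <- 1 / khz
  t <- seq(0, test_ms, by = dt)
  model <- decay_model_value(p$decay, t)
  traces <- purrr::map(seq_along(prepulse_mV), function(k) {
    avail <- boltzmann(prepulse_mV[k], p$ssi$v_half, p$ssi$slope,
                       "inactivation")
    y <- avail * model + seeded_noise(length(t), noise_sd * p$decay$peak,
                                      seed + k)
    current_trace(y, dt, "norm",
                  metadata = list(preset = p$preset,
                                  prepulse_mV = prepulse_mV[k],
                                  seed = seed))
  })
  sweep_set(traces, prepulse_mV, "prepulse_mV")
}

#' Generate a decay trace from a Markov gating scheme
#'
#' Propagates the scheme from the all-open state, scales the
#' conducting-weighted occupancy to a peak of 1, and adds seeded
#' Gaussian noise; bridges the stoichiometry models to the fitting
#' pipeline.
#'
#' @param scheme A [gating_scheme()].
#' @param duration_ms Trace length, ms.
#' @param noise_sd Noise SD as a fraction of peak.
#' @param seed Integer seed.
#' @param sampling_khz Sampling rate, kHz.
#' @return A [current_trace()].
#' @export
gen_markov_decay <- function(scheme, duration_ms = 1000, noise_sd = 0,
                             seed = 1, sampling_khz = 10) {
  stopifnot(inherits(scheme, "gating_scheme"))
  dt <- 1 / sampling_khz
  t_ms <- seq(0, duration_ms, by = dt)
  n <- length(scheme$states)
  p0 <- c(1, rep(0, n - 1))
  if (n == 1) {
    y <- rep(scheme$conducting[1], length(t_ms))
  } else {
    occ <- simulate_occupancy(scheme, p0, t_ms / 1000)
    y <- as.matrix(occ[, scheme$states]) %*% scheme$conducting
    y <- as.numeric(y)
  }
  if (y[1] != 0) y <- y / y[1]
  y <- y + seeded_noise(length(y), noise_sd, seed)
  current_trace(y, dt, "norm",
                metadata = list(scheme_states = scheme$states,
                                seed = seed, noise_sd = noise_sd))
}
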