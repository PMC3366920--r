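# broom-style tidiers and ggplot2 autoplot methods for fit objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a multi-exponential decay fit
#'
#' @param x An [fit_exp_decay()] result.
#' @param ... Unused.
#' @return One row per component: `component`, `tau_ms`, `amplitude`,
#'   `weight_pct`, plus a `steady` row carrying `w_ss_pct` as its
#'   weight.
#' @export
tidy.exp_decay_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(component = paste0("tau-", seq_along(x$taus_ms)),
                   tau_ms = x$taus_ms, amplitude = x$amplitudes,
                   weight_pct = x$weights_pct),
    tibble::tibble(component = "steady", tau_ms = NA_real_,
                   amplitude = x$offset, weight_pct = x$w_ss_pct))
}

#' @export
glance.exp_decay_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, rss = x$rss,
                 peak_value = x$peak_value, converged = x$converged,
                 n_iter = x$n_iter,
                 negative_amplitude_flag = x$negative_amplitude_flag)
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat("<exp_decay_fit> ", x$n_components, " component(s), rss = ",
      format(x$rss, digits = 4), "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a recovery-from-inactivation fit
#'
#' @param x An [fit_recovery()] result.
#' @param ... Unused.
#' @return One row per component: `component`, `tau_ms`, `weight`.
#' @export
tidy.recovery_fit <- function(x, ...) {
  tibble::tibble(component = paste0("tau-", seq_along(x$taus_ms)),
                 tau_ms = x$taus_ms, weight = x$weights)
}

#' @export
glance.recovery_fit <- function(x, ...) {
  tibble::tibble(n_components = length(x$taus_ms), rss = x$rss,
                 converged = x$converged, n_iter = x$n_iter)
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat("<recovery_fit> rss =", format(x$rss, digits = 4), "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a Boltzmann curve fit
#'
#' @param x An [fit_boltzmann_curve()] result.
#' @param ... Unused.
#' @return One-row tibble: `v_half`, `slope`, `y_max`, `direction`.
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble::tibble(v_half = x$v_half, slope = x$slope, y_max = x$y_max,
                 direction = x$direction)
}

#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged,
                 n_iter = x$n_iter,
                 slope_bound_flag = x$slope_bound_flag)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("<boltzmann_fit> ", x$direction, ": v_half = ",
      format(x$v_half, digits = 4), " mV, slope = ",
      format(x$slope, digits = 3), " mV/e-fold, rss = ",
      format(x$rss, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Plot a fitted decay over its data
#'
#' @param object An [fit_exp_decay()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exp_decay_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- predict(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$current),
                       colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                       colour = "firebrick") +
    ggplot2::labs(x = "time (ms)", y = "current",
                  title = "Multi-exponential decay fit")
}

#' Plot a recovery fit over its data
#'
#' @param object An [fit_recovery()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(
    interval_ms = seq(0, max(df$interval_ms), length.out = 200))
  grid$recovery <- 1 - vapply(grid$interval_ms, function(t)
    sum(object$weights * exp(-t / object$taus_ms)), numeric(1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval_ms,
                                   y = .data$recovery)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "recovery interval (ms)",
                  y = "fractional recovery",
                  title = "Recovery from inactivation")
}

#' Plot a Boltzmann fit over its data
#'
#' @param object An [fit_boltzmann_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(v = seq(min(df$v), max(df$v), length.out = 200))
  grid$y <- object$y_max *
    boltzmann(grid$v, object$v_half, object$slope, object$direction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "voltage (mV)", y = "normalized response",
                  title = paste("Boltzmann", object$direction, "fit"))
}

#' Plot the sweeps of a sweep set
#'
#' @param object A [sweep_set()].
#' @param ... Unused.
#' @return A ggplot object, sweeps coloured by the varied parameter.
#' @export
autoplot.sweep_set <- function(object, ...) {
  df <- sweeps_to_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_ms, y = .data$current, group = .data$sweep,
    colour = .data[[object$varied_param]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "current")
}

#' Plot predicted slowing of fast inactivation versus DPP6a fraction
#'
#' Companion figure to [predicted_fast_tau()]: the population-maximal
#' fast time constant (one DPP6a subunit) against the assumptions of
#' both stoichiometry models.
#'
#' @param mole_fractions_a DPP6a mole fractions for the x axis.
#' @param specs Named list of [model_spec()] objects.
#' @return A ggplot object of fast tau (one DPP6a) per model.
#' @export
plot_predicted_slowing <- function(mole_fractions_a = seq(0.05, 1, 0.05),
                                   specs = list(
                                     `model1-4` = model_spec("model1", 4),
                                     `model1-2` = model_spec("model1", 2))) {
  df <- purrr::imap_dfr(specs, function(spec, nm) {
    tau1 <- predicted_fast_tau(1, spec$n_sites - 1, spec) * 1000
    tau_pure <- predicted_fast_tau(spec$n_sites, 0, spec) * 1000
    tibble::tibble(model = nm, x_a = mole_fractions_a,
                   tau_fast_ms = ifelse(mole_fractions_a >= 1,
                                        tau_pure, tau1))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_a,
                                   y = .data$tau_fast_ms,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "DPP6a mole fraction",
                  y = "predicted maximal fast tau (ms)")
}
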