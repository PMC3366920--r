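biexp_trace <- function(taus, weights_pct, w_ss_pct, peak = 1,
                        duration = 1000, dt = 0.1) {
  t <- seq(0, duration, by = dt)
  y <- peak * (weights_pct[1] / 100 * exp(-t / taus[1]) +
                 weights_pct[2] / 100 * exp(-t / taus[2]) +
                 w_ss_pct / 100)
  tibble::tibble(time_ms = t, current = y)
}

test_that("noiseless bi-exponential decays are recovered exactly", {
  df <- biexp_trace(c(6, 461), c(71, 22), 7)
  fit <- fit_exp_decay(df, 2)
  expect_equal(fit$taus_ms, c(6, 461), tolerance = 1e-6)
  expect_equal(fit$weights_pct, c(71, 22), tolerance = 1e-6)
  expect_equal(fit$w_ss_pct, 7, tolerance = 1e-6)
  expect_equal(fit$weights_pct[1] / 100, 0.71, tolerance = 1e-6)
  expect_true(fit$converged)

  # repeated calls are bit-identical (pure function of the data)
  fit2 <- fit_exp_decay(df, 2)
  expect_identical(fit$taus_ms, fit2$taus_ms)
  expect_identical(fit$rss, fit2$rss)
})

test_that("decay weights always sum to 100 percent", {
  withr::with_seed(3, {
    for (k in 1:20) {
      taus <- sort(exp(runif(2, log(1), log(500))))
      if (taus[2] / taus[1] < 5) taus[2] <- taus[1] * 5
      w <- as.numeric(rmultinom(1, 100, c(2, 1, 0.3)))
      df <- biexp_trace(taus, w[1:2], w[3])
      df$current <- df$current + rnorm(nrow(df), 0, 0.005)
      fit <- fit_exp_decay(df, 2)
      expect_lt(abs(sum(fit$weights_pct) + fit$w_ss_pct - 100), 0.5)
    }
  })
})

test_that("noiseless random decays identify to 1e-4 relative", {
  withr::with_seed(19, {
    for (k in 1:100) {
      taus <- sort(exp(runif(2, log(1), log(500))))
      if (taus[2] / taus[1] < 5) taus[2] <- taus[1] * 5
      w <- as.numeric(stats::rgamma(3, c(4, 2, 1)))
      w <- 100 * w / sum(w)
      df <- biexp_trace(taus, w[1:2], w[3], duration = 5 * taus[2])
      fit <- fit_exp_decay(df, 2)
      expect_equal(fit$taus_ms, taus, tolerance = 1e-4)
      expect_equal(fit$weights_pct, w[1:2], tolerance = 1e-4)
    }
  })
})

test_that("median fast tau is recovered from noisy granule-cell decays", {
  errs <- vapply(1:20, function(seed) {
    tr <- gen_decay_trace("CG", duration_ms = 1000, noise_sd = 0.01,
                          seed = seed)
    fit <- fit_exp_decay(tr, 2)
    abs(fit$taus_ms[1] - 11) / 11
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("the F-test chooses the right number of components", {
  df2 <- biexp_trace(c(6, 461), c(71, 22), 7)
  expect_identical(select_n_components(df2)$n_components, 2L)

  t <- seq(0, 500, by = 0.5)
  df1 <- tibble::tibble(time_ms = t,
                        current = 0.9 * exp(-t / 40) + 0.1)
  expect_identical(select_n_components(df1)$n_components, 1L)

  # pure noise around a constant: the extra component rarely helps
  choices <- vapply(0:9, function(seed) {
    y <- withr::with_seed(seed, 0.5 + rnorm(500, 0, 0.01))
    df <- tibble::tibble(time_ms = seq(0, 499), current = y)
    select_n_components(df, y_col = "current")$n_components
  }, integer(1))
  expect_gte(sum(choices == 1L), 8)
})

test_that("recovery fits invert the two-pulse model", {
  t <- c(0, 2, 5, 10, 20, 35, 60, 100, 160, 250, 400, 650, 1000)
  w <- c(29, 72) / 101
  y <- 1 - w[1] * exp(-t / 43) - w[2] * exp(-t / 265)
  fit <- fit_recovery(tibble::tibble(interval_ms = t, recovery = y), 2)
  expect_equal(fit$taus_ms, c(43, 265), tolerance = 1e-6)
  expect_equal(fit$weights, w, tolerance = 1e-6)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-6)
  # the fitted curve passes through 0 at t = 0
  expect_equal(1 - sum(fit$weights), 0, tolerance = 1e-6)

  # noisy mono-exponential recovery, published DPP6a time constant
  errs <- vapply(0:9, function(seed) {
    yy <- 1 - exp(-t / 15.3) +
      withr::with_seed(seed, rnorm(length(t), 0, 0.02))
    yy <- pmin(pmax(yy, -0.05), 1.05)
    f <- fit_recovery(tibble::tibble(interval_ms = t, recovery = yy), 1)
    abs(f$taus_ms[1] - 15.3) / 15.3
  }, numeric(1))
  expect_lt(median(errs), 0.1)

  expect_error(
    fit_recovery(tibble::tibble(interval_ms = c(-1, 5),
                                recovery = c(0, 0.5)), 1),
    ">= 0")
})

test_that("Boltzmann curve fits recover generating parameters", {
  v <- seq(-110, -30, by = 5)
  fit <- fit_boltzmann_curve(
    tibble::tibble(v = v, y = boltzmann(v, -72.4, 3.7)))
  expect_equal(fit$v_half, -72.4, tolerance = 1e-6)
  expect_equal(fit$slope, 3.7, tolerance = 1e-6)

  # activation data fitted with the opposite convention is flagged or
  # fails outright
  va <- seq(-60, 40, by = 5)
  ya <- boltzmann(va, -20, 15, "activation")
  bad <- tryCatch(fit_boltzmann_curve(tibble::tibble(v = va, y = ya),
                                      direction = "inactivation"),
                  error = function(e) e)
  expect_true(inherits(bad, "error") || bad$slope_bound_flag ||
                bad$rss > 0.1)

  # noisy availability points: median midpoint error below 0.5 mV
  errs <- vapply(1:20, function(seed) {
    y <- boltzmann(v, -69.6, 4.5) +
      withr::with_seed(seed, rnorm(length(v), 0, 0.02))
    f <- fit_boltzmann_curve(tibble::tibble(v = v, y = y))
    abs(f$v_half + 69.6)
  }, numeric(1))
  expect_lt(median(errs), 0.5)
})

test_that("peak-over-area reproduces the fast time constant", {
  # pure exponential: area / peak = tau (1 - exp(-T / tau))
  t <- seq(0, 100, by = 0.05)
  df <- tibble::tibble(time_ms = t, current = 0.8 * exp(-t / 6))
  est <- average_fast_tau_peak_over_area(df, slow_fit = NULL)
  expect_equal(est, 6 * (1 - exp(-100 / 6)), tolerance = 1e-4)
  # T = 10 tau truncation bias is below 0.005%
  expect_equal(6 * (1 - exp(-10)), 6, tolerance = 5e-5)

  # bi-exponential with the published DPP6a parameters: slow + steady
  # fitted on the tail, fast tau from the subtracted remainder
  df2 <- biexp_trace(c(6, 461), c(71, 22), 7, duration = 1000)
  tail_df <- dplyr::filter(df2, time_ms > 100)
  slow_fit <- fit_exp_decay(tail_df, 1, from_peak = FALSE)
  est2 <- average_fast_tau_peak_over_area(df2, slow_fit)
  direct <- fit_exp_decay(df2, 2)$taus_ms[1]
  expect_equal(est2, direct, tolerance = 0.05)

  # agreement within 1% for well-separated taus and a long window
  df3 <- biexp_trace(c(5, 200), c(60, 30), 10, duration = 60, dt = 0.02)
  t3 <- seq(0, 60, by = 0.02)
  slow3 <- tibble::tibble(time_ms = t3,
                          current = 0.30 * exp(-t3 / 200) + 0.10)
  slow_fit3 <- fit_exp_decay(slow3, 1, from_peak = FALSE)
  est3 <- average_fast_tau_peak_over_area(df3, slow_fit3)
  expect_equal(est3, 5 * (1 - exp(-60 / 5)), tolerance = 0.01)

  expect_error(
    average_fast_tau_peak_over_area(
      tibble::tibble(time_ms = t3, current = slow3$current - 0.01),
      slow_fit3),
    "no positive fast component")
})

test_that("tidiers summarize fits in broom style", {
  df <- biexp_trace(c(6, 461), c(71, 22), 7)
  fit <- fit_exp_decay(df, 2)
  td <- tidy(fit)
  expect_equal(td$component, c("tau-1", "tau-2", "steady"))
  expect_equal(td$tau_ms[1:2], c(6, 461), tolerance = 1e-6)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_identical(gl$n_components, 2)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
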