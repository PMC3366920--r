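make_trace <- function(y, dt = 0.1, ...) current_trace(y, dt, "uA", ...)

test_that("scaled-null subtraction removes linear leak", {
  t <- seq(0, 49.9, by = 0.1)
  # scale 0 leaves the trace unchanged
  tr <- make_trace(exp(-t / 6))
  expect_equal(subtract_scaled_null(tr, make_trace(rep(1, length(t))),
                                    0)$current, tr$current)
  # trace equal to scale * null cancels exactly
  null <- make_trace(0.02 * sin(t / 5) + 0.1)
  tr2 <- make_trace(3 * null$current)
  expect_equal(subtract_scaled_null(tr2, null, 3)$current,
               rep(0, length(t)))

  # injected ohmic leak g (V - V_rev) removed by the voltage-ratio
  # scaled null recorded at -70 mV
  g <- 0.002; v_rev <- -90; v_test <- 50; v_null <- -70
  signal <- exp(-t / 6)
  leak_test <- g * (v_test - v_rev)
  leak_null <- g * (v_null - v_rev)
  total <- make_trace(signal + leak_test)
  null_tr <- make_trace(rep(leak_null, length(t)))
  scale <- (v_test - v_rev) / (v_null - v_rev)
  cleaned <- subtract_scaled_null(total, null_tr, scale)
  expect_lt(max(abs(cleaned$current - signal)), 1e-9 * max(total$current))
  expect_true(attr(cleaned, "metadata")$null_subtracted)

  expect_error(subtract_scaled_null(tr, make_trace(rep(1, 10)), 1),
               "share length")
})

test_that("trace subtraction is linear in its input", {
  t <- seq(0, 20, by = 0.1)
  null <- make_trace(0.3 + 0.01 * t)
  a <- make_trace(exp(-t / 4)); b <- make_trace(0.5 * cos(t / 3))
  ab <- make_trace(a$current + b$current)
  lhs <- subtract_scaled_null(ab, null, 2)$current
  rhs <- subtract_scaled_null(a, null, 2)$current +
    subtract_scaled_null(b, null, 0)$current
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("prepulse subtraction isolates the transient current", {
  t <- seq(0, 199.9, by = 0.1)
  isa <- 0.8 * exp(-t / 11)       # transient, fully available at -114
  sustained <- 0.3 * (1 - exp(-t / 2))
  volts <- c(-10, 10, 30, 50)
  hyper <- sweep_set(lapply(seq_along(volts), function(i)
    make_trace((0.8 + 0.05 * i) / 0.8 * isa + sustained)),
    volts, "test_mV")
  depol <- sweep_set(lapply(seq_along(volts), function(i)
    make_trace(sustained)), volts, "test_mV")

  out <- isolate_isa_by_prepulse_subtraction(hyper, depol)
  for (i in seq_along(volts)) {
    expect_lt(max(abs(out$traces[[i]]$current -
                        (0.8 + 0.05 * i) / 0.8 * isa)), 1e-9)
  }
  # identical sets cancel completely
  zero <- isolate_isa_by_prepulse_subtraction(depol, depol)
  expect_true(all(vapply(zero$traces, function(tr)
    all(tr$current == 0), logical(1))))
  # a missing test voltage is named in the error
  short <- sweep_set(depol$traces[1:3], volts[1:3], "test_mV")
  expect_error(isolate_isa_by_prepulse_subtraction(hyper, short), "50")
})

test_that("peak conductance follows G = I / (V - Vrev)", {
  expect_equal(peak_conductance(1, 50, -90), 1 / 140)
  expect_equal(peak_conductance(0, 50, -90), 0)
  # granule-cell reversal setting
  expect_equal(peak_conductance(1.4, -10, -80), 0.02)
  expect_error(peak_conductance(1, -90, -90), "reversal")
})

test_that("fractional recovery normalizes out the residual current", {
  t <- seq(0, 250, by = 0.1)
  model <- 0.7 * exp(-t / 11) + 0.25 * exp(-t / 120) + 0.05
  p1 <- make_trace(model)
  expect_equal(fractional_recovery(p1, p1), 1, tolerance = 1e-9)
  res <- model[length(model)]
  p_flat <- make_trace(rep(res, length(t)))
  expect_equal(fractional_recovery(p1, p_flat), 0, tolerance = 1e-9)
  # invariance to positive scaling of both pulses
  p2 <- make_trace(res + 0.37 * (model - res))
  f <- fractional_recovery(p1, p2)
  expect_equal(f, 0.37, tolerance = 1e-9)
  f_scaled <- fractional_recovery(make_trace(5 * model),
                                  make_trace(5 * p2$current))
  expect_equal(f_scaled, f, tolerance = 1e-12)
  expect_error(fractional_recovery(p_flat, p1), "no inactivating")
})

test_that("SSI points normalize to the most hyperpolarized sweep", {
  set <- gen_ssi_dataset("K3a+DPP6K",
                         prepulse_mV = seq(-120, -40, by = 10),
                         noise_sd = 0)
  pts <- ssi_points(set)
  expect_equal(pts$prepulse_mV, seq(-120, -40, by = 10))
  expect_equal(pts$availability[1], 1)
  # noiseless points lie on the normalized generating Boltzmann
  expected <- boltzmann(pts$prepulse_mV, -72.4, 3.7) /
    boltzmann(-120, -72.4, 3.7)
  expect_equal(pts$availability, expected, tolerance = 1e-9)

  # noisy points stay within the 3-sigma band above 1
  noisy <- gen_ssi_dataset("K3a+DPP6K",
                           prepulse_mV = seq(-120, -40, by = 10),
                           noise_sd = 0.01, seed = 4)
  pn <- ssi_points(noisy)
  expect_true(all(pn$availability >= 0 & pn$availability <= 1 + 0.03))
  expect_error(ssi_points(sweep_set(set$traces[1], -120, "prepulse_mV")),
               "at least 2")
})

test_that("junction correction shifts once and only once", {
  expect_equal(apply_junction_correction(-100), -114.2)
  proto <- voltage_protocol(tibble::tibble(
    duration_ms = c(10000, 250), voltage_mV = c(-100, 50),
    label = c("prepulse", "test")))
  corr <- apply_junction_correction(proto)
  expect_equal(corr$segments$voltage_mV, c(-114.2, 35.8))
  expect_error(apply_junction_correction(corr), "already")
  # zero offset is the identity
  expect_equal(apply_junction_correction(proto, 0)$segments$voltage_mV,
               proto$segments$voltage_mV)
})

test_that("sweep files round-trip through CSV plus sidecar", {
  set <- gen_ssi_dataset("K3a+aK_1to2", prepulse_mV = c(-120, -80, -60),
                         noise_sd = 0.01, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweeps(set, path)
  back <- read_sweeps(path)
  expect_equal(back$values, set$values)
  expect_equal(back$varied_param, "prepulse_mV")
  # a second write of the re-read set is bit-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_sweeps(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # values agree to the 9 printed significant digits
  for (i in seq_along(set$traces)) {
    expect_equal(back$traces[[i]]$current, set$traces[[i]]$current,
                 tolerance = 1e-8)
  }
  long <- sweeps_to_tibble(back)
  expect_setequal(names(long),
                  c("sweep", "prepulse_mV", "time_ms", "current"))
})
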