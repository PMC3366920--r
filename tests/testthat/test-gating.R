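test_that("rate constants invert a fast-component fit", {
  r <- rates_from_fast_fit(0.006, 0.71)
  expect_equal(r$k_on, 0.71 / 0.006)
  expect_equal(r$k_off, 0.29 / 0.006)
  expect_equal(r$k_on + r$k_off, 1 / 0.006)
  expect_equal(r$k_on / (r$k_on + r$k_off), 0.71)
  # published rounding: 30 s^-1 per subunit (of 4), 48 s^-1 per channel
  expect_equal(round(r$k_on / 4), 30)
  expect_equal(round(r$k_off), 48)
  r2 <- rates_from_fast_fit(0.035, 0.74)
  expect_equal(round(r2$k_on), 21)

  r3 <- rates_from_fast_fit(0.02, 1)
  expect_equal(r3$k_off, 0)
  expect_equal(r3$k_on, 50)
  r4 <- rates_from_fast_fit(0.010, 0.5)
  expect_equal(r4$k_on, r4$k_off)
  expect_equal(r4$k_on, 50)

  expect_error(rates_from_fast_fit(-1, 0.5), "positive")
  expect_error(rates_from_fast_fit(0.01, 1.2), "fraction")
})

test_that("generator matrix follows the row convention", {
  sch <- two_state_scheme(118.3, 48.3)
  G <- build_generator(sch)
  expect_equal(unname(G),
               rbind(c(-118.3, 118.3), c(48.3, -48.3)))

  Gs <- build_generator(star_scheme_1a3K())
  expect_equal(Gs["O", "O"], -47.4)
  expect_equal(Gs["O", "Ia"], 30)
  expect_equal(Gs["O", "IK"], 17.4)
  expect_equal(rowSums(Gs), c(O = 0, Ia = 0, IK = 0))

  empty <- gating_scheme("O", 1,
                         tibble::tibble(from = character(),
                                        to = character(),
                                        rate = numeric()))
  expect_equal(unname(build_generator(empty)), matrix(0, 1, 1))

  expect_error(gating_scheme(c("O", "O"), c(1, 0),
                             data.frame(from = "O", to = "O", rate = 1)),
               "duplicate")
  expect_error(
    gating_scheme(c("O", "I"), c(1, 0),
                  data.frame(from = "O", to = "X", rate = 1)),
    "unknown state")
})

test_that("equilibrium occupancy solves pQ = 0", {
  eq <- equilibrium_occupancy(two_state_scheme(118.3, 48.3))
  expect_equal(unname(eq["I"]), 118.3 / 166.6, tolerance = 1e-12)

  # all rates equal -> uniform
  sch <- gating_scheme(c("A", "B", "C"), c(1, 0, 0), tibble::tibble(
    from = c("A", "B", "B", "C"), to = c("B", "A", "C", "B"),
    rate = c(5, 5, 5, 5)))
  expect_equal(unname(equilibrium_occupancy(sch)), rep(1 / 3, 3))

  # star scheme: detailed balance on a tree gives occupancies
  # proportional to (1, 30/48, 17.4/7.5)
  eq_star <- equilibrium_occupancy(star_scheme_1a3K())
  expected <- c(1, 30 / 48, 17.4 / 7.5)
  expect_equal(unname(eq_star), expected / sum(expected),
               tolerance = 1e-12)
  # cross-check by long-time simulation
  occ <- simulate_occupancy(star_scheme_1a3K(), times = c(5, 10))
  expect_equal(as.numeric(occ[2, -1]), unname(eq_star),
               tolerance = 1e-9)

  expect_error(
    gating_scheme(c("A", "B", "C", "D"), c(1, 0, 0, 0), tibble::tibble(
      from = c("A", "B", "C", "D"), to = c("B", "A", "D", "C"),
      rate = c(1, 1, 1, 1))),
    "not connected")
})

test_that("relaxation spectrum reproduces known time constants", {
  sp <- relaxation_spectrum(two_state_scheme(118.3, 48.3))
  expect_equal(nrow(sp$components), 1)
  expect_equal(fast_tau(sp) * 1000, 6.0, tolerance = 1e-3)
  # observable at 0 equals steady + sum of amplitudes
  expect_equal(sp$steady_value + sum(sp$components$amplitude), 1,
               tolerance = 1e-9)
  # steady value equals the observable at equilibrium
  eq <- equilibrium_occupancy(two_state_scheme(118.3, 48.3))
  expect_equal(sp$steady_value, unname(eq["O"]), tolerance = 1e-9)

  sp_star <- relaxation_spectrum(star_scheme_1a3K())
  expect_equal(fast_tau(sp_star) * 1000, 11.6, tolerance = 0.05)

  empty <- gating_scheme("O", 1, tibble::tibble(
    from = character(), to = character(), rate = numeric()))
  sp0 <- relaxation_spectrum(empty)
  expect_equal(nrow(sp0$components), 0)
  expect_equal(sp0$steady_value, 1)
})

test_that("round trip: rates -> two-state spectrum -> (tau, f)", {
  cases <- list(c(0.006, 0.71), c(0.035, 0.74), c(0.010, 0.5),
                c(0.2, 0.9))
  for (cs in cases) {
    r <- rates_from_fast_fit(cs[1], cs[2])
    sp <- relaxation_spectrum(two_state_scheme(r$k_on, r$k_off))
    expect_equal(fast_tau(sp), cs[1], tolerance = 1e-12)
    expect_equal(1 - sp$steady_value, cs[2], tolerance = 1e-12)
  }
})

test_that("simulated occupancy conserves probability and matches expm", {
  withr::with_seed(42, {
    for (k in 1:10) {
      sch <- random_connected_scheme(sample(2:4, 1))
      times <- sort(stats::runif(8, 1e-4, 0.5))
      occ <- simulate_occupancy(sch, times = times)
      P <- as.matrix(occ[, -1])
      expect_true(all(abs(rowSums(P) - 1) < 1e-9))
      expect_true(all(P >= 0 & P <= 1 + 1e-12))
      n <- length(sch$states)
      oracle <- expm_observable(sch, c(1, rep(0, n - 1)),
                                sch$conducting, times)
      expect_equal(as.numeric(P %*% sch$conducting), oracle,
                   tolerance = 1e-8)
    }
  })
  # t = 0 returns p0 exactly
  occ0 <- simulate_occupancy(two_state_scheme(10, 5), c(0.3, 0.7),
                             times = c(0, 0.1))
  expect_equal(as.numeric(occ0[1, -1]), c(0.3, 0.7))
  expect_error(simulate_occupancy(two_state_scheme(10, 5),
                                  times = c(-1, 0)), "non-negative")
})

test_that("spectrum reconstruction matches the dense propagator", {
  withr::with_seed(7, {
    for (k in 1:50) {
      sch <- random_connected_scheme(sample(2:4, 1))
      sp <- relaxation_spectrum(sch)
      taus <- sp$components$tau
      tmax <- if (length(taus)) max(taus) * 3 else 0.1
      tmin <- if (length(taus)) min(taus) / 10 else 1e-3
      times <- exp(seq(log(tmin), log(tmax), length.out = 20))
      n <- length(sch$states)
      oracle <- expm_observable(sch, c(1, rep(0, n - 1)),
                                sch$conducting, times)
      expect_equal(spectrum_observable(sp, times), oracle,
                   tolerance = 1e-8)
    }
  })
})

test_that("schemes serialize to JSON and back", {
  sch <- star_scheme_1a3K()
  js <- scheme_to_json(sch)
  back <- scheme_from_json(js)
  expect_equal(back$states, sch$states)
  expect_equal(back$conducting, sch$conducting)
  expect_equal(back$transitions, sch$transitions)
  path <- withr::local_tempfile(fileext = ".json")
  scheme_to_json(sch, path)
  expect_equal(scheme_from_json(path)$transitions, sch$transitions)
})
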