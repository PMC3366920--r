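#' Channel-level inactivation rate constants from a fast-component fit
#'
#' Inverts the two-state open/inactivated relaxation: a fast inactivation
#' time constant `tau_i` and fast fractional inactivation `f_i` determine
#' the channel-level ON and OFF rate constants as k_on = f_i / tau_i and
#' k_off = (1 - f_i) / tau_i, so that k_on + k_off = 1 / tau_i and the
#' equilibrium inactivated fraction k_on / (k_on + k_off) equals f_i.
#'
#' @param tau_i Fast inactivation time constant in seconds (> 0).
#' @param f_i Fraction inactivated by the fast mechanism, in \[0, 1\].
#' @return A one-row tibble with columns `k_on`, `k_off` (s^-1).
#' @examples
#' rates_from_fast_fit(0.006, 0.71)  # ~118.3 and ~48.3 s^-1
#' @export
rates_from_fast_fit <- function(tau_i, f_i) {
  if (!is.numeric(tau_i) || length(tau_i) != 1 || !is.finite(tau_i) ||
      tau_i <= 0) {
    stop("`tau_i` must be a single positive time constant in seconds")
  }
  if (!is.numeric(f_i) || length(f_i) != 1 || f_i < 0 || f_i > 1) {
    stop("`f_i` must be a single fraction in [0, 1]")
  }
  tibble::tibble(k_on = f_i / tau_i, k_off = (1 - f_i) / tau_i)
}

#' Equilibrium state occupancy of a generator
#'
#' Solves p Q = 0 with sum(p) = 1 for the stationary occupancy of the
#' scheme (the "Equilibrium P" of kinetic-modelling software).
#'
#' @param gen Generator matrix from [build_generator()], or a
#'   [gating_scheme()].
#' @return Named probability vector over the states.
#' @export
equilibrium_occupancy <- function(gen) {
  if (inherits(gen, "gating_scheme")) {
    if (!is_connected(gen)) {
      stop("scheme is not connected; components: ", format_components(gen))
    }
    gen <- build_generator(gen)
  }
  assert_generator(gen)
  n <- nrow(gen)
  if (n == 1) return(stats::setNames(1, rownames(gen)))
  # stationary row vector: solve t(Q) p = 0 augmented with sum constraint
  A <- rbind(t(gen), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- stats::setNames(as.numeric(qr.solve(A, b)), rownames(gen))
  if (any(p < -1e-9)) {
    stop("no valid stationary distribution (is the scheme connected?)")
  }
  p[p < 0] <- 0
  p / sum(p)
}

#' Relaxation spectrum of an observable under a gating scheme
#'
#' Spectrally decomposes the relaxation of a linear observable
#' w'p(t) where dp/dt' = p Q, starting from occupancy `p0`:
#' observable(t) = steady_value + sum_j a_j exp(-t / tau_j).
#' The fast inactivation time constant is the reciprocal of the
#' largest-magnitude nonzero eigenvalue of the generator.
#'
#' Eigenvalues equal to within 1e-9 relative are merged into a single
#' component whose amplitude is the sum; components with amplitude below
#' 1e-12 of the t = 0 observable are dropped. For complex eigenvalue
#' pairs (possible in non-reversible schemes) the reported tau is
#' -1/Re(lambda) and the amplitude is the real part of the summed
#' conjugate contributions; full complex data are kept internally so
#' that [spectrum_observable()] reconstructs the trajectory exactly.
#' A numerically defective (non-diagonalizable) generator triggers a
#' dense-propagator fallback: amplitudes are re-estimated by least
#' squares on matrix-exponential trajectories and
#' `diagnostics$defective` is set.
#'
#' @param gen Generator matrix or [gating_scheme()].
#' @param p0 Initial occupancy vector (sums to 1).
#' @param observable Per-state weight vector; defaults to the scheme's
#'   conducting weights when `gen` is a scheme, else must be supplied.
#' @return Object of class `relaxation_spectrum` with a `components`
#'   tibble (`tau` seconds ascending, `amplitude`), `steady_value`, and
#'   `diagnostics`.
#' @examples
#' sch <- two_state_scheme(118.3, 48.3)
#' relaxation_spectrum(sch)  # single tau = 6 ms
#' @export
relaxation_spectrum <- function(gen, p0 = NULL, observable = NULL) {
  if (inherits(gen, "gating_scheme")) {
    if (is.null(observable)) observable <- gen$conducting
    gen <- build_generator(gen)
  }
  assert_generator(gen)
  n <- nrow(gen)
  if (is.null(p0)) {
    # default: start with all probability in the first (open) state
    p0 <- c(1, rep(0, n - 1))
  }
  stopifnot(length(p0) == n, length(observable) == n)
  if (abs(sum(p0) - 1) > 1e-9 || any(p0 < -1e-12)) {
    stop("`p0` must be a probability vector summing to 1")
  }

  A <- t(gen)                       # p(t) = expm(A t) p0
  eg <- eigen(A)
  V <- eg$vectors
  rc <- tryCatch(rcond(V), error = function(e) 0)
  defective <- !is.finite(rc) || rc < 1e-10

  scale <- max(abs(eg$values), 1)
  if (!defective) {
    coef <- solve(V, as.complex(p0))
    proj <- as.vector(t(as.complex(observable)) %*% V)   # w' v_j
    amps <- proj * coef
    lambda <- eg$values
  } else {
    # dense-propagator fallback: eigenvalues still locate the taus;
    # amplitudes by least squares on expm-propagated trajectories
    lambda <- eg$values
    nz <- Mod(lambda) > 1e-12 * scale
    taus <- -1 / Re(lambda[nz])
    taus <- taus[taus > 0]
    taus <- sort(unique(signif(taus, 12)))
    tmax <- if (length(taus)) max(taus) * 5 else 1
    tmin <- if (length(taus)) min(taus) / 10 else 0.01
    tt <- exp(seq(log(tmin), log(tmax), length.out = max(20, 4 * length(taus))))
    obs <- vapply(tt, function(t)
      sum(observable * as.numeric(Matrix::expm(A * t) %*% p0)), numeric(1))
    X <- cbind(1, vapply(taus, function(tau) exp(-tt / tau),
                         numeric(length(tt))))
    fit <- stats::lsfit(X, obs, intercept = FALSE)
    lambda <- c(0, -1 / taus)
    amps <- as.complex(fit$coefficients)
  }

  zero <- Mod(lambda) <= 1e-12 * scale
  steady <- sum(Re(amps[zero]))
  lam_nz <- lambda[!zero]
  amp_nz <- amps[!zero]

  comps <- tibble::tibble(tau = numeric(), amplitude = numeric())
  lam_keep <- complex(0); amp_keep <- complex(0)
  if (length(lam_nz) > 0) {
    # merge eigenvalues equal to 1e-9 relative
    ord <- order(Re(lam_nz), Im(lam_nz))
    lam_nz <- lam_nz[ord]; amp_nz <- amp_nz[ord]
    grp <- cumsum(c(1, abs(diff(lam_nz)) > 1e-9 * scale))
    lam_m <- vapply(split(lam_nz, grp), function(x) x[1], complex(1))
    amp_m <- vapply(split(amp_nz, grp), sum, complex(1))
    obs0 <- abs(steady + sum(Re(amp_m)))
    keep <- Mod(amp_m) > 1e-12 * max(obs0, 1e-300)
    lam_keep <- lam_m[keep]; amp_keep <- amp_m[keep]
    # conjugate pairs collapse to one reported row per distinct Re(lambda)
    tau_r <- -1 / Re(lam_keep)
    agg <- rowsum(Re(amp_keep), group = signif(tau_r, 12))
    comps <- tibble::tibble(tau = as.numeric(rownames(agg)),
                            amplitude = as.numeric(agg[, 1]))
    comps <- comps[order(comps$tau), , drop = FALSE]
  }

  structure(
    list(components = comps,
         steady_value = steady,
         eigenvalues = lam_keep,
         eigen_amplitudes = amp_keep,
         diagnostics = list(defective = defective, rcond = rc)),
    class = "relaxation_spectrum")
}

#' Evaluate a relaxation spectrum's observable at given times
#'
#' Reconstructs observable(t) from the stored spectral data (complex
#' eigencomponents included, so non-reversible schemes reconstruct
#' exactly).
#'
#' @param spectrum A [relaxation_spectrum()] result.
#' @param times Times in seconds.
#' @return Numeric vector of observable values.
#' @export
spectrum_observable <- function(spectrum, times) {
  stopifnot(inherits(spectrum, "relaxation_spectrum"))
  vapply(times, function(t)
    spectrum$steady_value +
      sum(Re(spectrum$eigen_amplitudes * exp(spectrum$eigenvalues * t))),
    numeric(1))
}

#' Fast relaxation time constant of a spectrum
#'
#' @param spectrum A [relaxation_spectrum()] result.
#' @return Smallest tau (seconds), i.e. the reciprocal of the
#'   largest-magnitude nonzero eigenvalue.
#' @export
fast_tau <- function(spectrum) {
  stopifnot(inherits(spectrum, "relaxation_spectrum"))
  if (nrow(spectrum$components) == 0) return(NA_real_)
  min(spectrum$components$tau)
}

#' @export
print.relaxation_spectrum <- function(x, ...) {
  cat("<relaxation_spectrum> steady_value =",
      format(x$steady_value, digits = 6), "\n")
  df <- x$components
  df$tau_ms <- df$tau * 1000
  print(df[, c("tau_ms", "amplitude")], ...)
  if (isTRUE(x$diagnostics$defective)) cat("(defective generator: dense-propagator fallback)\n")
  invisible(x)
}

#' Simulate state occupancies over time
#'
#' Exact propagation of dp/dt = p Q via eigen-decomposition (matrix
#' exponential fallback when the eigenbasis is ill-conditioned).
#'
#' @param gen Generator matrix or [gating_scheme()].
#' @param p0 Initial occupancy (sums to 1). Defaults to all probability
#'   in the first state.
#' @param times Non-negative, strictly increasing times in seconds.
#' @return Tibble with column `time` and one occupancy column per state.
#' @export
simulate_occupancy <- function(gen, p0 = NULL, times) {
  if (inherits(gen, "gating_scheme")) gen <- build_generator(gen)
  assert_generator(gen)
  n <- nrow(gen)
  if (is.null(p0)) p0 <- c(1, rep(0, n - 1))
  stopifnot(length(p0) == n)
  if (abs(sum(p0) - 1) > 1e-9) stop("`p0` must sum to 1")
  if (any(times < 0)) stop("`times` must be non-negative")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")

  A <- t(gen)
  eg <- eigen(A)
  rc <- tryCatch(rcond(eg$vectors), error = function(e) 0)
  if (is.finite(rc) && rc >= 1e-10) {
    coef <- solve(eg$vectors, as.complex(p0))
    P <- t(vapply(times, function(t)
      Re(as.vector(eg$vectors %*% (coef * exp(eg$values * t)))),
      numeric(n)))
  } else {
    P <- t(vapply(times, function(t)
      as.numeric(Matrix::expm(A * t) %*% p0), numeric(n)))
  }
  P[P < 0 & P > -1e-9] <- 0
  P <- P / rowSums(P)
  colnames(P) <- rownames(gen)
  dplyr::bind_cols(tibble::tibble(time = times), tibble::as_tibble(P))
}

#' Two-state open/inactivated scheme
#'
#' Convenience constructor for the O <-> I single-step inactivation
#' scheme.
#'
#' @param k_on,k_off Channel-level rate constants in s^-1.
#' @param inactivated_label Label for the inactivated state.
#' @return A [gating_scheme()].
#' @export
two_state_scheme <- function(k_on, k_off, inactivated_label = "I") {
  gating_scheme(
    states = c("O", inactivated_label), conducting = c(1, 0),
    transitions = tibble::tibble(
      from = c("O", inactivated_label), to = c(inactivated_label, "O"),
      rate = c(k_on, k_off)))
}
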