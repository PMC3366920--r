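# Shared fixtures built in code.

# Star scheme used throughout: one DPP6a branch and one DPP6K branch
# off the open state, with the published channel-level rates.
star_scheme_1a3K <- function() {
  gating_scheme(
    states = c("O", "Ia", "IK"), conducting = c(1, 0, 0),
    transitions = tibble::tibble(
      from = c("O", "Ia", "O", "IK"), to = c("Ia", "O", "IK", "O"),
      rate = c(30, 48, 17.4, 7.5)))
}

# Random connected scheme: a random spanning tree with rates in both
# directions (guarantees connectivity), plus optional extra edges.
random_connected_scheme <- function(n_states) {
  states <- paste0("S", seq_len(n_states))
  from <- character(); to <- character(); rate <- numeric()
  rand_rate <- function(k) exp(stats::runif(k, log(1), log(1000)))
  for (i in seq_len(n_states - 1)) {
    parent <- sample(i, 1)
    from <- c(from, states[parent], states[i + 1])
    to <- c(to, states[i + 1], states[parent])
    rate <- c(rate, rand_rate(2))
  }
  if (n_states > 2 && stats::runif(1) < 0.5) {
    a <- sample(n_states, 2)
    from <- c(from, states[a[1]]); to <- c(to, states[a[2]])
    rate <- c(rate, rand_rate(1))
  }
  conducting <- rep(0, n_states); conducting[1] <- 1
  gating_scheme(states, conducting,
                tibble::tibble(from = from, to = to, rate = rate))
}

# Independent dense-propagator oracle for an observable trajectory.
expm_observable <- function(scheme, p0, weights, times) {
  A <- t(build_generator(scheme))
  vapply(times, function(t)
    sum(weights * as.numeric(Matrix::expm(A * t) %*% p0)), numeric(1))
}
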