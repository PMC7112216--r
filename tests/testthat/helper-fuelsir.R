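# shared fixtures: the Fort Myers-Naples constant-rate fit and its
# complement initial state, plus a hand-coded Euler marcher kept deliberately
# independent of the package internals for use as an oracle.

ftm_params <- function() sir_params(beta = 0.0089, gamma = 0.1901)

ftm_init <- function() {
  s0 <- 2.90 * 0.1901 / 0.0089
  compartment_state(s = s0, i = 100 - s0)
}

irma_grid <- function() simulation_grid(dt = 0.25, horizon = 12)

# independent Euler oracle: plain loop over the controlled SIR update
oracle_euler <- function(beta, gamma, s0, i0, u, dt, n_steps) {
  if (length(u) == 1L) u <- rep(u, n_steps)
  s <- i <- numeric(n_steps + 1L)
  s[1L] <- s0
  i[1L] <- i0
  for (k in seq_len(n_steps)) {
    s[k + 1L] <- s[k] + (-beta * s[k] * i[k] - u[k] * s[k]) * dt
    i[k + 1L] <- i[k] + (beta * s[k] * i[k] - gamma * i[k]) * dt
  }
  list(s = s, i = i)
}
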