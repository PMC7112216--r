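#' Synthetic shortage scenario
#'
#' Ground-truth specification for a crowd-sourced-like aggregate shortage
#' series: a constant-parameter SIR trajectory on a uniform grid with
#' additive Gaussian observation noise on the percent scale, truncated to
#' \[0, 100\]. The default noise level (sd 2 percent) is a scenario choice,
#' not an inference about the real reporting error; the filter's default
#' measurement variance of 10 implies a comparable percent-scale scatter.
#'
#' @param params ground-truth [sir_params()].
#' @param init initial [compartment_state()].
#' @param grid a [simulation_grid()].
#' @param noise_sd standard deviation of the additive observation noise
#'   (percent), >= 0.
#' @param seed integer RNG seed; the generated series is a pure function of
#'   the spec, so a fixed seed gives an identical series.
#' @param surge_factor non-canonical demand-surge variant for filter
#'   tracking experiments: the transmission rate is multiplied by a factor
#'   ramping linearly from `surge_factor` at t = 0 down to 1 at day 2
#'   (1 = canonical constant-rate dynamics).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(params, init, grid, noise_sd = 2, seed = 1L,
                          surge_factor = 1) {
  if (!inherits(params, "sir_params"))
    stop("`params` must be a sir_params", call. = FALSE)
  if (!inherits(init, "compartment_state"))
    stop("`init` must be a compartment_state", call. = FALSE)
  if (!inherits(grid, "simulation_grid"))
    stop("`grid` must be a simulation_grid", call. = FALSE)
  .check_scalar(noise_sd, "noise_sd", lower = 0)
  .check_scalar(seed, "seed")
  .check_scalar(surge_factor, "surge_factor", lower = 0, strict = TRUE)
  structure(list(params = params, init = init, grid = grid,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 surge_factor = surge_factor),
            class = "scenario_spec")
}

#' Generate a synthetic observed shortage series
#'
#' Simulates the noiseless uncontrolled trajectory for the scenario, adds
#' independent Gaussian noise (sd = `noise_sd`) to the S and I channels,
#' and truncates to \[0, 100\]. Deterministic for a fixed spec (the seed is
#' part of the spec); the caller's RNG state is left untouched.
#'
#' @param spec a [scenario_spec()].
#' @param label region label attached to the series.
#' @return An [observation_series()].
#' @examples
#' spec <- scenario_spec(sir_params(0.0089, 0.1901),
#'                       compartment_state(61.95, 38.05),
#'                       simulation_grid(0.25, 12), noise_sd = 2, seed = 7)
#' generate_series(spec)
#' @export
generate_series <- function(spec, label = "synthetic") {
  if (!inherits(spec, "scenario_spec"))
    stop("`spec` must be a scenario_spec", call. = FALSE)
  if (spec$surge_factor == 1) {
    traj <- sir_simulate(spec$init, spec$params, control = 0, grid = spec$grid)
    s <- traj$s_pct
    i <- traj$i_pct
  } else {
    st <- .simulate_surge(spec)
    s <- st$s
    i <- st$i
  }
  n <- length(s)
  if (spec$noise_sd > 0) {
    noise <- .with_seed(spec$seed, stats::rnorm(2L * n, 0, spec$noise_sd))
    s <- s + noise[seq_len(n)]
    i <- i + noise[n + seq_len(n)]
  }
  observation_series(spec$grid$times,
                     pmin(pmax(s, 0), 100),
                     pmin(pmax(i, 0), 100),
                     label = label)
}

# non-canonical variant: transmission rate ramped from surge_factor*beta at
# t=0 to beta at day 2, constant after; Euler on the scenario grid
.simulate_surge <- function(spec) {
  n <- spec$grid$n_steps
  s <- i <- numeric(n + 1L)
  s[1L] <- spec$init$s
  i[1L] <- spec$init$i
  for (k in seq_len(n)) {
    t <- spec$grid$times[k]
    fac <- 1 + (spec$surge_factor - 1) * max(0, 1 - t / 2)
    b <- spec$params$beta * fac
    inf <- b * s[k] * i[k]
    s[k + 1L] <- max(s[k] - inf * spec$grid$dt, 0)
    i[k + 1L] <- max(i[k] + (inf - spec$params$gamma * i[k]) * spec$grid$dt, 0)
  }
  list(s = s, i = i)
}

#' Synthetic series for a registry city
#'
#' Assembles a [scenario_spec()] from the packaged registry row -- the
#' city's fitted rates, the complement initial state reconstructed by
#' [derive_initial_state()], and the window/cadence of the matching
#' hurricane (Irma cities: 12 days at 0.25-day steps; Florence cities: 18
#' days at 1-hour steps) -- and generates the series.
#'
#' @inheritParams city_parameters
#' @param noise_sd observation-noise standard deviation in percent.
#' @param seed integer RNG seed.
#' @return An [observation_series()] labelled with the city slug.
#' @examples
#' city_fixture("fort-myers-naples", noise_sd = 2, seed = 7)
#' @export
city_fixture <- function(name, noise_sd = 2, seed = 1L) {
  city <- city_parameters(name)
  spec <- scenario_spec(params = sir_params(city$beta, city$gamma),
                        init = derive_initial_state(city, mode = "complement"),
                        grid = .event_grid(city$event),
                        noise_sd = noise_sd, seed = seed)
  generate_series(spec, label = name)
}
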