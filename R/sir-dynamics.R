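#' SIR rate parameters
#'
#' The transmission/recovery rate pair of the fuel-shortage SIR model. All
#' compartments live on the 0--100 percent scale, so `beta` carries units
#' 1/(percent day) while `gamma` is 1/day. On this scale the fitted city
#' values (`beta` around 0.01, `gamma` around 0.2) are consistent with basic
#' reproduction numbers `beta * S0 / gamma` of a few.
#'
#' @param beta transmission rate per capita, 1/(percent day); must be >= 0.
#' @param gamma recovery (resupply) rate, 1/day; must be > 0.
#' @return An object of class `sir_params`.
#' @examples
#' sir_params(beta = 0.0089, gamma = 0.1901)
#' @export
sir_params <- function(beta, gamma) {
  .check_scalar(beta, "beta", lower = 0)
  .check_scalar(gamma, "gamma", lower = 0, strict = TRUE)
  structure(list(beta = beta, gamma = gamma), class = "sir_params")
}

#' @export
print.sir_params <- function(x, ...) {
  cat(sprintf("SIR parameters: beta = %g /(pct day), gamma = %g /day (gamma/beta = %g pct)\n",
              x$beta, x$gamma, if (x$beta > 0) x$gamma / x$beta else Inf))
  invisible(x)
}

#' Compartment state on the percent scale
#'
#' Susceptible, infected, infection-recovered and intervention-removed
#' percentages. The fourth compartment (`r_vac`) accumulates mass removed by
#' the refueling control, mirroring the resource-constraint derivative
#' dR/dt = u_v S; every integration step conserves the four-compartment sum.
#'
#' @param s percent of units susceptible (operational stations at risk).
#' @param i percent infected (stations out of fuel).
#' @param r_rec percent recovered from infection (resupplied after running dry).
#' @param r_vac percent removed by intervention (preemptively refueled).
#' @return An object of class `compartment_state`.
#' @export
compartment_state <- function(s, i, r_rec = 0, r_vac = 0) {
  .check_scalar(s, "s", lower = 0)
  .check_scalar(i, "i", lower = 0)
  .check_scalar(r_rec, "r_rec", lower = 0)
  .check_scalar(r_vac, "r_vac", lower = 0)
  structure(list(s = s, i = i, r_rec = r_rec, r_vac = r_vac),
            class = "compartment_state")
}

#' @export
print.compartment_state <- function(x, ...) {
  cat(sprintf("state: S = %.3f, I = %.3f, R_rec = %.3f, R_vac = %.3f (sum %.3f pct)\n",
              x$s, x$i, x$r_rec, x$r_vac, x$s + x$i + x$r_rec + x$r_vac))
  invisible(x)
}

#' Uniform simulation grid
#'
#' @param dt step length in days (0.25 for the daily-cadence hurricane-Irma
#'   windows, 1/24 for the hourly hurricane-Florence windows).
#' @param horizon total duration in days; must be an integer multiple of `dt`.
#' @return An object of class `simulation_grid` with fields `dt`, `horizon`,
#'   `n_steps` and the node times `times` (length `n_steps + 1`).
#' @examples
#' simulation_grid(dt = 0.25, horizon = 12)
#' @export
simulation_grid <- function(dt, horizon) {
  .check_scalar(dt, "dt", lower = 0, strict = TRUE)
  .check_scalar(horizon, "horizon", lower = 0, strict = TRUE)
  n_steps <- as.integer(round(horizon / dt))
  if (abs(n_steps * dt - horizon) > 1e-9)
    stop("`horizon` must be an integer multiple of `dt`", call. = FALSE)
  structure(list(dt = dt, horizon = horizon, n_steps = n_steps,
                 times = seq(0, by = dt, length.out = n_steps + 1L)),
            class = "simulation_grid")
}

#' Instantaneous SIR rates with refueling control
#'
#' Right-hand side of the controlled fuel-shortage SIR system:
#' dS = -beta S I - u_v S, dI = beta S I - gamma I, dR_rec = gamma I,
#' dR_vac = u_v S. The four components sum to zero exactly.
#'
#' @param state a [compartment_state()].
#' @param params a [sir_params()].
#' @param u_v per-capita refueling rate applied to the susceptible
#'   compartment, 1/day; must be >= 0.
#' @return Named numeric vector `c(ds, di, dr_rec, dr_vac)` in percent/day.
#' @examples
#' sir_rates(compartment_state(61.95, 37.15), sir_params(0.0089, 0.1901))
#' @export
sir_rates <- function(state, params, u_v = 0) {
  if (!inherits(state, "compartment_state"))
    stop("`state` must be a compartment_state", call. = FALSE)
  if (!inherits(params, "sir_params"))
    stop("`params` must be a sir_params", call. = FALSE)
  .check_scalar(u_v, "u_v", lower = 0)
  infection <- params$beta * state$s * state$i
  removal <- u_v * state$s
  recovery <- params$gamma * state$i
  c(ds = -infection - removal,
    di = infection - recovery,
    dr_rec = recovery,
    dr_vac = removal)
}

# raw Euler update on the 4-vector (s, i, r_rec, r_vac); clips negative
# overshoot to 0, depositing the clipped mass into r_rec so the
# four-compartment sum is conserved exactly. Returns c(state4, n_clipped).
.euler_core <- function(x, beta, gamma, u_v, dt) {
  infection <- beta * x[1L] * x[2L]
  removal <- u_v * x[1L]
  recovery <- gamma * x[2L]
  y <- c(x[1L] + (-infection - removal) * dt,
         x[2L] + (infection - recovery) * dt,
         x[3L] + recovery * dt,
         x[4L] + removal * dt)
  clipped <- 0L
  for (j in c(1L, 2L, 4L)) {
    if (y[j] < 0) {
      y[3L] <- y[3L] + y[j]
      y[j] <- 0
      clipped <- clipped + 1L
    }
  }
  c(y, clipped)
}

#' One forward-Euler step of the controlled SIR system
#'
#' Applies the discrete process equations
#' `S' = S + (-beta S I - u_v S) dt`, `I' = I + (beta S I - gamma I) dt`
#' (and the matching recovered/removed updates). If the step overshoots a
#' compartment below zero -- possible on coarse grids -- the compartment is
#' clipped to 0 and the clipped mass is deposited into `r_rec`, so the
#' four-compartment sum is conserved; a warning reports the clip.
#'
#' @inheritParams sir_rates
#' @param dt step length in days, > 0.
#' @return The updated [compartment_state()].
#' @export
euler_step <- function(state, params, u_v = 0, dt) {
  sir_rates(state, params, u_v)  # validates inputs
  .check_scalar(dt, "dt", lower = 0, strict = TRUE)
  y <- .euler_core(c(state$s, state$i, state$r_rec, state$r_vac),
                   params$beta, params$gamma, u_v, dt)
  if (y[5L] > 0)
    warning("Euler overshoot produced a negative compartment; clipped to 0",
            call. = FALSE)
  compartment_state(y[1L], y[2L], y[3L], y[4L])
}

#' Simulate the controlled SIR system on a uniform grid
#'
#' Forward-Euler integration of the fuel-shortage SIR model (the canonical
#' scheme of the discrete process equations). `control` gives the per-step
#' refueling rate `u_v` applied over each step; a scalar is recycled, and a
#' constant 0 is the uncontrolled case. A classical 4th-order Runge-Kutta
#' integrator is available for convergence checks; the Euler scheme is the
#' reference used everywhere else.
#'
#' @inheritParams sir_rates
#' @param init initial [compartment_state()].
#' @param control numeric scalar or vector of length `grid$n_steps`: the
#'   `u_v` rate in force over each step.
#' @param grid a [simulation_grid()].
#' @param method `"euler"` (default) or `"rk4"`.
#' @return An object of class `sir_trajectory`: a data frame with columns
#'   `time_days, s_pct, i_pct, r_rec_pct, r_vac_pct, u_v` and
#'   `grid$n_steps + 1` rows (`u_v` at the final node is 0: no step starts
#'   there). Attribute `n_clipped` counts negative-overshoot clips.
#' @examples
#' p <- sir_params(0.0089, 0.1901)
#' tr <- sir_simulate(compartment_state(61.95, 38.05), p,
#'                    grid = simulation_grid(0.25, 12))
#' max(tr$i_pct)
#' @export
sir_simulate <- function(init, params, control = 0, grid,
                         method = c("euler", "rk4")) {
  method <- match.arg(method)
  if (!inherits(init, "compartment_state"))
    stop("`init` must be a compartment_state", call. = FALSE)
  if (!inherits(params, "sir_params"))
    stop("`params` must be a sir_params", call. = FALSE)
  if (!inherits(grid, "simulation_grid"))
    stop("`grid` must be a simulation_grid", call. = FALSE)
  n <- grid$n_steps
  if (length(control) == 1L) control <- rep(control, n)
  if (length(control) != n)
    stop(sprintf("`control` must have length n_steps = %d, got %d",
                 n, length(control)), call. = FALSE)
  if (any(!is.finite(control)) || any(control < 0))
    stop("`control` rates must be finite and >= 0", call. = FALSE)

  out <- matrix(NA_real_, n + 1L, 4L)
  out[1L, ] <- c(init$s, init$i, init$r_rec, init$r_vac)
  n_clipped <- 0L
  for (k in seq_len(n)) {
    if (method == "euler") {
      y <- .euler_core(out[k, ], params$beta, params$gamma, control[k], grid$dt)
      n_clipped <- n_clipped + as.integer(y[5L])
      out[k + 1L, ] <- y[1:4]
    } else {
      out[k + 1L, ] <- .rk4_step(out[k, ], params$beta, params$gamma,
                                 control[k], grid$dt)
    }
  }
  if (n_clipped > 0L)
    warning(sprintf("%d Euler step(s) clipped a negative overshoot to 0", n_clipped),
            call. = FALSE)
  traj <- data.frame(time_days = grid$times,
                     s_pct = out[, 1L], i_pct = out[, 2L],
                     r_rec_pct = out[, 3L], r_vac_pct = out[, 4L],
                     u_v = c(control, 0))
  structure(traj, class = c("sir_trajectory", "data.frame"),
            n_clipped = n_clipped, dt = grid$dt)
}

.rk4_step <- function(x, beta, gamma, u_v, dt) {
  f <- function(x) {
    inf <- beta * x[1L] * x[2L]; rem <- u_v * x[1L]; rec <- gamma * x[2L]
    c(-inf - rem, inf - rec, rec, rem)
  }
  k1 <- f(x)
  k2 <- f(x + dt / 2 * k1)
  k3 <- f(x + dt / 2 * k2)
  k4 <- f(x + dt * k3)
  y <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  pmax(y, 0)
}

#' @export
print.sir_trajectory <- function(x, ...) {
  cat(sprintf("SIR trajectory: %d nodes over %g days (dt = %g)\n",
              nrow(x), max(x$time_days), attr(x, "dt")))
  cat(sprintf("  peak I = %.2f pct at day %.2f; final I = %.2f pct\n",
              max(x$i_pct), x$time_days[which.max(x$i_pct)],
              x$i_pct[nrow(x)]))
  invisible(x)
}

#' Basic reproduction number
#'
#' `R0 = beta * s0 / gamma`: the percent of stations driven empty by 1
#' percent of stations going dry at the start of the window. The shortage
#' grows into an epidemic when `R0 > 1`.
#'
#' @param params a [sir_params()]; `gamma` must be > 0.
#' @param s0 initial susceptible percentage.
#' @return Dimensionless ratio.
#' @examples
#' basic_reproduction_number(sir_params(0.0089, 0.1901), 61.95)
#' @export
basic_reproduction_number <- function(params, s0) {
  if (!inherits(params, "sir_params"))
    stop("`params` must be a sir_params", call. = FALSE)
  .check_scalar(s0, "s0", lower = 0)
  params$beta * s0 / params$gamma
}

#' Effective reproduction number
#'
#' `beta * s / gamma` at the current susceptible level; equals 1 exactly at
#' the threshold `s = gamma / beta`, where the infected compartment peaks.
#'
#' @inheritParams basic_reproduction_number
#' @param s current susceptible percentage.
#' @export
effective_reproduction_number <- function(params, s) {
  basic_reproduction_number(params, s)
}

#' Closed-form uncontrolled epidemic peak
#'
#' For the continuous uncontrolled SIR system the infected maximum has the
#' closed form `i0 + s0 - rho + rho * log(rho / s0)` with `rho = gamma /
#' beta`, valid when `s0 > rho` (supercritical start); otherwise I is
#' monotonically decreasing and the peak is `i0`. Used as an independent
#' oracle for the Euler-integrated peak.
#'
#' @inheritParams basic_reproduction_number
#' @param i0 initial infected percentage.
#' @export
epidemic_peak <- function(params, s0, i0) {
  if (!inherits(params, "sir_params"))
    stop("`params` must be a sir_params", call. = FALSE)
  .check_scalar(s0, "s0", lower = 0)
  .check_scalar(i0, "i0", lower = 0)
  if (params$beta == 0) return(i0)
  rho <- params$gamma / params$beta
  if (s0 <= rho) return(i0)
  i0 + s0 - rho + rho * log(rho / s0)
}

#' Write / read a simulated trajectory as CSV
#'
#' Schema: `time_days,s_pct,i_pct,r_rec_pct,r_vac_pct,u_v`. Writes are
#' atomic (temp file + rename) and keep full double precision.
#'
#' @param traj an object of class `sir_trajectory` (see [sir_simulate()]).
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the trajectory data frame.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time_days", "s_pct", "i_pct", "r_rec_pct", "r_vac_pct", "u_v")
  if (!all(cols %in% names(traj)))
    stop("`traj` is missing trajectory columns", call. = FALSE)
  .write_csv_atomic(as.data.frame(traj)[cols], path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  cols <- c("time_days", "s_pct", "i_pct", "r_rec_pct", "r_vac_pct", "u_v")
  if (!identical(names(df), cols))
    stop("malformed trajectory header in ", path, call. = FALSE)
  dt <- .uniform_dt(df$time_days, "time_days")
  structure(df, class = c("sir_trajectory", "data.frame"), dt = dt)
}
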