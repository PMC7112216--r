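#' Observed shortage series
#'
#' A noisy measured (S, I) percentage series at uniformly spaced times --
#' the shape of crowd-sourced aggregate outage data. Both outputs are direct
#' projections of the state: `Y1 = S`, `Y2 = I`.
#'
#' @param times observation times in days, strictly increasing and uniform.
#' @param s_obs observed susceptible percentages in \[0, 100\].
#' @param i_obs observed infected percentages in \[0, 100\].
#' @param label free-text region name.
#' @return An object of class `observation_series`: a data frame with
#'   columns `time_days, s_pct, i_pct`, attributes `label` and `dt`.
#' @export
observation_series <- function(times, s_obs, i_obs, label = "") {
  if (length(times) != length(s_obs) || length(times) != length(i_obs))
    stop("`times`, `s_obs`, `i_obs` must have equal length", call. = FALSE)
  dt <- .uniform_dt(times)
  for (v in list(s_obs = s_obs, i_obs = i_obs)) {
    if (any(!is.finite(v)) || any(v < 0) || any(v > 100))
      stop("observed percentages must lie in [0, 100]", call. = FALSE)
  }
  structure(data.frame(time_days = times, s_pct = s_obs, i_pct = i_obs),
            class = c("observation_series", "data.frame"),
            label = label, dt = dt)
}

#' @export
print.observation_series <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("observation series%s: %d points, dt = %g d, peak I = %.2f pct\n",
              if (nzchar(lab)) paste0(" [", lab, "]") else "",
              nrow(x), attr(x, "dt"), max(x$i_pct)))
  if (isTRUE(attr(x, "s_synthesized")))
    cat("  (s_pct synthesized from i_pct)\n")
  invisible(x)
}

#' Unscented Kalman filter settings
#'
#' Tuning constants of the sigma-point filter over the joint state
#' `[S, I, beta, gamma]`. Defaults are the canonical tuning for this
#' problem: `alpha = 1, beta_w = 2, kappa = 0`, process noise
#' `Q = diag(10, 10, 100, 100)`, measurement noise `R = diag(10, 10)`
#' (percent-scale variances) and `P0 = I4`. The coarse parameter process
#' noise lets the per-step `beta_k, gamma_k` roam widely; the subsequent
#' mean-square-error refit ([select_constant_parameters()]) is what pins
#' down the constants. For tight per-step parameter tracking pass a much
#' smaller `q_diag` on the parameter components.
#'
#' @param dt observation spacing in days.
#' @param alpha,beta_w,kappa sigma-point scaling constants (`beta_w` is the
#'   distribution weighting usually written beta; renamed to avoid clashing
#'   with the transmission rate).
#' @param q_diag diagonal of the 4x4 process-noise covariance.
#' @param r_diag diagonal of the 2x2 measurement-noise covariance.
#' @param p0 initial 4x4 state covariance (symmetric positive definite).
#' @return An object of class `ukf_settings`.
#' @export
ukf_settings <- function(dt, alpha = 1, beta_w = 2, kappa = 0,
                         q_diag = c(10, 10, 100, 100),
                         r_diag = c(10, 10),
                         p0 = diag(4)) {
  .check_scalar(dt, "dt", lower = 0, strict = TRUE)
  .check_scalar(alpha, "alpha", lower = 0, strict = TRUE)
  .check_scalar(beta_w, "beta_w")
  .check_scalar(kappa, "kappa")
  if (length(q_diag) != 4L || any(q_diag <= 0))
    stop("`q_diag` must be 4 positive variances", call. = FALSE)
  if (length(r_diag) != 2L || any(r_diag <= 0))
    stop("`r_diag` must be 2 positive variances", call. = FALSE)
  p0 <- as.matrix(p0)
  if (!isTRUE(all.equal(p0, t(p0))) || any(eigen(p0, symmetric = TRUE,
                                                 only.values = TRUE)$values <= 0))
    stop("`p0` must be symmetric positive definite", call. = FALSE)
  structure(list(dt = dt, alpha = alpha, beta_w = beta_w, kappa = kappa,
                 q_diag = q_diag, r_diag = r_diag, p0 = p0),
            class = "ukf_settings")
}

#' Sigma-point weights and scaling factor
#'
#' `lambda = alpha^2 (L + kappa) - L`; the mean weights are
#' `w_mean[1] = lambda / (L + lambda)` and `1 / (2 (L + lambda))` for the
#' remaining `2L` points; the covariance weights add `(1 - alpha^2 +
#' beta_w)` to the first entry. Mean weights always sum to 1.
#'
#' @param L state dimension (>= 1).
#' @inheritParams ukf_settings
#' @return List with `lambda`, `w_mean`, `w_cov` (each weight vector of
#'   length `2L + 1`).
#' @examples
#' ukf_weights(4, alpha = 1, beta_w = 2, kappa = 0)
#' @export
ukf_weights <- function(L, alpha = 1, beta_w = 2, kappa = 0) {
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L != round(L))
    stop("`L` must be a positive integer", call. = FALSE)
  .check_scalar(alpha, "alpha", lower = 0, strict = TRUE)
  lambda <- alpha^2 * (L + kappa) - L
  if (abs(L + lambda) < 1e-12)
    stop("degenerate sigma-point spread: L + lambda = 0", call. = FALSE)
  w_mean <- c(lambda / (L + lambda), rep(1 / (2 * (L + lambda)), 2 * L))
  w_cov <- w_mean
  w_cov[1L] <- w_cov[1L] + (1 - alpha^2 + beta_w)
  list(lambda = lambda, w_mean = w_mean, w_cov = w_cov)
}

# Cholesky with diagonal jitter retry: on failure add
# 1e-8 * (trace/L) * I, up to 3 times.
.chol_jitter <- function(m) {
  L <- nrow(m)
  jitter <- 1e-8 * sum(diag(m)) / L
  for (attempt in 0:3) {
    f <- tryCatch(chol(m + diag(L) * jitter * (attempt > 0) * 10^(attempt - 1)),
                  error = function(e) NULL)
    if (!is.null(f)) return(f)
  }
  stop("covariance Cholesky factorization failed even after jitter; ",
       "estimation aborted", call. = FALSE)
}

#' Generate sigma points
#'
#' The `2L + 1` deterministic samples `[m, m + sqrt(L + lambda) A_j,
#' m - sqrt(L + lambda) A_j]` where `A_j` are columns of the (lower)
#' Cholesky factor of `cov`. On factorization failure a small diagonal
#' jitter proportional to the trace is added and the factorization retried
#' up to 3 times before aborting.
#'
#' @param mean state mean vector (length L).
#' @param cov L x L symmetric positive (semi-)definite covariance.
#' @param weights a weight list from [ukf_weights()] for the same `L`.
#' @return An object of class `sigma_set`: list with `points`
#'   (L x (2L+1) matrix, mean first), `w_mean`, `w_cov`, `lambda`.
#' @export
sigma_points <- function(mean, cov, weights) {
  L <- length(mean)
  cov <- as.matrix(cov)
  if (!all(dim(cov) == L))
    stop("`cov` must be L x L", call. = FALSE)
  if (length(weights$w_mean) != 2L * L + 1L)
    stop("`weights` were computed for a different dimension", call. = FALSE)
  cf <- .chol_jitter((cov + t(cov)) / 2)
  A <- t(cf) * sqrt(L + weights$lambda)   # columns are scaled factor columns
  pts <- cbind(mean, mean + A, mean - A, deparse.level = 0)
  structure(list(points = pts, w_mean = weights$w_mean,
                 w_cov = weights$w_cov, lambda = weights$lambda),
            class = "sigma_set")
}

# discrete process map for the joint state [S, I, beta, gamma]:
# Euler SIR step with the point's own rates; beta, gamma persist.
.ukf_process <- function(x, dt) {
  c(x[1L] + (-x[3L] * x[1L] * x[2L]) * dt,
    x[2L] + (x[3L] * x[1L] * x[2L] - x[4L] * x[2L]) * dt,
    x[3L],
    x[4L])
}

#' UKF time update (predict)
#'
#' Propagates every sigma point through the discrete process equations
#' (Euler SIR step using each point's own `beta`, `gamma` components, which
#' persist unchanged), then forms the prior mean as the weighted point mean
#' and the prior covariance as `Q` plus the weighted outer-product spread.
#'
#' @param sigma a `sigma_set` from [sigma_points()].
#' @param dt step length in days.
#' @param q_diag diagonal of the process-noise covariance `Q` (length =
#'   state dimension), or `NULL` for zero process noise.
#' @return List with `mean`, `cov`, and `points` (the propagated sigma
#'   points, reused by the measurement update).
#' @export
ukf_predict <- function(sigma, dt, q_diag = NULL) {
  if (!inherits(sigma, "sigma_set"))
    stop("`sigma` must be a sigma_set", call. = FALSE)
  .check_scalar(dt, "dt", lower = 0, strict = TRUE)
  pts <- apply(sigma$points, 2L, .ukf_process, dt = dt)
  m <- drop(pts %*% sigma$w_mean)
  d <- pts - m
  P <- d %*% (t(d) * sigma$w_cov)
  if (!is.null(q_diag)) P <- P + diag(q_diag, nrow = length(m))
  list(mean = m, cov = (P + t(P)) / 2, points = pts,
       w_mean = sigma$w_mean, w_cov = sigma$w_cov)
}

#' UKF measurement update
#'
#' The observation operator is the projection onto the first `p` state
#' components (here `p = 2`: S and I). Computes the predicted output
#' statistics from the propagated sigma points, the innovation covariance
#' `Pyy = R + spread`, the cross covariance `Pxy`, the Kalman gain
#' `K = Pxy Pyy^-1`, and returns the corrected mean and covariance.
#'
#' @param prior the list returned by [ukf_predict()].
#' @param observation numeric vector of observed outputs (length `p`).
#' @param r_diag diagonal of the measurement-noise covariance `R`
#'   (length `p`).
#' @return List with `mean`, `cov` (symmetrized), `gain`, `innovation`.
#' @export
ukf_update <- function(prior, observation, r_diag) {
  p <- length(observation)
  if (length(r_diag) != p)
    stop("`r_diag` must match the observation dimension", call. = FALSE)
  psi <- prior$points[seq_len(p), , drop = FALSE]
  ym <- drop(psi %*% prior$w_mean)
  dy <- psi - ym
  dx <- prior$points - prior$mean
  Pyy <- diag(r_diag, nrow = p) + dy %*% (t(dy) * prior$w_cov)
  Pxy <- dx %*% (t(dy) * prior$w_cov)
  K <- tryCatch(Pxy %*% solve(Pyy),
                error = function(e)
                  stop("singular innovation covariance; estimation aborted",
                       call. = FALSE))
  innov <- observation - ym
  m <- prior$mean + drop(K %*% innov)
  P <- prior$cov - K %*% Pyy %*% t(K)
  list(mean = m, cov = (P + t(P)) / 2, gain = K, innovation = innov)
}

#' Run the joint state-parameter unscented Kalman filter
#'
#' Filters an observed (S, I) series through the sigma-point recursion over
#' the joint state `[S, I, beta, gamma]`. The state is initialized from the
#' first observation with `beta = gamma = 0` (to be learned) and `P0` from
#' the settings; each subsequent observation triggers a predict/update
#' cycle. After every update the posterior S, I are clipped to \[0, 100\]
#' and `beta, gamma` to >= 0 (the process model is meaningless outside these
#' ranges); the number of clips is recorded. Posterior covariances are
#' symmetrized each step.
#'
#' @param series an [observation_series()] (uniform spacing required).
#' @param settings a [ukf_settings()]; its `dt` must match the series.
#' @param keep_gains record per-step Kalman gains as diagnostics.
#' @return An object of class `ukf_estimate`: list with `times`, `mean`
#'   (N x 4 matrix, columns `s_hat, i_hat, beta_hat, gamma_hat`), `cov`
#'   (4 x 4 x N array), optional `gains`, `n_clipped`, `settings`, `label`.
#' @export
run_ukf <- function(series, settings, keep_gains = FALSE) {
  if (!inherits(series, "observation_series"))
    stop("`series` must be an observation_series", call. = FALSE)
  if (!inherits(settings, "ukf_settings"))
    stop("`settings` must be a ukf_settings", call. = FALSE)
  dt <- .uniform_dt(series$time_days)
  if (abs(dt - settings$dt) > 1e-9 * max(1, dt))
    stop("`settings$dt` does not match the series spacing", call. = FALSE)
  N <- nrow(series)
  w <- ukf_weights(4L, settings$alpha, settings$beta_w, settings$kappa)

  X <- c(series$s_pct[1L], series$i_pct[1L], 0, 0)
  P <- settings$p0
  mean_out <- matrix(NA_real_, N, 4L,
                     dimnames = list(NULL, c("s_hat", "i_hat", "beta_hat", "gamma_hat")))
  cov_out <- array(NA_real_, c(4L, 4L, N))
  gains <- if (keep_gains) vector("list", N) else NULL
  mean_out[1L, ] <- X
  cov_out[, , 1L] <- P
  n_clipped <- 0L

  for (k in 2:N) {
    sig <- sigma_points(X, P, w)
    prior <- ukf_predict(sig, dt, settings$q_diag)
    post <- ukf_update(prior, c(series$s_pct[k], series$i_pct[k]),
                       settings$r_diag)
    X <- post$mean
    clip <- c(pmin(pmax(X[1:2], 0), 100), pmax(X[3:4], 0))
    n_clipped <- n_clipped + sum(clip != X)
    X <- clip
    P <- post$cov
    mean_out[k, ] <- X
    cov_out[, , k] <- P
    if (keep_gains) gains[[k]] <- post$gain
  }
  structure(list(times = series$time_days, mean = mean_out, cov = cov_out,
                 gains = gains, n_clipped = n_clipped, settings = settings,
                 label = attr(series, "label")),
            class = "ukf_estimate")
}

#' @export
print.ukf_estimate <- function(x, ...) {
  N <- nrow(x$mean)
  cat(sprintf("UKF estimate%s: %d steps, dt = %g d\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              N, x$settings$dt))
  cat(sprintf("  final beta_hat = %.4g, gamma_hat = %.4g; %d posterior clip(s)\n",
              x$mean[N, "beta_hat"], x$mean[N, "gamma_hat"], x$n_clipped))
  invisible(x)
}

#' Select the best-fit constant (beta, gamma) pair by mean-square error
#'
#' The filter exposes a per-step rate trajectory; the continuous
#' time-invariant model that feeds the control planner needs a single
#' constant pair. Every combination of the per-step `beta_k` values with
#' the per-step `gamma_k` values (negatives excluded, `gamma = 0` excluded)
#' is used to simulate a constant-parameter Euler SIR from the series'
#' initial (S, I), and the pair minimizing the mean square error of I(t)
#' against the observations is returned. Ties break toward smaller `beta`,
#' then smaller `gamma`. The candidate simulations are vectorized across
#' pairs, so the full Cartesian product is affordable even for hourly
#' series.
#'
#' @param estimate a `ukf_estimate` from [run_ukf()].
#' @param series the [observation_series()] the estimate was fitted to.
#' @param on `"i"` (default) scores the fit on I(t) only; `"both"` adds the
#'   S(t) squared errors (the observed S channel is partially derived in
#'   real data, hence not scored by default).
#' @return An object of class `constant_fit`: list with `beta`, `gamma`,
#'   `mse`, `r0` (= `beta * S(0) / gamma` of the refit), `n_candidates`.
#' @export
select_constant_parameters <- function(estimate, series, on = c("i", "both")) {
  on <- match.arg(on)
  if (!inherits(estimate, "ukf_estimate"))
    stop("`estimate` must be a ukf_estimate", call. = FALSE)
  if (!inherits(series, "observation_series"))
    stop("`series` must be an observation_series", call. = FALSE)
  dt <- .uniform_dt(series$time_days)
  betas <- sort(unique(estimate$mean[, "beta_hat"]))
  gammas <- sort(unique(estimate$mean[, "gamma_hat"]))
  betas <- betas[betas >= 0]
  gammas <- gammas[gammas > 0]
  if (length(betas) == 0L || length(gammas) == 0L)
    stop("empty candidate set: no nonnegative beta / positive gamma estimates",
         call. = FALSE)
  cand <- expand.grid(beta = betas, gamma = gammas,
                      KEEP.OUT.ATTRS = FALSE)  # beta varies fastest
  n <- nrow(series) - 1L
  S <- rep(series$s_pct[1L], nrow(cand))
  I <- rep(series$i_pct[1L], nrow(cand))
  sse <- numeric(nrow(cand))
  for (k in seq_len(n)) {
    inf <- cand$beta * S * I
    Sn <- S - inf * dt
    In <- I + (inf - cand$gamma * I) * dt
    S <- Sn; I <- In
    sse <- sse + (I - series$i_pct[k + 1L])^2
    if (on == "both") sse <- sse + (S - series$s_pct[k + 1L])^2
  }
  mse <- sse / n
  best <- order(mse, cand$beta, cand$gamma)[1L]  # ties: smaller beta, then gamma
  structure(list(beta = cand$beta[best], gamma = cand$gamma[best],
                 mse = mse[best],
                 r0 = cand$beta[best] * series$s_pct[1L] / cand$gamma[best],
                 n_candidates = nrow(cand), scored_on = on),
            class = "constant_fit")
}

#' @export
print.constant_fit <- function(x, ...) {
  cat(sprintf("constant SIR fit: beta = %.4g, gamma = %.4g, R0 = %.3f (MSE %.3g on %s, %d candidates)\n",
              x$beta, x$gamma, x$r0, x$mse, x$scored_on, x$n_candidates))
  invisible(x)
}
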