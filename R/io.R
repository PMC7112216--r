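#' Read an observed shortage series from CSV
#'
#' Expected header: `time_days,i_pct[,s_pct]` (column order after
#' `time_days` is free). Times must be strictly increasing and uniformly
#' spaced; values must lie in \[0, 100\] (violations name the offending
#' row). When the file carries only `i_pct`, the susceptible channel is
#' synthesized as `100 - i - Rhat(t)` with the recovered mass `Rhat`
#' accumulated by trapezoidal integration of `gamma_provisional * i_obs`;
#' the synthesis is recorded in the `s_synthesized` attribute.
#'
#' @param path CSV file path.
#' @param gamma_provisional provisional recovery rate (1/day) used only to
#'   synthesize a missing susceptible channel.
#' @param label region label; defaults to the file name.
#' @return An [observation_series()].
#' @export
read_series <- function(path, gamma_provisional = 0.2, label = NULL) {
  df <- utils::read.csv(path)
  if (length(names(df)) < 2L || names(df)[1L] != "time_days" ||
      !"i_pct" %in% names(df) ||
      !all(names(df) %in% c("time_days", "i_pct", "s_pct")))
    stop("malformed header in ", path,
         ": expected `time_days,i_pct[,s_pct]`", call. = FALSE)
  .uniform_dt(df$time_days, "time_days")
  for (col in intersect(c("i_pct", "s_pct"), names(df))) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 100)
    if (length(bad) > 0L)
      stop(sprintf("value out of [0, 100] in column `%s`, row %d of %s",
                   col, bad[1L], path), call. = FALSE)
  }
  synthesized <- !"s_pct" %in% names(df)
  if (synthesized) {
    .check_scalar(gamma_provisional, "gamma_provisional", lower = 0)
    dt <- diff(df$time_days)[1L]
    rec <- gamma_provisional * df$i_pct
    rhat <- c(0, cumsum((rec[-1L] + rec[-length(rec)]) / 2 * dt))
    df$s_pct <- pmin(pmax(100 - df$i_pct - rhat, 0), 100)
  }
  series <- observation_series(df$time_days, df$s_pct, df$i_pct,
                               label = if (is.null(label)) basename(path) else label)
  attr(series, "s_synthesized") <- synthesized
  series
}

#' Write an observed shortage series as CSV
#'
#' Schema `time_days,i_pct,s_pct`; atomic write, full double precision, so
#' a write/read round trip reproduces the series to better than 1e-9.
#'
#' @param series an [observation_series()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  if (!inherits(series, "observation_series"))
    stop("`series` must be an observation_series", call. = FALSE)
  .write_csv_atomic(data.frame(time_days = series$time_days,
                               i_pct = series$i_pct,
                               s_pct = series$s_pct), path)
}

#' Write / read a constant-parameter fit
#'
#' Key-value JSON holding the selected `beta`, `gamma`, the refit `r0` and
#' `mse`, and an echo of the filter settings used.
#'
#' @param fit a `constant_fit` from [select_constant_parameters()].
#' @param path output file path.
#' @param settings optional [ukf_settings()] echoed into the file.
#' @return `write_constant_fit` returns `path` invisibly;
#'   `read_constant_fit` returns the parsed list.
#' @export
write_constant_fit <- function(fit, path, settings = NULL) {
  if (!inherits(fit, "constant_fit"))
    stop("`fit` must be a constant_fit", call. = FALSE)
  out <- list(beta = fit$beta, gamma = fit$gamma, r0 = fit$r0, mse = fit$mse,
              n_candidates = fit$n_candidates, scored_on = fit$scored_on)
  if (!is.null(settings))
    out$settings <- list(dt = settings$dt, alpha = settings$alpha,
                         beta_w = settings$beta_w, kappa = settings$kappa,
                         q_diag = settings$q_diag, r_diag = settings$r_diag)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA)
  if (!file.rename(tmp, path)) stop("failed to write ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_constant_fit
#' @export
read_constant_fit <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write per-step filter estimates as CSV
#'
#' Schema `time_days,s_hat,i_hat,beta_hat,gamma_hat`.
#'
#' @param estimate a `ukf_estimate` from [run_ukf()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_estimate <- function(estimate, path) {
  if (!inherits(estimate, "ukf_estimate"))
    stop("`estimate` must be a ukf_estimate", call. = FALSE)
  .write_csv_atomic(data.frame(time_days = estimate$times,
                               s_hat = estimate$mean[, "s_hat"],
                               i_hat = estimate$mean[, "i_hat"],
                               beta_hat = estimate$mean[, "beta_hat"],
                               gamma_hat = estimate$mean[, "gamma_hat"]),
                    path)
}
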