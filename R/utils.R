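# internal helpers shared across modules

# trapezoidal integral of y sampled at uniform spacing dt
.trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) / 2) * dt
}

# run `code` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  invisible(x)
}

# write a data.frame as CSV atomically (full double precision)
.write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  fmt <- df
  num <- vapply(fmt, is.numeric, logical(1L))
  fmt[num] <- lapply(fmt[num], function(x) formatC(x, digits = 15L, format = "g"))
  utils::write.csv(fmt, tmp, row.names = FALSE, quote = FALSE)
  if (!file.rename(tmp, path))
    stop("failed to write ", path, call. = FALSE)
  invisible(path)
}

.uniform_dt <- function(times, what = "times") {
  if (length(times) < 2L)
    stop(sprintf("`%s` needs at least two points", what), call. = FALSE)
  d <- diff(times)
  if (any(d <= 0))
    stop(sprintf("`%s` must be strictly increasing", what), call. = FALSE)
  dt <- d[1L]
  if (any(abs(d - dt) > 1e-8 * max(1, dt)))
    stop(sprintf("`%s` must be uniformly spaced", what), call. = FALSE)
  dt
}
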