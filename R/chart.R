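#' One-sided EWMA chart configuration
#'
#' Collects everything needed to run the lower-one-sided clipped EWMA on a
#' residual stream: the statistic is `F_t = min(lam * v_t + (1 - lam) *
#' F_{t-1}, xi)` started at `z0`, and the chart signals at the first `t`
#' with `F_t < LCL(t)` where
#' `LCL(t) = mu_e - L * sigma_e * sqrt(lam / (2 - lam) * (1 - (1 - lam)^(2t)))`.
#'
#' @param lam smoothing constant in (0, 1]; smaller values weight history
#'   more heavily and detect small sustained shifts faster.
#' @param L control coefficient (limit width in units of the asymptotic
#'   EWMA standard deviation); calibrated to a target in-control ARL.
#' @param xi clip level, the Phase-I residual mean: upward excursions of the
#'   statistic are absorbed at `xi` so only decreases in survival accumulate.
#' @param z0 initial statistic value; defaults to `xi` (in-control start).
#' @param mu_e,sigma_e Phase-I residual mean and SD feeding the limit.
#' @param limit_mode `"time_varying"` (exact variance at each `t`, default)
#'   or `"asymptotic"` (constant large-`t` limit).
#' @param horizon maximum number of observations before a run is declared
#'   censored (no signal).
#' @return object of class `chart_config`.
#' @examples
#' chart_config(lam = 0.1, L = 2.8)
#' @export
chart_config <- function(lam, L, xi = 0,
                         z0 = if (is.finite(xi)) xi else mu_e,
                         mu_e = 0, sigma_e = 1,
                         limit_mode = c("time_varying", "asymptotic"),
                         horizon = 1e6) {
  limit_mode <- match.arg(limit_mode)
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0 || lam > 1)
    stop("`lam` must lie in (0, 1]", call. = FALSE)
  if (!is.finite(z0))
    stop("`z0` must be finite (an infinite clip level `xi` is fine; the ",
         "statistic must still start somewhere)", call. = FALSE)
  if (L < 0) stop("`L` must be nonnegative", call. = FALSE)
  if (sigma_e <= 0) stop("`sigma_e` must be positive", call. = FALSE)
  if (horizon < 1) stop("`horizon` must be >= 1", call. = FALSE)
  structure(list(lam = lam, L = L, xi = xi, z0 = z0, mu_e = mu_e,
                 sigma_e = sigma_e, limit_mode = limit_mode,
                 horizon = as.integer(horizon)),
            class = "chart_config")
}

#' @export
print.chart_config <- function(x, ...) {
  cat(sprintf(
    "one-sided EWMA config: lam = %g, L = %g, xi = %g, z0 = %g, %s limit\n",
    x$lam, x$L, x$xi, x$z0, x$limit_mode))
  invisible(x)
}

#' One EWMA update
#'
#' `lam * v + (1 - lam) * prev`.
#'
#' @param prev previous statistic value.
#' @param v new residual.
#' @param lam smoothing constant in (0, 1].
#' @return updated statistic.
#' @export
ewma_step <- function(prev, v, lam) {
  if (lam <= 0 || lam > 1) stop("`lam` must lie in (0, 1]", call. = FALSE)
  lam * v + (1 - lam) * prev
}

#' One clipped (one-sided) EWMA update
#'
#' `min(lam * v + (1 - lam) * prev, xi)`: the statistic never exceeds the
#' clip level `xi`, so it accumulates evidence of decreased survival only.
#'
#' @inheritParams ewma_step
#' @param xi clip level.
#' @return updated statistic, `<= xi`.
#' @export
clipped_ewma_step <- function(prev, v, lam, xi) {
  min(ewma_step(prev, v, lam), xi)
}

#' Standard deviation of the EWMA statistic at time t
#'
#' `sigma_e * sqrt(lam * (1 - (1 - lam)^(2t)) / (2 - lam))`; increases in
#' `t` towards the asymptote `sigma_e * sqrt(lam / (2 - lam))`.
#'
#' @param t observation index, `>= 1` (may be `Inf` for the asymptote).
#' @param lam smoothing constant in (0, 1].
#' @param sigma_e residual standard deviation.
#' @return positive scalar (vectorized over `t`).
#' @export
ewma_sigma <- function(t, lam, sigma_e = 1) {
  if (lam <= 0 || lam > 1) stop("`lam` must lie in (0, 1]", call. = FALSE)
  if (any(t < 1)) stop("`t` must be >= 1", call. = FALSE)
  sigma_e * sqrt(lam * (1 - (1 - lam)^(2 * t)) / (2 - lam))
}

#' Lower control limit at time t
#'
#' `mu_e - L * ewma_sigma(t, lam, sigma_e)` in time-varying mode; the
#' asymptotic mode substitutes the large-`t` standard deviation.
#'
#' @param t observation index, `>= 1` (vectorized).
#' @param cfg a [chart_config()].
#' @return lower control limit(s); non-increasing in `t`.
#' @export
lcl <- function(t, cfg) {
  stopifnot(inherits(cfg, "chart_config"))
  s <- if (cfg$limit_mode == "time_varying")
    ewma_sigma(t, cfg$lam, cfg$sigma_e)
  else rep(cfg$sigma_e * sqrt(cfg$lam / (2 - cfg$lam)), length(t))
  cfg$mu_e - cfg$L * s
}

#' Run the one-sided EWMA chart on a residual stream
#'
#' Iterates the clipped statistic from `cfg$z0` over the supplied residuals
#' and signals at the first `t` with `F_t < LCL(t)`. If no signal occurs by
#' `min(length(residuals), cfg$horizon)` the run is censored there.
#'
#' @param residuals numeric residual stream (at least one value).
#' @param cfg a [chart_config()].
#' @return object of class `run_result`: list with `run_length`, `signaled`,
#'   `statistic_path` and `lcl_path` (paths up to the stopping time).
#' @examples
#' cfg <- chart_config(lam = 0.5, L = 2, xi = 0)
#' run_chart(c(-1, -1, -1, 1, -3), cfg)
#' @export
run_chart <- function(residuals, cfg) {
  stopifnot(inherits(cfg, "chart_config"))
  if (!length(residuals)) stop("residual stream is empty", call. = FALSE)
  n <- min(length(residuals), cfg$horizon)
  lcl_path <- lcl(seq_len(n), cfg)
  f <- numeric(n)
  prev <- cfg$z0
  signaled <- FALSE
  t_stop <- n
  for (t in seq_len(n)) {
    prev <- clipped_ewma_step(prev, residuals[t], cfg$lam, cfg$xi)
    f[t] <- prev
    if (prev < lcl_path[t]) {
      signaled <- TRUE
      t_stop <- t
      break
    }
  }
  structure(list(run_length = t_stop, signaled = signaled,
                 statistic_path = f[seq_len(t_stop)],
                 lcl_path = lcl_path[seq_len(t_stop)]),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("run %s at t = %d\n",
              if (x$signaled) "signaled" else "censored", x$run_length))
  invisible(x)
}
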