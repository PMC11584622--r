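# coerce a residual_series or numeric vector to a bootstrap pool
as_pool <- function(pool, floor_size = 1L) {
  v <- if (inherits(pool, "residual_series")) pool$values else as.numeric(pool)
  if (!length(v)) stop("residual pool is empty", call. = FALSE)
  if (any(!is.finite(v))) stop("residual pool must be finite", call. = FALSE)
  if (length(v) < floor_size)
    stop("residual pool smaller than the configured floor (",
         floor_size, ")", call. = FALSE)
  v
}

#' Simulate run lengths of the chart by Monte-Carlo
#'
#' Draws residual streams i.i.d. with replacement from a Phase-I pool
#' (`stream = "bootstrap"`) or from the standard normal (`stream =
#' "normal"`, the distributional alternative used for closed-form checks),
#' applies a shift of magnitude `delta` in the signaling (downward)
#' direction, and runs the chart to its first signal.
#'
#' @param pool `residual_series` or numeric vector of Phase-I residuals
#'   (ignored for the normal stream).
#' @param cfg a [chart_config()].
#' @param delta nonnegative shift magnitude (subtracted from each residual).
#' @param reps number of replicates.
#' @param stream `"bootstrap"` (default) or `"normal"`.
#' @return list with integer vector `run_length` and logical `signaled`.
#' @export
simulate_run_length <- function(pool, cfg, delta = 0, reps = 1L,
                                stream = c("bootstrap", "normal")) {
  stream <- match.arg(stream)
  stopifnot(inherits(cfg, "chart_config"))
  if (delta < 0) stop("`delta` must be nonnegative", call. = FALSE)
  v <- if (stream == "bootstrap") as_pool(pool) else 0
  rl_simulate_cpp(v, stream == "normal", cfg$lam, cfg$L, cfg$xi, cfg$z0,
                  cfg$mu_e, cfg$sigma_e, cfg$limit_mode == "time_varying",
                  delta, cfg$horizon, as.integer(reps))
}

#' Run-length profile (ARL, SDRL, percentiles) at one shift
#'
#' Repeats [simulate_run_length()] `reps` times and summarizes: ARL is the
#' mean run length, SDRL the sample standard deviation, and the percentiles
#' P05--P95 use linear interpolation between order statistics (so fractional
#' values can occur). Censored runs (horizon reached) are counted at the
#' horizon and reported, never dropped.
#'
#' @inheritParams simulate_run_length
#' @param seed optional integer seed.
#' @return object of class `run_length_summary`: list with `arl`, `sdrl`,
#'   `percentiles` (named P05..P95), `reps`, `censored_runs`, `delta`,
#'   `seed`, and `se` (Monte-Carlo standard error of the ARL).
#' @export
estimate_rl_profile <- function(pool, cfg, delta = 0, reps = 50000L,
                                stream = c("bootstrap", "normal"),
                                seed = NULL) {
  stream <- match.arg(stream)
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_run_length(pool, cfg, delta, reps, stream)
  rl <- as.numeric(sim$run_length)
  probs <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)
  pct <- quantile(rl, probs = probs, type = 7, names = FALSE)
  names(pct) <- c("P05", "P10", "P25", "P50", "P75", "P90", "P95")
  structure(list(arl = mean(rl),
                 sdrl = if (reps > 1) sd(rl) else 0,
                 percentiles = pct,
                 reps = as.integer(reps),
                 censored_runs = sum(!sim$signaled),
                 delta = delta,
                 seed = seed,
                 se = if (reps > 1) sd(rl) / sqrt(reps) else NA_real_),
            class = "run_length_summary")
}

#' @export
print.run_length_summary <- function(x, ...) {
  cat(sprintf("run-length profile at delta = %g (%d reps, %d censored)\n",
              x$delta, x$reps, x$censored_runs))
  cat(sprintf("  ARL = %.2f  SDRL = %.2f\n", x$arl, x$sdrl))
  cat("  ", paste(names(x$percentiles),
                  sprintf("%.2f", x$percentiles), sep = "=",
                  collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Calibrate the control coefficient L to a target in-control ARL
#'
#' Finds `L` such that the Monte-Carlo in-control (`delta = 0`) ARL matches
#' `target_arl0`. Uses common random numbers -- the same seed for every
#' evaluation -- so the statistic path of each replicate is identical across
#' candidate `L` values and the estimated ARL is an exactly non-decreasing
#' step function of `L`; a coarse bracket is then refined by bisection.
#'
#' @inheritParams estimate_rl_profile
#' @param lam smoothing constant of the chart to calibrate.
#' @param target_arl0 target in-control ARL, `> 1`.
#' @param seed seed reused for every evaluation (common random numbers).
#' @param tol calibration tolerance on `|ARL - target|`; default
#'   `max(1, 0.005 * target_arl0)`.
#' @param L_range bracketing interval searched for `L`.
#' @param xi,z0,mu_e,sigma_e,limit_mode,horizon chart parameters, as
#'   [chart_config()]; `xi` defaults to the pool mean (`0` for the normal
#'   stream), `z0` to `xi`, `mu_e`/`sigma_e` to the pool mean/SD.
#' @param max_iter bisection iteration cap.
#' @return object of class `ewma_calibration`: list with `L`, `arl0_hat`,
#'   `se` (standard error of `arl0_hat`), `cfg` (the calibrated
#'   [chart_config()]), `target`, `reps`, `seed`, `iterations` and
#'   `converged`.
#' @examples
#' \donttest{
#' cal <- calibrate_L(NULL, lam = 1, target_arl0 = 370, reps = 20000,
#'                    stream = "normal", seed = 1, xi = Inf)
#' cal$L   # close to -qnorm(1/370)
#' }
#' @export
calibrate_L <- function(pool, lam, target_arl0, reps = 50000L,
                        stream = c("bootstrap", "normal"),
                        seed = 1L, tol = NULL, L_range = c(0.2, 8),
                        xi = NULL, z0 = NULL, mu_e = NULL, sigma_e = NULL,
                        limit_mode = "time_varying", horizon = 1e6,
                        max_iter = 60L) {
  stream <- match.arg(stream)
  if (target_arl0 <= 1) stop("`target_arl0` must exceed 1", call. = FALSE)
  if (is.null(tol)) tol <- max(1, 0.005 * target_arl0)
  if (stream == "bootstrap") {
    v <- as_pool(pool, floor_size = 30L)
    if (is.null(mu_e)) mu_e <- mean(v)
    if (is.null(sigma_e)) sigma_e <- sd(v)
  } else {
    v <- 0
    if (is.null(mu_e)) mu_e <- 0
    if (is.null(sigma_e)) sigma_e <- 1
  }
  if (is.null(xi)) xi <- mu_e
  if (is.null(z0)) z0 <- if (is.finite(xi)) xi else mu_e
  cfg_at <- function(L, h = horizon) chart_config(
    lam = lam, L = L, xi = xi, z0 = z0, mu_e = mu_e, sigma_e = sigma_e,
    limit_mode = limit_mode, horizon = h)
  # evaluation horizon: runs are truncated at 50x the target ARL, where the
  # truncation probability of a near-target chart is ~exp(-50); this keeps
  # bracket evaluations at large L from running each replicate to the full
  # monitoring horizon
  h_eval <- min(horizon, ceiling(50 * target_arl0))
  eval_arl <- function(L) {
    set.seed(seed)
    sim <- simulate_run_length(if (stream == "bootstrap") v else NULL,
                               cfg_at(L, h_eval), delta = 0, reps = reps,
                               stream = stream)
    rl <- as.numeric(sim$run_length)
    c(mean(rl), sd(rl) / sqrt(length(rl)))
  }
  lo <- L_range[1L]; hi <- L_range[2L]
  a_lo <- eval_arl(lo); a_hi <- eval_arl(hi)
  if (a_lo[1L] > target_arl0 || a_hi[1L] < target_arl0)
    stop(sprintf(
      "calibration bracket not found in [%g, %g]: ARL range [%.2f, %.2f]",
      lo, hi, a_lo[1L], a_hi[1L]), call. = FALSE)
  it <- 0L
  best <- NULL
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    a <- eval_arl(mid)
    best <- list(L = mid, arl = a[1L], se = a[2L])
    if (abs(a[1L] - target_arl0) <= tol || it >= max_iter ||
        (hi - lo) < 1e-6) break
    if (a[1L] < target_arl0) lo <- mid else hi <- mid
  }
  structure(list(L = best$L, arl0_hat = best$arl, se = best$se,
                 cfg = cfg_at(best$L), target = target_arl0,
                 reps = as.integer(reps), seed = seed, iterations = it,
                 converged = abs(best$arl - target_arl0) <= tol),
            class = "ewma_calibration")
}

#' @export
print.ewma_calibration <- function(x, ...) {
  cat(sprintf(
    "calibrated L = %.5f (lam = %g): ARL0-hat = %.2f (se %.2f), target %g\n",
    x$L, x$cfg$lam, x$arl0_hat, x$se, x$target))
  if (!x$converged)
    cat("  NOTE: tolerance not met after", x$iterations, "iterations\n")
  invisible(x)
}

#' Run-length table over a grid of shifts
#'
#' One [estimate_rl_profile()] row per shift magnitude, in the standard
#' reporting layout `shift, ARL, SDRL, P05, P10, P25, P50, P75, P90, P95`.
#'
#' @inheritParams estimate_rl_profile
#' @param deltas nonnegative shift magnitudes, sorted ascending.
#' @param seed root seed; shift `k` uses `seed + k - 1`.
#' @return data.frame of class `shift_table`; the full
#'   `run_length_summary` objects are attached as attribute `"summaries"`.
#' @export
shift_table <- function(pool, cfg, deltas, reps = 50000L,
                        stream = c("bootstrap", "normal"), seed = NULL) {
  stream <- match.arg(stream)
  if (is.unsorted(deltas) || any(deltas < 0))
    stop("`deltas` must be nonnegative and sorted ascending", call. = FALSE)
  sums <- vector("list", length(deltas))
  for (k in seq_along(deltas)) {
    sums[[k]] <- estimate_rl_profile(
      pool, cfg, delta = deltas[k], reps = reps, stream = stream,
      seed = if (is.null(seed)) NULL else seed + k - 1L)
  }
  out <- data.frame(
    shift = deltas,
    ARL = vapply(sums, `[[`, numeric(1), "arl"),
    SDRL = vapply(sums, `[[`, numeric(1), "sdrl"))
  pct <- t(vapply(sums, `[[`, numeric(7), "percentiles"))
  colnames(pct) <- c("P05", "P10", "P25", "P50", "P75", "P90", "P95")
  out <- cbind(out, as.data.frame(pct))
  attr(out, "summaries") <- sums
  class(out) <- c("shift_table", "data.frame")
  out
}
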