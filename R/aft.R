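#' Fit the accelerated failure time risk-adjustment model
#'
#' Maximum-likelihood fit of `log T = beta0 + beta1 * Parsonnet (+ group
#' effects) + sigma * eps` on Phase-I (in-control) data, with right-censored
#' records contributing survivor-function terms. Estimation is the standard
#' censored AFT likelihood via [survival::survreg()]; the error law maps to
#' `dist = "lognormal"` (standard normal eps), `"loglogistic"` (logistic eps)
#' or `"weibull"` (minimum-Gumbel eps).
#'
#' @param cohort a data.frame with columns `parsonnet`, `time_days`,
#'   `censored`, and optionally `group` (used when `use_group = TRUE`).
#' @param error_dist error law of the log-scale residual.
#' @param use_group include surgeon-group dummies as extra covariates.
#' @return object of class `aft_fit`: list with `beta0`, `beta1`,
#'   `extra_betas` (named, possibly empty), `sigma`, `loglik`, `n_used`,
#'   `n_censored_used`, `error_dist`, `converged`, and the underlying
#'   `survreg` fit in `$fit`.
#' @examples
#' co <- generate_cohort(cohort_config(n = 500, seed = 1))
#' fit_aft(co)
#' @export
fit_aft <- function(cohort,
                    error_dist = c("standard_normal", "logistic",
                                   "gumbel_min"),
                    use_group = FALSE) {
  error_dist <- match.arg(error_dist)
  check_cohort_frame(cohort)
  if (sum(!cohort$censored) < 2L)
    stop("need at least 2 uncensored records to fit the AFT model",
         call. = FALSE)
  dist <- switch(error_dist,
                 standard_normal = "lognormal",
                 logistic = "loglogistic",
                 gumbel_min = "weibull")
  dat <- cohort
  dat$.event <- !dat$censored
  # degenerate case: log time exactly linear in the covariates (sigma -> 0);
  # the censored likelihood is unbounded there, so return the interpolant
  unc <- dat[!dat$censored, , drop = FALSE]
  ols <- stats::lm(log(time_days) ~ parsonnet, data = unc)
  if (!use_group && max(abs(stats::residuals(ols))) < 1e-10) {
    lp_cens <- stats::predict(ols, newdata = dat[dat$censored, ,
                                                 drop = FALSE])
    if (!nrow(dat[dat$censored, , drop = FALSE]) ||
        all(lp_cens >= log(dat$time_days[dat$censored]) - 1e-8)) {
      cf <- coef(ols)
      return(structure(list(beta0 = unname(cf[1L]), beta1 = unname(cf[2L]),
                            extra_betas = numeric(0),
                            sigma = max(sd(stats::residuals(ols)), 1e-12),
                            loglik = Inf, n_used = nrow(dat),
                            n_censored_used = sum(dat$censored),
                            error_dist = error_dist, converged = TRUE,
                            fit = NULL),
                       class = "aft_fit"))
    }
  }
  form <- survival::Surv(time_days, .event) ~ parsonnet
  if (use_group) {
    if (all(is.na(dat$group)))
      stop("`use_group = TRUE` but the cohort has no group labels",
           call. = FALSE)
    dat$group <- factor(dat$group)
    form <- survival::Surv(time_days, .event) ~ parsonnet + group
  }
  sr <- withCallingHandlers(
    survival::survreg(form, data = dat, dist = dist,
                      control = survival::survreg.control(maxiter = 100)),
    warning = function(w) {
      if (grepl("Ran out of iterations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- coef(sr)
  extra <- cf[setdiff(names(cf), c("(Intercept)", "parsonnet"))]
  structure(list(beta0 = unname(cf["(Intercept)"]),
                 beta1 = unname(cf["parsonnet"]),
                 extra_betas = extra,
                 sigma = unname(sr$scale),
                 loglik = sr$loglik[2L],
                 n_used = nrow(dat),
                 n_censored_used = sum(dat$censored),
                 error_dist = error_dist,
                 converged = is.null(sr$fail) &&
                   sr$iter < 100L,
                 fit = sr),
            class = "aft_fit")
}

#' @export
print.aft_fit <- function(x, ...) {
  cat("AFT risk-adjustment fit (", x$error_dist, " errors)\n", sep = "")
  cat(sprintf("  beta0 = %.5f  beta1 = %.5f  sigma = %.5f\n",
              x$beta0, x$beta1, x$sigma))
  if (length(x$extra_betas))
    cat("  extra coefficients:",
        paste(names(x$extra_betas),
              sprintf("%.4f", x$extra_betas), collapse = ", "), "\n")
  cat(sprintf("  n = %d (%d censored), loglik = %.2f\n",
              x$n_used, x$n_censored_used, x$loglik))
  invisible(x)
}

# linear predictor of an aft_fit on a cohort
aft_linpred <- function(fit, cohort) {
  lp <- fit$beta0 + fit$beta1 * cohort$parsonnet
  if (length(fit$extra_betas)) {
    mm <- predict(fit$fit, newdata = transform(cohort, .event = TRUE),
                  type = "lp")
    lp <- as.numeric(mm)
  }
  lp
}

#' Standardized AFT residuals (SR-AFT)
#'
#' Computes `e_t = (log T_t - sum_n beta_n P_tn) / sigma` per record, the
#' standardized residual monitored by the risk-adjusted EWMA chart. Censored
#' records have no observed `log T`; by default they are excluded from the
#' residual pool (they still informed the MLE). `censored = "include"` plugs
#' in the censoring time (a conservative lower bound); `"impute"` replaces
#' the unobserved residual by its conditional expectation given survival past
#' the horizon (normal errors only).
#'
#' @param cohort cohort data.frame.
#' @param fit an [fit_aft()] result.
#' @param censored policy for censored records: `"exclude"` (default),
#'   `"include"`, or `"impute"`.
#' @return object of class `residual_series`: list with `values`, `source`
#'   (`"SR_AFT"`), and the pool `mean` and `sd` (sample SD, n-1 denominator)
#'   that feed the chart's control-limit formula.
#' @examples
#' co <- generate_cohort(cohort_config(n = 500, seed = 1))
#' rs <- sr_aft(co, fit_aft(co))
#' c(rs$mean, rs$sd)
#' @export
sr_aft <- function(cohort, fit,
                   censored = c("exclude", "include", "impute")) {
  censored <- match.arg(censored)
  stopifnot(inherits(fit, "aft_fit"))
  check_cohort_frame(cohort)
  if (fit$sigma <= 0) stop("fit has non-positive sigma", call. = FALSE)
  if (any(cohort$time_days <= 0))
    stop("survival times must be positive", call. = FALSE)
  lp <- aft_linpred(fit, cohort)
  e <- (log(cohort$time_days) - lp) / fit$sigma
  if (censored == "exclude") {
    e <- e[!cohort$censored]
  } else if (censored == "impute") {
    if (fit$error_dist != "standard_normal")
      stop("conditional-mean imputation is implemented for normal errors only",
           call. = FALSE)
    cen <- cohort$censored
    # E[eps | eps > c] = phi(c) / (1 - Phi(c)), inverse Mills ratio
    cc <- e[cen]
    e[cen] <- dnorm(cc) / pnorm(cc, lower.tail = FALSE)
  }
  residual_series(e, source = "SR_AFT")
}

#' Residual series container
#'
#' @param values finite numeric residuals.
#' @param source `"SR_AFT"` or `"SR_SVM"`.
#' @param mean,sd pool mean and sample SD; computed from `values` when
#'   omitted (the Phase-I convention). Supply stored Phase-I constants when
#'   wrapping Phase-II residuals.
#' @return object of class `residual_series`.
#' @export
residual_series <- function(values, source = c("SR_AFT", "SR_SVM"),
                            mean = NULL, sd = NULL) {
  source <- match.arg(source)
  values <- as.numeric(values)
  if (length(values) && any(!is.finite(values)))
    stop("residuals must be finite", call. = FALSE)
  m <- if (is.null(mean)) base::mean(values) else mean
  s <- if (is.null(sd)) stats::sd(values) else sd
  structure(list(values = values, source = source, mean = m, sd = s),
            class = "residual_series")
}

#' @export
print.residual_series <- function(x, ...) {
  cat(sprintf("%s residual series: n = %d, mean = %.6f, sd = %.6f\n",
              x$source, length(x$values), x$mean, x$sd))
  invisible(x)
}

# shared cohort frame validation
check_cohort_frame <- function(cohort) {
  need <- c("parsonnet", "time_days", "censored")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(cohort)
}
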