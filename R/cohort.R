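#' Parsonnet score distribution specification
#'
#' Describes the marginal distribution of the Parsonnet score (an integer
#' preoperative cardiac-surgery risk score on 0--100; higher means higher
#' predicted mortality) used by the synthetic cohort generator.
#'
#' @param type one of `"geometric"` (geometric-shaped pmf truncated to
#'   0--100, right-skewed with most mass near 0, the default shape of real
#'   Parsonnet distributions), `"point"` (all patients share one score), or
#'   `"custom"` (an explicit pmf over 0--100).
#' @param mean target mean of the untruncated geometric law (`type =
#'   "geometric"` only); the truncated mean is slightly smaller and is
#'   available from [parsonnet_pmf()].
#' @param value the common score for `type = "point"`.
#' @param probs length-101 nonnegative weight vector over scores 0--100 for
#'   `type = "custom"`; normalized internally.
#' @return an object of class `parsonnet_dist`.
#' @examples
#' parsonnet_dist("geometric", mean = 10)
#' parsonnet_dist("point", value = 5)
#' @export
parsonnet_dist <- function(type = c("geometric", "point", "custom"),
                           mean = 10, value = 0L, probs = NULL) {
  type <- match.arg(type)
  out <- list(type = type)
  if (type == "geometric") {
    if (!is.numeric(mean) || length(mean) != 1L || mean <= 0)
      stop("`mean` must be a single positive number", call. = FALSE)
    out$mean <- mean
  } else if (type == "point") {
    if (!is.numeric(value) || length(value) != 1L || value < 0 || value > 100)
      stop("`value` must be a single score in [0, 100]", call. = FALSE)
    out$value <- as.integer(value)
  } else {
    if (is.null(probs) || length(probs) != 101L || any(probs < 0) ||
        sum(probs) <= 0)
      stop("`probs` must be 101 nonnegative weights over scores 0..100",
           call. = FALSE)
    out$probs <- probs / sum(probs)
  }
  structure(out, class = "parsonnet_dist")
}

#' Probability mass function of a Parsonnet score distribution
#'
#' @param dist a [parsonnet_dist()] object.
#' @return numeric vector of length 101: `P(score = k)` for `k = 0..100`.
#' @examples
#' pmf <- parsonnet_pmf(parsonnet_dist("geometric", mean = 10))
#' sum(pmf * 0:100) # truncated mean, slightly below 10
#' @export
parsonnet_pmf <- function(dist) {
  stopifnot(inherits(dist, "parsonnet_dist"))
  k <- 0:100
  switch(dist$type,
    geometric = {
      # success prob so the untruncated geometric mean (1-p)/p equals dist$mean
      p <- 1 / (1 + dist$mean)
      w <- (1 - p)^k * p
      w / sum(w)
    },
    point = {
      w <- numeric(101L)
      w[dist$value + 1L] <- 1
      w
    },
    custom = dist$probs
  )
}

#' Synthetic cohort configuration
#'
#' Bundles everything needed to generate a synthetic cardiac-surgery cohort
#' whose log survival times follow the accelerated failure time structure
#' `log T = beta0 + beta1 * Parsonnet + sigma * eps`, right-censored at a
#' follow-up horizon (30 days by default: patients alive at day 30 are
#' recorded as censored at 30).
#'
#' Defaults for `beta0`, `beta1` and `sigma` are the published Phase-I
#' estimates for the cardiac-surgery application (5.07026, -0.03348, 0.57).
#'
#' @param n number of patients.
#' @param beta0 intercept on the log-day scale.
#' @param beta1 slope per Parsonnet unit (log-days); negative means sicker
#'   patients die sooner.
#' @param sigma scale of the error term (log-days), `>= 0`.
#' @param error_dist error law of `eps`: `"standard_normal"` (log-normal
#'   survival), `"logistic"` (log-logistic) or `"gumbel_min"` (Weibull).
#' @param parsonnet a [parsonnet_dist()] specification.
#' @param censor_horizon_days right-censoring horizon in days; `Inf` disables
#'   censoring.
#' @param group_offsets optional named numeric vector of additive log-scale
#'   surgeon-group effects; groups are assigned uniformly at random. `NULL`
#'   (default) disables grouping.
#' @param seed optional integer seed making [generate_cohort()] deterministic.
#' @return an object of class `cohort_config`.
#' @examples
#' cohort_config(n = 100, seed = 1)
#' @export
cohort_config <- function(n,
                          beta0 = 5.07026,
                          beta1 = -0.03348,
                          sigma = 0.57,
                          error_dist = c("standard_normal", "logistic",
                                         "gumbel_min"),
                          parsonnet = parsonnet_dist("geometric", mean = 10),
                          censor_horizon_days = 30,
                          group_offsets = NULL,
                          seed = NULL) {
  error_dist <- match.arg(error_dist)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n))
    stop("`n` must be a nonnegative integer", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (censor_horizon_days <= 0)
    stop("`censor_horizon_days` must be positive", call. = FALSE)
  if (!inherits(parsonnet, "parsonnet_dist"))
    stop("`parsonnet` must be a parsonnet_dist object", call. = FALSE)
  if (!is.null(group_offsets) &&
      (is.null(names(group_offsets)) || any(names(group_offsets) == "")))
    stop("`group_offsets` must be a named numeric vector", call. = FALSE)
  structure(list(n = as.integer(n), beta0 = beta0, beta1 = beta1,
                 sigma = sigma, error_dist = error_dist,
                 parsonnet = parsonnet,
                 censor_horizon_days = censor_horizon_days,
                 group_offsets = group_offsets,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cohort_config")
}

#' Sample Parsonnet scores
#'
#' @param n number of scores to draw.
#' @param dist a [parsonnet_dist()] specification.
#' @return integer vector of length `n` with values in 0--100.
#' @examples
#' set.seed(1)
#' sample_parsonnet(5, parsonnet_dist("geometric", mean = 10))
#' @export
sample_parsonnet <- function(n, dist = parsonnet_dist("geometric", mean = 10)) {
  if (n < 0) stop("`n` must be nonnegative", call. = FALSE)
  if (n == 0L) return(integer(0))
  pmf <- parsonnet_pmf(dist)
  sample(0:100, size = n, replace = TRUE, prob = pmf)
}

# draw the error term of the log-linear survival model
draw_error <- function(n, error_dist) {
  switch(error_dist,
    standard_normal = rnorm(n),
    logistic = rlogis(n),
    gumbel_min = log(-log(runif(n))), # minimum-type Gumbel: log of Exp(1)
    stop("unsupported error distribution: ", error_dist, call. = FALSE)
  )
}

#' Simulate latent (uncensored) survival times
#'
#' Draws `T = exp(beta0 + beta1 * P + sigma * eps)` for a vector of Parsonnet
#' scores `P`, with `eps` i.i.d. from the configured error law.
#'
#' @param scores integer Parsonnet scores in 0--100.
#' @param cfg a [cohort_config()] (only the regression fields are used).
#' @return numeric vector of positive survival times in days.
#' @export
simulate_survival <- function(scores, cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (length(scores) && (any(scores < 0) || any(scores > 100)))
    stop("Parsonnet scores must lie in [0, 100]", call. = FALSE)
  n <- length(scores)
  eps <- draw_error(n, cfg$error_dist)
  exp(cfg$beta0 + cfg$beta1 * scores + cfg$sigma * eps)
}

#' Apply right-censoring at a follow-up horizon
#'
#' Times beyond the horizon are recorded at the horizon and flagged censored;
#' a time exactly equal to the horizon is treated as observed.
#'
#' @param times positive survival times (days).
#' @param horizon censoring horizon (days).
#' @return data.frame with columns `time_days` and `censored` (logical).
#' @examples
#' apply_censoring(c(10, 45, 30), horizon = 30)
#' @export
apply_censoring <- function(times, horizon = 30) {
  if (length(times) && any(times <= 0))
    stop("survival times must be positive", call. = FALSE)
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  cen <- times > horizon
  data.frame(time_days = ifelse(cen, horizon, times), censored = cen)
}

#' Generate a synthetic cardiac-surgery cohort
#'
#' Composes [sample_parsonnet()], [simulate_survival()] and
#' [apply_censoring()] into one deterministic (given `cfg$seed`) cohort draw.
#' The latent uncensored time is retained in `true_time_days` for oracle
#' checks; model-fitting code never reads it.
#'
#' @param cfg a [cohort_config()].
#' @return data.frame of class `cohort` with columns `patient_id`,
#'   `parsonnet`, `time_days`, `censored`, `group` (NA when grouping is off)
#'   and `true_time_days`.
#' @examples
#' head(generate_cohort(cohort_config(n = 5, seed = 42)))
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n
  scores <- sample_parsonnet(n, cfg$parsonnet)
  if (!is.null(cfg$group_offsets)) {
    grp <- sample(names(cfg$group_offsets), size = n, replace = TRUE)
    offset <- unname(cfg$group_offsets[grp])
  } else {
    grp <- rep(NA_character_, n)
    offset <- numeric(n)
  }
  eps <- draw_error(n, cfg$error_dist)
  true_t <- exp(cfg$beta0 + cfg$beta1 * scores + offset + cfg$sigma * eps)
  cen <- apply_censoring(if (n) true_t else numeric(0),
                         cfg$censor_horizon_days)
  out <- data.frame(patient_id = seq_len(n),
                    parsonnet = as.integer(scores),
                    time_days = cen$time_days,
                    censored = cen$censored,
                    group = grp,
                    true_time_days = true_t,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  out
}
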