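#' @section Kernels:
#' Linear kernel `<x, x'>` or Gaussian radial basis `exp(-gamma ||x - x'||^2)`.
#' @noRd
kernel_matrix <- function(x1, x2, kernel = "linear", gamma = 1) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (kernel == "linear") return(x1 %*% t(x2))
  if (kernel == "rbf") {
    d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
    d2[d2 < 0] <- 0
    return(exp(-gamma * d2))
  }
  stop("unsupported kernel: ", kernel, call. = FALSE)
}

#' Median-distance heuristic for the RBF kernel width
#'
#' Returns `gamma = 1 / (2 m^2)` where `m` is the median nonzero pairwise
#' Euclidean distance among (a deterministic subsample of) the inputs. Falls
#' back to `gamma = 1` when all points coincide.
#'
#' @param x numeric vector or matrix of inputs (rows = points).
#' @param max_points deterministic subsample cap (evenly spaced after
#'   ordering by the first coordinate).
#' @return positive scalar `gamma`.
#' @export
median_heuristic_gamma <- function(x, max_points = 1000L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n > max_points) {
    idx <- order(x[, 1L])[unique(round(seq(1L, n, length.out = max_points)))]
    x <- x[idx, , drop = FALSE]
  }
  d <- as.numeric(stats::dist(x))
  d <- d[d > 0]
  if (!length(d)) return(1)
  m <- median(d)
  1 / (2 * m^2)
}

#' Maximal-margin (hard-margin) linear classifier
#'
#' Solves the dual of the separating-hyperplane problem: minimize
#' `1/2 sum_ij alpha_i alpha_j y_i y_j <x_i, x_j> - sum_i alpha_i` subject to
#' `alpha >= 0` and `sum_i alpha_i y_i = 0`, then recovers the hyperplane
#' `omega = sum_i alpha_i y_i x_i` and offset
#' `b = -1/2 <omega, x_r + x_s>`, where `x_r`, `x_s` are the support vectors
#' with the largest multiplier in each class. The solution is in canonical
#' form: `min_i |<omega, x_i> + b| = 1`.
#'
#' The QP is solved by the generic interior-point routine
#' [kernlab::ipop()] and then polished by solving the support-set
#' Karush-Kuhn-Tucker linear system exactly.
#'
#' @param x numeric matrix of training points (rows) or a vector (1-D).
#' @param y labels in `{-1, +1}`, one per row of `x`.
#' @return object of class `margin_classifier`: list with `omega`, `b`,
#'   `alphas`, `support_indices`, and the dual `objective`.
#' @examples
#' cls <- solve_max_margin(c(-1, 1), c(-1, 1))
#' c(cls$omega, cls$b)       # 1, 0
#' margin_of(cls)            # 2
#' @export
solve_max_margin <- function(x, y) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  l <- nrow(x)
  if (length(y) != l) stop("`x` and `y` sizes differ", call. = FALSE)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L)
    stop("labels must be in {-1, +1} with both classes present",
         call. = FALSE)
  K <- kernel_matrix(x, x, "linear")
  Q <- (y %o% y) * K
  big <- 1e7
  sol <- kernlab::ipop(c = matrix(-1, l, 1),
                       H = Q + diag(1e-10, l),
                       A = matrix(y, 1, l), b = 0, r = 0,
                       l = matrix(0, l, 1), u = matrix(big, l, 1),
                       sigf = 9, maxiter = 100)
  alpha <- as.numeric(kernlab::primal(sol))
  if (max(alpha) > 0.9 * big)
    stop("data are not linearly separable: hard-margin dual is unbounded",
         call. = FALSE)
  sv <- which(alpha > 1e-6 * max(alpha))
  # KKT polish on the support set: [K_SS 1; 1' 0] [u; b] = [y_S; 0], u = alpha*y
  pol <- try({
    M <- rbind(cbind(K[sv, sv, drop = FALSE], 1), c(rep(1, length(sv)), 0))
    rhs <- c(y[sv], 0)
    sol_ub <- qr.solve(M, rhs, tol = 1e-12)
    u <- sol_ub[seq_along(sv)]
    a <- u * y[sv]
    if (any(a < -1e-8)) stop("negative multiplier after polish")
    a
  }, silent = TRUE)
  if (!inherits(pol, "try-error")) {
    alpha <- numeric(l)
    alpha[sv] <- pmax(pol, 0)
  }
  omega <- as.numeric(t(x) %*% (alpha * y))
  # Eq.-style offset from the largest-multiplier support vector in each class
  pos <- which(y > 0 & alpha > 0); neg <- which(y < 0 & alpha > 0)
  xr <- x[pos[which.max(alpha[pos])], ]
  xs <- x[neg[which.max(alpha[neg])], ]
  b <- -0.5 * sum(omega * (xr + xs))
  marg <- y * (as.numeric(x %*% omega) + b)
  if (min(marg) < 1 - 1e-4)
    stop("data are not linearly separable within tolerance", call. = FALSE)
  obj <- 0.5 * sum((alpha * y) * (K %*% (alpha * y))) - sum(alpha)
  structure(list(omega = omega, b = b, alphas = alpha,
                 support_indices = which(alpha > 0),
                 objective = obj),
            class = "margin_classifier")
}

#' @export
print.margin_classifier <- function(x, ...) {
  cat("maximal-margin classifier: d =", length(x$omega),
      ", support vectors:", length(x$support_indices),
      sprintf(", margin = %.6g\n", margin_of(x)))
  invisible(x)
}

#' Geometric margin of a maximal-margin classifier
#'
#' The full margin (sum of the distances from the hyperplane to the nearest
#' point of each class), `2 / ||omega||` in canonical form.
#'
#' @param cls a [solve_max_margin()] result.
#' @return positive scalar margin.
#' @export
margin_of <- function(cls) {
  stopifnot(inherits(cls, "margin_classifier"))
  nrm <- sqrt(sum(cls$omega^2))
  if (nrm <= 0) stop("degenerate model: zero normal vector", call. = FALSE)
  2 / nrm
}

#' Fit epsilon-insensitive support vector regression
#'
#' Trains the SVR predictor of log survival time from the Parsonnet score
#' used by the SVM-EWMA chart: minimize `1/2 ||w||^2 + C * sum(slack)` with
#' the epsilon-insensitive loss, solved in the dual (libsvm SMO via
#' [e1071::svm()], `scale = FALSE`). The dual coefficients satisfy
#' `|beta_i| <= C` and `sum(beta_i) = 0`; prediction is
#' `f(x) = sum_i beta_i K(x_i, x) + b`.
#'
#' @param x numeric vector or matrix of inputs (e.g. Parsonnet scores).
#' @param y numeric response (e.g. log survival in log-days).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C box constraint (cost), positive.
#' @param epsilon half-width of the insensitivity tube, nonnegative.
#' @param gamma RBF width; default is the median-distance heuristic
#'   [median_heuristic_gamma()].
#' @param tol SMO termination tolerance.
#' @return object of class `svr_fit`: list with `x` (training inputs),
#'   `beta` (dual coefficients `alpha_i - alpha_i*`, full length), `b`,
#'   `kernel`, `C`, `epsilon`, `gamma` and the underlying `e1071::svm`
#'   model in `$model`.
#' @examples
#' fit <- fit_svr(1:10, 2 * (1:10), kernel = "linear", C = 100,
#'                epsilon = 0.01)
#' predict(fit, 5)
#' @export
fit_svr <- function(x, y, kernel = c("rbf", "linear"), C = 1, epsilon = 0.1,
                    gamma = NULL, tol = 1e-6) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("`x` and `y` sizes differ", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 training points", call. = FALSE)
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  if (epsilon < 0) stop("`epsilon` must be nonnegative", call. = FALSE)
  if (kernel == "rbf") {
    if (is.null(gamma)) gamma <- median_heuristic_gamma(x)
    if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  } else gamma <- 0
  m <- e1071::svm(x = x, y = y, type = "eps-regression",
                  kernel = if (kernel == "rbf") "radial" else "linear",
                  cost = C, epsilon = epsilon,
                  gamma = if (kernel == "rbf") gamma else 1,
                  scale = FALSE, tolerance = tol, fitted = FALSE)
  beta <- numeric(nrow(x))
  beta[m$index] <- as.numeric(m$coefs)
  structure(list(x = x, beta = beta, b = -m$rho, kernel = kernel,
                 C = C, epsilon = epsilon, gamma = gamma, model = m),
            class = "svr_fit")
}

#' @export
print.svr_fit <- function(x, ...) {
  cat(sprintf(
    "epsilon-SVR fit: n = %d, kernel = %s, C = %g, epsilon = %g%s, SVs = %d\n",
    nrow(x$x), x$kernel, x$C, x$epsilon,
    if (x$kernel == "rbf") sprintf(", gamma = %.4g", x$gamma) else "",
    sum(x$beta != 0)))
  invisible(x)
}

#' Predict from a fitted support vector regression
#'
#' Evaluates the dual expansion `f(x) = sum_i beta_i K(x_i, x) + b`
#' directly, so prediction works even when no training point is a support
#' vector (e.g. a constant response inside the tube).
#'
#' @param object an [fit_svr()] result.
#' @param newdata numeric vector or matrix of inputs.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.svr_fit <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  if (ncol(nd) != ncol(object$x)) {
    if (ncol(object$x) == 1L) nd <- matrix(as.numeric(newdata), ncol = 1L)
    else stop("newdata dimension mismatch", call. = FALSE)
  }
  if (any(!is.finite(nd))) stop("inputs must be finite", call. = FALSE)
  sv <- which(object$beta != 0)
  if (!length(sv)) return(rep(object$b, nrow(nd)))
  K <- kernel_matrix(nd, object$x[sv, , drop = FALSE], object$kernel,
                     object$gamma)
  as.numeric(K %*% object$beta[sv]) + object$b
}

#' Dual objective value of a fitted SVR
#'
#' Evaluates `1/2 b' K b - y' b + epsilon ||b||_1` at the fitted dual
#' coefficients (`b = alpha - alpha*`), the quantity minimized by the SVR
#' dual; used for cross-checks against generic quadratic-programming
#' solutions.
#'
#' @param fit an [fit_svr()] result.
#' @param y the training response the model was fitted to.
#' @return scalar objective value.
#' @export
svr_dual_objective <- function(fit, y) {
  K <- kernel_matrix(fit$x, fit$x, fit$kernel, fit$gamma)
  b <- fit$beta
  0.5 * sum(b * (K %*% b)) - sum(y * b) + fit$epsilon * sum(abs(b))
}

#' Standardized SVM-regression residuals (SR-SVM)
#'
#' Raw residuals `r_t = log T_t - f(P_t)` from the fitted SVR are
#' standardized with the Phase-I pool mean and sample SD:
#' `v_t = (r_t - mean_I(r)) / sd_I(r)`. When `phase1` is `NULL` the supplied
#' cohort *is* the Phase-I pool and the constants are computed from it (so
#' the output has mean 0, SD 1 by construction); passing a Phase-I
#' `residual_series` re-uses its stored constants, the correct treatment of
#' prospective Phase-II data.
#'
#' @param cohort cohort data.frame.
#' @param fit an [fit_svr()] result trained on Parsonnet vs log time.
#' @param phase1 optional Phase-I `residual_series` whose `raw_mean` /
#'   `raw_sd` standardize this cohort.
#' @param censored policy for censored records: `"exclude"` (default; their
#'   log survival is unobserved) or `"include"` (plug in the censoring time).
#' @return `residual_series` with `source = "SR_SVM"`; carries `raw_mean`
#'   and `raw_sd`, the Phase-I standardization constants.
#' @export
sr_svm <- function(cohort, fit, phase1 = NULL,
                   censored = c("exclude", "include")) {
  censored <- match.arg(censored)
  stopifnot(inherits(fit, "svr_fit"))
  check_cohort_frame(cohort)
  keep <- if (censored == "exclude") !cohort$censored else
    rep(TRUE, nrow(cohort))
  if (sum(keep) < 2L)
    stop("need at least 2 usable records for SR-SVM", call. = FALSE)
  if (any(cohort$time_days[keep] <= 0))
    stop("survival times must be positive", call. = FALSE)
  r <- log(cohort$time_days[keep]) -
    predict(fit, cohort$parsonnet[keep])
  if (is.null(phase1)) {
    m <- mean(r); s <- sd(r)
    if (!is.finite(s) || s < 1e-12)
      stop(paste("raw residual SD is zero (perfect interpolation);",
                 "refit with larger epsilon or smaller C"), call. = FALSE)
  } else {
    stopifnot(inherits(phase1, "residual_series"))
    m <- phase1$raw_mean; s <- phase1$raw_sd
  }
  out <- residual_series((r - m) / s, source = "SR_SVM")
  out$raw_mean <- m
  out$raw_sd <- s
  out
}
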