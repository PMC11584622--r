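# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# Brute-force maximal-margin oracle: enumerate candidate active sets of the
# primal problem (min 1/2 ||w||^2 s.t. y_i(<w, x_i> + b) >= 1), solve the
# equality-constrained KKT system for each, and keep the feasible solution
# with the smallest objective. Exact for small instances.
max_margin_oracle <- function(x, y) {
  x <- as.matrix(x)
  l <- nrow(x)
  d <- ncol(x)
  best <- NULL
  for (k in 1:min(l, d + 1)) {
    for (S in asplit(utils::combn(l, k), 2)) {
      S <- as.integer(S)
      if (k > 1 && length(unique(y[S])) < 2) next
      xs <- x[S, , drop = FALSE]
      M <- rbind(cbind(xs %*% t(xs), 1), c(rep(1, k), 0))
      ub <- try(qr.solve(M, c(y[S], 0), tol = 1e-12), silent = TRUE)
      if (inherits(ub, "try-error")) next
      u <- ub[1:k]
      b <- ub[k + 1]
      if (any(u * y[S] < -1e-9)) next            # dual feasibility
      w <- as.numeric(t(xs) %*% u)
      if (min(y * (x %*% w + b)) < 1 - 1e-8) next # primal feasibility
      obj <- 0.5 * sum(w^2)
      if (is.null(best) || obj < best$objective - 1e-12)
        best <- list(objective = obj, omega = w, b = b)
    }
  }
  best
}

# Random linearly separable instance: classes pushed apart along a random
# direction so the full margin is at least ~1.
random_separable_instance <- function(d = NULL, l = NULL) {
  if (is.null(d)) d <- sample(1:3, 1)
  if (is.null(l)) l <- sample(4:12, 1)
  repeat {
    w0 <- rnorm(d)
    w0 <- w0 / sqrt(sum(w0^2))
    x <- matrix(rnorm(l * d), l, d)
    y <- ifelse(as.numeric(x %*% w0) > 0, 1, -1)
    if (length(unique(y)) == 2) break
  }
  x <- x + outer(y, w0) * 0.5
  list(x = x, y = y)
}

# Generic box-constrained QP oracle for the epsilon-SVR dual, via the
# interior-point solver on the (alpha, alpha*) formulation.
svr_dual_oracle <- function(x, y, kernel = "linear", C = 1, epsilon = 0.1,
                            gamma = 1) {
  x <- as.matrix(x)
  l <- nrow(x)
  K <- if (kernel == "linear") x %*% t(x) else {
    d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * x %*% t(x)
    exp(-gamma * pmax(d2, 0))
  }
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * l)
  sol <- kernlab::ipop(c = matrix(c(epsilon - y, epsilon + y)), H = H,
                       A = matrix(c(rep(1, l), rep(-1, l)), 1),
                       b = 0, r = 0, l = matrix(0, 2 * l),
                       u = matrix(C, 2 * l), sigf = 9, maxiter = 200)
  ab <- as.numeric(kernlab::primal(sol))
  beta <- ab[1:l] - ab[(l + 1):(2 * l)]
  list(beta = beta,
       objective = 0.5 * sum(beta * (K %*% beta)) - sum(y * beta) +
         epsilon * sum(abs(beta)))
}

# hand-built AFT fit with the published Phase-I coefficients
published_aft_fit <- function() {
  structure(list(beta0 = 5.07026, beta1 = -0.03348,
                 extra_betas = numeric(0), sigma = 0.57, loglik = NA_real_,
                 n_used = 0L, n_censored_used = 0L,
                 error_dist = "standard_normal", converged = TRUE,
                 fit = NULL),
            class = "aft_fit")
}
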