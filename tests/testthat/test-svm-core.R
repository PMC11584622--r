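test_that("the symmetric two-point problem is solved in closed form", {
  cls <- solve_max_margin(c(-1, 1), c(-1, 1))
  expect_equal(as.numeric(cls$omega), 1, tolerance = 1e-8)
  expect_equal(cls$b, 0, tolerance = 1e-8)
  expect_equal(margin_of(cls), 2, tolerance = 1e-8)
  expect_equal(sort(cls$support_indices), 1:2)
})

test_that("dual solution matches the brute-force primal oracle", {
  set.seed(2024)
  for (rep in 1:25) {
    inst <- random_separable_instance()
    cls <- solve_max_margin(inst$x, inst$y)
    oracle <- max_margin_oracle(inst$x, inst$y)
    expect_equal(0.5 * sum(cls$omega^2), oracle$objective,
                 tolerance = 1e-6)
    expect_equal(cls$omega, oracle$omega, tolerance = 1e-5)
    expect_equal(cls$b, oracle$b, tolerance = 1e-5)
  }
})

test_that("dual feasibility and KKT conditions hold on solved instances", {
  set.seed(99)
  for (rep in 1:10) {
    inst <- random_separable_instance()
    cls <- solve_max_margin(inst$x, inst$y)
    expect_true(all(cls$alphas >= 0))
    expect_lt(abs(sum(cls$alphas * inst$y)), 1e-8)
    marg <- inst$y * (as.numeric(inst$x %*% cls$omega) + cls$b)
    # canonical form and complementary slackness
    expect_equal(min(marg), 1, tolerance = 1e-6)
    expect_lt(max(abs(cls$alphas * (marg - 1))), 1e-6)
    expect_true(all(abs(marg[cls$support_indices] - 1) < 1e-6))
  }
})

test_that("margin identities and homogeneity hold", {
  set.seed(5)
  inst <- random_separable_instance(d = 2, l = 8)
  cls <- solve_max_margin(inst$x, inst$y)
  # sum of nearest point-to-plane distances per class equals 2 / ||omega||
  d_all <- abs(as.numeric(inst$x %*% cls$omega) + cls$b) /
    sqrt(sum(cls$omega^2))
  expect_equal(min(d_all[inst$y < 0]) + min(d_all[inst$y > 0]),
               margin_of(cls), tolerance = 1e-6)
  # scaling x by c scales omega by 1/c and the margin by c
  c0 <- 2.5
  cls2 <- solve_max_margin(inst$x * c0, inst$y)
  expect_equal(cls2$omega, cls$omega / c0, tolerance = 1e-5)
  expect_equal(margin_of(cls2), c0 * margin_of(cls), tolerance = 1e-5)
  # a classifier built from a (3,4) normal would have margin 2/5
  expect_equal(2 / sqrt(sum(c(3, 4)^2)), 0.4)
})

test_that("well-separated toy classifiers respect the 1/A distance bound", {
  # data of norm at most A admit no hyperplane closer than 1/A to a point
  sets <- list(
    list(x = matrix(c(-2, -1.5, 1.5, 2), 4, 1), y = c(-1, -1, 1, 1)),
    list(x = cbind(c(-2, -2, 2, 2), c(-1, 1, -1, 1)),
         y = c(-1, -1, 1, 1)))
  for (s in sets) {
    cls <- solve_max_margin(s$x, s$y)
    A <- max(sqrt(rowSums(as.matrix(s$x)^2)))
    dmin <- min(abs(as.numeric(s$x %*% cls$omega) + cls$b)) /
      sqrt(sum(cls$omega^2))
    expect_gte(dmin, 1 / A - 1e-9)
  }
})

test_that("non-separable data raises an explicit infeasibility error", {
  x <- matrix(c(-1, 0, 1, 0.1), 4, 1)
  y <- c(-1, 1, 1, -1)
  expect_error(solve_max_margin(x, y), "separable")
})

test_that("SVR reproduces realizable functions inside the tube", {
  x <- seq(1, 10)
  fit <- fit_svr(x, 2 * x, kernel = "linear", C = 1e4, epsilon = 0.01)
  res <- 2 * x - predict(fit, x)
  expect_true(all(abs(res) <= 0.01 + 1e-6))
  expect_equal(predict(fit, 10), 20, tolerance = 0.01 + 1e-6)
  # dual feasibility
  expect_true(all(abs(fit$beta) <= 1e4 + 1e-8))
  expect_lt(abs(sum(fit$beta)), 1e-6)
})

test_that("constant response yields the intercept-only predictor", {
  fit <- fit_svr(c(1, 2, 3), c(4, 4, 4), kernel = "linear", C = 1,
                 epsilon = 0.1)
  expect_equal(predict(fit, c(1, 2, 3)), rep(4, 3), tolerance = 0.1)
  expect_equal(max(predict(fit, 1:3)) - min(predict(fit, 1:3)), 0,
               tolerance = 1e-9)
})

test_that("SVR dual matches a generic box-constrained QP oracle", {
  set.seed(314)
  for (kernel in c("linear", "rbf")) {
    for (rep in 1:5) {
      l <- sample(5:10, 1)
      x <- rnorm(l)
      y <- 1.5 * x + rnorm(l, sd = 0.4)
      gamma <- 0.7
      fit <- fit_svr(x, y, kernel = kernel, C = 2, epsilon = 0.1,
                     gamma = gamma, tol = 1e-9)
      oracle <- svr_dual_oracle(x, y, kernel = kernel, C = 2,
                                epsilon = 0.1, gamma = gamma)
      expect_lt(svr_dual_objective(fit, y), oracle$objective + 1e-6)
      expect_equal(svr_dual_objective(fit, y), oracle$objective,
                   tolerance = 1e-5)
    }
  }
})

test_that("prediction equals the direct kernel expansion", {
  set.seed(8)
  x <- rnorm(20)
  y <- sin(x) + rnorm(20, sd = 0.1)
  fit <- fit_svr(x, y, kernel = "rbf", C = 3, epsilon = 0.05, gamma = 0.9)
  newx <- rnorm(7)
  direct <- vapply(newx, function(x0)
    sum(fit$beta * exp(-fit$gamma * (as.numeric(fit$x) - x0)^2)) + fit$b,
    numeric(1))
  expect_equal(predict(fit, newx), direct, tolerance = 1e-8)
  # and the underlying SMO solver evaluates the same function
  expect_equal(predict(fit, newx),
               as.numeric(predict(fit$model, matrix(newx))),
               tolerance = 1e-8)
})

test_that("SR-SVM standardizes with Phase-I constants", {
  # a constant-zero predictor turns log times into raw residuals directly
  fit0 <- fit_svr(c(1, 2, 3), c(0, 0, 0), kernel = "linear", C = 1,
                  epsilon = 1e-6)
  b <- predict(fit0, 1)[1]
  co <- data.frame(parsonnet = c(1L, 2L, 3L),
                   time_days = exp(c(1, 2, 3) + b),
                   censored = FALSE, group = NA_character_)
  rs <- sr_svm(co, fit0)
  expect_equal(rs$values, c(-1, 0, 1), tolerance = 1e-9)
  expect_equal(rs$raw_mean, 2, tolerance = 1e-9)
  expect_equal(rs$raw_sd, 1, tolerance = 1e-9)
  # Phase II uses the stored Phase-I constants, not its own moments
  co2 <- co
  co2$time_days <- exp(c(5, 6, 7) + b)
  rs2 <- sr_svm(co2, fit0, phase1 = rs)
  expect_equal(rs2$values, c(3, 4, 5), tolerance = 1e-9)
  # zero residual spread cannot be standardized
  co3 <- co
  co3$time_days <- exp(rep(2, 3) + b)
  expect_error(sr_svm(co3, fit0), "epsilon")
})

test_that("Phase-I SR-SVM pool has mean 0 and SD 1 by construction", {
  fx <- phase1_fixture()
  expect_equal(mean(fx$pool_svm$values), 0, tolerance = 1e-10)
  expect_equal(sd(fx$pool_svm$values), 1, tolerance = 1e-10)
})
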