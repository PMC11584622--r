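test_that("degenerate pools and huge shifts signal immediately", {
  cfg <- chart_config(lam = 0.1, L = 2.5)
  set.seed(1)
  sim <- simulate_run_length(-10, cfg, reps = 50)
  expect_true(all(sim$run_length == 1L))
  expect_true(all(sim$signaled))
  fx_pool <- rnorm(100)
  sim2 <- simulate_run_length(fx_pool, cfg, delta = 1000, reps = 50)
  expect_true(all(sim2$run_length == 1L))
  expect_error(simulate_run_length(numeric(0), cfg), "empty")
  expect_error(simulate_run_length(fx_pool, cfg, delta = -1), "nonnegative")
})

test_that("point-mass pools give a deterministic profile", {
  cfg <- chart_config(lam = 0.1, L = 2.5)
  pr <- estimate_rl_profile(-10, cfg, reps = 200, seed = 4)
  expect_equal(pr$sdrl, 0)
  expect_true(all(pr$percentiles == pr$arl))
  expect_equal(pr$arl, 1)
})

test_that("identical seeds reproduce summaries exactly", {
  set.seed(31); pool <- rnorm(500)
  cfg <- chart_config(lam = 0.2, L = 2.2)
  a <- estimate_rl_profile(pool, cfg, reps = 2000, seed = 99)
  b <- estimate_rl_profile(pool, cfg, reps = 2000, seed = 99)
  expect_identical(a$arl, b$arl)
  expect_identical(a$percentiles, b$percentiles)
})

test_that("lam = 1 run lengths are geometric with the Shewhart rate", {
  L <- 2.2; delta <- 0.5
  p <- pnorm(delta - L)
  cfg <- chart_config(lam = 1, L = L, xi = Inf, z0 = 0,
                      limit_mode = "asymptotic")
  reps <- 20000
  pr <- estimate_rl_profile(NULL, cfg, delta = delta, reps = reps,
                            stream = "normal", seed = 10)
  expect_lt(abs(pr$arl - 1 / p), 3 * pr$se)
  # geometric median, interpolation-aware tolerance
  med <- ceiling(log(0.5) / log(1 - p))
  expect_lt(abs(pr$percentiles[["P50"]] - med),
            max(3 * 1.2533 * pr$sdrl / sqrt(reps), 2))
  expect_lt(abs(pr$sdrl - sqrt(1 - p) / p), 6 * pr$se)
})

test_that("percentiles interpolate between order statistics", {
  # force a tiny run-length sample through a crafted two-value pool
  cfg <- chart_config(lam = 1, L = 1, xi = Inf, z0 = 0,
                      limit_mode = "asymptotic")
  set.seed(7)
  sim <- simulate_run_length(c(-5, 0.5), cfg, reps = 7)
  pr <- estimate_rl_profile(c(-5, 0.5), cfg, reps = 7, seed = 7)
  expect_equal(unname(pr$percentiles),
               unname(quantile(as.numeric(sim$run_length),
                               c(.05, .1, .25, .5, .75, .9, .95),
                               type = 7)))
})

test_that("estimated in-control ARL is monotone in L under CRN", {
  fx <- phase1_fixture()
  pool <- fx$pool_svm$values
  arls <- vapply(c(2.0, 2.4, 2.8), function(L) {
    set.seed(555)
    mean(simulate_run_length(pool,
                             chart_config(lam = 0.1, L = L),
                             reps = 2000)$run_length)
  }, numeric(1))
  expect_true(all(diff(arls) > 0))
})

test_that("calibration hits the closed-form Shewhart coefficient", {
  cal <- calibrate_L(NULL, lam = 1, target_arl0 = 370, reps = 20000,
                     stream = "normal", seed = 12, xi = Inf,
                     limit_mode = "asymptotic")
  expect_true(cal$converged)
  expect_lt(abs(cal$L - (-qnorm(1 / 370))), 0.03)
  expect_lt(abs(cal$arl0_hat - 370), max(1, 0.005 * 370) + 1e-9)
})

test_that("calibration reports an unreachable bracket", {
  expect_error(
    calibrate_L(NULL, lam = 1, target_arl0 = 1e7, reps = 500,
                stream = "normal", seed = 1, xi = Inf,
                L_range = c(0.2, 1)),
    "bracket")
})

test_that("shift tables have the reporting layout and respond to shifts", {
  fx <- phase1_fixture()
  cfg <- chart_config(lam = 0.1, L = 2.2)
  tab <- shift_table(fx$pool_svm, cfg, deltas = c(0, 0.1, 0.5, 2),
                     reps = 2000, seed = 77)
  expect_equal(names(tab),
               c("shift", "ARL", "SDRL", "P05", "P10", "P25", "P50",
                 "P75", "P90", "P95"))
  expect_equal(nrow(tab), 4L)
  sums <- attr(tab, "summaries")
  se <- vapply(sums, `[[`, numeric(1), "se")
  expect_true(all(diff(tab$ARL) <=
                    3 * sqrt(se[-1]^2 + se[-length(se)]^2)))
  # percentiles non-decreasing within each row
  pct <- as.matrix(tab[, 4:10])
  expect_true(all(apply(pct, 1, function(r) all(diff(r) >= 0))))
  expect_error(shift_table(fx$pool_svm, cfg, deltas = c(0.5, 0.1)),
               "ascending")
})

test_that("the full engine matches the Shewhart oracle across shifts", {
  L <- -qnorm(1 / 370)
  cfg <- chart_config(lam = 1, L = L, xi = Inf, z0 = 0,
                      limit_mode = "asymptotic")
  tab <- shift_table(NULL, cfg, deltas = c(0, 0.5, 1, 2), reps = 10000,
                     stream = "normal", seed = 200)
  se <- vapply(attr(tab, "summaries"), `[[`, numeric(1), "se")
  oracle <- 1 / pnorm(tab$shift - L)
  expect_true(all(abs(tab$ARL - oracle) < 3 * se))
})

test_that("smaller lambda detects small shifts faster", {
  fx <- phase1_fixture()
  pool <- fx$pool_svm
  arl_d <- function(lam) {
    cal <- calibrate_L(pool, lam = lam, target_arl0 = 370, reps = 4000,
                       seed = 5, tol = 8)
    pr <- estimate_rl_profile(pool, cal$cfg, delta = 0.05, reps = 4000,
                              seed = 6)
    c(pr$arl, pr$se)
  }
  a10 <- arl_d(0.10)
  a25 <- arl_d(0.25)
  expect_lt(a10[1] + 3 * sqrt(a10[2]^2 + a25[2]^2), a25[1])
})
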