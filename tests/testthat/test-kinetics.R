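test_that("steady state is the synthesis/degradation ratio", {
  expect_equal(steady_state_level(beta = 5, alpha = 2.0), 2.5)
  expect_equal(steady_state_level(beta = 5, alpha = 0.2), 25.0)
  expect_equal(steady_state_level(beta = 0, alpha = 1.0), 0.0)
  # the least stable transcript settles at the lowest level
  expect_equal(order(steady_state_level(5, c(2, 1, 0.5, 0.2))), 1:4)
  expect_error(steady_state_level(5, 0), "alpha")
  expect_error(steady_state_level(5, -1), "alpha")
})

test_that("half-life conversions are exact inverses", {
  expect_equal(half_life_from_rate(log(2)), 1.0)
  expect_equal(half_life_from_rate(0.2), log(2) / 0.2, tolerance = 1e-12)
  # published mouse atlas median, 274 minutes
  expect_equal(rate_from_half_life(274 / 60), 0.151784, tolerance = 1e-4)
  a <- c(0.05, 0.2, 1, 2, 7.3)
  expect_equal(rate_from_half_life(half_life_from_rate(a)), a, tolerance = 1e-12)
  expect_error(half_life_from_rate(0))
  expect_error(rate_from_half_life(-2))
})

test_that("transition level follows the closed-form solution", {
  # t = 0 returns x0 regardless of rates
  expect_equal(transition_level(0, beta = 7, alpha = 1.3, x0 = 4.2), 4.2)
  # half the transition is completed at one half-life
  for (a in c(2, 1, 0.5, 0.2)) {
    expect_equal(
      transition_level(log(2) / a, beta = 5, alpha = a, x0 = 0),
      steady_state_level(5, a) / 2,
      tolerance = 1e-12
    )
  }
  expect_equal(transition_level(5, beta = 5, alpha = 1, x0 = 0),
               5 * (1 - exp(-5)), tolerance = 1e-12)
  expect_error(transition_level(-1, 5, 1), "t")
})

test_that("closed form matches a Runge-Kutta integration of the ODE", {
  set.seed(42)
  for (i in 1:100) {
    beta <- runif(1, 0, 10)
    alpha <- runif(1, 0.05, 3)
    x0 <- runif(1, 0, 12)
    t <- runif(1, 0, 5)
    expect_lt(
      abs(transition_level(t, beta, alpha, x0) - rk4_transition(t, beta, alpha, x0)),
      1e-6 * max(beta / alpha, 1e-12) + 1e-9
    )
  }
})

test_that("time to k-fold induction obeys the -log2(1-f) law", {
  # f = 1/2 makes T_k equal one half-life
  expect_equal(time_to_fold_induction(k = 2, L = 3, t_half = 1), 1.0)
  expect_equal(time_to_fold_induction(k = 2, L = 5, t_half = 2),
               2 * (-log2(0.75)), tolerance = 1e-12)
  # vanishing induction requires no time; the asymptote is infinite
  expect_equal(time_to_fold_induction(k = 1 + 1e-12, L = 3, t_half = 1), 0,
               tolerance = 1e-9)
  expect_identical(time_to_fold_induction(k = 3, L = 3, t_half = 1), Inf)
  expect_error(time_to_fold_induction(k = 4, L = 3, t_half = 1), "unattainable")
  # linear in half-life at fixed (k, L)
  th <- c(0.3, 1, 2.5)
  expect_equal(
    time_to_fold_induction(2, 6, th) / th,
    rep(time_to_fold_induction(2, 6, 1), 3),
    tolerance = 1e-12
  )
})

test_that("T_k agrees with first-passage root finding on the transition", {
  set.seed(7)
  for (i in 1:20) {
    L <- runif(1, 2.2, 30)
    k <- runif(1, 1.1, L * 0.95)
    alpha <- runif(1, 0.1, 3)
    beta <- runif(1, 0.5, 10)
    x_old <- beta / alpha
    tk <- time_to_fold_induction(k, L, log(2) / alpha)
    root <- uniroot(
      function(t) transition_level(t, L * beta, alpha, x0 = x_old) - k * x_old,
      lower = 0, upper = tk * 10 + 1, tol = 1e-12
    )$root
    expect_equal(tk, root, tolerance = 1e-6)
  }
})

test_that("pulse simulation is piecewise exact and decays at ln2/alpha", {
  gr <- seq(0, 10, by = 0.001)
  tr <- simulate_pulse(alpha = 0.2, beta_on = 5, beta_off = 0, x0 = 0,
                       t_on = 0, t_off = 5, grid = gr)
  expect_equal(tr$level[tr$time_h == 5], 25 * (1 - exp(-1)), tolerance = 1e-9)
  expect_equal(tr$level[tr$time_h == 5], rk4_transition(5, 5, 0.2, 0),
               tolerance = 1e-6)
  # after shutoff the level halves every ln2/alpha hours
  lev5 <- tr$level[tr$time_h == 5]
  t_half <- log(2) / 0.2
  expect_equal(tr$level[which.min(abs(tr$time_h - (5 + t_half)))],
               lev5 / 2, tolerance = 1e-3)

  # already at steady state with a constant rate: flat trajectory
  tr2 <- simulate_pulse(alpha = 1, beta_on = 4, beta_off = 4, x0 = 4,
                        t_on = 0, t_off = 5, grid = seq(0, 8, 0.5))
  expect_equal(tr2$level, rep(4, nrow(tr2)), tolerance = 1e-12)

  # fraction of transition completed ranks by alpha at early times
  fracs <- vapply(c(2, 1, 0.5, 0.2), function(a) {
    tr <- simulate_pulse(a, 5, grid = c(0, 0.25))
    tr$level[2] / steady_state_level(5, a)
  }, numeric(1))
  expect_equal(order(fracs, decreasing = TRUE), 1:4)

  expect_error(simulate_pulse(1, 5, grid = numeric(0)), "grid")
  expect_error(simulate_pulse(1, 5, t_on = 2, t_off = 1, grid = 0:5), "t_on")
})

test_that("beta calibration hits the target level exactly", {
  b <- calibrate_beta_for_level(target_level = 5, alpha = 1, t_end = 5, x0 = 0)
  expect_equal(b, 5 / (1 - exp(-5)), tolerance = 1e-12)
  expect_equal(transition_level(5, b, 1, 0), 5, tolerance = 1e-9)
  # in the long-time limit the calibrated rate recovers beta = alpha * target
  expect_equal(calibrate_beta_for_level(25, 0.2, 1e6, 0), 5, tolerance = 1e-6)
  expect_equal(calibrate_beta_for_level(0, 1, 5, 0), 0)
  # even beta = 0 leaves the level above the target at t_end: unreachable
  expect_error(calibrate_beta_for_level(1, 1, 0.01, x0 = 100), "unreachable")
})

test_that("shutoff bound is exact for pure decay and monotone", {
  expect_equal(shutoff_max_half_life(2, 1), 1.0)
  expect_equal(shutoff_max_half_life(4, 2), 1.0)
  expect_equal(shutoff_max_half_life(2, 2), 2.0)
  # increasing in t, decreasing in fold_down
  t <- c(0.5, 1, 2, 4)
  expect_true(all(diff(shutoff_max_half_life(2, t)) > 0))
  fd <- c(1.5, 2, 4, 8)
  expect_true(all(diff(shutoff_max_half_life(fd, 2)) < 0))
  expect_error(shutoff_max_half_life(1, 1), "fold_down")
})
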