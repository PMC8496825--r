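test_that("rate transfer is thresholded, bounded and monotone", {
  expect_equal(rate_transfer(0.3, alpha = 0.3, beta = 2), 0) # tanh(0) at threshold
  expect_equal(rate_transfer(c(-1, 0.1), alpha = 0.3, beta = 2), c(0, 0))
  expect_gt(rate_transfer(1e3, alpha = 0, beta = 1), 1 - 1e-12)
  a <- seq(-2, 5, by = 0.01)
  f <- rate_transfer(a, alpha = 0.5, beta = 3)
  expect_true(all(f >= 0 & f < 1))
  expect_true(all(diff(f) >= 0))
  expect_error(rate_transfer(1, beta = -1), "beta")
})

test_that("euler step matches the exponential-decay closed form", {
  tau <- 0.05
  # full decay in a single step when dt = tau
  expect_equal(euler_step(1, list(), tau = tau, dt = tau), 0)
  # against the analytic solution a0 exp(-t/tau); explicit Euler is first
  # order, so the error at dt = tau/100 is O(dt) and halves with dt
  decay_err <- function(dt) {
    a <- 1
    n <- round(tau / dt) * 10 # integrate to t = 10 tau
    for (k in seq_len(n)) a <- euler_step(a, list(), tau, dt)
    abs(a - exp(-n * dt / tau))
  }
  e1 <- decay_err(tau / 100)
  e2 <- decay_err(tau / 200)
  expect_lt(e1, 2e-3)
  expect_lt(e2, 0.6 * e1)
  # fixed point under constant drive
  a <- 0
  for (k in 1:5000) {
    a <- euler_step(a, list(list(gain = 2, W = NULL, f = 0.4)), tau, tau / 10)
  }
  expect_equal(a, 0.8, tolerance = 1e-6)
})

test_that("euler step validates dimensions and step size", {
  expect_error(euler_step(1:3, list(), tau = 0.1, dt = 0), "dt")
  expect_error(euler_step(1:3, list(), tau = 0.1, dt = 0.2), "tau")
  expect_error(
    euler_step(1:3, list(list(gain = 1, W = diag(2), f = 1:3)), 0.1, 0.01),
    "columns"
  )
  expect_error(
    euler_step(1:3, list(list(gain = 1, W = NULL, f = 1:2)), 0.1, 0.01),
    "one-to-one"
  )
})

test_that("inhibition matrices are symmetric, non-negative, row-stochastic", {
  expect_equal(global_inhibition_matrix(1), matrix(1, 1, 1))
  expect_equal(global_inhibition_matrix(2), matrix(0.5, 2, 2))
  expect_equal(lateral_inhibition_matrix(2), matrix(c(0, 1, 1, 0), 2))
  m3 <- lateral_inhibition_matrix(3)
  expect_equal(diag(m3), rep(0, 3))
  expect_true(all(m3[row(m3) != col(m3)] == 0.5))
  for (n in c(2, 5, 17, 120)) {
    g <- global_inhibition_matrix(n)
    l <- lateral_inhibition_matrix(n)
    expect_equal(rowSums(g), rep(1, n))
    expect_equal(rowSums(l), rep(1, n))
    expect_equal(g, t(g))
    expect_equal(l, t(l))
    expect_true(all(g >= 0) && all(l >= 0))
    expect_equal(diag(l), rep(0, n))
  }
  expect_error(global_inhibition_matrix(0), ">= 1")
  expect_error(lateral_inhibition_matrix(1), ">= 2")
})
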