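test_that("attractor kernels have the even/odd structure", {
  w <- build_attractor_weights(36)
  expect_equal(w$sym, t(w$sym), tolerance = 1e-12)
  # odd kernel: the velocity matrix is exactly antisymmetric
  expect_equal(w$asym, -t(w$asym), tolerance = 1e-12)
  # circulant: every row is a rotation of the first
  expect_equal(w$sym[5, ], hdring:::circ_shift(w$sym[1, ], 4), tolerance = 1e-12)
})

test_that("a seeded bump persists for 60 s without input", {
  pars <- hd_params()$attractor
  pars$vel_gain <- 0 # no velocity pathway engaged at omega = 0
  st <- attractor_init(72, 45, pars)
  for (k in seq_len(round(20 / 0.0025))) st <- attractor_step(st, 0, NULL, 0.0025)
  d0 <- population_vector(st$f, st$theta)
  for (k in seq_len(round(60 / 0.0025))) st <- attractor_step(st, 0, NULL, 0.0025)
  expect_gt(max(st$f), 0.5)
  d1 <- population_vector(st$f, st$theta)
  expect_lt(abs(hdring:::circ_diff(d1, d0)), 1)
})

test_that("the bump recovers its shape after random perturbations", {
  pars <- hd_params()$attractor
  pars$vel_gain <- 0
  st <- attractor_init(72, 0, pars)
  for (k in 1:2000) st <- attractor_step(st, 0, NULL, 0.0025)
  template <- st$f
  set.seed(8)
  st$a <- st$a + rnorm(72, 0, 0.1)
  for (k in seq_len(round(10 / 0.0025))) st <- attractor_step(st, 0, NULL, 0.0025)
  shift <- which.max(st$f) - which.max(template)
  aligned <- hdring:::circ_shift(st$f, -shift)
  expect_gt(cor(aligned, template), 0.98)
})

test_that("velocity calibration reaches 1 percent over the commanded grid", {
  gain <- calibrate_velocity_gain(hd_params()$attractor, n = 120,
                                  omega_grid = c(-120, -60, -30, 30, 60, 120))
  expect_lt(attr(gain, "max_rel_error"), 0.01)
})

test_that("a path-integration gain above 1 drifts linearly under rotation", {
  pars <- hd_params()$attractor
  pars$vel_gain <- calibrate_velocity_gain(hd_params()$attractor, n = 72)
  pars$pi_gain <- 1.05
  st <- attractor_init(72, 0, pars)
  for (k in 1:400) st <- attractor_step(st, 0, NULL, 0.0025)
  drift <- c()
  ang <- 0
  last <- population_vector(st$f, st$theta)
  for (k in seq_len(round(40 / 0.0025))) {
    st <- attractor_step(st, 60, NULL, 0.0025)
    if (k %% 4000 == 0) {
      cur <- population_vector(st$f, st$theta)
      drift <- c(drift, cur)
    }
  }
  # decoded position leads true by 5% of the rotation: 3 deg/s
  true_pos <- wrap_angle(60 * seq(10, 40, by = 10) * 0.0025 * 4000 / 10)
  err <- hdring:::circ_diff(drift, wrap_angle(60 * seq(10, 40, by = 10)))
  expect_true(all(diff(err) > 0)) # grows monotonically
  expect_equal(err[4], 0.05 * 60 * 40, tolerance = 0.2 * 120)
})

test_that("corrective feedback moves the bump toward the feedback direction", {
  pars <- hd_params()$attractor
  pars$vel_gain <- 0
  pars$g_fb_inh <- 1 # moderate global suppression for this isolated probe
  st <- attractor_init(72, 0, pars)
  for (k in 1:2000) st <- attractor_step(st, 0, NULL, 0.0025)
  theta <- st$theta
  fb <- unimodal_profile(theta, 20, 8) # feedback bump offset +20 deg
  d0 <- population_vector(st$f, theta)
  for (k in 1:2000) st <- attractor_step(st, 0, fb, 0.0025)
  d1 <- population_vector(st$f, theta)
  expect_gt(hdring:::circ_diff(d1, d0), 5) # moved toward +20
  expect_lt(abs(hdring:::circ_diff(d1, 20)), 15)
})

test_that("Hebbian updates cap row norms without touching silent rows", {
  W <- matrix(0.1, 3, 4)
  expect_equal(hebbian_update(W, c(1, 1, 1), rep(1, 4), 0), W)
  W2 <- hebbian_update(W, c(1, 0, 2), c(1, 0, 0, 0), eta = 0.5)
  expect_equal(W2[1, 1], 0.6)
  expect_equal(W2[2, ], W[2, ])
  expect_equal(W2[3, 1], 1.1)
  expect_error(hebbian_update(W, 1:3, 1:4, -1), "eta")
  big <- matrix(2, 2, 4)
  capped <- normalize_rows(big, w_max = 1)
  expect_equal(sqrt(rowSums(capped^2)), c(1, 1))
  small <- matrix(0.1, 2, 4)
  expect_equal(normalize_rows(small, 1), small) # below cap unchanged
  floored <- normalize_rows(small, 1, mode = "floor")
  expect_equal(sqrt(rowSums(floored^2)), c(1, 1)) # printed max semantics
  # repeated pairing of one post/pre pair dominates the row under the cap
  W3 <- matrix(0.05, 1, 6)
  for (k in 1:500) {
    W3 <- hebbian_update(W3, 1, c(1, rep(0, 5)), 0.05)
    W3 <- normalize_rows(W3, 1)
  }
  expect_gt(W3[1, 1], 0.99)
})

test_that("gRSC relays a unimodal copy of the attractor bump", {
  net <- hd_network(mini_ring, mini_alb, seed = 1)
  p <- net$params
  for (k in 1:2000) {
    net$hd <- attractor_step(net$hd, 0, NULL, p$dt)
    net$rsc <- grsc_step(net$rsc, net$hd$f, p, p$dt)
  }
  expect_equal(unimodality_score(net$rsc$grsc$f, 0.5)$n_lobes, 1L)
  expect_lt(abs(hdring:::circ_diff(population_vector(net$rsc$grsc$f, net$theta),
                                   population_vector(net$hd$f, net$theta))), 5)
  # with zero attractor and aLB input the dRSC decays to silence
  net$rsc$grsc$f <- numeric(mini_ring)
  for (k in 1:2000) {
    net$rsc <- drsc_step(net$rsc, numeric(mini_alb), p, p$dt)
  }
  expect_equal(max(net$rsc$drsc$f), 0)
})
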