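test_that("mOSA keeps weights non-negative under random updates", {
  set.seed(42)
  n_alb <- 20; n_vis <- 15
  W <- lapply(1:2, function(j) matrix(runif(n_alb * n_vis, 0, 0.5), n_alb))
  for (k in 1:1000) {
    f <- pmax(0, runif(n_alb, -0.5, 1))
    vis <- matrix(runif(n_vis * 2), n_vis, 2)
    W <- mosa_update(W, f, vis, eta = 0.05)
    if (k %% 100 == 0) expect_true(all(unlist(W) >= 0))
  }
  expect_true(all(unlist(W) >= 0))
})

test_that("mOSA updates vanish without activity and cancel at expectation", {
  W <- list(matrix(0.3, 4, 6))
  vis <- matrix(runif(6), 6, 1)
  expect_identical(mosa_update(W, rep(0, 4), vis, eta = 0.1), W)
  # single active cell whose expected input equals the real input
  f <- c(1, 0, 0, 0)
  W2 <- list(rbind(as.numeric(vis), matrix(0.2, 3, 6)))
  out <- mosa_update(W2, f, vis, eta = 0.1)
  expect_equal(out[[1]][1, ], as.numeric(vis), tolerance = 1e-12)
})

test_that("active cells are depressed away from silent visual channels", {
  W <- list(matrix(0.4, 3, 5))
  vis <- matrix(0, 5, 1) # silent channel
  out <- mosa_update(W, c(1, 0.5, 0), vis, eta = 0.1)
  expect_true(all(out[[1]][1, ] < 0.4))
  expect_true(all(out[[1]][2, ] < 0.4))
  expect_equal(out[[1]][3, ], rep(0.4, 5)) # inactive row untouched
})

test_that("alternative rules follow their published forms", {
  set.seed(1)
  W <- list(matrix(runif(12, 0.1, 0.3), 3, 4))
  vis <- matrix(runif(4), 4, 1)
  expect_error(alt_rule_update("nope", W, rep(0, 3), vis, 0.1), "registered")
  # hebb: inactive -> unchanged; active -> grows toward input
  expect_equal(alt_rule_update("hebb", W, rep(0, 3), vis, 0.1)[[1]], W[[1]])
  Wh <- alt_rule_update("hebb", W, c(1, 0, 0), vis, 0.1)
  expect_true(all(Wh[[1]][1, ] > W[[1]][1, ]))
  # original subspace rule permits negative entries
  Wbig <- list(matrix(2, 3, 4))
  Wo <- alt_rule_update("osa_original", Wbig, c(1, 1, 1), matrix(0, 4, 1),
                        eta = 0.5) # large feedback step overshoots zero
  expect_true(any(Wo[[1]] < 0))
  # covariance and BCM keep running state and stay bounded
  Wc <- W
  for (k in 1:50) Wc <- alt_rule_update("hebb_covariance", Wc, runif(3), vis, 0.05)
  expect_false(is.null(attr(Wc, "rule_state")))
  expect_true(all(unlist(Wc) >= 0 & unlist(Wc) <= 1))
  Wb <- W
  for (k in 1:50) Wb <- alt_rule_update("intrator_bcm", Wb, runif(3), vis, 0.05)
  expect_true(all(unlist(Wb) >= 0 & unlist(Wb) <= 1))
})

test_that("recruitment report thresholds peak rates", {
  log <- rbind(c(0, 0.6, 0.2), c(0, 0.4, 0.49))
  expect_identical(recruit_report(log, 0.5), 2L)
  expect_identical(recruit_report(matrix(0, 5, 3), 0), integer(0))
  expect_identical(recruit_report(log, 0), c(2L, 3L)) # any activity
})

test_that("the feedback prefactor can be compensated exactly", {
  # zeta > 1 with eta scaled down, feed-forward gain scaled up and the
  # initialization interval scaled down reproduces the zeta = 1 run
  proto <- hd_protocol(list(list(
    scenery = scenery_conflict(mini_ring), duration = 60,
    tests = list(test_spec(label = "t"))
  )), seed = 3, test_revs = 1, name = "z")
  r1 <- run_protocol(proto, n_dirs = mini_ring, n_alb = mini_alb)
  d <- hd_params()$alb
  p2 <- hd_params(alb = list(zeta = 2, eta = d$eta / 2, g_vis = d$g_vis * 2,
                             w_lo = d$w_lo / 2, w_hi = d$w_hi / 2))
  r2 <- run_protocol(proto, network = hd_network(mini_ring, mini_alb,
                                                 params = p2, seed = 3))
  expect_gt(iou(r1$tests$t$recruited, r2$tests$t$recruited), 0.99)
  expect_gt(cor(as.numeric(r1$tests$t$reps$alb$tuning),
                as.numeric(r2$tests$t$reps$alb$tuning)), 0.99)
})
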