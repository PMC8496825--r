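test_that("population vector decodes rates as a circular mean", {
  dirs <- c(0, 90, 180, -90)
  expect_equal(population_vector(c(0, 1, 0, 0), dirs), 90)
  expect_equal(population_vector(c(1, 1, 0, 0), dirs), 45)
  expect_error(population_vector(c(1, 0, 1, 0), dirs), "undefined")
  expect_error(population_vector(rep(0, 4), dirs), "undefined")
  # equivariance: circularly shifting the rates shifts the decode
  theta <- theta_grid(72)
  f <- unimodal_profile(theta, 40, 6)
  d0 <- population_vector(f, theta)
  for (k in c(1, 7, 30)) {
    dk <- population_vector(hdring:::circ_shift(f, k), theta)
    expect_equal(hdring:::circ_diff(dk, d0), wrap_angle(k * 5), tolerance = 1e-6)
  }
})

test_that("IoU satisfies the similarity axioms", {
  expect_equal(iou(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(iou(1:2, 3:4), 0)
  expect_equal(iou(c(1, 2), c(2, 3)), 1 / 3)
  expect_equal(iou(integer(0), integer(0)), 0) # both-empty convention
  set.seed(9)
  for (k in 1:30) {
    a <- sample(20, sample(0:10, 1))
    b <- sample(20, sample(0:10, 1))
    expect_equal(iou(a, b), iou(b, a))
    expect_gte(iou(a, b), 0)
    expect_lte(iou(a, b), 1)
    if (length(a) && iou(a, b) == 1) expect_setequal(a, b)
  }
})

test_that("heading errors use circular statistics", {
  expect_equal(heading_error(c(10, 20, 30), c(10, 20, 30)),
               c(mean = 0, sem = 0))
  expect_equal(heading_error(c(20, 30), c(10, 20)), c(mean = 10, sem = 0))
  # antipodal pair: circular mean is +-180, never 0
  he <- heading_error(c(170, -170), c(0, 0))
  expect_equal(abs(he[["mean"]]), 180, tolerance = 1e-9)
  # oracle: compare with direct resultant-vector computation
  set.seed(4)
  err <- runif(200, -30, 30)
  he2 <- heading_error(err, rep(0, 200))
  oracle <- atan2(mean(sin(err * pi / 180)), mean(cos(err * pi / 180))) * 180 / pi
  expect_equal(he2[["mean"]], oracle, tolerance = 1e-9)
  # a uniformly rotated decode against itself has zero error
  tr <- test_rotation(0, 60, 12, 0.01)
  expect_equal(heading_error(tr$hd, tr$hd), c(mean = 0, sem = 0))
})

test_that("unimodality scoring counts circular lobes", {
  theta <- theta_grid(120)
  one <- unimodal_profile(theta, 20, 10)
  expect_equal(unimodality_score(one, 0.5),
               list(n_lobes = 1L, is_unimodal = TRUE))
  two <- unimodal_profile(theta, 0, 15) + unimodal_profile(theta, 180, 15)
  expect_equal(unimodality_score(two, 0.5)$n_lobes, 2L)
  expect_equal(unimodality_score(rep(0.1, 120), 0.5)$n_lobes, 0L)
  expect_equal(unimodality_score(rep(0.9, 120), 0.5)$n_lobes, 1L)
  # a lobe crossing the -180/180 seam counts once
  seam <- unimodal_profile(theta, -179, 10)
  expect_equal(unimodality_score(seam, 0.5)$n_lobes, 1L)
})

test_that("weight convergence reports distance and correlation", {
  fin <- list(matrix(1:6 / 6, 2, 3))
  wc <- weight_convergence(list(fin, list(matrix(0, 2, 3))), fin)
  expect_equal(wc$distance[1], 0)
  expect_equal(wc$correlation[1], 1)
  expect_equal(wc$distance[2], sqrt(sum((1:6 / 6)^2)))
  expect_equal(wc$correlation[2], 0) # undefined-correlation handled as 0
  expect_error(weight_convergence(list(list(matrix(0, 1, 2))), fin), "shape")
})

test_that("representations bin rates by true head direction", {
  tr <- test_rotation(0, 60, 12, 0.01)
  n <- length(tr$hd)
  log <- cbind(
    rep(0.7, n),                                   # constant cell
    ifelse(tr$hd >= 10 & tr$hd < 20, 0.9, 0)       # confined cell
  )
  rep_ <- build_representation(log, tr$hd, bins = 36, epsilon = 0.5)
  expect_true(all(abs(rep_$tuning[1, ] - 0.7) < 1e-9))
  support <- which(rep_$tuning[2, ] > 0)
  expect_true(all(rep_$bin_centers[support] > 5 &
                    rep_$bin_centers[support] < 25))
  expect_setequal(rep_$recruited, c(1L, 2L))
  expect_true(all(rep_$counts > 0))
  expect_equal(rep_$coverage, 1) # constant cell covers every bin
})
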