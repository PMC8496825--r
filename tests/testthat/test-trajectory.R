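test_that("synthetic trajectories are reproducible and hit the target speed", {
  t1 <- synth_trajectory(60, dt = 0.005, seed = 11)
  t2 <- synth_trajectory(60, dt = 0.005, seed = 11)
  t3 <- synth_trajectory(60, dt = 0.005, seed = 12)
  expect_identical(t1$omega, t2$omega)
  expect_false(identical(t1$omega, t3$omega))
  expect_length(t1$hd, 12000)
  m <- mean(abs(t1$omega))
  expect_gt(m, 72.88 * 0.98)
  expect_lt(m, 72.88 * 1.02)
})

test_that("trajectories are wrap-consistent and velocity roughly symmetric", {
  for (tr in list(synth_trajectory(30, dt = 0.01, seed = 3),
                  test_rotation(20, 60, 12, 0.01))) {
    n <- length(tr$hd)
    pred <- wrap_angle(tr$hd[-n] + tr$omega[-n] * tr$dt)
    expect_equal(pred, tr$hd[-1], tolerance = 1e-8)
  }
  long <- synth_trajectory(1200, dt = 0.01, seed = 3)
  sk <- mean(long$omega^3) / stats::sd(long$omega)^3
  expect_lt(abs(sk), 0.1)
})

test_that("the standard test rotation samples every direction equally", {
  tr <- test_rotation(start_hd = -37, speed = 60, duration = 60, dt = 0.005)
  # each 1-degree bin visited duration * speed / 360 = 10 times
  bins <- floor((wrap_angle(tr$hd) + 180))
  counts <- table(bins)
  expect_length(counts, 360)
  # 10 passes per bin; per pass a 1-degree bin holds 3 or 4 samples at this
  # step, so totals lie between 30 and 40 and every bin is seen in each pass
  expect_gte(min(counts), 30)
  expect_lte(max(counts), 40)
  expect_equal(wrap_angle(tail(tr$hd, 1) + 60 * 0.005), -37, tolerance = 1e-6)
  tr0 <- test_rotation(5, speed = 0, duration = 1, dt = 0.01)
  expect_true(all(tr0$hd == 5))
})

test_that("trajectories round-trip through CSV", {
  tr <- synth_trajectory(5, dt = 0.01, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$hd, tr$hd, tolerance = 1e-10)
  expect_equal(back$omega, tr$omega, tolerance = 1e-10)
  expect_equal(back$dt, tr$dt, tolerance = 1e-10)
  # omega derived from finite differences when the column is missing
  d <- utils::read.csv(path)
  write.csv(d[, c("time_s", "hd_deg")], path, row.names = FALSE)
  back2 <- read_trajectory(path)
  expect_equal(back2$omega[1:100], tr$omega[1:100], tolerance = 1e-6)
  expect_error(read_trajectory(tempfile()), "not found")
})
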