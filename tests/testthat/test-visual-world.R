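test_that("unimodal profile matches the scaled von Mises form", {
  theta <- theta_grid(72)
  f <- unimodal_profile(theta, phi = 40, kappa = 12, fmax = 0.7)
  expect_equal(max(f), unimodal_profile(40, 40, 12, 0.7))
  expect_equal(unimodal_profile(40, 40, 12, 0.7), 0.7) # peak = fmax
  expect_equal(unimodal_profile(220, 40, 12, 0.7), 0.7 * exp(-24)) # antipode
  expect_equal(unimodal_profile(theta, 0, 0, 0.5), rep(0.5, 72)) # kappa 0 flat
})

test_that("broad profile forms a symmetric plateau and degenerates cleanly", {
  theta <- seq(-180, 179, by = 1)
  f <- broad_profile(theta, phi = 0, kappa = 20, width = 90, fmax = 1)
  expect_equal(max(f), 1)
  # plateau dominates the shoulders
  expect_gt(f[theta == 0], f[theta == 90] + 0.2)
  expect_gt(f[theta == 0], f[theta == -90] + 0.2)
  # symmetric about the center
  expect_equal(f[match(30, theta)], f[match(-30, theta)], tolerance = 1e-9)
  # width -> 0 converges to the unimodal profile
  f0 <- broad_profile(theta, 0, 20, width = 1e-6)
  expect_equal(f0, unimodal_profile(theta, 0, 20, 1), tolerance = 1e-6)
})

test_that("channel responses are normalized to equal means, silent channels stay weak", {
  scn <- scenery_conflict(120)
  v <- channel_response(scn, hd = 30, noise_amp = 0)
  expect_true(all(v >= 0 & v <= 1))
  means <- colMeans(v)
  # red and blue carry cues: identical means; green has no cue and no noise
  expect_lt(abs(means["red"] - means["blue"]), 1e-9)
  expect_equal(unname(means["green"]), 0)
  # with background noise the silent channel stays far below the cue channels
  vn <- channel_response(scn, hd = 30, noise_amp = 0.005)
  expect_lt(mean(vn[, "green"]), 0.25 * mean(vn[, "red"]))
})

test_that("channel responses are equivariant under head rotation", {
  scn <- scenery_conflict(120)
  step <- 360 / 120
  v0 <- channel_response(scn, hd = 10, noise_amp = 0)
  v1 <- channel_response(scn, hd = 10 + 5 * step, noise_amp = 0)
  for (j in 1:3) {
    expect_equal(v1[, j], hdring:::circ_shift(v0[, j], -5), tolerance = 1e-9)
  }
})

test_that("cue dynamics advance as declared and teleports are seeded", {
  scn <- scenery("d", list(
    cue("red", "unimodal", centers = 10, dynamics = "static"),
    cue("blue", "broad", centers = 0, width = 90, dynamics = "rotate",
        speed = 90),
    cue("green", "unimodal", centers = 50, dynamics = "teleport", period = 1)
  ), n_dirs = 36)
  s1 <- scn
  for (k in 1:400) s1 <- advance_cues(s1, (k - 1) * 0.01, 0.01) # 4 s
  expect_equal(s1$cues[[1]]$centers, 10) # static unchanged
  # 90 deg/s for 4 s = full revolution
  expect_equal(wrap_angle(s1$cues[[2]]$centers), 0, tolerance = 1e-6)
  # seeded teleports replay identically
  run_tele <- function(seed) {
    set.seed(seed)
    s <- scn
    ctrs <- c()
    for (k in 1:300) {
      s <- advance_cues(s, (k - 1) * 0.01, 0.01)
      ctrs <- c(ctrs, s$cues[[3]]$centers)
    }
    ctrs
  }
  expect_identical(run_tele(7), run_tele(7))
  expect_false(identical(run_tele(7), run_tele(8)))
})

test_that("odor channels are direction-independent and environment-specific", {
  scn <- scenery("o", list(
    cue("red", "unimodal", centers = 0),
    cue("smellA", "constant", fmax = 0.5)
  ), n_dirs = 36, features = c("red", "smellA", "smellB"))
  o1 <- odor_channel(scn, hd = 0)
  o2 <- odor_channel(scn, hd = 123)
  expect_equal(o1, o2)
  expect_equal(diff(range(o1)), 0)
  # a second odor id occupies a disjoint channel
  v <- channel_response(scn, 0, noise_amp = 0)
  expect_true(all(v[, "smellB"] == 0))
  expect_true(all(v[, "smellA"] > 0))
  expect_error(odor_channel(scenery_conflict(36)), "constant")
})

test_that("whole-scenery rotation shifts every cue center", {
  scn <- scenery_conflict(36)
  r <- rotate_scenery(scn, 120)
  expect_equal(r$cues[[1]]$centers, wrap_angle(c(90, -90) + 120))
  expect_equal(r$cues[[2]]$centers, 120)
})
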