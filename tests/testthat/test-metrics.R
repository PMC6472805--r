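# Remodeling metrics on gridded fields and the synthetic fixture.

test_that("displacement length averages |u| over the ROI", {
  u <- array(0, c(21, 21, 21, 3))
  u[, , , 1] <- 1.2; u[, , , 2] <- -1.6   # |u| = 2 everywhere
  f <- displacement_field(u, spacing = 3, "overall", origin = c(-30, -30, -30))
  expect_equal(displacement_length(f, c(0, 0, 0), 60), 2)
  expect_equal(displacement_length(f, c(0, 0, 0), 30), 2)
  f0 <- displacement_field(array(0, c(21, 21, 21, 3)), 3, "overall",
                           c(-30, -30, -30))
  expect_equal(displacement_length(f0, c(0, 0, 0), 60), 0)
  expect_error(displacement_length(f, c(25, 0, 0), 60), "exceeds")
  # random field: equals the brute-force voxel loop
  set.seed(5)
  ur <- array(rnorm(21^3 * 3), c(21, 21, 21, 3))
  fr <- displacement_field(ur, 3, "overall", c(-30, -30, -30))
  manual <- mean(sqrt(apply(ur^2, 1:3, sum)))
  expect_equal(displacement_length(fr, c(0, 0, 0), 60), manual,
               tolerance = 1e-12)
})

test_that("the recoverability index is the decell-to-overall ratio in percent", {
  expect_equal(recoverability_index(2, 2), 100)
  expect_equal(recoverability_index(1, 4), 25)
  expect_true(is.na(recoverability_index(1, 0)))
  over <- recoverability_index(5, 4)
  expect_equal(as.numeric(over), 125)
  expect_match(attr(over, "flag"), "exceeds")
})

test_that("densification factor reads the fixture shell ratio", {
  fx <- synth_fixture(seed = 2, shell_ratio = 2, noise_sd = 0)
  expect_equal(densification_factor(fx$volume), 2, tolerance = 0.02)
  # uniform volume: DF = 1 regardless of intensity scale
  uni <- fx$volume
  uni$I[] <- 7
  expect_equal(densification_factor(uni), 1, tolerance = 1e-9)
  # invariant under global rescaling
  sc <- fx$volume
  sc$I <- sc$I * 123
  expect_equal(densification_factor(sc), densification_factor(fx$volume),
               tolerance = 1e-12)
  # background-free far field is a guarded failure
  dark <- fx$volume
  dark$I[] <- 0
  expect_error(densification_factor(dark), "far-field")
})

test_that("radial decay profiles reproduce the analytic power law", {
  fx <- synth_fixture(seed = 3, n = 2, u0 = 2, noise_sd = 0)
  a <- fx$truth$cell_radius
  prof <- radial_decay_profile(fx$overall, c(0, 0, 0), a, max_distance = 20)
  expect_equal(prof$normalized[1], 1)
  # profile shape matches (a/(a+d))^2 away from the membrane-blurred first
  # voxel (renormalized at d = 2 to factor out the blurred anchor point)
  d <- prof$distance[prof$distance >= 2]
  shape <- prof$normalized[prof$distance >= 2]
  expect_equal(shape / shape[1], (a / (a + d))^2 / (a / (a + 2))^2,
               tolerance = 0.01)
  expect_equal(decay_exponent(prof, a, min_distance = 1), -2, tolerance = 0.02)
  # zero membrane displacement is flagged
  f0 <- displacement_field(array(0, c(11, 11, 11, 3)), 2, "overall",
                           c(-10, -10, -10))
  expect_warning(p0 <- radial_decay_profile(f0, c(0, 0, 0), 3,
                                            max_distance = 4), "zero")
  expect_true(all(is.na(p0$normalized)))
})

test_that("metrics are linear in the field scale where they should be", {
  fx <- synth_fixture(seed = 4, n = 2, u0 = 1.5, f = 0.6, noise_sd = 0)
  a <- fx$truth$cell_radius
  len1 <- displacement_length(fx$overall, c(0, 0, 0), 60)
  scaled <- fx$overall
  scaled$u <- scaled$u * 3
  expect_equal(displacement_length(scaled, c(0, 0, 0), 60), 3 * len1,
               tolerance = 1e-12)
  # RI and the normalized profile are scale-free
  p1 <- radial_decay_profile(fx$overall, c(0, 0, 0), a)
  p3 <- radial_decay_profile(scaled, c(0, 0, 0), a)
  expect_equal(p1$normalized, p3$normalized, tolerance = 1e-12)
})

test_that("fixture ground truth is recovered exactly without noise", {
  fx <- synth_fixture(seed = 6, n = 2.3, f = 1, shell_ratio = 2.5,
                      noise_sd = 0)
  lo <- displacement_length(fx$overall, c(0, 0, 0), 60)
  ld <- displacement_length(fx$decell, c(0, 0, 0), 60)
  expect_equal(recoverability_index(ld, lo), 100, tolerance = 1e-9)
  rec <- recover_fixture_params(fx)
  expect_equal(rec$n, 2.3, tolerance = 0.01)
  expect_equal(rec$f, 1, tolerance = 1e-9)
  expect_equal(rec$shell_ratio, 2.5, tolerance = 0.05)
  # plastic + decell = overall, per voxel
  expect_equal(fx$decell$u + fx$plastic$u, fx$overall$u, tolerance = 1e-12)
})
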