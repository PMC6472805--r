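# Bell slip-bond kinetics: rates, probabilities, stochastic application.

test_that("the Bell rate responds exponentially to tension", {
  par <- micro_config(ku0 = 0.02, lambda = 2e-4)
  expect_equal(unbind_rate(0, par), 0.02)
  # lambda = 0: force has no effect
  par0 <- micro_config(ku0 = 0.02, lambda = 0)
  expect_equal(unbind_rate(c(0, 50, 5000), par0), rep(0.02, 3))
  # F = ln(2) kBT / lambda doubles the rate
  fdouble <- log(2) * par$kBT / par$lambda
  expect_equal(unbind_rate(fdouble, par), 0.04, tolerance = 1e-12)
  # monotone non-decreasing in force
  expect_true(all(diff(unbind_rate(seq(0, 200, 10), par)) >= 0))
  # exponent clamped with a warning
  expect_warning(r <- unbind_rate(1e9, par), "clamped")
  expect_equal(r, 0.02 * exp(par$exp_cap))
})

test_that("per-step unbinding probability follows the exponential law", {
  expect_equal(unbind_probability(0, 1e-3), 0)
  expect_equal(unbind_probability(100, 1e-3), 1 - exp(-0.1), tolerance = 1e-12)
  expect_equal(unbind_probability(1e9, 1), 1)
  expect_true(all(unbind_probability(10^(0:8), 1e-4) >= 0 &
                    unbind_probability(10^(0:8), 1e-4) <= 1))
})

test_that("mean survival time under constant force matches 1/k_u", {
  # 1e4 independent crosslinks at fixed cached tension; dt resolves the rate
  n_cl <- 10000
  par <- micro_config(ku0 = 0.05, lambda = 2e-4, dt = 1e-2)
  force <- 60
  k_u <- unbind_rate(force, par)
  stopifnot(k_u * par$dt < 0.02)
  pos <- rbind(c(1, 1, 1), c(1, 1, 2), c(2, 1, 1), c(2, 1, 2))
  segs <- data.frame(a = c(1, 3), b = c(2, 4), rest = 1, fiber = c(1L, 2L))
  cl <- data.frame(seg_a = 1L, seg_b = 2L, ta = 0.5, tb = 0.5, rest = 0.04,
                   bound = TRUE, tension = force)[rep(1, n_cl), ]
  net <- fiber_network(pos, rep(FALSE, 4), segs, cl, domain = c(6, 6, 6))
  set.seed(99)
  steps <- rep(NA_real_, n_cl)
  for (it in 1:5000) {
    res <- apply_unbinding(net, par)
    net <- res$network
    if (nrow(res$events) > 0) steps[res$events$crosslink] <- it
    # tension cache survives on remaining bound crosslinks by construction
    if (!any(net$crosslinks$bound)) break
  }
  expect_true(all(!is.na(steps)))
  mean_surv <- mean(steps) * par$dt
  # exact mean of the discrete process, and a 3-standard-error band
  p <- unbind_probability(k_u, par$dt)
  expected <- par$dt / p
  se <- expected / sqrt(n_cl)
  expect_lt(abs(mean_surv - 1 / k_u), 3 * se + abs(expected - 1 / k_u))
})

test_that("unbinding frequencies match the Bell rate over three force decades", {
  par <- micro_config(ku0 = 1e-3, lambda = 3e-4)
  n <- 10000
  set.seed(7)
  for (force in c(1, 30, 1000)) {
    k_u <- min(par$ku0 * exp(par$lambda * force / par$kBT),
               par$ku0 * exp(par$exp_cap))
    dt <- 0.05 / k_u               # resolve each decade
    p <- unbind_probability(k_u, dt)
    draws <- runif(n) < p
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(draws) - p), 3 * se + 1e-12)
  }
})

test_that("unbinding events are reproducible and conserve the crosslink pool", {
  cfg <- micro_config(seed = 31, ku0 = 0.2, lambda = 3e-4)
  net <- relax_network(generate_network(cfg, 31), cfg)$network
  s1 <- run_protocol(net, cfg, seed = 31)
  s2 <- run_protocol(net, cfg, seed = 31)
  expect_identical(s1$events, s2$events)
  expect_identical(c(s1$snap_pos), c(s2$snap_pos))
  # crosslinks are never created or destroyed, only flipped
  expect_equal(nrow(s1$final_network$crosslinks), nrow(net$crosslinks))
  # with ku0 = 0 and zero tension nothing ever unbinds
  net0 <- net
  net0$crosslinks$tension <- 0
  cfg0 <- micro_config(ku0 = 0)
  res <- apply_unbinding(net0, cfg0)
  expect_equal(nrow(res$events), 0)
})

test_that("rebinding requires reach and resets the spring to zero strain", {
  cfg <- micro_config(rebind_rate = 1e9, rebind_reach = 0.15, dt = 1e-3)
  # beyond reach: never rebinds
  far <- crosslinked_pair(gap = 0.5, cl_rest = 0.5)
  far$crosslinks$bound <- FALSE
  set.seed(1)
  expect_false(apply_rebinding(far, cfg)$crosslinks$bound[1])
  # within reach with a huge rate: rebinds at current geometry, zero strain
  nearby <- crosslinked_pair(gap = 0.1, cl_rest = 0.04)
  nearby$crosslinks$bound <- FALSE
  set.seed(1)
  reb <- apply_rebinding(nearby, cfg)
  expect_true(reb$crosslinks$bound[1])
  expect_equal(reb$crosslinks$rest[1], 0.1, tolerance = 1e-9)
  expect_equal(crosslink_forces(reb, cfg)$tension[1], 0, tolerance = 1e-9)
  # rebind_rate = 0 recovers the no-rebinding model
  cfg0 <- micro_config(rebind_rate = 0)
  set.seed(1)
  expect_false(apply_rebinding(nearby, cfg0)$crosslinks$bound[1])
})
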