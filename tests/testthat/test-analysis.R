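# Concentration profiles, accumulation series, plane stress, sweeps.

test_that("concentration profiles conserve fiber material exactly", {
  cfg <- micro_config(seed = 61)
  net <- generate_network(cfg, 61)
  prof <- concentration_profile(net, 1)
  widths <- prof$z_hi - prof$z_lo
  # normalization identity: length-weighted mean over bins is exactly 1
  expect_equal(sum(prof$concentration * widths) / net$domain[3], 1,
               tolerance = 1e-9)
  # freshly generated network: all bins within sampling noise of 1
  expect_true(all(abs(prof$concentration - 1) < 0.35))
})

test_that("segment clipping distributes material like the brute-force oracle", {
  # an oblique two-segment fiber crossing three bins
  pos <- rbind(c(2, 2, 0.4), c(2.4, 2, 1.6), c(2.8, 2, 2.8))
  segs <- data.frame(a = 1:2, b = 2:3, rest = 1.3, fiber = 1L)
  net <- fiber_network(pos, rep(FALSE, 3), segs, NULL, domain = c(6, 6, 6))
  prof <- concentration_profile(net, 1)
  # oracle: rest length distributed by z-extent overlap, per segment
  oracle <- numeric(6)
  for (k in 1:2) {
    z1 <- pos[k, 3]; z2 <- pos[k + 1, 3]
    for (b in 1:6) {
      ov <- max(0, min(max(z1, z2), b) - max(min(z1, z2), b - 1))
      oracle[b] <- oracle[b] + 1.3 * ov / abs(z2 - z1)
    }
  }
  rho0 <- sum(segs$rest) / 6
  expect_equal(prof$concentration, oracle / rho0, tolerance = 1e-12)

  # translating by half a bin moves the clipped overlap exactly
  net2 <- net; net2$pos[, 3] <- net2$pos[, 3] + 0.5
  prof2 <- concentration_profile(net2, 1)
  oracle2 <- numeric(6)
  for (k in 1:2) {
    z1 <- pos[k, 3] + 0.5; z2 <- pos[k + 1, 3] + 0.5
    for (b in 1:6) {
      ov <- max(0, min(max(z1, z2), b) - max(min(z1, z2), b - 1))
      oracle2[b] <- oracle2[b] + 1.3 * ov / abs(z2 - z1)
    }
  }
  expect_equal(prof2$concentration, oracle2 / rho0, tolerance = 1e-12)
})

test_that("accumulation series start near 1 and whole-domain aggregation is exact", {
  cfg <- micro_config(seed = 67, force_per_site = 50, ku0 = 0.05)
  net <- relax_network(generate_network(cfg, 67), cfg)$network
  series <- run_protocol(net, cfg, seed = 67)
  acc <- accumulation_timeseries(series, 3)
  expect_equal(acc$concentration[1], 1, tolerance = 0.3)
  # whole-domain region: identically 1 at every snapshot (mass conservation)
  acc_all <- accumulation_timeseries(series, series$network$domain[3])
  expect_equal(acc_all$concentration, rep(1, nrow(acc_all)), tolerance = 1e-9)
  # the accumulation value equals the re-aggregated profile bins
  prof <- profile_series(series, 1)
  manual <- rowMeans(prof[, 1:3])
  expect_equal(acc$concentration, manual, tolerance = 1e-9)
  # peak concentration is the maximum of the series
  expect_equal(peak_concentration(series, 3), max(acc$concentration))
})

test_that("plane stress matches the single-fiber and serial-chain oracles", {
  cfg <- micro_config(kappa_e = 1000)
  dom <- c(20, 20, 20)
  # straight vertical fiber under 100 pN tension crossing a 400 um^2 plane
  net <- chain_network(seq(2, 18, by = 1), domain = dom, x = 10, y = 10,
                       rest = 1 - 100 / 1000)   # stretched to tension 100
  expect_equal(plane_stress(net, cfg, 10.5), 100 / 400, tolerance = 1e-9)
  # uniform tension: equal stress at 5 plane positions within 1 percent
  st <- vapply(c(3.5, 6.5, 10.5, 13.5, 16.5),
               function(z) plane_stress(net, cfg, z), 1)
  expect_true(all(abs(st / st[1] - 1) < 0.01))
  # a fiber lying in the plane contributes nothing
  pos <- cbind(seq(2, 6, 1), 3, 10)
  segs <- data.frame(a = 1:4, b = 2:5, rest = 0.9, fiber = 1L)
  flat <- fiber_network(pos, rep(FALSE, 5), segs, NULL, domain = dom)
  expect_equal(plane_stress(flat, cfg, 10), 0)
  # planes outside the domain are rejected
  expect_error(plane_stress(net, cfg, 25), "inside the domain")
})

test_that("stress retention summarizes the loading phase correctly", {
  mono <- data.frame(t_norm = seq(0, 1, 0.1), stress = seq(0, 10, 1))
  expect_equal(stress_retention_ratio(mono), 1)
  peaked <- data.frame(t_norm = seq(0, 1, 0.25), stress = c(0, 8, 4, 3, 4))
  expect_equal(stress_retention_ratio(peaked), 0.5)
  zero <- data.frame(t_norm = seq(0, 1, 0.5), stress = c(0, 0, 0))
  expect_true(is.na(stress_retention_ratio(zero)))
})

test_that("parameter sweeps are reproducible and summarize replicates", {
  cfg <- micro_config(seed = 71, ku0 = 0.05)
  sw1 <- parameter_sweep(cfg, "force", c(10, 100), replicates = 2)
  sw2 <- parameter_sweep(cfg, "force", c(10, 100), replicates = 2)
  expect_equal(sw1$runs, sw2$runs)
  expect_equal(nrow(sw1$runs), 4)
  expect_true(all(c("peak_concentration", "final_concentration",
                    "peak_stress", "retention") %in% sw1$summary$metric))
  m <- subset(sw1$summary, metric == "peak_stress")
  expect_true(all(is.finite(m$mean)))
})
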