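# Spherical viscoplastic solver: constitutive pieces, elastic oracle,
# damage bookkeeping, convergence.

test_that("the damage law interpolates exactly between its anchors", {
  cfg <- continuum_config()
  expect_equal(damage_modulus(cfg$eps1s, cfg), 1000)
  expect_equal(damage_modulus(cfg$eps1e, cfg), 200)
  expect_equal(damage_modulus(0, cfg), 1000)
  expect_equal(damage_modulus(1, cfg), 200)
  # closed-form decay constant and continuity at both anchors
  B <- log(cfg$E_s / cfg$E_e) / (cfg$eps1e - cfg$eps1s)
  A <- cfg$E_s * exp(B * cfg$eps1s)
  eps <- 1e-12
  expect_equal(damage_modulus(cfg$eps1s + eps, cfg), A * exp(-B * (cfg$eps1s + eps)),
               tolerance = 1e-12)
  expect_equal(damage_modulus(cfg$eps1s + eps, cfg) / cfg$E_s, 1, tolerance = 1e-9)
  expect_equal(damage_modulus(cfg$eps1e - eps, cfg) / cfg$E_e, 1, tolerance = 1e-9)
  # monotone non-increasing
  ee <- seq(0, 0.12, by = 0.005)
  expect_true(all(diff(damage_modulus(ee, cfg)) <= 0))
  expect_error(continuum_config(eps1s = 0.06, eps1e = 0.02), "eps1s < eps1e")
})

test_that("yield softening is piecewise linear, continuous, and floored", {
  cfg <- continuum_config(sigma_y0 = 40, softening_slope = -200,
                          eps_p_crit = 0.05, sigma_y_min = 5)
  expect_equal(yield_stress(0, cfg), 40)
  expect_equal(yield_stress(0.05, cfg), 40)
  expect_equal(yield_stress(0.05 + 1e-9, cfg), 40, tolerance = 1e-6)
  expect_equal(yield_stress(0.1, cfg), 40 - 200 * 0.05)
  expect_equal(yield_stress(10, cfg), 5)
  # slope 0: perfect plasticity
  cfg0 <- continuum_config(softening_slope = 0)
  expect_equal(yield_stress(c(0, 0.5, 2), cfg0), rep(cfg0$sigma_y0, 3))
  # softening off reproduces constant yield
  cfgoff <- continuum_config(softening_on = FALSE)
  expect_equal(yield_stress(c(0, 1), cfgoff), rep(cfgoff$sigma_y0, 2))
})

test_that("the creep law is power-law overstress flow", {
  cfg <- continuum_config(NH_coefficient = 1e-3, NH_exponent = 2,
                          sigma_y0 = 50, sigma_ref = 50)
  expect_equal(creep_rate(30, 50, cfg), 0)
  expect_equal(creep_rate(50, 50, cfg), 0)
  # doubling the overstress multiplies the rate by 2^n
  r1 <- creep_rate(100, 50, cfg)   # overstress 50
  r2 <- creep_rate(150, 50, cfg)   # overstress 100
  expect_equal(r2 / r1, 4, tolerance = 1e-12)
  # n = 1: Bingham limit, linear in overstress
  cfg1 <- continuum_config(NH_coefficient = 1e-3, NH_exponent = 1)
  x <- seq(0, 100, 20)
  expect_equal(creep_rate(cfg1$sigma_y0 + x, rep(cfg1$sigma_y0, length(x)), cfg1),
               1e-3 * x / cfg1$sigma_ref, tolerance = 1e-12)
})

test_that("the pure elastic solution matches the closed-form cavity field", {
  cfg <- continuum_config(damage_on = FALSE, plasticity_on = FALSE,
                          outer_radius = 500, n_r = 400,
                          creep_duration = 30, hold_duration = 30)
  sol <- solve_sphere(cfg)
  u <- sol$snaps[[sol$idx_creep_end]]$u
  ref <- elastic_cavity_displacement(sol$r, cfg$load_p, cfg)
  sel <- sol$r <= 6 * cfg$cell_radius
  expect_lt(max(abs(u[sel] - ref[sel]) / abs(ref[sel])), 2e-3)
  # displacement is inward and decays as r^-2 in the far field
  expect_lt(u[1], 0)
  expect_equal(elastic_decay_exponent(sol), -2, tolerance = 0.02)
  # full recovery on unload and exact unit stress ratio
  expect_equal(recoverability_index_model(sol), 100, tolerance = 1e-6)
  ratio <- apparent_true_stress_ratio(sol)
  expect_equal(max(abs(ratio$ratio - 1), na.rm = TRUE), 0, tolerance = 1e-8)
  expect_equal(damage_radius(sol)$radius_um, 0)
  # linearity: the decay exponent does not depend on the load level
  cfg2 <- continuum_config(damage_on = FALSE, plasticity_on = FALSE,
                           outer_radius = 500, n_r = 400, load_p = 13,
                           creep_duration = 30, hold_duration = 30)
  expect_equal(elastic_decay_exponent(solve_sphere(cfg2)),
               elastic_decay_exponent(sol), tolerance = 1e-6)
})

test_that("damage is irreversible and dissipation is non-negative", {
  sol <- solve_sphere(continuum_config())
  Emat <- sapply(sol$snaps, function(s) s$E)
  # modulus non-increasing in time at every radius
  expect_true(all(apply(Emat, 1, function(e) all(diff(e) <= 1e-9))))
  expect_true(all(Emat >= 200 - 1e-9 & Emat <= 1000 + 1e-9))
  # equivalent plastic strain is cumulative
  ep <- sapply(sol$snaps, function(s) max(s$epeq))
  expect_true(all(diff(ep) >= -1e-12))
  # recoverability strictly below 100 under damage + softening
  expect_lt(recoverability_index_model(sol), 100)
  expect_gt(recoverability_index_model(sol), 0)
})

test_that("halving the grid and time resolution barely moves the outputs", {
  coarse <- continuum_config()
  fine <- continuum_config(n_r = 400, target_dep = 1e-4)
  s1 <- solve_sphere(coarse); s2 <- solve_sphere(fine)
  ri1 <- recoverability_index_model(s1); ri2 <- recoverability_index_model(s2)
  expect_lt(abs(ri1 - ri2) / ri2, 0.01)
  d1 <- damage_radius(s1)$radius_um; d2 <- damage_radius(s2)$radius_um
  expect_lt(abs(d1 - d2) / d2, 0.03)
})

test_that("continuum feature switches reproduce the expected orderings", {
  s_ds <- solve_sphere(continuum_config())
  s_d <- solve_sphere(continuum_config(softening_on = FALSE))
  # softening reduces recoverability
  expect_lt(recoverability_index_model(s_ds), recoverability_index_model(s_d))
  # larger loads reduce recoverability and extend damage
  s_hi <- solve_sphere(continuum_config(load_p = 200))
  expect_lt(recoverability_index_model(s_hi), recoverability_index_model(s_ds))
  expect_gt(damage_radius(s_hi)$radius_um, damage_radius(s_ds)$radius_um)
  # stress overestimation exceeds 1 wherever damage occurred
  ratio <- apparent_true_stress_ratio(s_ds)
  near <- ratio$r < 15
  expect_true(all(ratio$ratio[near] > 1, na.rm = TRUE))
  # and decays toward 1 with distance from the cell edge
  mid <- which.min(abs(ratio$r - 5 * 10))
  expect_lt(abs(ratio$ratio[mid] - 1), abs(attr(ratio, "at_probe") - 1))
  expect_lt(abs(ratio$ratio[mid] - 1), 0.5)
  expect_gt(attr(ratio, "peak"), attr(ratio, "at_probe"))
})
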