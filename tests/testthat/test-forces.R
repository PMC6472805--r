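# Internal force terms: values, action-reaction, and agreement with the
# negative numerical gradient of each potential.

test_that("stretch forces match the harmonic potential", {
  cfg <- micro_config(kappa_e = 10)
  # Delta r = 0: no force, no energy
  net0 <- chain_network(c(2, 4), domain = c(6, 6, 6), x = 3, y = 3, rest = 2)
  s0 <- stretch_forces(net0, cfg)
  expect_equal(max(abs(s0$forces)), 0)
  expect_equal(s0$energy, 0)
  # kappa_e = 10, Delta r = 0.2: |F| = 2 pN, U = 0.2 pN um
  net1 <- chain_network(c(2, 4.2), domain = c(6, 6, 6), x = 3, y = 3, rest = 2)
  s1 <- stretch_forces(net1, cfg)
  expect_equal(sqrt(sum(s1$forces[1, ]^2)), 2, tolerance = 1e-12)
  expect_equal(s1$energy, 0.2, tolerance = 1e-12)
  expect_equal(s1$seg_tension[1], 2, tolerance = 1e-12)
  # tensile when stretched: force on the lower node points up
  expect_gt(s1$forces[1, 3], 0)
  # zero-length segment is degenerate
  net_bad <- chain_network(c(3, 3), domain = c(6, 6, 6), rest = 1)
  expect_error(stretch_forces(net_bad, cfg), "degenerate")
})

test_that("stretch forces equal the negative numerical energy gradient", {
  cfg <- micro_config(kappa_e = 37)
  net <- random_fiber_network(50, 1, seed = 2, jitter = 0.3)
  fun <- function(p) { n2 <- net; n2$pos <- p; stretch_forces(n2, cfg)$energy }
  g <- numerical_gradient(fun, net$pos)
  f <- stretch_forces(net, cfg)$forces
  expect_lt(max(abs(f + g)) / max(abs(f)), 1e-4)
})

test_that("bend forces match the angular potential", {
  cfg <- micro_config(kappa_b = 1)
  # collinear triplet: zero bend force
  net0 <- chain_network(c(1, 2, 3), domain = c(6, 6, 6), x = 3, y = 3)
  b0 <- bend_forces(net0, cfg)
  expect_equal(max(abs(b0$forces)), 0, tolerance = 1e-12)
  expect_equal(b0$energy, 0, tolerance = 1e-12)
  # right angle, unit arms: U = (pi/2)^2 / 2
  pos <- rbind(c(3, 3, 3), c(3, 3, 4), c(3, 4, 4))
  segs <- data.frame(a = 1:2, b = 2:3, rest = 1, fiber = 1L)
  net1 <- fiber_network(pos, rep(FALSE, 3), segs, NULL, domain = c(6, 6, 6))
  b1 <- bend_forces(net1, cfg)
  expect_equal(b1$energy, 0.5 * (pi / 2)^2, tolerance = 1e-12)
  # zero net force and zero net torque per triplet
  expect_equal(colSums(b1$forces), c(0, 0, 0), tolerance = 1e-12)
  torque <- colSums(t(sapply(1:3, function(i)
    c(pos[i, 2] * b1$forces[i, 3] - pos[i, 3] * b1$forces[i, 2],
      pos[i, 3] * b1$forces[i, 1] - pos[i, 1] * b1$forces[i, 3],
      pos[i, 1] * b1$forces[i, 2] - pos[i, 2] * b1$forces[i, 1]))))
  expect_equal(torque, c(0, 0, 0), tolerance = 1e-10)
})

test_that("bend forces equal the negative numerical energy gradient", {
  cfg <- micro_config(kappa_b = 2.7)
  net <- random_fiber_network(50, 2, seed = 3, jitter = 0.25)
  fun <- function(p) { n2 <- net; n2$pos <- p; bend_forces(n2, cfg)$energy }
  g <- numerical_gradient(fun, net$pos)
  f <- bend_forces(net, cfg)$forces
  expect_lt(max(abs(f + g)) / max(abs(f)), 1e-4)
})

test_that("repulsion acts only on overlapping pairs, antisymmetrically", {
  cfg <- micro_config(k_rep = 100, rep_cap = 1e6)
  mk <- function(gap) {
    pos <- rbind(c(2, 3, 2), c(2, 3, 4), c(2 + gap, 3, 2), c(2 + gap, 3, 4))
    segs <- data.frame(a = c(1, 3), b = c(2, 4), rest = 2, fiber = c(1L, 2L))
    fiber_network(pos, rep(FALSE, 4), segs, NULL, domain = c(6, 6, 6))
  }
  # separated by 2x diameter: no force
  far <- repulsion_forces(mk(2 * cfg$diameter), cfg)
  expect_equal(max(abs(far$forces)), 0)
  # overlapping: forces equal and opposite between the fibers
  near <- repulsion_forces(mk(0.5 * cfg$diameter), cfg)
  expect_gt(max(abs(near$forces)), 0)
  expect_equal(colSums(near$forces), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(near$forces[1, ], -near$forces[3, ], tolerance = 1e-12)
  # energy decreases monotonically as the pair is pushed apart
  gaps <- seq(0.02, 0.12, by = 0.01)
  en <- vapply(gaps, function(g) repulsion_forces(mk(g), cfg)$energy, 1)
  expect_true(all(diff(en) <= 1e-12))
})

test_that("crosslink springs act between attachment points with lever-arm weights", {
  cfg <- micro_config(kappa_cl = 50)
  # separation equal to rest length: no force, no tension
  n0 <- crosslinked_pair(gap = 0.04, cl_rest = 0.04)
  c0 <- crosslink_forces(n0, cfg)
  expect_equal(max(abs(c0$forces)), 0, tolerance = 1e-12)
  expect_equal(c0$tension[1], 0)
  # compressed crosslink transmits force but caches zero kinetic tension
  nc <- crosslinked_pair(gap = 0.02, cl_rest = 0.04)
  cc <- crosslink_forces(nc, cfg)
  expect_gt(max(abs(cc$forces)), 0)
  expect_equal(cc$tension[1], 0)
  # stretched crosslink: tension = kappa_cl * extension
  ns <- crosslinked_pair(gap = 0.10, cl_rest = 0.04)
  cs <- crosslink_forces(ns, cfg)
  expect_equal(cs$tension[1], 50 * 0.06, tolerance = 1e-9)
  # unbound crosslinks exert no force
  nu <- ns; nu$crosslinks$bound <- FALSE
  expect_equal(max(abs(crosslink_forces(nu, cfg)$forces)), 0)

  # nodal distribution reproduces the attachment point force and torque
  net <- crosslinked_pair(gap = 0.3, cl_rest = 0.05)
  net$crosslinks$ta <- 0.3; net$crosslinks$tb <- 0.8
  fb <- crosslink_forces(net, cfg)
  s <- net$segments
  pa <- net$pos[s$a[1], ] + 0.3 * (net$pos[s$b[1], ] - net$pos[s$a[1], ])
  pb <- net$pos[s$a[2], ] + 0.8 * (net$pos[s$b[2], ] - net$pos[s$a[2], ])
  d <- pb - pa; L <- sqrt(sum(d^2))
  fvec <- cfg$kappa_cl * (L - 0.05) * d / L
  # resultant on fiber 1
  expect_equal(colSums(fb$forces[1:2, ]), fvec, tolerance = 1e-9)
  # moment about the origin matches the point-force moment
  cross3 <- function(a, b) c(a[2]*b[3] - a[3]*b[2], a[3]*b[1] - a[1]*b[3],
                             a[1]*b[2] - a[2]*b[1])
  m_nodes <- cross3(net$pos[1, ], fb$forces[1, ]) +
    cross3(net$pos[2, ], fb$forces[2, ])
  expect_equal(m_nodes, cross3(pa, fvec), tolerance = 1e-8)
})

test_that("internal forces sum to zero on a random crosslinked network", {
  cfg <- micro_config(seed = 13)
  net <- generate_network(cfg, 13)
  f <- network_forces(net, cfg)
  scale <- max(abs(f$total), 1)
  expect_lt(max(abs(colSums(f$total))) / scale, 1e-9)
  for (part in c("stretch", "bend", "repulsion", "crosslink"))
    expect_lt(max(abs(colSums(f[[part]]))) / scale, 1e-9)
})

test_that("Euler updates follow the overdamped equation of motion", {
  cfg <- micro_config(zeta = 10, dt = 1e-3)
  net <- chain_network(c(2, 4), domain = c(6, 6, 6), x = 3, y = 3, rest = 2)
  # zero force: no motion
  net0 <- euler_step(net, matrix(0, 2, 3), cfg)
  expect_identical(net0$pos, net$pos)
  # constant force: n steps displace n F dt / zeta exactly
  f <- rbind(c(0.5, -0.2, 0.3), c(0, 0, 0))
  n2 <- net
  for (i in 1:50) n2 <- euler_step(n2, f, cfg)
  expect_equal(n2$pos[1, ] - net$pos[1, ], 50 * f[1, ] * 1e-3 / 10,
               tolerance = 1e-9)
  # fixed nodes never move
  netf <- net; netf$fixed <- c(FALSE, TRUE)
  nf <- euler_step(netf, rbind(c(0, 0, 0), c(1e3, 0, 0)), cfg)
  expect_equal(nf$pos[2, ], net$pos[2, ])
  # stability cap triggers an error advising a smaller dt
  expect_error(euler_step(net, matrix(1e6, 2, 3), cfg), "smaller dt")
})

test_that("an overdamped spring relaxes on the analytic exponential", {
  kappa <- 10; zeta <- 10; dt <- 5e-4   # dt kappa / zeta = 5e-4
  cfg <- micro_config(kappa_e = kappa, kappa_b = 0, zeta = zeta, dt = dt)
  net <- chain_network(c(2, 4.4), domain = c(6, 6, 6), x = 3, y = 3, rest = 2)
  n2 <- net
  nsteps <- 400
  for (i in seq_len(nsteps)) {
    f <- network_forces(n2, cfg)$total
    n2 <- euler_step(n2, f, cfg)
  }
  # relative coordinate decays with rate 2 kappa / zeta
  delta <- abs(diff(n2$pos[, 3])) - 2
  expected <- 0.4 * exp(-2 * kappa / zeta * nsteps * dt)
  expect_equal(delta, expected, tolerance = 0.02)
})

test_that("elastic energy never increases along unloaded dynamics", {
  cfg <- micro_config(seed = 17)
  net <- generate_network(cfg, 17)
  e <- numeric(30)
  n2 <- net
  for (i in 1:30) {
    f <- network_forces(n2, cfg)
    e[i] <- sum(f$energies)
    n2 <- euler_step(n2, f$total, cfg)
  }
  expect_true(all(diff(e) <= 1e-9 * max(e)))
})
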