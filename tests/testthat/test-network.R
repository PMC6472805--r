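# Network generation, relaxation, boundary helpers.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- micro_config(seed = 3)
  n1 <- generate_network(cfg, seed = 3)
  n2 <- generate_network(cfg, seed = 3)
  expect_identical(n1, n2)
  n3 <- generate_network(cfg, seed = 4)
  expect_false(identical(n1$pos, n3$pos))
})

test_that("crosslink density scales linearly through subsampling", {
  cfg0 <- micro_config(seed = 5, crosslink_density_rel = 0)
  expect_equal(nrow(generate_network(cfg0, 5)$crosslinks), 0)

  cfg1 <- micro_config(seed = 5, crosslink_density_rel = 1)
  cfg5 <- micro_config(seed = 5, crosslink_density_rel = 0.5)
  n1 <- generate_network(cfg1, 5)
  n5 <- generate_network(cfg5, 5)
  expect_equal(nrow(n5$crosslinks), round(nrow(n1$crosslinks) / 2),
               tolerance = 0, ignore_attr = TRUE)
  # candidate pool equals the brute-force all-pairs count
  small <- random_fiber_network(8, 4, seed = 11, domain = c(10, 10, 10))
  cand <- crosslink_candidates(small, reach = 0.4)
  expect_equal(nrow(cand), brute_candidate_count(small, 0.4))
  # engine distances agree with the independent oracle
  for (k in seq_len(min(10, nrow(cand)))) {
    s <- small$segments
    d_oracle <- r_segment_distance(
      small$pos[s$a[cand$seg_a[k]], ], small$pos[s$b[cand$seg_a[k]], ],
      small$pos[s$a[cand$seg_b[k]], ], small$pos[s$b[cand$seg_b[k]], ])
    expect_equal(cand$dist[k], d_oracle, tolerance = 1e-5)
  }
})

test_that("unsatisfiable crosslink density fails naming the achievable maximum", {
  cfg <- micro_config(seed = 5, crosslink_density_rel = 5,
                      crosslink_base_fraction = 0.35)
  expect_error(generate_network(cfg, 5), "achievable maximum")
})

test_that("generation conserves the requested total fiber length", {
  cfg <- micro_config(seed = 7)
  net <- generate_network(cfg, 7)
  target <- cfg$line_density * prod(cfg$domain)
  expect_lt(abs(net$total_rest_length - target), cfg$segment_length + 1e-9)
  # interior nodes of each chain are shared by exactly two segments
  s <- net$segments
  counts <- table(c(s$a, s$b))
  expect_true(all(counts <= 2))
})

test_that("a freshly generated network is uniform along the loading axis", {
  cfg <- desk_config(seed = 21)
  prof <- Reduce(`+`, lapply(21:26, function(s)
    concentration_profile(generate_network(cfg, s))$concentration)) / 6
  expect_true(all(abs(prof - 1) < 0.1))
})

test_that("periodic wrapping is idempotent and preserves pair distances", {
  dom <- c(10, 10, 10)
  set.seed(1)
  pos <- cbind(runif(50, -15, 25), runif(50, -15, 25), runif(50, 0, 10))
  w1 <- wrap_xy(pos, dom)
  expect_equal(wrap_xy(w1, dom), w1)
  expect_true(all(w1[, 1] >= 0 & w1[, 1] < 10))
  # minimum-image distances unchanged by wrapping
  d0 <- min_image(pos[1:25, ], pos[26:50, ], dom)
  d1 <- min_image(w1[1:25, ], w1[26:50, ], dom)
  expect_equal(sqrt(rowSums(d0^2)), sqrt(rowSums(d1^2)), tolerance = 1e-12)
})

test_that("relaxation reaches per-node force balance on a straight fiber", {
  cfg <- micro_config()
  # a straight fiber at rest length carries no force at all
  net <- chain_network(seq(1, 5, by = 0.5), domain = c(6, 6, 6), x = 3, y = 3)
  f <- network_forces(net, cfg)
  expect_equal(max(abs(f$total)), 0)
  rl <- relax_network(net, cfg, max_steps = 500)
  expect_equal(rl$network$pos, net$pos, tolerance = 1e-12)

  # a stretched two-node segment relaxes back to rest length
  st <- chain_network(c(2, 4.2), domain = c(6, 6, 6), x = 3, y = 3, rest = 2)
  rl2 <- relax_network(st, cfg, max_steps = 20000, force_tol = 1e-3)
  len <- abs(diff(rl2$network$pos[, 3]))
  expect_equal(len, 2, tolerance = 1e-3)
})

test_that("generated networks relax to a plateau with small residual forces", {
  cfg <- micro_config(seed = 9)
  net <- generate_network(cfg, 9)
  rl <- relax_network(net, cfg)
  expect_lt(rl$max_force, 2)
  # energy non-increasing along the relaxation trace
  expect_true(all(diff(rl$trace$energy) <= 1e-9))
  # percolation of the reference network
  expect_true(network_percolates(rl$network))
  # residual prestress is tiny relative to the loaded state: cross-plane
  # stress after relaxation stays below 1 percent of the peak under load
  resid <- abs(plane_stress(rl$network, cfg, cfg$domain[3] / 2))
  series <- run_protocol(rl$network, cfg, seed = 9)
  peak <- attr(stress_series(series), "peak")
  expect_lt(resid, 0.01 * peak)
})
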