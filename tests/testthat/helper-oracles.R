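# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately independent of the engine code paths:
# numerical gradients, brute-force pair searches and closed forms.

# Small, fast configuration for unit tests (not the desk-scale preset).
micro_config <- function(...) {
  desk_config(domain = c(6, 6, 6), fiber_length = 3, line_density = 1.2,
              load_duration = 2, post_duration = 2,
              snapshots_per_phase = 10, ...)
}

# Hand-built single-fiber chain at fixed x, y.
chain_network <- function(zs, domain = c(10, 10, 10), x = 5, y = 5,
                          rest = NULL, fixed_top = FALSE) {
  n <- length(zs)
  pos <- cbind(rep(x, n), rep(y, n), zs)
  if (is.null(rest)) rest <- abs(diff(zs))
  segs <- data.frame(a = 1:(n - 1), b = 2:n, rest = rest, fiber = 1L)
  fixed <- rep(FALSE, n)
  if (fixed_top) fixed[which.max(zs)] <- TRUE
  fiber_network(pos, fixed, segs, NULL, domain = domain)
}

# Network of independent random fibers (no crosslinks), nseg segments each,
# positions kept away from the periodic boundaries.
random_fiber_network <- function(n_fibers, nseg, seed, domain = c(10, 10, 10),
                                 jitter = 0.15, l0 = 0.5) {
  set.seed(seed)
  pos <- NULL; segs <- NULL; off <- 0L
  for (f in seq_len(n_fibers)) {
    start <- runif(3, 2.5, domain - 2.5)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    nodes <- t(sapply(0:nseg, function(j) start + j * l0 * d))
    nodes <- nodes + matrix(rnorm(length(nodes), 0, jitter), nrow(nodes))
    pos <- rbind(pos, nodes)
    segs <- rbind(segs, data.frame(a = off + 1:nseg, b = off + 2:(nseg + 1),
                                   rest = l0, fiber = f))
    off <- off + nseg + 1L
  }
  fiber_network(pos, rep(FALSE, nrow(pos)), segs, NULL, domain = domain)
}

# Two parallel vertical 1-segment fibers joined by one crosslink at mid-arc.
crosslinked_pair <- function(gap, cl_rest = gap, domain = c(10, 10, 10)) {
  pos <- rbind(c(5, 5, 4), c(5, 5, 6),
               c(5 + gap, 5, 4), c(5 + gap, 5, 6))
  segs <- data.frame(a = c(1, 3), b = c(2, 4), rest = 2, fiber = c(1L, 2L))
  cl <- data.frame(seg_a = 1L, seg_b = 2L, ta = 0.5, tb = 0.5,
                   rest = cl_rest, bound = TRUE, tension = 0)
  fiber_network(pos, rep(FALSE, 4), segs, cl, domain = domain)
}

# Central-difference gradient of a scalar function of node positions.
numerical_gradient <- function(fun, pos, h = 1e-6) {
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) for (k in 1:3) {
    pp <- pos; pp[i, k] <- pp[i, k] + h
    pm <- pos; pm[i, k] <- pm[i, k] - h
    g[i, k] <- (fun(pp) - fun(pm)) / (2 * h)
  }
  g
}

# Independent segment-segment closest distance (pure R): coarse grid over
# the two arc coordinates followed by box-constrained numerical refinement.
r_segment_distance <- function(p1, p2, q1, q2, n = 41) {
  d2fun <- function(st) {
    pa <- p1 + st[1] * (p2 - p1)
    pb <- q1 + st[2] * (q2 - q1)
    sum((pb - pa)^2)
  }
  s <- seq(0, 1, length.out = n)
  grid <- as.matrix(expand.grid(s, s))
  v <- apply(grid, 1, d2fun)
  best <- grid[which.min(v), ]
  opt <- optim(best, d2fun, method = "L-BFGS-B", lower = 0, upper = 1)
  sqrt(opt$value)
}

# Brute-force crosslink candidate count (all pairs, no cell lists).
brute_candidate_count <- function(network, reach) {
  s <- network$segments
  pos <- network$pos
  count <- 0L
  for (i in seq_len(nrow(s) - 1)) for (j in (i + 1):nrow(s)) {
    if (s$fiber[i] == s$fiber[j]) next
    d <- r_segment_distance(pos[s$a[i], ], pos[s$b[i], ],
                            pos[s$a[j], ], pos[s$b[j], ])
    if (d <= reach) count <- count + 1L
  }
  count
}
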