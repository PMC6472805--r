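# Fiber network data model: nodes, fiber chains of equal-rest-length
# segments, and crosslinks attached by (segment, arc-coordinate) pairs.

#' Construct a fiber network object
#'
#' Low-level constructor; \code{\link{generate_network}} is the usual entry
#' point. Validates connectivity (no dangling references, chain topology).
#'
#' @param pos n x 3 matrix of node positions, um.
#' @param fixed Logical vector, nodes pinned at the +z boundary.
#' @param segments Data frame with columns \code{a}, \code{b} (node indices),
#'   \code{rest} (um), \code{fiber} (fiber id).
#' @param crosslinks Data frame with columns \code{seg_a}, \code{seg_b},
#'   \code{ta}, \code{tb}, \code{rest}, \code{bound}, \code{tension}; may
#'   have zero rows.
#' @param domain \code{c(Lxy, Lxy, Lz)}, um.
#' @param arm_length Crosslink arm length, um.
#' @return A \code{fiber_network}.
#' @export
fiber_network <- function(pos, fixed, segments, crosslinks = NULL,
                          domain, arm_length = 0.02) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  dimnames(pos) <- NULL
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3, length(fixed) == n)
  if (is.null(crosslinks) || nrow(crosslinks) == 0) {
    crosslinks <- data.frame(seg_a = integer(), seg_b = integer(),
                             ta = numeric(), tb = numeric(),
                             rest = numeric(), bound = logical(),
                             tension = numeric())
  }
  if (any(segments$a < 1 | segments$a > n | segments$b < 1 | segments$b > n))
    stop("segment node reference out of range")
  ns <- nrow(segments)
  if (nrow(crosslinks) > 0 &&
      any(crosslinks$seg_a < 1 | crosslinks$seg_a > ns |
          crosslinks$seg_b < 1 | crosslinks$seg_b > ns))
    stop("crosslink segment reference out of range")
  if (any(segments$rest <= 0)) stop("segment rest lengths must be > 0")
  net <- structure(list(
    pos = pos,
    fixed = as.logical(fixed),
    segments = segments,
    crosslinks = crosslinks,
    triplets = chain_triplets(segments),
    domain = domain,
    arm_length = arm_length,
    total_rest_length = sum(segments$rest)
  ), class = "fiber_network")
  net
}

# Interior-node triplets (n1, n2, n3) of each fiber chain, for bending.
# Boundary stub segments (flagged in segments$stub) hinge freely: a fiber
# cut at a z wall has no bending stiffness across the cut.
chain_triplets <- function(segments) {
  out <- matrix(integer(), 0, 3)
  stub <- if (is.null(segments$stub)) rep(FALSE, nrow(segments)) else segments$stub
  for (f in split(data.frame(segments, .stub = stub), segments$fiber)) {
    if (nrow(f) < 2) next
    # chain order: segments stored consecutively along each fiber
    nodes <- c(f$a[1], f$b)
    k <- length(nodes)
    tri <- cbind(nodes[1:(k - 2)], nodes[2:(k - 1)], nodes[3:k])
    keep <- !(f$.stub[1:(k - 2)] | f$.stub[2:(k - 1)])
    out <- rbind(out, tri[keep, , drop = FALSE])
  }
  storage.mode(out) <- "integer"
  out
}

#' Generate a random crosslinked fiber network
#'
#' Fibers nucleate at uniform random positions with uniform random
#' orientations and grow as straight chains of equal-rest-length segments;
#' chains are truncated at the z boundaries (x, y are periodic). Fibers are
#' added until the target total length \code{line_density * volume} is
#' reached to within one segment. Crosslink candidates are all distinct-fiber
#' segment pairs within \code{crosslink_reach} at closest approach; a
#' fraction \code{crosslink_base_fraction * crosslink_density_rel} of them,
#' sampled at random, becomes crosslinks, attached at the closest-approach
#' points with spring rest length equal to the formation-time separation
#' (prestress-free formation). Fiber end nodes within \code{capture_margin}
#' of z = Lz are pinned.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed RNG seed; defaults to \code{config$seed}. Identical
#'   config + seed gives a byte-identical network.
#' @return A \code{fiber_network}.
#' @export
generate_network <- function(config, seed = config$seed) {
  set.seed(seed)
  Lxy <- config$domain[1]; Lz <- config$domain[3]
  V <- Lxy * Lxy * Lz
  target <- config$line_density * V
  l0 <- config$segment_length
  nseg_nom <- max(2L, round(config$fiber_length / l0))

  pos_list <- list(); seg_list <- list()
  total <- 0; fiber_id <- 0L; node_off <- 0L
  # Nucleation sites are drawn from a z-extended slab so that clipping
  # fibers at the z boundaries leaves the in-domain length density uniform
  # (clipping a stationary line process preserves its intensity).
  z_margin <- nseg_nom * l0
  while (total < target - l0) {
    start <- c(runif(1, 0, Lxy), runif(1, 0, Lxy),
               runif(1, -z_margin, Lz + z_margin))
    u <- random_unit_vector()
    zs <- start[3] + (0:nseg_nom) * l0 * u[3]
    ok <- which(zs >= 0 & zs <= Lz)
    if (length(ok) < 2) next             # need at least 1 in-domain segment
    idx <- (min(ok) - 1L):(max(ok) - 1L) # contiguous: z is monotone along u
    nodes <- cbind(start[1] + idx * l0 * u[1],
                   start[2] + idx * l0 * u[2],
                   start[3] + idx * l0 * u[3])
    rests <- rep(l0, nrow(nodes) - 1L)
    stubs <- rep(FALSE, nrow(nodes) - 1L)
    # exact clipping at the z walls: terminal stub segments ending on the
    # boundary keep the in-domain density uniform (short stubs are dropped)
    if (abs(u[3]) > 1e-9) {
      zf <- nodes[1, 3]; zl <- nodes[nrow(nodes), 3]
      if (min(ok) > 1L) {
        stub <- if (u[3] > 0) zf / u[3] else (zf - Lz) / u[3]
        if (stub >= 0.4 * l0) {
          nodes <- rbind(nodes[1, ] - u * stub, nodes)
          rests <- c(stub, rests)
          stubs <- c(TRUE, stubs)
        }
      }
      if (max(ok) < length(zs)) {
        stub <- if (u[3] > 0) (Lz - zl) / u[3] else -zl / u[3]
        if (stub >= 0.4 * l0) {
          nodes <- rbind(nodes, nodes[nrow(nodes), ] + u * stub)
          rests <- c(rests, stub)
          stubs <- c(stubs, TRUE)
        }
      }
    }
    # never overshoot the target total length by more than one segment
    room <- target + l0 - total
    if (sum(rests) > room) {
      m <- max(1L, sum(cumsum(rests) <= room))
      nodes <- nodes[1:(m + 1L), , drop = FALSE]
      rests <- rests[1:m]
      stubs <- stubs[1:m]
    }
    keep <- nrow(nodes)
    nodes[, 1] <- nodes[, 1] %% Lxy
    nodes[, 2] <- nodes[, 2] %% Lxy
    fiber_id <- fiber_id + 1L
    pos_list[[fiber_id]] <- nodes
    seg_list[[fiber_id]] <- data.frame(
      a = node_off + 1:(keep - 1L),
      b = node_off + 2:keep,
      rest = rests, fiber = fiber_id, stub = stubs)
    node_off <- node_off + keep
    total <- total + sum(rests)
  }
  pos <- do.call(rbind, pos_list)
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL

  # pin fiber end nodes adjacent to the +z boundary
  fixed <- rep(FALSE, nrow(pos))
  for (f in seg_list) {
    ends <- c(f$a[1], f$b[nrow(f)])
    fixed[ends[pos[ends, 3] >= Lz - config$capture_margin]] <- TRUE
  }

  net <- fiber_network(pos, fixed, segments, NULL,
                       domain = config$domain, arm_length = config$arm_length)

  cand <- crosslink_candidates(net, config$crosslink_reach)
  frac <- config$crosslink_base_fraction * config$crosslink_density_rel
  n_req <- round(frac * nrow(cand))
  if (frac > 1) {
    stop(sprintf(paste0(
      "requested crosslink density %.3gx exceeds the candidate pool: ",
      "achievable maximum is %.3gx (%d candidate pairs)"),
      config$crosslink_density_rel, 1 / config$crosslink_base_fraction,
      nrow(cand)))
  }
  if (n_req > 0) {
    pick <- sort(sample.int(nrow(cand), n_req))
    cl <- cand[pick, , drop = FALSE]
    net$crosslinks <- data.frame(
      seg_a = cl$seg_a, seg_b = cl$seg_b, ta = cl$ta, tb = cl$tb,
      rest = cl$dist,                 # formed unstrained at current geometry
      bound = TRUE, tension = 0)
    rownames(net$crosslinks) <- NULL
  }
  net$n_candidates <- nrow(cand)
  net
}

#' Candidate crosslink pairs
#'
#' All pairs of segments on distinct fibers whose closest-approach distance
#' (minimum image in x, y) is at most \code{reach}, with the closest-approach
#' arc coordinates.
#'
#' @param network A \code{fiber_network}.
#' @param reach Capture distance, um.
#' @return Data frame \code{seg_a, seg_b, ta, tb, dist}.
#' @export
crosslink_candidates <- function(network, reach) {
  s <- network$segments
  cand <- cpp_candidate_pairs(network$pos,
                              as.integer(s$a - 1L), as.integer(s$b - 1L),
                              s$rest, as.integer(s$fiber - 1L),
                              network$domain[1], network$domain[3], reach)
  cand[order(cand$seg_a, cand$seg_b), , drop = FALSE]
}

random_unit_vector <- function() {
  z <- runif(1, -1, 1)
  phi <- runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

#' Relax a network to its prestress-free reference state
#'
#' Integrates the overdamped dynamics with no external loading and crosslink
#' kinetics disabled until the total elastic energy plateaus (relative change
#' below \code{energy_tol} between checks) and the maximum nodal force drops
#' below \code{force_tol}.
#'
#' @param network A \code{fiber_network}.
#' @param config A \code{\link{sim_config}}.
#' @param max_steps,check_every Iteration budget and plateau check cadence.
#' @param energy_tol Relative energy-change tolerance per check window.
#' @param force_tol Max nodal force tolerance, pN.
#' @return List with the relaxed \code{network} and a \code{trace} data frame
#'   (step, energy, max_force).
#' @export
relax_network <- function(network, config, max_steps = 60000L,
                          check_every = 200L, energy_tol = 2e-3,
                          force_tol = 2) {
  a <- engine_args(network, config)
  res <- cpp_relax(a$pos, a$fixed, a$sa, a$sb, a$srest, a$sfib,
                   a$t1, a$t2, a$t3, a$ca, a$cb, a$cta, a$ctb, a$crest,
                   a$cbound, a$par, as.integer(max_steps),
                   as.integer(check_every), energy_tol, force_tol)
  if (!res$converged)
    stop(sprintf(paste0("relax_network did not reach the plateau in %d steps ",
                        "(max force %.3g pN, tolerance %.3g pN)"),
                 max_steps, res$max_force, force_tol))
  network$pos <- res$pos
  list(network = network, trace = res$trace, steps = res$steps,
       max_force = res$max_force)
}

#' Network percolation check
#'
#' Whether the crosslink connectivity graph contains a component linking the
#' loading region (any fiber with a node below \code{zone_depth}) to the
#' pinned +z boundary.
#'
#' @param network A \code{fiber_network}.
#' @param zone_depth Loading zone depth, um.
#' @return Logical.
#' @export
network_percolates <- function(network, zone_depth = 2) {
  s <- network$segments
  nf <- max(s$fiber)
  cl <- network$crosslinks
  if (nrow(cl) == 0) return(FALSE)
  ef <- cbind(s$fiber[cl$seg_a], s$fiber[cl$seg_b])
  g <- igraph::graph_from_edgelist(ef, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nf - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  has_node_below <- tapply(network$pos[c(s$a, s$b), 3] < zone_depth,
                           c(s$fiber, s$fiber), any)
  fixed_fiber <- tapply(network$fixed[c(s$a, s$b)], c(s$fiber, s$fiber), any)
  any(vapply(seq_len(max(comp)), function(k) {
    f <- which(comp == k)
    any(has_node_below[f]) && any(fixed_fiber[f])
  }, logical(1)))
}

# Flatten a network + config into the 0-based argument list of the C++ engine
engine_args <- function(network, config, loading = FALSE) {
  s <- network$segments
  cl <- network$crosslinks
  tri <- network$triplets
  list(
    pos = network$pos,
    fixed = network$fixed,
    sa = as.integer(s$a - 1L), sb = as.integer(s$b - 1L),
    srest = as.numeric(s$rest), sfib = as.integer(s$fiber - 1L),
    t1 = as.integer(tri[, 1] - 1L), t2 = as.integer(tri[, 2] - 1L),
    t3 = as.integer(tri[, 3] - 1L),
    ca = as.integer(cl$seg_a - 1L), cb = as.integer(cl$seg_b - 1L),
    cta = as.numeric(cl$ta), ctb = as.numeric(cl$tb),
    crest = as.numeric(cl$rest), cbound = as.logical(cl$bound),
    par = engine_params(config),
    loading = loading
  )
}

engine_params <- function(config) {
  list(kappa_e = config$kappa_e, kappa_b = config$kappa_b,
       kappa_cl = config$kappa_cl, diameter = config$diameter,
       k_rep = config$k_rep, rep_cap = config$rep_cap,
       Lxy = config$domain[1], Lz = config$domain[3],
       zone_depth = config$zone_depth,
       force_per_site = config$force_per_site,
       per_fiber = identical(config$load_mode, "per_fiber"),
       zeta = config$zeta, dt = config$dt, cap_disp = config$cap_disp,
       ku0 = config$ku0, lambda = config$lambda, kBT = config$kBT,
       exp_cap = config$exp_cap,
       rebind_rate = config$rebind_rate, rebind_reach = config$rebind_reach,
       skin = config$skin, nlist_every = config$nlist_every)
}

#' Wrap x,y coordinates into the periodic box
#'
#' Idempotent periodic wrapping; z is untouched.
#'
#' @param pos n x 3 position matrix.
#' @param domain \code{c(Lxy, Lxy, Lz)}.
#' @return Wrapped position matrix.
#' @export
wrap_xy <- function(pos, domain) {
  pos[, 1] <- pos[, 1] %% domain[1]
  pos[, 2] <- pos[, 2] %% domain[1]
  pos
}

#' Minimum-image displacement between points
#'
#' @param from,to n x 3 matrices (or 3-vectors).
#' @param domain \code{c(Lxy, Lxy, Lz)}.
#' @return Displacement matrix applying the minimum-image convention in x, y.
#' @export
min_image <- function(from, to, domain) {
  if (is.null(dim(from))) from <- matrix(from, ncol = 3)
  if (is.null(dim(to))) to <- matrix(to, ncol = 3)
  d <- to - from
  L <- domain[1]
  d[, 1] <- d[, 1] - L * round(d[, 1] / L)
  d[, 2] <- d[, 2] - L * round(d[, 2] / L)
  d
}

#' @export
print.fiber_network <- function(x, ...) {
  cat("<fiber_network>\n")
  cat(sprintf("  nodes      : %d (%d pinned at +z)\n", nrow(x$pos), sum(x$fixed)))
  cat(sprintf("  fibers     : %d, segments %d, total rest length %.1f um\n",
              length(unique(x$segments$fiber)), nrow(x$segments),
              x$total_rest_length))
  cat(sprintf("  crosslinks : %d (%d bound)\n",
              nrow(x$crosslinks), sum(x$crosslinks$bound)))
  cat(sprintf("  domain     : %g x %g x %g um\n",
              x$domain[1], x$domain[2], x$domain[3]))
  invisible(x)
}
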