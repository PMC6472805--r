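# Simulation readouts: concentration profiles along the loading axis,
# accumulation time series, cross-plane stress, and parameter sweeps.

#' Fiber concentration profile along the loading axis
#'
#' Fiber material (rest length, the conserved material measure) is
#' distributed over z bins in proportion to each segment's geometric overlap
#' with the bin, then normalized by the uniform initial density
#' \code{total_rest_length / Lz}, so a homogeneous network reads 1 in every
#' bin and the length-weighted mean over bins is exactly 1 at all times.
#'
#' @param network A \code{fiber_network} (a snapshot state).
#' @param bin_width Bin width, um (default 1).
#' @return Data frame: \code{z_lo}, \code{z_hi}, \code{concentration}.
#' @export
concentration_profile <- function(network, bin_width = 1) {
  Lz <- network$domain[3]
  edges <- seq(0, Lz, by = bin_width)
  if (abs(edges[length(edges)] - Lz) > 1e-9) edges <- c(edges, Lz)
  s <- network$segments
  z1 <- pmin(pmax(network$pos[s$a, 3], 0), Lz)
  z2 <- pmin(pmax(network$pos[s$b, 3], 0), Lz)
  lo <- pmin(z1, z2); hi <- pmax(z1, z2)
  ext <- hi - lo
  nb <- length(edges) - 1
  len <- numeric(nb)
  point_like <- ext < 1e-12
  if (any(point_like)) {
    bin_idx <- pmin(nb, pmax(1L, findInterval(lo[point_like], edges,
                                              rightmost.closed = TRUE)))
    tab <- tapply(s$rest[point_like], bin_idx, sum)
    len[as.integer(names(tab))] <- len[as.integer(names(tab))] + tab
  }
  if (any(!point_like)) {
    loi <- lo[!point_like]; hii <- hi[!point_like]
    exti <- ext[!point_like]; resti <- s$rest[!point_like]
    for (b in seq_len(nb)) {
      ov <- pmin(hii, edges[b + 1]) - pmax(loi, edges[b])
      ov[ov < 0] <- 0
      len[b] <- len[b] + sum(resti * ov / exti)
    }
  }
  widths <- diff(edges)
  rho0 <- network$total_rest_length / Lz
  data.frame(z_lo = edges[-length(edges)], z_hi = edges[-1],
             concentration = (len / widths) / rho0)
}

#' Concentration profiles for every snapshot of a run
#'
#' @param series A \code{network_time_series}.
#' @param bin_width Bin width, um.
#' @return Matrix (snapshots x bins) plus attributes \code{t_norm},
#'   \code{edges}.
#' @export
profile_series <- function(series, bin_width = 1) {
  n <- length(series$time)
  first <- concentration_profile(snapshot_network(series, 1), bin_width)
  out <- matrix(NA_real_, n, nrow(first))
  out[1, ] <- first$concentration
  for (i in seq_len(n)[-1])
    out[i, ] <- concentration_profile(snapshot_network(series, i),
                                      bin_width)$concentration
  attr(out, "t_norm") <- series$t_norm
  attr(out, "edges") <- c(first$z_lo, first$z_hi[nrow(first)])
  out
}

#' Normalized concentration in the accumulation region vs time
#'
#' Mean normalized fiber concentration within \code{region_depth} of the
#' loading boundary (z = 0) at each snapshot.
#'
#' @param series A \code{network_time_series}.
#' @param region_depth Accumulation region depth, um (3 and 5 are the
#'   conventional choices).
#' @return Data frame: \code{t_norm}, \code{concentration}.
#' @export
accumulation_timeseries <- function(series, region_depth = 3) {
  stopifnot(region_depth > 0)
  Lz <- series$network$domain[3]
  rho0 <- series$network$total_rest_length / Lz
  n <- length(series$time)
  conc <- vapply(seq_len(n), function(i) {
    net <- snapshot_network(series, i)
    s <- net$segments
    z1 <- pmin(pmax(net$pos[s$a, 3], 0), Lz)
    z2 <- pmin(pmax(net$pos[s$b, 3], 0), Lz)
    lo <- pmin(z1, z2); hi <- pmax(z1, z2)
    ext <- hi - lo
    ov <- pmin(hi, region_depth) - pmax(lo, 0)
    ov[ov < 0] <- 0
    w <- ifelse(ext < 1e-12, as.numeric(lo < region_depth), ov / pmax(ext, 1e-12))
    sum(s$rest * w) / region_depth / rho0
  }, numeric(1))
  data.frame(t_norm = series$t_norm, concentration = conc)
}

#' Peak normalized concentration in the accumulation region
#'
#' @inheritParams accumulation_timeseries
#' @return Maximum of \code{\link{accumulation_timeseries}} over time.
#' @export
peak_concentration <- function(series, region_depth = 3) {
  max(accumulation_timeseries(series, region_depth)$concentration)
}

#' Cross-plane stress
#'
#' Sum of the normal (z) components of the axial forces carried by fiber
#' segments crossing the plane z = \code{z_plane} (tension positive), plus
#' the analogous contribution of crosslinks crossing the plane, divided by
#' the plane area. In pN/um^2, i.e. Pa.
#'
#' @param network A \code{fiber_network} snapshot.
#' @param config A \code{\link{sim_config}} (for stiffnesses).
#' @param z_plane Plane position, um; must lie inside the domain.
#' @return Stress, Pa.
#' @export
plane_stress <- function(network, config, z_plane) {
  Lz <- network$domain[3]
  if (z_plane <= 0 || z_plane >= Lz)
    stop("z_plane must lie strictly inside the domain (0, ", Lz, ")")
  area <- network$domain[1]^2
  s <- network$segments
  pos <- network$pos
  d <- min_image(pos[s$a, , drop = FALSE], pos[s$b, , drop = FALSE],
                 network$domain)
  len <- sqrt(rowSums(d^2))
  z1 <- pos[s$a, 3]; z2 <- pos[s$b, 3]
  crossing <- (z1 - z_plane) * (z2 - z_plane) < 0
  total <- 0
  if (any(crossing)) {
    tension <- config$kappa_e * (len[crossing] - s$rest[crossing])
    uz <- abs(d[crossing, 3]) / len[crossing]
    total <- total + sum(tension * uz)
  }
  cl <- network$crosslinks
  if (nrow(cl) > 0 && any(cl$bound)) {
    cb <- cl[cl$bound, , drop = FALSE]
    pa <- pos[s$a[cb$seg_a], , drop = FALSE] +
      min_image(pos[s$a[cb$seg_a], , drop = FALSE],
                pos[s$b[cb$seg_a], , drop = FALSE], network$domain) * cb$ta
    pb <- pos[s$a[cb$seg_b], , drop = FALSE] +
      min_image(pos[s$a[cb$seg_b], , drop = FALSE],
                pos[s$b[cb$seg_b], , drop = FALSE], network$domain) * cb$tb
    dcl <- min_image(pa, pb, network$domain)
    lcl <- sqrt(rowSums(dcl^2))
    crossing_cl <- (pa[, 3] - z_plane) * (pa[, 3] + dcl[, 3] - z_plane) < 0
    if (any(crossing_cl)) {
      f <- config$kappa_cl * (lcl[crossing_cl] - cb$rest[crossing_cl])
      uz <- abs(dcl[crossing_cl, 3]) / pmax(lcl[crossing_cl], 1e-12)
      total <- total + sum(f * uz)
    }
  }
  total / area
}

#' Cross-plane stress for every snapshot
#'
#' @param series A \code{network_time_series}.
#' @param z_plane Plane position, um; defaults to mid-domain.
#' @return A \code{stress_series} data frame: \code{t_norm}, \code{stress}
#'   (Pa), with attributes \code{peak} and \code{z_plane}.
#' @export
stress_series <- function(series, z_plane = series$network$domain[3] / 2) {
  n <- length(series$time)
  st <- vapply(seq_len(n), function(i)
    plane_stress(snapshot_network(series, i), series$config, z_plane),
    numeric(1))
  out <- data.frame(t_norm = series$t_norm, stress = st)
  attr(out, "peak") <- max(st)
  attr(out, "z_plane") <- z_plane
  class(out) <- c("stress_series", "data.frame")
  out
}

#' Stress retention ratio
#'
#' Stress immediately before loading stops (last snapshot with normalized
#' time <= 1) divided by the peak stress during loading. Near 1 for stable,
#' plateauing stress; small when the stress peaks early and decays through
#' crosslink unbinding.
#'
#' @param stress A \code{\link{stress_series}} (or data frame with
#'   \code{t_norm}, \code{stress}) covering normalized time [0, 1].
#' @return Ratio in [0, 1], or \code{NA} if the series is identically zero.
#' @export
stress_retention_ratio <- function(stress) {
  in_load <- stress$t_norm <= 1 + 1e-9
  s <- stress$stress[in_load]
  if (all(abs(s) < 1e-12)) return(NA_real_)
  s[length(s)] / max(s)
}

#' Parameter sweep over loading or crosslink properties
#'
#' Runs the full protocol (generate, relax, load, relax) for each value of
#' one swept parameter and each replicate seed, and summarizes peak
#' accumulation-region concentration, peak cross-plane stress, and stress
#' retention ratio as mean +/- s.e.m. over replicates.
#'
#' @param base_config A \code{\link{sim_config}}.
#' @param axis One of \code{"force"}, \code{"crosslink_density"},
#'   \code{"ku0"}, \code{"lambda"}. For the kinetic and density axes the
#'   values are relative multipliers of the baseline.
#' @param values Positive sweep values.
#' @param replicates Replicate seeds per value (>= 1).
#' @param region_depth Accumulation region depth, um.
#' @param z_plane Stress plane, um; defaults to mid-domain.
#' @param out_dir Optional directory; when given, each run's accumulation
#'   and stress series are persisted as CSV.
#' @return List with \code{runs} (per-run metrics: peak and
#'   post-relaxation accumulation-region concentration, peak cross-plane
#'   stress, stress retention ratio) and \code{summary} (mean and s.e.m.
#'   per value). Failed runs are recorded with NA metrics and the sweep
#'   continues.
#' @export
parameter_sweep <- function(base_config,
                            axis = c("force", "crosslink_density", "ku0", "lambda"),
                            values, replicates = 3,
                            region_depth = 3,
                            z_plane = base_config$domain[3] / 2,
                            out_dir = NULL) {
  axis <- match.arg(axis)
  stopifnot(all(values > 0) || axis == "force", replicates >= 1)
  # the generated + relaxed network is independent of the force and kinetic
  # axes, so each replicate's reference network is built once and shared
  cache <- if (axis == "crosslink_density") NULL else new.env(parent = emptyenv())
  relaxed_for <- function(cfg, seed) {
    if (is.null(cache))
      return(relax_network(generate_network(cfg, seed = seed), cfg)$network)
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- relax_network(generate_network(cfg, seed = seed),
                                    cfg)$network
    cache[[key]]
  }
  rows <- list()
  for (vi in seq_along(values)) {
    v <- values[vi]
    cfg <- base_config
    switch(axis,
      force = { cfg$force_per_site <- v },
      crosslink_density = { cfg$crosslink_density_rel <- v },
      ku0 = { cfg$ku0 <- base_config$ku0 * v },
      lambda = { cfg$lambda <- base_config$lambda * v })
    for (r in seq_len(replicates)) {
      seed <- base_config$seed + r
      metrics <- tryCatch({
        net <- relaxed_for(cfg, seed)
        series <- run_protocol(net, cfg, seed = seed)
        run <- list(series = series)
        acc <- accumulation_timeseries(run$series, region_depth)
        st <- stress_series(run$series, z_plane)
        if (!is.null(out_dir)) {
          dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
          tag <- sprintf("%s_%g_rep%d", axis, v, r)
          write.csv(acc, file.path(out_dir, paste0("accumulation_", tag, ".csv")),
                    row.names = FALSE)
          write.csv(st, file.path(out_dir, paste0("stress_", tag, ".csv")),
                    row.names = FALSE)
        }
        c(peak_concentration = max(acc$concentration),
          final_concentration = acc$concentration[nrow(acc)],
          peak_stress = max(st$stress),
          retention = stress_retention_ratio(st))
      }, error = function(e) {
        warning(sprintf("sweep run (%s = %g, rep %d) failed: %s",
                        axis, v, r, conditionMessage(e)))
        c(peak_concentration = NA_real_, final_concentration = NA_real_,
          peak_stress = NA_real_, retention = NA_real_)
      })
      rows[[length(rows) + 1]] <- data.frame(
        axis = axis, value = v, replicate = r, seed = seed,
        peak_concentration = metrics[["peak_concentration"]],
        final_concentration = metrics[["final_concentration"]],
        peak_stress = metrics[["peak_stress"]],
        retention = metrics[["retention"]])
    }
  }
  runs <- do.call(rbind, rows)
  sem <- function(x) if (sum(!is.na(x)) > 1) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))) else 0
  agg <- function(metric) {
    m <- tapply(runs[[metric]], runs$value, mean, na.rm = TRUE)
    s <- tapply(runs[[metric]], runs$value, sem)
    data.frame(value = as.numeric(names(m)), mean = as.numeric(m),
               sem = as.numeric(s), metric = metric)
  }
  summary <- rbind(agg("peak_concentration"), agg("final_concentration"),
                   agg("peak_stress"), agg("retention"))
  list(runs = runs, summary = summary)
}

#' Generate, relax, and run the loading protocol in one call
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Seed for both network generation and the kinetics stream.
#' @return List: \code{series} (a \code{network_time_series}),
#'   \code{network} (the relaxed pre-load network), \code{relax_trace}.
#' @export
simulate_remodeling <- function(config, seed = config$seed) {
  net <- generate_network(config, seed = seed)
  rl <- relax_network(net, config)
  series <- run_protocol(rl$network, config, seed = seed)
  list(series = series, network = rl$network, relax_trace = rl$trace)
}
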