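# Loading protocol: dynamic filopodial zone loading near z = 0, followed by
# force cessation and relaxation (the in-silico analogue of
# decellularization). Normalized time: 0 = loading onset, 1 = cessation.

#' Build a load schedule
#'
#' @param load_duration Active loading duration, s.
#' @param post_duration Post-loading relaxation duration, s; the normalized
#'   time axis then extends to \code{1 + post_duration / load_duration}.
#' @param force_per_site Load per site, pN.
#' @param zone_depth Loading zone depth above z = 0, um.
#' @return A \code{load_schedule}.
#' @export
load_schedule <- function(load_duration, post_duration,
                          force_per_site, zone_depth = 2) {
  stopifnot(load_duration > 0, post_duration > 0,
            force_per_site >= 0, zone_depth > 0)
  structure(list(
    phases = data.frame(
      kind = c("load", "relax_post"),
      duration = c(load_duration, post_duration)),
    force_per_site = force_per_site,
    zone_depth = zone_depth
  ), class = "load_schedule")
}

schedule_from_config <- function(config) {
  load_schedule(config$load_duration, config$post_duration,
                config$force_per_site, config$zone_depth)
}

#' Filopodial loading forces
#'
#' Every fiber segment whose midpoint lies within \code{zone_depth} of the
#' z = 0 boundary receives a point force of magnitude \code{force_per_site}
#' directed along -z, applied at its midpoint and split between its end
#' nodes. Segments gain or lose the load as they enter or leave the zone.
#' In \code{per_fiber} mode one site force is divided among a fiber's
#' in-zone segments.
#'
#' @param network A \code{fiber_network}.
#' @param config A \code{\link{sim_config}} (or a \code{load_schedule} plus
#'   \code{config} for mechanics).
#' @return List: \code{forces} (n x 3 external force matrix, pN) and
#'   \code{n_in_zone} (count of loaded segments).
#' @export
filopodial_forces <- function(network, config) {
  fb <- force_breakdown(network, config, loading = TRUE)
  list(forces = fb$external, n_in_zone = fb$n_in_zone)
}

#' Enforce boundary conditions
#'
#' Pinned nodes keep their positions; x,y are wrapped by minimum image into
#' the periodic box; z is floored at the loading wall z = 0.
#'
#' @param network A \code{fiber_network}.
#' @param reference Optional position matrix to restore pinned nodes from
#'   (defaults to the network's own positions, i.e. a no-op for them).
#' @return Updated network.
#' @export
enforce_boundaries <- function(network, reference = NULL) {
  if (!is.null(reference))
    network$pos[network$fixed, ] <- reference[network$fixed, ]
  network$pos <- wrap_xy(network$pos, network$domain)
  network$pos[, 3] <- pmax(network$pos[, 3], 0)
  network
}

#' Run the full loading protocol
#'
#' Starting from a relaxed network, integrates load then post-load
#' relaxation, interleaving per step: force computation, stochastic
#' unbinding (and rebinding when enabled), Euler update. Snapshots are
#' recorded at a fixed cadence per phase.
#'
#' @param network A relaxed \code{fiber_network}.
#' @param config A \code{\link{sim_config}}.
#' @param schedule A \code{\link{load_schedule}}; defaults to the one implied
#'   by \code{config}.
#' @param seed RNG seed for the kinetics stream; defaults to
#'   \code{config$seed}.
#' @param kinetics Enable stochastic unbinding (default TRUE).
#' @return A \code{network_time_series}: snapshot positions, crosslink bound
#'   states, times (absolute and normalized), energy components, external
#'   work, unbinding/rebinding events, and run metadata.
#' @export
run_protocol <- function(network, config, schedule = NULL,
                         seed = config$seed, kinetics = TRUE) {
  if (is.null(schedule)) schedule <- schedule_from_config(config)
  cfg <- config
  cfg$force_per_site <- schedule$force_per_site
  cfg$zone_depth <- schedule$zone_depth
  set.seed(seed)

  load_dur <- schedule$phases$duration[schedule$phases$kind == "load"]
  post_dur <- schedule$phases$duration[schedule$phases$kind == "relax_post"]
  n_load <- max(1L, round(load_dur / cfg$dt))
  n_post <- max(1L, round(post_dur / cfg$dt))
  snap_load <- max(1L, n_load %/% cfg$snapshots_per_phase)
  snap_post <- max(1L, n_post %/% cfg$snapshots_per_phase)

  run_phase <- function(net, nsteps, loading, snap_every, t0) {
    a <- engine_args(net, cfg)
    cpp_run_phase(a$pos, a$fixed, a$sa, a$sb, a$srest, a$sfib,
                  a$t1, a$t2, a$t3, a$ca, a$cb, a$cta, a$ctb, a$crest,
                  a$cbound, a$par, as.integer(nsteps), loading, kinetics,
                  cfg$rebinding_enabled, as.integer(snap_every), t0)
  }

  ph1 <- run_phase(network, n_load, TRUE, snap_load, 0)
  net1 <- network
  net1$pos <- ph1$pos
  net1$crosslinks$bound <- ph1$bound
  net1$crosslinks$rest <- ph1$crest
  ph2 <- run_phase(net1, n_post, FALSE, snap_post, n_load * cfg$dt)
  net2 <- net1
  net2$pos <- ph2$pos
  net2$crosslinks$bound <- ph2$bound
  net2$crosslinks$rest <- ph2$crest

  # stitch phases; drop the duplicated snapshot at the phase boundary
  s1 <- dim(ph1$snap_pos)[3]
  s2 <- dim(ph2$snap_pos)[3]
  keep2 <- 2:s2
  time <- c(ph1$snap_time, ph2$snap_time[keep2])
  t_norm <- time / (n_load * cfg$dt)
  snap_pos <- array(c(ph1$snap_pos, ph2$snap_pos[, , keep2]),
                    dim = c(nrow(network$pos), 3, s1 + s2 - 1))
  ev1 <- ph1$events; ev2 <- ph2$events
  events <- rbind(ev1, ev2)
  events$kind <- ifelse(events$kind == 1, "rebind", "unbind")

  structure(list(
    network = network,              # topology + initial (t=0) state
    final_network = net2,
    config = cfg,
    schedule = schedule,
    time = time,
    t_norm = t_norm,
    phase = c(rep("load", s1), rep("relax_post", s2 - 1)),
    snap_pos = snap_pos,
    snap_bound = rbind(ph1$snap_bound,
                       ph2$snap_bound[keep2, , drop = FALSE]),
    energy = c(ph1$snap_energy, ph2$snap_energy[keep2]),
    energies = rbind(ph1$snap_energies, ph2$snap_energies[keep2, , drop = FALSE]),
    ext_work = c(ph1$snap_work, ph2$snap_work[keep2] + ph1$snap_work[s1]),
    bound_count = c(ph1$snap_bound_count, ph2$snap_bound_count[keep2]),
    n_in_zone = c(ph1$snap_in_zone, ph2$snap_in_zone[keep2]),
    events = events,
    max_kudt = max(ph1$max_kudt, ph2$max_kudt),
    seed = seed
  ), class = "network_time_series")
}

#' @export
print.network_time_series <- function(x, ...) {
  cat("<network_time_series>\n")
  cat(sprintf("  snapshots : %d over t_norm [%.2f, %.2f]\n",
              length(x$time), min(x$t_norm), max(x$t_norm)))
  cat(sprintf("  loading   : %g pN, zone %g um\n",
              x$schedule$force_per_site, x$schedule$zone_depth))
  cat(sprintf("  crosslinks: %d -> %d bound; %d unbinding events\n",
              x$bound_count[1], x$bound_count[length(x$bound_count)],
              sum(x$events$kind == "unbind")))
  if (x$max_kudt > 0.1)
    cat(sprintf("  note      : max k_u*dt = %.3g exceeded 0.1 (saturating unbinding)\n",
                x$max_kudt))
  invisible(x)
}

# Network state at snapshot i of a series
snapshot_network <- function(series, i) {
  net <- series$network
  net$pos <- series$snap_pos[, , i]
  if (nrow(net$crosslinks) > 0)
    net$crosslinks$bound <- series$snap_bound[i, ] != 0
  net
}
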