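# Simulation configuration for the discrete fiber-network engine.
#
# Kinetic and drag baselines (zero-force unbinding rate, mechanosensitivity,
# drag, time step, absolute crosslink density) have no settled literature
# values; they are exposed as explicit defaults flagged "assumed", and
# relative sweep factors (0.1x, 0.3x, ...) multiply these baselines.

.kB <- 1.380649e-5  # pN um / K

# Parameters whose defaults are package assumptions rather than published
# values; load_config() warns when a run relies on them.
.assumed_params <- c(
  "kappa_cl", "zeta", "dt", "ku0", "lambda", "line_density",
  "crosslink_reach", "crosslink_base_fraction", "k_rep", "rebind_rate",
  "rebind_reach", "load_duration", "post_duration", "segment_length",
  "fiber_length"
)

#' Discrete network simulation configuration
#'
#' Builds and validates the full parameter set for network generation,
#' mechanics, crosslink kinetics and the loading protocol. Mechanical
#' stiffnesses default to values derived from the fiber material modulus:
#' \code{kappa_e = E A / l0} and \code{kappa_b = E I / l0} with
#' \code{A = pi d^2 / 4} and \code{I = pi d^4 / 64}; both can be overridden.
#'
#' @param E_fiber Fiber Young's modulus, Pa (default 125e6).
#' @param diameter Fiber diameter, um (default 0.1).
#' @param segment_length Rest length of one fiber segment, um.
#' @param fiber_length Nominal fiber length, um.
#' @param line_density Target total fiber length per unit volume, um^-2.
#' @param domain Domain edge lengths \code{c(Lxy, Lxy, Lz)}, um. x and y are
#'   periodic; fiber ends near z = Lz are pinned; loading acts near z = 0.
#' @param kappa_e Extensional stiffness, pN/um; \code{NULL} derives from
#'   \code{E_fiber}.
#' @param kappa_b Bending stiffness, pN um; \code{NULL} derives from
#'   \code{E_fiber}.
#' @param kappa_cl Crosslink spring stiffness, pN/um (assumed).
#' @param arm_length Crosslink arm length, um; a crosslink has two arms.
#' @param crosslink_density_rel Relative crosslink density (1 = baseline).
#' @param crosslink_base_fraction Fraction of candidate contact pairs
#'   converted to crosslinks at density 1x (assumed baseline).
#' @param crosslink_reach Capture distance for crosslink formation at
#'   gelation, um (assumed).
#' @param zeta Drag coefficient per node, pN s/um (assumed).
#' @param dt Integration time step, s (assumed).
#' @param temperature Temperature, K.
#' @param ku0 Zero-force crosslink unbinding rate, 1/s (assumed 1x baseline).
#' @param lambda Crosslink mechanosensitivity, um (assumed 1x baseline).
#' @param exp_cap Cap on the Bell exponent to guard overflow.
#' @param force_per_site Filopodial load per fiber segment in the zone, pN.
#' @param zone_depth Depth of the loading zone above z = 0, um.
#' @param load_mode \code{"per_segment"} (default) or \code{"per_fiber"}.
#' @param load_duration Duration of active loading, s.
#' @param post_duration Duration of the post-loading relaxation, s. The
#'   normalized time axis reaches \code{1 + post_duration/load_duration}.
#' @param rebinding_enabled Allow unbound crosslinks to rebind.
#' @param rebind_rate Rebinding rate when within reach, 1/s.
#' @param rebind_reach Maximum attachment separation for rebinding, um.
#' @param k_rep Volume-exclusion overlap penalty stiffness, pN/um.
#' @param rep_cap Cap on the repulsive force, pN.
#' @param skin Neighbor-list skin distance, um.
#' @param nlist_every Fallback neighbor list rebuild cadence, steps.
#' @param snapshots_per_phase Snapshots recorded per protocol phase.
#' @param capture_margin Fiber ends within this distance of z = Lz are
#'   pinned, um; defaults to one segment length.
#' @param cap_disp Per-step displacement stability cap, um; defaults to
#'   one tenth of the segment length.
#' @param seed Default RNG seed for runs using this configuration.
#'
#' @return An object of class \code{sim_config} (a validated named list with
#'   derived fields \code{kBT}, \code{kappa_e}, \code{kappa_b},
#'   \code{cap_disp} filled in).
#' @export
sim_config <- function(E_fiber = 125e6,
                       diameter = 0.1,
                       segment_length = 0.5,
                       fiber_length = 8,
                       line_density = 1.7,
                       domain = c(20, 20, 20),
                       kappa_e = NULL,
                       kappa_b = NULL,
                       kappa_cl = 1000,
                       arm_length = 0.02,
                       crosslink_density_rel = 1,
                       crosslink_base_fraction = 0.5,
                       crosslink_reach = 0.3,
                       zeta = 50,
                       dt = 1e-6,
                       temperature = 310,
                       ku0 = 0.01,
                       lambda = 1e-4,
                       exp_cap = 40,
                       force_per_site = 100,
                       zone_depth = 2,
                       load_mode = c("per_segment", "per_fiber"),
                       load_duration = 20,
                       post_duration = 25,
                       rebinding_enabled = FALSE,
                       rebind_rate = 10,
                       rebind_reach = 0.1,
                       k_rep = 1000,
                       rep_cap = 1000,
                       skin = 0.1,
                       nlist_every = 10,
                       snapshots_per_phase = 50,
                       capture_margin = NULL,
                       cap_disp = NULL,
                       seed = 1L) {
  load_mode <- match.arg(load_mode)
  A <- pi * diameter^2 / 4
  I <- pi * diameter^4 / 64
  # pN/um^2 == Pa, so E in Pa works directly in pN-um units
  if (is.null(kappa_e)) kappa_e <- E_fiber * A / segment_length
  if (is.null(kappa_b)) kappa_b <- E_fiber * I / segment_length
  if (is.null(capture_margin)) capture_margin <- segment_length
  if (is.null(cap_disp)) cap_disp <- segment_length / 10
  cfg <- list(
    E_fiber = E_fiber, diameter = diameter,
    segment_length = segment_length, fiber_length = fiber_length,
    line_density = line_density, domain = domain,
    kappa_e = kappa_e, kappa_b = kappa_b, kappa_cl = kappa_cl,
    arm_length = arm_length,
    crosslink_density_rel = crosslink_density_rel,
    crosslink_base_fraction = crosslink_base_fraction,
    crosslink_reach = crosslink_reach,
    zeta = zeta, dt = dt, temperature = temperature,
    kBT = .kB * temperature,
    ku0 = ku0, lambda = lambda, exp_cap = exp_cap,
    force_per_site = force_per_site, zone_depth = zone_depth,
    load_mode = load_mode,
    load_duration = load_duration, post_duration = post_duration,
    rebinding_enabled = rebinding_enabled,
    rebind_rate = rebind_rate, rebind_reach = rebind_reach,
    k_rep = k_rep, rep_cap = rep_cap, skin = skin,
    nlist_every = as.integer(nlist_every),
    snapshots_per_phase = as.integer(snapshots_per_phase),
    capture_margin = capture_margin,
    cap_disp = cap_disp,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  nonneg <- c("kappa_e", "kappa_b", "kappa_cl", "zeta", "dt", "ku0", "lambda",
              "force_per_site", "zone_depth", "load_duration", "post_duration",
              "rebind_rate", "k_rep", "crosslink_density_rel")
  for (f in nonneg)
    if (cfg[[f]] < 0) stop("sim_config: '", f, "' must be >= 0", call. = FALSE)
  if (cfg$temperature <= 0) stop("sim_config: temperature must be > 0", call. = FALSE)
  if (cfg$dt <= 0) stop("sim_config: dt must be > 0", call. = FALSE)
  if (cfg$zeta <= 0) stop("sim_config: zeta must be > 0", call. = FALSE)
  if (cfg$segment_length <= 0 || cfg$diameter <= 0)
    stop("sim_config: segment_length and diameter must be > 0", call. = FALSE)
  if (length(cfg$domain) != 3 || any(cfg$domain <= 0) ||
      cfg$domain[1] != cfg$domain[2])
    stop("sim_config: domain must be c(Lxy, Lxy, Lz) with positive entries",
         call. = FALSE)
  # zero-force kinetics must be well resolved by the time step
  if (cfg$ku0 * cfg$dt >= 0.1)
    stop("sim_config: ku0 * dt must be < 0.1 (zero-force unbinding per step)",
         call. = FALSE)
  invisible(cfg)
}

#' Desk-scale simulation preset
#'
#' A reduced problem size used for sweeps and property checks: a 10x10x10 um
#' domain, 5 um fibers, and a coarse-grained axial stiffness (1e4 pN/um)
#' at which fiber stretch stays below ~2 percent for the force range studied
#' while permitting a tractable explicit time step. All arguments of
#' \code{\link{sim_config}} may be overridden.
#'
#' @param ... Overrides passed to \code{\link{sim_config}}.
#' @return A \code{sim_config}.
#' @export
desk_config <- function(...) {
  defaults <- list(
    domain = c(10, 10, 10), fiber_length = 5,
    kappa_e = 5e3, kappa_b = 500, kappa_cl = 500, k_rep = 500,
    zeta = 20, dt = 1e-3, load_duration = 8, post_duration = 10,
    crosslink_base_fraction = 0.35, capture_margin = 1,
    cap_disp = 0.3,
    snapshots_per_phase = 40
  )
  args <- modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  domain       : %g x %g x %g um (periodic x,y)\n",
              x$domain[1], x$domain[2], x$domain[3]))
  cat(sprintf("  fibers       : L=%g um, segments %g um, d=%g um, line density %g um^-2\n",
              x$fiber_length, x$segment_length, x$diameter, x$line_density))
  cat(sprintf("  stiffness    : kappa_e=%.4g pN/um, kappa_b=%.4g pN um, kappa_cl=%.4g pN/um\n",
              x$kappa_e, x$kappa_b, x$kappa_cl))
  cat(sprintf("  kinetics     : ku0=%.3g 1/s, lambda=%.3g um, kBT=%.4g pN um\n",
              x$ku0, x$lambda, x$kBT))
  cat(sprintf("  crosslinks   : density %gx, reach %g um, arms 2 x %g um\n",
              x$crosslink_density_rel, x$crosslink_reach, x$arm_length))
  cat(sprintf("  loading      : %g pN %s, zone %g um, load %gs + post %gs\n",
              x$force_per_site, x$load_mode, x$zone_depth,
              x$load_duration, x$post_duration))
  cat(sprintf("  integration  : dt=%.3g s, zeta=%g pN s/um\n", x$dt, x$zeta))
  invisible(x)
}
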