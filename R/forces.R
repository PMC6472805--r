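# R-level surface over the compiled force kernels. Each force term is the
# negative gradient of its potential; all internal terms obey action-reaction
# so internal forces sum to zero over the whole network.

force_breakdown <- function(network, config, loading = FALSE) {
  a <- engine_args(network, config)
  cpp_forces(a$pos, a$fixed, a$sa, a$sb, a$srest, a$sfib,
             a$t1, a$t2, a$t3, a$ca, a$cb, a$cta, a$ctb, a$crest, a$cbound,
             a$par, loading, TRUE)
}

#' Stretch (extensional) forces
#'
#' Each segment acts as a linear spring: potential \eqn{U_s = \kappa_e
#' \Delta r^2 / 2} with \eqn{\Delta r} the deviation from rest length; the
#' axial force magnitude is \eqn{\kappa_e |\Delta r|}.
#'
#' @param network A \code{fiber_network}.
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{forces} (n x 3, pN), \code{energy} (pN um),
#'   \code{seg_tension} (per-segment signed axial force, pN, tension > 0).
#' @export
stretch_forces <- function(network, config) {
  fb <- force_breakdown(network, config)
  list(forces = fb$stretch, energy = unname(fb$energies["stretch"]),
       seg_tension = fb$seg_tension)
}

#' Bending forces
#'
#' Each interior node of a fiber chain contributes \eqn{U_b = \kappa_b
#' \Delta\theta^2 / 2}, with \eqn{\Delta\theta} the deviation of the segment
#' pair angle from straight. Per triplet the nodal forces have zero net force
#' and zero net torque.
#'
#' @inheritParams stretch_forces
#' @return List: \code{forces}, \code{energy}.
#' @export
bend_forces <- function(network, config) {
  fb <- force_breakdown(network, config)
  list(forces = fb$bend, energy = unname(fb$energies["bend"]))
}

#' Volume-exclusion (repulsion) forces
#'
#' Non-adjacent segment pairs closer than the fiber diameter at closest
#' approach are pushed apart by a quadratic overlap penalty (force
#' proportional to overlap depth, capped), directed along the closest-approach
#' vector. Pairs currently joined by a bound crosslink are exempt, as the
#' crosslink spring already represents that contact.
#'
#' @inheritParams stretch_forces
#' @return List: \code{forces}, \code{energy}.
#' @export
repulsion_forces <- function(network, config) {
  fb <- force_breakdown(network, config)
  list(forces = fb$repulsion, energy = unname(fb$energies["repulsion"]))
}

#' Crosslink spring forces
#'
#' A bound crosslink is a linear spring between its two attachment points
#' (segment, arc-coordinate); forces are distributed to segment end nodes by
#' lever-arm weights, reproducing the point force and its torque. The cached
#' kinetic tension is \code{max(0, extensional force)}: only positive
#' stretching forces drive unbinding.
#'
#' @inheritParams stretch_forces
#' @return List: \code{forces}, \code{energy}, \code{tension} (per
#'   crosslink, pN, >= 0; zero for unbound or compressed crosslinks).
#' @export
crosslink_forces <- function(network, config) {
  fb <- force_breakdown(network, config)
  list(forces = fb$crosslink, energy = unname(fb$energies["crosslink"]),
       tension = fb$cl_tension)
}

#' Total force field and energy breakdown
#'
#' @inheritParams stretch_forces
#' @param loading Include the filopodial zone loading term.
#' @return List with \code{total} (n x 3), per-origin matrices
#'   (\code{stretch}, \code{bend}, \code{repulsion}, \code{crosslink},
#'   \code{external}), \code{energies}, \code{cl_tension},
#'   \code{seg_tension}, and \code{n_in_zone}.
#' @export
network_forces <- function(network, config, loading = FALSE) {
  force_breakdown(network, config, loading)
}

#' Total elastic energy of a configuration
#'
#' @inheritParams stretch_forces
#' @return Named vector of energies (pN um): stretch, bend, repulsion,
#'   crosslink, and their total.
#' @export
elastic_energy <- function(network, config) {
  en <- network_forces(network, config)$energies
  c(en, total = sum(en))
}

#' One explicit Euler step of the overdamped dynamics
#'
#' Each free node moves by \eqn{F \Delta t / \zeta}; pinned nodes do not
#' move; x,y are wrapped periodically and z is floored at the loading
#' boundary wall z = 0. Errors if any displacement exceeds the stability cap
#' (\code{config$cap_disp}).
#'
#' @param network A \code{fiber_network}.
#' @param forces n x 3 force matrix, pN.
#' @param config A \code{\link{sim_config}}.
#' @return The network with updated positions.
#' @export
euler_step <- function(network, forces, config) {
  stopifnot(nrow(forces) == nrow(network$pos))
  disp <- forces * (config$dt / config$zeta)
  disp[network$fixed, ] <- 0
  dmag <- sqrt(rowSums(disp^2))
  if (any(dmag > config$cap_disp))
    stop(sprintf(paste0("per-step displacement %.3g um exceeds stability cap ",
                        "%.3g um: use a smaller dt"),
                 max(dmag), config$cap_disp))
  pos <- network$pos + disp
  pos <- wrap_xy(pos, network$domain)
  pos[, 3] <- pmax(pos[, 3], 0)
  network$pos <- pos
  network
}
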