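# Stochastic force-sensitive crosslink kinetics (slip bonds).

#' Bell-model unbinding rate
#'
#' \eqn{k_u = k_{u0} \exp(\lambda F / k_B T)}: the unbinding rate of a slip
#' bond grows exponentially with the tensile force it carries. The exponent
#' is clamped at \code{params$exp_cap} (with a warning) to guard overflow.
#'
#' @param force Tensile force on the crosslink, pN (>= 0; callers clamp
#'   compression to zero).
#' @param params A \code{\link{sim_config}} or any list with \code{ku0},
#'   \code{lambda}, \code{kBT}, \code{exp_cap}.
#' @return Unbinding rate, 1/s (vectorized over \code{force}).
#' @export
unbind_rate <- function(force, params) {
  stopifnot(all(force >= 0))
  expo <- params$lambda * force / params$kBT
  if (any(expo > params$exp_cap)) {
    warning("Bell exponent clamped at ", params$exp_cap,
            " for ", sum(expo > params$exp_cap), " crosslink(s)")
    expo <- pmin(expo, params$exp_cap)
  }
  params$ku0 * exp(expo)
}

#' Per-step unbinding probability
#'
#' \eqn{P = 1 - \exp(-k_u \Delta t)}, the probability that a bond with
#' constant hazard \eqn{k_u} unbinds within one time step.
#'
#' @param k_u Unbinding rate, 1/s.
#' @param dt Time step, s.
#' @return Probability in [0, 1].
#' @export
unbind_probability <- function(k_u, dt) {
  stopifnot(all(k_u >= 0), dt >= 0)
  -expm1(-k_u * dt)
}

#' Apply one step of stochastic unbinding
#'
#' Each bound crosslink unbinds independently with the probability implied by
#' its current cached tension (computed this step). Iterates crosslinks in
#' index order with one RNG stream for reproducibility.
#'
#' @param network A \code{fiber_network} with current \code{tension} values
#'   in \code{network$crosslinks}.
#' @param params A \code{\link{sim_config}}.
#' @return List: updated \code{network} and an \code{events} data frame
#'   (crosslink id, tension at unbinding).
#' @export
apply_unbinding <- function(network, params) {
  cl <- network$crosslinks
  bound <- which(cl$bound)
  if (length(bound) == 0)
    return(list(network = network,
                events = data.frame(crosslink = integer(), tension = numeric())))
  ku <- unbind_rate(pmax(cl$tension[bound], 0), params)
  p <- unbind_probability(ku, params$dt)
  u <- runif(length(bound))
  off <- bound[u < p]
  network$crosslinks$bound[off] <- FALSE
  list(network = network,
       events = data.frame(crosslink = off, tension = cl$tension[off]))
}

#' Apply one step of stochastic rebinding
#'
#' An unbound crosslink whose former attachment loci are within
#' \code{rebind_reach} rebinds with probability
#' \eqn{1 - \exp(-k_{re} \Delta t)}; it reattaches at the current geometry
#' with zero strain (its spring rest length is reset to the current
#' separation).
#'
#' @param network A \code{fiber_network}.
#' @param params A \code{\link{sim_config}} with \code{rebind_rate},
#'   \code{rebind_reach}.
#' @return Updated \code{fiber_network}.
#' @export
apply_rebinding <- function(network, params) {
  if (params$rebind_rate <= 0) return(network)
  cl <- network$crosslinks
  unb <- which(!cl$bound)
  if (length(unb) == 0) return(network)
  d <- crosslink_separation(network, unb)
  cand <- unb[d <= params$rebind_reach]
  if (length(cand) == 0) return(network)
  p <- -expm1(-params$rebind_rate * params$dt)
  on <- cand[runif(length(cand)) < p]
  if (length(on) > 0) {
    network$crosslinks$bound[on] <- TRUE
    network$crosslinks$rest[on] <- d[match(on, unb)]
    network$crosslinks$tension[on] <- 0
  }
  network
}

# Current separation of crosslink attachment points (minimum image in x,y)
crosslink_separation <- function(network, idx = seq_len(nrow(network$crosslinks))) {
  cl <- network$crosslinks[idx, , drop = FALSE]
  s <- network$segments
  pos <- network$pos
  dom <- network$domain
  attach_point <- function(seg, t) {
    a <- pos[s$a[seg], , drop = FALSE]
    d <- min_image(a, pos[s$b[seg], , drop = FALSE], dom)
    a + d * t
  }
  pa <- attach_point(cl$seg_a, cl$ta)
  pb <- attach_point(cl$seg_b, cl$tb)
  sqrt(rowSums(min_image(pa, pb, dom)^2))
}

#' Refresh cached crosslink tensions from the current geometry
#'
#' @param network A \code{fiber_network}.
#' @param config A \code{\link{sim_config}}.
#' @return Network with \code{crosslinks$tension} updated
#'   (\code{max(0, extensional force)}).
#' @export
update_crosslink_tensions <- function(network, config) {
  if (nrow(network$crosslinks) == 0) return(network)
  network$crosslinks$tension <- crosslink_forces(network, config)$tension
  network
}
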