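#' Double-well flip-flop potential
#'
#' The synthetic membrane evolves each lipid phosphate in a symmetric
#' quartic double-well along z,
#' \deqn{U(z) = B \, (1 - (z/z_0)^2)^2,}
#' with minima at the two leaflet positions z = +/- z0 and barrier B at the
#' membrane midplane z = 0. Only barrier heights are constrained by the
#' reference free-energy profiles; the quartic is the simplest smooth shape
#' with prescribed minima and barrier.
#'
#' An optional cylindrical "groove" region around a protein axis lowers the
#' local barrier to `groove_barrier` (the scramblase pathway). The barrier is
#' blended smoothly (cosine ramp over `blend` nm) across the groove edge so
#' U is continuous in xy. An optional gate bump adds a localized Gaussian
#' maximum on the groove path, emulating a hydrophobic gate that partially
#' obstructs the pathway.
#'
#' @param barrier bulk flip-flop barrier B in kJ/mol (>= 0)
#' @param z0 half-separation of the leaflet minima in nm (> 0); default
#'   2.0 nm, a POPC phosphate half-thickness
#' @param groove optional list(center = c(x, y), radius, barrier,
#'   gate_height = 0, gate_z = 0, gate_width = 0.3): groove axis position,
#'   radius (nm), in-groove barrier (kJ/mol) and optional gate bump
#' @param blend radial blending margin at the groove edge in nm
#' @return an object of class "sk_potential"
#' @export
flipflop_potential <- function(barrier, z0 = 2.0, groove = NULL, blend = 0.25) {
  stopifnot(barrier >= 0, z0 > 0, blend >= 0)
  if (!is.null(groove)) {
    stopifnot(length(groove$center) == 2L, groove$radius > 0,
              groove$barrier >= 0)
    groove$gate_height <- groove$gate_height %||% 0
    groove$gate_z <- groove$gate_z %||% 0
    groove$gate_width <- groove$gate_width %||% 0.3
    stopifnot(groove$gate_height >= 0, groove$gate_width > 0)
  }
  structure(list(barrier = barrier, z0 = z0, groove = groove, blend = blend),
            class = "sk_potential")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Radial weight of the groove at lateral distance r from its axis:
# 1 inside, 0 outside, cosine ramp across [radius, radius + blend].
groove_weight <- function(p, x, y, box = NULL) {
  if (is.null(p$groove)) return(rep(0, length(x)))
  dx <- x - p$groove$center[1]
  dy <- y - p$groove$center[2]
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
  }
  r <- sqrt(dx^2 + dy^2)
  w <- numeric(length(r))
  w[r <= p$groove$radius] <- 1
  ramp <- r > p$groove$radius & r < p$groove$radius + p$blend
  w[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - p$groove$radius) / p$blend))
  w
}

#' Evaluate the flip-flop potential
#'
#' @param p an sk_potential
#' @param pos 3-D point, N x 3 matrix of points, or (with `z_only = TRUE`) a
#'   vector of z values evaluated outside any groove
#' @param box optional box vector for xy periodicity of the groove distance
#' @param z_only if TRUE, `pos` is interpreted as z values in the bulk (or on
#'   the groove axis when `on_axis = TRUE`)
#' @param on_axis with `z_only`, evaluate on the groove axis instead of bulk
#' @return potential energy in kJ/mol (vectorised)
#' @export
evaluate_potential <- function(p, pos, box = NULL, z_only = FALSE,
                               on_axis = FALSE) {
  stopifnot(inherits(p, "sk_potential"))
  if (z_only) {
    z <- as.numeric(pos)
    w <- if (on_axis && !is.null(p$groove)) rep(1, length(z)) else rep(0, length(z))
    return(potential_z(p, z, w))
  }
  m <- if (is.matrix(pos)) pos else matrix(pos, ncol = 3)
  w <- groove_weight(p, m[, 1], m[, 2], box)
  potential_z(p, m[, 3], w)
}

potential_z <- function(p, z, w) {
  B <- p$barrier
  if (!is.null(p$groove)) {
    B <- (1 - w) * p$barrier + w * p$groove$barrier
  }
  u <- B * (1 - (z / p$z0)^2)^2
  if (!is.null(p$groove) && p$groove$gate_height > 0) {
    g <- p$groove
    u <- u + w * g$gate_height * exp(-(z - g$gate_z)^2 / (2 * g$gate_width^2))
  }
  u
}

# dU/dz at fixed xy (groove weight w precomputed); used by the integrator.
potential_dz <- function(p, z, w) {
  B <- p$barrier
  if (!is.null(p$groove)) {
    B <- (1 - w) * p$barrier + w * p$groove$barrier
  }
  du <- B * 2 * (1 - (z / p$z0)^2) * (-2 * z / p$z0^2)
  if (!is.null(p$groove) && p$groove$gate_height > 0) {
    g <- p$groove
    du <- du - w * g$gate_height * (z - g$gate_z) / g$gate_width^2 *
      exp(-(z - g$gate_z)^2 / (2 * g$gate_width^2))
  }
  du
}

#' Local barrier height at a lateral position
#'
#' Height of the midplane maximum of U(z) at fixed xy, relative to the
#' leaflet minima (which are at zero by construction).
#'
#' @param p an sk_potential
#' @param x,y lateral position (nm); defaults give the bulk barrier
#' @param box optional box for periodic groove distance
#' @return barrier in kJ/mol
#' @export
local_barrier <- function(p, x = Inf, y = Inf, box = NULL) {
  if (is.infinite(x)) return(p$barrier)
  w <- groove_weight(p, x, y, box)
  zg <- seq(-p$z0, p$z0, length.out = 2001)
  max(potential_z(p, zg, rep(w, length(zg))))
}
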