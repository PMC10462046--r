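#' Synthetic membrane scenario
#'
#' Bundles everything needed to generate a ground-truth-known synthetic
#' membrane trajectory: lipid count, box, flip-flop potential, Langevin
#' parameters and output cadence. Each lipid is represented by its phosphate
#' bead (name "PO4", resname "POPC"); optional static water and protein
#' pseudo-particle layouts support density and alignment tests.
#'
#' The Langevin timestep must satisfy the drift-stability bound
#' dt * max|U'| * D / kBT < 0.1 * z0, checked at construction.
#'
#' @param name scenario label
#' @param n_lipids number of lipids (one phosphate bead each)
#' @param box length-3 box vector in nm
#' @param potential an sk_potential
#' @param duration trajectory length in ns
#' @param snapshot_interval output interval in ns
#' @param D lateral/normal diffusion coefficient in nm^2/ns
#' @param dt integration timestep in ns
#' @param temperature temperature in K
#' @param seed integer RNG seed; same seed + scenario gives a bit-identical
#'   trajectory
#' @param water optional M x 3 matrix of static water pseudo-particles (name "W")
#' @param protein optional M x 3 matrix of static protein pseudo-particles
#'   (name "BB", resname "PROT")
#' @return an object of class "sk_scenario"
#' @export
membrane_scenario <- function(name, n_lipids, box = c(10, 10, 10),
                              potential = flipflop_potential(62),
                              duration = 1000, snapshot_interval = 10,
                              D = 0.1, dt = 0.01, temperature = 310,
                              seed = 1L, water = NULL, protein = NULL) {
  stopifnot(n_lipids >= 1, duration >= snapshot_interval,
            snapshot_interval > 0, D >= 0, dt > 0, temperature > 0)
  box <- validate_box(box)
  # drift-stability bound on the timestep
  zg <- seq(-1.5 * potential$z0, 1.5 * potential$z0, length.out = 4001)
  wmax <- if (is.null(potential$groove)) 0 else 1
  gmax <- max(abs(potential_dz(potential, zg, rep(0, length(zg)))),
              abs(potential_dz(potential, zg, rep(wmax, length(zg)))))
  if (D > 0 && dt * gmax * D / kBT(temperature) >= 0.1 * potential$z0) {
    stop("timestep too large for this barrier: dt * max|U'| * D / kBT must ",
         "be < 0.1 * z0; reduce dt")
  }
  structure(list(name = name, n_lipids = as.integer(n_lipids), box = box,
                 potential = potential, duration = duration,
                 snapshot_interval = snapshot_interval, D = D, dt = dt,
                 temperature = temperature, seed = as.integer(seed),
                 water = water, protein = protein),
            class = "sk_scenario")
}

# Topology of a scenario: lipids first (resid 1..n), then water, then protein.
scenario_topology <- function(sc) {
  name <- rep("PO4", sc$n_lipids)
  resname <- rep("POPC", sc$n_lipids)
  resid <- seq_len(sc$n_lipids)
  nw <- if (is.null(sc$water)) 0L else nrow(sc$water)
  np <- if (is.null(sc$protein)) 0L else nrow(sc$protein)
  if (nw > 0L) {
    name <- c(name, rep("W", nw))
    resname <- c(resname, rep("W", nw))
    resid <- c(resid, sc$n_lipids + seq_len(nw))
  }
  if (np > 0L) {
    name <- c(name, rep("BB", np))
    resname <- c(resname, rep("PROT", np))
    resid <- c(resid, sc$n_lipids + nw + seq_len(np))
  }
  system_topology(name, resname, resid)
}

# Deterministic initial placement: lipids alternate leaflets (+z0 for odd
# ids), laid out on an xy grid spanning the box.
scenario_initial_positions <- function(sc) {
  n <- sc$n_lipids
  side <- ceiling(sqrt(n))
  gx <- ((seq_len(n) - 1L) %% side + 0.5) * sc$box[1] / side
  gy <- ((seq_len(n) - 1L) %/% side + 0.5) * sc$box[2] / side
  gz <- ifelse(seq_len(n) %% 2L == 1L, sc$potential$z0, -sc$potential$z0)
  cbind(gx, gy, gz)
}
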