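#' Simulate an unbiased synthetic membrane trajectory
#'
#' Each lipid phosphate evolves by overdamped (Brownian) Langevin dynamics:
#' \deqn{z \leftarrow z - \frac{D}{k_B T} U'(z)\, dt + \sqrt{2 D\, dt}\,\eta}
#' with standard-normal \eqn{\eta}, while x and y diffuse freely under
#' periodic boundaries. Water and protein pseudo-particles, if configured,
#' are static. The run is fully reproducible: the same scenario and seed
#' give a bit-identical trajectory.
#'
#' This is a toy sampler of the configured potential, not a physical
#' membrane model: there are no lipid-lipid interactions and the diffusion
#' coefficient is chosen for event statistics at desk scale.
#'
#' @param scenario an sk_scenario
#' @return an sk_trajectory with one frame per snapshot interval (the initial
#'   configuration is frame 1 at t = 0)
#' @export
simulate_unbiased <- function(scenario) {
  stopifnot(inherits(scenario, "sk_scenario"))
  sc <- scenario
  n <- sc$n_lipids
  steps_per_snap <- round(sc$snapshot_interval / sc$dt)
  if (abs(steps_per_snap * sc$dt - sc$snapshot_interval) > 1e-9) {
    stop("snapshot_interval must be an integer multiple of dt")
  }
  n_snaps <- floor(sc$duration / sc$snapshot_interval)
  pos <- scenario_initial_positions(sc)
  extra <- rbind(sc$water, sc$protein)
  nf <- n_snaps + 1L
  out <- array(NA_real_, dim = c(n + NROW(extra), 3, nf))
  out[, , 1] <- rbind(pos, extra)
  times <- c(0, seq_len(n_snaps) * sc$snapshot_interval)

  set.seed(sc$seed)
  mob <- sc$D / kBT(sc$temperature)   # mobility, nm^2 ns^-1 / (kJ/mol)
  sig <- sqrt(2 * sc$D * sc$dt)
  p <- sc$potential
  has_groove <- !is.null(p$groove)
  x <- pos[, 1]; y <- pos[, 2]; z <- pos[, 3]
  for (s in seq_len(n_snaps)) {
    eta <- matrix(stats::rnorm(3L * n * steps_per_snap), nrow = 3L * n)
    for (k in seq_len(steps_per_snap)) {
      w <- if (has_groove) groove_weight(p, x, y, sc$box) else NULL
      force <- -potential_dz(p, z, if (has_groove) w else numeric(n))
      dz <- mob * force * sc$dt + sig * eta[(2L * n + 1L):(3L * n), k]
      if (any(abs(dz) > p$z0)) {
        stop("integration instability (|dz| > z0 in one step); reduce dt")
      }
      z <- z + dz
      x <- (x + sig * eta[1:n, k]) %% sc$box[1]
      y <- (y + sig * eta[(n + 1L):(2L * n), k]) %% sc$box[2]
    }
    out[1:n, 1, s + 1L] <- x
    out[1:n, 2, s + 1L] <- y
    out[1:n, 3, s + 1L] <- z
    if (NROW(extra) > 0L) out[(n + 1L):(n + NROW(extra)), , s + 1L] <- extra
  }
  trajectory(out, times, sc$box, scenario_topology(sc))
}

#' Build a trajectory with planted flip-flop events
#'
#' Deterministic oracle fixture for the scrambling counter: every scheduled
#' lipid's phosphate crosses the membrane midplane exactly at its flip time
#' (its z toggles between the two leaflet positions at the first snapshot at
#' or after the flip time); all other lipids stay in their starting leaflet.
#'
#' @param n_lipids number of lipids
#' @param schedule data.frame with columns `lipid` (1-based id) and `time`
#'   (ns); may be empty
#' @param duration trajectory length in ns
#' @param snapshot_interval snapshot cadence in ns
#' @param box box vector in nm
#' @param z0 leaflet half-separation in nm
#' @return an sk_trajectory whose topology is n_lipids POPC phosphates
#' @export
plant_events <- function(n_lipids, schedule, duration = 1000,
                         snapshot_interval = 10, box = c(10, 10, 10),
                         z0 = 2.0) {
  if (is.null(schedule) || nrow(schedule) == 0L) {
    schedule <- data.frame(lipid = integer(0), time = numeric(0))
  }
  stopifnot(all(c("lipid", "time") %in% names(schedule)))
  if (nrow(schedule) > 0L) {
    if (any(schedule$lipid < 1L | schedule$lipid > n_lipids)) {
      stop("schedule references lipids outside 1..n_lipids")
    }
    if (any(schedule$time < 0 | schedule$time > duration)) {
      stop("flip times must lie within [0, duration]")
    }
    if (anyDuplicated(schedule[, c("lipid", "time")])) {
      stop("duplicate (lipid, time) entries in the schedule")
    }
  }
  sc <- membrane_scenario("planted", n_lipids, box = box,
                          potential = flipflop_potential(0, z0 = z0),
                          duration = duration,
                          snapshot_interval = snapshot_interval, D = 0)
  pos0 <- scenario_initial_positions(sc)
  times <- seq(0, duration, by = snapshot_interval)
  nf <- length(times)
  # sign matrix: start from initial leaflet, toggle at the first snapshot
  # at or after each scheduled flip
  sign0 <- sign(pos0[, 3])
  signs <- matrix(rep(sign0, nf), nrow = n_lipids)
  if (nrow(schedule) > 0L) {
    for (r in seq_len(nrow(schedule))) {
      j0 <- which(times >= schedule$time[r])[1]
      li <- schedule$lipid[r]
      signs[li, j0:nf] <- -signs[li, j0:nf]
    }
  }
  out <- array(NA_real_, dim = c(n_lipids, 3, nf))
  for (j in seq_len(nf)) {
    out[, 1, j] <- pos0[, 1]
    out[, 2, j] <- pos0[, 2]
    out[, 3, j] <- signs[, j] * z0
  }
  trajectory(out, times, box, scenario_topology(sc))
}
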