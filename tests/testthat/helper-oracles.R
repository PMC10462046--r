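# Independent oracles and fixture builders used across the test suite.
# These deliberately avoid the package's own implementation paths.

# Simple 4-lipid coarse-grained topology (one PO4 bead per POPC residue).
toy_topology <- function(n_lipids = 4L, extra_names = character(0),
                         extra_resnames = character(0)) {
  system_topology(
    name = c(rep("PO4", n_lipids), extra_names),
    resname = c(rep("POPC", n_lipids), extra_resnames),
    resid = seq_len(n_lipids + length(extra_names))
  )
}

# Random-walk Metropolis chain targeting exp(-u(x)/kT); independent sampler
# used as the oracle for the inverse-CDF biased sampler.
metropolis_chain <- function(ufun, n, x0 = 0, step = 0.1, kt = kBT(310),
                             burn = 1000, thin = 5, seed = 1) {
  set.seed(seed)
  total <- burn + n * thin
  x <- numeric(total)
  x[1] <- x0
  u_cur <- ufun(x0)
  prop <- stats::rnorm(total, sd = step)
  accept <- stats::runif(total)
  for (i in 2:total) {
    cand <- x[i - 1] + prop[i]
    u_cand <- ufun(cand)
    if (accept[i] < exp((u_cur - u_cand) / kt)) {
      x[i] <- cand; u_cur <- u_cand
    } else {
      x[i] <- x[i - 1]
    }
  }
  x[seq(burn + thin, total, by = thin)]
}

# Brute-force cylinder CV: enumerate all xy periodic images explicitly
# instead of using the minimum-image convention.
brute_cylinder_cv <- function(fr, target, members, radius) {
  pos <- fr$positions
  tx <- pos[target, 1]; ty <- pos[target, 2]
  zs <- numeric(0)
  for (m in members) {
    best <- Inf
    for (ix in -1:1) for (iy in -1:1) {
      dx <- pos[m, 1] + ix * fr$box[1] - tx
      dy <- pos[m, 2] + iy * fr$box[2] - ty
      d2 <- dx^2 + dy^2
      if (d2 < best) best <- d2
    }
    if (best <= radius^2) zs <- c(zs, pos[m, 3])
  }
  pos[target, 3] - mean(zs)
}

# Euler-angle rotation (proper, det +1).
euler_rot <- function(a, b, c) {
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  Rz %*% Ry %*% Rx
}

rmsd_at_rotation <- function(P, Q, R) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
}

# Coarse-to-fine exhaustive grid search over Euler angles: the brute-force
# superposition oracle. Refines 9^3 grids around the running optimum.
grid_search_rmsd <- function(P, Q, levels = 12) {
  best <- c(0, 0, 0)
  width <- pi
  best_val <- rmsd_at_rotation(P, Q, euler_rot(0, 0, 0))
  for (lev in seq_len(levels)) {
    gr <- seq(-width, width, length.out = 9)
    for (a in best[1] + gr) for (b in best[2] + gr) for (c in best[3] + gr) {
      v <- rmsd_at_rotation(P, Q, euler_rot(a, b, c))
      if (v < best_val) { best_val <- v; best <- c(a, b, c) }
    }
    width <- width / 3.5
  }
  best_val
}

# Closed-form superposition RMSD via the quaternion (Horn) method: an
# algorithmically independent route to the optimal proper rotation.
quaternion_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[1, 3] + M[3, 1]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# Random planted-flip schedule on distinct (lipid, snapshot) slots so every
# scheduled flip is a distinct observable transition. Lipids 1 and 2 (one per
# leaflet) are never scheduled: a schedule that empties a leaflet entirely
# would leave the membrane midplane undefined, a configuration no bilayer
# reaches, so the oracle keeps both leaflets populated.
random_schedule <- function(n_events, n_lipids, duration, interval, seed) {
  set.seed(seed)
  stopifnot(n_lipids >= 4)
  slots <- expand.grid(lipid = 3:n_lipids,
                       time = seq(interval, duration, by = interval))
  slots[sample.int(nrow(slots), n_events), , drop = FALSE]
}
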