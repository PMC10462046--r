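random_rigid <- function(seed) {
  set.seed(seed)
  ang <- stats::runif(3, -pi, pi)
  list(R = euler_rot(ang[1], ang[2], ang[3]), t = stats::rnorm(3, sd = 2))
}

test_that("superposition recovers identity and undoes rigid motion", {
  set.seed(1)
  ref_xyz <- matrix(stats::rnorm(15, sd = 1.5), 5, 3)
  ref <- alignment_reference(ref_xyz, fit = 1:5)
  same <- kabsch_superpose(ref_xyz, ref)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$R, diag(3), tolerance = 1e-9)
  tr <- random_rigid(5)
  moved <- sweep(ref_xyz %*% t(tr$R), 2, tr$t, `+`)
  fit <- kabsch_superpose(moved, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$R), 1, tolerance = 1e-10)
  expect_equal(apply_transform(moved, fit), ref_xyz, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches the exhaustive grid-search oracle", {
  # 4-point toy with one perturbed point, plus a few randomized cases
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  pert <- base; pert[4, ] <- pert[4, ] + c(0.11, -0.07, 0.05)
  tr <- random_rigid(2)
  mob <- sweep(pert %*% t(tr$R), 2, tr$t, `+`)
  got <- kabsch_superpose(mob, base, fit = 1:4)$rmsd
  expect_equal(got, grid_search_rmsd(mob, base), tolerance = 1e-6)
  for (seed in 1:5) {
    set.seed(seed + 100)
    n <- sample(4:6, 1)
    Q <- matrix(stats::rnorm(3 * n), n, 3)
    P <- Q + matrix(stats::rnorm(3 * n, sd = 0.15), n, 3)
    expect_equal(kabsch_superpose(P, Q, fit = seq_len(n))$rmsd,
                 grid_search_rmsd(P, Q), tolerance = 1e-6)
  }
})

test_that("Kabsch RMSD matches the quaternion closed form on 1000 random systems", {
  set.seed(42)
  for (trial in 1:1000) {
    n <- sample(4:6, 1)
    Q <- matrix(stats::rnorm(3 * n), n, 3)
    P <- Q + matrix(stats::rnorm(3 * n, sd = 0.3), n, 3)
    expect_equal(kabsch_superpose(P, Q, fit = seq_len(n))$rmsd,
                 quaternion_rmsd(P, Q), tolerance = 1e-9)
  }
})

test_that("RMSD after superposition ignores rigid pre-transforms of the mobile", {
  set.seed(3)
  ref_xyz <- matrix(stats::rnorm(24, sd = 2), 8, 3)
  mob <- ref_xyz + matrix(stats::rnorm(24, sd = 0.2), 8, 3)
  ref <- alignment_reference(ref_xyz, fit = 1:8)
  r0 <- kabsch_superpose(mob, ref)$rmsd
  for (seed in 1:5) {
    tr <- random_rigid(seed)
    pre <- sweep(mob %*% t(tr$R), 2, tr$t, `+`)
    expect_equal(kabsch_superpose(pre, ref)$rmsd, r0, tolerance = 1e-9)
  }
})

test_that("collinear fit sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(alignment_reference(line, fit = 1:5), "collinear")
  ref <- alignment_reference(matrix(stats::rnorm(15), 5, 3), fit = 1:5)
  expect_error(kabsch_superpose(line, ref), "collinear|degenerate")
})

test_that("rmsd_series: zeros on reference copies, d/sqrt(N) on one displacement", {
  set.seed(8)
  n <- 12L
  ref_xyz <- matrix(stats::rnorm(3 * n, sd = 2), n, 3)
  pos <- array(rep(ref_xyz, 3), dim = c(n, 3, 3))
  traj <- trajectory(pos, times = 0:2, box = c(20, 20, 20))
  ref <- alignment_reference(ref_xyz, fit = 1:6)
  expect_equal(rmsd_series(traj, ref, report = 1:n)$rmsd, rep(0, 3),
               tolerance = 1e-12)
  # displace one particle outside the fit set by d: RMSD = d / sqrt(N_report)
  d <- 0.9
  pos2 <- pos
  pos2[10, 1, 2] <- pos2[10, 1, 2] + d
  traj2 <- trajectory(pos2, times = 0:2, box = c(20, 20, 20))
  rs <- rmsd_series(traj2, ref, report = 7:n)
  expect_equal(rs$rmsd[2], d / sqrt(6), tolerance = 1e-12)
  expect_equal(rs$rmsd[c(1, 3)], c(0, 0), tolerance = 1e-12)
  expect_error(rmsd_series(traj2, ref, report = integer(0)), "empty")
})

test_that("subset RMSD stays below full RMSD when only the loops move", {
  # helices (fit set) static, loop particles drift
  set.seed(9)
  helix <- matrix(stats::rnorm(30, sd = 1.5), 10, 3)
  loops <- matrix(stats::rnorm(15, sd = 1.5), 5, 3)
  ref_xyz <- rbind(helix, loops)
  nf <- 4L
  pos <- array(rep(ref_xyz, nf), dim = c(15, 3, nf))
  for (i in 2:nf) pos[11:15, , i] <- pos[11:15, , i] +
      matrix(stats::rnorm(15, sd = 0.3 * i), 5, 3)
  traj <- trajectory(pos, times = seq_len(nf) - 1, box = c(20, 20, 20))
  ref <- alignment_reference(ref_xyz, fit = 1:10)
  full <- rmsd_series(traj, ref, report = 1:15)$rmsd
  hel <- rmsd_series(traj, ref, report = 1:10)$rmsd
  expect_true(all(hel <= full + 1e-12))
})

test_that("density grids conserve particle counts exactly", {
  # one static particle: its voxel holds 1/(voxel volume)
  pos <- array(c(1.05, 2.05, 3.05), dim = c(1, 3, 100))
  traj <- trajectory(pos, times = seq(0, 990, by = 10), box = c(5, 5, 5))
  gs <- grid_spec(origin = c(0, 0, 0), spacing = 0.1, dims = c(50, 50, 50))
  dens <- accumulate_density(traj, 1L, gs, interval = 10)
  expect_equal(max(dens$density), 1 / 0.1^3)
  expect_equal(sum(dens$density > 0), 1L)
  # conservation: sum(density * voxvol) = mean in-bounds count per frame
  set.seed(30)
  n <- 50L; nf <- 20L
  pos2 <- array(stats::runif(n * 3 * nf, -1, 6), dim = c(n, 3, nf))
  traj2 <- trajectory(pos2, times = seq(0, by = 10, length.out = nf),
                      box = c(6, 6, 6))
  dens2 <- accumulate_density(traj2, seq_len(n), gs, interval = 10)
  inb <- sum(dens2$counts) / dens2$frames
  expect_equal(sum(dens2$density) * prod(gs$spacing), inb,
               tolerance = 1e-12)
  expect_equal(sum(dens2$counts) + dens2$out_of_bounds, n * nf)
})

test_that("density accumulation is linear over trajectory halves", {
  set.seed(31)
  n <- 20L; nf <- 10L
  pos <- array(stats::runif(n * 3 * nf, 0, 5), dim = c(n, 3, nf))
  times <- seq(0, by = 10, length.out = nf)
  gs <- grid_spec(origin = c(0, 0, 0), spacing = 0.5, dims = c(10, 10, 10))
  whole <- accumulate_density(trajectory(pos, times, c(5, 5, 5)),
                              seq_len(n), gs, interval = 10)
  h1 <- accumulate_density(trajectory(pos[, , 1:5], times[1:5], c(5, 5, 5)),
                           seq_len(n), gs, interval = 10)
  h2 <- accumulate_density(trajectory(pos[, , 6:10], times[6:10], c(5, 5, 5)),
                           seq_len(n), gs, interval = 10)
  expect_equal((h1$density * 5 + h2$density * 5) / 10, whole$density,
               tolerance = 1e-12)
})

test_that("uniform particles give Poisson-dispersed voxel counts", {
  set.seed(32)
  n <- 200L; nf <- 50L
  pos <- array(stats::runif(n * 3 * nf, 0, 4), dim = c(n, 3, nf))
  traj <- trajectory(pos, times = seq(0, by = 10, length.out = nf),
                     box = c(4, 4, 4))
  gs <- grid_spec(origin = c(0, 0, 0), spacing = 0.5, dims = c(8, 8, 8))
  dens <- accumulate_density(traj, seq_len(n), gs, interval = 10)
  counts <- as.vector(dens$counts)
  # index-of-dispersion test: (n-1) s^2 / mean ~ chi-square(n-1)
  stat <- (length(counts) - 1) * stats::var(counts) / mean(counts)
  lim <- stats::qchisq(c(0.005, 0.995), df = length(counts) - 1)
  expect_gt(stat, lim[1])
  expect_lt(stat, lim[2])
})

test_that("protein-centered density maps a static particle sharply after alignment", {
  # the 'protein' tumbles rigidly; a particle fixed in the protein frame
  # must land in a single voxel once frames are aligned
  set.seed(33)
  prot <- matrix(stats::rnorm(18, sd = 1), 6, 3)
  bead <- c(1.234, 0.567, -0.89)
  nf <- 8L
  pos <- array(NA_real_, dim = c(7, 3, nf))
  for (i in seq_len(nf)) {
    tr <- random_rigid(i + 50)
    pos[1:6, , i] <- sweep(prot %*% t(tr$R), 2, tr$t, `+`)
    pos[7, , i] <- as.numeric(tr$R %*% bead + tr$t)
  }
  traj <- trajectory(pos, times = seq(0, by = 10, length.out = nf),
                     box = c(30, 30, 30))
  ref <- alignment_reference(rbind(prot, bead), fit = 1:6)
  gs <- grid_spec(origin = c(-3, -3, -3), spacing = 0.1, dims = c(60, 60, 60))
  dens <- accumulate_density(traj, 7L, gs, ref = ref, interval = 10)
  expect_equal(sum(dens$density > 0), 1L)
  expect_equal(dens$out_of_bounds, 0L)
})

test_that("OpenDX files round trip exactly and follow the grid convention", {
  set.seed(34)
  gs <- grid_spec(origin = c(-1, 0, 2.5), spacing = c(0.1, 0.2, 0.25),
                  dims = c(4, 3, 5))
  dens <- structure(list(grid = gs,
                         density = array(stats::runif(60), dim = gs$dims),
                         counts = NULL, frames = 1, out_of_bounds = 0),
                    class = "sk_density")
  path <- tempfile(fileext = ".dx")
  write_dx(dens, path)
  back <- read_dx(path)
  expect_equal(back$grid$dims, gs$dims)
  expect_equal(back$grid$origin, gs$origin)
  expect_equal(back$grid$spacing, gs$spacing)
  expect_equal(back$density, dens$density, tolerance = 1e-9)
  # independent parse of the header and data layout (z varies fastest)
  lines <- readLines(path)
  expect_equal(as.integer(strsplit(sub(".*counts ", "",
    grep("gridpositions", lines, value = TRUE)), " ")[[1]]), c(4L, 3L, 5L))
  items <- as.integer(sub(".*items (\\d+) .*", "\\1",
    grep("items", lines, value = TRUE)))
  expect_equal(items, prod(gs$dims))
  first_row <- as.numeric(strsplit(lines[grep("data follows", lines) + 1L],
                                   " ")[[1]])
  expect_equal(first_row, dens$density[1, 1, 1:3], tolerance = 1e-9)
})
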