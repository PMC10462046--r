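#' Time-averaged 3-D number-density grids
#'
#' Particles of a target selection are binned on a regular voxel grid, one
#' analysed snapshot every `interval` ns, optionally after rigid alignment of
#' each frame onto a reference (protein-centered maps). The stored density is
#' counts / (frames x voxel volume), in nm^-3, so that
#' sum(density * voxel volume) equals the mean number of in-bounds particles
#' per analysed frame — an exact conservation identity.
#'
#' @name density_mapping
NULL

#' Define a density grid
#'
#' @param origin length-3 vector: position of the lower corner (nm)
#' @param spacing voxel edge length(s) in nm, scalar or length 3 (default 0.1)
#' @param dims length-3 integer vector of voxel counts
#' @return an "sk_gridspec"
#' @export
grid_spec <- function(origin, spacing = 0.1, dims) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, all(spacing > 0), length(dims) == 3L,
            all(dims >= 1L))
  structure(list(origin = as.numeric(origin), spacing = spacing, dims = dims),
            class = "sk_gridspec")
}

#' Accumulate a number-density grid over a trajectory
#'
#' @param traj an sk_trajectory
#' @param target sk_selection or index vector of particles to bin
#' @param grid an sk_gridspec
#' @param ref optional sk_alignment_ref; when given, every analysed frame is
#'   Kabsch-superposed onto it before binning
#' @param interval analysis interval in ns (default 10); frames nearest the
#'   interval grid are analysed
#' @return an "sk_density": list(grid, density [3-D array, nm^-3], counts,
#'   frames, out_of_bounds)
#' @export
accumulate_density <- function(traj, target, grid, ref = NULL, interval = 10) {
  stopifnot(inherits(traj, "sk_trajectory"), inherits(grid, "sk_gridspec"))
  idx <- if (inherits(target, "sk_selection")) target$indices else target
  if (length(idx) == 0L) stop("target selection is empty")
  times <- traj$times
  snap_times <- seq(times[1], times[length(times)], by = interval)
  snap_idx <- unique(vapply(snap_times, function(t) which.min(abs(times - t)), 1L))
  if (length(snap_idx) == 0L) stop("no frames to analyse at this interval")

  counts <- array(0, dim = grid$dims)
  oob <- 0L
  for (i in snap_idx) {
    fr <- get_frame(traj, i)
    pos <- fr$positions
    if (!is.null(ref)) {
      tr <- kabsch_superpose(fr, ref)
      pos <- apply_transform(pos, tr)
    }
    p <- pos[idx, , drop = FALSE]
    v <- floor(sweep(sweep(p, 2, grid$origin), 2, grid$spacing, `/`)) + 1
    ok <- v[, 1] >= 1 & v[, 1] <= grid$dims[1] &
          v[, 2] >= 1 & v[, 2] <= grid$dims[2] &
          v[, 3] >= 1 & v[, 3] <= grid$dims[3]
    oob <- oob + sum(!ok)
    if (any(ok)) {
      lin <- (v[ok, 3] - 1) * grid$dims[1] * grid$dims[2] +
             (v[ok, 2] - 1) * grid$dims[1] + v[ok, 1]
      tab <- tabulate(lin, nbins = prod(grid$dims))
      counts <- counts + array(tab, dim = grid$dims)
    }
  }
  nf <- length(snap_idx)
  voxvol <- prod(grid$spacing)
  structure(list(grid = grid, density = counts / (nf * voxvol),
                 counts = counts, frames = nf, out_of_bounds = oob),
            class = "sk_density")
}

#' @export
print.sk_density <- function(x, ...) {
  cat("<sk_density> ", paste(x$grid$dims, collapse = " x "), " voxels, ",
      x$frames, " frames, ", x$out_of_bounds, " out-of-bounds particles\n",
      sep = "")
  invisible(x)
}

#' Write a density grid as an OpenDX file
#'
#' Standard regular-grid scalar OpenDX layout (three values per data line,
#' z varying fastest), readable by VMD, PyMOL and the common grid libraries.
#'
#' @param dens an sk_density (or list with `grid` and `density`)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dx <- function(dens, path) {
  g <- dens$grid
  n <- prod(g$dims)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX density written by scramblekit",
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("origin %.17g %.17g %.17g", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.17g 0 0", g$spacing[1]),
    sprintf("delta 0 %.17g 0", g$spacing[2]),
    sprintf("delta 0 0 %.17g", g$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  ), con)
  # OpenDX stores with the last index (z) varying fastest
  vals <- as.vector(aperm(dens$density, c(3, 2, 1)))
  full_rows <- n %/% 3L
  if (full_rows > 0L) {
    m <- matrix(vals[seq_len(3L * full_rows)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n %% 3L != 0L) {
    rest <- vals[(3L * full_rows + 1L):n]
    writeLines(paste(sprintf("%.17g", rest), collapse = " "), con)
  }
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX density grid
#'
#' @param path OpenDX file path
#' @return an "sk_density" with `grid`, `density`; `counts`/`frames` are NA
#'   (a .dx file carries only the averaged field)
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions", lines, value = TRUE)
  if (length(gp) == 0L) stop("not an OpenDX regular grid: ", path)
  dims <- as.integer(strsplit(sub(".*counts\\s+", "", gp[1]), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(sub("^\\s*origin", "",
    grep("^\\s*origin", lines, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- t(vapply(grep("^\\s*delta", lines, value = TRUE)[1:3], function(l)
    as.numeric(strsplit(trimws(sub("^\\s*delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  spacing <- c(deltas[1, 1], deltas[2, 2], deltas[3, 3])
  if (any(abs(deltas - diag(spacing)) > 1e-12)) {
    stop("non-axis-aligned OpenDX deltas are not supported")
  }
  start <- grep("data follows", lines)[1]
  n <- prod(dims)
  vals <- numeric(0)
  i <- start + 1L
  while (length(vals) < n && i <= length(lines)) {
    if (grepl("^(attribute|object)", lines[i])) break
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  if (length(vals) != n) {
    stop("OpenDX data block has ", length(vals), " values, expected ", n)
  }
  dens <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  structure(list(grid = grid_spec(origin, spacing, dims), density = dens,
                 counts = NA, frames = NA, out_of_bounds = NA),
            class = "sk_density")
}
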