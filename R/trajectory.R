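#' Frames and trajectories
#'
#' A frame holds particle positions (an N x 3 matrix, nm), a simulation time
#' (ns) and orthorhombic box lengths (nm). A trajectory is an ordered
#' sequence of frames with a common particle count, stored as an
#' N x 3 x n_frames array for efficient per-frame access.
#'
#' @param positions numeric N x 3 matrix of coordinates in nm
#' @param time time stamp in ns
#' @param box numeric length-3 vector of box edge lengths (Lx, Ly, Lz) in nm
#' @return an object of class "sk_frame"
#' @export
frame <- function(positions, time = 0, box) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  if (!all(is.finite(positions))) stop("positions must be finite")
  box <- validate_box(box)
  structure(list(positions = positions, time = as.numeric(time), box = box),
            class = "sk_frame")
}

validate_box <- function(box) {
  box <- as.numeric(box)
  if (length(box) == 9L) {
    m <- matrix(box, 3, 3)
    off <- m[upper.tri(m) | lower.tri(m)]
    if (any(abs(off) > 1e-9)) {
      stop("triclinic boxes are not supported; only orthorhombic boxes")
    }
    box <- diag(m)
  }
  if (length(box) != 3L) stop("box must be 3 edge lengths (orthorhombic)")
  if (!all(is.finite(box)) || any(box <= 0)) {
    stop("box edge lengths must be strictly positive")
  }
  box
}

#' Construct a trajectory from frames or arrays
#'
#' @param positions N x 3 x n_frames numeric array (nm)
#' @param times numeric vector of frame times in ns, strictly increasing
#' @param box length-3 box vector shared by all frames, or 3 x n_frames matrix
#' @param topology optional sk_topology; particle count must match
#' @return an object of class "sk_trajectory"
#' @export
trajectory <- function(positions, times, box, topology = NULL) {
  if (length(dim(positions)) != 3L || dim(positions)[2] != 3L) {
    stop("positions must be an N x 3 x n_frames array")
  }
  nf <- dim(positions)[3]
  if (length(times) != nf) stop("times must match the number of frames")
  if (nf > 1L && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (is.matrix(box)) {
    if (!all(dim(box) == c(3L, nf))) stop("per-frame box must be 3 x n_frames")
    apply(box, 2, validate_box)
  } else {
    box <- validate_box(box)
  }
  if (!is.null(topology) && n_particles(topology) != dim(positions)[1]) {
    stop("particle count mismatch: trajectory has ", dim(positions)[1],
         " particles, topology has ", n_particles(topology))
  }
  structure(list(positions = positions, times = as.numeric(times), box = box,
                 topology = topology),
            class = "sk_trajectory")
}

#' @export
print.sk_trajectory <- function(x, ...) {
  cat("<sk_trajectory> ", dim(x$positions)[1], " particles, ",
      n_frames(x), " frames, t = ", x$times[1], " .. ",
      x$times[n_frames(x)], " ns\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an sk_trajectory
#' @return integer frame count
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame from a trajectory
#' @param traj an sk_trajectory
#' @param i 1-based frame index
#' @return an sk_frame
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  b <- if (is.matrix(traj$box)) traj$box[, i] else traj$box
  frame(matrix(traj$positions[, , i], ncol = 3), time = traj$times[i], box = b)
}

#' Wrap coordinates into the primary periodic image
#'
#' Maps each coordinate into [0, L) along the requested axes. Idempotent and
#' distance-preserving under the minimum-image convention.
#'
#' @param fr an sk_frame
#' @param axes integer subset of 1:3 (x, y, z); default all three
#' @return a new sk_frame with wrapped coordinates
#' @export
wrap_to_box <- function(fr, axes = 1:3) {
  stopifnot(inherits(fr, "sk_frame"))
  if (any(fr$box <= 0)) stop("box edge lengths must be strictly positive")
  pos <- fr$positions
  for (a in axes) {
    pos[, a] <- fr$positions[, a] %% fr$box[a]
  }
  frame(pos, time = fr$time, box = fr$box)
}

#' Minimum-image displacement between points under an orthorhombic box
#'
#' @param dvec numeric vector or matrix of raw displacements (rows = vectors)
#' @param box length-3 box vector; use NA for non-periodic axes
#' @return displacement(s) folded into [-L/2, L/2) per periodic axis
#' @export
min_image <- function(dvec, box) {
  m <- if (is.matrix(dvec)) dvec else matrix(dvec, nrow = 1)
  for (a in seq_len(ncol(m))) {
    L <- box[a]
    if (is.finite(L)) m[, a] <- m[, a] - L * round(m[, a] / L)
  }
  if (is.matrix(dvec)) m else drop(m)
}
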