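#' Plain-text trajectory container
#'
#' Trajectories are exchanged in a simple documented text container so that
#' fixtures and synthetic runs are fully portable:
#'
#' \preformatted{
#' # scramblekit trajectory v1
#' natoms <N>
#' frame <time ns> <Lx> <Ly> <Lz>
#' <x> <y> <z>          (N lines, nm, 6 decimals)
#' frame ...
#' }
#'
#' Binary Gromacs formats (XTC/TRR) have no installed reader in this
#' toolchain and are rejected with a clear error; convert externally or use
#' this container.
#'
#' @name trajectory_container
#' @keywords internal
NULL

TRJ_HEADER <- "# scramblekit trajectory v1"

#' Write a trajectory to the text container
#'
#' @param traj an sk_trajectory
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sk_trajectory"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- dim(traj$positions)[1]
  writeLines(c(TRJ_HEADER, paste("natoms", n)), con)
  for (i in seq_len(n_frames(traj))) {
    b <- if (is.matrix(traj$box)) traj$box[, i] else traj$box
    writeLines(sprintf("frame %.6f %.6f %.6f %.6f", traj$times[i],
                       b[1], b[2], b[3]), con)
    p <- traj$positions[, , i, drop = TRUE]
    if (n == 1L) p <- matrix(p, 1, 3)
    writeLines(sprintf("%.6f %.6f %.6f", p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Stream frames from a trajectory container
#'
#' Reads one frame at a time and passes it to a callback; memory use is
#' independent of trajectory length. This is the primitive behind
#' [read_trajectory()].
#'
#' @param path trajectory container file
#' @param topology sk_topology whose particle count must match the file
#' @param callback function(frame, index) called once per frame, in order
#' @return number of frames visited, invisibly
#' @export
stream_frames <- function(path, topology, callback) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xtc", "trr")) {
    stop("binary ", toupper(ext), " trajectories are not supported; ",
         "convert to the text container (see ?trajectory_container)")
  }
  con <- file(path, open = "rt")
  on.exit(close(con))
  header <- readLines(con, n = 2L)
  if (length(header) < 2L || !identical(header[1], TRJ_HEADER)) {
    stop("not a scramblekit trajectory container: ", path)
  }
  n <- suppressWarnings(as.integer(sub("^natoms\\s+", "", header[2])))
  if (is.na(n) || n < 1L) stop("trajectory parse error: bad natoms line")
  if (n != n_particles(topology)) {
    stop("particle count mismatch: trajectory has ", n,
         " particles, topology has ", n_particles(topology))
  }
  i <- 0L
  repeat {
    fl <- readLines(con, n = 1L)
    if (length(fl) == 0L) break
    i <- i + 1L
    hdr <- suppressWarnings(as.numeric(strsplit(fl, "\\s+")[[1]][-1]))
    if (!startsWith(fl, "frame ") || length(hdr) != 4L || anyNA(hdr)) {
      stop("trajectory parse error at frame ", i, ": bad frame header")
    }
    block <- readLines(con, n = n)
    if (length(block) < n) {
      stop("trajectory parse error at frame ", i, ": truncated frame")
    }
    xyz <- matrix(suppressWarnings(
      as.numeric(unlist(strsplit(block, "\\s+"), use.names = FALSE))),
      ncol = 3, byrow = TRUE)
    if (anyNA(xyz) || nrow(xyz) != n) {
      stop("trajectory parse error at frame ", i, ": malformed coordinates")
    }
    callback(frame(xyz, time = hdr[1], box = hdr[2:4]), i)
  }
  invisible(i)
}

#' Read a whole trajectory container into memory
#'
#' @param path trajectory container file
#' @param topology sk_topology whose particle count must match
#' @return an sk_trajectory
#' @export
read_trajectory <- function(path, topology) {
  frames <- list()
  times <- numeric(0)
  boxes <- list()
  stream_frames(path, topology, function(fr, i) {
    frames[[i]] <<- fr$positions
    times[i] <<- fr$time
    boxes[[i]] <<- fr$box
  })
  if (length(frames) == 0L) stop("trajectory contains no frames: ", path)
  pos <- array(unlist(frames, use.names = FALSE),
               dim = c(nrow(frames[[1]]), 3, length(frames)))
  boxm <- do.call(cbind, boxes)
  if (all(boxm == boxm[, 1])) boxm <- boxm[, 1]
  trajectory(pos, times, boxm, topology)
}
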