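#' Leaflet assignment and scrambling analysis
#'
#' A lipid is assigned to the upper or lower leaflet by comparing its
#' phosphate z-coordinate with the membrane center, and is counted as
#' "scrambled" when it sits in the opposite leaflet to the one it started
#' in. Analysis snapshots are taken every `interval` ns.
#'
#' @name scrambling
NULL

# Unwrap a set of z coordinates so the bilayer is z-connected: wrap into
# [0, Lz), locate the largest cyclic gap, and lift the values below the gap
# by Lz. Returns the lifted coordinates plus the lift applied to each.
unwrap_connected_z <- function(z, Lz) {
  zw <- z %% Lz
  ord <- order(zw)
  zs <- zw[ord]
  gaps <- diff(c(zs, zs[1] + Lz))
  gi <- which.max(gaps)
  cut <- if (gi == length(zs)) zs[1] else zs[gi + 1L]
  lift <- ifelse(zw < cut, Lz, 0)
  zw + lift
}

#' Membrane center along z
#'
#' Mean phosphate z after the bilayer has been made z-connected under
#' periodic boundaries (so a bilayer straddling the box edge is handled
#' correctly). The returned value is expressed in the periodic image closest
#' to the input coordinates.
#'
#' @param fr an sk_frame
#' @param phosphates an sk_selection of phosphate particles
#' @return membrane center z in nm
#' @export
membrane_center_z <- function(fr, phosphates) {
  stopifnot(inherits(fr, "sk_frame"))
  idx <- if (inherits(phosphates, "sk_selection")) phosphates$indices else phosphates
  if (length(idx) < 2L) stop("need at least 2 phosphates to define the membrane center")
  z <- fr$positions[idx, 3]
  Lz <- fr$box[3]
  m <- mean(unwrap_connected_z(z, Lz))
  m + round((stats::median(z) - m) / Lz) * Lz
}

#' Assign lipids to leaflets
#'
#' A lipid is "upper" iff its phosphate z exceeds the membrane center
#' (computed per snapshot). A phosphate exactly at the center keeps its
#' previous label, or is labelled "upper" if there is no history.
#'
#' @param fr an sk_frame
#' @param topology sk_topology with a non-empty phosphate map
#' @param previous optional previous label vector (same lipid order) used to
#'   resolve exact ties
#' @return list with `time`, `labels` (character vector "upper"/"lower",
#'   named by lipid residue id) and `center` (membrane center z, nm)
#' @export
assign_leaflets <- function(fr, topology, previous = NULL) {
  pmap <- topology$phosphate_map
  if (length(pmap) == 0L) stop("topology has no lipid phosphates")
  z <- fr$positions[pmap, 3]
  Lz <- fr$box[3]
  zu <- unwrap_connected_z(z, Lz)
  center <- mean(zu)
  labels <- ifelse(zu > center, "upper", ifelse(zu < center, "lower", NA))
  if (anyNA(labels)) {
    tied <- is.na(labels)
    labels[tied] <- if (!is.null(previous)) previous[tied] else "upper"
    labels[is.na(labels)] <- "upper"
  }
  names(labels) <- names(pmap)
  list(time = fr$time, labels = labels,
       center = center + round((stats::median(z) - center) / Lz) * Lz)
}

#' Scrambling trace of a trajectory
#'
#' Analyses one snapshot every `interval` ns. The reference leaflet of each
#' lipid is fixed at the first analysed snapshot; at every later snapshot the
#' trace reports the instantaneous number of scrambled lipids (currently in
#' the opposite leaflet to their origin) and the cumulative number of
#' leaflet-transition events (every label change between consecutive
#' snapshots counts one event, so a lipid that flips and returns contributes
#' two events but ends unscrambled).
#'
#' @param traj an sk_trajectory whose topology maps lipid phosphates
#' @param interval analysis interval in ns (default 10)
#' @param smoothing_window optional width in ns of a centered running average
#'   applied to the scrambled count (truncated at the trace edges)
#' @return data.frame of class "sk_scrambling_trace" with columns `time`,
#'   `count`, `cumulative_events`, `fraction` and (if smoothing requested)
#'   `count_smooth`; attributes `interval`, `n_lipids`
#' @export
scrambling_trace <- function(traj, interval = 10, smoothing_window = NULL) {
  stopifnot(inherits(traj, "sk_trajectory"))
  top <- traj$topology
  if (is.null(top)) stop("trajectory carries no topology")
  times <- traj$times
  dtmin <- if (length(times) > 1L) min(diff(times)) else Inf
  if (interval < dtmin - 1e-9) {
    stop("analysis interval (", interval, " ns) is finer than the ",
         "trajectory sampling (", dtmin, " ns)")
  }
  if (times[length(times)] - times[1] < interval) {
    stop("trajectory spans less than one analysis interval")
  }
  snap_times <- seq(times[1], times[length(times)], by = interval)
  snap_idx <- vapply(snap_times, function(t) which.min(abs(times - t)), 1L)
  snap_idx <- unique(snap_idx)

  n_lip <- length(top$phosphate_map)
  count <- integer(length(snap_idx))
  events <- integer(length(snap_idx))
  init <- NULL; prev <- NULL; cum <- 0L
  for (j in seq_along(snap_idx)) {
    la <- assign_leaflets(get_frame(traj, snap_idx[j]), top, previous = prev)
    if (is.null(init)) init <- la$labels
    if (!is.null(prev)) cum <- cum + sum(la$labels != prev)
    count[j] <- sum(la$labels != init)
    events[j] <- cum
    prev <- la$labels
  }
  out <- data.frame(time = times[snap_idx], count = count,
                    cumulative_events = events, fraction = count / n_lip)
  if (!is.null(smoothing_window)) {
    half <- max(0L, round(smoothing_window / interval / 2))
    out$count_smooth <- vapply(seq_len(nrow(out)), function(j) {
      lo <- max(1L, j - half); hi <- min(nrow(out), j + half)
      mean(count[lo:hi])
    }, numeric(1))
  }
  attr(out, "interval") <- interval
  attr(out, "n_lipids") <- n_lip
  class(out) <- c("sk_scrambling_trace", class(out))
  out
}

#' Scrambling rate from a trace
#'
#' Rate = cumulative transition events / observed span, in events per
#' microsecond, with a block-bootstrap confidence interval over the
#' per-snapshot event increments.
#'
#' @param trace an sk_scrambling_trace
#' @param conf confidence level for the bootstrap interval
#' @param n_boot bootstrap replicates
#' @param seed RNG seed for the bootstrap
#' @return list(rate, events, span_us, ci = c(lo, hi))
#' @export
scrambling_rate <- function(trace, conf = 0.95, n_boot = 200, seed = 1L) {
  stopifnot(inherits(trace, "sk_scrambling_trace"), nrow(trace) > 0)
  span_ns <- trace$time[nrow(trace)] - trace$time[1]
  if (span_ns <= 0) stop("trace has zero observation span")
  span_us <- span_ns / 1000
  events <- trace$cumulative_events[nrow(trace)]
  rate <- events / span_us
  if (events == 0L) {
    return(list(rate = 0, events = 0L, span_us = span_us, ci = c(0, 0)))
  }
  incr <- diff(trace$cumulative_events)
  block <- max(1L, floor(length(incr) / 20))
  n_blocks <- ceiling(length(incr) / block)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    starts <- sample.int(length(incr) - block + 1L, n_blocks, replace = TRUE)
    resampled <- unlist(lapply(starts, function(s) incr[s:(s + block - 1L)]))
    sum(resampled[seq_along(incr)]) / span_us
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(rate = rate, events = events, span_us = span_us,
       ci = unname(stats::quantile(reps, c(alpha, 1 - alpha))))
}
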