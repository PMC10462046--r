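#' Cylinder-based flip-flop collective variable
#'
#' The CV is the oriented z-distance between a target lipid phosphate and the
#' local membrane center of mass, where "local" means all membrane particles
#' whose xy minimum-image distance from the target is at most the cylinder
#' radius (the cylinder axis is +z through the target). Positive values point
#' toward +z. This mirrors the Gromacs pull "cylinder" geometry used to
#' restrain a translocating lipid relative to the membrane patch around it.
#'
#' @param fr an sk_frame
#' @param target 1-based particle index of the tracked phosphate
#' @param membrane sk_selection (or index vector) of membrane particles
#'   contributing to the local center of mass
#' @param radius cylinder radius in nm (2.0 for a plain bilayer, 3.0 for the
#'   protein systems)
#' @param masses optional per-particle mass vector for mass weighting;
#'   unweighted (equal-mass coarse-grained beads) when NULL
#' @return xi in nm
#' @export
cylinder_cv <- function(fr, target, membrane, radius, masses = NULL) {
  stopifnot(inherits(fr, "sk_frame"), radius > 0)
  idx <- if (inherits(membrane, "sk_selection")) membrane$indices else membrane
  if (length(idx) == 0L) stop("membrane selection is empty")
  pos <- fr$positions
  d <- min_image(cbind(pos[idx, 1] - pos[target, 1],
                       pos[idx, 2] - pos[target, 2]),
                 fr$box[1:2])
  if (!is.matrix(d)) d <- matrix(d, ncol = 2)
  inside <- d[, 1]^2 + d[, 2]^2 <= radius^2
  if (!any(inside)) stop("no membrane particles inside the cylinder of radius ",
                         radius, " nm around the target")
  members <- idx[inside]
  w <- if (is.null(masses)) rep(1, length(members)) else masses[members]
  # z of members taken relative to the target via minimum image, so a
  # bilayer split across the z boundary still yields a local reference
  dz <- min_image(matrix(pos[members, 3] - pos[target, 3], ncol = 1),
                  fr$box[3])
  pos[target, 3] - (pos[target, 3] + sum(w * dz) / sum(w))
}

#' Bias potential: harmonic umbrella plus optional flat-bottom xy restraint
#'
#' The umbrella term is 1/2 k (xi - center)^2 on the collective variable.
#' The flat-bottom term keeps the tracked lipid near an anchor particle in
#' the xy plane: zero for xy distance d <= d0, else 1/2 k_fb (d - d0)^2.
#' Defaults for the flat-bottom follow the published restraint (d0 = 2.5 nm,
#' k_fb = 500 kJ/mol/nm^2).
#'
#' @param center umbrella center in nm (NULL for no umbrella)
#' @param k umbrella force constant in kJ/mol/nm^2
#' @param flat_bottom optional list(anchor, d0 = 2.5, k = 500): anchor
#'   particle index, reference xy distance (nm) and force constant
#' @return an object of class "sk_bias"
#' @export
bias_potential <- function(center = NULL, k = 0, flat_bottom = NULL) {
  stopifnot(k >= 0)
  if (!is.null(flat_bottom)) {
    flat_bottom$d0 <- flat_bottom$d0 %||% 2.5
    flat_bottom$k <- flat_bottom$k %||% 500
    stopifnot(flat_bottom$d0 > 0, flat_bottom$k >= 0)
  }
  structure(list(center = center, k = k, flat_bottom = flat_bottom),
            class = "sk_bias")
}

#' Bias energy
#'
#' Sums the harmonic umbrella energy at the given CV value(s) and, when a
#' frame with a target particle is supplied, the flat-bottom xy restraint
#' energy (minimum-image xy distance between target and anchor).
#'
#' @param bias an sk_bias
#' @param xi CV value(s) in nm (required when the bias has an umbrella term)
#' @param fr optional sk_frame for the flat-bottom term
#' @param target particle index of the restrained lipid (with `fr`)
#' @param dxy alternatively, a precomputed xy distance in nm
#' @return energy in kJ/mol (vectorised over `xi`)
#' @export
bias_energy <- function(bias, xi = NULL, fr = NULL, target = NULL, dxy = NULL) {
  stopifnot(inherits(bias, "sk_bias"))
  e <- 0
  if (!is.null(bias$center) && bias$k > 0) {
    if (is.null(xi)) stop("umbrella bias needs a CV value")
    e <- 0.5 * bias$k * (xi - bias$center)^2
  } else if (!is.null(xi)) {
    e <- rep(0, length(xi))
  }
  fb <- bias$flat_bottom
  if (!is.null(fb)) {
    if (is.null(dxy)) {
      if (is.null(fr) || is.null(target)) {
        stop("flat-bottom bias needs a frame and target, or a precomputed dxy")
      }
      dvec <- min_image(fr$positions[target, 1:2] - fr$positions[fb$anchor, 1:2],
                        fr$box[1:2])
      dxy <- sqrt(sum(dvec^2))
    }
    excess <- pmax(0, dxy - fb$d0)
    e <- e + 0.5 * fb$k * excess^2
  }
  e
}

#' Place umbrella windows on a pulling trace
#'
#' Given a pulling trace (time, xi), returns for each requested center the
#' trace point whose CV is nearest (earliest point on ties) — the seed frame
#' for that window. Centers can be given explicitly or generated by a
#' spacing scheme that is dense near the membrane midplane: spacing grows
#' linearly from `core_spacing` at xi = 0 to `surface_spacing` at
#' |xi| >= `switch_at`.
#'
#' @param trace data.frame with columns `time` and `xi`
#' @param centers explicit numeric vector of window centers (nm), or NULL to
#'   use the spacing scheme
#' @param range CV range c(lo, hi) for the spacing scheme
#' @param surface_spacing window spacing near the membrane surface (nm)
#' @param core_spacing window spacing near the membrane center (nm)
#' @param switch_at |xi| beyond which the surface spacing applies (nm)
#' @return data.frame(center, time, xi, index) sorted by center
#' @export
place_windows <- function(trace, centers = NULL, range = c(-2.3, 2.3),
                          surface_spacing = 0.1, core_spacing = 0.03,
                          switch_at = 0.5) {
  stopifnot(all(c("time", "xi") %in% names(trace)))
  if (is.null(centers)) {
    centers <- spacing_scheme_centers(range, surface_spacing, core_spacing,
                                      switch_at)
  }
  lo <- min(trace$xi); hi <- max(trace$xi)
  uncovered <- centers[centers < lo - 1e-9 | centers > hi + 1e-9]
  if (length(uncovered)) {
    stop("requested center(s) outside the pulling trace range [",
         signif(lo, 4), ", ", signif(hi, 4), "]: ",
         paste(signif(uncovered, 4), collapse = ", "))
  }
  rows <- vapply(centers, function(cc) {
    d <- abs(trace$xi - cc)
    which(d == min(d))[1]          # earliest frame on ties
  }, 1L)
  out <- data.frame(center = centers, time = trace$time[rows],
                    xi = trace$xi[rows], index = rows)
  out[order(out$center), , drop = FALSE]
}

# Monotone window centers over `range`, dense near xi = 0: local spacing
# s(xi) = core + (surface - core) * min(1, |xi| / switch_at), accumulated
# outward from 0 and mirrored.
spacing_scheme_centers <- function(range, surface_spacing, core_spacing,
                                   switch_at) {
  stopifnot(range[1] < 0, range[2] > 0, core_spacing > 0,
            surface_spacing >= core_spacing)
  up <- 0
  while (TRUE) {
    x <- up[length(up)]
    s <- core_spacing + (surface_spacing - core_spacing) *
      min(1, abs(x) / switch_at)
    nx <- x + s
    if (nx > range[2] + 1e-12) break
    up <- c(up, nx)
  }
  dn <- 0
  while (TRUE) {
    x <- dn[1]
    s <- core_spacing + (surface_spacing - core_spacing) *
      min(1, abs(x) / switch_at)
    nx <- x - s
    if (nx < range[1] - 1e-12) break
    dn <- c(nx, dn)
  }
  c(dn[-length(dn)], up)
}

#' Harvest umbrella-window samples from per-window CV files
#'
#' Reads two-column whitespace-separated (time, xi) files, tolerating
#' comment lines starting with `#` or `@` (common pull-output dialects),
#' discards the equilibration segment (samples with time <= cutoff), and
#' assembles a window set.
#'
#' @param files character vector of per-window sample file paths
#' @param centers umbrella centers (nm), one per file
#' @param k umbrella force constants (kJ/mol/nm^2), recycled to all windows
#' @param cutoff equilibration cutoff in ns (default 10: the first 10 ns of
#'   each window are equilibration only)
#' @return an object of class "sk_windowset": list of windows (center, k,
#'   samples data.frame, n) ordered by center
#' @export
harvest_samples <- function(files, centers, k = 1000, cutoff = 10) {
  stopifnot(length(files) == length(centers), cutoff >= 0)
  k <- rep_len(k, length(files))
  windows <- lapply(seq_along(files), function(i) {
    sm <- read_cv_samples(files[i])
    keep <- sm$time > cutoff
    if (!any(keep)) {
      stop("window ", i, " (center ", centers[i], " nm, file ", files[i],
           ") has no samples after the ", cutoff, " ns equilibration cutoff")
    }
    list(center = centers[i], k = k[i], samples = sm[keep, , drop = FALSE],
         n = sum(keep))
  })
  window_set(windows)
}

read_cv_samples <- function(path) {
  if (!file.exists(path)) stop("sample file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data lines in sample file: ", path)
  vals <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(vals) < 2L)
  if (length(bad)) stop("malformed line ", bad[1], " in ", path)
  time <- suppressWarnings(as.numeric(vapply(vals, `[`, "", 1L)))
  xi <- suppressWarnings(as.numeric(vapply(vals, `[`, "", 2L)))
  if (anyNA(time) || anyNA(xi)) stop("non-numeric data in ", path)
  data.frame(time = time, xi = xi)
}

#' Assemble a window set
#'
#' Orders windows by center, enforces strictly monotone centers and warns
#' when adjacent windows' sample distributions barely overlap (estimated
#' overlap below 1 percent), which starves WHAM of cross-window information.
#'
#' @param windows list of windows: each list(center, k, samples, n)
#' @return an "sk_windowset"
#' @export
window_set <- function(windows) {
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  windows <- windows[ord]
  centers <- vapply(windows, `[[`, numeric(1), "center")
  if (any(diff(centers) <= 0)) {
    stop("window centers must be strictly monotone (duplicate center?)")
  }
  for (i in seq_len(length(windows) - 1L)) {
    ov <- gaussian_overlap(windows[[i]]$samples$xi, windows[[i + 1L]]$samples$xi)
    if (ov < 0.01) {
      warning("windows at centers ", centers[i], " and ", centers[i + 1L],
              " nm overlap by only ", signif(100 * ov, 2), "%")
    }
  }
  structure(list(windows = windows, range = range(centers)),
            class = "sk_windowset")
}

# Overlap coefficient of two Gaussians moment-matched to the samples.
gaussian_overlap <- function(a, b) {
  m1 <- mean(a); s1 <- max(stats::sd(a), 1e-12)
  m2 <- mean(b); s2 <- max(stats::sd(b), 1e-12)
  grid <- seq(min(m1 - 6 * s1, m2 - 6 * s2), max(m1 + 6 * s1, m2 + 6 * s2),
              length.out = 512)
  h <- grid[2] - grid[1]
  sum(pmin(stats::dnorm(grid, m1, s1), stats::dnorm(grid, m2, s2))) * h
}

#' @export
print.sk_windowset <- function(x, ...) {
  cat("<sk_windowset> ", length(x$windows), " windows, centers ",
      signif(x$range[1], 4), " .. ", signif(x$range[2], 4), " nm, ",
      sum(vapply(x$windows, `[[`, numeric(1), "n")), " samples\n", sep = "")
  invisible(x)
}
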