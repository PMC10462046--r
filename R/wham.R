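#' Weighted histogram analysis method (WHAM)
#'
#' Reconstructs the unbiased probability P(xi) over the collective variable
#' from a set of umbrella windows by iterating the self-consistent WHAM
#' equations
#' \deqn{P(b) = \frac{\sum_i n_i(b)}{\sum_i N_i \exp[(f_i - U_i(\xi_b)) / k_B T]}}
#' \deqn{f_i = -k_B T \ln \sum_b P(b) \exp[-U_i(\xi_b) / k_B T]}
#' where n_i(b) is window i's histogram count in bin b, N_i its sample
#' count, U_i the bias energy at the bin center and f_i the window free-energy
#' offset. Iteration stops when max |delta f_i| falls below `tol`.
#'
#' @param windows an sk_windowset (see [harvest_samples()] / [window_set()])
#' @param bins bin width in nm (default 0.05) or an explicit vector of bin
#'   edges over the CV range
#' @param temperature temperature in K (default 310)
#' @param tol convergence tolerance on the offsets, kJ/mol (default 1e-8)
#' @param max_iter iteration cap (default 1e5); non-convergence is an error
#'   reporting the residual
#' @return an "sk_wham": list(bin_centers, P, f [offsets, f[1] = 0],
#'   counts [total per bin], iterations, converged, temperature)
#' @export
wham_solve <- function(windows, bins = 0.05, temperature = 310,
                       tol = 1e-8, max_iter = 1e5) {
  stopifnot(inherits(windows, "sk_windowset"))
  win <- windows$windows
  xi_all <- unlist(lapply(win, function(w) w$samples$xi))
  if (length(bins) == 1L) {
    # histogram over the windowed CV range: bins past the outermost umbrella
    # centers are reweighted from a single window tail, and their noisy F
    # would corrupt the min-zero alignment of the profile. Falls back to the
    # sample range when the centers span < 2 bins (unbiased input).
    ctr <- vapply(win, `[[`, numeric(1), "center")
    lo <- min(ctr); hi <- max(ctr)
    if (hi - lo < 2 * bins) { lo <- min(xi_all); hi <- max(xi_all) }
    edges <- seq(floor(lo / bins) * bins, ceiling(hi / bins) * bins, by = bins)
  } else {
    edges <- sort(bins)
  }
  if (length(edges) < 3L) stop("need at least 2 bins")
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(centers)
  nw <- length(win)
  kt <- kBT(temperature)

  # samples outside the histogram range are discarded (with N_i reduced
  # accordingly), never clamped into the edge bins
  n_ib <- vapply(win, function(w) {
    xi <- w$samples$xi
    xi <- xi[xi >= edges[1] & xi <= edges[length(edges)]]
    idx <- findInterval(xi, edges, rightmost.closed = TRUE)
    tabulate(idx, nbins = nb)
  }, numeric(nb))                     # nb x nw
  N_i <- colSums(n_ib)
  if (any(N_i == 0)) {
    stop("window(s) ", paste(which(N_i == 0), collapse = ", "),
         " have no samples inside the histogram range")
  }
  U_ib <- vapply(win, function(w) {
    0.5 * w$k * (centers - w$center)^2 + (w$offset %||% 0)
  }, numeric(nb))                     # nb x nw
  M <- exp(-U_ib / kt)                # bias Boltzmann factors
  num <- rowSums(n_ib)

  # The WHAM equations are the stationarity conditions of a convex negative
  # log-likelihood in the window offsets g = f/kBT (Zhu & Hummer style), so
  # the offsets are first found by BFGS on that objective — orders of
  # magnitude faster than direct iteration when window coupling is weak —
  # and then polished by direct iteration to the stated tolerance.
  lN <- log(N_i)
  nll <- function(g2) {
    g <- c(0, g2)
    l <- sweep(-U_ib / kt, 2, g + lN, `+`)        # nb x nw
    mb <- apply(l, 1, max)
    lse <- mb + log(rowSums(exp(l - mb)))
    sum(num * lse) - sum(N_i * g)
  }
  nll_grad <- function(g2) {
    g <- c(0, g2)
    l <- sweep(-U_ib / kt, 2, g + lN, `+`)
    mb <- apply(l, 1, max)
    W <- exp(l - mb)
    W <- W / rowSums(W)
    (colSums(num * W) - N_i)[-1]
  }
  g2 <- if (nw > 1L) {
    stats::optim(numeric(nw - 1L), nll, nll_grad, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))$par
  } else numeric(0)
  f <- c(0, g2) * kt

  it <- 0L
  repeat {
    it <- it + 1L
    denom <- as.numeric(M %*% (N_i * exp(f / kt)))
    P <- ifelse(denom > 0, num / denom, 0)
    P <- P / sum(P)
    zi <- as.numeric(crossprod(M, P))
    f_new <- -kt * log(zi)
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) break
    if (it >= max_iter) {
      stop("WHAM did not converge in ", max_iter,
           " iterations (residual ", signif(resid, 3), " kJ/mol)")
    }
  }
  structure(list(bin_centers = centers, P = P, f = f, counts = num,
                 iterations = it, converged = TRUE,
                 temperature = temperature),
            class = "sk_wham")
}

#' Free-energy profile from a WHAM result
#'
#' F(xi) = -kBT ln P(xi), shifted so the global minimum is zero. Bins with no
#' samples are masked (NA), never extrapolated. The profile carries an
#' asymmetry error estimate: max over xi of |F(xi) - F(-xi)| / 2, the profile
#' mirrored about xi = 0 (a flip-flop profile in a symmetric bilayer should
#' be symmetric, so the residual asymmetry bounds the sampling error).
#'
#' @param result an sk_wham
#' @param min_count bins with fewer total samples are masked (default 1)
#' @return an "sk_profile": data.frame(xi, F, counts) with attributes
#'   `asymmetry_error` (kJ/mol) and `temperature`
#' @export
to_profile <- function(result, min_count = 1) {
  stopifnot(inherits(result, "sk_wham"))
  if (!isTRUE(result$converged)) stop("WHAM result is not converged")
  kt <- kBT(result$temperature)
  F <- ifelse(result$P > 0 & result$counts >= min_count,
              -kt * log(result$P), NA_real_)
  if (all(is.na(F))) stop("profile has no supported bins")
  F <- F - min(F, na.rm = TRUE)
  out <- data.frame(xi = result$bin_centers, F = F, counts = result$counts)
  attr(out, "asymmetry_error") <- profile_asymmetry(out$xi, out$F)
  attr(out, "temperature") <- result$temperature
  class(out) <- c("sk_profile", class(out))
  out
}

# max |F(xi) - F(-xi)| / 2 over points where the mirrored value is defined
# (linear interpolation onto -xi).
profile_asymmetry <- function(xi, F) {
  ok <- !is.na(F)
  if (sum(ok) < 2L) return(NA_real_)
  mirrored <- stats::approx(xi[ok], F[ok], xout = -xi[ok], rule = 1)$y
  d <- abs(F[ok] - mirrored) / 2
  if (all(is.na(d))) return(NA_real_)
  max(d, na.rm = TRUE)
}

#' Barrier height and reduction report
#'
#' The flip-flop barrier is the global maximum of the profile (the minimum is
#' zero by construction). With a reference profile (or a bare reference
#' barrier in kJ/mol), the percent reduction
#' (barrier_ref - barrier) / barrier_ref x 100 is reported — e.g. a drop from
#' 62 to 7 kJ/mol is an 88.7% reduction.
#'
#' @param profile an sk_profile
#' @param reference optional sk_profile or single numeric reference barrier
#' @return list(barrier, asymmetry_error, reference_barrier, reduction_pct)
#' @export
extract_barrier <- function(profile, reference = NULL) {
  stopifnot(inherits(profile, "sk_profile"))
  if (all(is.na(profile$F))) stop("profile is fully masked")
  barrier <- max(profile$F, na.rm = TRUE)
  ref_b <- NULL
  red <- NULL
  if (!is.null(reference)) {
    ref_b <- if (inherits(reference, "sk_profile")) {
      max(reference$F, na.rm = TRUE)
    } else as.numeric(reference)
    red <- (ref_b - barrier) / ref_b * 100
  }
  list(barrier = barrier,
       asymmetry_error = attr(profile, "asymmetry_error"),
       reference_barrier = ref_b, reduction_pct = red)
}

#' Pointwise mean of two free-energy profiles
#'
#' When umbrella sets from the two pulling directions show no hysteresis,
#' both profiles are reported separately and alongside their pointwise mean
#' (bins averaged where both are defined, min re-shifted to zero).
#'
#' @param a,b sk_profile objects on compatible bin grids
#' @return an sk_profile whose F is the bin-wise mean of `a` and `b`
#' @export
profile_mean <- function(a, b) {
  stopifnot(inherits(a, "sk_profile"), inherits(b, "sk_profile"))
  fb <- stats::approx(b$xi, b$F, xout = a$xi, rule = 1)$y
  F <- (a$F + fb) / 2
  F <- F - min(F, na.rm = TRUE)
  out <- data.frame(xi = a$xi, F = F,
                    counts = a$counts + stats::approx(b$xi, b$counts,
                                                      xout = a$xi, rule = 2)$y)
  attr(out, "asymmetry_error") <- profile_asymmetry(out$xi, out$F)
  attr(out, "temperature") <- attr(a, "temperature")
  class(out) <- c("sk_profile", class(out))
  out
}
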