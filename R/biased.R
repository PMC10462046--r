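#' Draw biased samples of the flip-flop collective variable
#'
#' Samples the 1-D marginal of the configured flip-flop potential under a
#' bias, i.e. xi distributed as exp(-(U0(xi) + U_bias(xi)) / kBT). Sampling
#' is by inverse-CDF lookup on a fine adaptive grid (piecewise-linear CDF),
#' which draws effectively independent samples from the target density —
#' exactly what a long, well-mixed umbrella window provides to WHAM.
#'
#' For groove scenarios the marginal is taken on the groove axis (the
#' umbrella-restrained lipid is confined to the scrambling pathway by the
#' flat-bottom restraint, so its xi samples feel the in-groove potential).
#'
#' @param potential an sk_potential (or an sk_scenario, whose potential and
#'   temperature are used)
#' @param bias an sk_bias (see [bias_potential()]); only its harmonic CV part
#'   enters the 1-D marginal
#' @param n_samples number of samples to draw
#' @param seed integer RNG seed
#' @param temperature temperature in K (ignored when a scenario is given)
#' @param on_axis sample the in-groove marginal (default TRUE when the
#'   potential has a groove)
#' @param range CV range covered by the sampling grid
#' @param sample_interval spacing of the emitted time stamps in ns
#' @return data.frame(time, xi) of CV samples
#' @export
sample_biased <- function(potential, bias, n_samples, seed = 1L,
                          temperature = 310, on_axis = NULL,
                          range = NULL, sample_interval = 0.1) {
  if (inherits(potential, "sk_scenario")) {
    temperature <- potential$temperature
    potential <- potential$potential
  }
  stopifnot(inherits(potential, "sk_potential"), inherits(bias, "sk_bias"),
            n_samples >= 1)
  if (is.null(on_axis)) on_axis <- !is.null(potential$groove)
  beta <- 1 / kBT(temperature)
  z0 <- potential$z0

  if (is.null(range)) range <- c(-1.6 * z0, 1.6 * z0)
  h <- 0.001
  if (!is.null(bias$k) && bias$k > 0) {
    sigma <- sqrt(kBT(temperature) / bias$k)
    range <- c(min(range[1], bias$center - 10 * sigma),
               max(range[2], bias$center + 10 * sigma))
    h <- min(h, sigma / 50)
  }
  grid <- seq(range[1], range[2], by = h)
  u <- evaluate_potential(potential, grid, z_only = TRUE, on_axis = on_axis) +
    bias_energy(bias, xi = grid)
  logw <- -beta * u
  dens <- exp(logw - max(logw))
  supp <- sum(dens > 1e-6 * max(dens))
  if (supp < 5L) {
    warning("bias confines the CV to fewer than 5 grid cells; window may ",
            "not overlap its neighbours")
  }
  # trapezoidal CDF at the grid nodes: second-order accurate, so the draws
  # carry no O(h) location bias (a plain cumsum staircase shifts every
  # sample by h/2, which WHAM would read as a spurious profile tilt)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)     # approx() needs strictly increasing x
  set.seed(seed)
  xi <- stats::approx(cdf[keep], grid[keep], xout = stats::runif(n_samples),
                      rule = 2)$y
  data.frame(time = seq_len(n_samples) * sample_interval, xi = xi)
}
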