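# Build a window set by exact Boltzmann sampling of a potential under
# harmonic umbrellas (the standard synthetic WHAM input used throughout).
make_windows <- function(pot, centers, k = 200, n = 5000, seed = 1,
                         temperature = 310) {
  wins <- lapply(seq_along(centers), function(i) {
    sm <- sample_biased(pot, bias_potential(centers[i], k), n,
                        seed = seed + i, temperature = temperature)
    list(center = centers[i], k = k, samples = sm, n = nrow(sm))
  })
  window_set(wins)
}

test_that("single unbiased window degenerates to Boltzmann inversion", {
  pot <- flipflop_potential(6)
  sm <- sample_biased(pot, bias_potential(), 50000, seed = 3)
  ws <- window_set(list(list(center = 0, k = 0, samples = sm, n = nrow(sm))))
  res <- wham_solve(ws, bins = 0.1)
  # direct histogram inversion on the same bins
  prof <- to_profile(res, min_count = 50)
  h <- hist(sm$xi, breaks = c(res$bin_centers - 0.05,
                              max(res$bin_centers) + 0.05), plot = FALSE)
  direct <- -kBT(310) * log(h$counts / sum(h$counts))
  direct <- direct - min(direct[is.finite(direct)])
  ok <- !is.na(prof$F) & is.finite(direct)
  expect_equal(prof$F[ok], direct[ok], tolerance = 1e-6)
})

test_that("duplicating every window leaves the profile unchanged", {
  pot <- flipflop_potential(10)
  ws <- make_windows(pot, seq(-2.2, 2.2, length.out = 15), n = 3000, seed = 7)
  edges <- seq(-2.5, 2.5, by = 0.1)   # fixed edges so both solves share bins
  res1 <- wham_solve(ws, bins = edges)
  dup <- window_set(c(ws$windows, lapply(ws$windows, function(w) {
    w$center <- w$center + 1e-9   # keep centers strictly monotone
    w
  })))
  res2 <- wham_solve(dup, bins = edges)
  expect_equal(to_profile(res2)$F, to_profile(res1)$F, tolerance = 1e-5)
})

test_that("WHAM is invariant under window reordering and bias constants", {
  pot <- flipflop_potential(10)
  ws <- make_windows(pot, seq(-2.2, 2.2, length.out = 15), n = 3000, seed = 21)
  res <- wham_solve(ws, bins = 0.1)
  # reorder (window_set re-sorts internally; feed pre-shuffled list)
  shuffled <- window_set(ws$windows[sample(seq_along(ws$windows))])
  expect_equal(wham_solve(shuffled, bins = 0.1)$P, res$P, tolerance = 1e-9)
  # add a constant to every bias potential
  offset <- lapply(ws$windows, function(w) { w$offset <- 13.7; w })
  res_off <- wham_solve(window_set(offset), bins = 0.1)
  expect_equal(res_off$P, res$P, tolerance = 1e-7)
})

test_that("harmonic ground truth is recovered with the right curvature", {
  # windows over a pure harmonic U0 = 1/2 kappa xi^2: the biased marginal in
  # window i is an exact Gaussian (closed form), so the windows can be drawn
  # directly and WHAM must give back a quadratic profile with curvature kappa
  kappa <- 50   # kJ/mol/nm^2
  centers <- seq(-1.5, 1.5, length.out = 20)
  k_umb <- 400
  wins <- lapply(seq_along(centers), function(i) {
    sigma2 <- kBT(310) / (kappa + k_umb)
    mu <- k_umb * centers[i] / (kappa + k_umb)
    set.seed(99 + i)
    xi <- stats::rnorm(10000, mu, sqrt(sigma2))
    list(center = centers[i], k = k_umb,
         samples = data.frame(time = seq_along(xi), xi = xi), n = length(xi))
  })
  res <- wham_solve(window_set(wins), bins = 0.05)
  prof <- to_profile(res, min_count = 100)
  ok <- !is.na(prof$F) & abs(prof$xi) < 1.2
  fit <- stats::lm(prof$F[ok] ~ I(prof$xi[ok]^2))
  kappa_hat <- 2 * stats::coef(fit)[2]
  expect_lt(abs(kappa_hat - kappa) / kappa, 0.05)
})

test_that("recovered profile tracks any configured double-well within 0.5 kJ/mol RMS", {
  for (B in c(8, 25)) {
    pot <- flipflop_potential(B)
    ws <- make_windows(pot, seq(-2.3, 2.3, length.out = 35), k = 1000, n = 8000,
                       seed = 200 + B)
    prof <- to_profile(wham_solve(ws))
    ok <- prof$counts >= 100 & !is.na(prof$F)
    truth <- evaluate_potential(pot, prof$xi[ok], z_only = TRUE)
    truth <- truth - min(truth)
    expect_lt(sqrt(mean((prof$F[ok] - truth)^2)), 0.5)
  }
})

test_that("halving the bin width moves the barrier by less than 0.5 kJ/mol", {
  pot <- flipflop_potential(20)
  ws <- make_windows(pot, seq(-2.3, 2.3, length.out = 35), k = 1000, n = 8000, seed = 5)
  b1 <- extract_barrier(to_profile(wham_solve(ws, bins = 0.05)))$barrier
  b2 <- extract_barrier(to_profile(wham_solve(ws, bins = 0.025)))$barrier
  expect_lt(abs(b1 - b2), 0.5)
})

test_that("profiles are min-zero, masked where unsupported, with asymmetry error", {
  pot <- flipflop_potential(15)
  ws <- make_windows(pot, seq(-2.0, 2.0, length.out = 21), n = 2000, seed = 11)
  prof <- to_profile(wham_solve(ws))
  expect_equal(min(prof$F, na.rm = TRUE), 0)
  expect_true(all(is.na(prof$F[prof$counts == 0])))
  expect_true(is.finite(attr(prof, "asymmetry_error")))
  # symmetric profile: zero asymmetry error by construction
  xi <- seq(-2, 2, by = 0.1)
  sym <- structure(data.frame(xi = xi, F = (xi^2 - 1)^2, counts = 1000),
                   class = c("sk_profile", "data.frame"))
  expect_equal(scramblekit:::profile_asymmetry(sym$xi, sym$F), 0,
               tolerance = 1e-12)
  # constructed asymmetry: F(1) = 10 vs F(-1) = 6 gives error 2
  F2 <- (xi^2 - 1)^2
  F2[xi == 1] <- 10; F2[xi == -1] <- 6
  expect_equal(scramblekit:::profile_asymmetry(xi, F2), 2)
})

test_that("non-convergence and empty inputs raise errors", {
  pot <- flipflop_potential(10)
  ws <- make_windows(pot, seq(-1, 1, length.out = 5), n = 500, seed = 2)
  expect_error(wham_solve(ws, tol = 0, max_iter = 3), "converge")
  res <- wham_solve(ws)
  res$converged <- FALSE
  expect_error(to_profile(res), "not converged")
})

test_that("barrier reports reproduce the published reduction percentages", {
  mk_prof <- function(barrier) {
    xi <- seq(-2.3, 2.3, by = 0.05)
    structure(data.frame(xi = xi,
                         F = barrier * (1 - (xi / 2)^2)^2 * (abs(xi) <= 2),
                         counts = 1000),
              class = c("sk_profile", "data.frame"))
  }
  # self-reference: zero reduction
  expect_equal(extract_barrier(mk_prof(62), reference = 62)$reduction_pct, 0)
  # flat profile: zero barrier
  flat <- structure(data.frame(xi = seq(-1, 1, 0.1), F = 0, counts = 10),
                    class = c("sk_profile", "data.frame"))
  expect_equal(extract_barrier(flat)$barrier, 0)
  # published barrier pairs: 62 -> 7 (~almost 90%), 83 -> 15 (~80%),
  # 92 -> 16 (over 80%)
  expect_equal(extract_barrier(mk_prof(7), reference = 62)$reduction_pct,
               88.7, tolerance = 0.001)
  expect_equal(extract_barrier(mk_prof(15), reference = 83)$reduction_pct,
               81.9, tolerance = 0.001)
  expect_equal(extract_barrier(mk_prof(16), reference = 92)$reduction_pct,
               82.6, tolerance = 0.001)
})

test_that("profile pairs from opposite pulling directions pool by pointwise mean", {
  xi <- seq(-2, 2, by = 0.1)
  mk <- function(F) structure(data.frame(xi = xi, F = F - min(F), counts = 100),
                              class = c("sk_profile", "data.frame"))
  a <- mk(10 * (1 - (xi / 2)^2)^2)
  b <- mk(14 * (1 - (xi / 2)^2)^2)
  m <- profile_mean(a, b)
  expect_equal(max(m$F, na.rm = TRUE), 12)
  expect_equal(min(m$F, na.rm = TRUE), 0)
  expect_equal(attr(m, "asymmetry_error"), 0, tolerance = 1e-12)
})
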