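test_that("a single unbiased window reduces WHAM to Boltzmann inversion", {
  Ffun <- function(x) 2 * (x - 0.5)^2 / 0.01 # harmonic well in kBT
  win <- gen_umbrella_samples(Ffun, centers = 0.5, k_spring = 0, n = 40000,
                              seed = 8, support = c(0.3, 0.7))
  prof <- wham_1d(win, n_bins = 60)
  # direct -ln(histogram) on the same grid
  h <- hist(win[[1]]$samples,
            breaks = seq(min(win[[1]]$samples), max(win[[1]]$samples),
                         length.out = 61), plot = FALSE)
  ref <- -log(h$counts[h$counts > 0])
  ref <- ref - min(ref)
  expect_equal(length(prof$F), length(ref))
  expect_equal(prof$F, ref, tolerance = 1e-10)
  # and both agree with the planted well where sampled well
  sel <- prof$F < 4
  d <- prof$F[sel] - Ffun(prof$r[sel])
  expect_lt(sd(d), 0.12)
})

test_that("WHAM is invariant under sample reordering and translation", {
  dw <- double_well()
  centers <- seq(0.3, 0.7, length.out = 12)
  win <- gen_umbrella_samples(dw, centers, k_spring = 10000, n = 1500, seed = 2)
  p1 <- wham_1d(win, n_bins = 80)
  win_shuf <- lapply(win, function(w) {
    w$samples <- rev(w$samples); w
  })
  p2 <- wham_1d(win_shuf, n_bins = 80)
  expect_equal(p1$F, p2$F, tolerance = 1e-9)
  # translation by +1 nm shifts the grid, not the shape
  win_tr <- lapply(win, function(w) {
    w$center <- w$center + 1; w$samples <- w$samples + 1; w
  })
  p3 <- wham_1d(win_tr, n_bins = 80)
  expect_equal(p3$F, p1$F, tolerance = 1e-9)
  expect_equal(p3$r, p1$r + 1, tolerance = 1e-12)
})

test_that("a single biased window with bias removed matches direct reweighting", {
  kBT <- mgff_constants()$kB * 298.15
  Ffun <- function(x) 4 * sin(8 * pi * x)
  win <- gen_umbrella_samples(Ffun, centers = 0.5, k_spring = 400, n = 60000,
                              seed = 13, support = c(0.25, 0.75))
  prof <- wham_1d(win, n_bins = 80)
  # direct estimate: histogram, then add back the bias at bin centers
  x <- win[[1]]$samples
  breaks <- seq(min(x), max(x), length.out = 81)
  h <- hist(x, breaks = breaks, plot = FALSE)
  occ <- h$counts > 0
  # remove the bias as its bin-averaged Boltzmann factor (fine midpoint rule)
  bias_fac <- vapply(which(occ), function(b) {
    xs <- seq(breaks[b], breaks[b + 1], length.out = 51)
    mean(exp(-0.5 * 400 * (xs - 0.5)^2 / kBT))
  }, 0)
  direct <- -log(h$counts[occ]) + log(bias_fac)
  direct <- direct - min(direct)
  keep <- prof$F < 6 & direct < 6
  expect_lt(max(abs((prof$F - mean(prof$F[keep])) -
                    (direct - mean(direct[keep])))[keep]), 1e-3)
})

test_that("non-overlapping windows fail with a gap-naming error", {
  w1 <- umbrella_window(0.3, 5000, rnorm(100, 0.3, 0.01))
  w2 <- umbrella_window(0.7, 5000, rnorm(100, 0.7, 0.01))
  expect_error(wham_1d(list(w1, w2)), "do not overlap")
})

test_that("planted double well is recovered to the stated accuracy", {
  dw <- double_well(h = 15)
  centers <- seq(0.29, 0.71, length.out = 20)
  win <- gen_umbrella_samples(dw, centers, k_spring = 10000, n = 5000, seed = 7)
  prof <- wham_1d(win, n_bins = 120)
  sel <- prof$r >= min(centers) & prof$r <= max(centers)
  d <- prof$F - dw(prof$r)
  d <- d - mean(d[sel])
  expect_lt(sqrt(mean(d[sel]^2)), 0.2)
  feat <- profile_features(prof, min_prominence = 2)
  expect_lt(abs(feat$dF_barrier - 15), 0.3)
  expect_lt(abs(feat$R_b - 0.35), 0.01)
})

test_that("profile features find minima, maxima and barriers on grids", {
  r <- seq(0.19, 0.40, by = 0.01)
  F <- c(8, 4, 0, 1.5, 5, 9, 13, 16.5, 15, 12, 9, 7, 5.5, 4.5, 4.2, 4.1,
         4.15, 4.3, 4.5, 4.8, 5.2, 5.6)
  p <- free_energy_profile(r, F)
  feat <- profile_features(p)
  expect_equal(feat$R_b, 0.21)
  expect_equal(feat$dF_barrier, 16.5)
  # idempotent on the already-min-shifted profile
  p2 <- free_energy_profile(p$r, p$F)
  expect_equal(profile_features(p2), feat)
  expect_error(profile_features(free_energy_profile(r, seq_along(r))),
               "no barrier|monotone")
})

test_that("TI integrates exact polynomials to quadrature accuracy", {
  lam <- seq(0, 1, length.out = 101)
  # linear integrand: trapezoid is exact
  res <- alchemical_dG(dudl = list(lambda = lam,
                                   samples = lapply(lam, function(l)
                                     rep(2 + 3 * l, 10))))
  expect_equal(res$dG_TI, 2 + 1.5, tolerance = 1e-12)
  expect_equal(res$se_TI, 0)
  # null transformation
  res0 <- alchemical_dG(dudl = list(lambda = c(0, 1),
                                    samples = list(rep(0, 10), rep(0, 10))))
  expect_equal(res0$dG_TI, 0)
  expect_error(alchemical_dG(dudl = list(lambda = 0.5, samples = list(1:5))),
               "at least 2 lambda")
})

test_that("harmonic stiffening free energy is recovered by TI and BAR", {
  # U_lambda = 0.5 k(lambda) x^2 with k = k1 + (k2 - k1) lambda (kBT units);
  # exact dG = 0.5 ln(k2/k1)
  k1 <- 1; k2 <- 2
  exact <- 0.5 * log(k2 / k1)
  lam <- seq(0, 1, length.out = 21)
  set.seed(31)
  dudl <- lapply(lam, function(l) {
    x <- rnorm(8000, sd = sqrt(1 / (k1 + (k2 - k1) * l)))
    0.5 * (k2 - k1) * x^2
  })
  wf <- 0.5 * (k2 - k1) * rnorm(8000, sd = sqrt(1 / k1))^2
  wr <- -0.5 * (k2 - k1) * rnorm(8000, sd = sqrt(1 / k2))^2
  res <- alchemical_dG(dudl = list(lambda = lam, samples = dudl),
                       work = list(forward = wf, backward = wr))
  expect_lt(abs(res$dG_TI - exact), 3 * res$se_TI + 0.002)
  expect_lt(abs(res$dG_BAR - exact), 3 * res$se_BAR + 0.002)
  # the two estimators agree within their combined uncertainty
  expect_lt(abs(res$dG_TI - res$dG_BAR),
            3 * sqrt(res$se_TI^2 + res$se_BAR^2) + 0.002)
})

test_that("stability constants convert to kBT binding free energies", {
  expect_equal(round(logK_to_kbt(0.45), 3), -1.036)
  expect_equal(logK_to_kbt(0), 0)
  expect_equal(logK_to_kbt(1), -log(10))
})
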