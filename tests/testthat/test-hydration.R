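make_ideal_gas_stream <- function(n_frames = 40, n_part = 400, L = 4, seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    list(time = f, box = c(L, L, L),
         positions = list(ion = matrix(stats::runif(3, 0, L), 1, 3),
                          oxygen = matrix(stats::runif(3 * n_part, 0, L),
                                          n_part, 3)))
  })
  frame_stream(frames)
}

test_that("ideal-gas RDF is flat at 1 within counting noise", {
  stream <- make_ideal_gas_stream()
  rdf <- compute_rdf(stream, bin_width = 0.05, r_max = 1.8)
  sel <- rdf$r_centers > 0.2
  # Poisson noise bound per bin: 3 / sqrt(expected count)
  expected <- 40 * rdf$rho_partner * 4 / 3 * pi *
    ((rdf$r_centers + 0.025)^3 - (rdf$r_centers - 0.025)^3)
  bound <- 3 / sqrt(expected[sel])
  expect_true(all(abs(rdf$g[sel] - 1) < pmax(bound, 0.2)))
  # high-count bins: the mean must sit on 1 tightly
  sel2 <- rdf$r_centers > 0.5
  expect_lt(abs(mean(rdf$g[sel2]) - 1), 0.02)
})

test_that("a constructed 6-coordinate shell lands in the right bin", {
  u <- matrix(rnorm(18), 6, 3); u <- u / sqrt(rowSums(u^2))
  frames <- list(list(time = 0, box = c(3, 3, 3),
                      positions = list(ion = matrix(1.5, 1, 3),
                                       oxygen = sweep(u * 0.21, 2, 1.5, `+`))))
  rdf <- compute_rdf(frame_stream(frames), bin_width = 0.02, r_max = 1.0)
  in_bin <- rdf$r_centers > 0.20 & rdf$r_centers < 0.22
  expect_true(all(rdf$g[!in_bin] == 0))
  expect_true(all(rdf$g[in_bin] > 0))
  # all six partners are recovered by the shell integral
  ss <- shell_summary(rdf)
  expect_equal(round(ss$n1), 6)
})

test_that("r_max beyond the box and empty groups are rejected", {
  stream <- make_ideal_gas_stream(n_frames = 2)
  expect_error(compute_rdf(stream, r_max = 2.5), "half the smallest box")
  expect_error(compute_rdf(stream, pair = c("ion", "nothere"), r_max = 1),
               "empty coordinate group")
  expect_error(frame_stream(list()), "empty")
})

test_that("analytic shell curves give the planted radius and occupancy", {
  gr <- gen_rdf(R1 = 0.209, width = 0.01, occupancy = 6)
  ss <- shell_summary(gr$rdf)
  expect_lt(abs(ss$R1 - 0.209), gr$rdf$bin_width + 1e-12)
  expect_lt(abs(ss$n1 - 6), 0.05)
  expect_gt(ss$r_min, ss$R1)
})

test_that("delta-like shells of k waters integrate back to k", {
  for (k in 4:8) {
    gr <- gen_rdf(R1 = 0.21, width = 0.008, occupancy = k)
    ss <- shell_summary(gr$rdf)
    expect_lt(abs(ss$n1 - k), 0.06)
  }
})

test_that("featureless g(r) raises a structured no-shell error", {
  r <- seq(0.005, 1, by = 0.01)
  flat <- rdf_curve(r, rep(1, length(r)), rho_partner = 33, bin_width = 0.01)
  expect_error(shell_summary(flat), "no shell")
})

test_that("toy shell trajectory yields n1 = 6 through the full RDF path", {
  toy <- gen_toy_trajectory(n_ion = 4, n1 = 6, exchange_rate = 0, dt = 200,
                            t_total = 6000, seed = 3)
  rdf <- compute_rdf(toy$stream, bin_width = 0.004, r_max = 0.6)
  ss <- shell_summary(rdf)
  expect_equal(round(ss$n1), 6)
  expect_lt(abs(ss$R1 - 0.209), 0.01)
})

test_that("Brownian walk diffusion is recovered within 5 percent", {
  set.seed(17)
  D <- 0.706e-3 # nm^2/ps, i.e. 0.706e-5 cm^2/s
  steps <- 1e5
  x <- apply(matrix(rnorm(3 * steps, sd = sqrt(2 * D * 1)), ncol = 3), 2, cumsum)
  est <- diffusion_coefficient(x, dt = 1, fit_window = c(10, 100))
  expect_lt(abs(est$D0 - 0.706) / 0.706, 0.05)
  expect_false(est$nonlinear)
  # translation invariance
  est2 <- diffusion_coefficient(sweep(x, 2, c(5, -3, 100), `+`), dt = 1,
                                fit_window = c(10, 100))
  expect_equal(est2$D0, est$D0)
})

test_that("ballistic input is flagged, zero input gives zero", {
  t <- 1:2000
  ball <- cbind(0.01 * t, 0.02 * t, -0.005 * t)
  expect_warning(est <- diffusion_coefficient(ball, dt = 1,
                                              fit_window = c(10, 100)),
                 "not diffusive")
  expect_true(est$nonlinear)
  still <- matrix(0, 2000, 3)
  est0 <- diffusion_coefficient(still, dt = 1, fit_window = c(10, 100))
  expect_equal(est0$D0, 0)
  expect_error(diffusion_coefficient(ball, dt = 1, fit_window = c(10, 1e5)),
               "beyond")
})
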