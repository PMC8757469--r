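axes_sigma_eps <- function() {
  list(sigma_io = seq(0.195, 0.22, by = 0.005),
       eps_io = seq(2, 26, by = 4))
}

test_that("a uniquely feasible planted node is found", {
  ax <- axes_sigma_eps()
  s <- gen_property_surfaces(ax, list(sigma_io = 0.21, eps_io = 10))
  feas <- feasible_set(s, attr(s, "targets"))
  expect_equal(nrow(feas), 1)
  expect_equal(feas$sigma_io, 0.21)
  expect_equal(feas$eps_io, 10)
})

test_that("impossible targets give an empty set with per-target diagnostics", {
  ax <- axes_sigma_eps()
  s <- gen_property_surfaces(ax, list(sigma_io = 0.21, eps_io = 10))
  targets <- list(target_spec("dG_solv", value = 0, tolerance = 1),
                  target_spec("R1", value = 0.209, tolerance = 0.004))
  feas <- feasible_set(s, targets)
  expect_equal(nrow(feas), 0)
  diag <- attr(feas, "diagnostics")
  expect_equal(unname(diag$per_target["dG_solv"]), 0)
  expect_gt(unname(diag$per_target["R1"]), 0)
})

test_that("loosening a tolerance never shrinks the feasible set", {
  ax <- axes_sigma_eps()
  s <- gen_property_surfaces(ax, list(sigma_io = 0.21, eps_io = 10))
  tight <- attr(s, "targets")
  for (fac in c(2, 5, 20)) {
    loose <- lapply(tight, function(t) {
      if (!is.null(t$value))
        target_spec(t$property, value = t$value, tolerance = t$tolerance * fac)
      else t
    })
    n_tight <- nrow(feasible_set(s, tight))
    n_loose <- nrow(feasible_set(s, loose))
    expect_gte(n_loose, n_tight)
  }
})

test_that("feasible_set equals brute-force enumeration on random surfaces", {
  ax <- list(a = seq(1, 5), b = seq(10, 40, by = 10))
  set.seed(55)
  for (rep in 1:100) {
    v1 <- matrix(runif(20), 5, 4); v2 <- matrix(runif(20), 5, 4)
    s <- list(p = grid_surface(ax, v1, "p"), q = grid_surface(ax, v2, "q"))
    targets <- list(target_spec("p", value = 0.5, tolerance = runif(1, 0.05, 0.4)),
                    target_spec("q", lower = runif(1, 0, 0.3)))
    feas <- feasible_set(s, targets)
    # brute force: loop every node, re-check every predicate by hand
    hits <- NULL
    for (i in 1:5) for (j in 1:4) {
      ok <- abs(v1[i, j] - 0.5) <= targets[[1]]$tolerance &&
        v2[i, j] >= targets[[2]]$lower
      if (ok) hits <- rbind(hits, data.frame(a = ax$a[i], b = ax$b[j]))
    }
    if (is.null(hits)) {
      expect_equal(nrow(feas), 0)
    } else {
      hits <- hits[order(hits$a, hits$b), ]
      expect_equal(feas$a, hits$a)
      expect_equal(feas$b, hits$b)
    }
  }
})

test_that("mismatched grids are rejected", {
  ax <- axes_sigma_eps()
  ax2 <- ax; ax2$eps_io <- ax2$eps_io + 1
  s <- list(p = grid_surface(ax, matrix(0, 6, 7), "p"),
            q = grid_surface(ax2, matrix(0, 6, 7), "q"))
  expect_error(feasible_set(s, list(target_spec("p", value = 0, tolerance = 1),
                                    target_spec("q", value = 0, tolerance = 1))),
               "common grid")
})

test_that("micro is log-nearest to the experimental range, nano is argmax", {
  ax <- axes_sigma_eps()
  # synthetic rates spanning 1e5..1e8: increasing in sigma, decreasing in eps
  U <- matrix(seq_along(ax$sigma_io), 6, 7)
  V <- matrix(seq_along(ax$eps_io), 6, 7, byrow = TRUE)
  kvals <- 10^(5 + 0.45 * U - 0.2 * V)
  ksurf <- grid_surface(ax, kvals, "k", "1/s")
  nodes <- as.data.frame(ksurf)[, 1:2] # every node feasible here
  sel <- select_micro_nano(nodes, ksurf)
  # exhaustive oracle
  mid <- sqrt(5.3e5 * 6.7e5)
  d <- abs(log(kvals) - log(mid))
  best <- which(d == min(d), arr.ind = TRUE)
  expect_equal(sel$micro$sigma_io, ax$sigma_io[best[1, 1]])
  expect_equal(sel$micro$eps_io, ax$eps_io[best[1, 2]])
  bmax <- which(kvals == max(kvals), arr.ind = TRUE)
  expect_equal(sel$nano$sigma_io, ax$sigma_io[bmax[1, 1]])
  expect_equal(sel$nano$eps_io, ax$eps_io[bmax[1, 2]])
  expect_true(sel$micro$k >= 1e5 && sel$micro$k <= 6.7e6) # experimental decade
})

test_that("single feasible node selects itself for both variants; ties break low-eps", {
  ax <- axes_sigma_eps()
  s <- gen_property_surfaces(ax, list(sigma_io = 0.21, eps_io = 10))
  feas <- feasible_set(s, attr(s, "targets"))
  sel <- select_micro_nano(feas, s$k)
  expect_equal(sel$micro, sel$nano)
  # constant rate surface: everything ties; smaller eps then smaller sigma wins
  allpass <- list(p = grid_surface(ax, matrix(1, 6, 7), "p"))
  feas_all <- feasible_set(allpass, list(target_spec("p", value = 1,
                                                     tolerance = 1)))
  kflat <- grid_surface(ax, matrix(1e6, 6, 7), "k")
  sel2 <- select_micro_nano(feas_all, kflat)
  expect_equal(sel2$nano$eps_io, min(ax$eps_io))
  expect_equal(sel2$nano$sigma_io, min(ax$sigma_io))
  expect_error(select_micro_nano(feas_all[0, ], kflat), "empty feasible")
})

test_that("lambda scan lands on the planted scaling factors", {
  lax <- list(lambda_sigma = seq(1.4, 1.8, by = 0.05),
              lambda_eps = seq(0.05, 0.3, by = 0.05))
  s <- gen_property_surfaces(lax, list(lambda_sigma = 1.6, lambda_eps = 0.1),
                             kind = "lambda")
  sf <- scan_lambda(s, attr(s, "targets"))
  expect_equal(sf$lambda_sigma, 1.6)
  expect_equal(sf$lambda_eps, 0.1)
  expect_equal(attr(sf, "score"), 0)
  # unattainable targets: structured nearest-miss error, no silent pick
  bad <- list(target_spec("a_cc", value = 10, tolerance = 0.01))
  err <- tryCatch(scan_lambda(s, bad), error = identity)
  expect_s3_class(err, "mgff_no_feasible_lambda")
  expect_true(!is.null(err$nearest))
})

test_that("tied lambda nodes break deterministically with a warning", {
  lax <- list(lambda_sigma = c(1.5, 1.6), lambda_eps = c(0.1, 0.2))
  v <- matrix(0.93, 2, 2)
  s <- list(a_cc = grid_surface(lax, v, "a_cc"))
  expect_warning(sf <- scan_lambda(s, list(target_spec("a_cc", value = 0.93,
                                                       tolerance = 0.01))),
                 "tied")
  expect_equal(sf$lambda_sigma, 1.5)
  expect_equal(sf$lambda_eps, 0.1)
})

test_that("surfaces round-trip through TSV files", {
  ax <- axes_sigma_eps()
  s <- gen_property_surfaces(ax, list(sigma_io = 0.21, eps_io = 10))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_surface_tsv(s$dG_solv, f)
  back <- read_surface_tsv(f)
  expect_equal(back$values, s$dG_solv$values, tolerance = 1e-12)
  expect_equal(back$axes, s$dG_solv$axes)
  expect_equal(back$property, "dG_solv")
})

test_that("selection pipeline is deterministic end to end", {
  ax <- axes_sigma_eps()
  run <- function() {
    s <- gen_property_surfaces(ax, list(sigma_io = 0.205, eps_io = 18),
                               noise = 0.01, seed = 77)
    feas <- feasible_set(s, attr(s, "targets"))
    sel <- select_micro_nano(feas, s$k)
    list(feas = feas, micro = sel$micro, nano = sel$nano)
  }
  expect_identical(serialize(run(), NULL), serialize(run(), NULL))
})

test_that("planted optimum survives 1 percent noise within one grid step", {
  ax <- axes_sigma_eps()
  for (seed in c(1, 9, 123)) {
    s <- gen_property_surfaces(ax, list(sigma_io = 0.21, eps_io = 10),
                               noise = 0.01, seed = seed)
    feas <- feasible_set(s, attr(s, "targets"))
    expect_gte(nrow(feas), 1)
    expect_lte(max(abs(feas$sigma_io - 0.21)), 0.005 + 1e-12)
    expect_lte(max(abs(feas$eps_io - 10)), 4 + 1e-12)
  }
})
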