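# Seeded synthetic inputs with known ground truth for every pipeline stage.
# All generators are pure functions of (parameters, seed): the RNG state is
# saved and restored around each call.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Toy ion-hydration-shell trajectory with a planted exchange rate
#'
#' Each ion carries `n1` first-shell slots at distance ~ N(R1, shell_width)
#' and a reservoir of waters near `2 R1`.  Exchanges are event-driven
#' (Gillespie clocks): slot swap events occur at rate `exchange_rate / 2`
#' per slot, so that the committed-crossing counter -- which sees one exit
#' and one entry per swap -- measures `exchange_rate` per shell water.
#' This gives exact planted rates with no time-discretization bias.
#'
#' @param n_ion Number of ions.
#' @param n1 First-shell occupancy per ion.
#' @param R1 Shell radius, nm.
#' @param shell_width Gaussian spread of shell distances, nm.
#' @param exchange_rate Planted per-shell-water exchange rate, 1/s.
#' @param dt Sampling interval, ps.
#' @param t_total Trajectory length, ps.
#' @param seed Integer seed.
#' @param n_reserve Reservoir waters per ion (default `n1`).
#' @param make_stream Also build the 3-D `FrameStream` embedding (skip for
#'   long kinetics-only runs).
#' @return List with `distances` (frames x pairs matrix, nm; pairs ordered
#'   ion-major), `times` (ps), `stream` (a `FrameStream` with `ion` and
#'   `oxygen` groups on a cubic lattice), and `ground_truth` (planted rate,
#'   occupancy, event count, cutout radii).
#' @export
#' @examples
#' toy <- gen_toy_trajectory(n_ion = 2, exchange_rate = 1e7, dt = 100,
#'                           t_total = 1e4, seed = 1)
#' dim(toy$distances)
gen_toy_trajectory <- function(n_ion = 10, n1 = 6, R1 = 0.209,
                               shell_width = 0.01, exchange_rate = 1e6,
                               dt = 100, t_total = 1e6, seed = 1,
                               n_reserve = n1, make_stream = TRUE) {
  stopifnot(exchange_rate >= 0, n1 >= 1, n_ion >= 1, dt > 0, t_total >= dt)
  event_rate_slot <- exchange_rate / 2               # 1/s
  if (exchange_rate > 0) {
    mean_wait_ps <- 1e12 / event_rate_slot
    if (dt >= mean_wait_ps / 10)
      warning(sprintf(
        "dt = %g ps resolves the mean slot waiting time (%.3g ps) poorly; counts will be biased low",
        dt, mean_wait_ps), call. = FALSE)
  }
  .with_seed(seed, {
    times <- seq(0, t_total, by = dt)
    nf <- length(times)
    n_w <- n1 + n_reserve
    r_res <- 2 * R1
    dist <- matrix(0, nf, n_ion * n_w)
    n_events <- 0L
    for (ion in seq_len(n_ion)) {
      # occupant[w] = TRUE while water w sits in the shell
      inside_at <- matrix(FALSE, nf, n_w)
      occupant <- c(rep(TRUE, n1), rep(FALSE, n_reserve))
      slot_of <- c(seq_len(n1), rep(NA_integer_, n_reserve))
      t_now <- 0; frame <- 1L
      total_rate_ps <- n1 * event_rate_slot * 1e-12
      repeat {
        t_next <- if (total_rate_ps > 0) t_now + stats::rexp(1, total_rate_ps) else Inf
        upto <- if (is.finite(t_next)) min(nf, sum(times < t_next)) else nf
        if (upto >= frame) {
          inside_at[frame:upto, ] <- matrix(occupant, upto - frame + 1L, n_w,
                                            byrow = TRUE)
          frame <- upto + 1L
        }
        if (t_next > t_total || frame > nf) break
        t_now <- t_next
        n_events <- n_events + 1L
        idx_in <- which(occupant); idx_out <- which(!occupant)
        leaving <- idx_in[sample.int(length(idx_in), 1L)]
        entering <- idx_out[sample.int(length(idx_out), 1L)]
        occupant[leaving] <- FALSE
        occupant[entering] <- TRUE
        slot_of[entering] <- slot_of[leaving]
        slot_of[leaving] <- NA_integer_
      }
      noise <- matrix(stats::rnorm(nf * n_w, sd = shell_width), nf, n_w)
      block <- ifelse(inside_at, R1, r_res) + noise
      block[block < 0.05] <- 0.05 # floor: excluded volume
      dist[, (ion - 1L) * n_w + seq_len(n_w)] <- block
    }
    # lattice embedding for structural analysis
    side <- ceiling(n_ion^(1 / 3))
    spacing <- 6 * R1
    L <- side * spacing
    ion_xyz <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                     z = seq_len(side)))[seq_len(n_ion), , drop = FALSE] * spacing - spacing / 2
    frames <- if (!make_stream) NULL else lapply(seq_len(nf), function(f) {
      ox <- matrix(0, n_ion * n_w, 3)
      for (ion in seq_len(n_ion)) {
        idx <- (ion - 1L) * n_w + seq_len(n_w)
        u <- matrix(stats::rnorm(3 * n_w), n_w, 3)
        u <- u / sqrt(rowSums(u^2))
        ox[idx, ] <- rep(ion_xyz[ion, ], each = n_w) + u * dist[f, idx]
      }
      list(time = times[f], box = c(L, L, L),
           positions = list(ion = ion_xyz, oxygen = ox))
    })
    list(distances = dist, times = times,
         stream = if (make_stream) frame_stream(frames) else NULL,
         ground_truth = list(exchange_rate = exchange_rate, n1 = n1, R1 = R1,
                             n_ion = n_ion, n_events = n_events,
                             t_total_s = t_total * 1e-12,
                             r_core = R1 + 3 * shell_width,
                             r_out = r_res - 3 * shell_width))
  })
}

#' Analytic radial distribution function with known shell and KB integrals
#'
#' Builds `g(r)` from a Gaussian first-shell peak of prescribed occupancy
#' at `R1` plus a long-range baseline `1 + A exp(-r/xi)` that is switched
#' on smoothly beyond the shell (so the curve has a genuine first minimum,
#' as ion-oxygen RDFs do).  Without a peak the curve is the pure baseline,
#' for which the Kirkwood-Buff integral has the closed form
#' `8 pi A xi^3 (1 - e^(-R/xi)(R^2/(2 xi^2) + R/xi + 1))`.
#'
#' @param R1 Peak position, nm.
#' @param width Peak Gaussian width, nm.
#' @param occupancy Shell integral `4 pi rho Int peak r^2 dr` (0 disables
#'   the peak).
#' @param baseline_A,baseline_xi Amplitude and decay length (nm) of the
#'   exponential baseline excess.
#' @param rho Partner number density, nm^-3.
#' @param bin_width,r_max Tabulation grid, nm.
#' @return List with `rdf` (`RDFCurve`), `n1_analytic`, `G_analytic` (KB
#'   integral of the tabulated range), and `G_closed_form` (exact value for
#'   the pure-baseline case, else NA).
#' @export
gen_rdf <- function(R1 = 0.209, width = 0.01, occupancy = 6,
                    baseline_A = 0, baseline_xi = 0.05, rho = 33.3,
                    bin_width = 0.002, r_max = 1.5) {
  stopifnot(width > 0, baseline_xi > 0, rho > 0)
  r <- seq(bin_width / 2, r_max, by = bin_width)
  gfun <- function(r) {
    base <- 1 + baseline_A * exp(-r / baseline_xi)
    if (occupancy > 0) {
      amp <- occupancy /
        (4 * pi * rho * sqrt(2 * pi) * width * (R1^2 + width^2))
      peak <- amp * exp(-(r - R1)^2 / (2 * width^2))
      sw <- stats::plogis(r, location = R1 + 5 * width, scale = width)
      peak + base * sw
    } else base
  }
  g <- gfun(r)
  # analytic references on a 20x finer grid (independent of the binning)
  rf <- seq(bin_width / 40, r_max, by = bin_width / 20)
  gf <- gfun(rf)
  n1_analytic <- if (occupancy > 0) occupancy else NA_real_
  G_analytic <- 4 * pi * .trapz(rf, (gf - 1) * rf^2)
  G_closed <- if (occupancy == 0) {
    A <- baseline_A; xi <- baseline_xi; R <- r_max
    8 * pi * A * xi^3 * (1 - exp(-R / xi) * (R^2 / (2 * xi^2) + R / xi + 1))
  } else NA_real_
  list(rdf = rdf_curve(r, g, rho, bin_width), n1_analytic = n1_analytic,
       G_analytic = G_analytic, G_closed_form = G_closed)
}

#' Harmonically biased samples from a known free-energy profile
#'
#' Draws samples from densities proportional to
#' `exp(-F(x) - 0.5 k (x - c)^2 / kBT)` by rejection sampling against a
#' uniform proposal on the window support (envelope located on a fine
#' grid).  `F` is supplied in kBT.
#'
#' @param F_fun Vectorized free-energy function of x (nm), in kBT.
#' @param centers Window centers, nm.
#' @param k_spring Spring constant(s), kJ/mol/nm^2 (recycled).
#' @param n Samples per window.
#' @param T Temperature, K.
#' @param seed Integer seed.
#' @param support Sampling support `c(lo, hi)` in nm; default spans the
#'   centers extended by 5 thermal widths of the stiffest spring (or the
#'   center range itself for unbiased windows).
#' @return List of `UmbrellaWindow` objects.
#' @export
gen_umbrella_samples <- function(F_fun, centers, k_spring, n = 5000,
                                 T = 298.15, seed = 1, support = NULL) {
  kBT <- mgff_constants()$kB * T
  k_spring <- rep_len(k_spring, length(centers))
  if (is.null(support)) {
    pad <- if (max(k_spring) > 0) 5 * sqrt(kBT / max(k_spring)) else 0
    support <- range(centers) + c(-1, 1) * max(pad, 0.05)
  }
  .with_seed(seed, {
    windows <- vector("list", length(centers))
    for (i in seq_along(centers)) {
      logdens <- function(x) -F_fun(x) - 0.5 * k_spring[i] * (x - centers[i])^2 / kBT
      xf <- seq(support[1], support[2], length.out = 4096)
      lmax <- max(logdens(xf))
      out <- numeric(0)
      while (length(out) < n) {
        m <- max(4L * (n - length(out)), 256L)
        x <- stats::runif(m, support[1], support[2])
        keep <- log(stats::runif(m)) < logdens(x) - lmax
        out <- c(out, x[keep])
      }
      windows[[i]] <- umbrella_window(centers[i], k_spring[i], out[seq_len(n)], T)
    }
    # adjacent-window overlap diagnostic
    if (length(windows) > 1) {
      rngs <- t(vapply(windows, function(w) range(w$samples), numeric(2)))
      ord <- order(centers)
      for (i in seq_len(length(ord) - 1L)) {
        a <- rngs[ord[i], ]; b <- rngs[ord[i + 1L], ]
        if (b[1] > a[2])
          warning(sprintf("windows at %.4g and %.4g nm do not overlap",
                          centers[ord[i]], centers[ord[i + 1L]]), call. = FALSE)
      }
    }
    windows
  })
}

#' Planted-optimum property surfaces for the grid-search selector
#'
#' Generates smooth synthetic response surfaces over a parameter grid such
#' that exactly one designated node satisfies the default selection targets
#' at zero noise.  Two kinds: `"sigma-eps"` mimics the ion-water stage
#' (solvation free energy, shell radius, coordination number, exchange
#' rate), `"lambda"` the scaling-factor stage (activity derivative, binding
#' affinity and distance).  Curvatures are quadratic bowls scaled to the
#' grid step, so one step off the optimum already violates the tolerance;
#' `noise` adds Gaussian noise expressed as a fraction of the one-step
#' response increment.
#'
#' @param axes Named list of two strictly increasing grids.
#' @param optimum Named list/vector with the two planted axis values (must
#'   lie on the grid).
#' @param kind `"sigma-eps"` or `"lambda"`.
#' @param noise Noise level as a fraction of the per-step increment.
#' @param seed Integer seed.
#' @return Named list of `GridSurface` objects, with attribute `targets`
#'   (the default `TargetSpec` list the planted node satisfies) and
#'   `optimum`.
#' @export
#' @examples
#' ax <- list(sigma_io = seq(0.195, 0.22, by = 0.005),
#'            eps_io = seq(2, 26, by = 4))
#' s <- gen_property_surfaces(ax, list(sigma_io = 0.21, eps_io = 10))
#' nrow(feasible_set(s, attr(s, "targets")))
gen_property_surfaces <- function(axes,
                                  optimum,
                                  kind = c("sigma-eps", "lambda"),
                                  noise = 0, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(length(axes) == 2)
  i0 <- which(abs(axes[[1]] - optimum[[names(axes)[1]]]) < 1e-12)
  j0 <- which(abs(axes[[2]] - optimum[[names(axes)[2]]]) < 1e-12)
  if (!length(i0) || !length(j0))
    stop("planted optimum must lie on the grid", call. = FALSE)
  step1 <- stats::median(diff(axes[[1]])); step2 <- stats::median(diff(axes[[2]]))
  u <- (axes[[1]] - axes[[1]][i0]) / step1
  v <- (axes[[2]] - axes[[2]][j0]) / step2
  U <- matrix(u, length(u), length(v))
  V <- matrix(v, length(u), length(v), byrow = TRUE)
  bowl <- U^2 + V^2
  .with_seed(seed, {
    jitter <- function(per_step) {
      if (noise > 0)
        matrix(stats::rnorm(length(bowl), sd = noise * per_step),
               length(u), length(v))
      else 0
    }
    if (kind == "sigma-eps") {
      targets <- list(
        target_spec("dG_solv", value = -2532, tolerance = 1),
        target_spec("R1", value = 0.209, tolerance = 0.004),
        target_spec("n1", value = 6, tolerance = 0.25))
      surf <- list(
        dG_solv = grid_surface(axes, -2532 + 3 * bowl + jitter(3),
                               "dG_solv", "kJ/mol"),
        R1 = grid_surface(axes, 0.209 + 0.0048 * U + jitter(0.0048),
                          "R1", "nm"),
        n1 = grid_surface(axes, 6 + 0.3 * U + 0.2 * V + jitter(0.3),
                          "n1", ""),
        # exchange rate: monotone decreasing in the well depth
        k = grid_surface(axes, 10^(log10(6e5) - 0.5 * V + 0.1 * U),
                         "k", "1/s"))
    } else {
      targets <- list(
        target_spec("a_cc", value = 0.93, tolerance = 0.01),
        target_spec("dG_b0", value = logK_to_kbt(0.45), tolerance = 0.5),
        target_spec("R_b", lower = 0.206, upper = 0.208))
      surf <- list(
        a_cc = grid_surface(axes, 0.93 + 0.03 * bowl + jitter(0.03),
                            "a_cc", ""),
        dG_b0 = grid_surface(axes, logK_to_kbt(0.45) + 0.6 * bowl + jitter(0.6),
                             "dG_b0", "kBT"),
        R_b = grid_surface(axes, 0.207 + 0.0015 * U + jitter(0.0015),
                           "R_b", "nm"))
    }
    attr(surf, "targets") <- targets
    attr(surf, "optimum") <- c(i = i0, j = j0)
    surf
  })
}
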