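#' Umbrella-sampling window
#'
#' @param center Harmonic restraint center, nm.
#' @param k_spring Spring constant, kJ/mol/nm^2 (0 for an unbiased window).
#' @param samples Reaction-coordinate samples, nm; non-empty.
#' @param T Temperature, K.
#' @return Object of class `UmbrellaWindow`.
#' @export
umbrella_window <- function(center, k_spring, samples, T = 298.15) {
  stopifnot(k_spring >= 0, length(samples) > 0, T > 0)
  structure(list(center = center, k_spring = k_spring,
                 samples = as.numeric(samples), T = T),
            class = "UmbrellaWindow")
}

#' One-dimensional free-energy profile
#'
#' @param r Strictly increasing coordinate grid, nm.
#' @param F Free energies in kBT; shifted so the minimum is 0.
#' @param uncertainty Optional per-bin uncertainty, kBT.
#' @return Object of class `FreeEnergyProfile`.
#' @export
free_energy_profile <- function(r, F, uncertainty = NULL) {
  stopifnot(length(r) == length(F), all(diff(r) > 0))
  F <- F - min(F, na.rm = TRUE)
  structure(list(r = r, F = F, uncertainty = uncertainty),
            class = "FreeEnergyProfile")
}

#' @export
print.FreeEnergyProfile <- function(x, ...) {
  cat(sprintf("<FreeEnergyProfile> %d points on [%.4g, %.4g] nm, max %.3g kBT\n",
              length(x$r), min(x$r), max(x$r), max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Weighted histogram analysis (WHAM) of umbrella-sampled data
#'
#' Solves the classic binned WHAM equations: with histogram counts `H_b`,
#' per-window sample counts `n_i` and bias factors
#' `c_ib = exp(-beta U_i(x_b))`, iterate
#' `P_b = H_b / sum_i n_i f_i c_ib` and `1/f_i = sum_b c_ib P_b` until the
#' window free-energy constants change by less than `tol`.  A single
#' unbiased window reduces to Boltzmann inversion of its histogram.  The
#' returned profile is `-ln P` in kBT, minimum-shifted.
#'
#' @param windows List of `UmbrellaWindow` objects with overlapping
#'   coverage.
#' @param grid Bin breaks (nm), or `NULL` to span the sampled range with
#'   `n_bins` uniform bins.
#' @param n_bins Number of bins when `grid` is `NULL`.
#' @param tol Convergence tolerance on the window constants, kBT.
#' @param max_iter Iteration cap.
#' @return A `FreeEnergyProfile` with attributes `f` (window constants,
#'   kBT), `iterations` and `converged`.
#' @export
wham_1d <- function(windows, grid = NULL, n_bins = 200, tol = 1e-7,
                    max_iter = 1e5) {
  stopifnot(length(windows) >= 1,
            all(vapply(windows, inherits, TRUE, "UmbrellaWindow")))
  kBT <- mgff_constants()$kB * windows[[1]]$T
  all_x <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(grid)) grid <- seq(min(all_x), max(all_x), length.out = n_bins + 1L)
  centers <- (grid[-1] + grid[-length(grid)]) / 2
  nb <- length(centers); nw <- length(windows)
  H <- numeric(nb); n_i <- integer(nw)
  for (i in seq_len(nw)) {
    xi <- windows[[i]]$samples
    xi <- xi[xi >= grid[1] & xi <= grid[length(grid)]]
    n_i[i] <- length(xi)
    H <- H + tabulate(findInterval(xi, grid, rightmost.closed = TRUE), nbins = nb)
  }
  .check_window_overlap(windows, grid)
  # bias matrix: rows windows, cols bins; bin-averaged with a 5-point
  # midpoint rule so that steep harmonic tails do not bias the estimate
  nq <- 5L
  qoff <- ((seq_len(nq) - 0.5) / nq - 0.5) * diff(grid)[1]
  C <- t(vapply(windows, function(w) {
    acc <- numeric(nb)
    for (o in qoff)
      acc <- acc + exp(-0.5 * w$k_spring * (centers + o - w$center)^2 / kBT)
    acc / nq
  }, numeric(nb)))
  g <- numeric(nw) # -ln f_i in kBT
  occupied <- H > 0
  for (it in seq_len(max_iter)) {
    denom <- colSums(n_i * exp(g) * C) # n_i f_i c_ib
    P <- ifelse(occupied, H / denom, 0)
    g_new <- -log(as.vector(C %*% P))
    g_new <- g_new - g_new[1]
    delta <- max(abs(g_new - g))
    g <- g_new
    if (delta < tol) break
  }
  P <- ifelse(occupied, H / colSums(n_i * exp(g) * C), NA_real_)
  Fv <- -log(P)
  prof <- free_energy_profile(centers[occupied], Fv[occupied] - min(Fv, na.rm = TRUE))
  attr(prof, "f") <- g
  attr(prof, "iterations") <- it
  attr(prof, "converged") <- delta < tol
  if (!attr(prof, "converged"))
    warning(sprintf("WHAM not converged after %d iterations (delta %.3g)",
                    it, delta), call. = FALSE)
  prof
}

# Windows must form a connected chain of overlapping sampled ranges;
# otherwise the relative offsets of disconnected segments are undetermined.
.check_window_overlap <- function(windows, grid) {
  rng <- t(vapply(windows, function(w) range(w$samples), numeric(2)))
  ord <- order(rng[, 1])
  hi <- rng[ord[1], 2]
  for (i in ord[-1]) {
    if (rng[i, 1] > hi)
      stop(sprintf(
        "umbrella windows do not overlap: gap between %.4g and %.4g nm",
        hi, rng[i, 1]), call. = FALSE)
    hi <- max(hi, rng[i, 2])
  }
  invisible(TRUE)
}

#' Binding distance and barrier height from a free-energy profile
#'
#' Locates (on the grid, no interpolation, ties toward smaller r) the first
#' local minimum (`R_b`, the bound state) and the first local maximum after
#' it; the barrier is `dF = F(max) - F(min)` in kBT.
#'
#' @param p A `FreeEnergyProfile`.
#' @param search_range Optional `c(lo, hi)` restriction in nm.
#' @param min_prominence Minimum rise (kBT) a maximum must have over the
#'   preceding minimum, and fall after it, to count as the barrier; 0
#'   accepts the first strict sign change (exact for noise-free profiles,
#'   use ~1 kBT for estimated ones).
#' @return List with `R_b` (nm), `dF_barrier` (kBT), and the grid indices.
#' @export
profile_features <- function(p, search_range = NULL, min_prominence = 0) {
  stopifnot(inherits(p, "FreeEnergyProfile"))
  r <- p$r; F <- p$F
  if (!is.null(search_range)) {
    sel <- r >= search_range[1] & r <= search_range[2]
    r <- r[sel]; F <- F[sel]
  }
  n <- length(F)
  if (n < 3) stop("profile too short", call. = FALSE)
  if (min_prominence <= 0) {
    dF <- diff(F)
    i_min <- NA_integer_
    for (i in seq_len(n - 1)) {
      if (dF[i] > 0 && (i == 1 || dF[i - 1] <= 0)) { i_min <- i; break }
    }
    if (is.na(i_min))
      stop("no barrier: profile is monotone after the first point", call. = FALSE)
    i_max <- NA_integer_
    for (i in seq(i_min, n - 1)) {
      if (dF[i] < 0 && F[i] > F[i_min]) { i_max <- i; break }
    }
    if (is.na(i_max))
      stop("no barrier: no interior maximum after the first minimum", call. = FALSE)
  } else {
    # prominence walker: first minimum followed by a rise of at least
    # min_prominence, whose maximum is confirmed by an equal fall
    i_min <- 1L; i_max <- NA_integer_; cur_max <- NA_integer_
    state <- "rise"
    for (i in 2:n) {
      if (state == "rise") {
        if (F[i] < F[i_min]) { i_min <- i
        } else if (F[i] - F[i_min] >= min_prominence) {
          cur_max <- i; state <- "fall"
        }
      } else {
        if (F[i] > F[cur_max]) { cur_max <- i
        } else if (F[cur_max] - F[i] >= min_prominence) {
          i_max <- cur_max; break
        }
      }
    }
    if (is.na(i_max))
      stop(sprintf(
        "no barrier with prominence >= %.3g kBT after the first minimum",
        min_prominence), call. = FALSE)
  }
  list(R_b = r[i_min], dF_barrier = F[i_max] - F[i_min],
       i_min = i_min, i_max = i_max)
}

#' Standard-state binding free energy from a log stability constant
#'
#' `dG_b0 = -ln(10) * logK`, in units of kBT.
#'
#' @param logK Decadic log of the stability constant.
#' @return Binding free energy in kBT.
#' @export
#' @examples
#' logK_to_kbt(0.45)
logK_to_kbt <- function(logK) -log(10) * logK
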