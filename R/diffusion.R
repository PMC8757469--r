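#' Self-diffusion coefficient from the Einstein relation
#'
#' Computes the mean-squared displacement of one or more 3-D tracks and
#' fits `MSD(t) = 6 D t` by least squares over a lag-time window.  The
#' uncertainty is the standard error over tracks (or over contiguous blocks
#' of a single track).  A log-log slope far from 1 inside the fit window
#' flags non-diffusive (e.g. ballistic) input.
#'
#' @param tracks A single N x 3 coordinate matrix (nm) or a list of them
#'   (independent trajectories).
#' @param dt Sampling interval, ps.
#' @param fit_window Lag-time window `c(t_lo, t_hi)` in ps for the linear
#'   fit.
#' @param n_blocks Number of contiguous blocks a single track is split into
#'   for the uncertainty estimate (at least 3 blocks of data are required).
#' @return List with `D0` and `D0_err` in 1e-5 cm^2/s, the fitted `msd`
#'   data frame, and `nonlinear` (TRUE when the MSD is not consistent with
#'   diffusive scaling; also raised as a warning).
#' @export
#' @examples
#' set.seed(1)
#' x <- apply(matrix(rnorm(3000, sd = 0.05), ncol = 3), 2, cumsum)
#' diffusion_coefficient(x, dt = 1, fit_window = c(5, 50))$D0
diffusion_coefficient <- function(tracks, dt, fit_window, n_blocks = 5) {
  if (is.matrix(tracks)) {
    n <- nrow(tracks)
    if (n < 3 * n_blocks) stop("track too short to block", call. = FALSE)
    idx <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
    tracks <- lapply(idx, function(i) tracks[i, , drop = FALSE])
  }
  if (length(tracks) < 3)
    stop("need >= 3 tracks or blocks for an uncertainty estimate", call. = FALSE)
  lag_lo <- max(1L, floor(fit_window[1] / dt))
  lag_hi <- ceiling(fit_window[2] / dt)
  n_min <- min(vapply(tracks, nrow, 0L))
  if (lag_hi >= n_min)
    stop("fit window extends beyond the available trajectory", call. = FALSE)
  lags <- lag_lo:lag_hi
  msd_one <- function(xyz) {
    vapply(lags, function(k) {
      d <- xyz[-(1:k), , drop = FALSE] - xyz[seq_len(nrow(xyz) - k), , drop = FALSE]
      mean(rowSums(d^2))
    }, 0)
  }
  per_track <- vapply(tracks, msd_one, numeric(length(lags)))
  slopes <- apply(per_track, 2, function(m)
    stats::coef(stats::lm(m ~ I(lags * dt)))[2])
  D_blocks <- slopes / 6 * 1e3 # nm^2/ps -> 1e-5 cm^2/s
  msd_mean <- rowMeans(per_track)
  nonlinear <- FALSE
  if (all(msd_mean > 0)) {
    llslope <- stats::coef(stats::lm(log(msd_mean) ~ log(lags * dt)))[2]
    if (abs(llslope - 1) > 0.25) {
      nonlinear <- TRUE
      warning(sprintf(
        "MSD scales as t^%.2f inside the fit window; input is not diffusive",
        llslope), call. = FALSE)
    }
  }
  list(D0 = mean(D_blocks),
       D0_err = stats::sd(D_blocks) / sqrt(length(D_blocks)),
       msd = data.frame(t = lags * dt, msd = msd_mean),
       nonlinear = nonlinear)
}
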