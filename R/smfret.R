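#' Crosstalk and brightness corrections for ratiometric FRET
#'
#' Bundles the correction constants used when converting two-channel
#' intensities to FRET efficiencies: `beta_crosstalk` is the fraction of
#' donor photons registered in the acceptor channel, `gamma_brightness`
#' the relative brightness factor (phi_A * eta_A)/(phi_D * eta_D) built
#' from quantum yields and detection efficiencies, and `r0` the Foerster
#' radius in Angstrom (51 A for the Alexa 555/647 pair used here).
#'
#' @param beta_crosstalk donor -> acceptor leakage fraction in [0, 1).
#' @param gamma_brightness relative brightness factor (> 0).
#' @param r0 Foerster radius in Angstrom (> 0).
#' @return A list of class `fret_corrections`.
#' @export
fret_corrections <- function(beta_crosstalk = 0, gamma_brightness = 1,
                             r0 = 51) {
  stopifnot(is.numeric(beta_crosstalk), beta_crosstalk >= 0,
            beta_crosstalk < 1,
            is.numeric(gamma_brightness), gamma_brightness > 0,
            is.numeric(r0), r0 > 0)
  structure(list(beta_crosstalk = beta_crosstalk,
                 gamma_brightness = gamma_brightness, r0 = r0),
            class = "fret_corrections")
}

#' Corrected FRET efficiency per time bin
#'
#' Ratiometric efficiency with crosstalk-then-gamma correction: the
#' acceptor signal is first stripped of donor leakage,
#' `I_A_corr = I_A - beta * I_D` (clamped at zero), then
#' `E = I_A_corr / (I_A_corr + gamma * I_D)`.
#' Bins at or after the photobleaching change point (the trajectory's
#' `bleach_index`, or the one found by [detect_bleach()]) are excluded;
#' empty bins (`I_D = I_A = 0`) are dropped.
#'
#' @param traj a `binned_trajectory` (see [simulate_fret_trajectories()])
#'   or any list with numeric `I_D` and `I_A` and optional `bleach_index`.
#' @param corr a [fret_corrections()] object.
#' @return Numeric vector of efficiencies in [0, 1], one per retained bin.
#'   The indices of the retained bins are attached as attribute `"bins"`.
#' @examples
#' tr <- list(I_D = c(100, 100), I_A = c(100, 120))
#' compute_efficiency(tr, fret_corrections())           # 0.5, ...
#' compute_efficiency(tr, fret_corrections(0.1, 1.2))   # ..., 0.478
#' @export
compute_efficiency <- function(traj, corr = fret_corrections()) {
  stopifnot(inherits(corr, "fret_corrections"))
  id <- as.numeric(traj$I_D)
  ia <- as.numeric(traj$I_A)
  if (length(id) != length(ia)) stop("I_D and I_A must have equal length")
  n <- length(id)
  keep <- rep(TRUE, n)
  bl <- traj$bleach_index
  if (!is.null(bl) && is.finite(bl) && bl >= 1 && bl <= n)
    keep[seq.int(bl, n)] <- FALSE
  empty <- (id <= 0 & ia <= 0)
  keep <- keep & !empty
  ia_corr <- pmax(ia[keep] - corr$beta_crosstalk * id[keep], 0)
  denom <- ia_corr + corr$gamma_brightness * id[keep]
  e <- ifelse(denom > 0, ia_corr / denom, NA_real_)
  bins <- which(keep)[!is.na(e)]
  e <- e[!is.na(e)]
  attr(e, "bins") <- bins
  e
}

#' Convert FRET efficiency to dye separation and back
#'
#' The Foerster relation: `E = 1 / (1 + (R/R0)^6)`, inverted as
#' `R = R0 * (1/E - 1)^(1/6)`.  `r0 = 1` expresses distances in units of
#' the Foerster radius, the convention used throughout the package.
#'
#' @param e efficiency values strictly inside (0, 1).
#' @param r distances (> 0), in the same units as `r0`.
#' @param r0 Foerster radius (default 1, i.e. distances in R0 units).
#' @return `efficiency_to_distance`: distances; `distance_to_efficiency`:
#'   efficiencies.  Efficiencies of exactly 0 or 1 are out of the
#'   invertible domain and raise an error.
#' @examples
#' efficiency_to_distance(0.5)          # exactly R0
#' distance_to_efficiency(0.87)         # 0.698
#' distance_to_efficiency(1.38)         # 0.126
#' @export
efficiency_to_distance <- function(e, r0 = 1) {
  stopifnot(is.numeric(e), is.numeric(r0), r0 > 0)
  if (any(!is.finite(e)) || any(e <= 0) || any(e >= 1))
    stop("efficiencies must lie strictly inside (0, 1): ",
         "E = 0 or 1 maps to an infinite or zero distance")
  r0 * (1 / e - 1)^(1 / 6)
}

#' @rdname efficiency_to_distance
#' @export
distance_to_efficiency <- function(r, r0 = 1) {
  stopifnot(is.numeric(r), is.numeric(r0), r0 > 0)
  if (any(!is.finite(r)) || any(r <= 0)) stop("distances must be positive")
  1 / (1 + (r / r0)^6)
}

#' Detect the photobleaching step in an intensity trace
#'
#' Single-molecule TIRF traces end in single-step photobleaching.  The
#' final change point is located at the largest single-step drop of the
#' total intensity `I_D + I_A` after which the trace stays, on average,
#' at background level (within noise) until the end.  Because acceptor
#' photobleaching already invalidates the FRET readout, the acceptor
#' channel is additionally scanned for an earlier step to background;
#' the first change point found is returned.  `NA` when no step exists.
#'
#' @param traj a trajectory with numeric `I_D` and `I_A` (>= 5 bins).
#' @param background expected residual level after bleaching (counts per
#'   bin, default 0: background-subtracted traces).
#' @param noise_factor the post-step tail must stay below
#'   `background + noise_factor * sqrt(background + 1)` on average.
#' @return Integer index of the first post-bleach bin, or `NA_integer_`.
#' @export
detect_bleach <- function(traj, background = 0, noise_factor = 3) {
  id <- as.numeric(traj$I_D)
  ia <- as.numeric(traj$I_A)
  n <- length(id)
  if (n < 5L) stop("need at least 5 bins to locate a bleaching step")
  thr <- background + noise_factor * sqrt(background + 1)
  step_to_floor <- function(x, last) {
    # first index idx such that x drops by > thr entering idx and stays
    # at background (on average) through bin `last`
    drops <- x[-length(x)] - x[-1]
    for (i in order(drops, decreasing = TRUE)) {
      if (drops[i] <= thr) break
      idx <- i + 1L
      if (idx > last) next
      if (mean(x[idx:last]) <= thr) return(idx)
    }
    NA_integer_
  }
  full <- step_to_floor(id + ia, n)
  # acceptor may bleach first while the donor keeps emitting
  acc <- if (!is.na(full) && full > 2L)
    step_to_floor(ia[seq_len(full - 1L)], full - 1L) else NA_integer_
  if (!is.na(acc)) return(acc)
  full
}
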