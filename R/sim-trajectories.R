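#' Configuration for the binned smFRET trajectory simulator
#'
#' Emulates camera-based (TIRF) single-molecule FRET trajectories of
#' surface-immobilized molecules: 100 ms intensity bins, single-step
#' photobleaching with exponentially distributed trace length (mean
#' 8.8 s), and a two-state conformational coordinate expressed as a
#' dye separation in units of the Foerster radius R0.
#'
#' Two regimes: in `"static"` each molecule keeps one latent state for
#' its whole trace (states drawn with `state_weights`); in
#' `"switching"` the state follows a two-state Markov chain with rates
#' `k_open`/`k_close` and each bin's distance is the occupancy-weighted
#' mixture of fresh per-state Gaussian draws.  In the switching regime
#' the state weights are, by construction, the equilibrium populations
#' `k_close/(k_open+k_close)` (closed) and its complement; supplying
#' inconsistent weights is an error.
#'
#' @param n_trajectories number of molecules.
#' @param bin_width bin width, s (default 0.1).
#' @param mean_length mean pre-bleach trace length, s (default 8.8).
#' @param regime `"static"` or `"switching"`.
#' @param state_distance_means closed/open distance centres, R0 units.
#' @param state_distance_sds per-state Gaussian sds, R0 units.
#' @param state_weights probabilities (closed, open), summing to 1;
#'   in the switching regime derived from the rates when omitted.
#' @param k_open,k_close switching rates, 1/s (switching regime).
#'   Defaults give a 2 s relaxation time with open fraction 0.45, slow
#'   enough that single bins are state-pure but traces visit both
#'   states.
#' @param total_photons_per_bin_mean mean detected photons per bin.
#' @param crosstalk_beta,gamma_brightness distortion factors applied to
#'   the emitted counts so that the corrections of
#'   [compute_efficiency()] are exercised.
#' @param background_per_bin mean background counts per bin per channel
#'   (added, then subtracted in expectation, as in real processing).
#' @param tail_bins post-bleach background-only bins appended to each
#'   trace so bleach detection is exercised.
#' @param seed integer RNG seed.
#' @return List of class `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(n_trajectories = 26L,
                                  bin_width = 0.1,
                                  mean_length = 8.8,
                                  regime = c("static", "switching"),
                                  state_distance_means = c(0.87, 1.38),
                                  state_distance_sds = c(0.08, 0.08),
                                  state_weights = NULL,
                                  k_open = 0.225, k_close = 0.275,
                                  total_photons_per_bin_mean = 400,
                                  crosstalk_beta = 0.05,
                                  gamma_brightness = 1.2,
                                  background_per_bin = 2,
                                  tail_bins = 10L,
                                  seed = 1L) {
  regime <- match.arg(regime)
  if (regime == "switching") {
    if (k_open <= 0 || k_close <= 0)
      stop("switching regime needs positive rates")
    eq <- c(k_close, k_open) / (k_open + k_close)  # (closed, open)
    if (is.null(state_weights)) state_weights <- eq
    else if (max(abs(state_weights - eq)) > 1e-8)
      stop("in the switching regime state_weights must equal the ",
           "rate-derived equilibrium populations (",
           sprintf("%.4f, %.4f", eq[1], eq[2]), ")")
  } else if (is.null(state_weights)) state_weights <- c(0.55, 0.45)
  stopifnot(n_trajectories >= 1, bin_width > 0, mean_length > 0,
            length(state_distance_means) == 2L,
            all(state_distance_means > 0),
            length(state_distance_sds) == 2L,
            all(state_distance_sds > 0),
            length(state_weights) == 2L, all(state_weights >= 0),
            all(state_weights <= 1),
            total_photons_per_bin_mean > 0,
            crosstalk_beta >= 0, crosstalk_beta < 1,
            gamma_brightness > 0, background_per_bin >= 0,
            tail_bins >= 0)
  if (abs(sum(state_weights) - 1) > 1e-8)
    stop("state_weights must sum to 1")
  structure(list(n_trajectories = as.integer(n_trajectories),
                 bin_width = bin_width, mean_length = mean_length,
                 regime = regime,
                 state_distance_means = state_distance_means,
                 state_distance_sds = state_distance_sds,
                 state_weights = state_weights,
                 k_open = k_open, k_close = k_close,
                 total_photons_per_bin_mean = total_photons_per_bin_mean,
                 crosstalk_beta = crosstalk_beta,
                 gamma_brightness = gamma_brightness,
                 background_per_bin = background_per_bin,
                 tail_bins = as.integer(tail_bins),
                 seed = as.integer(seed)),
            class = "trajectory_sim_config")
}

#' Sample a two-state Markov path
#'
#' Exact continuous-time sampling of the closed (0) / open (1) Markov
#' chain: exponential dwell times with rates `k_open` (leaving closed)
#' and `k_close` (leaving open), initial state drawn from equilibrium.
#'
#' @param k_open,k_close switching rates, 1/s.
#' @param duration path length, s.
#' @param seed optional seed (uses the current RNG state when `NULL`).
#' @return List with `t` (transition times, starting at 0), `state`
#'   (state entered at each time) and `duration`.
#' @export
sample_two_state_path <- function(k_open, k_close, duration,
                                  seed = NULL) {
  stopifnot(k_open > 0, k_close > 0, duration > 0)
  with_seed(seed, {
    p_open <- k_open / (k_open + k_close)
    s <- if (stats::runif(1) < p_open) 1L else 0L
    ts <- 0; ss <- s; t <- 0
    repeat {
      t <- t + stats::rexp(1, if (s == 1L) k_close else k_open)
      if (t >= duration) break
      s <- 1L - s
      ts <- c(ts, t); ss <- c(ss, s)
    }
    list(t = ts, state = ss, duration = duration)
  })
}

# open-state occupancy fraction of each bin for a two-state path
bin_occupancy <- function(path, bin_width, n_bins) {
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  ts <- c(path$t, path$duration)
  occ <- numeric(n_bins)
  for (j in seq_along(path$state)) {
    if (path$state[j] != 1L) next
    a <- ts[j]; b <- min(ts[j + 1L], edges[n_bins + 1L])
    if (b <= a) next
    i0 <- max(1L, floor(a / bin_width) + 1L)
    i1 <- min(n_bins, ceiling(b / bin_width))
    for (i in i0:i1)
      occ[i] <- occ[i] + max(0, min(b, edges[i + 1L]) - max(a, edges[i]))
  }
  occ / bin_width
}

#' Simulate binned smFRET trajectories
#'
#' Per trajectory: a bleach time drawn from an exponential with mean
#' `mean_length` truncates the trace; each pre-bleach bin receives a
#' latent distance (static regime: the molecule's single state;
#' switching regime: occupancy-weighted mixture of per-state Gaussian
#' draws from an exactly sampled Markov path); the distance maps to a
#' FRET efficiency through the Foerster relation; donor/acceptor
#' counts are Poisson with gamma and crosstalk distortions applied, so
#' the corrections of [compute_efficiency()] are exercised; post-bleach
#' tail bins carry only background.  Fully deterministic given the
#' config seed.
#'
#' @param config a [trajectory_sim_config()].
#' @return List of `binned_trajectory` objects (fields
#'   `trajectory_id`, `bin_width`, `I_D`, `I_A`, `bleach_index`, and
#'   latent ground truth `distance_true`, `occupancy_open`,
#'   `state_static`), with the config as attribute `"config"`.
#' @export
simulate_fret_trajectories <- function(config) {
  stopifnot(inherits(config, "trajectory_sim_config"))
  cf <- config
  with_seed(cf$seed, {
    lapply(seq_len(cf$n_trajectories), function(id) {
      n_sig <- max(1L, floor(stats::rexp(1, 1 / cf$mean_length) /
                               cf$bin_width))
      if (cf$regime == "static") {
        # one conformation per molecule: the state's Gaussian width is
        # split into molecule-to-molecule heterogeneity (0.8 sd, drawn
        # once) and fast conformational breathing around that centre
        # (0.6 sd, per bin; 0.8^2 + 0.6^2 = 1 keeps the pooled width),
        # so per-molecule histograms stay narrow and single-peaked
        # while the pooled histogram is smooth
        st <- if (stats::runif(1) < cf$state_weights[1]) 1L else 2L
        occ <- rep(if (st == 1L) 0 else 1, n_sig)  # open occupancy
        static_state <- st
        centre <- stats::rnorm(1, cf$state_distance_means[st],
                               0.8 * cf$state_distance_sds[st])
        r <- centre + stats::rnorm(n_sig, 0,
                                   0.6 * cf$state_distance_sds[st])
      } else {
        path <- sample_two_state_path(cf$k_open, cf$k_close,
                                      n_sig * cf$bin_width)
        occ <- bin_occupancy(path, cf$bin_width, n_sig)
        static_state <- NA_integer_
        r_closed <- stats::rnorm(n_sig, cf$state_distance_means[1],
                                 cf$state_distance_sds[1])
        r_open <- stats::rnorm(n_sig, cf$state_distance_means[2],
                               cf$state_distance_sds[2])
        r <- (1 - occ) * r_closed + occ * r_open
      }
      r <- pmax(r, 0.05)
      e <- distance_to_efficiency(r)
      n_tot <- stats::rpois(n_sig, cf$total_photons_per_bin_mean)
      lam_d <- n_tot * (1 - e) / cf$gamma_brightness
      i_d <- stats::rpois(n_sig, lam_d)
      i_a <- stats::rpois(n_sig, n_tot * e) +
        stats::rpois(n_sig, cf$crosstalk_beta * lam_d)
      bg <- cf$background_per_bin
      tail_d <- tail_a <- integer(0)
      if (cf$tail_bins > 0L) {
        tail_d <- stats::rpois(cf$tail_bins, bg)
        tail_a <- stats::rpois(cf$tail_bins, bg)
      }
      I_D <- pmax(c(i_d + stats::rpois(n_sig, bg), tail_d) - bg, 0)
      I_A <- pmax(c(i_a + stats::rpois(n_sig, bg), tail_a) - bg, 0)
      structure(list(trajectory_id = id, bin_width = cf$bin_width,
                     I_D = I_D, I_A = I_A,
                     bleach_index = if (cf$tail_bins > 0L)
                       n_sig + 1L else NA_integer_,
                     distance_true = r, occupancy_open = occ,
                     state_static = static_state),
                class = "binned_trajectory")
    }) -> trajs
    attr(trajs, "config") <- cf
    trajs
  })
}

#' @export
print.binned_trajectory <- function(x, ...) {
  cat(sprintf("Binned trajectory %d: %d bins of %.3g s (bleach at %s)\n",
              x$trajectory_id, length(x$I_D), x$bin_width,
              ifelse(is.na(x$bleach_index), "none", x$bleach_index)))
  invisible(x)
}
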