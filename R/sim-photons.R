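#' Configuration for the confocal photon-stream simulator
#'
#' Defines a Brownian-dynamics emulation of a two-colour FCS/FCCS
#' measurement: `n_molecules` point emitters diffuse in a periodic box,
#' interconvert between a closed and an open conformation, and emit
#' photons into donor/acceptor channels weighted by a 3D Gaussian
#' detection profile, with triplet blinking, donor-to-acceptor
#' crosstalk and uncorrelated background.  Lengths are micrometres,
#' times seconds, rates 1/s.
#'
#' The defaults emulate the apo Ykt6 FCCS condition: switching rates
#' 2250/2750 1/s (relaxation 200 us, open fraction 0.45), per-state
#' channel brightness split by the FRET efficiencies of the closed
#' (0.87 R0) and open (1.38 R0) conformations, per-dye triplet
#' amplitudes 0.282/0.331 with 3.813/8.827 us time constants, and a
#' focus transit time of 200 us.
#'
#' @param n_molecules number of molecules (> 0).
#' @param focus_lateral lateral 1/e^2 radius of the focus, um.
#' @param aspect_ratio lateral/axial ratio p (axial radius = p * mu).
#' @param diffusion_coeff um^2/s; the implied transit time is
#'   `mu^2 / (4 D)`.
#' @param box_half_widths periodic box half widths, um (3 values);
#'   default 5 axial radii in every direction.
#' @param brightness 2 x 2 matrix of centre brightness (counts/s),
#'   rows = states (closed, open), columns = channels (donor,
#'   acceptor).
#' @param k_open,k_close conformational switching rates, 1/s.
#' @param triplet_f stationary triplet (dark) fractions in [0, 1),
#'   one per dye (donor, acceptor); the two dyes blink independently.
#' @param triplet_tau triplet correlation times, s (donor, acceptor).
#' @param crosstalk_beta donor -> acceptor registration probability.
#' @param background_rate background counts/s per channel (donor,
#'   acceptor).
#' @param time_step integration step, s; must satisfy
#'   `time_step < min(1/(k_open + k_close), triplet_tau) / 5`.
#' @param duration simulated time, s.
#' @param seed integer RNG seed (simulations are fully deterministic).
#' @return List of class `diffusion_sim_config`.  Reported convenience
#'   fields: `tau_D_implied = mu^2/(4 D)` and `n_eff`, the effective
#'   (profile-weighted) mean number of molecules in the focal volume
#'   `pi^(3/2) mu^2 (p mu)`.
#' @export
diffusion_sim_config <- function(n_molecules = 6L,
                                 focus_lateral = 0.3,
                                 aspect_ratio = 3,
                                 diffusion_coeff = focus_lateral^2 / (4 * 200e-6),
                                 box_half_widths = rep(5 * aspect_ratio * focus_lateral, 3),
                                 brightness = NULL,
                                 k_open = 2250, k_close = 2750,
                                 triplet_f = c(0.282, 0.331),
                                 triplet_tau = c(3.813e-6, 8.827e-6),
                                 crosstalk_beta = 0.05,
                                 background_rate = c(200, 200),
                                 time_step = 7e-7,
                                 duration = 60,
                                 seed = 1L) {
  if (is.null(brightness)) {
    e_closed <- distance_to_efficiency(0.87)
    e_open <- distance_to_efficiency(1.38)
    total <- 2e6
    brightness <- rbind(closed = total * c(1 - e_closed, e_closed),
                        open = total * c(1 - e_open, e_open))
    colnames(brightness) <- c("donor", "acceptor")
  }
  brightness <- as.matrix(brightness)
  stopifnot(nrow(brightness) == 2L, ncol(brightness) == 2L,
            all(brightness >= 0),
            n_molecules >= 1, focus_lateral > 0, aspect_ratio > 0,
            diffusion_coeff > 0, length(box_half_widths) == 3L,
            all(box_half_widths > 0), k_open >= 0, k_close >= 0,
            length(triplet_f) == 2L, all(triplet_f >= 0),
            all(triplet_f < 1), length(triplet_tau) == 2L,
            all(triplet_tau > 0),
            crosstalk_beta >= 0, crosstalk_beta < 1,
            length(background_rate) == 2L, all(background_rate >= 0),
            time_step > 0)
  if (duration <= 0) stop("duration must be positive")
  lim <- min(if (k_open + k_close > 0) 1 / (k_open + k_close) else Inf,
             if (any(triplet_f > 0))
               min(triplet_tau[triplet_f > 0]) else Inf) / 5
  if (time_step >= lim)
    stop(sprintf(paste0("time_step (%.3g s) must be below one fifth of",
                        " the fastest process time scale (%.3g s)"),
                 time_step, lim))
  if (k_open + k_close > 0 &&
      all(abs(brightness[1, ] - brightness[2, ]) == 0))
    warning("states switch but have identical brightness in both ",
            "channels: the dynamics will be invisible in correlations")
  mu <- focus_lateral
  v_eff <- pi^1.5 * mu^2 * (aspect_ratio * mu)
  v_box <- prod(2 * box_half_widths)
  structure(list(n_molecules = as.integer(n_molecules),
                 focus_lateral = mu, aspect_ratio = aspect_ratio,
                 diffusion_coeff = diffusion_coeff,
                 box_half_widths = box_half_widths,
                 brightness = brightness, k_open = k_open,
                 k_close = k_close, triplet_f = triplet_f,
                 triplet_tau = triplet_tau,
                 crosstalk_beta = crosstalk_beta,
                 background_rate = background_rate,
                 time_step = time_step, duration = duration,
                 seed = as.integer(seed),
                 tau_D_implied = mu^2 / (4 * diffusion_coeff),
                 n_eff = n_molecules * v_eff / v_box),
            class = "diffusion_sim_config")
}

#' Simulate a two-channel photon stream
#'
#' Runs the Brownian-dynamics simulator of [diffusion_sim_config()]:
#' per time step, Gaussian displacements (variance `2 D dt` per axis,
#' periodic wrap), an exact-waiting-time two-state Markov chain for the
#' conformational state and for the triplet dark state, Poisson photon
#' emission with rate `brightness(state, channel) * profile`, crosstalk
#' reassignment of donor photons, and Poisson background.  Identical
#' seeds give identical photon lists.
#'
#' @param config a [diffusion_sim_config()].
#' @param record_transitions keep the conformational transition event
#'   log (time, molecule, new state) for oracle tests.
#' @return Object of class `photon_stream`: list with `times` (sorted
#'   arrival times, s), `channel` (integer, 1 = donor, 2 = acceptor),
#'   `duration`, `resolution` (the integration step), `config`, `seed`
#'   and optionally `transitions`.
#' @export
simulate_photon_stream <- function(config, record_transitions = FALSE) {
  stopifnot(inherits(config, "diffusion_sim_config"))
  res <- simulate_photons_cpp(
    config$n_molecules, config$box_half_widths, config$diffusion_coeff,
    config$focus_lateral, config$aspect_ratio, config$brightness,
    config$k_open, config$k_close, config$triplet_f, config$triplet_tau,
    config$crosstalk_beta, config$background_rate, config$time_step,
    config$duration, config$seed, record_transitions)
  structure(list(times = res$times, channel = res$channel,
                 duration = config$duration,
                 resolution = config$time_step, config = config,
                 seed = config$seed,
                 transitions = if (record_transitions) res$transitions),
            class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Photon stream: %d photons over %.3g s (%.0f cps)\n",
              n, x$duration, n / x$duration))
  cat(sprintf("  donor %d, acceptor %d; seed %d\n",
              sum(x$channel == 1L), sum(x$channel == 2L), x$seed))
  invisible(x)
}
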