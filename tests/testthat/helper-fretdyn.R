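# shared fixtures, all generated in code

# photon stream object from explicit times/channels
make_stream <- function(times, channel, duration,
                        resolution = 1e-6) {
  ord <- order(times)
  structure(list(times = times[ord], channel = as.integer(channel)[ord],
                 duration = duration, resolution = resolution,
                 config = NULL, seed = NA_integer_),
            class = "photon_stream")
}

# homogeneous Poisson photon stream, both channels independent
make_poisson_stream <- function(rate_d, rate_a, duration, seed) {
  withr::with_seed(seed, {
    nd <- stats::rpois(1, rate_d * duration)
    na <- stats::rpois(1, rate_a * duration)
    make_stream(c(stats::runif(nd, 0, duration),
                  stats::runif(na, 0, duration)),
                c(rep(1L, nd), rep(2L, na)), duration)
  })
}

# sinusoid-modulated Poisson stream (same modulation on both channels):
# closed-form correlation G(tau) = (m^2 / 2) cos(2 pi f tau)
make_modulated_stream <- function(rate, m, freq, duration, seed) {
  withr::with_seed(seed, {
    n_max <- stats::rpois(1, rate * (1 + m) * duration)
    tt <- sort(stats::runif(n_max, 0, duration))
    keep <- stats::runif(n_max) <
      (1 + m * cos(2 * pi * freq * tt)) / (1 + m)
    tt <- tt[keep]
    ch <- ifelse(stats::runif(length(tt)) < 0.5, 1L, 2L)
    make_stream(tt, ch, duration)
  })
}

# apo-condition reference objects used across tests
apo_sep_acd <- function() fccs_reference_params("apo", "separate")[["AC-d"]]
apo_global <- function() fccs_reference_params("apo", "global")

fixed_consts <- function(gp) {
  list(f_d = gp$f_d, tau_T_d = gp$tau_T_d, f_a = gp$f_a,
       tau_T_a = gp$tau_T_a, p = gp$p)
}

# small, fast photon-sim config for structural tests
tiny_sim_config <- function(seed = 1L, ...) {
  diffusion_sim_config(n_molecules = 4L, duration = 0.5,
                       background_rate = c(2000, 2000), seed = seed,
                       ...)
}

quiet_correlate <- function(...) suppressWarnings(multitau_correlate(...))

# cohort simulation + anchored decomposition for a reference condition
run_population_recovery <- function(condition, seed) {
  rs <- fret_reference_states(condition)
  cfg <- trajectory_sim_config(
    n_trajectories = rs$n_trajectories, regime = "static",
    state_distance_means = rs$means, state_weights = rs$weights,
    state_distance_sds = rs$sds, seed = seed)
  trajs <- simulate_fret_trajectories(cfg)
  classify_cohort(trajs,
                  fret_corrections(cfg$crosstalk_beta,
                                   cfg$gamma_brightness),
                  init = list(weights = rs$weights, means = rs$means,
                              sds = rs$sds),
                  anchor = TRUE)
}

# one full photon-stream -> correlation -> global-fit pass; returns the
# fitted global model
run_fccs_pipeline <- function(seed, duration = 60, n_molecules = 6L) {
  cfg <- diffusion_sim_config(n_molecules = n_molecules,
                              duration = duration, seed = seed)
  st <- simulate_photon_stream(cfg)
  pairs <- c("AC-d", "AC-a", "CC-da", "CC-ad")
  curves <- lapply(pairs, function(p) quiet_correlate(st, p))
  names(curves) <- pairs
  cvs <- lapply(curves, function(cv) {
    d <- as.data.frame(cv)
    d[d$lag <= 0.5, ]
  })
  names(cvs) <- pairs
  sf <- fit_separate(cvs[["AC-d"]], kind = "AC")
  sfa <- fit_separate(cvs[["AC-a"]], kind = "AC")
  fx <- list(f_d = sf$params$f, tau_T_d = sf$params$tau_T,
             f_a = sfa$params$f, tau_T_a = sfa$params$tau_T,
             p = sf$params$p)
  init <- global_params(N = sf$params$N, tau_D = sf$params$tau_D,
                        tau_I = 1e-4, alpha = 0.1, beta = 0.05,
                        gamma = 0.05, delta = 0.05, Delta = 0,
                        f_d = fx$f_d, tau_T_d = fx$tau_T_d,
                        f_a = fx$f_a, tau_T_a = fx$tau_T_a, p = fx$p)
  fit_global(cvs, init = init, fixed = fx)
}
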