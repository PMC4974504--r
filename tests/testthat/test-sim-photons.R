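test_that("config validation enforces the documented invariants", {
  expect_error(diffusion_sim_config(duration = 0), "duration")
  expect_error(diffusion_sim_config(n_molecules = 0))
  # step must resolve the fastest process (triplet here: 3.813 us)
  expect_error(diffusion_sim_config(time_step = 1e-6), "time_step")
  expect_warning(diffusion_sim_config(
    brightness = rbind(c(1e6, 1e6), c(1e6, 1e6)),
    time_step = 5e-7), "identical brightness")
  # reported derived quantities
  cfg <- diffusion_sim_config()
  expect_equal(cfg$tau_D_implied, 200e-6, tolerance = 1e-12)
  expect_equal(cfg$n_eff,
               6 * pi^1.5 * 0.3^2 * 0.9 / prod(2 * cfg$box_half_widths))
})

test_that("identical seeds give identical photon streams", {
  cfg <- tiny_sim_config()
  s1 <- simulate_photon_stream(cfg)
  s2 <- simulate_photon_stream(cfg)
  expect_identical(s1$times, s2$times)
  expect_identical(s1$channel, s2$channel)
  s3 <- simulate_photon_stream(tiny_sim_config(seed = 2L))
  expect_false(identical(s1$times, s3$times))
})

test_that("mean count rate matches the profile-weighted expectation", {
  cfg <- diffusion_sim_config(n_molecules = 10L, duration = 10,
                              triplet_f = c(0.2, 0.2),
                              triplet_tau = c(4e-6, 4e-6),
                              background_rate = c(300, 300), seed = 6)
  st <- simulate_photon_stream(cfg)
  mu <- cfg$focus_lateral
  w_mean <- (pi / 2)^1.5 * mu^3 * cfg$aspect_ratio /
    prod(2 * cfg$box_half_widths)
  p_open <- cfg$k_open / (cfg$k_open + cfg$k_close)
  b_state <- rowSums(cfg$brightness)    # total brightness per state
  per_ch <- colSums(cfg$brightness * c(1 - p_open, p_open)) *
    (1 - cfg$triplet_f)
  expected <- cfg$n_molecules * w_mean * sum(per_ch) +
    sum(cfg$background_rate)
  # standard error from one-second chunks
  chunks <- tabulate(floor(st$times) + 1L, nbins = 10L)
  se <- stats::sd(chunks) / sqrt(10)
  expect_lt(abs(length(st$times) / st$duration - expected), 3 * se)
})

test_that("state occupancy and dwell times follow the Markov model", {
  cfg <- diffusion_sim_config(n_molecules = 10L, duration = 10,
                              k_open = 45, k_close = 55,
                              background_rate = c(0, 0), seed = 9)
  st <- simulate_photon_stream(cfg, record_transitions = TRUE)
  tr <- st$transitions
  fracs <- vapply(1:10, function(m) {
    tt <- tr$time[tr$molecule == m]
    ss <- tr$state[tr$molecule == m]
    # state before the first transition is the complement of its target
    bounds <- c(0, tt, cfg$duration)
    states <- c(1L - ss[1], ss)
    sum(diff(bounds)[states == 1L]) / cfg$duration
  }, numeric(1))
  p_open <- 45 / 100
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - p_open), 3 * se)
  # dwell times in the open state are exponential with rate k_close
  dw <- unlist(lapply(1:10, function(m) {
    tt <- tr$time[tr$molecule == m]
    ss <- tr$state[tr$molecule == m]
    enter <- tt[ss == 1L]
    leave <- tt[ss == 0L]
    if (length(enter) && length(leave)) {
      leave <- leave[leave > enter[1]]
      n <- min(length(enter), length(leave))
      leave[seq_len(n)] - enter[seq_len(n)]
    }
  }))
  ks <- stats::ks.test(dw, "pexp", 55)
  expect_gt(ks$p.value, 0.01)
})

test_that("a static single species reproduces the diffusion model", {
  cfg <- diffusion_sim_config(
    n_molecules = 10L, focus_lateral = 0.25, aspect_ratio = 2,
    diffusion_coeff = 0.25^2 / (4 * 100e-6),
    brightness = rbind(c(2e6, 0), c(2e6, 0)), k_open = 0, k_close = 0,
    triplet_f = c(0, 0), crosstalk_beta = 0, background_rate = c(0, 0),
    time_step = 1e-6, duration = 30, seed = 42)
  st <- simulate_photon_stream(cfg)
  sm <- smooth_curve(quiet_correlate(st, "AC-d"), 3)
  oracle <- separate_params(N = cfg$n_eff, f = 0,
                            tau_D = cfg$tau_D_implied,
                            p = cfg$aspect_ratio)
  sel <- sm$lag >= 1e-6 & sm$lag <= 10 * cfg$tau_D_implied
  # the fixed-count periodic box carries a -1/n depletion offset on
  # top of the open-volume diffusion law
  th <- eval_separate(sm$lag[sel], oracle) - 1 / cfg$n_molecules
  rel <- sm$G[sel] / th - 1
  expect_lt(sqrt(mean(rel^2)), 0.05)
})

test_that("zero brightness contrast hides the switching dynamics", {
  # states exchange but emit identically: AC must look single-species
  cfg <- suppressWarnings(diffusion_sim_config(
    n_molecules = 10L, brightness = rbind(c(1e6, 1e6), c(1e6, 1e6)),
    k_open = 2250, k_close = 2750, triplet_f = c(0, 0),
    crosstalk_beta = 0, background_rate = c(0, 0), time_step = 5e-7,
    duration = 8, seed = 33))
  st <- simulate_photon_stream(cfg)
  crv <- quiet_correlate(st, "AC-d")
  fit <- fit_separate(as.data.frame(crv)[crv$lag <= 0.1, ],
                      kind = "AC", fixed = list(f = 0, tau_T = 1e-6))
  sel <- crv$lag <= 10 * cfg$tau_D_implied
  rel <- crv$G[sel] / predict(fit, crv$lag[sel]) - 1
  expect_lt(sqrt(mean(rel^2)), 0.07)
})
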