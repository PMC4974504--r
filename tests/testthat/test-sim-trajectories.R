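test_that("trajectory config enforces weights and regime consistency", {
  expect_error(trajectory_sim_config(state_weights = c(0.6, 0.6)),
               "sum to 1")
  # switching regime: weights must match the rate-derived equilibrium
  expect_error(trajectory_sim_config(regime = "switching",
                                     k_open = 1, k_close = 1,
                                     state_weights = c(0.7, 0.3)),
               "equilibrium")
  ok <- trajectory_sim_config(regime = "switching", k_open = 0.225,
                              k_close = 0.275)
  expect_equal(ok$state_weights, c(0.55, 0.45))
})

test_that("static cohorts are deterministic and never change state", {
  cfg <- trajectory_sim_config(n_trajectories = 12L, seed = 7L)
  t1 <- simulate_fret_trajectories(cfg)
  t2 <- simulate_fret_trajectories(cfg)
  expect_identical(lapply(t1, `[[`, "I_D"), lapply(t2, `[[`, "I_D"))
  for (tr in t1) {
    expect_false(is.na(tr$state_static))
    expect_equal(length(unique(tr$occupancy_open)), 1L)
  }
})

test_that("degenerate weights put every bin in the chosen state", {
  cfg <- trajectory_sim_config(n_trajectories = 10L,
                               state_weights = c(1, 0), seed = 2L)
  trajs <- simulate_fret_trajectories(cfg)
  for (tr in trajs) {
    expect_equal(tr$state_static, 1L)
    # latent distances all near the closed centre
    expect_lt(max(abs(tr$distance_true - 0.87)), 5 * 0.08)
  }
})

test_that("simulated bleach steps are found by detect_bleach", {
  cfg <- trajectory_sim_config(n_trajectories = 30L, seed = 4L)
  trajs <- simulate_fret_trajectories(cfg)
  hits <- vapply(trajs, function(tr) {
    if (length(tr$I_D) < 5L) return(NA)
    isTRUE(detect_bleach(tr, background = 2) == tr$bleach_index)
  }, NA)
  expect_gt(mean(hits, na.rm = TRUE), 0.9)
})

test_that("corrected efficiencies recover the planted distances", {
  cfg <- trajectory_sim_config(n_trajectories = 20L,
                               total_photons_per_bin_mean = 2000,
                               seed = 10L)
  trajs <- simulate_fret_trajectories(cfg)
  err <- unlist(lapply(trajs, function(tr) {
    e <- compute_efficiency(tr, fret_corrections(cfg$crosstalk_beta,
                                                 cfg$gamma_brightness))
    e <- pmin(pmax(e, 1e-3), 1 - 1e-3)
    efficiency_to_distance(e) - tr$distance_true[attr(e, "bins")]
  }))
  # photon noise only: distances unbiased and tight at 2000 photons/bin
  expect_lt(abs(mean(err)), 0.01)
  expect_lt(stats::sd(err), 0.04)
})

test_that("fast switching collapses bins to the population mean", {
  # relaxation time 1 ms << 100 ms bins: occupancy-averaged bins
  cfg <- trajectory_sim_config(n_trajectories = 25L,
                               regime = "switching",
                               k_open = 450, k_close = 550, seed = 12L)
  trajs <- simulate_fret_trajectories(cfg)
  occ <- unlist(lapply(trajs, `[[`, "occupancy_open"))
  r <- unlist(lapply(trajs, `[[`, "distance_true"))
  # unimodal around the occupancy-weighted mean, not at the state
  # centres: nearly all bins are mixtures
  expect_gt(mean(occ > 0.2 & occ < 0.8), 0.95)
  target <- 0.55 * 0.87 + 0.45 * 1.38
  expect_lt(abs(mean(r) - target), 0.02)
  # brute-force oracle for the occupancy distribution: discretized
  # chain at 1 ms steps
  set.seed(99)
  p_oc <- 0.45
  n_steps <- 500L                      # 0.2 ms steps over one bin
  occ_bf <- replicate(400, {
    s <- stats::runif(1) < p_oc
    mean(replicate(n_steps, {
      s <<- if (s) stats::runif(1) > 550 * 2e-4 else
        stats::runif(1) < 450 * 2e-4
      s
    }))
  })
  expect_lt(abs(mean(occ) - mean(occ_bf)), 0.03)
  expect_lt(abs(stats::sd(occ) - stats::sd(occ_bf)), 0.03)
})

test_that("slow switching lets single trajectories visit both peaks", {
  cfg <- trajectory_sim_config(n_trajectories = 30L,
                               regime = "switching", k_open = 0.9,
                               k_close = 1.1, seed = 21L)
  trajs <- simulate_fret_trajectories(cfg)
  co <- classify_cohort(trajs,
                        fret_corrections(cfg$crosstalk_beta,
                                         cfg$gamma_brightness))
  # relaxation (0.5 s) << observation (~8.8 s) but dwells (~1 s) >>
  # bins (0.1 s): most molecules show both states for >= 3 bins each
  long_enough <- vapply(trajs, function(tr)
    sum(seq_along(tr$I_D) < tr$bleach_index) >= 30, NA)
  expect_gt(mean(co$classes[long_enough] == "both"), 0.9)
})

test_that("two-state path sampler has exponential dwell times", {
  path <- sample_two_state_path(100, 100, 110, seed = 77L)
  dt <- diff(c(path$t, path$duration))
  st <- path$state
  # ~1e4 dwells per state; drop the censored final dwell
  open_dw <- dt[st == 1L][-sum(st == 1L)]
  closed_dw <- dt[st == 0L][-sum(st == 0L)]
  expect_gt(length(open_dw), 5000)
  expect_gt(stats::ks.test(open_dw, "pexp", 100)$p.value, 0.01)
  expect_gt(stats::ks.test(closed_dw, "pexp", 100)$p.value, 0.01)
})
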