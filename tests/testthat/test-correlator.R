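test_that("uncorrelated Poisson streams give a null correlation", {
  st <- make_poisson_stream(3e4, 3e4, 2, seed = 8)
  for (pr in c("AC-d", "CC-da")) {
    crv <- quiet_correlate(st, pr, n_levels = 12)
    # Poisson product noise: var(G_hat) = (1/m^2 + 2/m)/M with
    # m = rate * bin width at the lag's coarsening level
    lv <- pmax(0, floor(log2(crv$lag / 1e-6 / 16)) + 1)
    m <- 3e4 * 1e-6 * 2^lv
    se <- sqrt((1 / m^2 + 2 / m) / crv$n_samples)
    expect_true(all(abs(crv$G) < 4 * se))
  }
})

test_that("modulated stream matches the closed-form cosine correlation", {
  st <- make_modulated_stream(2e5, 0.6, 200, 4, seed = 2)
  crv <- quiet_correlate(st, "AC-d", n_levels = 14)
  theory <- 0.6^2 / 2 * cos(2 * pi * 200 * crv$lag)
  # below ~1/8 of the period the multi-tau bin smearing of the cosine
  # is negligible and the estimate should track the closed form
  sel <- crv$lag < 0.01
  expect_lt(max(abs(crv$G[sel] - theory[sel])), 0.02)
  # the oscillation minimum sits at half the modulation period
  half <- crv$G[which.min(abs(crv$lag - 1 / (2 * 200)))]
  expect_lt(abs(half - (-0.18)), 0.02)
})

test_that("multi-tau agrees with the brute-force correlator", {
  st <- make_modulated_stream(2e5, 0.6, 200, 4, seed = 21)
  mt <- quiet_correlate(st, "AC-d", n_levels = 12)
  dc <- direct_correlate(st, "AC-d", lags = mt$lag, max_bins = 4e6)
  # restrict to lags where the coarse-bin smearing of the two
  # estimators is matched (bin width << modulation period)
  ok <- mt$n_samples > 100 & abs(dc$G) > 0.02 & mt$lag < 1e-3
  rel <- abs(mt$G[ok] - dc$G[ok]) / abs(dc$G[ok])
  expect_gt(sum(ok), 50)
  expect_lt(stats::median(rel), 0.02)
  expect_lt(max(rel), 0.1)
})

test_that("single photon pairs and edge cases", {
  # one photon per channel at a known offset: CC peaks at that lag bin
  st <- make_stream(c(0.001, 0.001 + 64e-6), c(1L, 2L), duration = 0.01)
  crv <- direct_correlate(st, "CC-da", lags = c(16, 32, 64, 128) * 1e-6)
  expect_equal(crv$lag[which.max(crv$G)], 64e-6)
  # empty lag list gives an empty curve
  empty <- direct_correlate(st, "CC-da", lags = numeric(0))
  expect_equal(nrow(empty), 0L)
  # missing channel is reported by name
  donly <- make_stream(runif(100, 0, 1), rep(1L, 100), 1)
  expect_error(quiet_correlate(donly, "AC-a"), "acceptor")
  expect_error(quiet_correlate(donly, "CC-da"), "acceptor")
  # brute-force guard
  long <- make_poisson_stream(1e3, 1e3, 20, seed = 1)
  expect_error(direct_correlate(long, "AC-d", lags = 1e-5,
                                max_bins = 1e6), "too long")
})

test_that("normalization is invariant under intensity scaling", {
  st <- make_poisson_stream(2e4, 2e4, 1, seed = 14)
  # tripling every photon multiplies both channel intensities by 3
  st3 <- make_stream(rep(st$times, each = 3),
                     rep(st$channel, each = 3), st$duration)
  g1 <- quiet_correlate(st, "CC-da", n_levels = 10)
  g3 <- quiet_correlate(st3, "CC-da", n_levels = 10)
  expect_equal(g1$G, g3$G, tolerance = 1e-12)
})

test_that("smoothing averages adjacent lags and shrinks noise", {
  crv <- new_correlation_curve(log_lags(1e-6, 1e-2, 64),
                               rnorm(64), rep(c(1, 3), 32),
                               "AC-d", 1)
  expect_equal(smooth_curve(crv, 1), crv)
  one <- smooth_curve(crv, 64)
  expect_equal(nrow(one), 1L)
  expect_equal(one$G, sum(crv$G * crv$n_samples) / sum(crv$n_samples))
  expect_error(smooth_curve(crv, 65), "exceeds")
  # white-noise sd shrinks roughly like 1/sqrt(factor)
  set.seed(9)
  ratios <- replicate(40, {
    x <- new_correlation_curve(log_lags(1e-6, 1e-2, 128),
                               rnorm(128), rep(1, 128), "AC-d", 1)
    sd(smooth_curve(x, 4)$G) / sd(x$G)
  })
  expect_lt(abs(mean(ratios) - 0.5), 0.08)
})

test_that("the two cross-correlation directions agree within noise", {
  cfg <- diffusion_sim_config(n_molecules = 8L, duration = 4,
                              seed = 17)
  st <- simulate_photon_stream(cfg)
  da <- quiet_correlate(st, "CC-da", n_levels = 14)
  ad <- quiet_correlate(st, "CC-ad", n_levels = 14)
  sel <- da$lag <= 0.05
  sm_da <- smooth_curve(da[sel, ], 4)
  sm_ad <- smooth_curve(ad[sel, ], 4)
  amp <- max(abs(sm_da$G))
  expect_lt(mean(abs(sm_da$G - sm_ad$G)), 0.1 * amp)
})

test_that("doubling the duration halves the correlation noise variance", {
  var_at <- function(dur) {
    gs <- sapply(1:20, function(s) {
      st <- make_poisson_stream(2e4, 2e4, dur, seed = 100 + s)
      crv <- quiet_correlate(st, "CC-da", n_levels = 8,
                             resolution = 1e-5)
      mean(crv$G[crv$lag > 1e-4]^2)
    })
    mean(gs)
  }
  ratio <- var_at(1) / var_at(2)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
})
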