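test_that("corrected efficiency follows the ratiometric formula", {
  tr <- list(I_D = c(100, 0, 100), I_A = c(100, 50, 0))
  e <- compute_efficiency(tr, fret_corrections())
  expect_equal(e[1], 0.5)
  expect_equal(e[2], 1)          # donor-dark bin
  expect_equal(e[3], 0)          # acceptor fully crosstalk-free zero
  # beta/gamma corrections: I_A_corr = 120 - 0.1*100 = 110,
  # E = 110 / (110 + 1.2*100)
  e2 <- compute_efficiency(list(I_D = 100, I_A = 120),
                           fret_corrections(0.1, 1.2))
  expect_equal(round(e2[1], 3), 0.478)
  # crosstalk larger than the acceptor signal clamps at zero
  e3 <- compute_efficiency(list(I_D = 100, I_A = 5),
                           fret_corrections(0.2, 1))
  expect_equal(e3[1], 0)
})

test_that("empty bins are dropped and post-bleach bins excluded", {
  tr <- list(I_D = c(100, 0, 100, 0, 0), I_A = c(100, 0, 100, 0, 0),
             bleach_index = 4L)
  e <- compute_efficiency(tr, fret_corrections())
  expect_equal(length(e), 2L)
  expect_equal(attr(e, "bins"), c(1L, 3L))
})

test_that("distance/efficiency conversions match the Foerster relation", {
  expect_equal(efficiency_to_distance(0.5), 1)
  expect_equal(round(distance_to_efficiency(0.87), 3), 0.698)
  expect_equal(round(distance_to_efficiency(1.38), 3), 0.126)
  # Angstrom scale through r0
  expect_equal(efficiency_to_distance(0.5, r0 = 51), 51)
  # strictly decreasing in R
  r <- seq(0.3, 3, length.out = 100)
  expect_true(all(diff(distance_to_efficiency(r)) < 0))
  # out-of-domain efficiencies are signalled
  expect_error(efficiency_to_distance(0), "strictly inside")
  expect_error(efficiency_to_distance(1), "strictly inside")
  expect_error(distance_to_efficiency(-1), "positive")
})

test_that("conversion round-trips to 1e-10 R0", {
  r <- c(seq(0.4, 2.5, length.out = 50), 0.87, 1.38)
  back <- efficiency_to_distance(distance_to_efficiency(r))
  expect_lt(max(abs(back - r)), 1e-10)
  e <- seq(0.01, 0.99, length.out = 50)
  expect_lt(max(abs(distance_to_efficiency(efficiency_to_distance(e)) - e)),
            1e-10)
})

test_that("bleach detection finds the right change point", {
  set.seed(5)
  # clean single step at bin 70
  n <- 90
  tot <- c(rpois(69, 200), rpois(21, 1))
  tr <- list(I_D = tot * 0.5, I_A = tot * 0.5)
  expect_equal(detect_bleach(tr), 70L)
  # monotone noisy trace without a step: no bleach
  tr2 <- list(I_D = 300 - seq_len(80) + rpois(80, 4),
              I_A = 200 + rpois(80, 4))
  expect_true(is.na(detect_bleach(tr2)))
  # acceptor bleaches at 40, donor at 70: the first step is reported
  ia <- c(rpois(39, 150), rpois(51, 1))
  id <- c(rpois(39, 150), rpois(30, 280), rpois(21, 1))
  expect_equal(detect_bleach(list(I_D = id, I_A = ia)), 40L)
  expect_error(detect_bleach(list(I_D = 1:3, I_A = 1:3)), "5 bins")
})
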