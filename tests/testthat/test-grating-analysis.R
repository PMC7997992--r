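bin_centres <- function(n = 100, period = 1) (seq_len(n) - 0.5) / n * period

test_that("harmonic amplitudes use the sinusoid convention", {
  tt <- bin_centres()
  h <- harmonic_amplitudes(5 + 3 * sin(2 * pi * tt), period_s = 1)
  expect_equal(h$f1, 3, tolerance = 1e-10)
  expect_equal(h$f2, 0, tolerance = 1e-10)

  h_abs <- harmonic_amplitudes(abs(sin(2 * pi * tt)), period_s = 1)
  expect_equal(h_abs$f1, 0, tolerance = 1e-10)
  expect_equal(h_abs$f2, 4 / (3 * pi), tolerance = 1e-3)

  h_const <- harmonic_amplitudes(rep(7, 50), period_s = 1)
  expect_equal(c(h_const$f1, h_const$f2), c(0, 0))
  expect_equal(h_const$mean_rate, 7)

  expect_error(harmonic_amplitudes(1:3, period_s = 1), "few bins")
})

test_that("harmonic energy is bounded by the PSTH variance", {
  set.seed(9)
  for (i in 1:25) {
    r <- pmax(rnorm(100, 10, 3), 0)
    h <- harmonic_amplitudes(r, period_s = 1)
    v <- mean((r - mean(r))^2)
    expect_lte((h$f1^2 + h$f2^2) / 2, v + 1e-9)
  }
  # equality for a band-limited rate
  tt <- bin_centres()
  r <- 10 + 2 * sin(2 * pi * tt) + 1.5 * cos(4 * pi * tt)
  h <- harmonic_amplitudes(r, period_s = 1)
  expect_equal((h$f1^2 + h$f2^2) / 2, mean((r - mean(r))^2), tolerance = 1e-9)
})

test_that("single-period folding excludes the first period", {
  # one spike per period at a fixed phase, 10 periods of 1 s
  st <- (0:9) + 0.305
  p <- psth_over_period(st, period_s = 1, n_periods = 10)
  expect_equal(p$n_trials, 9) # first period dropped
  expect_equal(sum(p$rate > 0), 1L)
  expect_equal(max(p$rate), 9 / (9 * 0.01))
  expect_equal(p$mid[which.max(p$rate)], 0.305)
  expect_error(psth_over_period(st, period_s = 1.003, n_periods = 10), "divide")
})

test_that("the grating nonlinearity index is F2/F1 at the smallest F1", {
  hp <- function(f1, f2, max_rate = 20) {
    structure(list(f1 = f1, f2 = f2, max_rate = max_rate),
              class = "harmonic_pair")
  }
  harms <- mapply(hp, f1 = c(9, 5, 1, 6), f2 = c(1, 1, 0.4, 1),
                  SIMPLIFY = FALSE)
  expect_equal(grating_nonlinearity_index(harms), 0.4)

  # pure-F1 responses give an index near zero
  pure <- mapply(hp, f1 = c(9, 5, 2), f2 = c(0, 0, 0), SIMPLIFY = FALSE)
  expect_equal(grating_nonlinearity_index(pure), 0)

  # ties at minimal F1 resolve to the lowest stimulus index
  tied <- mapply(hp, f1 = c(2, 2, 5), f2 = c(0.5, 1.5, 1), SIMPLIFY = FALSE)
  expect_equal(grating_nonlinearity_index(tied), 0.25)

  # cells below the 5-Hz PSTH criterion are excluded, not crashed
  weak <- mapply(hp, f1 = c(1, 2), f2 = c(1, 1), max_rate = c(3, 4),
                 SIMPLIFY = FALSE)
  out <- grating_nonlinearity_index(weak)
  expect_true(is.na(out))
  expect_identical(attr(out, "reason"), "excluded")
})

test_that("the spatial nonlinearity index takes independent maxima", {
  hp <- function(f1, f2) structure(list(f1 = f1, f2 = f2, max_rate = 50),
                                   class = "harmonic_pair")
  harms <- list(hp(10, 1), hp(2, 14), hp(6, 3))
  expect_equal(spatial_nonlinearity_index(harms), 14 / 10)
  expect_equal(spatial_nonlinearity_index(list(hp(4, 2))), 0.5)
  expect_true(is.na(spatial_nonlinearity_index(list(hp(0, 2)))))
})

test_that("selectivity indices follow the normalised vector sum", {
  th <- eight_directions
  expect_equal(selectivity_index(rep(3, 8), th), 0, tolerance = 1e-12)
  one <- rep(0, 8); one[3] <- 5
  expect_equal(selectivity_index(one, th), 1)
  # cosine tuning over 8 equidistant directions gives exactly 1/2
  expect_equal(selectivity_index(1 + cos(th - 2.2), th), 0.5,
               tolerance = 1e-12)
  # orientation: doubling the angle detects axial tuning
  axial <- 1 + cos(2 * (th - 0.7))
  expect_equal(selectivity_index(axial, th, "orientation"), 0.5,
               tolerance = 1e-12)
  expect_lt(selectivity_index(axial, th, "direction"), 1e-12)
  expect_true(is.na(selectivity_index(rep(0, 8), th)))
})

test_that("selectivity is invariant to rate scaling and mirroring", {
  set.seed(12)
  th <- eight_directions
  for (i in 1:30) {
    r <- runif(8, 0, 10)
    expect_equal(selectivity_index(3.7 * r, th), selectivity_index(r, th),
                 tolerance = 1e-12)
    # mirroring the tuning curve across any axis preserves the DSI
    expect_equal(selectivity_index(rev(r), th), selectivity_index(r, th),
                 tolerance = 1e-12)
  }
})

test_that("the permutation test separates tuned from untuned cells", {
  th <- eight_directions
  # strongly tuned: all spikes in one direction
  counts <- matrix(0, nrow = 4, ncol = 8)
  counts[, 2] <- c(30, 28, 33, 29)
  pt <- permutation_test(counts, th, n_perm = 1000, seed = 5)
  expect_equal(pt$index, 1)
  expect_equal(pt$p_value, 1 / 1001)

  # degenerate all-equal counts
  flat <- matrix(4, nrow = 3, ncol = 8)
  expect_equal(permutation_test(flat, th, seed = 1)$p_value, 1)

  expect_error(permutation_test(matrix(1, 1, 8), th), "repetitions")

  # decision rule: tuned cell with adequate rate is direction selective
  set.seed(8)
  tuned <- matrix(rpois(32, rep(2 + 18 * (1 + cos(th - 1))/2, each = 4)),
                  nrow = 4)
  dec <- classify_selectivity(tuned, th, duration_s = 1, n_perm = 500, seed = 2)
  expect_true(dec$direction_selective)
  expect_gt(dec$dsi, 0.3)
  expect_lt(dec$dsi_p, 0.05)

  # sub-1-Hz cells are excluded by the rate floor
  quiet <- matrix(rpois(32, 0.3), nrow = 4)
  dec_q <- classify_selectivity(quiet, th, duration_s = 1, n_perm = 200, seed = 3)
  expect_false(dec_q$direction_selective)
})
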