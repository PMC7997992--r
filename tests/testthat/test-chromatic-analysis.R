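test_that("PSTH normalisation is count over trials times bin width", {
  p1 <- compute_psth(0.055, n_trials = 1)
  expect_equal(max(p1$rate), 100)
  expect_equal(sum(p1$rate > 0), 1L)

  p2 <- compute_psth(spikes_in_bin(10, 0.05), n_trials = 5)
  expect_equal(max(p2$rate), 200) # 10 / (5 * 0.01)

  p0 <- compute_psth(numeric(0), n_trials = 3)
  expect_true(all(p0$rate == 0))
  expect_error(compute_psth(0.1, n_trials = 0), "trial")

  # integral over the window times trials recovers the spike count
  set.seed(1)
  st <- runif(500, -0.5, 0.5)
  p <- compute_psth(st, n_trials = 7)
  expect_equal(sum(p$rate * diff(p$edges)) * 7, 500)
})

test_that("baseline subtraction uses the matched 200-ms windows", {
  # 10 spikes in the response window, 2 in baseline, 5 trials
  r <- data.frame(trial = c(rep(1:5, each = 2), 1, 2),
                  spike_time_s = c(rep(c(0.1, 0.2), 5), -0.1, -0.15))
  expect_equal(baseline_subtracted_response(r, 5), (10 - 2) / (5 * 0.2))

  # identical spike pattern in both windows cancels
  r2 <- data.frame(trial = rep(1, 4), spike_time_s = c(-0.15, -0.05, 0.05, 0.15))
  expect_equal(baseline_subtracted_response(r2, 1), 0)

  # baseline-only activity gives negative R
  r3 <- data.frame(trial = 1:4, spike_time_s = rep(-0.1, 4))
  expect_lt(baseline_subtracted_response(r3, 4), 0)
})

test_that("integration curves align sets and report the trial SEM", {
  cell <- model_cell("linear-Off", cell_id = "c")
  r <- simulate_step_responses(cell, the_set, n_trials = 30, seed = 5)
  cv <- integration_curves(r, the_set)
  expect_identical(cv$index, 1:11)
  expect_length(cv$r_onoff, 11)
  expect_length(cv$responses, 22)

  # SEM oracle: direct per-trial computation for one stimulus
  id <- "green-Off-UV-On:03"
  sub <- r[r$stimulus_id == id, ]
  per_trial <- baseline_subtracted_response(sub, 30, per_trial = TRUE)
  expect_equal(unname(cv$sem_offon[3]), sd(per_trial) / sqrt(30))
  expect_equal(unname(cv$r_offon[3]), mean(per_trial))

  # opposite slopes crossing near zero for a linear cell
  expect_lt(cor(cv$r_onoff, cv$r_offon), 0)
  expect_true(find_crossing(cv)$exists)

  bad <- r; bad$stimulus_id[1] <- "unknown:99"
  expect_error(integration_curves(bad, the_set), "not in the set")
})

test_that("the crossing lower-bound rule matches its worked examples", {
  # bracketing values [2, 6] vs [5, 3]: per-curve minima 2 and 3, bound 3
  cv <- curves_from_responses(c(2, 6), c(5, 3))
  cr <- find_crossing(cv)
  expect_true(cr$exists)
  expect_equal(cr$lower_bound, 3)

  # both curves straddle zero: bound 0
  cv2 <- curves_from_responses(c(-1, 2), c(2, -1))
  expect_equal(find_crossing(cv2)$lower_bound, 0)

  # strictly ordered curves never cross (colour-opponent pattern)
  cv3 <- curves_from_responses(c(5, 6, 7), c(1, 2, 3))
  expect_false(find_crossing(cv3)$exists)

  # touching counts as a crossing, with the bound from the shared value
  cv4 <- curves_from_responses(c(4, 1), c(2, 1))
  cr4 <- find_crossing(cv4)
  expect_true(cr4$exists)
  expect_equal(cr4$lower_bound, 1)
})

test_that("crossing search agrees with brute force on random curve pairs", {
  set.seed(42)
  n_checked <- 0L
  for (i in seq_len(10000)) {
    n <- sample(4:11, 1)
    c1 <- round(rnorm(n, 0, 8), 3)
    c2 <- round(rnorm(n, 0, 8), 3)
    cv <- curves_from_responses(c1, c2)
    got <- find_crossing(cv)
    want <- oracle_find_crossing(c1, c2)
    if (is.null(want)) {
      expect_false(got$exists)
    } else {
      n_checked <- n_checked + 1L
      expect_true(got$exists)
      expect_equal(got$lower_bound, want$lb, tolerance = 1e-9)
    }
  }
  expect_gt(n_checked, 5000)
})

test_that("the chromatic nonlinearity index normalises the lower bound", {
  cv <- curves_from_responses(c(2, 6, 30), c(5, 3, -2))
  cr <- find_crossing(cv)
  expect_equal(chromatic_nonlinearity_index(cv, cr), 3 / 30)

  cv0 <- curves_from_responses(c(-1, 2, 10), c(2, -1, -10))
  expect_equal(chromatic_nonlinearity_index(cv0), 0)

  no_cross <- curves_from_responses(c(5, 6), c(1, 2))
  expect_true(is.na(chromatic_nonlinearity_index(no_cross)))
})

test_that("relative UV sensitivity follows the interpolated contrasts", {
  # linear curves crossing exactly at ladder index 5: contrasts (0.12, 0.08)
  idx <- 1:11
  cv <- curves_from_responses(5 - idx, idx - 5)
  cr <- find_crossing(cv)
  expect_equal(relative_uv_sensitivity(cv, cr), 0.6)

  # symmetric balance at equal contrasts (index 6): 0.5
  cv6 <- curves_from_responses(6 - idx, idx - 6)
  expect_equal(relative_uv_sensitivity(cv6), 0.5)

  # crossing at index 1 (no UV contrast needed to balance): 1.0
  cv1 <- curves_from_responses(1 - idx, idx - 1)
  expect_equal(relative_uv_sensitivity(cv1), 1.0)

  # interpolation: crossing midway between indices 5 and 6
  shift <- 5.5
  cvm <- curves_from_responses(shift - idx, idx - shift)
  expect_equal(relative_uv_sensitivity(cvm), 1 - 0.09 / 0.20)
})

test_that("the polarity bias is the difference of local slopes", {
  # slopes: green-On curve +4, green-Off curve -6 across the bracket
  cv <- curves_from_responses(c(-2, 2), c(3, -3))
  cr <- find_crossing(cv)
  expect_equal(balance_point_polarity_bias(cv, cr), -6 - 4)

  cv_eq <- curves_from_responses(c(-2, 2), c(2, -2))
  expect_equal(balance_point_polarity_bias(cv_eq), -4 - 4)
  cv_flat <- curves_from_responses(c(1, 1, 1), c(2, 0, 1))
  cr_flat <- find_crossing(cv_flat)
  expect_equal(balance_point_polarity_bias(cv_flat, cr_flat),
               (cv_flat$r_offon[cr_flat$bracket[2]] - cv_flat$r_offon[cr_flat$bracket[1]]) - 0)
})

test_that("UV-green and On-Off indices follow their formulas", {
  ids <- pure <- list(
    green_on = "green-On-UV-Off:01", green_off = "green-Off-UV-On:01",
    uv_on = "green-Off-UV-On:11", uv_off = "green-On-UV-Off:11")
  # equal peaks -> 0; f_green = 15, f_uv = 5 -> 0.5
  mk <- function(g_on, g_off, u_on, u_off) {
    structure(data.frame(
      cell_id = "c",
      stimulus_id = rep(unlist(ids), c(g_on, g_off, u_on, u_off)),
      trial = 1L,
      spike_time_s = c(spikes_in_bin(g_on, 0.10), spikes_in_bin(g_off, 0.10),
                       spikes_in_bin(u_on, 0.10), spikes_in_bin(u_off, 0.10))),
      n_trials = 1L)
  }
  expect_equal(uv_green_index(mk(15, 2, 15, 3), the_set), 0)
  expect_equal(uv_green_index(mk(15, 3, 5, 2), the_set), 0.5)
  expect_equal(uv_green_index(mk(0, 0, 8, 8), the_set), -1)

  # On-Off: R_On = 10, R_Off = 0 -> +1; equal -> 0
  r_onoff <- raster_from_counts(list(
    "green-On-UV-Off:01" = c(baseline = 0, response = 2),
    "green-Off-UV-On:01" = c(baseline = 0, response = 0),
    "green-Off-UV-On:11" = c(baseline = 0, response = 0),
    "green-On-UV-Off:11" = c(baseline = 0, response = 0)), n_trials = 5)
  expect_equal(on_off_index(r_onoff, the_set), 1)

  r_eq <- raster_from_counts(list(
    "green-On-UV-Off:01" = c(baseline = 0, response = 2),
    "green-Off-UV-On:01" = c(baseline = 0, response = 2)), n_trials = 5)
  expect_equal(on_off_index(r_eq, the_set), 0)

  # R_On = 8, R_Off = -2 -> (8 + 2) / (8 + 2) = 1
  r_neg <- raster_from_counts(list(
    "green-On-UV-Off:01" = c(baseline = 0, response = 8),
    "green-Off-UV-On:01" = c(baseline = 2, response = 0)), n_trials = 5)
  expect_equal(on_off_index(r_neg, the_set), 1)
})

test_that("classification precedence and thresholds are applied exactly", {
  th <- default_thresholds()
  lin <- classify_cell(list(nli = 0.05, uv_green = 0.1, on_off = 0.9,
                            crossing_exists = TRUE), th)
  expect_identical(lin$linearity, "linear")
  expect_identical(lin$polarity, "On")

  sup <- classify_cell(list(nli = -0.2, uv_green = 0, on_off = 0.8,
                            crossing_exists = TRUE), th)
  expect_identical(sup$linearity, "nonlinear")
  expect_identical(sup$nli_sign, "negative")
  expect_identical(sup$polarity, "On")

  uvs <- classify_cell(list(nli = NA, uv_green = -0.9, on_off = -0.8,
                            crossing_exists = FALSE), th)
  expect_identical(uvs$special, "UV-selective")

  co <- classify_cell(list(nli = NA, uv_green = -0.3, on_off = -0.8,
                           crossing_exists = FALSE), th)
  expect_identical(co$special, "color-opponent")

  border <- classify_cell(list(nli = 0.1, uv_green = 0, on_off = 0,
                               crossing_exists = TRUE), th)
  expect_identical(border$linearity, "nonlinear") # |NLI| >= 0.1 is nonlinear
})

test_that("indices are invariant under response scaling and channel swap", {
  set.seed(31)
  for (i in 1:40) {
    c1 <- rnorm(11, 0, 6); c2 <- rnorm(11, 0, 6)
    cv <- curves_from_responses(c1, c2)
    cr <- find_crossing(cv)
    if (!cr$exists) next
    k <- runif(1, 0.2, 5)
    cv_k <- curves_from_responses(k * c1, k * c2)
    expect_equal(chromatic_nonlinearity_index(cv_k),
                 chromatic_nonlinearity_index(cv), tolerance = 1e-12)
    expect_equal(relative_uv_sensitivity(cv_k),
                 relative_uv_sensitivity(cv), tolerance = 1e-12)

    # swapping the UV and green channels maps ladder index i -> 12 - i and
    # exchanges the two sets; relative UV sensitivity maps u -> 1 - u.
    # Restricted to curves with a unique crossing: when several brackets tie
    # at the same lower bound the tie-break has no symmetric counterpart.
    d <- c1 - c2
    n_brackets <- sum((d[-11] > 0 & d[-1] <= 0) | (d[-11] < 0 & d[-1] >= 0) |
                        (d[-11] == 0 & d[-1] != 0) | (d[-1] == 0 & d[-11] != 0))
    if (n_brackets == 1) {
      cv_s <- curves_from_responses(rev(c2), rev(c1))
      u <- relative_uv_sensitivity(cv)
      us <- relative_uv_sensitivity(cv_s)
      if (!is.na(u) && !is.na(us)) {
        expect_equal(us, 1 - u, tolerance = 1e-8)
      }
    }
  }
})

test_that("local site selection picks the receptive-field vertex", {
  set <- the_set
  cell <- model_cell("nonlinear-Off", rf_center = c(320, 160), rf_sigma = 80,
                     cell_id = "loc")
  # 3x3 patch of grid vertices at 160-um pitch around the rf centre
  verts <- expand.grid(col = 1:4, row = 1:3)
  verts$vertex <- seq_len(nrow(verts))
  verts$x_um <- (verts$col - 1) * 160
  verts$y_um <- (verts$row - 1) * 160
  resp <- list()
  for (v in verts$vertex) {
    d2 <- (verts$x_um[v] - 320)^2 + (verts$y_um[v] - 160)^2
    w <- exp(-d2 / (2 * 80^2))
    r <- simulate_step_responses(cell, set, n_trials = 25, seed = 100 + v,
                                 surround_active = FALSE, rf_weight = w)
    R <- vapply(set$stimulus_id, function(id) {
      baseline_subtracted_response(r[r$stimulus_id == id, ], 25)
    }, 0)
    resp[[v]] <- data.frame(vertex = v, stimulus_id = set$stimulus_id, R = R)
  }
  rbv <- do.call(rbind, resp)
  sel <- select_local_site(rbv, set, verts, rf_center = c(320, 160),
                           rf_radius = 120)
  target <- verts$vertex[verts$x_um == 320 & verts$y_um == 160]
  expect_identical(sel$site, target)
  expect_false(sel$excluded)

  # a site two grid units from the centre with a 1-unit radius is excluded
  far <- select_local_site(rbv, set, verts, rf_center = c(640, 160),
                           rf_radius = 160)
  expect_true(far$distance_um <= 160 || far$excluded)

  # local stimulation (surround inactive) linearises the cell
  local_nli <- chromatic_nonlinearity_index(sel$curves)
  full <- simulate_step_responses(cell, set, n_trials = 25, seed = 999)
  full_nli <- chromatic_cell_summary(full, set)$nli
  expect_lt(abs(local_nli), abs(full_nli))
})
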