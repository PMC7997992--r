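#' Phenomenological model ganglion cell
#'
#' A linear-nonlinear Poisson cell parameterised by its chromatic archetype.
#' The archetypes reproduce the response phenomenology seen in dichromatic
#' step stimulation: linear cells null at their balance point; nonlinear Off
#' and On-Off cells respond at the balance point; nonlinear On cells are
#' suppressed below their baseline there; UV-selective cells ignore the green
#' channel; colour-opponent cells carry opposite-signed channel weights and no
#' rectification, so their two chromatic-integration curves never cross.
#'
#' The opposing-contrast nonlinearity of the nonlinear archetypes is surround
#' mediated: it is only expressed when the receptive-field surround is
#' stimulated (`surround_active = TRUE` in the simulators, the full-field
#' case). Under locally restricted stimulation the same cell integrates its
#' two chromatic inputs linearly.
#'
#' @param archetype one of `"linear-On"`, `"linear-Off"`, `"linear-OnOff"`,
#'   `"nonlinear-Off"`, `"nonlinear-On"`, `"nonlinear-OnOff"`,
#'   `"UV-selective"`, `"color-opponent"`.
#' @param w_green,w_uv signed channel weights (dimensionless).
#' @param surround_weight weight of an optional subtractive linear surround
#'   term (nonlinear archetypes only; default 0).
#' @param surround_uv_fraction UV share of the surround drive (default 0.5).
#' @param on_suppression suppression gain `k` of the nonlinear-On archetype:
#'   the drive is reduced by `k` times the overlap of opposing-sign channel
#'   contrasts, making the net drive negative at the balance point.
#' @param onoff_on_fraction weight of the linear On term of the
#'   nonlinear-OnOff archetype relative to its rectified Off terms (< 1 makes
#'   the cell Off-dominated, the common case).
#' @param onoff_asymmetry Off/On gain ratio of the linear-OnOff archetype.
#'   Real On-Off cells have unequal On and Off lobes; a ratio different from
#'   1 lets the two chromatic-integration curves cross genuinely at the
#'   response minimum instead of coinciding everywhere.
#' @param baseline_rate spontaneous rate in Hz; must be positive for
#'   `"nonlinear-On"` so that suppression is observable.
#' @param gain firing-rate gain in Hz per unit drive.
#' @param rf_center receptive-field centre `(x, y)` in micrometers on the
#'   virtual retina.
#' @param rf_sigma receptive-field Gaussian sigma in micrometers.
#' @param transientness fraction of the evoked drive confined to the
#'   50-250 ms transient window (default 1; the remainder spills into a
#'   sustained tail until stimulus offset).
#' @param spatial_nonlinearity logical; if `TRUE` the cell pools rectified
#'   subunits and shows frequency doubling under fine reversing gratings.
#' @param subunit_weight gain of the full-wave-rectified subunit component
#'   relative to the linear drive (default 1.5, a strongly doubling Y-type
#'   cell); only used when `spatial_nonlinearity` is `TRUE`.
#' @param cell_id optional identifier.
#' @return A `model_cell` object.
#' @export
model_cell <- function(archetype,
                       w_green = 1, w_uv = 1,
                       surround_weight = 0, surround_uv_fraction = 0.5,
                       on_suppression = 2, onoff_on_fraction = 0.6,
                       onoff_asymmetry = 0.7,
                       baseline_rate = 3, gain = 120,
                       rf_center = c(0, 0), rf_sigma = 60,
                       transientness = 1,
                       spatial_nonlinearity = FALSE, subunit_weight = 1.5,
                       cell_id = NULL) {
  archetype <- match.arg(archetype, cell_archetypes())
  stopifnot(baseline_rate >= 0, gain >= 0, rf_sigma > 0,
            transientness >= 0, transientness <= 1)
  if (archetype == "nonlinear-On" && baseline_rate <= 0) {
    stop("nonlinear-On cells need baseline_rate > 0 for suppression to be observable")
  }
  if (archetype == "UV-selective") w_green <- 0
  if (archetype == "color-opponent" && sign(w_green) == sign(w_uv)) {
    w_uv <- -w_uv
  }
  structure(list(
    archetype = archetype, w_green = w_green, w_uv = w_uv,
    surround_weight = surround_weight,
    surround_uv_fraction = surround_uv_fraction,
    on_suppression = on_suppression, onoff_on_fraction = onoff_on_fraction,
    onoff_asymmetry = onoff_asymmetry,
    baseline_rate = baseline_rate, gain = gain,
    rf_center = rf_center, rf_sigma = rf_sigma,
    transientness = transientness,
    spatial_nonlinearity = spatial_nonlinearity,
    subunit_weight = subunit_weight,
    cell_id = cell_id %||% archetype
  ), class = "model_cell")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cell_archetypes <- function() {
  c("linear-On", "linear-Off", "linear-OnOff",
    "nonlinear-Off", "nonlinear-On", "nonlinear-OnOff",
    "UV-selective", "color-opponent")
}

#' @export
print.model_cell <- function(x, ...) {
  cat(sprintf("Model ganglion cell '%s' (%s)\n", x$cell_id, x$archetype))
  cat(sprintf("  weights (green, uv) = (%.2f, %.2f); baseline %.1f Hz; gain %.0f Hz\n",
              x$w_green, x$w_uv, x$baseline_rate, x$gain))
  cat(sprintf("  rf centre (%.0f, %.0f) um, sigma %.0f um%s\n",
              x$rf_center[1], x$rf_center[2], x$rf_sigma,
              if (x$spatial_nonlinearity) ", spatially nonlinear" else ""))
  invisible(x)
}

#' Drive of a model cell for a UV/green contrast pair
#'
#' Evaluates the archetype-specific combination rule on opsin-level Weber
#' contrasts. Vectorised over pairs.
#'
#' @param cell a [model_cell()].
#' @param green,uv Weber contrasts of the two channels.
#' @param surround_active logical; full-field stimulation engages the
#'   surround-mediated nonlinearity, local stimulation (`FALSE`) does not.
#' @return numeric drive (dimensionless; negative values mean suppression
#'   below baseline).
#' @export
drive <- function(cell, green, uv, surround_active = TRUE) {
  stopifnot(inherits(cell, "model_cell"))
  wg <- cell$w_green
  wu <- cell$w_uv
  lin <- wg * green + wu * uv
  surround <- if (surround_active && cell$surround_weight > 0) {
    f <- cell$surround_uv_fraction
    cell$surround_weight * rectify(-(f * uv + (1 - f) * green))
  } else 0
  switch(cell$archetype,
    "linear-On" = rectify(lin),
    "linear-Off" = rectify(-lin),
    "linear-OnOff" = rectify(lin) + cell$onoff_asymmetry * rectify(-lin),
    "UV-selective" = rectify(-wu * uv),
    "color-opponent" = lin,
    "nonlinear-Off" = if (surround_active) {
      rectify(-wg * green) + rectify(-wu * uv) - surround
    } else {
      rectify(-lin)
    },
    "nonlinear-On" = if (surround_active) {
      opp <- pmin(rectify(wg * green), rectify(-wu * uv)) +
        pmin(rectify(-wg * green), rectify(wu * uv))
      rectify(lin) - cell$on_suppression * opp
    } else {
      rectify(lin)
    },
    "nonlinear-OnOff" = if (surround_active) {
      rectify(-wg * green) + rectify(-wu * uv) +
        cell$onoff_on_fraction * rectify(lin) - surround
    } else {
      rectify(-lin) + cell$onoff_on_fraction * rectify(lin)
    },
    stop("unknown archetype: ", cell$archetype)
  )
}

#' Simulate Poisson spike trains to the chromatic-integration step stimulus
#'
#' Generates an inhomogeneous Poisson raster for every contrast combination of
#' a stimulus set. The rate equals the baseline everywhere except an evoked
#' window: a transient window 50-250 ms after onset receives
#' `gain * drive * transientness` on top of baseline, the remaining
#' 250-500 ms receives the `1 - transientness` remainder. Rates are floored
#' at zero after summation, so suppression can silence the cell but never
#' produces negative rates.
#'
#' @param cell a [model_cell()].
#' @param set a [chromatic_integration_set()] (or any data.frame with
#'   `stimulus_id`, `green`, `uv`).
#' @param n_trials trials per combination (default 50).
#' @param seed optional integer seed.
#' @param surround_active passed to [drive()]; set `FALSE` for locally
#'   restricted stimulation.
#' @param rf_weight multiplicative attenuation of the evoked drive (Gaussian
#'   receptive-field overlap of a local spot; 1 for full-field).
#' @param window recorded window in seconds relative to onset.
#' @return A trial raster: data.frame with columns `cell_id`, `stimulus_id`,
#'   `trial`, `spike_time_s`, spike times sorted within trials; attribute
#'   `n_trials`.
#' @export
simulate_step_responses <- function(cell, set, n_trials = 50, seed = NULL,
                                    surround_active = TRUE, rf_weight = 1,
                                    window = c(-0.5, 0.5)) {
  stopifnot(inherits(cell, "model_cell"), n_trials >= 1)
  d <- drive(cell, set$green, set$uv, surround_active = surround_active)
  evoked <- cell$gain * rf_weight * d
  b <- cell$baseline_rate
  tr <- cell$transientness
  # piecewise-constant rate segments of the recorded window
  seg_edges <- c(window[1], 0.05, 0.25, window[2])
  out <- with_seed(seed, {
    pieces <- vector("list", nrow(set))
    for (i in seq_len(nrow(set))) {
      rates <- c(b,
                 max(0, b + tr * evoked[i]),
                 max(0, b + (1 - tr) * evoked[i]))
      pieces[[i]] <- poisson_segments(rates, seg_edges, n_trials,
                                      cell$cell_id, set$stimulus_id[i])
    }
    do.call(rbind, pieces)
  })
  structure(out, n_trials = n_trials, window = window)
}

# Draw Poisson spikes for piecewise-constant rates over n_trials trials.
poisson_segments <- function(rates, edges, n_trials, cell_id, stimulus_id) {
  widths <- diff(edges)
  counts <- matrix(rpois(length(rates) * n_trials, rep(rates * widths, each = n_trials)),
                   nrow = n_trials)
  total <- rowSums(counts)
  if (sum(total) == 0L) {
    return(data.frame(cell_id = character(0), stimulus_id = character(0),
                      trial = integer(0), spike_time_s = numeric(0)))
  }
  trial <- rep(seq_len(n_trials), total)
  seg <- unlist(lapply(seq_len(n_trials), function(tr) rep(seq_along(rates), counts[tr, ])),
                use.names = FALSE)
  times <- edges[seg] + runif(length(seg)) * widths[seg]
  o <- order(trial, times)
  data.frame(cell_id = cell_id, stimulus_id = stimulus_id,
             trial = trial[o], spike_time_s = times[o])
}

#' Simulate a retinal population with a dorsal-ventral gradient
#'
#' Places `n_cells` receptive-field centres uniformly over a rectangle of
#' retina and draws an archetype for each cell. The probability of the
#' ventrally enriched archetypes (UV-selective and the nonlinear ones)
#' follows a logistic gradient along the dorsal-ventral (y) axis: with
#' positive slope they concentrate on the ventral side (y < midpoint); slope
#' 0 makes archetypes independent of position.
#'
#' @param n_cells population size.
#' @param retina_extent width and height of the sampled rectangle in
#'   micrometers, centred on the origin.
#' @param gradient_slope logistic slope per millimetre of the
#'   ventral-enrichment gradient (default 4; 0 disables the gradient).
#' @param gradient_midpoint y position (um) of the gradient midpoint.
#' @param archetype_weights named base mixture weights over the eight
#'   archetypes (normalised internally).
#' @param seed optional integer seed.
#' @return list with `cells` (list of [model_cell()]) and `truth`
#'   (data.frame: `cell_id`, `archetype`, `x_um`, `y_um`, plus the expected
#'   classification columns `true_polarity`, `true_linearity`,
#'   `true_special`).
#' @export
simulate_population <- function(n_cells = 200,
                                retina_extent = c(3000, 3000),
                                gradient_slope = 4,
                                gradient_midpoint = 0,
                                archetype_weights = NULL,
                                seed = NULL) {
  weights <- archetype_weights %||% c(
    "linear-On" = 0.17, "linear-Off" = 0.17, "linear-OnOff" = 0.10,
    "nonlinear-Off" = 0.14, "nonlinear-On" = 0.10, "nonlinear-OnOff" = 0.14,
    "UV-selective" = 0.09, "color-opponent" = 0.09)
  stopifnot(all(names(weights) %in% cell_archetypes()), all(weights >= 0))
  ventral_set <- c("UV-selective", "nonlinear-Off", "nonlinear-On", "nonlinear-OnOff")
  with_seed(seed, {
    x <- runif(n_cells, -retina_extent[1] / 2, retina_extent[1] / 2)
    y <- runif(n_cells, -retina_extent[2] / 2, retina_extent[2] / 2)
    # ventral = negative y; enrichment factor per mm below the midpoint
    g <- plogis(-gradient_slope * (y - gradient_midpoint) / 1000)
    archetype <- character(n_cells)
    for (i in seq_len(n_cells)) {
      w <- weights
      w[names(w) %in% ventral_set] <- w[names(w) %in% ventral_set] * g[i]
      w[!(names(w) %in% ventral_set)] <- w[!(names(w) %in% ventral_set)] * (1 - g[i])
      archetype[i] <- sample(names(w), 1L, prob = w / sum(w))
    }
    cells <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      a <- archetype[i]
      baseline <- switch(a,
        "nonlinear-On" = runif(1, 8, 12),
        "UV-selective" = runif(1, 0.2, 0.8),
        "color-opponent" = runif(1, 4, 7),
        runif(1, 2, 4))
      gain <- switch(a, "UV-selective" = runif(1, 140, 170), runif(1, 100, 140))
      asym <- runif(1, 0.55, 0.85)
      if (runif(1) < 0.5) asym <- 1 / asym
      cells[[i]] <- model_cell(
        a,
        onoff_asymmetry = asym,
        w_green = if (a == "UV-selective") 0 else runif(1, 0.85, 1.15),
        w_uv = runif(1, 0.85, 1.15) * if (a == "color-opponent") -1 else 1,
        baseline_rate = baseline, gain = gain,
        rf_center = c(x[i], y[i]), rf_sigma = runif(1, 45, 80),
        spatial_nonlinearity = a %in% c("nonlinear-Off", "nonlinear-OnOff"),
        cell_id = sprintf("cell_%03d", i))
    }
    expected <- expected_classification(archetype)
    truth <- data.frame(cell_id = vapply(cells, `[[`, "", "cell_id"),
                        archetype = archetype, x_um = x, y_um = y,
                        true_polarity = expected$polarity,
                        true_linearity = expected$linearity,
                        true_special = expected$special)
    list(cells = cells, truth = truth)
  })
}

#' Expected classification labels for simulator archetypes
#'
#' Maps ground-truth archetypes onto the (polarity, linearity, special)
#' labels that the step-stimulus classifier should recover.
#'
#' @param archetype character vector of archetype names.
#' @return data.frame with columns `polarity`, `linearity`, `special`.
#' @export
expected_classification <- function(archetype) {
  polarity <- c("linear-On" = "On", "linear-Off" = "Off",
                "linear-OnOff" = "On-Off", "nonlinear-Off" = "Off",
                "nonlinear-On" = "On", "nonlinear-OnOff" = "On-Off",
                "UV-selective" = NA, "color-opponent" = NA)[archetype]
  linearity <- ifelse(grepl("^nonlinear", archetype), "nonlinear",
                      ifelse(grepl("^linear", archetype), "linear", NA))
  special <- ifelse(archetype == "UV-selective", "UV-selective",
                    ifelse(archetype == "color-opponent", "color-opponent", "none"))
  data.frame(polarity = unname(polarity), linearity = linearity,
             special = special)
}

#' Simulate Poisson responses to a drifting or reversing grating
#'
#' The firing rate is a rectified sinusoid of the cell's drive at the
#' stimulus temporal frequency. For chromatic drifting gratings with the two
#' colours in spatial anti-phase, the effective amplitude is
#' `w_green * green_amp - w_uv * uv_amp`, attenuated by the receptive field's
#' Gaussian modulation transfer factor at the grating's spatial frequency.
#' For reversing gratings the amplitude is additionally phase dependent
#' (`cos(phase)`), and a spatially nonlinear cell adds a full-wave-rectified
#' subunit component (insensitive to spatial phase and period) whenever the
#' spatial period is finer than the receptive-field diameter, producing
#' frequency doubling.
#'
#' @param cell a [model_cell()].
#' @param spec one row of [chromatic_grating_set()] or
#'   [reversing_grating_set()].
#' @param n_periods number of temporal periods to simulate (the analysis
#'   conventionally discards the first).
#' @param seed optional integer seed.
#' @param dt simulation resolution in seconds (default 0.002).
#' @return trial raster data.frame (`cell_id`, `stimulus_id`, `trial` = 1,
#'   `spike_time_s` in `[0, n_periods * T)`), with attributes `period_s` and
#'   `n_periods`.
#' @export
simulate_grating_responses <- function(cell, spec, n_periods = 30, seed = NULL,
                                       dt = 0.002) {
  stopifnot(inherits(cell, "model_cell"), n_periods >= 1)
  if (identical(spec$kind, "chromatic-drift")) {
    period <- spec$temporal_period_s
    lambda <- spec$spatial_period_um
    amp <- (cell$w_green * spec$green_amp - cell$w_uv * spec$uv_amp) *
      rf_mtf(cell$rf_sigma, lambda)
    sub_amp <- 0
    id <- sprintf("grating:%02d", spec$stimulus_index)
  } else {
    period <- 2 * spec$reversal_period_s
    lambda <- spec$spatial_period_um
    amp <- spec$contrast * rf_mtf(cell$rf_sigma, lambda) *
      cospi(spec$phase_deg / 180)
    fine <- is.finite(lambda) && lambda < 3 * cell$rf_sigma
    sub_amp <- if (cell$spatial_nonlinearity && fine) spec$contrast else 0
    id <- sprintf("reversing:%s:%03d", format(spec$spatial_period_um),
                  round(spec$phase_deg))
  }
  tt <- seq(0, n_periods * period - dt, by = dt)
  s <- sin(2 * pi * tt / period)
  rate <- pmax(cell$baseline_rate +
                 cell$gain * (rectify(amp * s) +
                                cell$subunit_weight * sub_amp * abs(s)), 0)
  times <- with_seed(seed, {
    counts <- rpois(length(tt), rate * dt)
    sort(rep(tt, counts) + runif(sum(counts)) * dt)
  })
  structure(data.frame(cell_id = cell$cell_id, stimulus_id = id,
                       trial = 1L, spike_time_s = times),
            period_s = period, n_periods = n_periods)
}

# Gaussian receptive-field modulation transfer factor at spatial period
# lambda (um): attenuation of a sinusoid of that period by a Gaussian of
# width rf_sigma. Full-field (lambda = Inf) passes unattenuated.
rf_mtf <- function(rf_sigma, lambda) {
  if (!is.finite(lambda)) return(1)
  exp(-2 * (pi * rf_sigma / lambda)^2)
}

#' Simulate Poisson spikes of a linear-nonlinear cell under white noise
#'
#' Filters a binary white-noise frame sequence with a separable
#' Gaussian-spatial, biphasic-temporal receptive field and draws Poisson
#' spike counts per frame from the rectified filtered signal. Used for
#' spike-triggered-average recovery.
#'
#' @param frames array from [white_noise_frames()].
#' @param spatial matrix of spatial filter weights (same rows/cols as frames).
#' @param temporal numeric vector of temporal weights, most recent lag first.
#' @param gain rate gain in Hz per unit filtered signal.
#' @param baseline_rate baseline rate in Hz.
#' @param seed optional integer seed.
#' @return integer vector of spike counts per frame.
#' @export
simulate_whitenoise_counts <- function(frames, spatial, temporal,
                                       gain = 50, baseline_rate = 1,
                                       seed = NULL) {
  d <- dim(frames)
  stopifnot(identical(dim(spatial), d[1:2]))
  mean_level <- attr(frames, "mean_level") %||% mean(frames)
  fm <- matrix(frames - mean_level, d[1] * d[2], d[3])
  sig <- drop(crossprod(matrix(spatial, ncol = 1), fm))
  n_lags <- length(temporal)
  # temporal filtering: signal at frame t = sum_l temporal[l] * sig[t - l + 1]
  filt <- stats::filter(sig, temporal, method = "convolution", sides = 1)
  filt[is.na(filt)] <- 0
  dt <- 1 / (attr(frames, "update_rate_hz") %||% 30)
  rate <- pmax(baseline_rate + gain * rectify(filt), 0)
  with_seed(seed, rpois(d[3], rate * dt))
}
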