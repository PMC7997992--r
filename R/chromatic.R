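#' Peristimulus time histogram
#'
#' Bins spike times relative to stimulus onset and normalises by trial count
#' and bin width, yielding a trial-averaged firing rate per bin. Empty bins
#' are zero.
#'
#' @param spike_times numeric vector of spike times in seconds relative to
#'   onset (pooled over trials).
#' @param n_trials number of trials the spikes were pooled over (must be
#'   >= 1, including trials without spikes).
#' @param bin_width bin size in seconds (default 0.010).
#' @param window time window `c(from, to)` in seconds.
#' @return A `psth` list with `edges` (bin edges), `mid` (bin centres) and
#'   `rate` (Hz).
#' @export
compute_psth <- function(spike_times, n_trials, bin_width = 0.010,
                         window = c(-0.5, 0.5)) {
  if (n_trials < 1) stop("PSTH needs at least one trial")
  edges <- seq(window[1], window[2], by = bin_width)
  if (max(edges) < window[2] - 1e-12) edges <- c(edges, window[2])
  keep <- spike_times >= window[1] & spike_times < max(edges)
  counts <- if (any(keep)) {
    tabulate(findInterval(spike_times[keep], edges,
                          rightmost.closed = FALSE, left.open = FALSE),
             nbins = length(edges) - 1L)
  } else {
    integer(length(edges) - 1L)
  }
  structure(list(edges = edges, mid = (edges[-1] + edges[-length(edges)]) / 2,
                 rate = counts / (n_trials * diff(edges)),
                 n_trials = n_trials, bin_width = bin_width),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins of %g ms over [%g, %g] s, %d trials, peak %.1f Hz\n",
              length(x$rate), 1000 * x$bin_width, min(x$edges), max(x$edges),
              x$n_trials, max(x$rate)))
  invisible(x)
}

#' Baseline-subtracted response to one contrast step
#'
#' The response measure for chromatic-integration curves: mean firing rate in
#' the 50-250 ms window after stimulus onset minus the rate in the 200 ms
#' preceding onset, averaged over trials. May be negative (suppression below
#' baseline).
#'
#' @param raster data.frame with columns `trial` and `spike_time_s` for a
#'   single cell and stimulus.
#' @param n_trials number of trials (including silent ones).
#' @param response_window evoked window in seconds (default `c(0.05, 0.25)`).
#' @param baseline_window baseline window (default `c(-0.2, 0)`).
#' @param per_trial if `TRUE` return the per-trial responses instead of their
#'   mean.
#' @return scalar R in Hz, or a numeric vector of per-trial values.
#' @export
baseline_subtracted_response <- function(raster, n_trials,
                                         response_window = c(0.05, 0.25),
                                         baseline_window = c(-0.2, 0),
                                         per_trial = FALSE) {
  if (n_trials < 1) stop("need at least one trial")
  w <- attr(raster, "window")
  if (!is.null(w) && (w[1] > baseline_window[1] || w[2] < response_window[2])) {
    stop("raster window does not cover the baseline and response windows")
  }
  t <- raster$spike_time_s
  rw <- diff(response_window)
  bw <- diff(baseline_window)
  in_resp <- t >= response_window[1] & t < response_window[2]
  in_base <- t >= baseline_window[1] & t < baseline_window[2]
  r_cnt <- tabulate(raster$trial[in_resp], nbins = n_trials)
  b_cnt <- tabulate(raster$trial[in_base], nbins = n_trials)
  vals <- r_cnt / rw - b_cnt / bw
  if (per_trial) vals else mean(vals)
}

#' Chromatic-integration curves of one cell
#'
#' Computes the baseline-subtracted response R for all 22 contrast
#' combinations and aligns them as two 11-point curves over the stimulus
#' index, so that index i of the green-On-UV-Off curve is the exact contrast
#' negation of index i of the green-Off-UV-On curve. Dispersion is the
#' standard error of the per-trial responses (n - 1 denominator).
#'
#' @param raster trial raster of one cell (columns `stimulus_id`, `trial`,
#'   `spike_time_s`); attribute or argument `n_trials` gives trials per
#'   stimulus.
#' @param set the [chromatic_integration_set()] the raster was recorded with.
#' @param n_trials trials per combination; defaults to the raster attribute.
#' @return A `chromatic_integration_curves` list: `index`, `r_onoff`,
#'   `r_offon` (Hz), `sem_onoff`, `sem_offon`, `responses` (named over all 22
#'   ids), `max_abs_response`, `n_trials`, plus the ladder geometry
#'   (`max_contrast`, `step`).
#' @export
integration_curves <- function(raster, set, n_trials = attr(raster, "n_trials")) {
  if (is.null(n_trials)) stop("n_trials not given and not an attribute of the raster")
  alien <- setdiff(unique(raster$stimulus_id), set$stimulus_id)
  if (length(alien)) {
    stop("raster contains stimulus ids not in the set: ",
         paste(utils::head(alien, 3), collapse = ", "))
  }
  # stimuli with zero spikes are legitimate silent responses (R = 0 - baseline)
  split_r <- split(raster[, c("trial", "spike_time_s")],
                   factor(raster$stimulus_id, levels = set$stimulus_id))
  per_trial <- lapply(split_r, baseline_subtracted_response,
                      n_trials = n_trials, per_trial = TRUE)
  means <- vapply(per_trial, mean, 0)
  sems <- vapply(per_trial, function(v) sd(v) / sqrt(length(v)), 0)
  on_ids <- set$stimulus_id[set$set_label == "green-On-UV-Off"]
  off_ids <- set$stimulus_id[set$set_label == "green-Off-UV-On"]
  on_idx <- set$stimulus_index[match(on_ids, set$stimulus_id)]
  off_idx <- set$stimulus_index[match(off_ids, set$stimulus_id)]
  structure(list(
    index = sort(on_idx),
    r_onoff = means[on_ids][order(on_idx)],
    r_offon = means[off_ids][order(off_idx)],
    sem_onoff = sems[on_ids][order(on_idx)],
    sem_offon = sems[off_ids][order(off_idx)],
    responses = means,
    max_abs_response = max(abs(means)),
    n_trials = n_trials,
    max_contrast = attr(set, "max_contrast") %||% 0.20,
    step = attr(set, "step") %||% 0.02
  ), class = "chromatic_integration_curves")
}

#' @export
print.chromatic_integration_curves <- function(x, ...) {
  cat(sprintf("Chromatic-integration curves (%d points per set, %d trials)\n",
              length(x$index), x$n_trials))
  df <- data.frame(index = x$index,
                   green_on_uv_off = round(x$r_onoff, 2),
                   green_off_uv_on = round(x$r_offon, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Construct curves directly from response values
#'
#' Convenience constructor when the two 11-point response vectors are already
#' available (analytical tests, external data).
#'
#' @param r_onoff,r_offon numeric response vectors of equal length (Hz),
#'   aligned by stimulus index.
#' @param max_contrast,step ladder geometry.
#' @return A `chromatic_integration_curves` object.
#' @export
curves_from_responses <- function(r_onoff, r_offon,
                                  max_contrast = 0.20, step = 0.02) {
  stopifnot(length(r_onoff) == length(r_offon), length(r_onoff) >= 2)
  responses <- c(r_onoff, r_offon)
  structure(list(index = seq_along(r_onoff),
                 r_onoff = r_onoff, r_offon = r_offon,
                 sem_onoff = rep(NA_real_, length(r_onoff)),
                 sem_offon = rep(NA_real_, length(r_onoff)),
                 responses = responses,
                 max_abs_response = max(abs(responses)),
                 n_trials = NA_integer_,
                 max_contrast = max_contrast, step = step),
            class = "chromatic_integration_curves")
}

#' Find the balance-point crossing of the two chromatic-integration curves
#'
#' A crossing is bracketed by two neighbouring stimulus indices where one
#' curve is strictly higher at one index and lower or equal at the other.
#' For each bracket a conservative lower bound on the response at the
#' crossing assumes only that both curves run monotonically between the
#' bracketing points: per curve, take the bracketing value closer to zero
#' (zero if the curve's two values straddle zero), then take the
#' farther-from-zero of the two curves' values, keeping its sign. Among
#' multiple crossings, the one whose lower-bound activity is closest to zero
#' is selected (ties broken by proximity of the bracket to the ladder
#' midpoint, then by lower index). Curves that touch (equal values at one
#' index, strict order at the neighbour) count as crossings.
#'
#' @param curves a `chromatic_integration_curves` object.
#' @return A `crossing_point` list: `exists`, `bracket` = `c(i, i + 1)`,
#'   `lower_bound` (signed Hz), `t` (interpolated position of the curve
#'   intersection within the bracket, in `[0, 1]`), `contrasts` (absolute
#'   `c(green, uv)` at the interpolated crossing).
#' @export
find_crossing <- function(curves) {
  c1 <- curves$r_onoff
  c2 <- curves$r_offon
  n <- length(c1)
  d <- c1 - c2
  found <- list()
  for (i in seq_len(n - 1L)) {
    a <- d[i]; b <- d[i + 1L]
    is_cross <- (a > 0 && b <= 0) || (a < 0 && b >= 0) ||
      (a == 0 && b != 0) || (b == 0 && a != 0)
    if (!is_cross) next
    lb <- crossing_lower_bound(c1[i], c1[i + 1L], c2[i], c2[i + 1L])
    found[[length(found) + 1L]] <- list(i = i, lb = lb)
  }
  if (length(found) == 0L) {
    return(structure(list(exists = FALSE, bracket = NULL,
                          lower_bound = NA_real_, t = NA_real_,
                          contrasts = c(green = NA_real_, uv = NA_real_)),
                     class = "crossing_point"))
  }
  lbs <- vapply(found, function(f) abs(f$lb), 0)
  mid <- (1 + n) / 2
  dist_mid <- vapply(found, function(f) abs(f$i + 0.5 - mid), 0)
  ord <- order(lbs, dist_mid, vapply(found, `[[`, 0, "i"))
  best <- found[[ord[1L]]]
  i <- best$i
  denom <- (c1[i + 1L] - c1[i]) - (c2[i + 1L] - c2[i])
  t <- if (abs(denom) < .Machine$double.eps) 0.5 else (c2[i] - c1[i]) / denom
  t <- min(max(t, 0), 1)
  x <- i + t # interpolated ladder position, 1..n
  c_green <- curves$max_contrast - curves$step * (x - 1)
  c_uv <- curves$step * (x - 1)
  structure(list(exists = TRUE, bracket = c(i, i + 1L),
                 lower_bound = best$lb, t = t,
                 contrasts = c(green = abs(c_green), uv = abs(c_uv))),
            class = "crossing_point")
}

# Signed conservative bound: distance from zero to the interval
# intersection of the two curves' bracketing values, carrying the sign.
crossing_lower_bound <- function(a1, b1, a2, b2) {
  near_zero <- function(a, b) {
    if (sign(a) * sign(b) < 0) 0 else if (abs(a) <= abs(b)) a else b
  }
  v1 <- near_zero(a1, b1)
  v2 <- near_zero(a2, b2)
  if (abs(v1) >= abs(v2)) v1 else v2
}

#' @export
print.crossing_point <- function(x, ...) {
  if (!x$exists) {
    cat("No crossing point (UV-selective or colour-opponent pattern)\n")
  } else {
    cat(sprintf("Crossing in bracket [%d, %d], lower-bound activity %.2f Hz\n",
                x$bracket[1], x$bracket[2], x$lower_bound))
    cat(sprintf("  interpolated contrasts: green %.3f, UV %.3f\n",
                x$contrasts["green"], x$contrasts["uv"]))
  }
  invisible(x)
}

#' Chromatic nonlinearity index
#'
#' The conservative lower bound on the response at the balance point,
#' normalised by the maximum absolute response over all 22 stimuli. Positive
#' values mean elevated activity at the balance point (nonlinear Off/On-Off
#' pattern), negative values suppression below baseline (nonlinear On
#' pattern); magnitudes below the conventional 0.1 threshold are taken as
#' linear.
#'
#' @param curves a `chromatic_integration_curves` object.
#' @param crossing optional precomputed [find_crossing()] result.
#' @param normalizer `"abs"` (default) normalises by the maximum absolute
#'   response over all 22 stimuli, so strong suppressive responses also
#'   count; `"signed"` uses the maximum signed response.
#' @return signed index, or `NA` (with attribute `reason`) when no crossing
#'   exists or the maximum response is zero.
#' @export
chromatic_nonlinearity_index <- function(curves, crossing = find_crossing(curves),
                                         normalizer = c("abs", "signed")) {
  normalizer <- match.arg(normalizer)
  if (!crossing$exists) {
    return(structure(NA_real_, reason = "no crossing"))
  }
  denom <- if (normalizer == "abs") curves$max_abs_response else
    max(curves$responses)
  if (denom <= 0) {
    return(structure(NA_real_, reason = "zero maximum response"))
  }
  unname(crossing$lower_bound / denom)
}

#' Relative UV sensitivity at the balance point
#'
#' From the absolute UV and green contrasts at the linearly interpolated
#' intersection of the two curves, `1 - C_uv / (C_uv + C_green)`. Values near
#' 1 mean high UV sensitivity (little UV contrast suffices to balance the
#' green contrast).
#'
#' @inheritParams chromatic_nonlinearity_index
#' @return value in `[0, 1]`, or `NA` when no crossing exists or both
#'   contrasts are zero.
#' @export
relative_uv_sensitivity <- function(curves, crossing = find_crossing(curves)) {
  if (!crossing$exists) return(structure(NA_real_, reason = "no crossing"))
  cg <- crossing$contrasts[["green"]]
  cu <- crossing$contrasts[["uv"]]
  if (cg + cu == 0) return(structure(NA_real_, reason = "zero contrasts"))
  1 - cu / (cu + cg)
}

#' Balance-point polarity bias
#'
#' Difference between the local slopes of the two curves at the balance
#' point: the slope of each curve is the difference of its two bracketing
#' response values, and the bias is the green-Off-UV-On slope minus the
#' green-On-UV-Off slope. Positive values indicate On-driven responses at the
#' balance point, negative values Off-driven responses.
#'
#' @inheritParams chromatic_nonlinearity_index
#' @return signed bias in Hz, or `NA` when no crossing exists.
#' @export
balance_point_polarity_bias <- function(curves, crossing = find_crossing(curves)) {
  if (!crossing$exists) return(structure(NA_real_, reason = "no crossing"))
  i <- crossing$bracket[1]
  j <- crossing$bracket[2]
  slope_onoff <- curves$r_onoff[j] - curves$r_onoff[i]
  slope_offon <- curves$r_offon[j] - curves$r_offon[i]
  unname(slope_offon - slope_onoff)
}

#' UV-green index from the pure-colour stimuli
#'
#' Normalised difference `(f_green - f_uv) / (f_green + f_uv)` of the peak
#' PSTH rates (10-ms bins, 50-250 ms after onset, maximum over the two
#' contrast signs) for pure green and pure UV stimulation. +1 means a purely
#' green-driven cell, -1 purely UV-driven; values below -0.7 mark
#' UV-selective cells.
#'
#' @param raster trial raster of one cell covering the four pure-colour
#'   stimuli of the chromatic-integration set.
#' @param set the stimulus set.
#' @param n_trials trials per combination.
#' @param peak_window window for the peak rate (default `c(0.05, 0.25)`).
#' @return index in `[-1, 1]`, or `NA` when both peaks are zero.
#' @export
uv_green_index <- function(raster, set, n_trials = attr(raster, "n_trials"),
                           peak_window = c(0.05, 0.25)) {
  pure <- pure_color_ids(set)
  peak <- function(ids) {
    max(vapply(ids, function(id) {
      st <- raster$spike_time_s[raster$stimulus_id == id]
      p <- compute_psth(st, n_trials, window = c(-0.5, 0.5))
      keep <- p$mid >= peak_window[1] & p$mid <= peak_window[2]
      max(p$rate[keep])
    }, 0))
  }
  f_green <- peak(pure$green)
  f_uv <- peak(pure$uv)
  if (f_green + f_uv == 0) return(structure(NA_real_, reason = "no response"))
  (f_green - f_uv) / (f_green + f_uv)
}

# ids of the four pure-colour stimuli: +/- max contrast of each channel
pure_color_ids <- function(set) {
  pure_green <- set$stimulus_id[set$uv == 0]
  pure_uv <- set$stimulus_id[set$green == 0]
  list(green = pure_green, uv = pure_uv,
       green_on = set$stimulus_id[set$uv == 0 & set$green > 0],
       green_off = set$stimulus_id[set$uv == 0 & set$green < 0],
       uv_on = set$stimulus_id[set$green == 0 & set$uv > 0],
       uv_off = set$stimulus_id[set$green == 0 & set$uv < 0])
}

#' On-Off index from the stronger pure colour
#'
#' Selects the pure colour (green or UV) with the larger maximum absolute
#' baseline-subtracted response, then computes
#' `(R_On - R_Off) / (|R_On| + |R_Off|)` from the responses to its +20% and
#' -20% presentations. Cells above +0.6 are On, below -0.6 Off, otherwise
#' On-Off.
#'
#' @inheritParams uv_green_index
#' @return index in `[-1, 1]`, or `NA` when both responses are zero.
#' @export
on_off_index <- function(raster, set, n_trials = attr(raster, "n_trials")) {
  pure <- pure_color_ids(set)
  R <- function(id) {
    sub <- raster[raster$stimulus_id == id, , drop = FALSE]
    baseline_subtracted_response(sub, n_trials)
  }
  r <- vapply(c(pure$green_on, pure$green_off, pure$uv_on, pure$uv_off), R, 0)
  names(r) <- c("green_on", "green_off", "uv_on", "uv_off")
  green_max <- max(abs(r[c("green_on", "green_off")]))
  uv_max <- max(abs(r[c("uv_on", "uv_off")]))
  if (green_max >= uv_max) {
    r_on <- r[["green_on"]]; r_off <- r[["green_off"]]
  } else {
    r_on <- r[["uv_on"]]; r_off <- r[["uv_off"]]
  }
  if (abs(r_on) + abs(r_off) == 0) {
    return(structure(NA_real_, reason = "no response"))
  }
  (r_on - r_off) / (abs(r_on) + abs(r_off))
}

#' Default classification thresholds
#'
#' @return named list of thresholds: `nli` (0.1), `uv_green` (-0.7),
#'   `on_off` (0.6), `dsi` / `osi` (0.3), `selectivity_p` (0.05),
#'   `grating_rate_hz` (5), `rate_floor_hz` (1).
#' @export
default_thresholds <- function() {
  list(nli = 0.1, uv_green = -0.7, on_off = 0.6,
       dsi = 0.3, osi = 0.3, selectivity_p = 0.05,
       grating_rate_hz = 5, rate_floor_hz = 1)
}

#' Classify a cell from its chromatic indices
#'
#' Deterministic decision tree: a UV-green index below the UV threshold marks
#' the cell UV-selective; otherwise, absence of a curve crossing marks it
#' colour-opponent; otherwise polarity follows the On-Off index (On above
#' +0.6, Off below -0.6, On-Off between) and linearity follows the chromatic
#' nonlinearity index (nonlinear when its magnitude reaches 0.1, with the
#' sign recorded). For the special classes the chromatic nonlinearity index
#' is undefined.
#'
#' @param indices named list with elements `nli`, `uv_green`, `on_off`,
#'   `crossing_exists`.
#' @param thresholds threshold list as from [default_thresholds()].
#' @return A `cell_classification` list: `polarity`, `linearity`, `special`,
#'   `nli_sign`, and the input indices.
#' @export
classify_cell <- function(indices, thresholds = default_thresholds()) {
  uv <- indices$uv_green
  special <- "none"
  if (!is.na(uv) && uv < thresholds$uv_green) {
    special <- "UV-selective"
  } else if (!isTRUE(indices$crossing_exists)) {
    special <- "color-opponent"
  }
  polarity <- NA_character_
  oo <- indices$on_off
  if (!is.na(oo)) {
    polarity <- if (oo > thresholds$on_off) "On"
      else if (oo < -thresholds$on_off) "Off" else "On-Off"
  }
  linearity <- NA_character_
  nli_sign <- NA_character_
  if (special == "none") {
    nli <- indices$nli
    if (!is.na(nli)) {
      linearity <- if (abs(nli) >= thresholds$nli) "nonlinear" else "linear"
      nli_sign <- if (nli > 0) "positive" else if (nli < 0) "negative" else "zero"
    }
  }
  structure(list(polarity = polarity, linearity = linearity, special = special,
                 nli_sign = nli_sign, indices = indices),
            class = "cell_classification")
}

#' @export
print.cell_classification <- function(x, ...) {
  lab <- if (x$special != "none") x$special else {
    paste(x$linearity, x$polarity)
  }
  cat(sprintf("Cell classification: %s\n", lab))
  idx <- x$indices
  cat(sprintf("  NLI %.3f | UV-green %.3f | On-Off %.3f | crossing: %s\n",
              idx$nli, idx$uv_green, idx$on_off,
              if (isTRUE(idx$crossing_exists)) "yes" else "no"))
  invisible(x)
}

#' Full chromatic summary of one cell's step responses
#'
#' Computes curves, crossing point and every step-stimulus index for one
#' cell, and classifies it.
#'
#' @param raster trial raster of one cell.
#' @param set the [chromatic_integration_set()] used.
#' @param n_trials trials per combination.
#' @param thresholds classification thresholds.
#' @return one-row data.frame: `cell_id`, `nli`, `uv_green`, `on_off`,
#'   `polarity_bias`, `relative_uv_sensitivity`, `crossing_exists`,
#'   `max_abs_response`, `polarity`, `linearity`, `special`.
#' @export
chromatic_cell_summary <- function(raster, set,
                                   n_trials = attr(raster, "n_trials"),
                                   thresholds = default_thresholds()) {
  curves <- integration_curves(raster, set, n_trials)
  crossing <- find_crossing(curves)
  idx <- list(
    nli = as.numeric(chromatic_nonlinearity_index(curves, crossing)),
    uv_green = as.numeric(uv_green_index(raster, set, n_trials)),
    on_off = as.numeric(on_off_index(raster, set, n_trials)),
    crossing_exists = crossing$exists
  )
  cls <- classify_cell(idx, thresholds)
  data.frame(
    cell_id = raster$cell_id[1] %||% NA_character_,
    nli = idx$nli,
    uv_green = idx$uv_green,
    on_off = idx$on_off,
    polarity_bias = as.numeric(balance_point_polarity_bias(curves, crossing)),
    relative_uv_sensitivity = as.numeric(relative_uv_sensitivity(curves, crossing)),
    crossing_exists = crossing$exists,
    max_abs_response = curves$max_abs_response,
    polarity = cls$polarity,
    linearity = cls$linearity,
    special = cls$special,
    stringsAsFactors = FALSE
  )
}

#' Per-site curves and site selection for the local-spot stimulus
#'
#' For locally restricted stimulation, responses are collected per grid
#' vertex. The analysis site is the vertex maximising the summed absolute
#' responses to the four pure-colour stimuli; the cell is excluded when the
#' distance between that site and the receptive-field centre exceeds the
#' receptive-field radius.
#'
#' @param responses_by_vertex data.frame with columns `vertex`,
#'   `stimulus_id`, `R` (baseline-subtracted response in Hz).
#' @param set the stimulus set.
#' @param vertex_positions data.frame `vertex`, `x_um`, `y_um`.
#' @param rf_center numeric `(x, y)` receptive-field centre in um.
#' @param rf_radius receptive-field radius in um.
#' @return list: `site` (chosen vertex id), `excluded` (logical),
#'   `distance_um`, `curves` (`chromatic_integration_curves` at the chosen
#'   site), `pure_sum` (named vector over vertices).
#' @export
select_local_site <- function(responses_by_vertex, set, vertex_positions,
                              rf_center, rf_radius) {
  pure <- pure_color_ids(set)
  pure_ids <- c(pure$green_on, pure$green_off, pure$uv_on, pure$uv_off)
  sub <- responses_by_vertex[responses_by_vertex$stimulus_id %in% pure_ids, ]
  if (nrow(sub) == 0L) stop("no responsive site: no pure-colour responses present")
  sums <- tapply(abs(sub$R), sub$vertex, sum)
  site <- as.integer(names(sums)[which.max(sums)])
  pos <- vertex_positions[vertex_positions$vertex == site, ]
  dist <- sqrt((pos$x_um - rf_center[1])^2 + (pos$y_um - rf_center[2])^2)
  site_resp <- responses_by_vertex[responses_by_vertex$vertex == site, ]
  r <- setNames(site_resp$R, site_resp$stimulus_id)[set$stimulus_id]
  r[is.na(r)] <- 0
  on_ids <- set$stimulus_id[set$set_label == "green-On-UV-Off"]
  off_ids <- set$stimulus_id[set$set_label == "green-Off-UV-On"]
  curves <- curves_from_responses(unname(r[on_ids]), unname(r[off_ids]),
                                  attr(set, "max_contrast") %||% 0.2,
                                  attr(set, "step") %||% 0.02)
  list(site = site, excluded = dist > rf_radius, distance_um = unname(dist),
       curves = curves, pure_sum = sums)
}
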