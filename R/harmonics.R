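#' Fold a spike train into a single-period PSTH
#'
#' Wraps spike times modulo the stimulus temporal period and bins them,
#' treating each period as one trial. The first period after a condition
#' switch is conventionally excluded.
#'
#' @param spike_times spike times in seconds from condition onset.
#' @param period_s temporal period in seconds.
#' @param n_periods number of periods covered by the spike train.
#' @param bin_width bin size in seconds (default 0.010; must divide the
#'   period).
#' @param skip_first drop the first period (default `TRUE`).
#' @return A `psth` over `[0, period_s)`.
#' @export
psth_over_period <- function(spike_times, period_s, n_periods,
                             bin_width = 0.010, skip_first = TRUE) {
  k <- period_s / bin_width
  if (abs(k - round(k)) > 1e-9) stop("bin width must divide the period")
  first <- if (skip_first) period_s else 0
  n_used <- n_periods - as.integer(skip_first)
  if (n_used < 1) stop("need at least one analysable period")
  st <- spike_times[spike_times >= first & spike_times < n_periods * period_s]
  folded <- (st - first) %% period_s
  compute_psth(folded, n_trials = n_used, bin_width = bin_width,
               window = c(0, period_s))
}

#' First- and second-harmonic amplitudes of a periodic response
#'
#' Fourier amplitudes of a PSTH covering exactly one temporal period, in the
#' single-sided sinusoid convention: a rate `m + a * sin(2 pi f t)` yields
#' `F1 = a`. F2 is the amplitude at twice the stimulus frequency.
#'
#' @param psth a `psth` over one period, or a plain numeric rate vector.
#' @param period_s temporal period in seconds (taken from the PSTH window if
#'   omitted).
#' @return A `harmonic_pair` list: `f1`, `f2` (Hz amplitude), `base_freq_hz`,
#'   `mean_rate`, `max_rate`.
#' @export
harmonic_amplitudes <- function(psth, period_s = NULL) {
  if (inherits(psth, "psth")) {
    rate <- psth$rate
    span <- max(psth$edges) - min(psth$edges)
    if (is.null(period_s)) period_s <- span
    if (abs(span - period_s) > 1e-9) {
      stop("PSTH does not cover exactly one temporal period")
    }
  } else {
    rate <- as.numeric(psth)
    if (is.null(period_s)) stop("period_s required for a plain rate vector")
  }
  n <- length(rate)
  if (n < 5) stop("too few bins to resolve the second harmonic")
  x <- fft(rate) / n
  structure(list(f1 = 2 * Mod(x[2]), f2 = 2 * Mod(x[3]),
                 base_freq_hz = 1 / period_s,
                 mean_rate = Re(x[1]), max_rate = max(rate)),
            class = "harmonic_pair")
}

#' @export
print.harmonic_pair <- function(x, ...) {
  cat(sprintf("Harmonics at %.3g Hz: F1 = %.2f Hz, F2 = %.2f Hz (F2/F1 = %.2f)\n",
              x$base_freq_hz, x$f1, x$f2,
              if (x$f1 > 0) x$f2 / x$f1 else NA_real_))
  invisible(x)
}

#' Grating nonlinearity index over the chromatic contrast ladder
#'
#' F2/F1 evaluated at the contrast combination with the smallest first
#' harmonic (the combination nearest the balance point). Cells whose maximum
#' PSTH rate stays below 5 Hz across all combinations are excluded as too
#' weakly responsive for reliable harmonics. Values above 1 flag frequency
#' doubling.
#'
#' @param harmonics list of `harmonic_pair`s, one per contrast combination,
#'   ordered by stimulus index.
#' @param rate_threshold_hz exclusion threshold on the maximum PSTH rate
#'   (default 5).
#' @return index (ratio), or `NA` with attribute `reason = "excluded"` when
#'   every combination is below threshold. Ties at the minimal F1 resolve to
#'   the lowest stimulus index.
#' @export
grating_nonlinearity_index <- function(harmonics, rate_threshold_hz = 5) {
  max_rates <- vapply(harmonics, `[[`, 0, "max_rate")
  if (max(max_rates) < rate_threshold_hz) {
    return(structure(NA_real_, reason = "excluded"))
  }
  f1 <- vapply(harmonics, `[[`, 0, "f1")
  f2 <- vapply(harmonics, `[[`, 0, "f2")
  i <- which.min(f1) # which.min takes the first (lowest index) on ties
  if (f1[i] == 0) {
    return(if (f2[i] == 0) 0 else Inf)
  }
  f2[i] / f1[i]
}

#' Spatial nonlinearity index from reversing gratings
#'
#' Maximum second-harmonic amplitude over all grating periods and phases
#' divided by the maximum first-harmonic amplitude over all periods and
#' phases (maxima taken independently). Values above 1 indicate frequency
#' doubling, the signature of nonlinear spatial integration.
#'
#' @param harmonics list of `harmonic_pair`s, one per (period, phase)
#'   condition.
#' @return index, or `NA` when the maximum F1 is zero.
#' @export
spatial_nonlinearity_index <- function(harmonics) {
  f1 <- vapply(harmonics, `[[`, 0, "f1")
  f2 <- vapply(harmonics, `[[`, 0, "f2")
  if (max(f1) == 0) return(structure(NA_real_, reason = "zero F1"))
  max(f2) / max(f1)
}

#' Direction or orientation selectivity index
#'
#' Normalised vector sum of the direction-tuned mean rates:
#' `|sum(R * exp(1i * m * theta))| / sum(R)` with `m = 1` for direction and
#' `m = 2` for orientation.
#'
#' @param rates mean firing rates per direction (Hz).
#' @param directions directions in radians (typically 8 equidistant angles).
#' @param mode `"direction"` or `"orientation"`.
#' @return index in `[0, 1]`, `NA` when all rates are zero.
#' @export
selectivity_index <- function(rates, directions,
                              mode = c("direction", "orientation")) {
  mode <- match.arg(mode)
  stopifnot(length(rates) == length(directions), all(rates >= 0))
  if (sum(rates) == 0) return(structure(NA_real_, reason = "no response"))
  m <- if (mode == "direction") 1 else 2
  Mod(sum(rates * exp(1i * m * directions))) / sum(rates)
}

#' Permutation test for direction or orientation tuning
#'
#' Shuffles the per-repetition spike counts across all angles and repetitions
#' `n_perm` times, recomputes the selectivity index for each shuffle, and
#' reports the percentile of the observed index as a p-value with add-one
#' smoothing, `p = (k + 1) / (n_perm + 1)` where `k` shuffles reach the
#' observed index. Degenerate all-equal counts give p = 1.
#'
#' @param counts matrix of spike counts, repetitions x directions.
#' @param directions directions in radians, one per column.
#' @param mode `"direction"` or `"orientation"`.
#' @param n_perm number of shuffles (default 1000).
#' @param seed optional integer seed.
#' @return list: `index` (observed), `p_value`, `null_indices`.
#' @export
permutation_test <- function(counts, directions,
                             mode = c("direction", "orientation"),
                             n_perm = 1000, seed = NULL) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("permutation test needs at least 2 repetitions")
  stopifnot(ncol(counts) == length(directions))
  obs <- selectivity_index(colMeans(counts), directions, mode)
  if (all(counts == counts[1])) {
    return(list(index = obs, p_value = 1, null_indices = rep(obs, n_perm)))
  }
  m <- if (mode == "direction") 1 else 2
  phase <- exp(1i * m * directions)
  flat <- as.vector(counts)
  n <- length(flat)
  n_reps <- nrow(counts)
  null_idx <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      shuf <- matrix(flat[sample.int(n)], nrow = n_reps)
      mu <- colMeans(shuf)
      s <- sum(mu)
      if (s == 0) 0 else Mod(sum(mu * phase)) / s
    }, 0)
  })
  p <- (sum(null_idx >= obs) + 1) / (n_perm + 1)
  list(index = unname(obs), p_value = p, null_indices = null_idx)
}

#' Direction/orientation selectivity decision
#'
#' A cell is direction selective when its DSI exceeds 0.3 with a permutation
#' p-value below 0.05 and its mean rate over directions is at least 1 Hz;
#' orientation selectivity is decided analogously on cells that are not
#' direction selective.
#'
#' @param counts repetitions x directions spike-count matrix.
#' @param directions directions in radians.
#' @param duration_s presentation duration per direction, to convert counts
#'   to rates for the rate floor.
#' @param thresholds threshold list from [default_thresholds()].
#' @param n_perm,seed passed to [permutation_test()].
#' @return list with `dsi`, `dsi_p`, `osi`, `osi_p`, `mean_rate_hz`,
#'   `direction_selective`, `orientation_selective`.
#' @export
classify_selectivity <- function(counts, directions, duration_s = 1,
                                 thresholds = default_thresholds(),
                                 n_perm = 1000, seed = NULL) {
  mean_rate <- mean(counts) / duration_s
  ds <- permutation_test(counts, directions, "direction", n_perm, seed)
  os <- permutation_test(counts, directions, "orientation", n_perm,
                         if (is.null(seed)) NULL else seed + 1L)
  eligible <- mean_rate >= thresholds$rate_floor_hz
  is_ds <- eligible && !is.na(ds$index) && ds$index > thresholds$dsi &&
    ds$p_value < thresholds$selectivity_p
  is_os <- eligible && !is_ds && !is.na(os$index) &&
    os$index > thresholds$osi && os$p_value < thresholds$selectivity_p
  list(dsi = ds$index, dsi_p = ds$p_value,
       osi = os$index, osi_p = os$p_value,
       mean_rate_hz = mean_rate,
       direction_selective = is_ds, orientation_selective = is_os)
}
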