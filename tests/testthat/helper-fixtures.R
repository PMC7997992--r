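# Shared fixtures built in code.

the_set <- chromatic_integration_set()

# A raster with prescribed spike counts per (stimulus, trial, window).
# counts: named list stimulus_id -> c(baseline = k, response = m) per trial.
raster_from_counts <- function(counts, n_trials, cell_id = "cell") {
  rows <- list()
  for (id in names(counts)) {
    k <- counts[[id]]
    for (tr in seq_len(n_trials)) {
      tb <- if (k[["baseline"]] > 0) {
        seq(-0.19, -0.01, length.out = k[["baseline"]])
      } else numeric(0)
      tr_resp <- if (k[["response"]] > 0) {
        seq(0.06, 0.24, length.out = k[["response"]])
      } else numeric(0)
      tt <- c(tb, tr_resp)
      if (length(tt)) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cell_id, stimulus_id = id, trial = tr, spike_time_s = tt)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), stimulus_id = character(0),
               trial = integer(0), spike_time_s = numeric(0))
  structure(out, n_trials = n_trials)
}

# Deterministic spike train with `n` spikes in one 10-ms bin starting at t0.
spikes_in_bin <- function(n, t0) t0 + (seq_len(n) - 0.5) / n * 0.01

# Independent brute-force oracle for the crossing lower bound: the minimum
# |v| over a fine grid of crossing values v that are reachable by monotone
# curves within the bracket (the intersection of the two curves' value
# intervals), signed by the minimiser.
oracle_lower_bound <- function(a1, b1, a2, b2, n_grid = 2001) {
  lo <- max(min(a1, b1), min(a2, b2))
  hi <- min(max(a1, b1), max(a2, b2))
  stopifnot(lo <= hi + 1e-12)
  v <- seq(lo, hi, length.out = n_grid)
  if (lo <= 0 && hi >= 0) v <- c(v, 0) # the grid always reaches an attained minimum
  v[which.min(abs(v))]
}

# Oracle crossing search: every bracket with a (weak) order change, each
# bracket's bound from oracle_lower_bound, selection by minimal |bound|.
oracle_find_crossing <- function(c1, c2) {
  n <- length(c1)
  best <- NULL
  for (i in seq_len(n - 1)) {
    d1 <- c1[i] - c2[i]; d2 <- c1[i + 1] - c2[i + 1]
    cross <- (d1 > 0 && d2 <= 0) || (d1 < 0 && d2 >= 0) ||
      (d1 == 0 && d2 != 0) || (d2 == 0 && d1 != 0)
    if (!cross) next
    lb <- oracle_lower_bound(c1[i], c1[i + 1], c2[i], c2[i + 1])
    mid_dist <- abs(i + 0.5 - (1 + n) / 2)
    if (is.null(best) || abs(lb) < abs(best$lb) - 1e-12 ||
        (abs(abs(lb) - abs(best$lb)) <= 1e-12 && mid_dist < best$mid_dist)) {
      best <- list(i = i, lb = lb, mid_dist = mid_dist)
    }
  }
  best
}

eight_directions <- seq(0, 2 * pi, length.out = 9)[1:8]
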