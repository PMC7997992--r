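#' One frame of the local chromatic-integration spot stimulus
#'
#' Spot locations for one 500-ms frame are drawn by random sequential
#' selection on a square grid: repeatedly pick a uniformly random vertex that
#' is not yet inside any selected vertex's 5x5 exclusion square (+/-2 vertices
#' in each grid direction, clipped at the borders), select it and mark its 24
#' surrounding vertices ineligible, until every vertex of the grid is covered
#' by some selected vertex's square. On the default 44x24 grid this saturates
#' at around 80-90 selected locations per frame. Each selected vertex is then
#' assigned an independently random contrast combination.
#'
#' @param n_cols,n_rows grid dimensions in vertices (defaults 44 and 24).
#' @param n_combinations number of contrast combinations to assign from
#'   (default 22, the chromatic-integration set).
#' @param pitch_um grid pitch in micrometers, metadata only (default 160; the
#'   spot diameter equals the pitch).
#' @param seed optional integer seed.
#' @return A `spot_frame`: data.frame with columns `vertex` (1-based, column
#'   major), `col`, `row`, `combination`.
#' @export
local_spot_frame <- function(n_cols = 44, n_rows = 24, n_combinations = 22,
                             pitch_um = 160, seed = NULL) {
  stopifnot(n_cols >= 1, n_rows >= 1)
  with_seed(seed, {
    sel <- select_spot_vertices(n_cols, n_rows)
    # independent uniform draw per spot (first element of a fresh shuffle)
    comb <- 1L + floor(runif(length(sel)) * n_combinations)
    structure(data.frame(
      vertex = sel,
      col = ((sel - 1L) %/% n_rows) + 1L,
      row = ((sel - 1L) %% n_rows) + 1L,
      combination = comb
    ), class = c("spot_frame", "data.frame"),
    n_cols = n_cols, n_rows = n_rows, pitch_um = pitch_um,
    frame_duration_s = 0.5)
  })
}

# Random sequential selection to saturation. A vertex is eligible exactly
# while it is uncovered (outside every selected vertex's 5x5 square), so the
# loop stops when coverage is complete.
select_spot_vertices <- function(n_cols, n_rows) {
  eligible <- rep(TRUE, n_cols * n_rows)
  selected <- integer(0)
  repeat {
    open <- which(eligible)
    if (length(open) == 0L) break
    v <- if (length(open) == 1L) open else open[sample.int(length(open), 1L)]
    selected <- c(selected, v)
    r <- ((v - 1L) %% n_rows) + 1L
    cl <- ((v - 1L) %/% n_rows) + 1L
    rr <- max(1L, r - 2L):min(n_rows, r + 2L)
    cc <- max(1L, cl - 2L):min(n_cols, cl + 2L)
    eligible[rep((cc - 1L) * n_rows, each = length(rr)) + rr] <- FALSE
  }
  selected
}

#' Vertices inside a selected spot's exclusion square
#'
#' The 5x5 square centred on a grid vertex, clipped at the borders; in the
#' grid interior this contains the 24 neighbours that become ineligible when
#' the vertex is selected.
#'
#' @param col,row vertex position (1-based).
#' @param n_cols,n_rows grid dimensions.
#' @return data.frame of the neighbouring vertices (`col`, `row`), excluding
#'   the centre vertex itself.
#' @export
spot_exclusion_zone <- function(col, row, n_cols = 44, n_rows = 24) {
  cc <- max(1L, col - 2L):min(n_cols, col + 2L)
  rr <- max(1L, row - 2L):min(n_rows, row + 2L)
  z <- expand.grid(col = cc, row = rr)
  z[!(z$col == col & z$row == row), , drop = FALSE]
}

#' Simulate a run of local-spot frames and its selection statistics
#'
#' Repeats the per-frame random-exclusion selection of [local_spot_frame()]
#' over `n_frames` frames of `frame_duration_s` each and accumulates, per grid
#' location, the number of selections and the intervals between consecutive
#' selections. With 500-ms frames on the 44x24 grid each location is reselected
#' about every 6.4 s, i.e. about 595 times over a 65-minute run.
#'
#' @param n_frames number of frames to simulate.
#' @param n_cols,n_rows grid dimensions.
#' @param frame_duration_s frame duration in seconds (default 0.5).
#' @param seed optional integer seed.
#' @return A `spot_run` list: `counts` (selections per vertex),
#'   `mean_interval_s` (per-vertex mean re-selection interval; `NA` for
#'   vertices selected fewer than twice), `selections_per_frame`, `n_frames`,
#'   `frame_duration_s`, grid dimensions.
#' @export
simulate_spot_run <- function(n_frames, n_cols = 44, n_rows = 24,
                              frame_duration_s = 0.5, seed = NULL) {
  stopifnot(n_frames >= 1)
  n <- n_cols * n_rows
  counts <- integer(n)
  last_frame <- integer(n) # 0 = never selected
  int_sum <- numeric(n)
  int_n <- integer(n)
  per_frame <- integer(n_frames)
  with_seed(seed, {
    for (f in seq_len(n_frames)) {
      sel <- select_spot_vertices(n_cols, n_rows)
      per_frame[f] <- length(sel)
      counts[sel] <- counts[sel] + 1L
      prev <- last_frame[sel]
      seen <- prev > 0L
      if (any(seen)) {
        s <- sel[seen]
        int_sum[s] <- int_sum[s] + (f - prev[seen])
        int_n[s] <- int_n[s] + 1L
      }
      last_frame[sel] <- f
    }
  })
  mean_interval <- ifelse(int_n > 0L, int_sum / int_n * frame_duration_s, NA_real_)
  structure(list(
    counts = counts,
    mean_interval_s = mean_interval,
    selections_per_frame = per_frame,
    n_frames = n_frames, frame_duration_s = frame_duration_s,
    n_cols = n_cols, n_rows = n_rows
  ), class = "spot_run")
}

#' @export
print.spot_run <- function(x, ...) {
  cat(sprintf("Local-spot run: %d frames on a %dx%d grid (%g s frames)\n",
              x$n_frames, x$n_cols, x$n_rows, x$frame_duration_s))
  cat(sprintf("  selections per frame: mean %.1f (range %d-%d)\n",
              mean(x$selections_per_frame),
              min(x$selections_per_frame), max(x$selections_per_frame)))
  cat(sprintf("  selections per location: mean %.1f; mean re-selection interval %.2f s\n",
              mean(x$counts), mean(x$mean_interval_s, na.rm = TRUE)))
  invisible(x)
}
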