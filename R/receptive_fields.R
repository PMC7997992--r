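#' Spike-triggered average under white noise
#'
#' Averages the `n_lags`-frame stimulus history preceding each spike and
#' subtracts the stimulus ensemble mean, yielding the linear receptive-field
#' estimate.
#'
#' @param spike_frames integer frame indices at which spikes occurred (one
#'   entry per spike; repeated indices weight the frame by its spike count).
#' @param frames stimulus array from [white_noise_frames()] (rows x cols x
#'   frames).
#' @param n_lags number of lags (default 20); lag 1 is the spike's own frame.
#' @return numeric array rows x cols x n_lags, the mean-subtracted STA.
#' @export
compute_sta <- function(spike_frames, frames, n_lags = 20) {
  if (length(spike_frames) == 0) stop("cannot compute an STA from zero spikes")
  d <- dim(frames)
  mean_level <- attr(frames, "mean_level") %||% mean(frames)
  fm <- matrix(frames, d[1] * d[2], d[3]) - mean_level
  spike_frames <- spike_frames[spike_frames >= n_lags & spike_frames <= d[3]]
  if (length(spike_frames) == 0) stop("no spikes with a full stimulus history")
  sta <- array(0, dim = c(d[1], d[2], n_lags))
  for (lag in seq_len(n_lags)) {
    idx <- spike_frames - lag + 1L
    w <- tabulate(idx, nbins = d[3])
    sta[, , lag] <- matrix(fm %*% w / length(spike_frames), d[1], d[2])
  }
  sta
}

#' Space-time separation of an STA by singular value decomposition
#'
#' Rank-1 factorisation of the spatiotemporal receptive field into a spatial
#' map and a temporal profile. The sign convention puts the dominant spatial
#' lobe positive, so an Off cell's temporal profile peaks negative.
#'
#' @param sta array rows x cols x lags from [compute_sta()].
#' @return list: `spatial` (rows x cols matrix, unit norm), `temporal`
#'   (length-lags vector, carries the amplitude), `singular_values`,
#'   `separability` (fraction of energy in the first component).
#' @export
decompose_sta <- function(sta) {
  d <- dim(sta)
  m <- matrix(sta, d[1] * d[2], d[3])
  if (all(m == 0)) stop("degenerate all-zero STA")
  s <- svd(m)
  spatial <- matrix(s$u[, 1], d[1], d[2])
  temporal <- s$v[, 1] * s$d[1]
  peak <- which.max(abs(spatial))
  if (spatial[peak] < 0) {
    spatial <- -spatial
    temporal <- -temporal
  }
  list(spatial = spatial, temporal = temporal,
       singular_values = s$d,
       separability = s$d[1]^2 / sum(s$d^2))
}

#' Two-dimensional Gaussian fit of a spatial receptive field
#'
#' Least-squares fit of an elliptical Gaussian to the spatial component of a
#' receptive field, initialised from the map's weighted centroid and second
#' moments. The receptive-field diameter is defined as the diameter of the
#' circle with the same area as the 1.5-sigma contour of the fitted ellipse,
#' `2 * 1.5 * sqrt(sigma_x * sigma_y)`.
#'
#' @param spatial matrix spatial map; the dominant lobe must be positive (as
#'   returned by [decompose_sta()]).
#' @param pixel_size_um side length of one stimulus square in micrometers.
#' @return A `receptive_field` list: `center` (x, y in um), `sigmas`
#'   (`sigma_x >= sigma_y`, um), `angle` (radians, orientation of the major
#'   axis), `diameter` (um), `amplitude`, `converged`.
#' @export
fit_gaussian_rf <- function(spatial, pixel_size_um = 1) {
  nr <- nrow(spatial); nc <- ncol(spatial)
  xs <- (col(spatial) - 0.5) * pixel_size_um
  ys <- (row(spatial) - 0.5) * pixel_size_um
  w <- pmax(spatial, 0)
  if (sum(w) == 0) stop("spatial map has no positive lobe to fit")
  x0 <- sum(w * xs) / sum(w)
  y0 <- sum(w * ys) / sum(w)
  # threshold the moment weights to keep the init local to the main lobe
  w2 <- w * (w > 0.3 * max(w))
  vxx <- sum(w2 * (xs - x0)^2) / sum(w2)
  vyy <- sum(w2 * (ys - y0)^2) / sum(w2)
  vxy <- sum(w2 * (xs - x0) * (ys - y0)) / sum(w2)
  cov0 <- rbind(c(vxx, vxy), c(vxy, vyy))
  # guard against degenerate single-pixel maps
  cov0 <- cov0 + diag(2) * (0.25 * pixel_size_um^2)
  q0 <- solve(cov0)
  df <- data.frame(z = as.vector(spatial), x = as.vector(xs), y = as.vector(ys))
  start <- list(amp = max(spatial), x0 = x0, y0 = y0,
                qa = q0[1, 1], qb = q0[1, 2], qc = q0[2, 2])
  fit <- try(minpack.lm::nlsLM(
    z ~ amp * exp(-0.5 * (qa * (x - x0)^2 + 2 * qb * (x - x0) * (y - y0) +
                            qc * (y - y0)^2)),
    data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  converged <- !inherits(fit, "try-error")
  if (converged) {
    p <- as.list(coef(fit))
    q <- rbind(c(p$qa, p$qb), c(p$qb, p$qc))
    if (any(!is.finite(q)) || det(q) <= 0 || p$qa <= 0) converged <- FALSE
  }
  if (!converged) {
    # fall back to the moment estimate, flagged
    p <- list(amp = max(spatial), x0 = x0, y0 = y0,
              qa = q0[1, 1], qb = q0[1, 2], qc = q0[2, 2])
    q <- rbind(c(p$qa, p$qb), c(p$qb, p$qc))
  }
  e <- eigen(q, symmetric = TRUE)
  sig <- 1 / sqrt(e$values) # descending eigenvalues -> ascending sigmas
  sigma_x <- max(sig); sigma_y <- min(sig)
  major <- e$vectors[, which.min(e$values)]
  angle <- atan2(major[2], major[1]) %% pi
  structure(list(center = c(x = p$x0, y = p$y0),
                 sigmas = c(sigma_x = sigma_x, sigma_y = sigma_y),
                 angle = angle,
                 diameter = 2 * 1.5 * sqrt(sigma_x * sigma_y),
                 amplitude = p$amp, converged = converged),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("Receptive field: centre (%.1f, %.1f) um, sigmas (%.1f, %.1f) um\n",
              x$center[1], x$center[2], x$sigmas[1], x$sigmas[2]))
  cat(sprintf("  orientation %.1f deg, diameter %.1f um (equal-area 1.5-sigma)%s\n",
              x$angle * 180 / pi, x$diameter,
              if (!x$converged) " [fit did not converge; moment estimate]" else ""))
  invisible(x)
}

#' Dorsal-ventral midline from UV-selective cell positions
#'
#' The midline is the line through the centre of mass of all receptive-field
#' centres whose angle maximises the ratio of the mean signed distance of the
#' UV-selective cells to the standard deviation of those distances, found by
#' grid search. The normal's sign is fixed so that UV-selective cells have
#' negative mean signed distance (negative = ventral).
#'
#' @param centers matrix or data.frame of receptive-field centres (n x 2, um).
#' @param uv_selective logical vector marking UV-selective cells; at least 3
#'   are required, otherwise the retina is excluded with an error.
#' @param angle_step_deg grid-search resolution in degrees (default 0.5).
#' @param objective_cells `"uv"` (default) evaluates the objective on the
#'   UV-selective cells only; `"all"` uses every centre (the sign convention
#'   is still anchored to the UV-selective cells).
#' @return A `midline_fit` list: `anchor`, `angle` (line direction in
#'   `[0, pi)`), `normal`, `objective` (`|mean| / sd` of UV distances),
#'   `signed_distances` (all cells, negative = ventral).
#' @export
estimate_midline <- function(centers, uv_selective, angle_step_deg = 0.5,
                             objective_cells = c("uv", "all")) {
  objective_cells <- match.arg(objective_cells)
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2, nrow(centers) == length(uv_selective))
  if (sum(uv_selective) < 3) {
    stop("retina excluded: fewer than 3 UV-selective cells")
  }
  anchor <- colMeans(centers)
  rel <- sweep(centers, 2, anchor)
  rel_uv <- if (objective_cells == "uv") {
    rel[uv_selective, , drop = FALSE]
  } else rel
  angles <- seq(0, pi, by = angle_step_deg * pi / 180)
  angles <- angles[angles < pi]
  best <- -Inf; best_angle <- 0
  for (th in angles) {
    nrm <- c(-sin(th), cos(th))
    d <- drop(rel_uv %*% nrm)
    s <- sd(d)
    if (s == 0) next
    obj <- abs(mean(d)) / s
    if (obj > best) {
      best <- obj
      best_angle <- th
    }
  }
  nrm <- c(-sin(best_angle), cos(best_angle))
  d_uv <- drop(rel[uv_selective, , drop = FALSE] %*% nrm)
  if (mean(d_uv) > 0) nrm <- -nrm
  structure(list(anchor = anchor, angle = best_angle, normal = nrm,
                 objective = best,
                 signed_distances = drop(rel %*% nrm)),
            class = "midline_fit")
}

#' @export
print.midline_fit <- function(x, ...) {
  cat(sprintf("Dorsal-ventral midline: angle %.1f deg through (%.0f, %.0f) um\n",
              x$angle * 180 / pi, x$anchor[1], x$anchor[2]))
  cat(sprintf("  objective |mean|/sd = %.2f; %d cells, %d on the ventral side\n",
              x$objective, length(x$signed_distances),
              sum(x$signed_distances < 0)))
  invisible(x)
}
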