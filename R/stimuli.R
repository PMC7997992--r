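#' Opsin transfer matrix between light sources and opsin activations
#'
#' The 2x2 transfer matrix maps contrasts of the two light sources (UV LED,
#' green LED) to contrasts of the two opsin channels (S-opsin; M-opsin, whose
#' row also stands in for rods given their near-identical spectral
#' sensitivity). In absolute form entries are isomerisation rates per unit
#' source intensity and are converted to contrast form using the background
#' intensities of the two sources: the contrast seen by opsin o for source
#' contrasts `c` is `(A[o, ] * I_b) %*% c / sum(A[o, ] * I_b)`.
#'
#' @param entries 2x2 non-negative matrix; rows = opsins (S, M), columns =
#'   sources (UV, green).
#' @param form `"contrast"` (canonical) or `"absolute"`.
#' @param backgrounds background intensities of the two sources, required for
#'   `form = "absolute"`.
#' @param det_tol lower bound on `|det|` of the contrast-form matrix below
#'   which the calibration is rejected as singular.
#' @return An object of class `opsin_transfer_matrix` holding the
#'   contrast-form matrix.
#' @examples
#' A <- opsin_transfer_matrix(rbind(c(1, 0.1), c(0.4, 1)))
#' opsin_isolating_contrast(c(0.2, 0), A)
#' @export
opsin_transfer_matrix <- function(entries, form = c("contrast", "absolute"),
                                  backgrounds = NULL, det_tol = 1e-8) {
  form <- match.arg(form)
  entries <- as.matrix(entries)
  stopifnot(identical(dim(entries), c(2L, 2L)), all(is.finite(entries)))
  if (any(entries < 0)) stop("transfer matrix entries must be non-negative")
  if (form == "absolute") {
    if (is.null(backgrounds) || length(backgrounds) != 2L || any(backgrounds <= 0)) {
      stop("absolute form requires two positive background intensities")
    }
    w <- sweep(entries, 2L, backgrounds, `*`)
    entries <- w / rowSums(w)
  }
  if (abs(det(entries)) < det_tol) {
    stop("opsin calibration error: transfer matrix is singular or ill-conditioned")
  }
  structure(list(entries = entries, det_tol = det_tol),
            class = "opsin_transfer_matrix")
}

#' @export
print.opsin_transfer_matrix <- function(x, ...) {
  cat("Opsin transfer matrix (contrast form)\n")
  m <- x$entries
  dimnames(m) <- list(c("S-opsin", "M-opsin/rod"), c("UV", "green"))
  print(round(m, 4))
  invisible(x)
}

#' Silent-substitution source contrasts for a target opsin contrast
#'
#' Inverts the source-to-opsin transfer matrix to find the UV and green source
#' contrasts that produce a desired pair of opsin-level Weber contrasts. An
#' S-opsin-isolating target `(c, 0)` silences M-opsins (and, to the degree
#' that rods share the M row, rods); an M-isolating target `(0, c)`
#' co-activates rods with approximately contrast `c`.
#'
#' @param target numeric length-2 opsin contrast target `(S, M)`.
#' @param A an [opsin_transfer_matrix()].
#' @return numeric length-2 source contrasts `(UV, green)` with
#'   `A %*% result == target`. Values outside `[-1, 1]` trigger an
#'   out-of-gamut warning but are returned unclipped.
#' @export
opsin_isolating_contrast <- function(target, A) {
  stopifnot(inherits(A, "opsin_transfer_matrix"),
            length(target) == 2L, all(is.finite(target)))
  c_led <- drop(solve(A$entries, target))
  if (any(abs(c_led) > 1)) {
    warning("required source contrast outside [-1, 1]: stimulus is out of gamut")
  }
  c_led
}

#' The dichromatic chromatic-integration contrast ladder
#'
#' Builds the 22-combination UV/green step-stimulus set: a green-On-UV-Off set
#' whose green contrast runs from `max_contrast` down to 0 while UV runs from
#' 0 down to `-max_contrast` in steps of `step`, and the contrast-reversed
#' green-Off-UV-On set. Contrasts are Weber contrasts at the opsin level.
#'
#' @param max_contrast peak Weber contrast (default 0.20).
#' @param step ladder step (default 0.02); must divide `max_contrast`.
#' @param presentation_s step presentation duration in seconds.
#' @param gap_s background gap between presentations in seconds.
#' @return A `chromatic_stimulus_set`: data.frame with columns
#'   `stimulus_id`, `set_label`, `stimulus_index`, `green`, `uv`.
#' @export
chromatic_integration_set <- function(max_contrast = 0.20, step = 0.02,
                                      presentation_s = 0.5, gap_s = 2) {
  k <- max_contrast / step
  if (abs(k - round(k)) > 1e-9) {
    stop("parameter error: `step` must divide `max_contrast`")
  }
  n <- as.integer(round(k)) + 1L
  idx <- seq_len(n)
  g_on <- data.frame(
    set_label = "green-On-UV-Off",
    stimulus_index = idx,
    green = max_contrast - step * (idx - 1),
    uv = -step * (idx - 1)
  )
  g_off <- transform(g_on, set_label = "green-Off-UV-On",
                     green = -green, uv = -uv)
  set <- rbind(g_on, g_off)
  set$stimulus_id <- stimulus_id(set$set_label, set$stimulus_index)
  set <- set[, c("stimulus_id", "set_label", "stimulus_index", "green", "uv")]
  structure(set,
            class = c("chromatic_stimulus_set", "data.frame"),
            max_contrast = max_contrast, step = step,
            presentation_s = presentation_s, gap_s = gap_s)
}

stimulus_id <- function(set_label, stimulus_index) {
  sprintf("%s:%02d", set_label, stimulus_index)
}

#' @export
print.chromatic_stimulus_set <- function(x, ...) {
  cat(sprintf("Chromatic-integration stimulus set: %d combinations (%d per set),\n",
              nrow(x), nrow(x) / 2L))
  cat(sprintf("  ladder 0 to %.2f in steps of %.2f; %g ms steps, %g s gaps\n",
              attr(x, "max_contrast"), attr(x, "step"),
              1000 * attr(x, "presentation_s"), attr(x, "gap_s")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Randomised presentation order of a stimulus set
#'
#' Repeats every combination `n_repeats` times and shuffles the full sequence
#' with a Fisher-Yates permutation, reproducibly for a fixed seed.
#'
#' @param set a `chromatic_stimulus_set` (or any data.frame with a
#'   `stimulus_id` column).
#' @param n_repeats presentations per combination (default 50).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return character vector of `stimulus_id`s, length `nrow(set) * n_repeats`.
#' @export
presentation_order <- function(set, n_repeats = 50, seed = NULL) {
  stopifnot(n_repeats >= 1)
  ids <- rep(set$stimulus_id, times = n_repeats)
  with_seed(seed, fisher_yates(ids))
}

#' Chromatic drifting-grating specifications
#'
#' Eleven slowly drifting UV/green sinusoidal gratings whose per-channel
#' amplitudes follow the green-On-UV-Off contrast ladder and whose two colour
#' components are in exact spatial anti-phase, so that a linearly integrating
#' cell sees an effective amplitude proportional to the difference of its
#' channel weights times the two contrasts.
#'
#' @param spatial_period grating period in micrometers (default 480).
#' @param temporal_period drift period in seconds (default 1).
#' @param max_contrast,step contrast ladder parameters as in
#'   [chromatic_integration_set()].
#' @return data.frame of 11 grating specs with columns `stimulus_index`,
#'   `green_amp`, `uv_amp`, `green_phase_deg`, `uv_phase_deg`,
#'   `spatial_period_um`, `temporal_period_s`, `kind`.
#' @export
chromatic_grating_set <- function(spatial_period = 480, temporal_period = 1,
                                  max_contrast = 0.20, step = 0.02) {
  n <- as.integer(round(max_contrast / step)) + 1L
  idx <- seq_len(n)
  data.frame(
    stimulus_index = idx,
    green_amp = max_contrast - step * (idx - 1),
    uv_amp = step * (idx - 1),
    green_phase_deg = 0,
    uv_phase_deg = 180,
    spatial_period_um = spatial_period,
    temporal_period_s = temporal_period,
    kind = "chromatic-drift"
  )
}

#' Contrast-reversing grating specifications
#'
#' Monochromatic square-wave gratings at 100% contrast with spatial periods of
#' 32, 64, 128, 224 and 448 micrometers plus a spatially homogeneous
#' full-field condition; one spatial phase at 32 um and full field, two phases
#' (90 degrees apart) at 64 and 128 um, four phases (45 degrees apart) at 224
#' and 448 um. Polarity reverses every second for 30 reversals.
#'
#' @return data.frame of 14 condition specs with columns
#'   `spatial_period_um` (`Inf` = full field), `phase_deg`, `contrast`,
#'   `reversal_period_s`, `n_reversals`, `kind`.
#' @export
reversing_grating_set <- function() {
  conds <- rbind(
    data.frame(spatial_period_um = 32, phase_deg = 0),
    data.frame(spatial_period_um = 64, phase_deg = c(0, 90)),
    data.frame(spatial_period_um = 128, phase_deg = c(0, 90)),
    data.frame(spatial_period_um = 224, phase_deg = c(0, 45, 90, 135)),
    data.frame(spatial_period_um = 448, phase_deg = c(0, 45, 90, 135)),
    data.frame(spatial_period_um = Inf, phase_deg = 0)
  )
  conds$contrast <- 1
  conds$reversal_period_s <- 1
  conds$n_reversals <- 30L
  conds$kind <- "achromatic-reversing"
  conds
}

#' Binary white-noise checkerboard frames
#'
#' Independent binary frames on a checkerboard layout; every square takes one
#' of two values symmetric about the mean level, `mean_level * (1 +/- contrast)`.
#'
#' @param n_rows,n_cols checkerboard dimensions in squares.
#' @param n_frames number of frames.
#' @param contrast binary contrast (0.75 or 1 in typical use).
#' @param mean_level mean intensity (default 0.5).
#' @param square_size_um side length of one square, carried as metadata.
#' @param update_rate_hz frame rate, carried as metadata.
#' @param seed integer seed; frames are reproducible per seed.
#' @return numeric array `n_rows x n_cols x n_frames` with attributes
#'   `mean_level`, `contrast`, `square_size_um`, `update_rate_hz`, `seed`.
#' @export
white_noise_frames <- function(n_rows, n_cols, n_frames, contrast = 1,
                               mean_level = 0.5, square_size_um = 60,
                               update_rate_hz = 30, seed = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_frames >= 1,
            contrast > 0, contrast <= 1, mean_level > 0)
  vals <- with_seed(seed, {
    bits <- runif(n_rows * n_cols * n_frames) < 0.5
    mean_level * (1 + contrast * ifelse(bits, 1, -1))
  })
  structure(array(vals, dim = c(n_rows, n_cols, n_frames)),
            mean_level = mean_level, contrast = contrast,
            square_size_um = square_size_um,
            update_rate_hz = update_rate_hz, seed = seed)
}
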