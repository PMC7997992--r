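#' Two-channel scene container
#'
#' Pairs co-registered UV and green intensity images (matrices of identical
#' shape, arbitrary non-negative intensity units, row 1 = top of scene).
#'
#' @param green,uv numeric matrices of identical dimensions, non-negative
#'   with strictly positive means.
#' @return A `scene_pair` list.
#' @export
scene_pair <- function(green, uv) {
  green <- as.matrix(green); uv <- as.matrix(uv)
  stopifnot(identical(dim(green), dim(uv)))
  if (any(green < 0) || any(uv < 0)) stop("intensities must be non-negative")
  if (mean(green) <= 0 || mean(uv) <= 0) stop("channel means must be positive")
  structure(list(green = green, uv = uv), class = "scene_pair")
}

#' @export
print.scene_pair <- function(x, ...) {
  cat(sprintf("Scene pair: %d x %d pixels; channel means green %.3f, uv %.3f\n",
              nrow(x$green), ncol(x$green), mean(x$green), mean(x$uv)))
  invisible(x)
}

#' Synthetic skyline scene with distinct UV and green transitions
#'
#' Emulates the structure of natural UV/green scene pairs: a bright sky above
#' a dimmer foreground, with the vertical intensity transition of the UV
#' channel above (earlier than) that of the green channel. Each channel
#' follows a vertical logistic step at its transition row, modulated by
#' seeded multiplicative noise and a mild horizontal texture. The band of
#' rows between the two transitions carries opposing UV/green Weber
#' contrasts.
#'
#' @param height,width image size in pixels (defaults 300 x 550).
#' @param uv_transition_row,green_transition_row rows of the UV and green
#'   sky-to-foreground transitions; the UV transition must not lie below the
#'   green one.
#' @param sharpness logistic width in pixels (default 6).
#' @param noise multiplicative noise amplitude (default 0.05).
#' @param sky,foreground named lists of channel intensities above and below
#'   the transitions.
#' @param seed optional integer seed.
#' @return A [scene_pair()].
#' @export
synthesize_scene <- function(height = 300, width = 550,
                             uv_transition_row = 120,
                             green_transition_row = 150,
                             sharpness = 6, noise = 0.05,
                             sky = list(green = 1.0, uv = 1.0),
                             foreground = list(green = 0.45, uv = 0.15),
                             seed = NULL) {
  if (uv_transition_row > green_transition_row) {
    stop("UV transition must lie at or above the green transition (UV drops first)")
  }
  if (uv_transition_row < 1 || green_transition_row > height) {
    stop("transition rows outside the image")
  }
  channel <- function(t_row, lo, hi, texture_phase) {
    rows <- seq_len(height)
    profile <- lo + (hi - lo) * plogis((t_row - rows) / sharpness)
    base <- matrix(profile, height, width)
    tex <- 1 + 0.03 * sin(2 * pi * (seq_len(width) / width * 3 + texture_phase))
    base <- sweep(base, 2, tex, `*`)
    if (noise > 0) {
      base <- base * matrix(exp(rnorm(height * width, 0, noise)), height, width)
    }
    pmax(base, 1e-6)
  }
  with_seed(seed, {
    g <- channel(green_transition_row, foreground$green, sky$green, 0)
    u <- channel(uv_transition_row, foreground$uv, sky$uv, 0)
    scene_pair(g, u)
  })
}

#' Per-channel Weber contrast maps of a scene
#'
#' Converts each channel to Weber contrast `(I - I_B) / I_B` with `I_B` the
#' channel's mean intensity over the image, so each contrast map has zero
#' mean by construction. This assumes the two opsin channels adapt
#' independently to their channel means.
#'
#' @param scene a [scene_pair()].
#' @return list of matrices `green`, `uv`.
#' @export
weber_contrast_image <- function(scene) {
  stopifnot(inherits(scene, "scene_pair"))
  mg <- mean(scene$green); mu <- mean(scene$uv)
  if (mg == 0 || mu == 0) stop("zero-mean channel")
  list(green = (scene$green - mg) / mg, uv = (scene$uv - mu) / mu)
}

#' Gaussian receptive-field kernel
#'
#' Circular Gaussian kernel truncated at +/- `truncate` sigma and normalised
#' to unit sum.
#'
#' @param sigma standard deviation in pixels (default 25).
#' @param truncate truncation radius in sigmas (default 3).
#' @return square matrix kernel.
#' @export
gaussian_kernel <- function(sigma = 25, truncate = 3) {
  r <- ceiling(truncate * sigma)
  x <- (-r):r
  k1 <- exp(-0.5 * (x / sigma)^2)
  k <- outer(k1, k1)
  k / sum(k)
}

# separable "same"-size Gaussian filtering; rows/cols whose kernel support
# leaves the image are marked NA (invalid border region)
filter_gaussian <- function(map, sigma = 25, truncate = 3) {
  r <- ceiling(truncate * sigma)
  x <- (-r):r
  k1 <- exp(-0.5 * (x / sigma)^2)
  k1 <- k1 / sum(k1)
  conv_valid <- function(v) {
    out <- convolve(v, rev(k1), type = "open")[(2 * r + 1):length(v)]
    c(rep(NA_real_, r), out, rep(NA_real_, r))
  }
  tmp <- apply(map, 2, conv_valid)          # along rows (vertical)
  t(apply(t(tmp), 2, conv_valid))           # along columns (horizontal)
}

#' Linear and nonlinear Off-model responses at one location
#'
#' Both models filter the two chromatic contrast channels independently with
#' the Gaussian receptive field; as Off-type models the filtered contrasts
#' are sign-inverted. The linear model sums the two channels and half-wave
#' rectifies the sum; the nonlinear model half-wave rectifies each channel
#' first, so opposing UV/green contrasts fail to cancel. The nonlinear
#' response is therefore never below the linear one, with equality exactly
#' when the two filtered signals share a sign.
#'
#' @param cmaps contrast maps from [weber_contrast_image()].
#' @param location integer `c(row, col)` of the receptive-field centre.
#' @param sigma,truncate kernel parameters (defaults 25 px, 3 sigma).
#' @return list `linear`, `nonlinear`, `valid` (FALSE when the kernel
#'   support extends beyond the image).
#' @export
model_response <- function(cmaps, location, sigma = 25, truncate = 3) {
  r <- ceiling(truncate * sigma)
  nr <- nrow(cmaps$green); nc <- ncol(cmaps$green)
  i <- location[1]; j <- location[2]
  if (i - r < 1 || i + r > nr || j - r < 1 || j + r > nc) {
    return(list(linear = NA_real_, nonlinear = NA_real_, valid = FALSE))
  }
  k <- gaussian_kernel(sigma, truncate)
  rows <- (i - r):(i + r); cols <- (j - r):(j + r)
  fg <- sum(k * cmaps$green[rows, cols])
  fu <- sum(k * cmaps$uv[rows, cols])
  list(linear = rectify(-(fg + fu)),
       nonlinear = rectify(rectify(-fg) + rectify(-fu)),
       valid = TRUE)
}

#' Sampled map of nonlinear-minus-linear model response differences
#'
#' Evaluates both chromatic-integration models at randomly sampled patch
#' locations (without repetition) and reports the response difference.
#' Locations whose kernel support leaves the image are reported but flagged
#' invalid.
#'
#' @param scene a [scene_pair()].
#' @param n_patches number of sampled locations (default 10000).
#' @param sigma,truncate kernel parameters.
#' @param include_border if `TRUE`, sample among all pixels and flag border
#'   locations invalid; if `FALSE` (default) sample interior locations only.
#' @param seed optional integer seed.
#' @return data.frame: `row`, `col`, `linear`, `nonlinear`, `difference`,
#'   `valid`.
#' @export
response_difference_map <- function(scene, n_patches = 10000,
                                    sigma = 25, truncate = 3,
                                    include_border = FALSE, seed = NULL) {
  cmaps <- weber_contrast_image(scene)
  fg <- filter_gaussian(cmaps$green, sigma, truncate)
  fu <- filter_gaussian(cmaps$uv, sigma, truncate)
  nr <- nrow(fg); nc <- ncol(fg)
  valid_mask <- !is.na(fg)
  pool <- if (include_border) seq_len(nr * nc) else which(valid_mask)
  if (length(pool) == 0) stop("no valid locations: kernel larger than image")
  n_patches <- min(n_patches, length(pool))
  picks <- with_seed(seed, pool[sample.int(length(pool), n_patches)])
  lin <- rectify(-(fg[picks] + fu[picks]))
  nl <- rectify(rectify(-fg[picks]) + rectify(-fu[picks]))
  data.frame(row = ((picks - 1L) %% nr) + 1L,
             col = ((picks - 1L) %/% nr) + 1L,
             linear = lin, nonlinear = nl,
             difference = nl - lin,
             valid = valid_mask[picks])
}

#' Per-column logistic transition midpoints of a contrast map
#'
#' Fits a four-parameter logistic (floor, amplitude, midpoint, width) to the
#' contrast values along each vertical column and reports the fitted
#' transition midpoint. Columns whose fit fails to converge or whose
#' midpoint falls outside the image rows are flagged invalid. Comparing
#' midpoints between the UV and green channels measures how much earlier the
#' UV contrast drops when moving from sky to foreground.
#'
#' @param cmap contrast matrix of one channel (rows x cols).
#' @param columns which columns to fit (default all).
#' @return data.frame: `column`, `midpoint`, `width`, `valid`.
#' @export
column_sigmoid_midpoints <- function(cmap, columns = seq_len(ncol(cmap))) {
  nr <- nrow(cmap)
  if (nr < 4) stop("columns shorter than 4 pixels cannot constrain the fit")
  rows <- seq_len(nr)
  fit_col <- function(j) {
    z <- cmap[, j]
    if (max(z) - min(z) < 1e-10) {
      return(c(NA_real_, NA_real_)) # constant column: no transition
    }
    half <- (max(z) + min(z)) / 2
    below <- which(z <= half)
    mid0 <- if (length(below)) below[1] else nr / 2
    start <- list(lo = min(z), amp = max(z) - min(z), mid = mid0, wd = 8)
    f <- try(suppressWarnings(minpack.lm::nlsLM(
      z ~ lo + amp * plogis((mid - rows) / wd),
      data = data.frame(z = z, rows = rows), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 100))), silent = TRUE)
    if (inherits(f, "try-error")) return(c(NA_real_, NA_real_))
    p <- coef(f)
    c(p[["mid"]], p[["wd"]])
  }
  res <- vapply(columns, fit_col, numeric(2))
  midpoint <- res[1, ]
  data.frame(column = columns, midpoint = midpoint, width = res[2, ],
             valid = !is.na(midpoint) & midpoint >= 1 & midpoint <= nr)
}

#' Compare UV and green transition midpoints of a scene
#'
#' Runs [column_sigmoid_midpoints()] on both contrast channels and reports
#' the per-column and median UV-green midpoint differences over columns where
#' both fits are valid.
#'
#' @param scene a [scene_pair()].
#' @param columns which columns to analyse (default all).
#' @return list: `per_column` data.frame (`column`, `uv_midpoint`,
#'   `green_midpoint`, `difference`, `valid`), `median_difference`.
#' @export
scene_transition_analysis <- function(scene, columns = NULL) {
  cmaps <- weber_contrast_image(scene)
  if (is.null(columns)) columns <- seq_len(ncol(cmaps$green))
  mu <- column_sigmoid_midpoints(cmaps$uv, columns)
  mg <- column_sigmoid_midpoints(cmaps$green, columns)
  valid <- mu$valid & mg$valid
  diff <- mg$midpoint - mu$midpoint
  list(per_column = data.frame(column = columns,
                               uv_midpoint = mu$midpoint,
                               green_midpoint = mg$midpoint,
                               difference = diff, valid = valid),
       median_difference = stats::median(diff[valid]))
}
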