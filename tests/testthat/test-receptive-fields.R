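make_separable_sta <- function(nr = 12, nc = 12, n_lags = 15,
                               cx = 7, cy = 5, sigma = 1.8) {
  xs <- col(matrix(0, nr, nc)); ys <- row(matrix(0, nr, nc))
  spatial <- exp(-0.5 * ((xs - cx)^2 + (ys - cy)^2) / sigma^2)
  temporal <- c(0.5, 1, 0.4, -0.3, -0.5, -0.2, rep(0, n_lags - 6))
  list(spatial = spatial, temporal = temporal,
       sta = array(outer(as.vector(spatial), temporal), c(nr, nc, n_lags)))
}

test_that("the STA is flat for stimulus-independent spiking", {
  fr <- white_noise_frames(8, 8, 6000, contrast = 1, seed = 1)
  set.seed(2)
  spikes <- sample(30:6000, 1500, replace = TRUE)
  sta <- compute_sta(spikes, fr, n_lags = 10)
  # binary pixels have sd 0.5; STA entries are means over ~1500 draws
  expect_lt(max(abs(sta)), 4 * 0.5 / sqrt(1500))
})

test_that("the STA recovers a generating filter and is weight-invariant", {
  truth <- make_separable_sta()
  fr <- white_noise_frames(12, 12, 40000, contrast = 1, seed = 3)
  counts <- simulate_whitenoise_counts(fr, truth$spatial / sqrt(sum(truth$spatial^2)),
                                       truth$temporal, gain = 40,
                                       baseline_rate = 1, seed = 4)
  expect_gt(sum(counts), 1e4)
  spike_frames <- rep(seq_along(counts), counts)
  sta <- compute_sta(spike_frames, fr, n_lags = 15)
  dec <- decompose_sta(sta)
  expect_gt(cor(as.vector(dec$spatial), as.vector(truth$spatial)), 0.8)
  expect_gt(cor(dec$temporal, truth$temporal), 0.8)

  # doubling every spike leaves the average unchanged
  sta2 <- compute_sta(rep(spike_frames, 2), fr, n_lags = 15)
  expect_equal(sta2, sta)

  expect_error(compute_sta(integer(0), fr), "zero spikes")
})

test_that("SVD separation is exact for separable fields and optimal", {
  truth <- make_separable_sta()
  dec <- decompose_sta(truth$sta)
  recon <- array(outer(as.vector(dec$spatial), dec$temporal),
                 dim(truth$sta))
  expect_equal(recon, truth$sta, tolerance = 1e-10)
  expect_equal(dec$separability, 1, tolerance = 1e-10)
  expect_gt(cor(as.vector(dec$spatial), as.vector(truth$spatial)), 0.999)

  # small noise: spatial map still recovered
  set.seed(5)
  noisy <- truth$sta + array(rnorm(length(truth$sta), 0, 0.02 * max(truth$sta)),
                             dim(truth$sta))
  dec_n <- decompose_sta(noisy)
  expect_gt(cor(as.vector(dec_n$spatial), as.vector(truth$spatial)), 0.95)

  # rank-1 optimality: no random rank-1 candidate beats the SVD factorisation
  m <- matrix(noisy, prod(dim(noisy)[1:2]), dim(noisy)[3])
  svd_err <- sum((m - as.vector(dec_n$spatial) %o% dec_n$temporal)^2)
  for (i in 1:20) {
    u <- rnorm(nrow(m)); v <- rnorm(ncol(m))
    alpha <- sum(m * (u %o% v)) / sum((u %o% v)^2)
    expect_gte(sum((m - alpha * (u %o% v))^2), svd_err - 1e-9)
  }

  # Off-type field: dominant spatial lobe positive, temporal peak negative
  dec_off <- decompose_sta(-truth$sta)
  expect_gt(max(dec_off$spatial), 0)
  expect_lt(dec_off$temporal[2], 0)

  expect_error(decompose_sta(array(0, c(3, 3, 4))), "all-zero")
})

test_that("Gaussian receptive-field fits recover geometry and diameter", {
  grid <- expand.grid(x = seq_len(40), y = seq_len(30))
  gauss_map <- function(x0, y0, sx, sy, ang) {
    ca <- cos(ang); sa <- sin(ang)
    u <- ca * (grid$x - x0) + sa * (grid$y - y0)
    v <- -sa * (grid$x - x0) + ca * (grid$y - y0)
    matrix(exp(-0.5 * (u^2 / sx^2 + v^2 / sy^2)), nrow = 30, byrow = TRUE)
  }
  # circular sigma 4 px at 10 um/px -> sigma 40 um -> diameter 120 um
  m <- gauss_map(21.5, 14.5, 4, 4, 0)
  rf <- fit_gaussian_rf(m, pixel_size_um = 10)
  expect_equal(unname(rf$diameter), 120, tolerance = 0.5)
  expect_equal(unname(rf$center), c(21 * 10, 14 * 10), tolerance = 2)

  # anisotropic: sigmas (2.5, 6.4) px -> diameter 3 * sqrt(25 * 64) = 120 um
  m2 <- gauss_map(20.5, 15.5, 2.5, 6.4, 0.6)
  rf2 <- fit_gaussian_rf(m2, pixel_size_um = 10)
  expect_equal(unname(rf2$diameter), 2 * 1.5 * sqrt(25 * 64), tolerance = 1)
  expect_true(rf2$converged)

  # diameter is rotation invariant
  for (ang in c(0, 0.4, 1.1)) {
    rfa <- fit_gaussian_rf(gauss_map(20.5, 15.5, 3, 5, ang), pixel_size_um = 10)
    expect_equal(unname(rfa$diameter), 2 * 1.5 * sqrt(30 * 50), tolerance = 1)
  }
})

test_that("receptive-field centres are recovered from simulated noise runs", {
  truth <- make_separable_sta(cx = 8, cy = 6, sigma = 1.6)
  fr <- white_noise_frames(12, 12, 30000, contrast = 1, seed = 6)
  counts <- simulate_whitenoise_counts(fr, truth$spatial, truth$temporal,
                                       gain = 15, baseline_rate = 1, seed = 7)
  sta <- compute_sta(rep(seq_along(counts), counts), fr, n_lags = 15)
  dec <- decompose_sta(sta)
  rf <- fit_gaussian_rf(dec$spatial, pixel_size_um = 1)
  # centre within half a stimulus square of the generating filter
  expect_lt(abs(rf$center[["x"]] - 7.5), 0.5)
  expect_lt(abs(rf$center[["y"]] - 5.5), 0.5)
})

test_that("the midline maximises UV separation with ventral sign", {
  set.seed(17)
  n <- 120
  x <- runif(n, -1000, 1000); y <- runif(n, -1000, 1000)
  uv <- rep(FALSE, n)
  uv[y < -200] <- runif(sum(y < -200)) < 0.8
  if (sum(uv) < 3) uv[order(y)[1:3]] <- TRUE
  ml <- estimate_midline(cbind(x, y), uv)
  ang <- ml$angle * 180 / pi
  expect_lt(min(ang, 180 - ang), 10) # near-horizontal line
  expect_lt(mean(ml$signed_distances[uv]), 0)
  expect_gt(mean(ml$signed_distances[uv] < 0), 0.9)

  expect_error(estimate_midline(cbind(x, y), rep(FALSE, n)), "excluded")
})

test_that("the midline is equivariant under rotation", {
  set.seed(19)
  pop <- simulate_population(250, gradient_slope = 10, seed = 19)
  uv <- pop$truth$archetype == "UV-selective"
  centers <- cbind(pop$truth$x_um, pop$truth$y_um)
  ml0 <- estimate_midline(centers, uv)
  phi <- 0.7
  rot <- rbind(c(cos(phi), -sin(phi)), c(sin(phi), cos(phi)))
  ml1 <- estimate_midline(centers %*% t(rot), uv)
  d_ang <- (ml1$angle - ml0$angle - phi) %% pi
  expect_lt(min(d_ang, pi - d_ang), 2 * pi / 180)
  expect_equal(ml1$signed_distances, ml0$signed_distances, tolerance = 0.05)
})

test_that("steep synthetic gradients are recovered within a few degrees", {
  angles <- numeric(10)
  for (s in seq_along(angles)) {
    pop <- simulate_population(500, gradient_slope = 12, seed = 400 + s)
    uv <- pop$truth$archetype == "UV-selective"
    ml <- estimate_midline(cbind(pop$truth$x_um, pop$truth$y_um), uv)
    a <- ml$angle * 180 / pi
    angles[s] <- min(a, 180 - a)
  }
  # generating axis is horizontal (angle 0); accuracy is limited by the
  # ~40 UV-selective cells spread through the ventral half
  expect_lt(median(angles), 5)
  expect_lt(max(angles), 15)
})

test_that("nonlinear cells sit ventral of linear cells when the gradient is on", {
  pop <- simulate_population(300, gradient_slope = 8, seed = 23)
  tr <- pop$truth
  nl <- grepl("^nonlinear", tr$archetype)
  li <- grepl("^linear", tr$archetype)
  p_on <- wilcox.test(tr$y_um[nl], tr$y_um[li], alternative = "less")$p.value
  expect_lt(p_on, 0.05)

  pop0 <- simulate_population(300, gradient_slope = 0, seed = 24)
  tr0 <- pop0$truth
  nl0 <- grepl("^nonlinear", tr0$archetype)
  li0 <- grepl("^linear", tr0$archetype)
  p_off <- wilcox.test(tr0$y_um[nl0], tr0$y_um[li0])$p.value
  expect_gt(p_off, 0.05)
})
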