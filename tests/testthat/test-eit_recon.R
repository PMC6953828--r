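test_that("adjoint Jacobian matches finite-difference perturbation", {
  ph <- build_phantom(grid_shape = 32, ellipse_axes = c(28, 22))
  belt <- electrode_belt(ph)
  J <- eit_jacobian(ph, belt)
  expect_equal(dim(J), c(208L, sum(ph$body_mask)))

  base <- matrix(NA_real_, 32, 32)
  base[ph$body_mask] <- ph$background_conductivity
  f0 <- acquire_frame(base, belt, ph)$measurements
  set.seed(9)
  for (k in sample(ncol(J), 10)) {
    fld <- base
    fld[ph$body_mask][k] <- fld[ph$body_mask][k] + 1e-4
    f1 <- acquire_frame(fld, belt, ph)$measurements
    fd <- (f1 - f0) / 1e-4
    q <- which.max(abs(J[, k]))
    expect_lt(abs(J[q, k] - fd[q]) / abs(fd[q]), 0.01)
    # and over all rows with non-negligible sensitivity
    big <- abs(fd) > 0.05 * max(abs(fd))
    expect_lt(max(abs(J[big, k] - fd[big]) / abs(fd[big])), 0.01)
  }
})

test_that("sensitivity is highest near the drive electrodes", {
  ctx <- fix_ctx()
  J <- ctx$jacobian
  ph <- ctx$phantom
  body <- attr(J, "body")
  pos <- arrayInd(body, c(ph$grid_shape, ph$grid_shape))
  # pixel nearest electrode 1 vs pixel at the body center
  e1 <- ctx$belt$positions[1, ]
  near <- which.min((pos[, 1] - e1[1])^2 + (pos[, 2] - e1[2])^2)
  ctr <- which.min((pos[, 1] - 32.5)^2 + (pos[, 2] - 32.5)^2)
  expect_gt(max(abs(J[, near])), max(abs(J[, ctr])))
})

test_that("difference reconstruction is zero on null input, linear, damped", {
  ctx <- fix_ctx()
  v <- rnorm(208)
  img0 <- reconstruct_difference(v, v, ctx$operator)
  expect_true(all(img0$values == 0))

  r <- rnorm(208)
  i1 <- reconstruct_difference(v, r, ctx$operator)
  i2 <- reconstruct_difference(v + 0.5 * (v - r), r, ctx$operator)
  expect_equal(i2$values, 1.5 * i1$values, tolerance = 1e-10)

  # image norm decreases monotonically as lambda grows
  norms <- sapply(c(0.1, 0.3, 1, 3, 10), function(l)
    sqrt(sum(reconstruct_difference(v, r, ctx$jacobian, lambda = l)$values^2)))
  expect_true(all(diff(norms) < 0))
  expect_error(reconstruct_difference(v[-1], r, ctx$operator), "length")
})

test_that("orientation contract: ventral-right truth stays ventral-right", {
  sim <- fix_transcc_case()   # lesion in segment 2 (ventral right lung)
  twin <- fix_twin_case()
  deficit <- twin$tidal$values - sim$tidal$values
  w <- which(deficit == max(deficit), arr.ind = TRUE)
  expect_lte(w[1, 1], 16)   # ventral half (row 1 = ventral)
  expect_lte(w[1, 2], 16)   # animal's right = image left
})

test_that("breath detection finds the right count, resists spikes", {
  fs <- 25
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- -cos(2 * pi * (20 / 60) * t)
  br <- detect_breaths(x, frame_rate = fs)
  expect_equal(nrow(br), 20, tolerance = 0.051)
  expect_true(all(br$end_expiration_frame < br$end_inspiration_frame))
  expect_true(all(diff(br$end_expiration_frame) > 0))

  expect_identical(nrow(detect_breaths(rep(1, 200), frame_rate = fs)), 0L)

  # cardiac spikes at 90/min, 10% of the tidal swing
  spike_t <- seq(0.4, 60, by = 60 / 90)
  sp <- numeric(length(t))
  sp[round(spike_t * fs)] <- -0.2   # drops, 10% of the 2-unit swing
  br2 <- detect_breaths(x + sp, frame_rate = fs)
  expect_equal(nrow(br2), nrow(br))

  expect_error(detect_breaths(x[1:20], frame_rate = fs), "2 s")
})

test_that("tidal image subtracts the breath endpoints", {
  sim <- fix_healthy_case()
  rec <- sim$recon
  br <- rec$breaths
  expect_gte(nrow(br), 2)
  same <- data.frame(end_expiration_frame = 3, end_inspiration_frame = 3)
  expect_true(all(tidal_image(rec$images, same)$values == 0))

  t1 <- tidal_image(rec$images, br[1, ])
  expect_equal(t1$values,
               rec$images[, , br$end_inspiration_frame[1]] -
                 rec$images[, , br$end_expiration_frame[1]])
  # healthy lungs ventilate: positive tidal content
  expect_gt(sum(t1$values), 0)
  expect_error(tidal_image(rec$images,
                           data.frame(end_expiration_frame = 1,
                                      end_inspiration_frame = 10000)),
               "range")
})

test_that("a non-ventilated lesion suppresses tidal signal in its footprint", {
  sim <- fix_transcc_case()
  twin <- fix_twin_case()
  # lesion core footprint on the display grid
  les <- sim$truth$lesions[[1]]
  foot <- eitptx:::to_image_grid(
    as.numeric(les$in_plane_mask[sim$phantom$body_mask]),
    which(sim$phantom$body_mask), sim$phantom$grid_shape)$values > 0.8
  expect_gt(sum(foot), 0)
  # the residual signal is point-spread bleed-through from surrounding
  # ventilated lung: 16-electrode EIT cannot null a peripheral region, so
  # we assert suppression to below half the healthy twin's level (measured
  # ratio on this fixture is about 0.25)
  expect_lt(mean(sim$tidal$values[foot]), 0.5 * mean(twin$tidal$values[foot]))
})

test_that("quadrant waveforms partition the global sum", {
  sim <- fix_healthy_case()
  wf <- quadrant_waveforms(sim$recon)
  qsum <- wf[["ventral-right"]]$samples + wf[["ventral-left"]]$samples +
    wf[["dorsal-right"]]$samples + wf[["dorsal-left"]]$samples
  expect_equal(qsum, wf$global$samples, tolerance = 1e-9)

  z <- array(0, c(32, 32, 4))
  wz <- quadrant_waveforms(z, frame_rate = 10)
  expect_true(all(wz$global$samples == 0))

  # a ventral-right lesion depresses the ventral-right quadrant signal
  siml <- fix_transcc_case()
  wfl <- quadrant_waveforms(siml$recon)
  amp <- function(w) diff(range(w$samples))
  ratio_lesion <- amp(wfl[["ventral-right"]]) / amp(wfl$global)
  ratio_healthy <- amp(wf[["ventral-right"]]) / amp(wf$global)
  expect_lt(ratio_lesion, ratio_healthy)
})

test_that("phase map recovers synchrony, injected lag, and undefined pixels", {
  ctx <- fix_ctx()
  sim <- fix_healthy_case()
  pm <- phase_map(sim$recon)
  lungish <- is.finite(pm) & abs(sim$tidal$values) >
    0.2 * max(abs(sim$tidal$values))
  expect_gt(sum(lungish), 20)
  expect_lt(median(abs(pm[lungish])), 0.1)

  # lesion ventilating out of phase by pi/2
  dyn <- dynamics_config(frame_rate = 10, duration = 12,
                         lesion_ventilation_fraction = 1,
                         lesion_phase_lag = pi / 2, seed = 77)
  sim2 <- simulate_case(ctx, seed = 77, lesion = list(segment_id = 2,
                                                      trans_frac = 0.28,
                                                      cc_cm = 6),
                        dynamics = dyn)
  pm2 <- phase_map(sim2$recon)
  les <- sim2$truth$lesions[[1]]
  foot <- eitptx:::to_image_grid(
    as.numeric(les$in_plane_mask[sim2$phantom$body_mask]),
    which(sim2$phantom$body_mask), sim2$phantom$grid_shape)$values > 0.9
  # in-phase bleed-through from surrounding lung adds spectral amplitude
  # and biases the phase toward zero, so the cleanest estimate of the
  # injected lag lives in the lower-amplitude half of the lesion core
  amp <- attr(pm2, "amplitude")
  a <- amp[foot]; p <- pm2[foot]
  clean <- p[order(a)][seq_len(floor(sum(foot) / 2))]
  lag <- median(clean, na.rm = TRUE)
  expect_lt(abs(lag - pi / 2), 0.2)

  # pixels without signal are flagged undefined
  expect_true(anyNA(pm))
  expect_true(all(!is.finite(pm[!sim$recon$mask])) || all(is.na(pm[!sim$recon$mask])))
})
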