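test_that("phantom geometry follows its definition and is reproducible", {
  ph <- build_phantom(grid_shape = 64, pixel_size = 0.5,
                      ellipse_axes = c(28, 22))
  expect_equal(ph$sternovertebral_distance, 11)   # 22 px * 0.5 cm
  # mask extent agrees with the declared axis within a pixel
  rows <- range(which(apply(ph$body_mask, 1, any)))
  expect_lte(abs(diff(rows) + 1 - 22), 1)

  p1 <- build_phantom(seed = 5, geometry_jitter = 0.05)
  p2 <- build_phantom(seed = 5, geometry_jitter = 0.05)
  expect_identical(p1, p2)
  p3 <- build_phantom(seed = 6, geometry_jitter = 0.05)
  expect_false(identical(p1$lung_masks$right, p3$lung_masks$right))

  expect_error(build_phantom(grid_shape = 16), "grid_shape")
  expect_error(build_phantom(pixel_size = -1), "pixel_size")
  expect_error(build_phantom(background_conductivity = 0), "conductivities")
})

test_that("default phantom masks are disjoint, contained, plausibly sized", {
  ph <- fix_phantom()
  lung <- ph$lung_masks$right | ph$lung_masks$left | ph$lung_masks$accessory
  expect_false(any(lung & ph$heart_mask))
  expect_true(all(ph$body_mask[lung]))
  expect_true(all(ph$body_mask[ph$heart_mask]))
  frac <- sum(lung) / sum(ph$body_mask)
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.55)
})

test_that("segment map partitions the lung into the ten labelled segments", {
  ph <- fix_phantom()
  seg <- segment_map(ph)
  lung <- ph$lung_masks$right | ph$lung_masks$left | ph$lung_masks$accessory
  expect_true(all(seg[lung] > 0))
  expect_true(all(seg[!lung] == 0))
  expect_setequal(sort(unique(seg[seg > 0])), 1:10)

  ctr <- (ph$grid_shape + 1) / 2
  # anterior set in the ventral half
  for (s in c(2, 3, 5, 6)) {
    cen <- colMeans(which(seg == s, arr.ind = TRUE))
    expect_lt(cen[1], ctr)
  }
  # accessory lobe ventro-medial: within 25% of the midline
  cen6 <- colMeans(which(seg == 6, arr.ind = TRUE))
  expect_lt(abs(cen6[2] - ctr), 0.25 * ph$ellipse_axes[1] / 2)
  # stable across rebuilds
  expect_identical(seg, segment_map(build_phantom()))
})

test_that("lesion placement honours diameter, fit and determinism", {
  ph <- fix_phantom()   # SV = 22 cm
  les <- place_lesion(ph, 2, trans_frac = 0.25, cc_cm = 6, seed = 3)
  expect_equal(les$transversal_diameter, 0.25 * 22)
  # realized mask diameter within one pixel of the target
  idx <- which(les$in_plane_mask, arr.ind = TRUE)
  dmax <- max(dist(idx)) * ph$pixel_size
  expect_lte(abs(dmax - les$transversal_diameter), ph$pixel_size)
  expect_true(all(ph$body_mask[les$in_plane_mask]))

  expect_error(place_lesion(ph, 1, trans_frac = 10, cc_cm = 1), "does not fit")
  expect_identical(place_lesion(ph, 3, 0.2, 2, seed = 9),
                   place_lesion(ph, 3, 0.2, 2, seed = 9))
  expect_error(place_lesion(ph, 11, 0.2, 2), "segment_id")
  expect_error(place_lesion(ph, 2, -0.1, 2), "trans_frac")
})

test_that("relevance classification applies strict thresholds", {
  sv <- 11
  mk <- function(td, cc) list(transversal_diameter = td, craniocaudal_extent = cc)
  # exactly at both boundaries: all false (strict inequalities)
  r <- classify_relevance(mk(2.2, 2), sv)
  expect_false(r$is_trans20); expect_false(r$is_cc3)
  expect_false(r$is_transcc); expect_false(r$is_relevant)
  r <- classify_relevance(mk(2.75, 4), sv)
  expect_true(r$is_trans20); expect_true(r$is_cc3); expect_true(r$is_transcc)
  r <- classify_relevance(mk(1, 3.5), sv)
  expect_false(r$is_trans20); expect_true(r$is_cc3)
  expect_false(r$is_transcc); expect_true(r$is_relevant)
  # invariants hold over a random grid
  for (td in seq(0.5, 5, by = 0.75)) for (cc in seq(0, 8, by = 1.6)) {
    r <- classify_relevance(mk(td, cc), sv)
    expect_identical(r$is_transcc, r$is_trans20 && r$is_cc3)
    expect_identical(r$is_relevant, r$is_trans20 || r$is_cc3)
  }
})

test_that("partial volume weight is the saturating linear ramp", {
  expect_equal(partial_volume_weight(0), 0)
  expect_equal(partial_volume_weight(3), 0.5)
  expect_equal(partial_volume_weight(6), 1)
  expect_equal(partial_volume_weight(10), 1)
  w <- partial_volume_weight(seq(0, 12, by = 0.5))
  expect_true(all(diff(w) >= 0))
  expect_true(all(w >= 0 & w <= 1))
  expect_error(partial_volume_weight(-1), "non-negative")
})

test_that("conductivity series: static limit, breath count, determinism", {
  ph <- fix_phantom()
  dyn0 <- dynamics_config(frame_rate = 5, duration = 2, tidal_modulation = 0,
                          noise_sd_frac = 0, seed = 1)
  cs0 <- conductivity_series(ph, list(), dyn0)
  expect_true(all(cs0$sigma == cs0$sigma[, 1]))

  dyn <- dynamics_config(frame_rate = 10, duration = 60,
                         respiratory_rate = 20, noise_sd_frac = 0, seed = 1)
  cs <- conductivity_series(ph, list(), dyn)
  lungmean <- colMeans(cs$sigma[ph$lung_masks$right[ph$body_mask], ])
  # exactly 20 oscillation periods: count minima of the lung-mean trace
  d <- diff(lungmean)
  minima <- sum(d[-1] > 0 & d[-length(d)] < 0)
  expect_equal(minima, 20)

  dyn2 <- dynamics_config(frame_rate = 10, duration = 6, seed = 42)
  expect_identical(conductivity_series(ph, list(), dyn2)$sigma,
                   conductivity_series(ph, list(), dyn2)$sigma)
})

test_that("lesion pixels are static without gas movement, modulated with it", {
  ph <- fix_phantom()
  les <- place_lesion(ph, 2, 0.25, cc_cm = 6, seed = 3)
  dyn <- dynamics_config(frame_rate = 10, duration = 6, noise_sd_frac = 0,
                         lesion_ventilation_fraction = 0, seed = 1)
  cs <- conductivity_series(ph, list(les), dyn)
  lesrows <- which(les$in_plane_mask[ph$body_mask])
  expect_true(all(apply(cs$sigma[lesrows, ], 1, var) == 0))

  dynv <- dynamics_config(frame_rate = 10, duration = 6, noise_sd_frac = 0,
                          lesion_ventilation_fraction = 0.8, seed = 1)
  csv <- conductivity_series(ph, list(les), dynv)
  expect_true(all(apply(csv$sigma[lesrows, ], 1, var) > 0))
})

test_that("cardiac spike transients appear once per cycle on heart contact", {
  ph <- fix_phantom()
  # segment 6 (accessory lobe) lies against the heart
  les <- place_lesion(ph, 6, 0.22, cc_cm = 6, seed = 2)
  tr <- case_truth(ph, list(les))
  expect_true(tr$heart_contact)

  dyn <- dynamics_config(frame_rate = 50, duration = 60, heart_rate = 96,
                         spike_enabled = TRUE, noise_sd_frac = 0, seed = 1)
  cs <- conductivity_series(ph, list(les), dyn)
  expect_true(abs(length(cs$spike_frames) - 96) <= 1)

  expect_error(conductivity_series(ph, list(),
                                   dynamics_config(spike_enabled = TRUE)),
               "heart contact")
})

test_that("case truth aggregates labels, largest segment and quadrants", {
  ph <- fix_phantom()
  expect_true(is.na(case_truth(ph, list())$largest_relevant_segment))
  l1 <- place_lesion(ph, 2, 0.25, 6, seed = 1)  # relevant, ventral-right
  l2 <- place_lesion(ph, 5, 0.10, 1, seed = 1)  # not relevant
  tr <- case_truth(ph, list(l1, l2))
  expect_equal(tr$largest_relevant_segment, 2L)
  expect_true("ventral-right" %in% tr$quadrant_labels)
})
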