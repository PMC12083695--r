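test_that("areal extent counts suprathreshold pixels and converts to mm2", {
  spec <- phase_spec("initial_dip")
  n <- 32L
  roi <- matrix(TRUE, n, n)
  zero <- matrix(0, n, n)
  expect_equal(areal_extent(zero, spec, roi, 7 / 512)$area_px, 0)
  # 300 pixels at -2e-4 against the 1.75e-4 dip threshold
  frame <- zero
  frame[seq_len(300)] <- -2e-4
  ext <- areal_extent(frame, spec, roi, 7 / 512)
  expect_equal(ext$area_px, 300)
  expect_equal(ext$area_mm2, 300 * (7 / 512)^2, tolerance = 1e-12)
  expect_equal(ext$area_mm2, 0.0561, tolerance = 0.01)
  expect_error(areal_extent(zero, spec, matrix(FALSE, n, n), 1), "empty")
})

test_that("extent of a Gaussian blob matches the analytic level-set area", {
  A <- -7e-4; sigma <- 20; t <- 1.75e-4
  n <- 161L
  blob <- gaussian_blob(n, A, sigma)
  ext <- areal_extent(blob, phase_spec("initial_dip"), matrix(TRUE, n, n), 1)
  analytic <- 2 * pi * sigma^2 * log(abs(A) / t)
  expect_equal(ext$area_px, analytic, tolerance = 0.02)
})

test_that("extent is monotone in threshold and in ROI", {
  with_seed_local(3, frame <- matrix(rnorm(48 * 48, sd = 2e-4), 48, 48))
  frame_s <- smooth_frame(frame, 3)
  roi_small <- disc_mask(48, c(24, 24), 10)
  roi_big <- disc_mask(48, c(24, 24), 20)
  thresholds <- c(0.5, 1, 1.5, 2, 3) * 1e-5
  areas <- vapply(thresholds, function(th)
    areal_extent(frame_s, phase_spec("initial_dip", threshold = th),
                 roi_big, 1)$area_px, numeric(1))
  expect_true(all(diff(areas) <= 0))
  a_small <- areal_extent(frame_s, phase_spec("initial_dip", threshold = 1e-5),
                          roi_small, 1)$area_px
  expect_lte(a_small, areas[2])
})

test_that("extent equals a brute-force per-pixel scan", {
  for (seed in 1:3) {
    with_seed_local(seed, {
      frame <- matrix(rnorm(32 * 64, sd = 3e-4), 32, 64)
      roi <- matrix(runif(32 * 64) < 0.6, 32, 64)
    })
    roi[1, 1] <- TRUE
    for (ph in c("initial_dip", "overshoot")) {
      spec <- phase_spec(ph)
      got <- areal_extent(frame, spec, roi, 0.1)
      brute <- 0
      for (i in 1:32) for (j in 1:64)
        if (roi[i, j] && spec$polarity * frame[i, j] >= spec$threshold)
          brute <- brute + 1
      expect_equal(got$area_px, brute)
      expect_equal(got$area_mm2, brute * 0.01)
    }
  }
})

test_that("sparse peak amplitude takes the slit extremum with fallback and tie rules", {
  n <- 20L
  frame <- matrix(0, n, n)
  slit <- rect_mask(n, c(10, 10), 6, 6)
  extent <- matrix(TRUE, n, n)
  frame[9, 11] <- -6e-4
  pk <- peak_amplitude_sparse(frame, extent, slit, polarity = -1)
  expect_equal(pk$value, -6e-4)
  expect_equal(pk$pixel, c(9, 11))
  expect_false(pk$fallback)
  # empty extent: flagged near-noise fallback from the slit alone
  pk2 <- peak_amplitude_sparse(frame * 0, matrix(FALSE, n, n), slit, -1)
  expect_true(pk2$fallback)
  expect_equal(pk2$value, 0)
  # tie broken by raster order (lowest row, then column)
  frame3 <- matrix(0, n, n)
  frame3[12, 9] <- -5e-4
  frame3[8, 12] <- -5e-4
  pk3 <- peak_amplitude_sparse(frame3, extent, slit, -1)
  expect_equal(pk3$pixel, c(8, 12))
  expect_error(peak_amplitude_sparse(frame, extent, matrix(FALSE, n, n), -1),
               "empty")
})

test_that("condensed peak amplitudes are paired at the baseline peak pixel", {
  n <- 16L
  slit <- rect_mask(n, c(8, 8), 5, 5)
  base <- gaussian_blob(n, -5e-4, 3, c(8, 8))
  pair <- peak_amplitude_condensed(base, base, slit)
  expect_equal(pair$baseline, pair$h24)
  expect_equal(pair$pixel, c(8, 8))
  h24 <- base; h24[slit] <- 0
  pair2 <- peak_amplitude_condensed(base, h24, slit)
  expect_equal(pair2$baseline, -5e-4)
  expect_equal(pair2$h24, 0)
  atten <- peak_amplitude_condensed(base, base * 0.5, slit)
  expect_equal(atten$h24 / atten$baseline, 0.5)
  expect_error(peak_amplitude_condensed(base, base[1:8, ], slit),
               "co-registered")
})

test_that("per-animal quantification recovers the generator contract", {
  des <- study_design(n_per_group = 1)
  study <- make_study(des, seed = 21, groups = c(1, 4))
  a1 <- simulate_animal(study, "g1_a01")
  r1 <- quantify_animal(a1$blocks, a1$rois, animal = "g1_a01", group = 1)
  expect_equal(nrow(r1), 6)  # 2 sparse phases + condensed, both timepoints
  for (ph in unique(r1$phase)) {
    d <- r1[r1$phase == ph, ]
    base <- d$area_mm2[d$timepoint == "baseline"]
    h24 <- d$area_mm2[d$timepoint == "h24"]
    expect_gt(base, 0)
    expect_gt(h24, 0.5 * base)  # recovered, not abolished
  }
  # phase polarity of reported amplitudes
  expect_true(all(r1$peak_amplitude[r1$phase != "overshoot"] < 0))
  expect_true(all(r1$peak_amplitude[r1$phase == "overshoot"] > 0))
  a4 <- simulate_animal(study, "g4_a01")
  r4 <- quantify_animal(a4$blocks, a4$rois, animal = "g4_a01", group = 4)
  for (ph in unique(r4$phase)) {
    d <- r4[r4$phase == ph, ]
    expect_lt(d$area_px[d$timepoint == "h24"],
              0.3 * d$area_px[d$timepoint == "baseline"])
  }
  # missing timepoint / empty block errors
  broken <- a1$blocks
  broken$sparse$h24 <- NULL
  expect_error(quantify_animal(broken, a1$rois), "timepoints")
  broken2 <- a1$blocks
  broken2$condensed$h24 <- list()
  expect_error(quantify_animal(broken2, a1$rois), "empty block")
})

test_that("roi_set validates containment", {
  roi <- disc_mask(16, c(8, 8), 6)
  slit <- rect_mask(16, c(8, 8), 3, 3)
  expect_silent(roi_set(roi, slit))
  expect_error(roi_set(slit, roi), "contain")
  expect_error(roi_set(roi, matrix(FALSE, 16, 16)), "empty")
})
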