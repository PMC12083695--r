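test_that("segmentation recovers known infarct masks from synthetic slices", {
  tt <- ttc_truth(volume_mm3 = 12, edema_factor = 1)
  slices <- make_ttc_series(tt, seed = 2)
  gt <- attr(slices, "ground_truth")
  for (i in seq_along(slices)) {
    seg <- segment_slice(slices[[i]])
    expect_equal(sum(seg$infarct), gt$infarct_px[i])
    expect_equal(sum(seg$infarct_contra), 0)
  }
})

test_that("fully stained slices yield an empty infarct mask", {
  tt <- ttc_truth(volume_mm3 = 0)
  slices <- make_ttc_series(tt, seed = 1)
  segs <- lapply(slices, segment_slice)
  expect_equal(sum(vapply(segs, function(s) sum(s$infarct), numeric(1))), 0)
  res <- infarct_volume(slices, segs)
  expect_equal(res$raw_volume_mm3, 0)
  expect_equal(res$corrected_volume_mm3, 0)
})

test_that("exclusion mask removes surgical-site pixels from the infarct", {
  tt <- ttc_truth(volume_mm3 = 10, surgical_site = TRUE)
  slices <- make_ttc_series(tt, seed = 3)
  s3 <- slices[[3]]
  expect_false(is.null(s3$exclusion_mask))
  expect_gt(sum(s3$exclusion_mask), 0)
  seg_with <- segment_slice(s3)
  s3_no <- s3; s3_no$exclusion_mask <- NULL
  seg_without <- segment_slice(s3_no)
  expect_gt(sum(seg_without$infarct), sum(seg_with$infarct))
  expect_equal(sum(seg_with$infarct & s3$exclusion_mask), 0)
})

test_that("volumetry follows area x thickness and the edema ratio convention", {
  # hand-built segmentations: areas 10, 15, 5 mm2 at 2 mm thickness
  mk_seg <- function(inf_px, ipsi_px, contra_px) {
    inf <- matrix(FALSE, 50, 50); inf[seq_len(inf_px)] <- TRUE
    ti <- matrix(FALSE, 50, 50); ti[seq_len(ipsi_px)] <- TRUE
    tc <- matrix(FALSE, 50, 50); tc[seq_len(contra_px)] <- TRUE
    list(infarct = inf, tissue_ipsi = ti, tissue_contra = tc)
  }
  img <- array(0.5, dim = c(50, 50, 3))
  sl <- function() ttc_slice(img, mm_per_pixel = 0.1, thickness_mm = 2)
  slices <- list(sl(), sl(), sl())
  segs <- list(mk_seg(1000, 2000, 2000), mk_seg(1500, 2000, 2000),
               mk_seg(500, 2000, 2000))
  res <- infarct_volume(slices, segs)
  expect_equal(res$per_slice_area_mm2, c(10, 15, 5))
  expect_equal(res$raw_volume_mm3, 60)
  # equal hemispheres: corrected equals raw
  expect_equal(res$corrected_volume_mm3, res$raw_volume_mm3)
  # swollen ipsi 110 vs contra 100 with raw 22 -> corrected 20
  segs2 <- list(mk_seg(1100, 2750, 2500))
  res2 <- infarct_volume(list(sl()), segs2)
  expect_equal(res2$raw_volume_mm3, 22)
  expect_equal(res2$ipsi_hemisphere_volume_mm3, 55)
  expect_equal(res2$contra_hemisphere_volume_mm3, 50)
  expect_equal(res2$corrected_volume_mm3, 20)
  # indirect (Swanson-style) alternative
  res3 <- infarct_volume(list(sl()), segs2, method = "indirect")
  expect_equal(res3$corrected_volume_mm3, 50 - (55 - 22))
  expect_error(infarct_volume(list()), "at least one")
})

test_that("adding empty slices keeps infarct volume but grows hemispheres", {
  tt <- ttc_truth(volume_mm3 = 8)
  slices <- make_ttc_series(tt, seed = 4)
  res_a <- infarct_volume(slices)
  tt2 <- ttc_truth(volume_mm3 = 8, n_slices = 10)
  slices2 <- make_ttc_series(tt2, seed = 4)
  res_b <- infarct_volume(slices2)
  expect_equal(res_b$raw_volume_mm3, res_a$raw_volume_mm3)
  expect_gt(res_b$ipsi_hemisphere_volume_mm3,
            res_a$ipsi_hemisphere_volume_mm3)
})

test_that("pipeline corrected volume matches generator ground truth", {
  for (v in c(6, 20)) {
    tt <- ttc_truth(volume_mm3 = v, edema_factor = 1.08,
                    surgical_site = TRUE)
    slices <- make_ttc_series(tt, seed = 5)
    gt <- attr(slices, "ground_truth")
    res <- infarct_volume(slices)
    # raw recovers the drawn (edema-inflated) volume exactly
    expect_equal(res$raw_volume_mm3, gt$drawn_volume_mm3, tolerance = 1e-9)
    # corrected equals the generator-side corrected value
    expect_equal(res$corrected_volume_mm3, gt$corrected_volume_mm3,
                 tolerance = 1e-9)
    # and the intended volume within one pixel-layer per slice
    px_layer <- vapply(seq_along(slices), function(i) {
      seg <- segment_slice(slices[[i]])
      if (!any(seg$infarct)) return(0)
      # boundary pixels of the infarct mask
      m <- seg$infarct
      shifted <- m[c(1, seq_len(nrow(m) - 1)), ] & m[c(seq_len(nrow(m) - 1) + 1, nrow(m)), ] &
        m[, c(1, seq_len(ncol(m) - 1))] & m[, c(seq_len(ncol(m) - 1) + 1, ncol(m))]
      sum(m & !shifted)
    }, numeric(1))
    tol <- sum(px_layer) * tt$mm_per_pixel^2 * tt$thickness_mm
    expect_lt(abs(res$corrected_volume_mm3 - v), tol)
  }
})

test_that("midline falls back to the tissue centroid when unspecified", {
  tt <- ttc_truth(volume_mm3 = 0, edema_factor = 1)
  sl <- make_ttc_series(tt, seed = 1)[[4]]
  seg_manual <- segment_slice(sl)
  sl$midline_x <- NULL
  seg_auto <- segment_slice(sl)
  expect_equal(seg_auto$midline_x, seg_manual$midline_x, tolerance = 1)
  expect_equal(sum(seg_auto$tissue_ipsi), sum(seg_manual$tissue_ipsi),
               tolerance = 0.02)
})

test_that("otsu threshold agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  with_seed_local(13, {
    x <- c(rnorm(600, 0.3, 0.05), rnorm(400, 0.8, 0.05))
  })
  x <- pmin(pmax(x, 0), 1)
  ours <- isoistroke:::otsu_threshold(x)
  ref <- EBImage::otsu(matrix(x, 50, 20))
  expect_gt(ours, 0.4); expect_lt(ours, 0.7)
  agree <- mean((x > ours) == (x > ref))
  expect_gt(agree, 0.98)
})

test_that("slit regression recovers exact and simulated slopes", {
  d <- data.frame(slit_size_mm2 = c(1, 2, 3, 4),
                  corrected_volume_mm3 = c(3, 5, 7, 9))
  r <- slit_regression(d)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  expect_equal(unname(coef(r)), c(1, 2))
  expect_equal(unname(predict(r, data.frame(slit_size_mm2 = 5))), 11)
  # parameter recovery: true slope 3, noise sd 0.5, n = 8
  with_seed_local(17, {
    slit <- runif(8, 1, 6)
    vol <- 5 + 3 * slit + rnorm(8, sd = 0.5)
  })
  r2 <- slit_regression(data.frame(slit_size_mm2 = slit,
                                   corrected_volume_mm3 = vol))
  expect_lt(abs(r2$slope - 3), 2 * r2$slope_se)
  expect_lt(r2$p_value, 0.05)
  # degenerate designs
  expect_error(slit_regression(data.frame(slit_size_mm2 = rep(2, 5),
                                          corrected_volume_mm3 = 1:5)),
               "zero variance")
  expect_error(slit_regression(d[1:2, ]), "at least 3")
})
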