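# filled-ellipse mask on an h x w grid
ellipse_mask <- function(h, w, center, semi_r, semi_c) {
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - center[1]) / semi_r)^2 + ((c_ - center[2]) / semi_c)^2 <= 1
}

#' Ground truth for a synthetic TTC slice series
#'
#' Describes one brain's coronal slice set: slice count and thickness,
#' calibration, the intended (edema-free) infarct volume distributed over
#' the middle slices, the ipsilateral swelling factor and whether a small
#' surgical-site lesion is present. `make_ttc_series()` rasterizes it;
#' the actually drawn per-slice infarct pixel counts are retained in the
#' result as ground truth.
#'
#' @param volume_mm3 Intended edema-free infarct volume (0 for none).
#' @param n_slices Number of 2 mm coronal slices (default 8).
#' @param thickness_mm Slice thickness (mm).
#' @param mm_per_pixel Calibration of slice photographs (default 0.1).
#' @param edema_factor Ipsilateral area multiplier, >= 1.
#' @param surgical_site If `TRUE`, a small unstained lesion at the pMCAo
#'   surgical site is drawn (and masked out via the exclusion mask).
#' @param img_h,img_w Slice photograph dimensions (pixels).
#' @param spread `"focal"` (infarct confined to the barrel-field slices,
#'   groups 3-4) or `"extended"` (larger territory, the large-infarct
#'   group-5 outcome).
#' @return Object of class `ttc_truth`.
#' @export
ttc_truth <- function(volume_mm3 = 0, n_slices = 8L, thickness_mm = 2,
                      mm_per_pixel = 0.1, edema_factor = 1,
                      surgical_site = FALSE, img_h = 120L, img_w = 160L,
                      spread = c("focal", "extended")) {
  spread <- match.arg(spread)
  if (edema_factor < 1) stop("edema_factor must be >= 1")
  if (volume_mm3 < 0) stop("volume_mm3 must be >= 0")
  structure(list(
    volume_mm3 = volume_mm3, n_slices = as.integer(n_slices),
    thickness_mm = thickness_mm, mm_per_pixel = mm_per_pixel,
    edema_factor = edema_factor, surgical_site = surgical_site,
    img_h = as.integer(img_h), img_w = as.integer(img_w), spread = spread
  ), class = "ttc_truth")
}

# per-slice weights for distributing infarct area across slices
slice_weights <- function(truth) {
  w <- numeric(truth$n_slices)
  if (truth$spread == "focal") {
    idx <- intersect(4:7, seq_len(truth$n_slices))
    w[idx] <- c(0.2, 0.35, 0.3, 0.15)[seq_along(idx)]
  } else {
    idx <- intersect(2:8, seq_len(truth$n_slices))
    prof <- c(0.05, 0.12, 0.2, 0.25, 0.2, 0.12, 0.06)[seq_along(idx)]
    w[idx] <- prof
  }
  w / sum(w)
}

#' Rasterize a synthetic TTC slice series
#'
#' Draws each coronal slice as two half-ellipse hemispheres of red
#' TTC-stained tissue on a dark background. The ipsilateral (left)
#' hemisphere is dilated so its area is `edema_factor` times the
#' contralateral one, and the drawn infarct pixel area is likewise scaled
#' by `edema_factor`, so the edema-corrected pipeline volume recovers the
#' intended edema-free volume. Unstained infarct tissue is drawn
#' off-white; an optional surgical-site spot is drawn on slice 3 together
#' with its exclusion mask.
#'
#' @param truth A [ttc_truth()].
#' @param seed Integer seed (placement jitter).
#' @return List of [ttc_slice()] objects with attribute
#'   `ground_truth`: list with `infarct_px` (drawn per-slice counts,
#'   exclusion excluded), `drawn_volume_mm3` (raw, edema-inflated),
#'   `corrected_volume_mm3` (drawn volume divided by the drawn
#'   hemispheric area ratio) and `intended_volume_mm3`.
#' @export
make_ttc_series <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "ttc_truth"))
  h <- truth$img_h; w <- truth$img_w
  mid <- w / 2 + 0.5
  brain_sr <- 0.375 * h   # hemisphere semi-axes, pixels
  brain_sc <- 0.41 * w
  s <- sqrt(truth$edema_factor)
  px_area <- truth$mm_per_pixel^2
  weights <- slice_weights(truth)
  target_px <- truth$volume_mm3 / truth$thickness_mm * weights / px_area *
    truth$edema_factor
  jit <- with_seed(seed, stats::runif(2 * truth$n_slices, -2, 2))
  col_bg <- c(0.08, 0.08, 0.10)
  col_red <- c(0.78, 0.22, 0.20)
  col_white <- c(0.92, 0.90, 0.86)
  slices <- vector("list", truth$n_slices)
  infarct_px <- integer(truth$n_slices)
  ipsi_px <- integer(truth$n_slices)
  contra_px <- integer(truth$n_slices)
  for (i in seq_len(truth$n_slices)) {
    cy <- h / 2
    ipsi <- ellipse_mask(h, w, c(cy, mid), brain_sr * s, brain_sc * s) &
      matrix(seq_len(w), h, w, byrow = TRUE) <= floor(mid)
    contra <- ellipse_mask(h, w, c(cy, mid), brain_sr, brain_sc) &
      matrix(seq_len(w), h, w, byrow = TRUE) > floor(mid)
    inf_mask <- matrix(FALSE, h, w)
    if (target_px[i] > 0.5) {
      # elongated dorso-lateral ellipse of approximately the target area
      aspect <- 1.6
      sb <- sqrt(target_px[i] / (pi * aspect))
      sa <- aspect * sb
      ctr <- c(cy - 0.2 * h + jit[2 * i - 1], mid - 0.22 * w + jit[2 * i])
      inf_mask <- ellipse_mask(h, w, ctr, sb, sa) & ipsi
    }
    excl <- NULL
    if (truth$surgical_site && i == 3L) {
      site <- ellipse_mask(h, w, c(cy - 0.15 * h, mid - 0.3 * w), 3, 4) & ipsi
      excl <- site
      inf_mask <- inf_mask & !site
    } else site <- matrix(FALSE, h, w)
    img <- array(rep(col_bg, each = h * w), dim = c(h, w, 3))
    tissue <- ipsi | contra
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[tissue] <- col_red[ch]
      plane[inf_mask | site] <- col_white[ch]
      img[, , ch] <- plane
    }
    infarct_px[i] <- sum(inf_mask)
    ipsi_px[i] <- sum(ipsi)
    contra_px[i] <- sum(contra)
    slices[[i]] <- ttc_slice(img, truth$mm_per_pixel, truth$thickness_mm,
                             midline_x = floor(mid) + 0.5,
                             exclusion_mask = excl)
  }
  drawn <- sum(infarct_px) * px_area * truth$thickness_mm
  ratio <- sum(contra_px) / sum(ipsi_px)
  attr(slices, "ground_truth") <- list(
    infarct_px = infarct_px,
    drawn_volume_mm3 = drawn,
    corrected_volume_mm3 = drawn * ratio,
    intended_volume_mm3 = truth$volume_mm3,
    edema_factor = truth$edema_factor
  )
  slices
}
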