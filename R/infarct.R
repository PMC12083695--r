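#' TTC-stained coronal slice
#'
#' Wraps one photographed slice: RGB raster, spatial calibration, slice
#' thickness, the midline separating hemispheres and an optional
#' exclusion mask (e.g. superficial damage at the pMCAo surgical site,
#' which is excluded from infarct analysis).
#'
#' @param image Numeric array `height x width x 3`, values in `[0, 1]`.
#' @param mm_per_pixel Spatial calibration.
#' @param thickness_mm Slice thickness (default 2 mm).
#' @param midline_x Column coordinate of the vertical midline; columns
#'   `<= midline_x` are the ipsilateral (lesioned) hemisphere. If `NULL`
#'   it is estimated from the tissue centroid at segmentation time.
#' @param exclusion_mask Optional logical matrix removed from the infarct.
#' @return Object of class `ttc_slice`.
#' @export
ttc_slice <- function(image, mm_per_pixel, thickness_mm = 2,
                      midline_x = NULL, exclusion_mask = NULL) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be height x width x 3 RGB")
  if (thickness_mm <= 0) stop("thickness_mm must be > 0")
  if (!is.null(exclusion_mask) && !identical(dim(exclusion_mask), d[1:2]))
    stop("exclusion_mask must match image dimensions")
  structure(list(image = image, mm_per_pixel = mm_per_pixel,
                 thickness_mm = thickness_mm, midline_x = midline_x,
                 exclusion_mask = exclusion_mask),
            class = "ttc_slice")
}

# Otsu's histogram threshold (maximizing between-class variance)
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (diff(range(x)) == 0) return(x[1])
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  mids[which.max(sb2)]
}

#' Segment a TTC slice into tissue and infarct
#'
#' Tissue is separated from the dark background by an Otsu threshold on
#' luminance. Within the tissue, infarct (unstained white) pixels are
#' those whose red-channel dominance `R - (G + B) / 2` falls below
#' `red_margin` *and* whose lightness exceeds an Otsu cut on the tissue
#' lightness distribution; viable TTC-stained tissue is strongly
#' red-dominant. Exclusion-mask pixels are removed from the infarct.
#' Masks are split at the midline into ipsilateral and contralateral
#' hemispheres.
#'
#' @param slice A [ttc_slice()].
#' @param red_margin Red-dominance cut below which a bright pixel counts
#'   as unstained (default 0.1).
#' @return List: `tissue` (logical matrix), `infarct` (logical matrix,
#'   ipsilateral by construction), per-hemisphere tissue masks
#'   `tissue_ipsi` / `tissue_contra`, and the `midline_x` used.
#' @export
segment_slice <- function(slice, red_margin = 0.1) {
  stopifnot(inherits(slice, "ttc_slice"))
  img <- slice$image
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  tissue <- lum > otsu_threshold(lum)
  if (!any(tissue)) stop("no foreground tissue detected")
  dominance <- img[, , 1] - (img[, , 2] + img[, , 3]) / 2
  tl <- lum[tissue]
  light_cut <- if (length(unique(round(tl, 6))) > 1) otsu_threshold(tl) else Inf
  white <- tissue & dominance < red_margin & lum > light_cut
  # if lightness does not separate (uniform tissue), rely on dominance only
  if (!any(white)) white <- tissue & dominance < red_margin
  if (!is.null(slice$exclusion_mask)) white <- white & !slice$exclusion_mask
  midline_x <- slice$midline_x
  if (is.null(midline_x)) {
    cols <- col(tissue)[tissue]
    midline_x <- mean(cols)
  }
  ipsi <- col(tissue) <= midline_x
  list(tissue = tissue, infarct = white & ipsi,
       infarct_contra = white & !ipsi,
       tissue_ipsi = tissue & ipsi, tissue_contra = tissue & !ipsi,
       midline_x = midline_x)
}

#' Infarct volumetry with edema correction
#'
#' Per-slice infarct areas (pixel count times `mm_per_pixel^2`) are
#' multiplied by slice thickness and summed into a raw volume. The edema
#' correction multiplies the raw volume by the contralateral-to-
#' ipsilateral hemispheric volume ratio (`method = "ratio"`, the
#' default), removing the bias from ipsilateral swelling; the
#' Swanson-style indirect alternative
#' `V_contra - (V_ipsi - V_raw)` is available as `method = "indirect"`.
#'
#' @param slices List of [ttc_slice()] objects with consistent
#'   calibration.
#' @param segmentations Optional list of [segment_slice()] results (one
#'   per slice); computed if omitted.
#' @param method `"ratio"` or `"indirect"` edema correction.
#' @return Object of class `infarct_result`: `per_slice_area_mm2`,
#'   `raw_volume_mm3`, `ipsi_hemisphere_volume_mm3`,
#'   `contra_hemisphere_volume_mm3`, `corrected_volume_mm3`, `method`.
#' @export
infarct_volume <- function(slices, segmentations = NULL,
                           method = c("ratio", "indirect")) {
  method <- match.arg(method)
  if (length(slices) < 1) stop("need at least one slice")
  mpp <- vapply(slices, `[[`, numeric(1), "mm_per_pixel")
  if (diff(range(mpp)) > 1e-12)
    stop("mixed calibrations across slices")
  if (is.null(segmentations)) segmentations <- lapply(slices, segment_slice)
  px_area <- mpp[1]^2
  areas <- vapply(segmentations, function(s) sum(s$infarct) * px_area,
                  numeric(1))
  thick <- vapply(slices, `[[`, numeric(1), "thickness_mm")
  raw <- sum(areas * thick)
  ipsi <- sum(vapply(seq_along(slices), function(i)
    sum(segmentations[[i]]$tissue_ipsi) * px_area * thick[i], numeric(1)))
  contra <- sum(vapply(seq_along(slices), function(i)
    sum(segmentations[[i]]$tissue_contra) * px_area * thick[i], numeric(1)))
  corrected <- if (method == "ratio") raw * contra / ipsi
  else contra - (ipsi - raw)
  corrected <- max(corrected, 0)
  structure(list(
    per_slice_area_mm2 = areas, raw_volume_mm3 = raw,
    ipsi_hemisphere_volume_mm3 = ipsi,
    contra_hemisphere_volume_mm3 = contra,
    corrected_volume_mm3 = corrected, method = method
  ), class = "infarct_result")
}

#' @export
print.infarct_result <- function(x, ...) {
  cat(sprintf(
    "infarct_result: raw %.2f mm3, corrected %.2f mm3 (%s edema correction)\n",
    x$raw_volume_mm3, x$corrected_volume_mm3, x$method
  ))
  cat(sprintf("  hemispheres: ipsi %.1f mm3, contra %.1f mm3; %d slice(s)\n",
              x$ipsi_hemisphere_volume_mm3, x$contra_hemisphere_volume_mm3,
              length(x$per_slice_area_mm2)))
  invisible(x)
}

#' Regression of infarct volume on dura-slit size
#'
#' Ordinary least squares of edema-corrected infarct volume (mm3) on the
#' dura slit opening area (mm2), fitted per experimental group. The slit
#' opening controls the drug diffusion area and is expected to predict
#' infarct volume in the lidocaine-treated occluded groups.
#'
#' @param table `data.frame` with columns `slit_size_mm2`,
#'   `corrected_volume_mm3` and (if `groups` given) `group`.
#' @param groups Optional group id(s) to filter on.
#' @return Object of class `slit_regression` wrapping the `lm` fit, with
#'   `slope`, `intercept`, `r_squared`, `p_value` (two-sided, slope),
#'   `conf_int` (95% for the slope) and `n`.
#' @export
slit_regression <- function(table, groups = NULL) {
  if (!is.null(groups)) table <- table[table$group %in% groups, , drop = FALSE]
  ok <- is.finite(table$slit_size_mm2) & is.finite(table$corrected_volume_mm3)
  table <- table[ok, , drop = FALSE]
  if (nrow(table) < 3) stop("need at least 3 animals with finite values")
  if (stats::sd(table$slit_size_mm2) == 0)
    stop("zero variance in slit_size: regression undefined")
  fit <- stats::lm(corrected_volume_mm3 ~ slit_size_mm2, data = table)
  sm <- summary(fit)
  structure(list(
    fit = fit,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_se = sm$coefficients[2, 2],
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    conf_int = unname(stats::confint(fit)[2, ]),
    n = nrow(table), groups = groups
  ), class = "slit_regression")
}

#' @export
print.slit_regression <- function(x, ...) {
  cat(sprintf(
    "slit_regression%s: volume = %.3f + %.3f x slit (mm3 per mm2), n = %d\n",
    if (is.null(x$groups)) "" else paste0(" [group ",
                                          paste(x$groups, collapse = ","), "]"),
    x$intercept, x$slope, x$n
  ))
  cat(sprintf("  R2 = %.3f, slope p = %.3g, 95%% CI [%.3f, %.3f]\n",
              x$r_squared, x$p_value, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' @export
summary.slit_regression <- function(object, ...) summary(object$fit, ...)

#' @export
coef.slit_regression <- function(object, ...) stats::coef(object$fit)

#' @export
predict.slit_regression <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.slit_regression <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.slit_regression <- function(x, ...) {
  d <- x$fit$model
  graphics::plot(d$slit_size_mm2, d$corrected_volume_mm3,
                 xlab = "slit size (mm2)",
                 ylab = "corrected infarct volume (mm3)",
                 pch = 19, ...)
  graphics::abline(x$fit, lwd = 2)
  invisible(x)
}
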