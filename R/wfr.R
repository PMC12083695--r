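#' ROI set: analysis region and drug-slit footprint
#'
#' The analysis ROI is drawn around the skull-dura slit (in practice from
#' surface-vasculature landmarks); the slit mask is the footprint of the
#' dura opening through which the drug diffuses. The slit mask must be
#' contained in the analysis ROI.
#'
#' @param analysis_roi Logical matrix.
#' @param slit_mask Logical matrix, same dimensions, subset of
#'   `analysis_roi`.
#' @param provenance Free-text note on how the masks were defined.
#' @return Object of class `roi_set`.
#' @export
roi_set <- function(analysis_roi, slit_mask,
                    provenance = "unspecified") {
  if (!identical(dim(analysis_roi), dim(slit_mask)))
    stop("analysis_roi and slit_mask must share dimensions")
  if (!any(slit_mask)) stop("slit_mask is empty")
  if (any(slit_mask & !analysis_roi))
    stop("analysis_roi must contain slit_mask")
  structure(list(analysis_roi = analysis_roi, slit_mask = slit_mask,
                 provenance = provenance), class = "roi_set")
}

#' Areal extent of a phase at threshold
#'
#' Counts ROI pixels whose polarity-signed fractional change reaches the
#' phase threshold ("away from zero") on a smoothed ratio frame, and
#' converts the count to physical area.
#'
#' @param frame Smoothed dR/R matrix.
#' @param spec A [phase_spec()].
#' @param roi Logical matrix (non-empty).
#' @param mm_per_pixel Spatial calibration.
#' @return Object of class `wfr_extent`: `area_px`, `area_mm2`, `mask`
#'   (the suprathreshold pixels), `threshold`, `phase`.
#' @export
areal_extent <- function(frame, spec, roi, mm_per_pixel) {
  stopifnot(inherits(spec, "phase_spec"))
  if (!any(roi)) stop("roi is empty")
  mask <- spec$polarity * frame >= spec$threshold & roi
  mask[is.na(mask)] <- FALSE
  n <- sum(mask)
  structure(list(
    area_px = n, area_mm2 = n * mm_per_pixel^2, mask = mask,
    threshold = spec$threshold, phase = spec$phase
  ), class = "wfr_extent")
}

#' @export
print.wfr_extent <- function(x, ...) {
  cat(sprintf("wfr_extent (%s): %d px = %.4f mm2 at threshold %g dR/R\n",
              x$phase, x$area_px, x$area_mm2, x$threshold))
  invisible(x)
}

# extremal pixel of polarity-signed values inside a mask; ties broken by
# lowest (row, col) in raster order
extremal_pixel <- function(frame, mask, polarity) {
  idx <- which(mask & !is.na(frame))
  if (length(idx) == 0) return(NULL)
  score <- polarity * frame[idx]
  tied <- idx[score >= max(score) - 0]
  nr <- nrow(frame)
  rows <- (tied - 1L) %% nr + 1L
  cols <- (tied - 1L) %/% nr + 1L
  k <- order(rows, cols)[1]
  list(value = frame[tied[k]], pixel = c(rows[k], cols[k]))
}

#' Peak amplitude within the slit (sparse protocol)
#'
#' Returns the polarity-extremal fractional change over the intersection
#' of the suprathreshold extent mask and the skull-dura slit mask. When
#' the intersection is empty (e.g. an abolished representation), the
#' extremum over the slit mask alone is returned with `fallback = TRUE`,
#' so a blocked cortex yields a near-zero amplitude rather than a missing
#' value.
#'
#' @param frame Smoothed dR/R matrix.
#' @param extent_mask Logical matrix (from [areal_extent()]).
#' @param slit_mask Logical matrix, non-empty.
#' @param polarity -1 for dip phases, +1 for the overshoot.
#' @return List: `value` (signed dR/R), `pixel` `(row, col)`, `fallback`.
#' @export
peak_amplitude_sparse <- function(frame, extent_mask, slit_mask,
                                  polarity = -1) {
  if (!any(slit_mask)) stop("slit_mask is empty")
  hit <- extremal_pixel(frame, extent_mask & slit_mask, polarity)
  if (is.null(hit)) {
    hit <- extremal_pixel(frame, slit_mask, polarity)
    hit$fallback <- TRUE
  } else hit$fallback <- FALSE
  hit
}

#' Paired peak amplitudes at a fixed pixel (condensed protocol)
#'
#' The peak pixel is chosen as the baseline extremum inside the drug
#' diffusion area; both the baseline and 24 h amplitudes are read at that
#' same pixel, so the pair is directly comparable.
#'
#' @param baseline_frame,h24_frame Co-registered smoothed dR/R matrices.
#' @param slit_mask Logical matrix, non-empty.
#' @param polarity Phase polarity (-1: the condensed dip).
#' @return List: `baseline`, `h24` (signed dR/R), `pixel`.
#' @export
peak_amplitude_condensed <- function(baseline_frame, h24_frame, slit_mask,
                                     polarity = -1) {
  if (!identical(dim(baseline_frame), dim(h24_frame)))
    stop("frames are not co-registered (shape mismatch)")
  if (!any(slit_mask)) stop("slit_mask is empty")
  hit <- extremal_pixel(baseline_frame, slit_mask, polarity)
  list(baseline = hit$value,
       h24 = h24_frame[hit$pixel[1], hit$pixel[2]],
       pixel = hit$pixel)
}

#' Quantify one animal's whisker functional representation
#'
#' Runs the full per-animal analysis: trial-averages each block, selects
#' the maximum-extent frame per sparse phase (initial dip, overshoot) and
#' the fixed 0.5-1.0 s condensed frame, and scores areal extent and peak
#' amplitude inside the ROI/slit. Returns one tidy row per
#' (timepoint, protocol, phase).
#'
#' @param blocks Nested list:
#'   `blocks$sparse$baseline`, `blocks$sparse$h24`,
#'   `blocks$condensed$baseline`, `blocks$condensed$h24`, each a list of
#'   raw [trial_stack()]s (protocols may be omitted; missing timepoints
#'   are an error).
#' @param rois A [roi_set()].
#' @param animal,group Identifiers copied into the output rows.
#' @param half_width Smoothing kernel half-width (px).
#' @param thresholds Named list overriding phase thresholds
#'   (`initial_dip`, `overshoot`, `condensed_dip`).
#' @return `data.frame` with columns animal, group, timepoint, protocol,
#'   phase, frame_index, frame_time_s, area_px, area_mm2, peak_amplitude,
#'   peak_row, peak_col, peak_fallback, threshold, half_width,
#'   mm_per_pixel.
#' @export
quantify_animal <- function(blocks, rois, animal = NA, group = NA,
                            half_width = 5, thresholds = list()) {
  stopifnot(inherits(rois, "roi_set"))
  protocols <- intersect(c("sparse", "condensed"), names(blocks))
  if (length(protocols) == 0) stop("blocks must contain sparse and/or condensed data")
  rows <- list()
  for (proto in protocols) {
    pb <- blocks[[proto]]
    if (is.null(pb$baseline) || is.null(pb$h24))
      stop(sprintf("%s protocol: both timepoints must be present", proto))
    if (length(pb$baseline) == 0 || length(pb$h24) == 0)
      stop(sprintf("%s protocol: empty block list", proto))
    series <- lapply(pb[c("baseline", "h24")], block_to_ratio)
    if (proto == "sparse") {
      for (ph in c("initial_dip", "overshoot")) {
        spec <- phase_spec(ph, threshold = thresholds[[ph]])
        for (tp in c("baseline", "h24")) {
          sel <- withCallingHandlers(
            select_phase_frame(series[[tp]], spec, rois$analysis_roi,
                               half_width, details = TRUE),
            warning = function(w) invokeRestart("muffleWarning")
          )
          ext <- areal_extent(sel$smoothed, spec, rois$analysis_roi,
                              series[[tp]]$mm_per_pixel)
          pk <- peak_amplitude_sparse(sel$smoothed, ext$mask,
                                      rois$slit_mask, spec$polarity)
          rows[[length(rows) + 1L]] <- data.frame(
            animal = animal, group = group, timepoint = tp,
            protocol = proto, phase = ph,
            frame_index = sel$fallback_index,
            frame_time_s = series[[tp]]$times_s[sel$fallback_index],
            area_px = ext$area_px, area_mm2 = ext$area_mm2,
            peak_amplitude = pk$value,
            peak_row = pk$pixel[1], peak_col = pk$pixel[2],
            peak_fallback = pk$fallback, threshold = spec$threshold,
            half_width = half_width,
            mm_per_pixel = series[[tp]]$mm_per_pixel
          )
        }
      }
    } else {
      spec <- phase_spec("condensed_dip",
                         threshold = thresholds[["condensed_dip"]])
      idx <- vapply(series, select_condensed_frame, integer(1))
      sm <- lapply(c("baseline", "h24"), function(tp)
        smooth_frame(series[[tp]]$fc[, , idx[[tp]]], half_width))
      names(sm) <- c("baseline", "h24")
      pair <- peak_amplitude_condensed(sm$baseline, sm$h24,
                                       rois$slit_mask, spec$polarity)
      for (tp in c("baseline", "h24")) {
        ext <- areal_extent(sm[[tp]], spec, rois$analysis_roi,
                            series[[tp]]$mm_per_pixel)
        rows[[length(rows) + 1L]] <- data.frame(
          animal = animal, group = group, timepoint = tp,
          protocol = proto, phase = "condensed_dip",
          frame_index = idx[[tp]],
          frame_time_s = series[[tp]]$times_s[idx[[tp]]],
          area_px = ext$area_px, area_mm2 = ext$area_mm2,
          peak_amplitude = if (tp == "baseline") pair$baseline else pair$h24,
          peak_row = pair$pixel[1], peak_col = pair$pixel[2],
          peak_fallback = FALSE, threshold = spec$threshold,
          half_width = half_width,
          mm_per_pixel = series[[tp]]$mm_per_pixel
        )
      }
    }
  }
  do.call(rbind, rows)
}
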