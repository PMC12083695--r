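#' Sum raw frames into analysis frames
#'
#' Sums consecutive groups of `factor` raw frames (100 ms by default) into
#' analysis frames (500 ms) to improve signal-to-noise. A trailing
#' remainder that does not fill a full group is dropped with a warning.
#' The onset frame index is remapped to the analysis frame containing the
#' first stimulus frame.
#'
#' @param stack A [trial_stack()].
#' @param factor Number of raw frames per analysis frame (default 5).
#' @return A [trial_stack()] at `factor * frame_ms` resolution.
#' @examples
#' st <- make_trial_stack(isoi_protocol("condensed"),
#'                        signal_truth(amplitudes = c(dip = 0),
#'                                     peak_times = c(dip = 2),
#'                                     half_widths = c(dip = 1),
#'                                     img_px = 16))
#' dim(sum_to_analysis_frames(st)$frames)[3]  # 45 raw -> 9 analysis frames
#' @export
sum_to_analysis_frames <- function(stack, factor = 5L) {
  stopifnot(inherits(stack, "trial_stack"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  d <- dim(stack$frames)
  n_out <- d[3] %/% factor
  if (n_out < 1) stop("stack has fewer frames than one analysis frame")
  rem <- d[3] - n_out * factor
  if (rem > 0)
    warning(sprintf("dropping %d trailing raw frame(s) not filling an analysis frame", rem))
  kept <- stack$frames[, , seq_len(n_out * factor), drop = FALSE]
  dim(kept) <- c(d[1] * d[2], factor, n_out)
  out <- apply(kept, 3, rowSums)
  dim(out) <- c(d[1], d[2], n_out)
  res <- trial_stack(
    out, stack$frame_ms * factor,
    onset_frame = (stack$onset_frame - 1L) %/% factor + 1L,
    mm_per_pixel = stack$mm_per_pixel, protocol = stack$protocol,
    meta = c(stack$meta, list(sum_factor = factor))
  )
  res$saturate_level <- 65535 * res$frame_ms / 100
  res
}

#' Fractional-change (dR/R) ratio series
#'
#' Divides each analysis frame from stimulus onset onwards by the single
#' analysis frame collected immediately before onset and subtracts 1, so
#' positive values are brighter than the pre-stimulus baseline and
#' negative values darker. Pixels at or above the 16-bit saturation level
#' in the reference or any post frame are flagged and set to `NA` so they
#' are excluded from downstream statistics.
#'
#' @param stack A [trial_stack()] at analysis (500 ms) resolution.
#' @return An object of class `ratio_series`: list with `fc` (array
#'   `height x width x n`, dR/R), `times_s` (frame mid-times relative to
#'   onset, 0.5 s spacing), `n_trials_averaged`, `mm_per_pixel`,
#'   `saturated` (logical matrix) and `provenance` (reference frame index,
#'   frame duration).
#' @export
compute_ratio_series <- function(stack) {
  stopifnot(inherits(stack, "trial_stack"))
  if (stack$onset_frame < 2)
    stop("onset_frame must be >= 2 so a pre-stimulus reference frame exists")
  ref <- stack$frames[, , stack$onset_frame - 1L]
  if (any(ref == 0)) {
    bad <- which(ref == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero pixel in reference frame at (row %d, col %d)",
                 bad[1], bad[2]))
  }
  idx <- stack$onset_frame:dim(stack$frames)[3]
  sat <- ref >= stack$saturate_level
  fc <- array(NA_real_, dim = c(dim(ref), length(idx)))
  for (k in seq_along(idx)) {
    fr <- stack$frames[, , idx[k]]
    sat <- sat | fr >= stack$saturate_level
    fc[, , k] <- fr / ref - 1
  }
  if (any(sat)) {
    warning(sprintf("%d saturated pixel(s) flagged and excluded", sum(sat)))
    fc[array(sat, dim = dim(fc))] <- NA_real_
  }
  dt <- stack$frame_ms / 1000
  structure(list(
    fc = fc,
    times_s = (seq_along(idx) - 0.5) * dt,
    n_trials_averaged = 1L,
    mm_per_pixel = stack$mm_per_pixel,
    saturated = sat,
    provenance = list(reference_frame = stack$onset_frame - 1L,
                      frame_ms = stack$frame_ms,
                      protocol = stack$protocol)
  ), class = "ratio_series")
}

#' @export
print.ratio_series <- function(x, ...) {
  d <- dim(x$fc)
  cat(sprintf(
    "ratio_series: %d x %d px, %d frames (%.2f-%.2f s post-onset), %d trial(s) averaged\n",
    d[1], d[2], d[3], min(x$times_s), max(x$times_s), x$n_trials_averaged
  ))
  invisible(x)
}

#' Average ratio series across trials
#'
#' Pixelwise mean of fractional-change frames across a block of trials.
#' All series must share shape, timing and calibration. `NA` pixels
#' (saturation flags) propagate.
#'
#' @param series_list List of `ratio_series` objects.
#' @return A `ratio_series` with `n_trials_averaged` set.
#' @export
average_trials <- function(series_list) {
  if (length(series_list) < 1) stop("series_list must be non-empty")
  ref <- series_list[[1]]
  for (s in series_list[-1]) {
    if (!identical(dim(s$fc), dim(ref$fc)) ||
        !isTRUE(all.equal(s$times_s, ref$times_s)) ||
        !isTRUE(all.equal(s$mm_per_pixel, ref$mm_per_pixel)))
      stop("all series must share shape, timing and calibration")
  }
  acc <- Reduce(`+`, lapply(series_list, `[[`, "fc"))
  out <- ref
  out$fc <- acc / length(series_list)
  out$n_trials_averaged <- sum(vapply(series_list, `[[`, integer(1),
                                      "n_trials_averaged"))
  out$saturated <- Reduce(`|`, lapply(series_list, `[[`, "saturated"))
  out
}

#' Trial-average a block of raw stacks into a ratio series
#'
#' Convenience wrapper: sums each raw trial to analysis frames, computes
#' its ratio series and averages across trials.
#'
#' @param block List of raw [trial_stack()] objects (100 ms frames).
#' @param factor Summation factor (default 5).
#' @return A trial-averaged `ratio_series`.
#' @export
block_to_ratio <- function(block, factor = 5L) {
  average_trials(lapply(block, function(st)
    compute_ratio_series(sum_to_analysis_frames(st, factor))))
}
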