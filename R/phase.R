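#' Phase specification for areal-extent analysis
#'
#' Bundles the polarity, dR/R threshold and post-onset search window used
#' to score one intrinsic-signal phase. Defaults follow the study
#' conventions: initial dip at threshold 1.75e-4 (negative polarity),
#' overshoot at 3.5e-4 (positive), condensed-protocol dip at 2.5e-4
#' (negative, fixed 0.5-1.0 s frame). Sparse-phase windows are limited to
#' the first 7 s of data acquisition.
#'
#' @param phase `"initial_dip"`, `"overshoot"` or `"condensed_dip"`.
#' @param threshold dR/R threshold magnitude (> 0); default per phase.
#' @param window Search window (s post-onset), `c(from, to)`; frames whose
#'   mid-time falls in `[from, to)` are candidates.
#' @return Object of class `phase_spec` with fields `phase`, `polarity`
#'   (-1 dip, +1 overshoot), `threshold`, `window`.
#' @export
phase_spec <- function(phase = c("initial_dip", "overshoot", "condensed_dip"),
                       threshold = NULL, window = NULL) {
  phase <- match.arg(phase)
  defaults <- list(
    initial_dip   = list(polarity = -1, threshold = 1.75e-4, window = c(0, 7)),
    overshoot     = list(polarity = +1, threshold = 3.5e-4,  window = c(0, 7)),
    condensed_dip = list(polarity = -1, threshold = 2.5e-4,  window = c(0.5, 1))
  )[[phase]]
  if (is.null(threshold)) threshold <- defaults$threshold
  if (is.null(window)) window <- defaults$window
  if (threshold <= 0) stop("threshold must be > 0")
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(from, to) with to > from")
  structure(list(phase = phase, polarity = defaults$polarity,
                 threshold = threshold, window = window),
            class = "phase_spec")
}

#' @export
print.phase_spec <- function(x, ...) {
  cat(sprintf("phase_spec: %s (polarity %+d), threshold %g dR/R, window [%g, %g) s\n",
              x$phase, x$polarity, x$threshold, x$window[1], x$window[2]))
  invisible(x)
}

#' Select the maximum-areal-extent frame for a signal phase
#'
#' Smooths every candidate frame in the phase's search window and returns
#' the index (into the ratio series) of the frame with the largest count
#' of suprathreshold pixels (polarity-signed) inside the ROI. Ties are
#' broken in favour of the earliest frame. If no frame has any
#' suprathreshold pixel, `NA` is returned with a warning ("no
#' suprathreshold activity") rather than silently reporting frame 1.
#'
#' @param series A `ratio_series` (trial-averaged).
#' @param spec A [phase_spec()].
#' @param roi Logical matrix, analysis region of interest.
#' @param half_width Smoothing kernel half-width (px), see
#'   [smooth_frame()].
#' @param details If `TRUE`, return a list with the chosen index, the
#'   smoothed chosen frame and per-candidate suprathreshold counts.
#' @return Frame index (or `NA`), with attribute `counts`; or a list when
#'   `details = TRUE`.
#' @export
select_phase_frame <- function(series, spec, roi, half_width = 5,
                               details = FALSE) {
  stopifnot(inherits(series, "ratio_series"), inherits(spec, "phase_spec"))
  cand <- which(series$times_s >= spec$window[1] &
                  series$times_s < spec$window[2])
  if (length(cand) == 0) stop("empty search window for this series")
  counts <- integer(length(cand))
  smoothed <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    sm <- smooth_frame(series$fc[, , cand[i]], half_width)
    smoothed[[i]] <- sm
    counts[i] <- sum(spec$polarity * sm >= spec$threshold & roi, na.rm = TRUE)
  }
  if (all(counts == 0)) {
    warning(sprintf("no suprathreshold activity for phase %s", spec$phase))
    idx <- NA_integer_
    best <- which.max(-abs(series$times_s[cand] - mean(spec$window)))
  } else {
    best <- which.max(counts)  # which.max takes the earliest on ties
    idx <- cand[best]
  }
  if (details)
    return(list(index = idx, candidates = cand, counts = counts,
                smoothed = smoothed[[best]],
                fallback_index = cand[best]))
  structure(idx, counts = counts)
}

#' Select the condensed-protocol analysis frame
#'
#' The condensed protocol always scores the 500 ms ratio frame spanning
#' 0.5-1.0 s after stimulus delivery, independent of content.
#'
#' @param series A `ratio_series` covering at least 1.0 s post-onset.
#' @return Frame index of the 0.5-1.0 s frame.
#' @export
select_condensed_frame <- function(series) {
  stopifnot(inherits(series, "ratio_series"))
  dt <- diff(series$times_s[1:2])
  idx <- which(abs(series$times_s - 0.75) < dt / 4)
  last_end <- max(series$times_s) + dt / 2
  if (length(idx) != 1 || last_end < 1.0 - 1e-9)
    stop("series too short: must cover the 0.5-1.0 s post-stimulus window")
  idx
}
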