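#' Ground truth for the evoked intrinsic signal of one animal/timepoint
#'
#' Describes the triphasic fractional-change (dR/R) signal carried by
#' synthetic trial stacks: per-phase amplitudes, raised-cosine temporal
#' lobes, a 2-D Gaussian spatial profile, frame noise, a smooth baseline
#' reflectance field with static dark vessel streaks, and an optional block
#' mask where the signal is abolished (emulating local anaesthetic
#' diffusion).
#'
#' Amplitudes are in fractional-change units relative to the pre-stimulus
#' baseline: the initial dip and undershoot darken the cortex (negative),
#' the overshoot brightens it (positive). Defaults put the dip peak at
#' 2.5 s and the overshoot peak at 5 s post-onset, inside the first 7 s
#' analysed for the sparse protocol.
#'
#' @param amplitudes Named numeric, dR/R per phase. Any subset of
#'   `c(dip =, overshoot =, undershoot =)`. Dip/undershoot must be <= 0,
#'   overshoot >= 0, magnitudes <= 1e-2.
#' @param peak_times Named numeric, seconds post-onset of each lobe peak.
#'   Must be ordered dip < overshoot < undershoot.
#' @param half_widths Named numeric, half-duration (s) of each raised-cosine
#'   lobe; lobes must not start before stimulus onset.
#' @param img_px Image side length in pixels (square field of view).
#' @param mm_per_pixel Spatial calibration; defaults to a 7 mm field of
#'   view (`7 / img_px`).
#' @param center Blob centre `(row, col)` in pixels; default image centre.
#' @param sigma_px Spatial Gaussian s.d. in pixels; default `0.55 mm`
#'   converted to pixels.
#' @param noise_sd Fractional (dR/R) noise s.d. per pixel per 100 ms frame.
#' @param baseline_mean Mean baseline reflectance in camera counts.
#' @param n_vessels Number of static dark vessel streaks in the baseline.
#' @param field_seed Seed for the (static) baseline field and vessels.
#' @param block_mask Optional logical matrix (`img_px x img_px`); the evoked
#'   signal is multiplied by `block_gain` where `TRUE`.
#' @param block_gain Signal gain inside `block_mask`, in `[0, 1]`:
#'   0 abolishes the representation there (full pharmacological block),
#'   intermediate values model partial functional recovery.
#' @return An object of class `signal_truth`.
#' @seealso [signal_kernel()], [make_trial_stack()]
#' @export
signal_truth <- function(amplitudes = c(dip = -7e-4, overshoot = 1e-3,
                                        undershoot = -4e-4),
                         peak_times = c(dip = 2.5, overshoot = 5,
                                        undershoot = 9),
                         half_widths = c(dip = 2, overshoot = 2.5,
                                         undershoot = 2.5),
                         img_px = 128L,
                         mm_per_pixel = 7 / img_px,
                         center = NULL,
                         sigma_px = 0.55 / mm_per_pixel,
                         noise_sd = 0,
                         baseline_mean = 10000,
                         n_vessels = 4L,
                         field_seed = 1L,
                         block_mask = NULL,
                         block_gain = 0) {
  phases <- names(amplitudes)
  if (is.null(phases) || !all(phases %in% c("dip", "overshoot", "undershoot")))
    stop("amplitudes must be named with phases dip/overshoot/undershoot")
  if (!all(phases %in% names(peak_times)) ||
      !all(phases %in% names(half_widths)))
    stop("peak_times and half_widths must cover every amplitude phase")
  peak_times <- peak_times[phases]
  half_widths <- half_widths[phases]
  if (any(abs(amplitudes) > 1e-2))
    stop("phase amplitudes must be within the physiological range |A| <= 1e-2")
  if ("dip" %in% phases && amplitudes[["dip"]] > 0)
    stop("dip amplitude must be <= 0 (dark relative to baseline)")
  if ("overshoot" %in% phases && amplitudes[["overshoot"]] < 0)
    stop("overshoot amplitude must be >= 0 (bright relative to baseline)")
  if ("undershoot" %in% phases && amplitudes[["undershoot"]] > 0)
    stop("undershoot amplitude must be <= 0")
  ord <- c("dip", "overshoot", "undershoot")
  present <- ord[ord %in% phases]
  if (length(present) > 1 && is.unsorted(peak_times[present], strictly = TRUE))
    stop("phase peak times must be ordered dip < overshoot < undershoot")
  if (any(peak_times - half_widths < -1e-9))
    stop("temporal lobes must not start before stimulus onset")
  if (baseline_mean <= 0) stop("baseline_mean must be positive")
  img_px <- as.integer(img_px)
  if (is.null(center)) center <- c((img_px + 1) / 2, (img_px + 1) / 2)
  if (!is.null(block_mask)) {
    if (!is.logical(block_mask) ||
        !identical(dim(block_mask), c(img_px, img_px)))
      stop("block_mask must be a logical img_px x img_px matrix (within image bounds)")
  }
  if (block_gain < 0 || block_gain > 1) stop("block_gain must be in [0, 1]")
  structure(list(
    amplitudes = amplitudes, peak_times = peak_times,
    half_widths = half_widths, img_px = img_px,
    mm_per_pixel = mm_per_pixel, center = center, sigma_px = sigma_px,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    n_vessels = as.integer(n_vessels), field_seed = as.integer(field_seed),
    block_mask = block_mask, block_gain = block_gain
  ), class = "signal_truth")
}

#' Ground truth preset for the condensed protocol
#'
#' The condensed protocol shows a single growing initial dip; this preset
#' carries only a dip lobe, peaking at 1.5 s with a 1.5 s half-width, so
#' the scored 0.5-1.0 s analysis frame sees a rising suprathreshold dip.
#' The default amplitude is stronger than the sparse dip: without the
#' reperfusion overshoot the deoxyhemoglobin darkening keeps
#' accumulating through the short trial.
#'
#' @inheritParams signal_truth
#' @param dip_amplitude dR/R of the dip lobe (negative).
#' @param ... Passed to [signal_truth()].
#' @return A `signal_truth` object with a single dip phase.
#' @export
condensed_truth <- function(dip_amplitude = -1.4e-3, ...) {
  signal_truth(
    amplitudes = c(dip = dip_amplitude),
    peak_times = c(dip = 1.5), half_widths = c(dip = 1.5), ...
  )
}

#' @export
print.signal_truth <- function(x, ...) {
  cat(sprintf(
    "signal_truth: %d x %d px (%.4f mm/px), blob sigma %.1f px, noise sd %g\n",
    x$img_px, x$img_px, x$mm_per_pixel, x$sigma_px, x$noise_sd
  ))
  for (p in names(x$amplitudes))
    cat(sprintf("  %-10s A = %+.2e dR/R, peak %.2f s, half-width %.2f s\n",
                p, x$amplitudes[[p]], x$peak_times[[p]], x$half_widths[[p]]))
  if (!is.null(x$block_mask))
    cat(sprintf("  signal x %g in %d blocked px\n", x$block_gain,
                sum(x$block_mask)))
  invisible(x)
}

#' Temporal kernel of the ground-truth signal
#'
#' Evaluates the summed raised-cosine lobes at times `t` (seconds relative
#' to stimulus onset), in dR/R units at the blob centre. This is the
#' generating kernel used by [make_trial_stack()]; noise-free recovery
#' checks compare pipeline output against it directly.
#'
#' @param truth A [signal_truth()] object.
#' @param t Numeric vector of times (s, relative to stimulus onset).
#' @return Numeric vector, fractional change at the blob centre.
#' @export
signal_kernel <- function(truth, t) {
  out <- numeric(length(t))
  for (p in names(truth$amplitudes)) {
    pk <- truth$peak_times[[p]]
    hw <- truth$half_widths[[p]]
    inside <- abs(t - pk) < hw
    out[inside] <- out[inside] +
      truth$amplitudes[[p]] * 0.5 * (1 + cos(pi * (t[inside] - pk) / hw))
  }
  out
}

# 2-D Gaussian spatial profile, 1 at the centre
spatial_profile <- function(truth) {
  n <- truth$img_px
  r <- matrix(seq_len(n), n, n)
  c_ <- t(r)
  exp(-((r - truth$center[1])^2 + (c_ - truth$center[2])^2) /
        (2 * truth$sigma_px^2))
}

# Static baseline reflectance field: smooth low-frequency modulation of
# baseline_mean plus dark vessel streaks. Deterministic given field_seed.
baseline_field <- function(truth) {
  n <- truth$img_px
  with_seed(truth$field_seed, {
    x <- seq(0, 1, length.out = n)
    field <- matrix(1, n, n)
    for (k in 1:3) {
      fx <- stats::runif(1, 0.5, 2.5)
      fy <- stats::runif(1, 0.5, 2.5)
      ph <- stats::runif(2, 0, 2 * pi)
      field <- field + (0.05 / k) * outer(
        cos(2 * pi * fx * x + ph[1]),
        cos(2 * pi * fy * x + ph[2])
      )
    }
    for (v in seq_len(truth$n_vessels)) {
      p0 <- stats::runif(2, 1, n)
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, n / 2, 1.5 * n)
      depth <- stats::runif(1, 0.10, 0.20)
      ts <- seq(0, 1, length.out = ceiling(2 * len))
      rr <- round(p0[1] + ts * len * sin(ang))
      cc <- round(p0[2] + ts * len * cos(ang))
      keep <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      field[cbind(rr[keep], cc[keep])] <-
        field[cbind(rr[keep], cc[keep])] * (1 - depth)
    }
    truth$baseline_mean * field
  })
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  )
  set.seed(seed)
  code
}

#' Circular mask helper
#'
#' @param img_px Image side length (pixels).
#' @param center `(row, col)` centre.
#' @param radius Radius in pixels.
#' @return Logical `img_px x img_px` matrix.
#' @export
disc_mask <- function(img_px, center, radius) {
  r <- matrix(seq_len(img_px), img_px, img_px)
  c_ <- t(r)
  (r - center[1])^2 + (c_ - center[2])^2 <= radius^2
}

#' Rectangular mask helper
#'
#' @param img_px Image side length (pixels).
#' @param center `(row, col)` centre.
#' @param height,width Extent in pixels.
#' @return Logical `img_px x img_px` matrix.
#' @export
rect_mask <- function(img_px, center, height, width) {
  r <- matrix(seq_len(img_px), img_px, img_px)
  c_ <- t(r)
  abs(r - center[1]) <= height / 2 & abs(c_ - center[2]) <= width / 2
}
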