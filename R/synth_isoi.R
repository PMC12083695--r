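#' Construct a trial stack object
#'
#' Container for one trial's frame sequence with timing and spatial
#' calibration. Frames are stored as a `height x width x time` numeric
#' array of camera counts; values must be non-negative and representable
#' on the 16-bit scale used at acquisition/export.
#'
#' @param frames Numeric array `height x width x n_frames` of counts.
#' @param frame_ms Frame duration in milliseconds.
#' @param onset_frame 1-based index of the first stimulus frame.
#' @param mm_per_pixel Spatial calibration (mm per pixel).
#' @param protocol Protocol name (`"sparse"`/`"condensed"`) or `NA`.
#' @param meta Optional list of provenance metadata.
#' @return Object of class `trial_stack`.
#' @export
trial_stack <- function(frames, frame_ms, onset_frame, mm_per_pixel,
                        protocol = NA_character_, meta = list()) {
  if (length(dim(frames)) != 3) stop("frames must be a 3-D array")
  if (any(frames < 0)) stop("all intensities must be >= 0")
  onset_frame <- as.integer(onset_frame)
  if (onset_frame < 2 || onset_frame > dim(frames)[3])
    stop("onset_frame must leave at least one pre-stimulus frame")
  structure(list(
    frames = frames, frame_ms = frame_ms, onset_frame = onset_frame,
    mm_per_pixel = mm_per_pixel, protocol = protocol,
    saturate_level = 65535 * frame_ms / 100, meta = meta
  ), class = "trial_stack")
}

#' @export
print.trial_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "trial_stack: %d x %d px, %d frames @ %g ms (onset frame %d), %.4f mm/px%s\n",
    d[1], d[2], d[3], x$frame_ms, x$onset_frame, x$mm_per_pixel,
    if (is.na(x$protocol)) "" else paste0(", ", x$protocol, " protocol")
  ))
  invisible(x)
}

# mid-times (s, relative to stimulus onset) of each frame in a stack;
# frame k spans [(k - onset) * dt, (k - onset + 1) * dt)
frame_mid_times <- function(stack) {
  dt <- stack$frame_ms / 1000
  (seq_len(dim(stack$frames)[3]) - stack$onset_frame + 0.5) * dt
}

#' Simulate one raw ISOI trial
#'
#' Generates a 100 ms frame stack spanning the protocol's pre/stim/post
#' windows. The expected pixel value is
#' `baseline(x, y) * (1 + FC(t) * G(x, y))` where `FC` is the triphasic
#' temporal kernel ([signal_kernel()]) evaluated at the frame mid-time and
#' `G` the 2-D Gaussian spatial profile (zeroed inside the truth's
#' `block_mask`); zero-mean Gaussian noise of s.d.
#' `noise_sd * baseline` is added per frame. Frames are kept as floats;
#' quantization to 16-bit integers happens only on TIFF export
#' ([write_trial_stack()]).
#'
#' @param protocol An [isoi_protocol()].
#' @param truth A [signal_truth()].
#' @param seed Integer seed; output is deterministic given
#'   `(protocol, truth, seed)`.
#' @return A [trial_stack()] at 100 ms resolution.
#' @export
make_trial_stack <- function(protocol, truth, seed = 1L) {
  stopifnot(inherits(protocol, "isoi_protocol"), inherits(truth, "signal_truth"))
  n <- truth$img_px
  nt <- n_raw_frames(protocol)
  onset <- raw_onset_frame(protocol)
  dt <- protocol$frame_ms_raw / 1000
  t_mid <- (seq_len(nt) - onset + 0.5) * dt
  kern <- signal_kernel(truth, t_mid)
  g <- spatial_profile(truth)
  if (!is.null(truth$block_mask))
    g[truth$block_mask] <- g[truth$block_mask] * truth$block_gain
  base <- baseline_field(truth)
  frames <- array(base, dim = c(n, n, nt))
  for (k in seq_len(nt)) {
    if (kern[k] != 0)
      frames[, , k] <- frames[, , k] * (1 + kern[k] * g)
  }
  if (truth$noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(frames), sd = truth$noise_sd))
    frames <- frames * (1 + array(noise, dim = dim(frames)))
    frames[frames < 0] <- 0
  }
  trial_stack(
    frames, protocol$frame_ms_raw, onset, truth$mm_per_pixel,
    protocol = protocol$name,
    meta = list(seed = seed, trial_s_nominal = protocol$trial_s_nominal)
  )
}

#' Simulate a block of trials
#'
#' Per-trial seeds are drawn deterministically from the master seed, so a
#' block is reproducible as a whole while trials are independent.
#'
#' @inheritParams make_trial_stack
#' @param n_trials Number of trials (>= 1); defaults to the protocol's
#'   block size (64 sparse / 40 condensed).
#' @return List of [trial_stack()] objects.
#' @export
make_block <- function(protocol, truth, n_trials = protocol$trials_per_block,
                       seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  trial_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_trials))
  lapply(seq_len(n_trials), function(i)
    make_trial_stack(protocol, truth, seed = trial_seeds[i]))
}
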