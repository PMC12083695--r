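#' Whisker stimulation protocol specification
#'
#' The two imaging/whisking protocols used at baseline and 24 h. The *sparse*
#' protocol uses a long post-stimulus window so that all three intrinsic
#' signal phases (initial dip, overshoot, undershoot) develop within a trial;
#' the *condensed* protocol mimics naturalistic whisking with short trials
#' that capture only a growing initial dip.
#'
#' Raw frames are 100 ms; analysis frames are 500 ms (sums of 5 raw frames).
#' The stimulus is a single whisker deflected 9 degrees rostro-caudally at
#' 5 Hz for 1 s.
#'
#' @param name `"sparse"` or `"condensed"`.
#' @return An object of class `isoi_protocol`: a list with fields `name`,
#'   `pre_s`, `stim_s`, `post_s`, `frame_ms_raw` (100), `frame_ms_analysis`
#'   (500), `trials_per_block` (64 sparse / 40 condensed), `stim_rate_hz`
#'   (5), `deflection_deg` (9) and `iti` (inter-trial interval description).
#' @examples
#' p <- isoi_protocol("sparse")
#' p$pre_s + p$stim_s + p$post_s  # 16 s of frames per trial
#' @export
isoi_protocol <- function(name = c("sparse", "condensed")) {
  name <- match.arg(name)
  p <- if (name == "sparse") {
    list(
      name = "sparse", pre_s = 1.5, stim_s = 1.0, post_s = 13.5,
      trials_per_block = 64L, iti = "random 6 +/- 5 s",
      trial_s_nominal = 15
    )
  } else {
    list(
      name = "condensed", pre_s = 1.5, stim_s = 1.0, post_s = 2.0,
      trials_per_block = 40L, iti = "constant 1 s",
      trial_s_nominal = 4.5
    )
  }
  p$frame_ms_raw <- 100
  p$frame_ms_analysis <- 500
  p$stim_rate_hz <- 5
  p$deflection_deg <- 9
  structure(p, class = "isoi_protocol")
}

#' @export
print.isoi_protocol <- function(x, ...) {
  cat(sprintf(
    "ISOI %s protocol: %.1f s pre / %.1f s stim / %.1f s post, %d trials/block\n",
    x$name, x$pre_s, x$stim_s, x$post_s, x$trials_per_block
  ))
  cat(sprintf(
    "  frames: %d ms raw -> %d ms analysis; stimulus %g Hz, %g deg; ITI %s\n",
    x$frame_ms_raw, x$frame_ms_analysis, x$stim_rate_hz, x$deflection_deg,
    x$iti
  ))
  invisible(x)
}

# number of raw (100 ms) frames in a trial
n_raw_frames <- function(protocol) {
  as.integer(round(
    (protocol$pre_s + protocol$stim_s + protocol$post_s) * 1000 /
      protocol$frame_ms_raw
  ))
}

# 1-based index of first raw stimulus frame
raw_onset_frame <- function(protocol) {
  as.integer(round(protocol$pre_s * 1000 / protocol$frame_ms_raw)) + 1L
}
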