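#' Write a trial stack as multi-page TIFF with JSON sidecar
#'
#' Frames are quantized to 16-bit on export (counts clipped to
#' `[0, 65535 * frame_ms / 100]`). The sidecar (`<path>.json`) records
#' protocol timing, onset frame, calibration and the generating seed so a
#' stack can be re-loaded without external context.
#'
#' @param stack A [trial_stack()].
#' @param path Output TIFF path.
#' @return Invisibly, `path`.
#' @export
write_trial_stack <- function(stack, path) {
  stopifnot(inherits(stack, "trial_stack"))
  top <- stack$saturate_level
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(k) {
    m <- stack$frames[, , k] / top
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "deflate")
  sidecar <- list(
    frame_ms = stack$frame_ms, onset_frame = stack$onset_frame,
    mm_per_pixel = stack$mm_per_pixel, protocol = stack$protocol,
    count_scale = top, meta = stack$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trial stack written by [write_trial_stack()]
#'
#' @param path TIFF path (with `<path>.json` sidecar alongside).
#' @return A [trial_stack()].
#' @export
read_trial_stack <- function(path) {
  if (!file.exists(path)) stop("no such TIFF: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("corrupt or unreadable TIFF: ", path))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  frames <- frames * side$count_scale
  trial_stack(frames, side$frame_ms, side$onset_frame, side$mm_per_pixel,
              protocol = side$protocol,
              meta = if (is.null(side$meta)) list() else side$meta)
}

#' Write / read a binary mask as PNG
#'
#' Nonzero pixels are in-mask.
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Write / read a TTC slice image as PNG
#'
#' @param slice A [ttc_slice()].
#' @param path PNG path; calibration metadata goes to `<path>.json`.
#' @return `write_ttc_slice` returns `path` invisibly; `read_ttc_slice`
#'   returns a [ttc_slice()].
#' @export
write_ttc_slice <- function(slice, path) {
  stopifnot(inherits(slice, "ttc_slice"))
  png::writePNG(slice$image, path)
  jsonlite::write_json(list(
    mm_per_pixel = slice$mm_per_pixel, thickness_mm = slice$thickness_mm,
    midline_x = slice$midline_x
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(slice$exclusion_mask))
    write_mask_png(slice$exclusion_mask,
                   sub("\\.png$", "_exclusion.png", path))
  invisible(path)
}

#' @rdname write_ttc_slice
#' @export
read_ttc_slice <- function(path) {
  img <- png::readPNG(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  excl_path <- sub("\\.png$", "_exclusion.png", path)
  excl <- if (file.exists(excl_path)) read_mask_png(excl_path) else NULL
  ttc_slice(img, side$mm_per_pixel, side$thickness_mm,
            midline_x = side$midline_x, exclusion_mask = excl)
}
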