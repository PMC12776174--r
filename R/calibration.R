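#' Physical pixel calibration
#'
#' All physical conversions go through a single calibration constant, the
#' scanner's pixel size in micrometres. The default (0.1109 um/px at x40
#' magnification) is the pipeline's only physical anchor: 1600 px correspond
#' to 177.44 um and 200 px to 22.18 um.
#'
#' @param um_per_px micrometres per pixel; must be > 0.
#' @return An object of class `calibration`.
#' @examples
#' cal <- calibration()
#' px_to_um(1600, cal) # 177.44
#' @export
calibration <- function(um_per_px = 0.1109) {
  stopifnot(is.numeric(um_per_px), length(um_per_px) == 1L, is.finite(um_per_px))
  if (um_per_px <= 0) stop("um_per_px must be > 0", call. = FALSE)
  structure(list(um_per_px = um_per_px), class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %.6g um/px (%.6g mm2/Mpx)\n",
              x$um_per_px, (x$um_per_px / 1000)^2 * 1e6))
  invisible(x)
}

#' Convert pixel lengths to micrometres
#'
#' @param length_px numeric vector of nonnegative lengths in pixels.
#' @param cal a [calibration()] object.
#' @return lengths in micrometres.
#' @export
px_to_um <- function(length_px, cal = calibration()) {
  stopifnot(inherits(cal, "calibration"), is.numeric(length_px))
  if (any(length_px < 0, na.rm = TRUE)) {
    stop("length_px must be nonnegative", call. = FALSE)
  }
  length_px * cal$um_per_px
}

# Physical area of a w x h pixel box in mm^2.
px_area_mm2 <- function(w_px, h_px, cal) {
  w_px * h_px * (cal$um_per_px / 1000)^2
}
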