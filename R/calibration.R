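#' Device calibration
#'
#' Physical calibration of the recording tablet: screen size in pixels, pixel
#' density, and the vertical axis convention of the raw coordinates. The
#' defaults reproduce the 9.7-inch, 1536 x 2048 px study tablet; its panel is
#' of the 264 ppi class, i.e. about 103.9 px/cm. Scoring thresholds are
#' physical (cm), so the density must always be stated explicitly rather than
#' inferred.
#'
#' @param screen_w_px,screen_h_px screen size in pixels.
#' @param px_per_cm pixel density, pixels per centimetre (> 0).
#' @param y_axis `"down"` if raw y grows downward from the top edge (the usual
#'   touch-device convention), `"up"` if it already grows upward.
#' @return an object of class `device_calibration`.
#' @examples
#' device_calibration()
#' device_calibration(px_per_cm = 100)
#' @export
device_calibration <- function(screen_w_px = 1536L, screen_h_px = 2048L,
                               px_per_cm = 103.9, y_axis = c("down", "up")) {
  y_axis <- match.arg(y_axis)
  if (!is_scalar_number(screen_w_px) || screen_w_px <= 0 ||
      !is_scalar_number(screen_h_px) || screen_h_px <= 0) {
    stop_validation("screen dimensions must be positive numbers")
  }
  if (!is_scalar_number(px_per_cm) || px_per_cm <= 0) {
    stop_validation("px_per_cm must be a positive number")
  }
  structure(
    list(
      screen_w_px = as.numeric(screen_w_px),
      screen_h_px = as.numeric(screen_h_px),
      px_per_cm = as.numeric(px_per_cm),
      y_axis = y_axis
    ),
    class = "device_calibration"
  )
}

#' Physical screen size
#'
#' @param cal a [device_calibration()].
#' @return named numeric vector `c(w_cm, h_cm)`.
#' @export
screen_size_cm <- function(cal) {
  stopifnot(inherits(cal, "device_calibration"))
  c(w_cm = cal$screen_w_px / cal$px_per_cm,
    h_cm = cal$screen_h_px / cal$px_per_cm)
}

#' @export
print.device_calibration <- function(x, ...) {
  sz <- screen_size_cm(x)
  cat(sprintf("<device_calibration> %g x %g px @ %g px/cm (%.1f x %.1f cm), y-axis %s\n",
              x$screen_w_px, x$screen_h_px, x$px_per_cm, sz[1], sz[2], x$y_axis))
  invisible(x)
}

calibration_to_list <- function(cal) {
  list(screen_w_px = cal$screen_w_px, screen_h_px = cal$screen_h_px,
       px_per_cm = cal$px_per_cm, y_axis = cal$y_axis)
}

calibration_from_list <- function(x) {
  device_calibration(screen_w_px = x$screen_w_px, screen_h_px = x$screen_h_px,
                     px_per_cm = x$px_per_cm, y_axis = x$y_axis)
}
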