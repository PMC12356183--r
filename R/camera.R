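#' Camera specification
#'
#' Bundle the camera constants needed to scale an aerial image: focal length,
#' physical sensor width, and image dimensions in pixels. These are the fixed
#' terms of the ground-sampling-distance equation; only altitude varies from
#' image to image.
#'
#' Camera constants are kept in the units in which manufacturers report them
#' (millimetres for focal length and sensor width, pixels for image size);
#' all object lengths elsewhere in the package are in metres.
#'
#' @param focal_length_mm Focal length of the camera lens (mm), `> 0`. Use an
#'   adjusted focal length (see [adjusted_focal_length()]) when the drone's
#'   internal image processing alters the effective field of view.
#' @param sensor_width_mm Physical width of the camera sensor (mm), `> 0`.
#' @param image_width_px Image width in pixels (positive integer).
#' @param image_height_px Image height in pixels (positive integer).
#'
#' @return An object of class `camera_spec`.
#' @examples
#' # DJI Phantom 4 Pro stills
#' camera_spec(8.8, 13.2, 5472, 3648)
#' @export
camera_spec <- function(focal_length_mm, sensor_width_mm,
                        image_width_px, image_height_px) {
  for (nm in c("focal_length_mm", "sensor_width_mm",
               "image_width_px", "image_height_px")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("`%s` must be a single positive finite number", nm),
           call. = FALSE)
    }
  }
  if (image_width_px != round(image_width_px) ||
      image_height_px != round(image_height_px)) {
    stop("image dimensions must be whole numbers of pixels", call. = FALSE)
  }
  structure(
    list(
      focal_length_mm  = as.numeric(focal_length_mm),
      sensor_width_mm  = as.numeric(sensor_width_mm),
      image_width_px   = as.integer(image_width_px),
      image_height_px  = as.integer(image_height_px)
    ),
    class = "camera_spec"
  )
}

#' @export
print.camera_spec <- function(x, ...) {
  cat(sprintf("<camera_spec> f = %g mm, sensor width = %g mm, image = %d x %d px\n",
              x$focal_length_mm, x$sensor_width_mm,
              x$image_width_px, x$image_height_px))
  invisible(x)
}
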