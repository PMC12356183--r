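#' Ground sampling distance
#'
#' The ground sampling distance (GSD) is the real-world footprint of a single
#' image pixel at the target plane, in metres per pixel. For a nadir
#' (straight-down) image it is
#' \deqn{GSD = \frac{a}{f} \times \frac{S_w}{I_w},}
#' where \eqn{a} is the altitude above the target (m), \eqn{f} the focal
#' length (mm), \eqn{S_w} the sensor width (mm), and \eqn{I_w} the image
#' width (px). Focal length and sensor width enter only through their ratio,
#' so their shared unit cancels.
#'
#' @param altitude_m Altitude of the camera above the measured object (m),
#'   `> 0`. Vectorised.
#' @param camera A [camera_spec()].
#'
#' @return Metres per pixel, same length as `altitude_m`.
#' @seealso [pixels_to_meters()], [meters_to_pixels()]
#' @examples
#' gsd(25, camera_spec(8.8, 13.2, 5472, 3648))
#' @export
gsd <- function(altitude_m, camera) {
  stopifnot(inherits(camera, "camera_spec"))
  if (!is.numeric(altitude_m) || any(!is.finite(altitude_m)) ||
      any(altitude_m <= 0)) {
    stop("`altitude_m` must be positive and finite", call. = FALSE)
  }
  (altitude_m / camera$focal_length_mm) *
    (camera$sensor_width_mm / camera$image_width_px)
}

#' Convert a pixel measurement to metres
#'
#' A length measured in pixels on a nadir image is converted to metres by
#' multiplying by the ground sampling distance: \eqn{L = GSD \times L_p}.
#'
#' @param length_px Measured length in pixels, `> 0`. Vectorised.
#' @inheritParams gsd
#' @return Length in metres.
#' @examples
#' cam <- camera_spec(8.8, 13.2, 5472, 3648)
#' pixels_to_meters(1000, 25, cam)
#' @export
pixels_to_meters <- function(length_px, altitude_m, camera) {
  if (!is.numeric(length_px) || any(!is.finite(length_px)) ||
      any(length_px <= 0)) {
    stop("`length_px` must be positive and finite", call. = FALSE)
  }
  gsd(altitude_m, camera) * length_px
}

#' Convert a metric length to pixels
#'
#' Exact inverse of [pixels_to_meters()]: the number of pixels a length in
#' metres spans at a given altitude.
#'
#' @param length_m Length in metres, `> 0`. Vectorised.
#' @inheritParams gsd
#' @return Length in pixels.
#' @export
meters_to_pixels <- function(length_m, altitude_m, camera) {
  if (!is.numeric(length_m) || any(!is.finite(length_m)) ||
      any(length_m <= 0)) {
    stop("`length_m` must be positive and finite", call. = FALSE)
  }
  length_m / gsd(altitude_m, camera)
}

#' Adjusted focal length from a known-size object
#'
#' Many consumer drones internally reprocess imagery (distortion correction,
#' resolution changes), so the effective focal length can differ from the
#' manufacturer's value. Photographing an object of known length at a known
#' distance in a controlled setting and solving the scaling equations for
#' \eqn{f} gives an adjusted focal length
#' \deqn{f_{adj} = \frac{a \, S_w \, L_p}{L \, I_w},}
#' which, substituted back into the GSD equation, reproduces the true object
#' length exactly. Only the ratio \eqn{S_w / f} enters the scale, so adjusting
#' the focal length alone suffices (an adjusted sensor width would be
#' equivalent). Each camera/resolution combination needs its own adjustment.
#'
#' @param altitude_m Distance between camera sensor and object (m), `> 0`.
#' @param sensor_width_mm Sensor width (mm), `> 0`.
#' @param length_px Measured length of the object in pixels, `> 0`.
#' @param known_length_m True object length (m), `> 0`.
#' @param image_width_px Image width (px), `> 0`.
#'
#' @return Adjusted focal length in mm.
#' @examples
#' adjusted_focal_length(1, 13.2, 1000, 0.5, 5472)
#' @export
adjusted_focal_length <- function(altitude_m, sensor_width_mm, length_px,
                                  known_length_m, image_width_px) {
  args <- list(altitude_m = altitude_m, sensor_width_mm = sensor_width_mm,
               length_px = length_px, known_length_m = known_length_m,
               image_width_px = image_width_px)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      stop(sprintf("`%s` must be positive and finite", nm), call. = FALSE)
    }
  }
  (altitude_m * sensor_width_mm * length_px) /
    (known_length_m * image_width_px)
}
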