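#' Screen geometry for visual-angle computations
#'
#' Bundles the monitor's pixel resolution, physical panel size and the
#' viewing distance. All angular quantities in the package (the velocity
#' threshold in particular) are computed from pixel displacements through
#' this geometry.
#'
#' The defaults describe a plausible 17-inch 5:4 clinical workstation panel
#' (1280 x 1024 on 33.7 x 27.0 cm) viewed at 65 cm. The resolution and panel
#' size are a documented example, not an assertion about any particular
#' study hardware; the 65 cm viewing distance is the standardized value used
#' throughout.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_cm,height_cm Physical panel size in centimeters.
#' @param viewing_distance_cm Eye-to-screen distance in centimeters.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' pixels_to_degrees(43, geom)
#' @export
screen_geometry <- function(width_px = 1280, height_px = 1024,
                            width_cm = 33.7, height_cm = 27.0,
                            viewing_distance_cm = 65) {
  vals <- c(width_px = width_px, height_px = height_px,
            width_cm = width_cm, height_cm = height_cm,
            viewing_distance_cm = viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be strictly positive", call. = FALSE)
  }
  pitch <- width_cm / width_px
  if (pitch < 0.01 || pitch > 0.1) {
    stop(sprintf(
      "pixel pitch %.4f cm/px outside the sanity band [0.01, 0.1]", pitch),
      call. = FALSE)
  }
  structure(list(width_px = width_px, height_px = height_px,
                 width_cm = width_cm, height_cm = height_cm,
                 viewing_distance_cm = viewing_distance_cm,
                 pitch_cm_per_px = pitch),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px on %.1f x %.1f cm at %.0f cm (pitch %.4f cm/px)\n",
              x$width_px, x$height_px, x$width_cm, x$height_cm,
              x$viewing_distance_cm, x$pitch_cm_per_px))
  invisible(x)
}

#' Convert an on-screen pixel displacement to degrees of visual angle
#'
#' Uses the exact subtended-angle formula
#' `theta = 2 * atan(d_cm / (2 * D))`, where `d_cm` is the physical length of
#' the displacement (pixels times the horizontal pixel pitch) and `D` the
#' viewing distance. Monotone in the displacement; close to linear below a
#' few degrees.
#'
#' @param displacement_px Nonnegative pixel displacement(s).
#' @param geometry A [screen_geometry()].
#' @return Visual angle(s) in degrees.
#' @export
pixels_to_degrees <- function(displacement_px, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (any(displacement_px < 0, na.rm = TRUE)) {
    stop("displacement_px must be nonnegative", call. = FALSE)
  }
  d_cm <- displacement_px * geometry$pitch_cm_per_px
  2 * atan(d_cm / (2 * geometry$viewing_distance_cm)) * 180 / pi
}

#' Convert degrees of visual angle to an on-screen pixel displacement
#'
#' Inverse of [pixels_to_degrees()].
#'
#' @param degrees Nonnegative visual angle(s) in degrees.
#' @param geometry A [screen_geometry()].
#' @return Pixel displacement(s).
#' @export
degrees_to_pixels <- function(degrees, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (any(degrees < 0, na.rm = TRUE)) {
    stop("degrees must be nonnegative", call. = FALSE)
  }
  2 * geometry$viewing_distance_cm * tan(degrees * pi / 360) /
    geometry$pitch_cm_per_px
}

#' Angular gaze velocity between two samples
#'
#' Two-point estimator: Euclidean pixel displacement converted to visual
#' angle, divided by the elapsed time. The velocity is a property of the
#' inter-sample interval and is conventionally reported at the later sample.
#'
#' @param prev,next_ Gaze samples: lists or one-row data frames with fields
#'   `t_ms`, `x_px`, `y_px` and `valid`.
#' @param geometry A [screen_geometry()].
#' @return Velocity in degrees of visual angle per second.
#' @export
angular_velocity <- function(prev, next_, geometry) {
  if (!isTRUE(as.logical(prev$valid)) || !isTRUE(as.logical(next_$valid))) {
    stop("angular velocity requires two valid samples", call. = FALSE)
  }
  dt_ms <- next_$t_ms - prev$t_ms
  if (!is.finite(dt_ms) || dt_ms <= 0) {
    stop("non-positive time step between samples", call. = FALSE)
  }
  disp <- sqrt((next_$x_px - prev$x_px)^2 + (next_$y_px - prev$y_px)^2)
  pixels_to_degrees(disp, geometry) / (dt_ms / 1000)
}

# Pixel displacement over one interval of dt_ms that corresponds exactly to
# the angular velocity threshold. Internal: used by the classifier tests and
# the generator to reason about sub/supra-threshold steps.
threshold_px <- function(velocity_deg_s, dt_ms, geometry) {
  degrees_to_pixels(velocity_deg_s * dt_ms / 1000, geometry)
}
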