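#' Screen geometry of the display used for free visual exploration
#'
#' Describes the display in pixels, degrees of visual angle and viewing
#' distance. All coordinate conversions in the package flow through this
#' object. The default corresponds to a 1680 x 1050 px display subtending
#' 35 x 22 degrees at 83 cm.
#'
#' @param width_px,height_px Display size in pixels.
#' @param width_deg,height_deg Display size in degrees of visual angle.
#' @param viewing_distance_cm Eye-to-screen distance in centimetres.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(17.7, geom)
#' @export
screen_geometry <- function(width_px = 1680, height_px = 1050,
                            width_deg = 35, height_deg = 22,
                            viewing_distance_cm = 83) {
  fields <- c(width_px = width_px, height_px = height_px,
              width_deg = width_deg, height_deg = height_deg,
              viewing_distance_cm = viewing_distance_cm)
  if (any(!is.finite(fields)) || any(fields <= 0)) {
    stop("all screen_geometry fields must be strictly positive", call. = FALSE)
  }
  structure(as.list(fields), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.3g x %.3g deg, %.3g cm\n",
              x$width_px, x$height_px, x$width_deg, x$height_deg,
              x$viewing_distance_cm))
  invisible(x)
}

#' Centre a horizontal pixel coordinate on the picture midline
#'
#' Converts screen coordinates (0 at the left edge) into coordinates relative
#' to the picture centre: negative values lie left of centre, positive values
#' right of centre.
#'
#' @param x_px Horizontal screen coordinate(s) in pixels.
#' @param geometry A [screen_geometry()].
#' @return Centred pixel coordinate(s), `x_px - width_px / 2`.
#' @export
center_x <- function(x_px, geometry = screen_geometry()) {
  x_px - geometry$width_px / 2
}

#' @rdname center_x
#' @param x_centered Centred pixel coordinate(s) to map back to screen
#'   coordinates.
#' @export
uncenter_x <- function(x_centered, geometry = screen_geometry()) {
  x_centered + geometry$width_px / 2
}

#' Convert pixel displacements to degrees of visual angle
#'
#' The default conversion is linear, `dx_px * width_deg / width_px`
#' (0.02083 deg/px for the default geometry), the scale implied by quoting
#' the display as spanning a fixed visual angle. A trigonometric conversion
#' from the viewing distance is available via `method = "trig"`; it assumes
#' the physical screen width is the one subtending `width_deg` at the
#' viewing distance and measures the angle of the displacement from the
#' screen centre. The two differ in the second decimal for displacements of
#' tens of pixels.
#'
#' @param dx_px Horizontal displacement(s) in pixels (sign-preserving).
#' @param geometry A [screen_geometry()].
#' @param method `"linear"` (default) or `"trig"`.
#' @return Displacement(s) in degrees of visual angle.
#' @export
px_to_deg <- function(dx_px, geometry = screen_geometry(),
                      method = c("linear", "trig")) {
  method <- match.arg(method)
  if (method == "linear") {
    return(dx_px * geometry$width_deg / geometry$width_px)
  }
  # physical half-width consistent with the stated angular subtense
  half_cm <- geometry$viewing_distance_cm * tanpi(geometry$width_deg / 360)
  cm_per_px <- 2 * half_cm / geometry$width_px
  atan2(dx_px * cm_per_px, geometry$viewing_distance_cm) * 180 / pi
}

#' @rdname px_to_deg
#' @param dx_deg Displacement(s) in degrees to convert back to pixels
#'   (linear rule only).
#' @export
deg_to_px <- function(dx_deg, geometry = screen_geometry()) {
  dx_deg * geometry$width_px / geometry$width_deg
}

#' Stimulation electrode specification and current density
#'
#' `electrode_spec()` describes a tDCS electrode; `current_density()` returns
#' the nominal current density in mA/cm^2. Rectangle dimensions are side
#' lengths in cm, disc dimension is the diameter in cm, ring dimensions are
#' the outer and inner diameter in cm.
#'
#' @param shape One of `"rectangle"`, `"disc"`, `"ring"`.
#' @param dimensions Numeric vector of dimensions in cm (see Details).
#' @param current_mA Applied current in milliamperes.
#' @return `electrode_spec()`: an object of class `electrode_spec` with the
#'   derived `area_cm2`; `current_density()`: mA/cm^2.
#' @examples
#' current_density(electrode_spec("rectangle", c(5, 5), 1))   # 0.04
#' current_density(electrode_spec("disc", 2.5, 1))            # ~0.2
#' @export
electrode_spec <- function(shape = c("rectangle", "disc", "ring"),
                           dimensions, current_mA) {
  shape <- match.arg(shape)
  if (!is.numeric(dimensions) || any(dimensions <= 0)) {
    stop("electrode dimensions must be positive", call. = FALSE)
  }
  area <- switch(shape,
    rectangle = {
      if (length(dimensions) != 2) stop("rectangle needs two side lengths", call. = FALSE)
      prod(dimensions)
    },
    disc = {
      if (length(dimensions) != 1) stop("disc needs a single diameter", call. = FALSE)
      pi * (dimensions / 2)^2
    },
    ring = {
      if (length(dimensions) != 2 || dimensions[1] <= dimensions[2]) {
        stop("ring needs outer then inner diameter, outer > inner", call. = FALSE)
      }
      pi * ((dimensions[1] / 2)^2 - (dimensions[2] / 2)^2)
    }
  )
  structure(list(shape = shape, dimensions = dimensions,
                 area_cm2 = area, current_mA = current_mA),
            class = "electrode_spec")
}

#' @rdname electrode_spec
#' @param electrode An `electrode_spec`.
#' @export
current_density <- function(electrode) {
  if (!inherits(electrode, "electrode_spec")) {
    stop("`electrode` must be an electrode_spec", call. = FALSE)
  }
  if (!is.finite(electrode$area_cm2) || electrode$area_cm2 <= 0) {
    stop("electrode area must be strictly positive", call. = FALSE)
  }
  electrode$current_mA / electrode$area_cm2
}
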