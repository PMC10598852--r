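#' Camera calibration linking image pixels to world millimetres
#'
#' The side-view camera images a shooting window of physical height `Hs`
#' (mm) onto `Ht` image rows, so a vertical pixel coordinate `Zt` maps to the
#' world height `Zs = Zt * Hs / Ht` (same proportion both ways). The
#' horizontal axis uses the same millimetre-per-pixel scale unless
#' `x_scale` is overridden. `Hz` is the blade reference height: the height of
#' the picking blade above the window base when the picker is parked at its
#' top position.
#'
#' @param Ht Image height in pixels (> 0).
#' @param Hs Shooting-area height in mm (default 196).
#' @param Hz Blade reference height in mm (default 212, must be >= `Hs`).
#' @param x_scale Horizontal scale in mm/px (default `Hs / Ht`).
#' @return A list of class `camera_calibration`.
#' @export
#' @examples
#' calib <- camera_calibration(Ht = 980)
#' pixel_to_world(c(0, 980), calib)  # bottom row -> Zs = 196 mm
camera_calibration <- function(Ht, Hs = 196, Hz = 212, x_scale = Hs / Ht) {
  stopf(is_count(Ht) && Ht > 0, "Ht must be a positive integer pixel count")
  stopf(Hs > 0, "Hs must be positive")
  stopf(Hz >= Hs, "Hz must be >= Hs (blade parks above the window top)")
  structure(list(Ht = as.integer(Ht), Hs = Hs, Hz = Hz, x_scale = x_scale),
            class = "camera_calibration")
}

#' Map pixel coordinates to world millimetres (and back)
#'
#' The vertical mapping is the exact proportionality `Zt / Ht = Zs / Hs`;
#' the horizontal mapping is `Xs = Xt * x_scale`. Both are linear and
#' invertible.
#'
#' @param point Numeric `c(Xt, Zt)` in continuous pixel coordinates, or an
#'   n x 2 matrix of such points.
#' @param calib A [camera_calibration()].
#' @return `c(Xs, Zs)` in mm (or an n x 2 matrix).
#' @export
pixel_to_world <- function(point, calib) {
  stopf(inherits(calib, "camera_calibration"), "calib must be a camera_calibration")
  if (is.matrix(point)) {
    cbind(Xs = point[, 1] * calib$x_scale,
          Zs = point[, 2] * calib$Hs / calib$Ht)
  } else {
    c(Xs = point[1] * calib$x_scale, Zs = point[2] * calib$Hs / calib$Ht)
  }
}

#' @rdname pixel_to_world
#' @export
world_to_pixel <- function(point, calib) {
  stopf(inherits(calib, "camera_calibration"), "calib must be a camera_calibration")
  if (is.matrix(point)) {
    cbind(Xt = point[, 1] / calib$x_scale,
          Zt = point[, 2] * calib$Ht / calib$Hs)
  } else {
    c(Xt = point[1] / calib$x_scale, Zt = point[2] * calib$Ht / calib$Hs)
  }
}

#' Vertical blade displacement to reach a picking height
#'
#' From the parked (top) position the blade sits `Hz` above the window base,
#' i.e. `Hz - Hs` above the window top, so reaching a world height `z_next`
#' (measured downward from the window top) requires a downward displacement
#' `(Hz - Hs) + z_next`. Between consecutive picks the displacement is the
#' signed difference of the two heights (positive = downward).
#'
#' @param z_next Target world height in mm, within `[0, Hs]`.
#' @param calib A [camera_calibration()].
#' @param from `"top"` (default) or the previous world height `z_prev` in mm.
#' @return Signed displacement in mm (positive downward).
#' @export
#' @examples
#' calib <- camera_calibration(980)
#' blade_displacement(0, calib)             # 16 mm
#' blade_displacement(100, calib, from = 40)  # +60 mm
blade_displacement <- function(z_next, calib, from = "top") {
  stopf(inherits(calib, "camera_calibration"), "calib must be a camera_calibration")
  stopf(is.numeric(z_next) && z_next >= 0 && z_next <= calib$Hs,
        "z_next (%.1f mm) outside the shooting window [0, %.0f]", z_next, calib$Hs)
  if (identical(from, "top")) {
    (calib$Hz - calib$Hs) + z_next
  } else {
    stopf(is.numeric(from), "from must be \"top\" or a numeric height")
    z_next - from
  }
}
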