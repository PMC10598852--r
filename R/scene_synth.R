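#' Default biometric ranges for a tea shoot tip
#'
#' Ranges (min, max) for the physical parameters of a harvest-grade
#' "one bud one leaf" tea shoot tip: shoot length `L` (mm), stalk diameter
#' `phi` (mm), pickable stalk region `A2` (mm), leaf insertion angle `beta`
#' (degrees from the stem axis), growth height of the tip above the canopy
#' surface (mm), and the generator-internal lateral bow amplitude of the stem
#' (mm). Shoot parameters are drawn uniformly within these intervals.
#'
#' @return Named list of length-2 numeric vectors `c(min, max)`.
#' @export
#' @examples
#' shoot_param_ranges()
shoot_param_ranges <- function() {
  list(
    shoot_length_L      = c(27.5, 30.2),
    stalk_diameter_phi  = c(1.1, 2.3),
    pickable_region_A2  = c(11.2, 15.3),
    leaf_angle_beta     = c(45.6, 54.2),
    tip_height          = c(50, 110),
    curvature_amplitude = c(0, 3)
  )
}

check_ranges <- function(ranges) {
  defaults <- shoot_param_ranges()
  stopf(all(names(defaults) %in% names(ranges)),
        "ranges must contain: %s", paste(names(defaults), collapse = ", "))
  for (nm in names(defaults)) {
    r <- ranges[[nm]]
    stopf(is.numeric(r) && length(r) == 2 && r[1] <= r[2],
          "range '%s' must be numeric c(min, max) with min <= max", nm)
    lo <- if (nm == "curvature_amplitude") 0 else .Machine$double.eps
    stopf(r[1] >= lo, "range '%s' must be positive", nm)
  }
  invisible(ranges)
}

#' Draw the physical parameters of one tea shoot
#'
#' Each field is drawn independently and uniformly within its range. Uses the
#' current R random number stream, so results are reproducible under
#' [set.seed()].
#'
#' @param ranges Named list of `c(min, max)` intervals, as returned by
#'   [shoot_param_ranges()].
#' @return An object of class `shoot_params`: a named list with elements
#'   `shoot_length_L`, `stalk_diameter_phi`, `pickable_region_A2`,
#'   `leaf_angle_beta`, `tip_height`, `curvature_amplitude` (all scalar) and
#'   the optional annotation `optimal_region_A1` (always `NA`; the optimal
#'   picking region is a named concept with no quantified extent).
#' @export
#' @examples
#' set.seed(1)
#' sample_shoot_params()
sample_shoot_params <- function(ranges = shoot_param_ranges()) {
  check_ranges(ranges)
  p <- lapply(ranges, function(r) runif(1, r[1], r[2]))
  p$optimal_region_A1 <- NA_real_
  structure(p, class = "shoot_params")
}

#' Generator configuration for synthetic tea-row scenes
#'
#' @param ranges Parameter ranges, see [shoot_param_ranges()].
#' @param spacing_mm Interval `c(min, max)` for the horizontal gap between
#'   consecutive shoot tips (mm).
#' @param canopy_z_mm Depth of the canopy surface below the top of the
#'   shooting window (mm). Shoot tips sit `tip_height` above it.
#' @param window_height_mm Height of the world window (mm); by default the
#'   shooting-area height `Hs` of the reference camera setup.
#' @param margin_mm Horizontal clearance kept left of the first and right of
#'   the last tip (mm).
#' @param world_width_mm Optional fixed window width (mm). When `NULL` the
#'   width is whatever the sampled spacings require.
#' @param offset_mm Vertical drop from the tip to the true picking point (mm).
#' @param polyline_step_mm Sampling step of the stem polylines (mm).
#' @param bud_radius_mm Radius of the bud blob drawn at the tip (mm); also the
#'   depth of the bud base below the tip used for residual-stalk accounting.
#' @param leaf_length_frac Leaf length as a fraction of the shoot length `L`.
#' @param leaf_width_frac Maximum leaf width as a fraction of the leaf length.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(ranges = shoot_param_ranges(),
                         spacing_mm = c(50, 80),
                         canopy_z_mm = 160,
                         window_height_mm = 196,
                         margin_mm = 25,
                         world_width_mm = NULL,
                         offset_mm = 4,
                         polyline_step_mm = 0.5,
                         bud_radius_mm = 1.2,
                         leaf_length_frac = 0.8,
                         leaf_width_frac = 0.3) {
  check_ranges(ranges)
  stopf(spacing_mm[1] > 0 && spacing_mm[1] <= spacing_mm[2],
        "spacing_mm must be a positive c(min, max) interval")
  stopf(canopy_z_mm < window_height_mm,
        "canopy must lie inside the window (canopy_z_mm < window_height_mm)")
  structure(list(
    ranges = ranges, spacing_mm = spacing_mm, canopy_z_mm = canopy_z_mm,
    window_height_mm = window_height_mm, margin_mm = margin_mm,
    world_width_mm = world_width_mm, offset_mm = offset_mm,
    polyline_step_mm = polyline_step_mm, bud_radius_mm = bud_radius_mm,
    leaf_length_frac = leaf_length_frac, leaf_width_frac = leaf_width_frac
  ), class = "scene_config")
}

#' True picking point on a stem polyline
#'
#' The picking point sits a fixed vertical drop (default 4 mm) below the tip,
#' on the stem. The X coordinate is obtained by linear interpolation between
#' polyline vertices at `Z = tip_Z + offset_mm`.
#'
#' @param stem_polyline Two-column matrix `(X, Z)` in mm ordered from tip to
#'   base, Z strictly increasing.
#' @param offset_mm Vertical drop below the tip (mm), default 4.
#' @param id Optional shoot identifier used in error messages.
#' @return Numeric `c(X, Z)` in mm.
#' @export
#' @examples
#' stem <- cbind(X = rep(10, 5), Z = seq(20, 60, by = 10))
#' true_pick_point(stem, 4)  # (10, 24)
true_pick_point <- function(stem_polyline, offset_mm = 4, id = NULL) {
  stopf(is.matrix(stem_polyline) && ncol(stem_polyline) == 2 &&
          nrow(stem_polyline) >= 2, "stem_polyline must be an n x 2 matrix")
  z <- stem_polyline[, 2]
  stopf(all(diff(z) > 0), "stem polyline Z must be strictly increasing")
  stopf(offset_mm >= 0, "offset_mm must be non-negative")
  tip <- stem_polyline[1, ]
  zt <- tip[2] + offset_mm
  stopf(zt <= z[length(z)],
        "shoot%s: stem polyline (%.1f mm) shorter than offset %.1f mm",
        if (is.null(id)) "" else paste0(" ", id), z[length(z)] - z[1], offset_mm)
  c(X = unname(interp_polyline_x(stem_polyline, zt)), Z = unname(zt))
}

# leaf centreline + outline polygon for one leaf.
# Attached at the tip, pointing down-outward at `beta` degrees from the stem
# axis; width tapers to zero at both ends (sine profile) so the leaf/stem
# junction is exactly the tip point.
leaf_geometry <- function(tip, beta_deg, length_mm, width_mm, side, n = 24) {
  b <- beta_deg * pi / 180
  dir <- c(side * sin(b), cos(b))      # (dX, dZ), unit
  nrm <- c(-dir[2], dir[1])
  t <- seq(0, 1, length.out = n)
  centre <- cbind(tip[1] + t * length_mm * dir[1],
                  tip[2] + t * length_mm * dir[2])
  w <- width_mm * sin(pi * t)          # zero at both ends
  left  <- centre + outer(w / 2, nrm)
  right <- centre - outer(w / 2, nrm)
  polygon <- rbind(left, right[n:1, , drop = FALSE])
  colnames(polygon) <- colnames(centre) <- c("X", "Z")
  list(centre = centre, half_width = w / 2, polygon = polygon)
}

# build one shoot record at tip position (x_tip, .) given sampled params
build_shoot <- function(x_tip, params, cfg, id) {
  tip_z <- cfg$canopy_z_mm - params$tip_height
  stopf(tip_z > 0, "shoot %d: tip above the window top (tip_height too large)", id)
  base_z <- cfg$canopy_z_mm
  side <- sample(c(-1, 1), 1)
  span <- base_z - tip_z
  z <- seq(tip_z, base_z, by = cfg$polyline_step_mm)
  if (z[length(z)] < base_z) z <- c(z, base_z)
  amp <- params$curvature_amplitude
  x <- x_tip + side * amp * ((z - tip_z) / span)^2   # single-bow quadratic
  stem <- cbind(X = x, Z = z)

  leaf_len <- cfg$leaf_length_frac * params$shoot_length_L
  leaf_w <- cfg$leaf_width_frac * leaf_len
  tip <- c(x_tip, tip_z)
  leaves <- list(
    leaf_geometry(tip, params$leaf_angle_beta, leaf_len, leaf_w, -1),
    leaf_geometry(tip, params$leaf_angle_beta, leaf_len, leaf_w, +1)
  )

  pick <- true_pick_point(stem, cfg$offset_mm, id = id)

  # world bounding box: bud + leaves + stem down to tip + L, padded 1 mm
  box_bottom <- tip_z + params$shoot_length_L
  stem_part <- stem[stem[, 2] <= box_bottom + 1e-9, , drop = FALSE]
  xs <- c(tip[1] - cfg$bud_radius_mm, tip[1] + cfg$bud_radius_mm,
          stem_part[, 1], unlist(lapply(leaves, function(l) l$polygon[, 1])))
  zs <- c(tip[2] - cfg$bud_radius_mm, box_bottom,
          unlist(lapply(leaves, function(l) l$polygon[, 2])))
  pad <- 1
  bbox <- c(x_min = min(xs) - pad, z_min = min(zs) - pad,
            x_max = max(xs) + pad, z_max = max(zs) + pad)

  list(id = id, params = params, tip = c(X = tip[1], Z = tip[2]),
       stem_polyline = stem, true_pick_point = pick,
       leaves = leaves,
       leaf_polygons = lapply(leaves, function(l) l$polygon),
       bud_radius_mm = cfg$bud_radius_mm, bow_side = side,
       bbox_world = bbox)
}

#' Generate the ground truth of a synthetic side-view tea row
#'
#' Places `n_shoots` tea shoots along a row with inter-tip spacing drawn
#' uniformly from the configured interval, samples each shoot's physical
#' parameters, models every stem as a single-bow quadratic curve from the tip
#' down to the canopy, attaches two tapered leaves at the tip at the sampled
#' leaf angle, and computes the exact picking point of every shoot.
#'
#' @param n_shoots Number of shoots (>= 1).
#' @param config A [scene_config()].
#' @param seed Optional integer seed applied locally (the caller's RNG state
#'   is restored on exit).
#' @return An object of class `scene_truth`: list with `shoots` (list of
#'   shoot records carrying `tip`, `stem_polyline`, `true_pick_point`,
#'   `leaf_polygons`, `bbox_world`, `params`), `canopy_z_mm`, and
#'   `world_window` `c(width, height)` in mm.
#' @export
#' @examples
#' truth <- build_scene(3, seed = 7)
#' diff(sapply(truth$shoots, function(s) s$tip["X"]))  # gaps in [50, 80]
build_scene <- function(n_shoots, config = scene_config(), seed = NULL) {
  stopf(is_count(n_shoots) && n_shoots >= 1, "n_shoots must be a positive integer")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cfg <- config
  sp <- cfg$spacing_mm
  if (!is.null(cfg$world_width_mm) && n_shoots > 1) {
    avail <- cfg$world_width_mm - 2 * cfg$margin_mm
    stopf(avail >= (n_shoots - 1) * sp[1],
          "world window (%.0f mm) too small for %d shoots at %.0f mm minimum spacing",
          cfg$world_width_mm, n_shoots, sp[1])
    sp[2] <- min(sp[2], avail / (n_shoots - 1))
  }
  gaps <- if (n_shoots > 1) runif(n_shoots - 1, sp[1], sp[2]) else numeric(0)
  x_tips <- cfg$margin_mm + cumsum(c(0, gaps))
  width <- if (is.null(cfg$world_width_mm)) {
    x_tips[n_shoots] + cfg$margin_mm
  } else cfg$world_width_mm

  shoots <- vector("list", n_shoots)
  for (i in seq_len(n_shoots)) {
    params <- sample_shoot_params(cfg$ranges)
    shoots[[i]] <- build_shoot(x_tips[i], params, cfg, i)
  }
  structure(list(shoots = shoots, canopy_z_mm = cfg$canopy_z_mm,
                 world_window = c(width = width, height = cfg$window_height_mm),
                 config = cfg),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d shoots, window %.0f x %.0f mm, canopy at %.0f mm\n",
              length(x$shoots), x$world_window[1], x$world_window[2], x$canopy_z_mm))
  for (s in x$shoots) {
    cat(sprintf("  shoot %d: tip (%.1f, %.1f) mm, pick point (%.1f, %.1f) mm\n",
                s$id, s$tip[1], s$tip[2], s$true_pick_point[1], s$true_pick_point[2]))
  }
  invisible(x)
}
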