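#' Rendering configuration for synthetic scenes
#'
#' @param px_per_mm Pixel pitch (px/mm), >= 2 so the thinnest stalk is at
#'   least two pixels wide. The default 5 px/mm together with the default
#'   196 mm window height gives a 980-pixel-high image, matching the
#'   reference camera calibration.
#' @param fg_gray,bg_gray Foreground/background gray levels (0-255).
#' @param noise Additive Gaussian noise level as a fraction of full scale
#'   (standard deviation `noise * 255` gray levels); 0 disables it.
#' @param n_clutter Number of dim clutter blobs drawn below the canopy line.
#' @param clutter_gray Gray level of clutter blobs.
#' @param stamp_step_mm Spacing of the disk stamps used to rasterize strokes.
#' @return A list of class `render_config`.
#' @export
render_config <- function(px_per_mm = 5, fg_gray = 230, bg_gray = 20,
                          noise = 0, n_clutter = 0, clutter_gray = 70,
                          stamp_step_mm = 0.2) {
  stopf(px_per_mm >= 2, "px_per_mm must be >= 2 (a 1.1 mm stalk must cover >= 2 px)")
  stopf(noise >= 0, "noise must be non-negative")
  structure(list(px_per_mm = px_per_mm, fg_gray = fg_gray, bg_gray = bg_gray,
                 noise = noise, n_clutter = n_clutter,
                 clutter_gray = clutter_gray, stamp_step_mm = stamp_step_mm),
            class = "render_config")
}

# stamp filled disks onto an image matrix. centres_px: n x 2 matrix of
# continuous pixel coords (x = col, z = row); radii_px: length n. Pixels whose
# centre (index + 0.5) lies within a radius are set to `value`. 0-based maths,
# 1-based matrix writes.
stamp_disks <- function(img, centres_px, radii_px, value) {
  nr <- nrow(img); nc <- ncol(img)
  for (k in seq_len(nrow(centres_px))) {
    x <- centres_px[k, 1]; z <- centres_px[k, 2]; rad <- radii_px[k]
    if (rad <= 0) next
    r0 <- max(0L, floor(z - rad - 0.5)); r1 <- min(nr - 1L, ceiling(z + rad))
    c0 <- max(0L, floor(x - rad - 0.5)); c1 <- min(nc - 1L, ceiling(x + rad))
    if (r1 < r0 || c1 < c0) next
    rr <- r0:r1; cc <- c0:c1
    dz2 <- (rr + 0.5 - z)^2
    dx2 <- (cc + 0.5 - x)^2
    hit <- outer(dz2, dx2, "+") <= rad^2
    if (any(hit)) {
      idx <- which(hit, arr.ind = TRUE)
      img[cbind(rr[idx[, 1]] + 1L, cc[idx[, 2]] + 1L)] <- value
    }
  }
  img
}

# resample a polyline at approximately `step` spacing (by vertex interpolation
# over Z, adequate for near-vertical stems)
resample_by_z <- function(polyline, step) {
  z <- seq(polyline[1, 2], polyline[nrow(polyline), 2], by = step)
  cbind(approx(polyline[, 2], polyline[, 1], xout = z)$y, z)
}

#' Rasterize a synthetic scene into a grayscale image
#'
#' Stems are drawn as thick strokes of width equal to the stalk diameter,
#' leaves as elongated tapered blobs meeting the stem at the tip, and the bud
#' as a small blob centred on the tip, so the area above each tip is blank.
#' Per-shoot pixel bounding boxes are derived from the world-coordinate truth.
#'
#' @param truth A `scene_truth` from [build_scene()].
#' @param config A [render_config()].
#' @param seed Optional integer seed for noise/clutter (RNG state restored).
#' @return An object of class `rendered_scene`: list with `image` (integer
#'   matrix, gray 0-255, rows = Z), `px_per_mm`, `image_height_Ht`,
#'   `image_width_px` and `boxes` (data frame of half-open 0-based pixel boxes
#'   `x_min, z_min, x_max, z_max` plus `shoot_id`).
#' @export
render_scene <- function(truth, config = render_config(), seed = NULL) {
  stopf(inherits(truth, "scene_truth"), "truth must be a scene_truth")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ppm <- config$px_per_mm
  H <- as.integer(ceiling(truth$world_window[2] * ppm))
  W <- as.integer(ceiling(truth$world_window[1] * ppm))
  img <- matrix(as.integer(config$bg_gray), nrow = H, ncol = W)

  step <- config$stamp_step_mm
  for (s in truth$shoots) {
    # stem stroke
    stem <- resample_by_z(s$stem_polyline, step)
    r_stem <- s$params$stalk_diameter_phi / 2 * ppm
    img <- stamp_disks(img, stem * ppm, rep(r_stem, nrow(stem)), config$fg_gray)
    # leaves: tapered strokes along the leaf centreline
    for (l in s$leaves) {
      n <- max(2L, ceiling(sum(sqrt(rowSums(diff(l$centre)^2))) / step))
      t <- seq(0, 1, length.out = n)
      ctr <- cbind(approx(seq_along(l$centre[, 1]), l$centre[, 1], xout = 1 + t * (nrow(l$centre) - 1))$y,
                   approx(seq_along(l$centre[, 2]), l$centre[, 2], xout = 1 + t * (nrow(l$centre) - 1))$y)
      hw <- approx(seq_along(l$half_width), l$half_width, xout = 1 + t * (length(l$half_width) - 1))$y
      img <- stamp_disks(img, ctr * ppm, hw * ppm, config$fg_gray)
    }
    # bud blob at the tip
    img <- stamp_disks(img, matrix(s$tip * ppm, 1), s$bud_radius_mm * ppm,
                       config$fg_gray)
  }

  if (config$n_clutter > 0) {
    cz0 <- truth$canopy_z_mm
    for (i in seq_len(config$n_clutter)) {
      cx <- runif(1, 0, truth$world_window[1])
      cz <- runif(1, cz0, truth$world_window[2])
      img <- stamp_disks(img, matrix(c(cx, cz) * ppm, 1),
                         runif(1, 1, 4) * ppm, config$clutter_gray)
    }
  }
  if (config$noise > 0) {
    img <- img + as.integer(round(rnorm(length(img), 0, config$noise * 255)))
    img <- matrix(as.integer(clamp(img, 0L, 255L)), nrow = H)
  }

  img <- matrix(as.integer(img), H, W)

  boxes <- do.call(rbind, lapply(truth$shoots, function(s) {
    b <- s$bbox_world
    data.frame(shoot_id = s$id,
               x_min = max(0L, floor(b["x_min"] * ppm)),
               z_min = max(0L, floor(b["z_min"] * ppm)),
               x_max = min(W, ceiling(b["x_max"] * ppm)),
               z_max = min(H, ceiling(b["z_max"] * ppm)))
  }))
  rownames(boxes) <- NULL
  for (i in seq_len(nrow(boxes))) {
    stopf(boxes$x_min[i] < boxes$x_max[i] && boxes$z_min[i] < boxes$z_max[i],
          "shoot %d: degenerate pixel box", boxes$shoot_id[i])
  }
  structure(list(image = img, px_per_mm = ppm, image_height_Ht = H,
                 image_width_px = W, boxes = boxes),
            class = "rendered_scene")
}

#' @export
print.rendered_scene <- function(x, ...) {
  cat(sprintf("<rendered_scene> %d x %d px (%.1f px/mm), %d boxes\n",
              x$image_height_Ht, x$image_width_px, x$px_per_mm, nrow(x$boxes)))
  invisible(x)
}

#' Read and write grayscale images
#'
#' Images are stored as 8-bit grayscale PNG (or TIFF when the `tiff` package
#' is available and the filename ends in `.tif`/`.tiff`). In memory an image
#' is an integer matrix of gray levels 0-255 with rows running down the scene.
#'
#' @param image Integer/numeric matrix, gray levels 0-255.
#' @param path File path.
#' @return `read_image()` returns an integer matrix; `write_image()` returns
#'   `path` invisibly.
#' @export
write_image <- function(image, path) {
  stopf(is.matrix(image), "image must be a matrix")
  m <- clamp(image, 0, 255) / 255
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stopf(requireNamespace("tiff", quietly = TRUE), "package 'tiff' required for TIFF output")
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  } else {
    png::writePNG(m, path)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  m <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stopf(requireNamespace("tiff", quietly = TRUE), "package 'tiff' required for TIFF input")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(m)) == 3) m <- m[, , 1]   # first channel of RGB(A)
  matrix(as.integer(round(m * 255)), nrow = nrow(m))
}

#' Write a synthetic scene to disk
#'
#' Writes `scene.png` (8-bit grayscale), `truth.json` (world-coordinate
#' ground truth: shoots with stem polylines, tips, picking points, leaf
#' polygons and boxes) and `labels.txt` (normalized detection labels, one
#' `class xc yc w h` line per box).
#'
#' @param scene A `rendered_scene`.
#' @param truth The matching `scene_truth`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, "scene.png")
  write_image(scene$image, img_path)
  lbl_path <- file.path(dir, "labels.txt")
  write_yolo_labels(scene$boxes, scene$image_width_px, scene$image_height_Ht,
                    lbl_path)
  truth_path <- file.path(dir, "truth.json")
  write_scene_truth(truth, scene, truth_path)
  invisible(c(image = img_path, labels = lbl_path, truth = truth_path))
}

#' Serialize / deserialize scene ground truth as JSON
#'
#' @param truth A `scene_truth`.
#' @param scene Optional matching `rendered_scene` (adds pixel metadata).
#' @param path JSON file path.
#' @return `write_scene_truth()` returns `path` invisibly;
#'   `read_scene_truth()` returns a `scene_truth`.
#' @export
write_scene_truth <- function(truth, scene = NULL, path) {
  obj <- list(
    world_window = as.numeric(truth$world_window),
    canopy_z_mm = truth$canopy_z_mm,
    px_per_mm = if (!is.null(scene)) scene$px_per_mm else NULL,
    shoots = lapply(truth$shoots, function(s) list(
      id = s$id,
      tip = as.numeric(s$tip),
      pick_point = as.numeric(s$true_pick_point),
      bud_radius_mm = s$bud_radius_mm,
      stem_polyline = unname(s$stem_polyline),
      leaf_polygons = lapply(s$leaf_polygons, unname),
      bbox_world = as.numeric(s$bbox_world),
      params = s$params[!vapply(s$params, is.na, logical(1))]
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_truth
#' @export
read_scene_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_mat <- function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
    colnames(m) <- c("X", "Z")
    m
  }
  shoots <- lapply(obj$shoots, function(s) {
    list(id = s$id, tip = setNames(as.numeric(unlist(s$tip)), c("X", "Z")),
         true_pick_point = setNames(as.numeric(unlist(s$pick_point)), c("X", "Z")),
         bud_radius_mm = s$bud_radius_mm,
         stem_polyline = as_mat(s$stem_polyline),
         leaf_polygons = lapply(s$leaf_polygons, as_mat),
         bbox_world = setNames(as.numeric(unlist(s$bbox_world)),
                               c("x_min", "z_min", "x_max", "z_max")),
         params = lapply(s$params, function(p) as.numeric(p)))
  })
  structure(list(shoots = shoots, canopy_z_mm = obj$canopy_z_mm,
                 world_window = setNames(as.numeric(obj$world_window),
                                         c("width", "height"))),
            class = "scene_truth")
}
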