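# build a synthetic skeleton directly: vertical stem with two leaf branches
# diverging at a known junction row (0-based coordinates)
synthetic_y_skeleton <- function(nr = 60, nc = 41, junction_row = 10,
                                 stem_col = 20, leaf_len = 12) {
  sk <- matrix(0L, nr, nc)
  sk[(junction_row + 1):nr, stem_col + 1] <- 1L
  for (k in seq_len(leaf_len)) {
    sk[junction_row + 1 + k, stem_col + 1 - k] <- 1L
    sk[junction_row + 1 + k, stem_col + 1 + k] <- 1L
  }
  sk
}

test_that("the bud-leaf intersection is found at the known junction row", {
  sk <- synthetic_y_skeleton()
  box <- detection_box(0, 0, 41, 60)
  ix <- find_intersection(sk, box)
  expect_lte(abs(ix$point["row"] - 10), 1)
  expect_equal(unname(ix$point["col"]), 20)
  expect_true(is.na(ix$flag))

  # a bare vertical line has no multi-pixel row: flagged fallback at its bottom
  line <- matrix(0L, 30, 11); line[5:25, 6] <- 1L
  ixl <- find_intersection(line, detection_box(0, 0, 11, 30))
  expect_equal(ixl$flag, "leafless_fallback")
  expect_equal(unname(ixl$point["row"]), 24)

  expect_error(find_intersection(matrix(0L, 10, 10), detection_box(0, 0, 10, 10)),
               "no skeleton pixel")
})

test_that("stem tracing follows the vertical stem, not the leaf branches", {
  sk <- synthetic_y_skeleton()
  box <- detection_box(0, 0, 41, 60)
  ix <- find_intersection(sk, box)
  tr <- trace_stem(sk, ix$point, box)
  expect_s3_class(tr, "stem_trace")
  # all traced columns on the stem, rows reach the box bottom
  expect_true(all(tr$path[-1, "col"] == 20))
  expect_equal(unname(tr$path[nrow(tr$path), "row"]), 59)
  expect_true(is.na(tr$flag))

  # straight vertical skeleton: path has constant column, length = extent
  line <- matrix(0L, 55, 11); line[3:52, 6] <- 1L
  trl <- trace_stem(line, c(2, 5), detection_box(0, 0, 11, 55))
  expect_equal(nrow(trl$path), 50)
  expect_true(all(trl$path[, "col"] == 5))
  expect_equal(trl$arc_length_px, 49)

  # dead end: starting at the bottom tip pointing down
  trd <- trace_stem(line, c(51, 5), detection_box(0, 45, 11, 52))
  expect_equal(trd$flag, "short_trace")
})

test_that("growth-curve fitting reduces degree, interpolates exact polynomials, and tolerates noise", {
  # vertical trace collapses to a constant fit
  line <- matrix(0L, 30, 11); line[2:29, 6] <- 1L
  tr <- trace_stem(line, c(1, 5), detection_box(0, 0, 11, 30))
  cv <- fit_growth_curve(tr)
  expect_equal(cv$degree, 0)
  expect_equal(predict_curve(cv, c(5, 20)), c(5, 5))

  # exact quadratic is interpolated to numerical precision
  rows <- 0:20
  cols <- 3 + 0.05 * (rows - 10)^2
  trq <- structure(list(path = cbind(row = rows, col = cols),
                        arc_length_px = 20, flag = NA_character_),
                   class = "stem_trace")
  cvq <- fit_growth_curve(trq, degree = 3)
  expect_lt(cvq$fit_residual, 1e-6)
  expect_equal(predict_curve(cvq, 4), 3 + 0.05 * 36, tolerance = 1e-6)

  # noisy quadratic: residual stays below 3 sigma
  set.seed(31)
  noisy <- cols + rnorm(length(cols), 0, 0.5)
  trn <- structure(list(path = cbind(row = rows, col = noisy),
                        arc_length_px = 20, flag = NA_character_),
                   class = "stem_trace")
  expect_lt(fit_growth_curve(trn, degree = 2)$fit_residual, 1.5)
})

test_that("the 4 mm offset is exactly 20 rows at the 980 px / 196 mm calibration", {
  calib <- camera_calibration(Ht = 980)
  line <- matrix(0L, 100, 11); line[2:99, 6] <- 1L
  tr <- trace_stem(line, c(1, 5), detection_box(0, 0, 11, 100))
  cv <- fit_growth_curve(tr)
  pt <- locate_pick_point_px(cv, c(10, 5), offset_mm = 4, calib = calib)
  expect_equal(unname(pt$point), c(30, 5))   # 4 * 980 / 196 = 20 rows down
  expect_true(is.na(pt$flag))

  pt0 <- locate_pick_point_px(cv, c(10, 5), offset_mm = 0, calib = calib)
  expect_equal(unname(pt0$point["row"]), 10)

  # offsets beyond the fitted range clamp and flag
  ptc <- locate_pick_point_px(cv, c(95, 5), offset_mm = 4, calib = calib)
  expect_equal(ptc$flag, "offset_clamped")
  expect_equal(unname(ptc$point["row"]), 98)

  # monotonicity: larger offsets move strictly down
  zs <- sapply(1:8, function(o) {
    locate_pick_point_px(cv, c(10, 5), o, calib)$point["row"]
  })
  expect_true(all(diff(zs) > 0))
})

test_that("pixel-to-world calibration is linear, proportional and invertible", {
  calib <- camera_calibration(Ht = 980)
  expect_equal(unname(pixel_to_world(c(0, 0), calib)), c(0, 0))
  expect_equal(unname(pixel_to_world(c(0, 980), calib)["Zs"]), 196)
  expect_equal(unname(pixel_to_world(c(0, 490), calib)["Zs"]), 98)
  # linearity
  a <- pixel_to_world(c(100, 200), calib)
  b <- pixel_to_world(c(300, 500), calib)
  ab <- pixel_to_world(c(400, 700), calib)
  expect_equal(unname(a + b), unname(ab), tolerance = 1e-12)
  # round trip
  set.seed(3)
  pts <- cbind(runif(20, 0, 900), runif(20, 0, 979))
  back <- world_to_pixel(pixel_to_world(pts, calib), calib)
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("blade displacement is measured from the parked blade or the previous cut", {
  calib <- camera_calibration(980)
  expect_equal(blade_displacement(0, calib), 16)           # Hz - Hs
  expect_equal(blade_displacement(40, calib, from = 40), 0)
  expect_equal(blade_displacement(100, calib, from = 40), 60)
  expect_equal(blade_displacement(40, calib, from = 100), -60)
  expect_error(blade_displacement(300, calib), "outside the shooting window")
})

test_that("locate_all recovers every shoot of a rendered scene within tolerance", {
  vs <- vertical_shoot_scene(seed = 5, n_shoots = 3)
  pp <- locate_all(vs$scene$image, vs$scene$boxes, vs$calib)
  expect_equal(nrow(pp), 3)
  expect_true(all(!is.na(pp$Xs_mm)))
  le <- localization_errors(pp, vs$truth)
  expect_equal(nrow(le$errors), 3)
  expect_lt(max(le$errors$error_mm), 3)

  # empty box list
  expect_equal(nrow(locate_all(vs$scene$image, vs$scene$boxes[0, ], vs$calib)), 0)

  # FOV filter on: off-centre boxes are skipped with a recorded reason
  ppf <- locate_all(vs$scene$image, vs$scene$boxes, vs$calib,
                    locate_config(fov_width_px = 200))
  skipped <- ppf[ppf$flags == "fov_skipped" & !is.na(ppf$flags), ]
  centred <- abs((vs$scene$boxes$x_min + vs$scene$boxes$x_max) / 2 -
                   ncol(vs$scene$image) / 2) <= 100
  expect_equal(nrow(skipped), sum(!centred))
  expect_equal(nrow(ppf), 3)
})

test_that("the traced stem of a bowed shoot stays within a pixel of the true centreline", {
  cfg <- scene_config(ranges = utils::modifyList(shoot_param_ranges(),
                                                 list(curvature_amplitude = c(2.5, 2.5))))
  truth <- build_scene(1, cfg, seed = 19)
  sc <- render_scene(truth, seed = 19)
  calib <- camera_calibration(Ht = sc$image_height_Ht)
  b <- sc$boxes[1, ]
  crop <- sc$image[(b$z_min + 1):b$z_max, (b$x_min + 1):b$x_max]
  sk <- thin(binarize(crop))
  lbox <- detection_box(0, 0, ncol(sk), nrow(sk))
  ix <- find_intersection(sk, lbox)
  tr <- trace_stem(sk, ix$point, lbox)
  ppm <- sc$px_per_mm
  s <- truth$shoots[[1]]
  # compare traced columns (skip the junction neighbourhood) to the quadratic
  path <- tr$path[tr$path[, "row"] > unname(ix$point["row"]) + 10, , drop = FALSE]
  true_cols <- approx(s$stem_polyline[, 2] * ppm - b$z_min,
                      s$stem_polyline[, 1] * ppm - b$x_min,
                      xout = path[, "row"] + 0.5)$y
  expect_lt(max(abs(path[, "col"] + 0.5 - true_cols)), 1.5)
})

test_that("normalized label files convert to pixel boxes and back", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "labels.txt")
  boxes <- data.frame(class_id = c(0L, 0L),
                      x_min = c(10L, 200L), z_min = c(20L, 300L),
                      x_max = c(110L, 360L), z_max = c(220L, 700L))
  write_yolo_labels(boxes, 640, 980, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  expect_match(lines[1], "^0 0\\.\\d{6} 0\\.\\d{6} 0\\.\\d{6} 0\\.\\d{6}$")
  rt <- read_yolo_labels(path, 640, 980)
  expect_equal(rt[, c("x_min", "z_min", "x_max", "z_max")],
               boxes[, c("x_min", "z_min", "x_max", "z_max")],
               tolerance = 1e-9)
  # malformed labels are rejected
  writeLines("0 0.5 0.5 0.1", path)
  expect_error(read_yolo_labels(path, 640, 980), "5 fields")
})
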