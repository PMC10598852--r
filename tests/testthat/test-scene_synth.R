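test_that("sampled shoot parameters stay inside their biometric ranges and are reproducible", {
  rng <- shoot_param_ranges()
  set.seed(1)
  p <- sample_shoot_params()
  for (nm in names(rng)) {
    expect_gte(p[[nm]], rng[[nm]][1])
    expect_lte(p[[nm]], rng[[nm]][2])
  }
  set.seed(1)
  p2 <- sample_shoot_params()
  expect_identical(p, p2)

  # collapsed intervals return exact values
  degen <- lapply(rng, function(r) rep(28.0, 2))
  degen$curvature_amplitude <- c(0, 0)
  degen$tip_height <- c(60, 60)
  pd <- sample_shoot_params(degen)
  expect_equal(pd$shoot_length_L, 28.0)
  expect_equal(pd$tip_height, 60)
  expect_equal(pd$curvature_amplitude, 0)

  bad <- rng; bad$shoot_length_L <- c(30, 20)
  expect_error(sample_shoot_params(bad), "min <= max")
  bad <- rng; bad$stalk_diameter_phi <- c(-1, 2)
  expect_error(sample_shoot_params(bad), "positive")
})

test_that("scene tips are spaced 50-80 mm apart and pick points drop exactly offset_mm below tips", {
  for (seed in c(7, 21, 99)) {
    truth <- build_scene(3, seed = seed)
    tips_x <- sapply(truth$shoots, function(s) s$tip["X"])
    gaps <- diff(tips_x)
    expect_true(all(gaps >= 50 & gaps <= 80))
    for (s in truth$shoots) {
      expect_equal(unname(s$true_pick_point["Z"] - s$tip["Z"]),
                   truth$config$offset_mm, tolerance = 1e-12)
      expect_true(all(diff(s$stem_polyline[, 2]) > 0))
    }
  }
  # spacing law over many seeds
  for (seed in 1:100) {
    truth <- build_scene(2, seed = seed)
    gap <- truth$shoots[[2]]$tip["X"] - truth$shoots[[1]]$tip["X"]
    expect_gte(unname(gap), 50)
    expect_lte(unname(gap), 80)
  }
  # single shoot: no spacing constraint involved
  expect_length(build_scene(1, seed = 3)$shoots, 1)
  # window too small for the shoots at minimum spacing
  expect_error(build_scene(5, scene_config(world_width_mm = 150), seed = 1),
               "too small")
})

test_that("pick point interpolation matches the generator's quadratic analytically", {
  # hand-built bowed stem: X(Z) = 10 + 0.01 (Z - 20)^2, tip at Z = 20
  z <- seq(20, 60, by = 0.25)
  stem <- cbind(X = 10 + 0.01 * (z - 20)^2, Z = z)
  pp <- true_pick_point(stem, 4)
  expect_equal(unname(pp["Z"]), 24)
  expect_equal(unname(pp["X"]), 10 + 0.01 * 16, tolerance = 1e-4)

  # vertical stem and identity offset
  stem_v <- cbind(X = rep(10, 5), Z = seq(20, 60, by = 10))
  expect_equal(unname(true_pick_point(stem_v, 4)), c(10, 24))
  expect_equal(unname(true_pick_point(stem_v, 0)), c(10, 20))
  expect_error(true_pick_point(stem_v, 100), "shorter than offset")

  # zero curvature amplitude makes every stem exactly vertical
  cfg <- scene_config(ranges = utils::modifyList(shoot_param_ranges(),
                                                 list(curvature_amplitude = c(0, 0))))
  truth <- build_scene(2, cfg, seed = 11)
  for (s in truth$shoots) {
    expect_equal(diff(range(s$stem_polyline[, 1])), 0)
  }
})

test_that("rendering is deterministic, leaves the area above the tip blank, and boxes are noise-invariant", {
  truth <- build_scene(1, seed = 13)
  sc1 <- render_scene(truth, seed = 4)
  sc2 <- render_scene(truth, seed = 4)
  expect_identical(sc1$image, sc2$image)
  expect_equal(nrow(sc1$boxes), 1)

  ppm <- sc1$px_per_mm
  s <- truth$shoots[[1]]
  b <- sc1$boxes[1, ]
  crop <- sc1$image[(b$z_min + 1):b$z_max, (b$x_min + 1):b$x_max]
  expect_gt(sum(crop > 100), 0)
  # blank above the tip minus the bud radius
  top_clear <- floor((s$tip["Z"] - s$bud_radius_mm) * ppm) - 1
  expect_true(all(sc1$image[1:top_clear, ] <= 100))

  # noise changes pixels but not ground-truth boxes
  sc_noise <- render_scene(truth, render_config(noise = 0.1), seed = 4)
  expect_identical(sc1$boxes, sc_noise$boxes)
  expect_false(identical(sc1$image, sc_noise$image))

  expect_error(render_scene(truth, render_config(px_per_mm = 1)), "px_per_mm")
})

test_that("world-to-pixel round trip recovers coordinates within half a pixel pitch", {
  truth <- build_scene(2, seed = 17)
  sc <- render_scene(truth)
  calib <- camera_calibration(Ht = sc$image_height_Ht)
  for (s in truth$shoots) {
    px <- world_to_pixel(unname(s$true_pick_point), calib)
    # quantize to the containing pixel centre, map back
    centre <- floor(px) + 0.5
    back <- pixel_to_world(centre, calib)
    pitch <- 1 / sc$px_per_mm
    expect_lt(max(abs(back - s$true_pick_point)), pitch / 2 + 1e-12)
  }
})

test_that("scenes round-trip through PNG, truth JSON and label text", {
  dir <- withr::local_tempdir()
  truth <- build_scene(2, seed = 23)
  sc <- render_scene(truth, seed = 23)
  paths <- write_scene(sc, truth, dir)
  expect_true(all(file.exists(paths)))

  img <- read_image(paths["image"])
  expect_identical(img, sc$image)

  tr <- read_scene_truth(paths["truth"])
  expect_equal(length(tr$shoots), 2)
  expect_equal(tr$shoots[[1]]$true_pick_point, truth$shoots[[1]]$true_pick_point,
               tolerance = 1e-9)
  expect_equal(tr$shoots[[2]]$stem_polyline, truth$shoots[[2]]$stem_polyline,
               ignore_attr = TRUE, tolerance = 1e-9)

  boxes <- read_yolo_labels(paths["labels"], sc$image_width_px, sc$image_height_Ht)
  expect_equal(nrow(boxes), 2)
  # normalized 6-decimal round trip is exact to within one pixel
  expect_true(all(abs(boxes$x_min - sc$boxes$x_min) <= 1))
  expect_true(all(abs(boxes$z_max - sc$boxes$z_max) <= 1))
})
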