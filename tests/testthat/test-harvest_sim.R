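test_that("localization matching pairs points within the radius and counts misses", {
  truth <- build_scene(3, seed = 7)
  exact <- do.call(rbind, lapply(truth$shoots, function(s) {
    data.frame(Xs_mm = s$true_pick_point[1], Zs_mm = s$true_pick_point[2])
  }))
  le <- localization_errors(exact, truth)
  expect_equal(nrow(le$errors), 3)
  expect_equal(le$errors$error_mm, rep(0, 3))
  expect_equal(le$n_unmatched_truth, 0)

  # a 2 mm vertical displacement is measured as exactly 2 mm
  off <- exact; off$Zs_mm[1] <- off$Zs_mm[1] + 2
  le2 <- localization_errors(off, truth)
  expect_equal(le2$errors$error_mm[le2$errors$shoot_id == 1], 2)
  expect_equal(le2$errors$dz_mm[le2$errors$shoot_id == 1], 2)

  # beyond the radius: unmatched on both sides
  far <- exact; far$Xs_mm[2] <- far$Xs_mm[2] + 15
  le3 <- localization_errors(far, truth, match_radius_mm = 10)
  expect_equal(le3$n_unmatched_truth, 1)
  expect_equal(le3$n_unmatched_pred, 1)

  # NA predictions count as failed localizations
  nas <- exact; nas$Xs_mm[3] <- NA
  expect_equal(localization_errors(nas, truth)$n_unmatched_truth, 1)
})

test_that("success rates reproduce the field-trial accounting", {
  expect_equal(unname(success_rates(98, 90, 82)), c(91.8, 83.6))
  expect_equal(unname(success_rates(10, 10, 10)), c(100, 100))
  expect_equal(unname(success_rates(10, 5, 0)), c(50, 0))
  expect_error(success_rates(0, 0, 0), "positive")
  expect_error(success_rates(10, 5, 7), "n_picked <= n_clamped")

  # monotonicity: picking more shoots never lowers a rate
  set.seed(12)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    cl <- sample(0:n, 1)
    pk <- sample(0:cl, 1)
    r1 <- success_rates(n, cl, pk)
    if (cl < n) expect_gte(success_rates(n, cl + 1, pk)[1], r1[1])
    if (pk < cl) expect_gte(success_rates(n, cl, pk + 1)[2], r1[2])
  }
})

test_that("detection metrics follow the precision/recall/harmonic-mean definitions", {
  expect_equal(unname(detection_metrics(1, 0, 0)), c(1, 1, 1))

  m <- detection_metrics(83, 17, 25)
  expect_equal(unname(m["Pc"]), 0.83)
  # closed-form harmonic mean of the computed precision and recall
  expect_equal(unname(m["Fc"]),
               2 * m[["Pc"]] * m[["Rc"]] / (m[["Pc"]] + m[["Rc"]]))

  # the published-style operating point: Pc = 0.83, Rc = 0.75
  fc <- 2 * 0.83 * 0.75 / (0.83 + 0.75)
  expect_equal(fc, 0.7879747, tolerance = 1e-6)

  z <- detection_metrics(0, 5, 5)
  expect_equal(unname(z[c("Pc", "Rc")]), c(0, 0))
  expect_true(is.na(z["Fc"]))
  expect_true(is.na(detection_metrics(0, 0, 5)["Pc"]))

  # harmonic-mean bounds: Fc <= 2 min(Pc, Rc) and min(Pc, Rc) >= Fc / 2
  set.seed(8)
  for (i in 1:30) {
    tp <- sample(1:100, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    mm <- detection_metrics(tp, fp, fn)
    expect_lte(mm[["Fc"]], 2 * min(mm[["Pc"]], mm[["Rc"]]) + 1e-12)
    expect_gte(min(mm[["Pc"]], mm[["Rc"]]), mm[["Fc"]] / 2 - 1e-12)
    expect_lte(mm[["Fc"]], max(mm[["Pc"]], mm[["Rc"]]) + 1e-12)
  }
})

test_that("a feasible schedule with accurate localization yields a 100% pick rate", {
  vs <- vertical_shoot_scene(seed = 41, n_shoots = 3)
  pp <- locate_all(vs$scene$image, vs$scene$boxes, vs$calib)
  ord <- order(pp$Xs_mm)
  sched <- schedule_row(pp[ord, ], V = 0.001, scurve_params(),
                        geometry = list(calib = vs$calib))
  rep <- run_trial(vs$truth, sched, pp[ord, ])
  expect_equal(rep$n_shoots, 3)
  expect_equal(rep$n_clamped, 3)
  expect_equal(rep$n_picked, 3)
  expect_equal(rep$pick_rate_pct, 100)

  # all cycles infeasible (carriage far too fast): clamp rate 0
  fast <- schedule_row(pp[ord, ], V = 5, scurve_params(),
                       geometry = list(calib = vs$calib))
  rep0 <- run_trial(vs$truth, fast, pp[ord, ])
  expect_equal(rep0$n_clamped, 0)
  expect_equal(rep0$clamp_rate_pct, 0)
  expect_equal(rep0$n_picked, 0)

  # schedule/points mismatch is an error
  expect_error(run_trial(vs$truth, sched, pp[ord, ][1:2, ]), "does not match")
})

test_that("noisy rendering degrades gracefully: flagged failures, no crash", {
  truth <- build_scene(3, seed = 55)
  sc <- render_scene(truth, render_config(noise = 0.1), seed = 55)
  calib <- camera_calibration(Ht = sc$image_height_Ht)
  pp <- locate_all(sc$image, sc$boxes, calib)
  expect_equal(nrow(pp), 3)          # every box reported, flagged or located
  rep <- run_trial(truth, NULL, pp)
  expect_s3_class(rep, "trial_report")
  expect_lte(rep$n_picked, rep$n_clamped)
})

test_that("residual stalk accounting separates clean picks from bud damage", {
  truth <- build_scene(1, seed = 3)
  s <- truth$shoots[[1]]
  mk <- function(z) data.frame(Xs_mm = s$true_pick_point[1], Zs_mm = z)
  # cut at the true point: picked
  rep1 <- run_trial(truth, NULL, mk(s$true_pick_point[2]))
  expect_equal(rep1$n_picked, 1)
  # cut inside the bud (above the bud base) but within tolerance of the true
  # point: clamped, yet not picked — the bud is damaged
  rep2 <- run_trial(truth, NULL, mk(s$tip[2] + 1.1))
  expect_equal(rep2$n_clamped, 1)
  expect_equal(rep2$n_picked, 0)
  # cut far below: residual stalk exceeds the 5 mm limit
  rep3 <- run_trial(truth, NULL, mk(s$tip[2] + 8))
  expect_equal(rep3$n_picked, 0)
})
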