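#' Trial scoring configuration
#'
#' @param tolerance_mm Maximum allowed distance between the cut height and
#'   the true picking point for a pick to count as successful (default 3).
#' @param stalk_success_mm Maximum residual stalk length on a successfully
#'   picked shoot (default 5): the picked shoot must carry less than this
#'   much stalk below the bud base.
#' @param match_radius_mm Matching radius for pairing predicted and true
#'   picking points (default 10).
#' @param carriage_speed_V Horizontal carriage speed in m/s (default 0.05).
#' @param seed Integer seed recorded with the trial.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(tolerance_mm = 3, stalk_success_mm = 5,
                         match_radius_mm = 10, carriage_speed_V = 0.05,
                         seed = 1L) {
  stopf(tolerance_mm > 0 && stalk_success_mm > 0 && match_radius_mm > 0 &&
          carriage_speed_V > 0, "all trial_config values must be positive")
  structure(list(tolerance_mm = tolerance_mm, stalk_success_mm = stalk_success_mm,
                 match_radius_mm = match_radius_mm,
                 carriage_speed_V = carriage_speed_V, seed = seed),
            class = "trial_config")
}

#' Match predicted picking points to ground truth and measure errors
#'
#' Greedy nearest-neighbour matching in world coordinates: the globally
#' closest (prediction, truth) pair within `match_radius_mm` is matched
#' first, then the next closest among the remainder, and so on. Unmatched
#' truths count as misses; unmatched predictions as spurious.
#'
#' @param predicted Data frame with `Xs_mm`, `Zs_mm` (rows with `NA`
#'   coordinates are treated as failed localizations).
#' @param truth A `scene_truth` from [build_scene()].
#' @param match_radius_mm Matching radius (mm), default 10.
#' @return List with `errors` data frame (`shoot_id`, `pred_row`, `error_mm`
#'   Euclidean, `dz_mm` vertical component), `n_unmatched_truth`,
#'   `n_unmatched_pred`.
#' @export
localization_errors <- function(predicted, truth, match_radius_mm = 10) {
  stopf(inherits(truth, "scene_truth"), "truth must be a scene_truth")
  tp <- do.call(rbind, lapply(truth$shoots, function(s) s$true_pick_point))
  ok <- !is.na(predicted$Xs_mm) & !is.na(predicted$Zs_mm)
  pp <- cbind(predicted$Xs_mm[ok], predicted$Zs_mm[ok])
  pred_idx <- which(ok)
  nt <- nrow(tp); np <- nrow(pp)
  errors <- data.frame(shoot_id = integer(), pred_row = integer(),
                       error_mm = numeric(), dz_mm = numeric())
  if (np > 0 && nt > 0) {
    d <- outer(seq_len(np), seq_len(nt),
               Vectorize(function(i, j) sqrt(sum((pp[i, ] - tp[j, ])^2))))
    repeat {
      m <- which.min(d)
      if (!length(m) || !is.finite(d[m]) || d[m] > match_radius_mm) break
      i <- ((m - 1) %% np) + 1
      j <- ((m - 1) %/% np) + 1
      errors <- rbind(errors, data.frame(
        shoot_id = truth$shoots[[j]]$id, pred_row = pred_idx[i],
        error_mm = d[m], dz_mm = pp[i, 2] - tp[j, 2]))
      d[i, ] <- Inf
      d[, j] <- Inf
    }
  }
  list(errors = errors[order(errors$shoot_id), , drop = FALSE],
       n_unmatched_truth = nt - nrow(errors),
       n_unmatched_pred = np - nrow(errors))
}

#' Clamping and picking success rates
#'
#' Both rates use the total number of test shoots as the denominator and are
#' truncated (rounded toward zero) to one decimal, mirroring how field-trial
#' tables report them: 82/98 shoots is reported as 83.6%, not 83.7%.
#'
#' @param n_shoots Total shoots tested (> 0).
#' @param n_clamped Shoots whose stalk was successfully clamped upright.
#' @param n_picked Shoots picked undamaged with residual stalk under the
#'   success limit.
#' @return Named numeric `c(clamp_rate_pct, pick_rate_pct)`.
#' @export
#' @examples
#' success_rates(98, 90, 82)  # 91.8, 83.6
success_rates <- function(n_shoots, n_clamped, n_picked) {
  stopf(is_count(n_shoots) && is_count(n_clamped) && is_count(n_picked),
        "counts must be non-negative integers")
  stopf(n_shoots > 0, "n_shoots must be positive")
  stopf(n_picked <= n_clamped && n_clamped <= n_shoots,
        "need n_picked <= n_clamped <= n_shoots")
  c(clamp_rate_pct = trunc_1dp(100 * n_clamped / n_shoots),
    pick_rate_pct = trunc_1dp(100 * n_picked / n_shoots))
}

#' Detection precision, recall and F-score
#'
#' `Pc = TP / (TP + FP)`, `Rc = TP / (TP + FN)`, and their harmonic mean
#' `Fc = 2 Pc Rc / (Pc + Rc)`. Undefined quantities (zero denominators) are
#' reported as `NA`, not coerced to 0.
#'
#' @param TP,FP,FN Non-negative integer counts: correctly identified,
#'   incorrectly identified, and unidentified shoots.
#' @return Named numeric `c(Pc, Rc, Fc)` with `NA` for undefined values.
#' @export
#' @examples
#' detection_metrics(82, 17, 27)
detection_metrics <- function(TP, FP, FN) {
  stopf(is_count(TP) && is_count(FP) && is_count(FN),
        "counts must be non-negative integers")
  Pc <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  Rc <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  Fc <- if (!is.na(Pc) && !is.na(Rc) && (Pc + Rc) > 0) {
    2 * Pc * Rc / (Pc + Rc)
  } else NA_real_
  c(Pc = Pc, Rc = Rc, Fc = Fc)
}

# residual stalk length: along-stem arc length from the cut height down from
# the bud base (tip + bud radius). Negative when the cut lands inside the bud.
residual_stalk_mm <- function(shoot, cut_z_mm) {
  stem <- shoot$stem_polyline
  arc <- polyline_arclen(stem)
  z <- stem[, 2]
  base_z <- shoot$tip[2] + shoot$bud_radius_mm
  at <- function(zz) approx(z, arc, xout = clamp(zz, z[1], z[length(z)]))$y
  at(cut_z_mm) - at(base_z)
}

#' Score a simulated harvest trial
#'
#' A shoot counts as *clamped* when its localization matched a true shoot and
#' its scheduled picker transition was feasible (the picker reached the
#' waiting zone before the shoot arrived). A clamped shoot counts as *picked*
#' when the cut height lies within `tolerance_mm` of the true picking point
#' and the residual stalk below the bud base is non-negative and shorter
#' than `stalk_success_mm` (an intact, short-stalked shoot).
#'
#' @param truth A `scene_truth`.
#' @param schedule A [schedule_row()] result for `pick_points` (or `NULL`,
#'   in which case every matched shoot is treated as clamped).
#' @param pick_points A `pick_points` data frame from [locate_all()].
#' @param config A [trial_config()].
#' @return Object of class `trial_report`: counts `n_shoots`, `n_clamped`,
#'   `n_picked`, rates `clamp_rate_pct`, `pick_rate_pct`, the per-shoot
#'   `errors_mm` data frame, and `infeasible` (indices of shoots whose
#'   transition was skipped).
#' @export
run_trial <- function(truth, schedule, pick_points, config = trial_config()) {
  stopf(inherits(truth, "scene_truth"), "truth must be a scene_truth")
  if (!is.null(schedule)) {
    stopf(nrow(schedule) == nrow(pick_points),
          "schedule (%d rows) does not match pick_points (%d rows)",
          nrow(schedule), nrow(pick_points))
  }
  n <- length(truth$shoots)
  loc <- localization_errors(pick_points, truth, config$match_radius_mm)
  clamped <- logical(n)
  picked <- logical(n)
  infeasible <- integer(0)
  for (k in seq_len(nrow(loc$errors))) {
    e <- loc$errors[k, ]
    sid <- e$shoot_id
    shoot <- truth$shoots[[sid]]
    feas <- if (is.null(schedule)) TRUE else isTRUE(schedule$feasible[e$pred_row])
    if (!feas) {
      infeasible <- c(infeasible, sid)
      next
    }
    clamped[sid] <- TRUE
    cut_z <- pick_points$Zs_mm[e$pred_row]
    resid <- residual_stalk_mm(shoot, cut_z)
    dz <- abs(cut_z - shoot$true_pick_point[2])
    picked[sid] <- dz <= config$tolerance_mm &&
      resid >= 0 && resid < config$stalk_success_mm
  }
  rates <- success_rates(n, sum(clamped), sum(picked))
  structure(list(n_shoots = n, n_clamped = sum(clamped), n_picked = sum(picked),
                 clamp_rate_pct = unname(rates[1]),
                 pick_rate_pct = unname(rates[2]),
                 errors_mm = loc$errors,
                 n_unmatched_truth = loc$n_unmatched_truth,
                 infeasible = infeasible, config = config),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("<trial_report> %d shoots: %d clamped (%.1f%%), %d picked (%.1f%%)\n",
              x$n_shoots, x$n_clamped, x$clamp_rate_pct,
              x$n_picked, x$pick_rate_pct))
  if (nrow(x$errors_mm)) {
    cat(sprintf("  localization error: mean %.2f mm, max %.2f mm over %d matches\n",
                mean(x$errors_mm$error_mm), max(x$errors_mm$error_mm),
                nrow(x$errors_mm)))
  }
  if (x$n_unmatched_truth > 0) {
    cat(sprintf("  %d true shoots unmatched\n", x$n_unmatched_truth))
  }
  invisible(x)
}

#' Serialize a trial report to JSON
#'
#' @param report A `trial_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trial_report <- function(report, path) {
  obj <- report[c("n_shoots", "n_clamped", "n_picked",
                  "clamp_rate_pct", "pick_rate_pct",
                  "n_unmatched_truth", "infeasible")]
  obj$errors_mm <- report$errors_mm
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
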