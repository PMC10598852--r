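#' Construct a detection box
#'
#' Axis-aligned box in 0-based, half-open pixel coordinates: the box covers
#' rows `z_min .. z_max - 1` and columns `x_min .. x_max - 1`.
#'
#' @param x_min,z_min,x_max,z_max Integer pixel bounds, `min < max`.
#' @param class_id Integer class label (default 0).
#' @param confidence Optional detection confidence in `[0, 1]`.
#' @return A list of class `detection_box`.
#' @export
detection_box <- function(x_min, z_min, x_max, z_max, class_id = 0L,
                          confidence = NA_real_) {
  stopf(x_min < x_max && z_min < z_max, "box must satisfy min < max on both axes")
  stopf(x_min >= 0 && z_min >= 0, "box must have non-negative pixel bounds")
  structure(list(x_min = as.integer(x_min), z_min = as.integer(z_min),
                 x_max = as.integer(x_max), z_max = as.integer(z_max),
                 class_id = as.integer(class_id), confidence = confidence),
            class = "detection_box")
}

as_detection_box <- function(b) {
  if (inherits(b, "detection_box")) return(b)
  detection_box(b[["x_min"]], b[["z_min"]], b[["x_max"]], b[["z_max"]],
                if (!is.null(b[["class_id"]])) b[["class_id"]] else 0L,
                if (!is.null(b[["confidence"]])) b[["confidence"]] else NA_real_)
}

# skeleton pixels (0-based rows/cols) in one 0-based row of a box
row_skel_cols <- function(skeleton, row0, box) {
  cols <- box$x_min:(box$x_max - 1L)
  cols[skeleton[row0 + 1L, cols + 1L] == 1L]
}

# number of skeleton 8-neighbours of a 0-based pixel
skel_degree <- function(skeleton, r0, c0) {
  unname(neighbor_stats(skeleton, c(r0, c0))["B"])
}

#' Find the bud-leaf intersection inside a detection box
#'
#' Scans the skeleton rows inside the box from top to bottom and stops at the
#' first row holding two or more skeleton pixels — the row where the leaf
#' branches diverge from the stem. Within a small window below that row the
#' junction pixel (a skeleton pixel with three or more skeleton neighbours)
#' is preferred as the returned point; if no junction pixel exists, the
#' skeleton pixel of the stop row nearest the row's median column is
#' returned. A skeleton that never shows a multi-pixel row (a leafless,
#' degenerate shoot) falls back to its lowest single-pixel row and is
#' flagged.
#'
#' @param skeleton Integer 0/1 matrix from [thin()].
#' @param box A [detection_box()] (or coercible list), inside the skeleton.
#' @param junction_window Rows below the stop row searched for a junction
#'   pixel (default 3).
#' @return List with `point` (`c(row, col)`, 0-based) and `flag`
#'   (`NA` or `"leafless_fallback"`).
#' @export
find_intersection <- function(skeleton, box, junction_window = 3L) {
  box <- as_detection_box(box)
  stopf(box$x_max <= ncol(skeleton) && box$z_max <= nrow(skeleton),
        "box extends outside the skeleton")
  rows <- box$z_min:(box$z_max - 1L)
  first_multi <- NA_integer_
  last_single <- NA_integer_
  for (r in rows) {
    cs <- row_skel_cols(skeleton, r, box)
    if (length(cs) >= 2L) { first_multi <- r; break }
    if (length(cs) == 1L) last_single <- r
  }
  if (is.na(first_multi)) {
    stopf(!is.na(last_single), "box contains no skeleton pixel")
    cs <- row_skel_cols(skeleton, last_single, box)
    return(list(point = c(row = last_single, col = cs[1]),
                flag = "leafless_fallback"))
  }
  cs <- row_skel_cols(skeleton, first_multi, box)
  med <- stats::median(cs)
  # junction pixels: skeleton degree >= 3 at or (a few rows) below the stop row
  search_rows <- first_multi:min(first_multi + junction_window, box$z_max - 1L)
  junctions <- NULL
  for (r in search_rows) {
    for (c in row_skel_cols(skeleton, r, box)) {
      if (skel_degree(skeleton, r, c) >= 3L) junctions <- rbind(junctions, c(r, c))
    }
    if (!is.null(junctions)) break   # take the topmost junction row
  }
  if (!is.null(junctions)) {
    pick <- junctions[which.min(abs(junctions[, 2] - med)), ]
    return(list(point = c(row = pick[1], col = pick[2]), flag = NA_character_))
  }
  list(point = c(row = first_multi, col = cs[which.min(abs(cs - med))]),
       flag = NA_character_)
}

# greedy probe: walk `depth` steps down a branch starting with `first`,
# returning net row progress minus net column drift. The stem is near
# vertical (score ~ depth); a leaf branch at >= 45 degrees from the stem
# axis drifts at least one column per row (score ~ 0), so the stem always
# scores higher.
probe_branch <- function(skeleton, first, from, box, depth = 12L) {
  r <- first[1]; c <- first[2]
  seen <- matrix(c(from, first), ncol = 2, byrow = TRUE)
  for (step in seq_len(depth)) {
    best <- NULL; best_key <- c(-Inf, Inf)
    for (dr in 1:-1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr < box$z_min || rr >= box$z_max || cc < box$x_min || cc >= box$x_max) next
      if (rr < 0L || rr >= nrow(skeleton) || cc < 0L || cc >= ncol(skeleton)) next
      if (skeleton[rr + 1L, cc + 1L] != 1L) next
      if (any(seen[, 1] == rr & seen[, 2] == cc)) next
      key <- c(dr, -abs(dc))
      if (key[1] > best_key[1] || (key[1] == best_key[1] && key[2] > best_key[2])) {
        best <- c(rr, cc); best_key <- key
      }
    }
    if (is.null(best) || best_key[1] < 0) break   # dead end or upward-only
    r <- best[1]; c <- best[2]
    seen <- rbind(seen, best)
  }
  (r - from[1]) - abs(c - from[2])
}

#' Trace the stem skeleton downward from the intersection
#'
#' Walks 8-connected skeleton pixels starting at the intersection, never
#' revisiting a pixel. At junctions the neighbour maximizing downward
#' progress is taken (largest row increase; ties broken by the smallest
#' column deviation from the current heading), and when several branches
#' descend equally a short greedy look-ahead down each branch picks the one
#' with the best vertical progress per column drift — the near-vertical stem
#' rather than an oblique leaf. Single-row back-steps are tolerated (skeleton
#' staircases) but the walk stops rather than climb persistently. The walk
#' ends at the box bottom, the image edge, or a dead end.
#'
#' @param skeleton Integer 0/1 matrix.
#' @param start `c(row, col)`, 0-based, on the skeleton.
#' @param box A [detection_box()] restricting the walk.
#' @return Object of class `stem_trace`: list with `path` (n x 2 matrix of
#'   0-based `row, col`), `arc_length_px`, and `flag` (`NA` or
#'   `"short_trace"` when fewer than 3 pixels were traced).
#' @export
trace_stem <- function(skeleton, start, box) {
  box <- as_detection_box(box)
  r <- as.integer(start[1]); c <- as.integer(start[2])
  stopf(skeleton[r + 1L, c + 1L] == 1L, "start pixel (%d, %d) not on the skeleton", r, c)
  visited <- matrix(FALSE, nrow(skeleton), ncol(skeleton))
  path <- matrix(NA_integer_, nrow = (box$z_max - box$z_min) * 4L, ncol = 2)
  n <- 1L
  path[1, ] <- c(r, c)
  visited[r + 1L, c + 1L] <- TRUE
  heading_dc <- 0L
  arc <- 0
  up_steps <- 0L
  repeat {
    cand <- NULL
    for (dr in 1:-1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr < box$z_min || rr >= box$z_max || cc < box$x_min || cc >= box$x_max) next
      if (rr < 0L || rr >= nrow(skeleton) || cc < 0L || cc >= ncol(skeleton)) next
      if (visited[rr + 1L, cc + 1L] || skeleton[rr + 1L, cc + 1L] != 1L) next
      dev <- abs(cc - (c + heading_dc))
      cand <- rbind(cand, c(rr, cc, dr, dev))
    }
    if (is.null(cand)) break
    best_score <- NA_real_
    if (nrow(cand) == 1L) {
      best <- cand[1, 1:2]
    } else {
      # branching: look ahead down every branch (the stem may continue via a
      # sideways step while a leaf offers the immediate downward pixel) and
      # prefer the most vertical one; ties broken by the largest immediate
      # row gain, then the smallest deviation from the current heading
      scores <- apply(cand, 1, function(k) {
        probe_branch(skeleton, k[1:2], c(r, c), box)
      })
      top <- which(scores == max(scores))
      if (length(top) > 1L) top <- top[order(-cand[top, 3], cand[top, 4])]
      best <- cand[top[1], 1:2]
      best_score <- max(scores)
    }
    dr <- best[1] - r
    if (dr < 0L) {
      # start (or continue) climbing only when the look-ahead confirms the
      # branch heads downward overall — a staircase around the junction —
      # not when the skeleton simply dead-ends below
      if (is.na(best_score)) best_score <- probe_branch(skeleton, best, c(r, c), box)
      if (best_score <= 0) break
      up_steps <- up_steps + 1L
      if (up_steps > 1L) break   # persistent climbing: stop
    } else if (dr > 0L) up_steps <- 0L
    arc <- arc + sqrt(dr^2 + (best[2] - c)^2)
    heading_dc <- best[2] - c
    r <- best[1]; c <- best[2]
    n <- n + 1L
    if (n > nrow(path)) path <- rbind(path, path)  # grow (rare)
    path[n, ] <- c(r, c)
    visited[r + 1L, c + 1L] <- TRUE
    if (r >= box$z_max - 1L || r >= nrow(skeleton) - 1L) break
  }
  path <- path[seq_len(n), , drop = FALSE]
  colnames(path) <- c("row", "col")
  structure(list(path = path, arc_length_px = arc,
                 flag = if (n < 3L) "short_trace" else NA_character_),
            class = "stem_trace")
}

#' Fit the stem growth curve
#'
#' Least-squares polynomial fit of the skeleton column as a function of the
#' row over the traced stem (rows are centred before fitting for numerical
#' stability). The requested degree is reduced automatically when the trace
#' holds fewer than `degree + 1` points.
#'
#' @param trace A [trace_stem()] result.
#' @param degree Polynomial degree (default 3).
#' @return Object of class `growth_curve`: `coeffs` (ascending powers of the
#'   centred row), `center`, `valid_rows` `c(min, max)`, `fit_residual`
#'   (RMS, px) and `degree`.
#' @export
fit_growth_curve <- function(trace, degree = 3L) {
  stopf(inherits(trace, "stem_trace"), "trace must be a stem_trace")
  rows <- trace$path[, 1]; cols <- trace$path[, 2]
  stopf(length(rows) >= 2, "trace must hold at least 2 points")
  deg <- min(degree, length(unique(rows)) - 1L)
  deg <- max(deg, 0L)
  if (stats::var(cols) == 0) deg <- 0L   # perfectly vertical stem
  ctr <- mean(rows)
  x <- rows - ctr
  if (deg == 0L) {
    coeffs <- mean(cols)
    fitted <- rep(coeffs, length(cols))
  } else {
    fit <- lm(cols ~ poly(x, deg, raw = TRUE))
    coeffs <- unname(coef(fit))
    coeffs[is.na(coeffs)] <- 0
    fitted <- fitted(fit)
  }
  structure(list(coeffs = coeffs, center = ctr,
                 valid_rows = range(rows),
                 fit_residual = sqrt(mean((cols - fitted)^2)),
                 degree = deg),
            class = "growth_curve")
}

#' Evaluate a growth curve at given rows
#'
#' @param curve A [fit_growth_curve()] result.
#' @param rows Numeric vector of (continuous) row coordinates.
#' @return Predicted column coordinates.
#' @export
predict_curve <- function(curve, rows) {
  x <- rows - curve$center
  pw <- seq_along(curve$coeffs) - 1
  vapply(x, function(xi) sum(curve$coeffs * xi^pw), numeric(1))
}

#' Offset the picking point down the growth curve
#'
#' Converts the fixed picking offset (default 4 mm) into a vertical pixel
#' drop `offset_mm * Ht / Hs` and evaluates the growth curve that many rows
#' below the intersection, i.e. 4 mm toward the stalk base. Rows outside the
#' fitted range are clamped and flagged.
#'
#' @param curve A [fit_growth_curve()] result.
#' @param start Intersection point `c(row, col)`, 0-based.
#' @param offset_mm Vertical picking offset in mm (default 4).
#' @param calib A [camera_calibration()].
#' @return List with `point` (`c(row, col)`, continuous pixel coords) and
#'   `flag` (`NA` or `"offset_clamped"`).
#' @export
#' @examples
#' # at Ht = 980 px / Hs = 196 mm, 4 mm is exactly 20 rows
#' camera_calibration(980)$Ht / camera_calibration(980)$Hs * 4
locate_pick_point_px <- function(curve, start, offset_mm = 4, calib) {
  stopf(inherits(curve, "growth_curve"), "curve must be a growth_curve")
  stopf(inherits(calib, "camera_calibration"), "calib must be a camera_calibration")
  stopf(offset_mm >= 0, "offset_mm must be non-negative")
  dz_px <- offset_mm * calib$Ht / calib$Hs
  target <- start[1] + dz_px
  flag <- NA_character_
  if (target > curve$valid_rows[2] || target < curve$valid_rows[1]) {
    target <- clamp(target, curve$valid_rows[1], curve$valid_rows[2])
    flag <- "offset_clamped"
  }
  list(point = c(row = unname(target), col = unname(predict_curve(curve, target))),
       flag = flag)
}

#' Localization configuration for [locate_all()]
#'
#' @param offset_mm Picking offset (mm), default 4.
#' @param fov_width_px Width of the central field-of-view strip in pixels;
#'   boxes whose centre falls outside it are skipped. The imaging device
#'   narrows its view to a 200 px central strip when operating on a moving
#'   row; pass 200 to emulate that. `NULL` (default) disables the filter.
#' @param binarize_method,threshold Passed to [binarize()].
#' @param degree Growth-curve degree, default 3.
#' @param pad_px Padding added around each box before cropping (default 2).
#' @param arc_length_offset If `TRUE`, measure the 4 mm offset along the
#'   traced skeleton arc instead of as a vertical drop.
#' @return A list of class `locate_config`.
#' @export
locate_config <- function(offset_mm = 4, fov_width_px = NULL,
                          binarize_method = "otsu", threshold = NULL,
                          degree = 3L, pad_px = 2L, arc_length_offset = FALSE) {
  structure(list(offset_mm = offset_mm, fov_width_px = fov_width_px,
                 binarize_method = binarize_method, threshold = threshold,
                 degree = degree, pad_px = pad_px,
                 arc_length_offset = arc_length_offset),
            class = "locate_config")
}

# offset along the traced arc: walk the path until `offset_px` of cumulative
# arc length is consumed, interpolating the final step
arc_offset_point <- function(trace, offset_px) {
  p <- trace$path
  if (nrow(p) == 1L) return(c(row = p[1, 1], col = p[1, 2]))
  d <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(d))
  if (offset_px >= cum[length(cum)]) return(c(row = p[nrow(p), 1], col = p[nrow(p), 2]))
  i <- findInterval(offset_px, cum)
  f <- (offset_px - cum[i]) / d[i]
  c(row = p[i, 1] + f * (p[i + 1, 1] - p[i, 1]),
    col = p[i, 2] + f * (p[i + 1, 2] - p[i, 2]))
}

#' Locate picking points for every detection box in an image
#'
#' Runs the full localization pipeline per box: crop, binarize, thin to a
#' skeleton, find the bud-leaf intersection, trace the stem downward, fit the
#' growth curve, apply the picking offset, map back to full-image pixel
#' coordinates and then to world millimetres. Degenerate boxes are reported
#' with flags rather than dropped; boxes outside the configured central
#' field-of-view strip are skipped with the reason recorded.
#'
#' @param image Grayscale matrix (0-255).
#' @param boxes Data frame with columns `x_min, z_min, x_max, z_max` (0-based,
#'   half-open), or a list of [detection_box()] objects.
#' @param calib A [camera_calibration()]; its `Ht` must equal `nrow(image)`.
#' @param config A [locate_config()].
#' @return Object of class `pick_points`: a data frame with one row per box —
#'   `box_id`, intersection pixel (`ix_row`, `ix_col`), pick point in
#'   continuous full-image pixel coordinates (`Xt`, `Zt`), world coordinates
#'   (`Xs_mm`, `Zs_mm`), `fit_residual_px` and `flags` (comma-separated;
#'   `"fov_skipped"`, `"empty_box"`, `"leafless_fallback"`, `"short_trace"`,
#'   `"offset_clamped"`). Skipped/failed boxes carry `NA` coordinates.
#' @export
locate_all <- function(image, boxes, calib, config = locate_config()) {
  stopf(is.matrix(image), "image must be a matrix")
  stopf(inherits(calib, "camera_calibration"), "calib must be a camera_calibration")
  stopf(calib$Ht == nrow(image),
        "calibration Ht (%d) does not match image height (%d)", calib$Ht, nrow(image))
  if (is.data.frame(boxes)) {
    boxes <- lapply(seq_len(nrow(boxes)), function(i) as_detection_box(boxes[i, ]))
  } else {
    boxes <- lapply(boxes, as_detection_box)
  }
  out <- vector("list", length(boxes))
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    stopf(b$x_max <= ncol(image) && b$z_max <= nrow(image),
          "box %d extends outside the image", i)
    row <- data.frame(box_id = i, ix_row = NA_real_, ix_col = NA_real_,
                      Xt = NA_real_, Zt = NA_real_, Xs_mm = NA_real_,
                      Zs_mm = NA_real_, fit_residual_px = NA_real_,
                      flags = NA_character_)
    if (!is.null(config$fov_width_px)) {
      cx <- (b$x_min + b$x_max) / 2
      if (abs(cx - ncol(image) / 2) > config$fov_width_px / 2) {
        row$flags <- "fov_skipped"
        out[[i]] <- row
        next
      }
    }
    res <- tryCatch({
      pad <- config$pad_px
      r0 <- max(0L, b$z_min - pad); r1 <- min(nrow(image), b$z_max + pad)
      c0 <- max(0L, b$x_min - pad); c1 <- min(ncol(image), b$x_max + pad)
      crop <- image[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE]
      mask <- binarize(crop, config$binarize_method, config$threshold)
      skel <- thin(mask)
      lbox <- detection_box(b$x_min - c0, b$z_min - r0, b$x_max - c0, b$z_max - r0)
      ix <- find_intersection(skel, lbox)
      tr <- trace_stem(skel, ix$point, lbox)
      cv <- fit_growth_curve(tr, config$degree)
      flags <- c(ix$flag, tr$flag)
      if (config$arc_length_offset) {
        off_px <- config$offset_mm * calib$Ht / calib$Hs
        pt <- list(point = arc_offset_point(tr, off_px), flag = NA_character_)
      } else {
        pt <- locate_pick_point_px(cv, ix$point, config$offset_mm, calib)
      }
      flags <- flags[!is.na(flags)]
      if (!is.na(pt$flag)) flags <- c(flags, pt$flag)
      # full-image continuous pixel coords: pixel centres sit at index + 0.5
      Xt <- pt$point["col"] + c0 + 0.5
      Zt <- pt$point["row"] + r0 + 0.5
      w <- pixel_to_world(c(Xt, Zt), calib)
      row$ix_row <- ix$point["row"] + r0
      row$ix_col <- ix$point["col"] + c0
      row$Xt <- Xt; row$Zt <- Zt
      row$Xs_mm <- w[1]; row$Zs_mm <- w[2]
      row$fit_residual_px <- cv$fit_residual
      row$flags <- if (length(flags)) paste(flags, collapse = ",") else NA_character_
      row
    }, error = function(e) {
      row$flags <- paste0("empty_box(", conditionMessage(e), ")")
      row
    })
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(box_id = integer(), ix_row = numeric(), ix_col = numeric(),
                      Xt = numeric(), Zt = numeric(), Xs_mm = numeric(),
                      Zs_mm = numeric(), fit_residual_px = numeric(),
                      flags = character())
  }
  rownames(res) <- NULL
  class(res) <- c("pick_points", "data.frame")
  res
}

#' Write located picking points
#'
#' Writes a JSON file and a TSV (`box_id Xt Zt Xs_mm Zs_mm flags`).
#'
#' @param points A `pick_points` data frame from [locate_all()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_pick_points <- function(points, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- file.path(dir, "pick_points.json")
  jsonlite::write_json(as.data.frame(points), js, auto_unbox = TRUE,
                       digits = NA, na = "null")
  tsv <- file.path(dir, "pick_points.tsv")
  write.table(points[, c("box_id", "Xt", "Zt", "Xs_mm", "Zs_mm", "flags")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json = js, tsv = tsv))
}
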