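#' Calibrate the logistic velocity ramp to its segment length
#'
#' The S-curve segment must start essentially at rest and reach essentially
#' the maximum velocity after the fixed ramp distance `S1`. A pure logistic
#' only attains its asymptotes at infinity, so the curve is pinned at a
#' boundary tolerance `eps`: the shift is `b = S1 / 2` (curve centred on the
#' ramp) and the steepness `a = 2 ln((1 - eps) / eps) / S1`, which gives
#' `v(0) = eps * vlmax` and `v(S1) = (1 - eps) * vlmax` exactly.
#'
#' @param S1 Ramp (acceleration/deceleration) distance in m.
#' @param eps Boundary tolerance in `(0, 0.5)`, default 0.01.
#' @return Named list `list(a, b)`.
#' @export
#' @examples
#' calibrate_sigmoid(0.04)  # b = 0.02, a = 2 ln(99) / 0.04
calibrate_sigmoid <- function(S1, eps = 0.01) {
  stopf(S1 > 0, "S1 must be positive")
  stopf(eps > 0 && eps < 0.5, "eps must lie in (0, 0.5)")
  list(a = 2 * log((1 - eps) / eps) / S1, b = S1 / 2)
}

#' S-curve velocity parameters
#'
#' Parameters of the logistic (S-curve) velocity ramp used by the picker's
#' vertical drive: `V(s) = vl0 + (vlmax - vl0) / (1 + exp(-a (s - b)))`.
#' By default `a` and `b` are calibrated from the ramp length `S1` and the
#' boundary tolerance `eps` via [calibrate_sigmoid()]. Setting
#' `use_paper_ab = TRUE` instead forces the reference constants
#' `a = 0.0067`, `b = 0.02` for reproducing the published control function
#' exactly as printed (with those constants the ramp does not reach `vlmax`
#' within `S1`).
#'
#' @param vl0 Initial velocity (m/s), default 0.
#' @param vlmax Maximum velocity (m/s), default 0.12.
#' @param S1 Ramp distance (m), default 0.04.
#' @param eps Boundary tolerance, default 0.01.
#' @param use_paper_ab Force the printed reference constants.
#' @param a,b Optional explicit curve coefficients (override calibration).
#' @return A list of class `scurve_params`.
#' @export
scurve_params <- function(vl0 = 0, vlmax = 0.12, S1 = 0.04, eps = 0.01,
                          use_paper_ab = FALSE, a = NULL, b = NULL) {
  stopf(vl0 >= 0 && vl0 < vlmax, "need 0 <= vl0 < vlmax")
  stopf(S1 > 0, "S1 must be positive")
  stopf(eps > 0 && eps < 0.5, "eps must lie in (0, 0.5)")
  if (use_paper_ab) {
    a <- 0.0067; b <- 0.02
  } else if (is.null(a) || is.null(b)) {
    ab <- calibrate_sigmoid(S1, eps)
    a <- ab$a; b <- ab$b
  }
  stopf(a > 0, "a must be positive")
  structure(list(vl0 = vl0, vlmax = vlmax, S1 = S1, eps = eps, a = a, b = b),
            class = "scurve_params")
}

#' Logistic velocity at a displacement
#'
#' @param s Displacement(s) along the ramp in m (vectorized).
#' @param p A [scurve_params()].
#' @return Velocity in m/s.
#' @export
#' @examples
#' p <- scurve_params()
#' sigmoid_velocity(p$b, p)  # midpoint: vlmax / 2
sigmoid_velocity <- function(s, p) {
  stopf(inherits(p, "scurve_params"), "p must be scurve_params")
  p$vl0 + (p$vlmax - p$vl0) / (1 + exp(-p$a * (s - p$b)))
}

#' Plan one vertical picking cycle
#'
#' A standard cycle between two picking heights is an S-curve acceleration
#' over the fixed ramp distance `S1`, a uniform segment `Sy = |S| - 2 S1`,
#' and a mirrored S-curve deceleration over `S1`. Moves shorter than `2 S1`
#' cannot fit both full ramps; they are planned as symmetric
#' acceleration/deceleration halves of `|S| / 2` each with the ramp
#' re-calibrated to the shortened distance, and flagged degenerate. A zero
#' displacement yields a null cycle (wait in place).
#'
#' @param z_current,z_next Current and target heights in mm (world Z,
#'   downward positive).
#' @param p A [scurve_params()].
#' @param V Constant horizontal carriage speed in m/s.
#' @param waiting_zone_mm Width of the waiting (standoff) zone, default 10.
#' @return A list of class `motion_cycle` with `S_total` (signed, m),
#'   `segments` `c(accel, uniform, decel)` in m, `direction`
#'   (`"up"`/`"down"`/`"none"`), per-cycle curve constants `a`, `b`, `S1_eff`,
#'   `horizontal_speed_V`, `waiting_zone_mm` and `degenerate`/`null` flags.
#' @export
#' @examples
#' plan_cycle(0, 150, scurve_params(), V = 0.05)$segments  # 0.04 0.07 0.04
plan_cycle <- function(z_current, z_next, p, V = 0.05, waiting_zone_mm = 10) {
  stopf(inherits(p, "scurve_params"), "p must be scurve_params")
  S_total <- (z_next - z_current) / 1000
  mag <- abs(S_total)
  if (mag == 0) {
    return(structure(list(S_total = 0, segments = c(accel = 0, uniform = 0, decel = 0),
                          direction = "none", a = p$a, b = p$b, S1_eff = 0,
                          horizontal_speed_V = V, waiting_zone_mm = waiting_zone_mm,
                          degenerate = FALSE, null = TRUE),
                     class = "motion_cycle"))
  }
  if (mag >= 2 * p$S1) {
    segs <- c(accel = p$S1, uniform = mag - 2 * p$S1, decel = p$S1)
    a <- p$a; b <- p$b; s1e <- p$S1; degen <- FALSE
  } else {
    s1e <- mag / 2
    ab <- calibrate_sigmoid(s1e, p$eps)
    segs <- c(accel = s1e, uniform = 0, decel = s1e)
    a <- ab$a; b <- ab$b; degen <- TRUE
  }
  structure(list(S_total = S_total, segments = segs,
                 direction = if (S_total > 0) "down" else "up",
                 a = a, b = b, S1_eff = s1e,
                 horizontal_speed_V = V, waiting_zone_mm = waiting_zone_mm,
                 degenerate = degen, null = FALSE),
            class = "motion_cycle")
}

#' @export
print.motion_cycle <- function(x, ...) {
  if (x$null) {
    cat("<motion_cycle> null (wait in place)\n")
  } else {
    cat(sprintf("<motion_cycle> %s %.3f m: accel %.3f + uniform %.3f + decel %.3f m%s\n",
                x$direction, abs(x$S_total), x$segments[1], x$segments[2],
                x$segments[3], if (x$degenerate) " [degenerate]" else ""))
  }
  invisible(x)
}

#' Sample the velocity profile of a cycle and integrate its duration
#'
#' Samples the acceleration ramp (logistic), the uniform segment (constant
#' `vlmax`, or the ramp peak for degenerate cycles) and the deceleration ramp
#' (the mirrored logistic, `v_dec(s) = v_acc(S1 - s)`) at spacing `ds`, and
#' accumulates the traversal time as `sum(ds / v)` with velocities floored at
#' `eps * vlmax` so the start from (near) rest takes finite time.
#'
#' @param cycle A [plan_cycle()] result.
#' @param p The [scurve_params()] used to plan it.
#' @param ds Sample spacing in m, default 1e-4 (0.1 mm).
#' @return Object of class `velocity_profile`: `samples` data frame
#'   (`s` m, `v` m/s, ordered in s), `duration` (s), `peak_v` (m/s) and
#'   `displacement` (m).
#' @export
integrate_profile <- function(cycle, p, ds = 1e-4) {
  stopf(inherits(cycle, "motion_cycle"), "cycle must be a motion_cycle")
  stopf(ds > 0, "ds must be positive")
  if (cycle$null) {
    return(structure(list(samples = data.frame(s = numeric(), v = numeric()),
                          duration = 0, peak_v = 0, displacement = 0),
                     class = "velocity_profile"))
  }
  s1 <- cycle$segments[["accel"]]
  sy <- cycle$segments[["uniform"]]
  pk <- scurve_params(p$vl0, p$vlmax, S1 = max(cycle$S1_eff, ds), eps = p$eps,
                      a = cycle$a, b = cycle$b)
  v_acc <- function(s) sigmoid_velocity(s, pk)
  peak <- if (sy > 0) p$vlmax else v_acc(s1)
  s_a <- seq(0, s1, by = ds)
  if (s_a[length(s_a)] < s1) s_a <- c(s_a, s1)
  s_u <- if (sy > 0) seq(ds, sy, by = ds) else numeric(0)
  if (sy > 0 && (length(s_u) == 0 || s_u[length(s_u)] < sy)) s_u <- c(s_u, sy)
  s_d <- seq(ds, s1, by = ds)
  if (length(s_d) == 0 || s_d[length(s_d)] < s1) s_d <- c(s_d, s1)
  s_all <- c(s_a, s1 + s_u, s1 + sy + s_d)
  v_all <- c(v_acc(s_a),
             rep(p$vlmax, length(s_u)),
             v_acc(s1 - s_d))
  if (sy == 0) v_all[length(s_a) + seq_along(s_u)] <- peak
  floor_v <- p$eps * p$vlmax
  dseg <- diff(s_all)
  vmid <- pmax((head(v_all, -1) + tail(v_all, -1)) / 2, floor_v)
  duration <- sum(dseg / vmid)
  structure(list(samples = data.frame(s = s_all, v = v_all),
                 duration = duration, peak_v = max(v_all),
                 displacement = s_all[length(s_all)]),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<velocity_profile> %d samples over %.3f m, peak %.3f m/s, %.2f s\n",
              nrow(x$samples), x$displacement, x$peak_v, x$duration))
  invisible(x)
}

#' @export
plot.velocity_profile <- function(x, ...) {
  plot(x$samples$s, x$samples$v, type = "l", xlab = "displacement s (m)",
       ylab = "vertical velocity (m/s)", ...)
  invisible(x)
}

#' Schedule the picker over a row of picking points
#'
#' The carriage advances at constant horizontal speed `V` while the picker
#' moves vertically between consecutive picking points. For each transition
#' the horizontal arrival time is `dX / V` and the vertical cycle duration
#' comes from [integrate_profile()]; the transition is feasible when the
#' vertical move finishes before the carriage has closed to the waiting-zone
#' standoff, and when the transition interval respects the recognition
#' cadence `min_cycle_time_s`. Infeasible transitions are flagged (that shoot
#' is missed), not dropped.
#'
#' @param points Data frame with world columns `Xs_mm`, `Zs_mm`, sorted by
#'   increasing `Xs_mm`.
#' @param V Horizontal carriage speed in m/s.
#' @param p A [scurve_params()].
#' @param geometry List: `waiting_zone_mm` (default 10), `min_cycle_time_s`
#'   (default 0.7), `calib` (a [camera_calibration()] giving the blade's top
#'   reference for the first cycle; default `camera_calibration(980)`).
#' @param ds Profile sample spacing (m).
#' @return Object of class `pick_schedule`: data frame with per-point
#'   `Xs_mm`, `Zs_mm`, `t_arrive_s`, `t_available_s`, `t_cycle_s`,
#'   `feasible`, `degenerate`; the planned `cycles` as an attribute.
#' @export
schedule_row <- function(points, V, p = scurve_params(),
                         geometry = list(), ds = 1e-4) {
  stopf(V > 0, "V must be positive")
  stopf(all(c("Xs_mm", "Zs_mm") %in% names(points)),
        "points must have Xs_mm and Zs_mm columns")
  g <- utils::modifyList(list(waiting_zone_mm = 10, min_cycle_time_s = 0.7,
                              calib = camera_calibration(980)), geometry)
  x <- points$Xs_mm; z <- points$Zs_mm
  stopf(!is.unsorted(x), "points must be sorted by increasing Xs_mm")
  n <- length(x)
  t_arrive <- x / 1000 / V
  dwell <- g$waiting_zone_mm / 1000 / V
  t_avail <- c(t_arrive[1], diff(t_arrive)) - dwell
  cycles <- vector("list", n)
  t_cycle <- numeric(n)
  feasible <- logical(n)
  degen <- logical(n)
  z_ref <- -(g$calib$Hz - g$calib$Hs)   # blade parked above the window top
  for (i in seq_len(n)) {
    cyc <- plan_cycle(z_ref, z[i], p, V, g$waiting_zone_mm)
    prof <- integrate_profile(cyc, p, ds)
    cycles[[i]] <- cyc
    t_cycle[i] <- prof$duration
    degen[i] <- cyc$degenerate
    ok_time <- t_cycle[i] <= t_avail[i]
    ok_cadence <- i == 1 || (t_arrive[i] - t_arrive[i - 1]) >= g$min_cycle_time_s
    feasible[i] <- ok_time && ok_cadence && (i == 1 || x[i] > x[i - 1])
    z_ref <- z[i]
  }
  out <- data.frame(Xs_mm = x, Zs_mm = z, t_arrive_s = t_arrive,
                    t_available_s = t_avail, t_cycle_s = t_cycle,
                    feasible = feasible, degenerate = degen)
  attr(out, "cycles") <- cycles
  attr(out, "params") <- list(V = V, scurve = p, geometry = g)
  class(out) <- c("pick_schedule", "data.frame")
  out
}
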