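#' Assign arena zones to samples
#'
#' Zone 1 is the central part of the leaf disc (the disc minus an edge margin);
#' zone 2 is everything else inside the arena. Undetected samples get the
#' `undetected` zone. Samples outside the arena wall raise a warning and are
#' assigned zone 2, since the subject cannot physically leave the arena.
#'
#' @param x,y numeric positions in mm (vectors).
#' @param detected logical vector (default all `TRUE`).
#' @param arena an [arena_geometry()].
#' @return factor with levels `zone1`, `zone2`, `undetected`.
#' @examples
#' a <- arena_geometry(disc_radius = 3, wall_radius = 9)
#' assign_zone(c(0, 2.8), c(0, 0), arena = a)
#' @export
assign_zone <- function(x, y, detected = rep(TRUE, length(x)), arena) {
  stopifnot(inherits(arena, "arena_geometry"))
  d <- sqrt((x - arena$centre[1])^2 + (y - arena$centre[2])^2)
  zone <- rep("zone2", length(x))
  zone[d <= arena$disc_radius - arena$zone1_margin] <- "zone1"
  out <- which(detected & !is.na(d) & d > arena$wall_radius + 1e-9)
  if (length(out))
    warning(sprintf("%d sample(s) outside the arena wall; assigned zone2",
                    length(out)))
  zone[!detected | is.na(d)] <- "undetected"
  factor(zone, levels = c("zone1", "zone2", "undetected"))
}

#' Compute smoothed kinematics from a trajectory
#'
#' Down-samples the acquisition-rate trajectory (25 fps) to the analysis rate
#' (5 samples per s), computes instantaneous speed as the backward finite
#' difference between consecutive analysis samples, and reports speed as a
#' centred moving average over `smooth_window` analysis samples (shrunk at the
#' series boundaries). Each analysis sample is assigned an arena zone, and a
#' running zone-1 travelled distance is accumulated.
#'
#' Undetected gaps up to `gap_max` seconds (bounded by detected frames) are
#' linearly interpolated so that a brief tracker dropout does not cut a probe
#' in two; interpolated samples keep `detected = FALSE` for quality-control
#' accounting but receive a position-based zone. Across longer gaps speed is
#' undefined (`NA`) and the zone is `undetected`.
#'
#' @param traj an [trajectory()] object.
#' @param arena an [arena_geometry()].
#' @param analysis_rate analysis samples per s; must divide the frame rate.
#' @param smooth_window moving-average window in analysis samples (odd
#'   recommended; default 5).
#' @param gap_max longest undetected gap (s) bridged by interpolation.
#' @param position_average if `TRUE`, each analysis sample is the mean
#'   position of its frame block rather than the block's first frame.
#'   Default `FALSE` (plain decimation; position noise is handled by the
#'   speed smoothing).
#' @param distance_zones zones whose displacement counts towards
#'   `cumulative_distance` (default zone 1 only, since only on-disc behaviour
#'   enters the analysis).
#' @return A data frame of class `aphid_kinematics` with columns `t`, `x`,
#'   `y`, `speed` (smoothed, mm/s), `speed_raw` (unsmoothed), `zone`,
#'   `detected`, `cumulative_distance` (mm), and attributes `dt`, `duration`,
#'   `arena`, `detected_fraction`.
#' @export
compute_kinematics <- function(traj, arena, analysis_rate = 5,
                               smooth_window = 5, gap_max = 1,
                               position_average = FALSE,
                               distance_zones = "zone1") {
  stopifnot(inherits(traj, "aphid_trajectory"), inherits(arena, "arena_geometry"))
  fr <- attr(traj, "frame_rate")
  step <- fr / analysis_rate
  if (abs(step - round(step)) > 1e-8)
    stop("analysis_rate must divide the frame rate")
  step <- as.integer(round(step))
  n_raw <- nrow(traj)
  if (n_raw < smooth_window + 1) stop("trajectory too short")

  x <- traj$x; y <- traj$y; det <- traj$detected
  x[!det] <- NA_real_; y[!det] <- NA_real_

  # bridge short dropouts at acquisition rate
  interp_gap <- function(v) {
    miss <- is.na(v)
    if (!any(miss) || all(miss)) return(v)
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      if (i0 > 1 && i1 < length(v) && (i1 - i0 + 1L) / fr <= gap_max) {
        v[i0:i1] <- stats::approx(c(i0 - 1L, i1 + 1L), v[c(i0 - 1L, i1 + 1L)],
                                  xout = i0:i1)$y
      }
    }
    v
  }
  xi <- interp_gap(x); yi <- interp_gap(y)

  idx <- seq(1L, n_raw, by = step)
  if (position_average) {
    blk <- rep(seq_along(idx), each = step, length.out = n_raw)
    xs <- as.numeric(tapply(xi, blk, function(v) mean(v)))
    ys <- as.numeric(tapply(yi, blk, function(v) mean(v)))
    ts <- traj$t[idx]
  } else {
    xs <- xi[idx]; ys <- yi[idx]; ts <- traj$t[idx]
  }
  det_s <- det[idx]
  n <- length(ts)
  dt <- 1 / analysis_rate

  disp <- c(NA_real_, sqrt(diff(xs)^2 + diff(ys)^2))
  speed_raw <- disp / dt
  # centred moving average, shrunk at boundaries, ignoring undefined neighbours
  half <- smooth_window %/% 2
  speed <- vapply(seq_len(n), function(i) {
    w <- speed_raw[max(1L, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))

  zone <- assign_zone(xs, ys, detected = !is.na(xs), arena = arena)
  dstep <- ifelse(!is.na(disp) & as.character(zone) %in% distance_zones, disp, 0)
  cumdist <- cumsum(dstep)

  structure(data.frame(t = ts, x = xs, y = ys, speed = speed,
                       speed_raw = speed_raw, zone = zone, detected = det_s,
                       cumulative_distance = cumdist),
            dt = dt, duration = n * dt, arena = arena,
            detected_fraction = mean(det_s),
            class = c("aphid_kinematics", "data.frame"))
}

#' Construct a kinematics series directly
#'
#' Builds an `aphid_kinematics` object from already-computed speed and zone
#' series, e.g. velocity output exported by other tracking software. Samples
#' are taken to be equally spaced at `1/analysis_rate` s starting at 0.
#'
#' @param speed smoothed speed in mm/s (`NA` for undefined samples).
#' @param zone `"zone1"`, `"zone2"` or `"undetected"`; recycled.
#' @param analysis_rate samples per s.
#' @param x,y optional positions (mm).
#' @param detected optional detection flags (default: speed not `NA`).
#' @return an `aphid_kinematics` object.
#' @export
kinematics_series <- function(speed, zone = "zone1", analysis_rate = 5,
                              x = NULL, y = NULL, detected = NULL) {
  n <- length(speed)
  dt <- 1 / analysis_rate
  zone <- factor(rep_len(as.character(zone), n),
                 levels = c("zone1", "zone2", "undetected"))
  if (is.null(detected)) detected <- !is.na(speed)
  if (is.null(x)) x <- rep(NA_real_, n)
  if (is.null(y)) y <- rep(NA_real_, n)
  disp <- ifelse(is.na(speed), 0, speed * dt)
  disp[1] <- 0                   # backward difference undefined at the start
  structure(data.frame(t = (seq_len(n) - 1) * dt, x = x, y = y, speed = speed,
                       speed_raw = speed, zone = zone, detected = detected,
                       cumulative_distance = cumsum(ifelse(zone == "zone1",
                                                           disp, 0))),
            dt = dt, duration = n * dt, arena = NULL,
            detected_fraction = mean(detected),
            class = c("aphid_kinematics", "data.frame"))
}

#' @export
print.aphid_kinematics <- function(x, ...) {
  cat(sprintf(
    "Kinematics: %d samples at %.0f Hz (%.1f s), %.0f%% detected, %.1f mm travelled\n",
    nrow(x), 1 / attr(x, "dt"), attr(x, "duration"),
    100 * attr(x, "detected_fraction"),
    x$cumulative_distance[nrow(x)]))
  invisible(x)
}

#' @export
plot.aphid_kinematics <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$x, x$y, type = "l", asp = 1, xlab = "x (mm)", ylab = "y (mm)", ...)
  a <- attr(x, "arena")
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(a$centre[1] + (a$disc_radius - a$zone1_margin) * cos(th),
                  a$centre[2] + (a$disc_radius - a$zone1_margin) * sin(th), lty = 2)
  graphics::lines(a$centre[1] + a$wall_radius * cos(th),
                  a$centre[2] + a$wall_radius * sin(th))
  graphics::plot(x$t, x$speed, type = "l", xlab = "time (s)",
                 ylab = "speed (mm/s)")
  invisible(x)
}
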