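#' Arena geometry
#'
#' Describes one circular leaf-disc arena: a central leaf disc (zone 1)
#' surrounded by agar up to the arena wall (zone 2). A margin at the disc edge
#' is excluded from zone 1 so that aphids sitting on the disc rim or the wall
#' are not falsely assigned to the leaf.
#'
#' @param centre numeric length-2, arena centre (x, y) in mm.
#' @param disc_radius leaf-disc radius in mm (a 6 mm disc has radius 3).
#' @param wall_radius arena wall radius in mm; must exceed `disc_radius`.
#' @param zone1_margin mm excluded at the disc edge; zone 1 is the disc of
#'   radius `disc_radius - zone1_margin`. Default 0.75 mm, which turns a 6 mm
#'   leaf disc into an effective zone-1 diameter of about 5 mm.
#' @return An object of class `arena_geometry`.
#' @examples
#' arena_geometry(disc_radius = 3, wall_radius = 9)
#' @export
arena_geometry <- function(centre = c(0, 0), disc_radius = 3, wall_radius = 9,
                           zone1_margin = 0.75) {
  stopifnot(is.numeric(centre), length(centre) == 2, all(is.finite(centre)))
  if (!(disc_radius > 0 && wall_radius > disc_radius))
    stop("need 0 < disc_radius < wall_radius")
  if (zone1_margin < 0 || zone1_margin >= disc_radius)
    stop("zone1_margin must be in [0, disc_radius)")
  structure(list(centre = as.numeric(centre), disc_radius = disc_radius,
                 wall_radius = wall_radius, zone1_margin = zone1_margin),
            class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf(
    "Arena: disc radius %.2f mm (zone 1 radius %.2f mm), wall radius %.2f mm\n",
    x$disc_radius, x$disc_radius - x$zone1_margin, x$wall_radius))
  invisible(x)
}

#' Build a trajectory from samples
#'
#' A trajectory is the time-stamped centre-point track of one aphid in one
#' arena: a data frame with columns `t` (s), `x`, `y` (mm) and `detected`
#' (logical; was the subject found in this frame). Undetected frames are kept,
#' with `NA` positions allowed.
#'
#' @param t,x,y numeric vectors; time in s (non-negative, strictly
#'   increasing), positions in mm.
#' @param detected logical vector; positions must be finite where `TRUE`.
#' @param frame_rate acquisition rate in frames per s (video standard: 25).
#' @param pixel_scale pixels per mm of the source video (kept as metadata;
#'   positions are already in mm).
#' @param arena_id arena identifier.
#' @return A data frame of class `aphid_trajectory` with attributes
#'   `frame_rate`, `pixel_scale`, `arena_id`.
#' @export
trajectory <- function(t, x, y, detected = rep(TRUE, length(t)),
                       frame_rate = 25, pixel_scale = 16.6, arena_id = "arena1") {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, length(detected) == n)
  if (n == 0) stop("empty trajectory")
  if (any(!is.finite(t)) || any(t < 0)) stop("times must be finite and non-negative")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(detected & (!is.finite(x) | !is.finite(y))))
    stop("positions must be finite where detected")
  if (!(pixel_scale > 0)) stop("pixel_scale must be positive")
  if (!(frame_rate > 0)) stop("frame_rate must be positive")
  out <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                    detected = as.logical(detected))
  structure(out, frame_rate = frame_rate, pixel_scale = pixel_scale,
            arena_id = arena_id, class = c("aphid_trajectory", "data.frame"))
}

#' Nominal duration of a trajectory or event stream, in seconds
#'
#' For a trajectory this is `n / frame_rate` (each frame stands for one frame
#' interval); for an event stream it is the stored observation duration.
#'
#' @param x an `aphid_trajectory`, `aphid_kinematics` or `event_stream`.
#' @return duration in seconds.
#' @export
observation_duration <- function(x) {
  if (inherits(x, "aphid_trajectory")) return(nrow(x) / attr(x, "frame_rate"))
  if (inherits(x, "aphid_kinematics")) return(attr(x, "duration"))
  if (inherits(x, "event_stream")) return(attr(x, "duration"))
  stop("no duration defined for this object")
}

#' @export
print.aphid_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s': %d samples at %g fps (%.1f s), %.1f px/mm\n",
              attr(x, "arena_id"), nrow(x), attr(x, "frame_rate"),
              observation_duration(x), attr(x, "pixel_scale")))
  cat(sprintf("  detected: %d/%d frames\n", sum(x$detected), nrow(x)))
  invisible(x)
}

#' Read a trajectory file
#'
#' Reads a comma-delimited trajectory file with header `t,x,y,detected`
#' (times in s; positions in px or mm as declared by `config$units`;
#' `detected` as 0/1 or TRUE/FALSE; undetected rows may leave x,y empty).
#'
#' @param path file path.
#' @param config acquisition metadata: a list (or path to a YAML/JSON config
#'   read by [read_config()]) with at least `pixel_scale` (px per mm) and
#'   `frame_rate`; optional `units` ("px", the default, or "mm") and
#'   `arena_id`.
#' @return An [trajectory()] object with positions in mm.
#' @export
read_trajectory <- function(path, config) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$pixel_scale) || is.null(config$frame_rate))
    stop("config must provide pixel_scale and frame_rate")
  units <- if (is.null(config$units)) "px" else config$units
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "detected")
  if (!all(need %in% names(raw)))
    stop("trajectory file must have columns t,x,y,detected")
  for (col in c("t", "x", "y")) {
    v <- raw[[col]]
    if (is.character(v)) {
      v[v == ""] <- NA
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop(sprintf("cannot parse column '%s' at line %d of %s",
                     col, bad[1] + 1L, path))
      raw[[col]] <- num
    }
  }
  det <- raw$detected
  if (is.character(det)) det <- toupper(trimws(det)) %in% c("TRUE", "T", "1")
  det <- as.logical(det)
  if (is.unsorted(raw$t, strictly = TRUE))
    stop("non-monotone time column in ", path)
  sc <- if (units == "px") 1 / config$pixel_scale else 1
  trajectory(t = raw$t, x = raw$x * sc, y = raw$y * sc, detected = det,
             frame_rate = config$frame_rate, pixel_scale = config$pixel_scale,
             arena_id = if (is.null(config$arena_id)) "arena1" else config$arena_id)
}

#' Write a trajectory file
#'
#' Inverse of [read_trajectory()]: writes `t,x,y,detected` in mm
#' (round-trips field-for-field with `units: "mm"` in the config).
#'
#' @param traj an [trajectory()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "aphid_trajectory"))
  out <- as.data.frame(traj)
  out$detected <- as.integer(out$detected)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an arena/species configuration file
#'
#' Structured text (YAML; JSON is a YAML subset) with acquisition metadata
#' (`pixel_scale`, `frame_rate`, `analysis_rate`, `smooth_window`, `units`)
#' and optionally `arena` (centre, disc_radius, wall_radius, zone1_margin)
#' and `species` (a [species_profile()] name or explicit thresholds).
#'
#' @param path config file path.
#' @return a named list; `$arena` is promoted to an [arena_geometry()] when
#'   present.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$arena)) {
    a <- cfg$arena
    cfg$arena <- arena_geometry(
      centre = if (is.null(a$centre)) c(0, 0) else unlist(a$centre),
      disc_radius = a$disc_radius, wall_radius = a$wall_radius,
      zone1_margin = if (is.null(a$zone1_margin)) 0.75 else a$zone1_margin)
  }
  cfg
}

#' Event streams: ordered labelled intervals
#'
#' An event stream is an ordered set of half-open intervals `[start, stop)` in
#' seconds from observation start, each labelled `probe`/`non_probe` or
#' `moving`/`not_moving`. Intervals of one label family must be
#' non-overlapping and ordered.
#'
#' @param start,stop numeric vectors (s); `stop > start` elementwise.
#' @param label character vector of labels.
#' @param duration observation duration in s (defaults to `max(stop)`).
#' @return A data frame of class `event_stream` with attribute `duration`.
#' @export
event_stream <- function(start, stop, label, duration = NULL) {
  n <- length(start)
  stopifnot(length(stop) == n, length(label) == n)
  if (n > 0) {
    if (any(!(stop > start))) stop("every interval needs stop > start")
    o <- order(start)
    start <- start[o]; stop <- stop[o]; label <- as.character(label)[o]
    if (n > 1 && any(start[-1] < stop[-n] - 1e-9))
      stop("intervals overlap")
  }
  if (is.null(duration)) duration <- if (n) max(stop) else 0
  structure(data.frame(start = as.numeric(start), stop = as.numeric(stop),
                       label = as.character(label)),
            duration = duration, class = c("event_stream", "data.frame"))
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("Event stream: %d intervals over %.1f s\n", nrow(x),
              attr(x, "duration")))
  if (nrow(x)) {
    tab <- tapply(x$stop - x$start, x$label, sum)
    for (lb in names(tab))
      cat(sprintf("  %-11s %3d bouts, %8.1f s total\n", lb,
                  sum(x$label == lb), tab[[lb]]))
  }
  invisible(x)
}

#' Read / write interval annotation files
#'
#' Delimited text `start,stop,label` in seconds, used both for software
#' output and for manual reference annotations.
#'
#' @param path file path.
#' @param duration observation duration in s (default: last stop).
#' @return [read_intervals()]: an [event_stream()].
#' @export
read_intervals <- function(path, duration = NULL) {
  if (!file.exists(path)) stop("interval file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("start", "stop", "label") %in% names(raw)))
    stop("interval file must have columns start,stop,label")
  event_stream(raw$start, raw$stop, raw$label, duration = duration)
}

#' @rdname read_intervals
#' @param events an [event_stream()].
#' @export
write_intervals <- function(events, path) {
  stopifnot(inherits(events, "event_stream"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# intervals of one family restricted to one label
events_of <- function(events, lab) {
  events[events$label == lab, , drop = FALSE]
}

# complement of a set of ordered disjoint intervals within [0, duration)
complement_intervals <- function(start, stop, duration) {
  if (!length(start)) return(data.frame(start = 0, stop = duration)[duration > 0, ])
  edges_s <- c(0, stop)
  edges_e <- c(start, duration)
  keep <- edges_e - edges_s > 1e-12
  data.frame(start = edges_s[keep], stop = edges_e[keep])
}
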