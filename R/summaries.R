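#' Probe duration categories
#'
#' Probes are categorised by duration: short probes (< 3 min) indicate
#' superficial penetrations; long probes (>= 25 min) approximate phloem
#' uptake; sustained probes (> 35 min) indicate committed phloem ingestion.
#' "Other" probes are the complement of long probes.
#'
#' @param short_max upper bound (s) of a short probe (exclusive).
#' @param long_min lower bound (s) of a long probe (inclusive).
#' @param sustained_min lower bound (s) of a sustained probe (exclusive).
#' @return object of class `probe_categories`.
#' @export
probe_categories <- function(short_max = 180, long_min = 1500,
                             sustained_min = 2100) {
  if (!(short_max < long_min && long_min < sustained_min))
    stop("need short_max < long_min < sustained_min")
  structure(list(short_max = short_max, long_min = long_min,
                 sustained_min = sustained_min), class = "probe_categories")
}

#' Categorise a probe by its duration
#'
#' A probe can fall in several categories at once: a 40-minute probe is both
#' long and sustained; a 2-minute probe is both short and "other".
#'
#' @param duration probe duration(s) in s (vectorised).
#' @param cats a [probe_categories()].
#' @return a logical matrix with one row per duration and columns
#'   `short`, `long`, `sustained`, `other`.
#' @examples
#' categorize_probe(c(120, 1500, 2100, 2101), probe_categories())
#' @export
categorize_probe <- function(duration, cats = probe_categories()) {
  stopifnot(all(duration > 0))
  cbind(short = duration < cats$short_max,
        long = duration >= cats$long_min,
        sustained = duration > cats$sustained_min,
        other = duration < cats$long_min)
}

#' Summarise one observation into response variables
#'
#' Computes the per-arena response variables used for resistance screening:
#' total durations (minutes) of non-probing, long probes, sustained probes,
#' other probes and not moving; counts of non-probe bouts, short probes and
#' long probes; the mean duration of long probes and the latency to the first
#' long probe (minutes; `NA` when no long probe occurred — absent, not zero);
#' total distance moved on the leaf disc (cm); maximum smoothed velocity
#' (mm/s); and the fraction of analysis samples with a valid detection, used
#' for quality control.
#'
#' @param events probe/non-probe [event_stream()].
#' @param movement moving/not-moving [event_stream()].
#' @param kin the [compute_kinematics()] series the events came from.
#' @param cats a [probe_categories()].
#' @param duration observation duration in s; defaults to the event stream's.
#' @param arena_id identifier copied into the summary row.
#' @return A one-row data frame of class `observation_summary`.
#' @export
summarize_observation <- function(events, movement, kin,
                                  cats = probe_categories(),
                                  duration = NULL, arena_id = NULL) {
  stopifnot(inherits(events, "event_stream"))
  if (is.null(duration)) duration <- attr(events, "duration")
  for (ev in list(events, movement)) {
    tot <- sum(ev$stop - ev$start)
    if (abs(tot - duration) > 1e-6)
      stop(sprintf("event stream (%.3f s) does not tile the observation (%.3f s)",
                   tot, duration))
  }
  pr <- events_of(events, "probe")
  dur_p <- pr$stop - pr$start
  cat_m <- if (nrow(pr)) categorize_probe(dur_p, cats) else
    matrix(FALSE, 0, 4, dimnames = list(NULL, c("short", "long", "sustained", "other")))
  np <- events_of(events, "non_probe")
  nm <- events_of(movement, "not_moving")

  long_d <- dur_p[cat_m[, "long"]]
  first_long <- if (length(long_d)) min(pr$start[cat_m[, "long"]]) else NA_real_

  out <- data.frame(
    arena_id = if (is.null(arena_id)) "arena1" else arena_id,
    duration_min = duration / 60,
    total_non_probing_min = sum(np$stop - np$start) / 60,
    total_long_probes_min = sum(dur_p[cat_m[, "long"]]) / 60,
    total_sustained_probes_min = sum(dur_p[cat_m[, "sustained"]]) / 60,
    total_other_probes_min = sum(dur_p[cat_m[, "other"]]) / 60,
    total_not_moving_min = sum(nm$stop - nm$start) / 60,
    n_non_probe_bouts = nrow(np),
    n_short_probes = sum(cat_m[, "short"]),
    n_long_probes = sum(cat_m[, "long"]),
    mean_long_probe_min = if (length(long_d)) mean(long_d) / 60 else NA_real_,
    latency_first_long_min = first_long / 60,
    total_distance_cm = if (!is.null(kin))
      kin$cumulative_distance[nrow(kin)] / 10 else NA_real_,
    max_velocity_mm_s = if (!is.null(kin)) suppressWarnings(
      max(kin$speed, na.rm = TRUE)) else NA_real_,
    qc_detected_fraction = if (!is.null(kin))
      attr(kin, "detected_fraction") else NA_real_)
  class(out) <- c("observation_summary", "data.frame")
  out
}

#' Per-time-bin summaries
#'
#' Splits the observation into equal bins (default 1 h) and reports, per bin,
#' the percentage of time spent in long probes and the distance moved. A
#' probe's category is decided by its full duration; its time is apportioned
#' to bins by overlap.
#'
#' @param events probe/non-probe [event_stream()].
#' @param kin the kinematics series (for per-bin distance; may be `NULL`).
#' @param bin_width bin width in s; must divide the observation duration.
#' @param duration observation duration in s.
#' @param cats a [probe_categories()].
#' @return data frame with one row per bin: `bin`, `t_start_min`,
#'   `pct_long_probes`, `distance_cm`.
#' @export
summarize_bins <- function(events, kin = NULL, bin_width = 3600,
                           duration = NULL, cats = probe_categories()) {
  stopifnot(inherits(events, "event_stream"))
  if (is.null(duration)) duration <- attr(events, "duration")
  nb <- duration / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("bin_width must divide duration")
  nb <- as.integer(round(nb))
  edges <- seq(0, duration, by = bin_width)

  pr <- events_of(events, "probe")
  isl <- if (nrow(pr)) categorize_probe(pr$stop - pr$start, cats)[, "long"] else logical(0)
  longs <- pr[isl, , drop = FALSE]
  long_time <- vapply(seq_len(nb), function(b) {
    lo <- edges[b]; hi <- edges[b + 1]
    sum(pmax(0, pmin(longs$stop, hi) - pmax(longs$start, lo)))
  }, numeric(1))

  dist_cm <- rep(NA_real_, nb)
  if (!is.null(kin)) {
    # per-sample displacement already zone-filtered in cumulative_distance
    dstep <- c(0, diff(kin$cumulative_distance))
    b <- pmin(nb, findInterval(kin$t, edges, rightmost.closed = FALSE))
    b[b < 1] <- 1
    dist_cm <- vapply(seq_len(nb), function(k) sum(dstep[b == k]) / 10, numeric(1))
  }
  data.frame(bin = seq_len(nb), t_start_min = edges[-length(edges)] / 60,
             pct_long_probes = 100 * long_time / bin_width,
             distance_cm = dist_cm)
}

#' Quality-control partition of observation summaries
#'
#' Observations where the subject was not found for too large a fraction of
#' samples are excluded from analysis.
#'
#' @param summaries a data frame of stacked [summarize_observation()] rows.
#' @param min_detected_fraction retain observations with
#'   `qc_detected_fraction >=` this (default 0.9).
#' @return list with data frames `retained` and `excluded`; the latter gains
#'   a `reason` column.
#' @export
qc_exclude <- function(summaries, min_detected_fraction = 0.9) {
  ok <- summaries$qc_detected_fraction >= min_detected_fraction
  ok[is.na(ok)] <- FALSE
  excluded <- summaries[!ok, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf("detected fraction %.2f < %.2f",
                               excluded$qc_detected_fraction,
                               min_detected_fraction)
  list(retained = summaries[ok, , drop = FALSE], excluded = excluded)
}

#' @export
print.observation_summary <- function(x, ...) {
  cat(sprintf("Observation '%s' (%.0f min):\n", x$arena_id, x$duration_min))
  cat(sprintf("  probes: %d long (%.1f min total), %d short; non-probing %.1f min (%d bouts)\n",
              x$n_long_probes, x$total_long_probes_min, x$n_short_probes,
              x$total_non_probing_min, x$n_non_probe_bouts))
  cat(sprintf("  mean long probe %.1f min, latency %.1f min; distance %.1f cm; max v %.2f mm/s\n",
              x$mean_long_probe_min, x$latency_first_long_min,
              x$total_distance_cm, x$max_velocity_mm_s))
  invisible(x)
}
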