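#' Species-specific velocity and dwell thresholds
#'
#' The probe state machine uses hysteresis: a probe starts only after the
#' centre-point velocity drops below a low start threshold and stays low for a
#' dwell time; it stops only after velocity exceeds a higher stop threshold
#' and remains above an intermediate hysteresis level for a second dwell time,
#' so brief body movements during probing do not end the probe. The larger
#' winged *N. ribisnigri* swings faster around its fixated mouthparts than
#' wingless *M. persicae* and needs a higher stop threshold.
#'
#' @param species `"m_persicae"` or `"n_ribisnigri"`, or `"custom"` with
#'   explicit thresholds.
#' @param v_probe_start velocity below which a probe may start (mm/s).
#' @param t_probe_start dwell time for a probe start (s).
#' @param v_probe_stop velocity above which a probe stop is triggered (mm/s);
#'   0.3 for *M. persicae*, 0.35 for *N. ribisnigri*.
#' @param v_hysteresis velocity the excursion must not fall below for the stop
#'   to be confirmed (mm/s).
#' @param t_probe_stop dwell time for a probe stop (s).
#' @param v_move_start,v_move_stop start/stop velocities of the independent
#'   moving/not-moving state machine (mm/s).
#' @return object of class `species_profile`.
#' @examples
#' species_profile("n_ribisnigri")
#' @export
species_profile <- function(species = c("m_persicae", "n_ribisnigri", "custom"),
                            v_probe_start = 0.02, t_probe_start = 10,
                            v_probe_stop = NULL, v_hysteresis = 0.1,
                            t_probe_stop = 2,
                            v_move_start = 0.3, v_move_stop = 0.02) {
  species <- match.arg(species)
  if (is.null(v_probe_stop))
    v_probe_stop <- switch(species, m_persicae = 0.3, n_ribisnigri = 0.35,
                           custom = stop("custom profile needs v_probe_stop"))
  if (!(v_probe_start > 0 && v_probe_start < v_hysteresis &&
        v_hysteresis < v_probe_stop))
    stop("need 0 < v_probe_start < v_hysteresis < v_probe_stop")
  if (!(t_probe_start > 0 && t_probe_stop > 0)) stop("dwell times must be > 0")
  structure(list(species = species, v_probe_start = v_probe_start,
                 t_probe_start = t_probe_start, v_probe_stop = v_probe_stop,
                 v_hysteresis = v_hysteresis, t_probe_stop = t_probe_stop,
                 v_move_start = v_move_start, v_move_stop = v_move_stop),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "Species profile '%s':\n",
    "  probe start: v < %g mm/s for %g s (never exceeding %g mm/s)\n",
    "  probe stop : v > %g mm/s, staying >= %g mm/s for %g s\n",
    "  movement   : start > %g mm/s, stop < %g mm/s\n"),
    x$species, x$v_probe_start, x$t_probe_start, x$v_probe_stop,
    x$v_probe_stop, x$v_hysteresis, x$t_probe_stop,
    x$v_move_start, x$v_move_stop))
  invisible(x)
}

#' Zone-transition filter parameters
#'
#' When an aphid sits exactly on the zone-1/zone-2 edge, the assigned position
#' flickers between zones and the detector emits a train of consecutive short
#' probes. Such probes — shorter than `max_filtered_probe` and preceded by a
#' non-probe bout of at most `max_preceding_gap` — are filtered out after
#' acquisition.
#'
#' @param max_filtered_probe probes shorter than this (s) are candidates.
#' @param max_preceding_gap longest preceding non-probe bout (s) that marks a
#'   candidate as a train member.
#' @return object of class `filter_params`.
#' @export
filter_params <- function(max_filtered_probe = 3, max_preceding_gap = 15) {
  if (!(max_filtered_probe > 0 && max_preceding_gap > 0))
    stop("filter parameters must be > 0")
  structure(list(max_filtered_probe = max_filtered_probe,
                 max_preceding_gap = max_preceding_gap),
            class = "filter_params")
}

# all(cond) over sliding windows of length w anchored at each index:
# TRUE at i iff cond[i..i+w-1] are all TRUE and the window fits in the series
window_all <- function(cond, w) {
  n <- length(cond)
  bad <- cumsum(c(0L, as.integer(!cond)))
  out <- rep(FALSE, n)
  i <- seq_len(max(0L, n - w + 1L))
  out[i] <- (bad[i + w] - bad[i]) == 0L
  out
}

#' Detect probes from smoothed kinematics
#'
#' Runs the probe start/stop state machine over a kinematics series. A probe
#' starts at the first sample of a qualifying stillness window: the subject is
#' in zone 1, speed drops below `v_probe_start` and does not reach
#' `v_probe_stop` for at least `t_probe_start` seconds (remaining in zone 1
#' throughout). A probe stops at the onset of a qualifying excursion: speed
#' exceeds `v_probe_stop` and does not fall below `v_hysteresis` for at least
#' `t_probe_stop` seconds; shorter excursions (brief body movements during
#' probing) do not end the probe. Leaving zone 1 force-ends a probe at the
#' exit sample. Threshold comparisons are strict; samples with undefined speed
#' never qualify and disqualify any window containing them. A probe still open
#' at the end of the observation ends there; a stillness window truncated by
#' the end of the observation before its dwell time has elapsed does not start
#' a probe.
#'
#' The `start_at` argument selects the probe-start timestamp convention.
#' `"onset"` (default) backdates the probe to the beginning of the qualifying
#' stillness window, so rendered probes span the still period and every
#' detected probe lasts at least `t_probe_start`. `"confirmed"` records the
#' start when the dwell condition has been met, as event exports of
#' commercial tracking software do; under this convention an aphid flickering
#' across the zone boundary produces trains of very short probes — the
#' artifact that [filter_zone_transitions()] removes.
#'
#' @param kin an [compute_kinematics()] result.
#' @param profile a [species_profile()].
#' @param start_at probe-start timestamp convention, `"onset"` or
#'   `"confirmed"` (see Details).
#' @return An [event_stream()] of alternating `probe`/`non_probe` intervals
#'   tiling the observation.
#' @export
detect_probes <- function(kin, profile, start_at = c("onset", "confirmed")) {
  start_at <- match.arg(start_at)
  stopifnot(inherits(kin, "aphid_kinematics"), inherits(profile, "species_profile"))
  n <- nrow(kin)
  if (n == 0) stop("empty kinematics series")
  dur <- attr(kin, "duration")
  v <- kin$speed
  inz1 <- kin$zone == "zone1"
  if (all(is.na(v))) {
    warning("no valid detections in series; returning one non_probe interval")
    return(event_stream(0, dur, "non_probe", duration = dur))
  }
  dt <- attr(kin, "dt")
  w1 <- as.integer(round(profile$t_probe_start / dt))
  w2 <- as.integer(round(profile$t_probe_stop / dt))

  okv <- !is.na(v)
  start_win_ok <- okv & (v < profile$v_probe_stop) & inz1
  startable <- okv & (v < profile$v_probe_start) & inz1 & window_all(start_win_ok, w1)
  stop_win_ok <- okv & (v >= profile$v_hysteresis)
  stopcand <- okv & (v > profile$v_probe_stop) & window_all(stop_win_ok, w2)

  starts <- numeric(0); stops <- numeric(0)
  in_probe <- FALSE
  for (i in seq_len(n)) {
    if (!in_probe) {
      if (startable[i]) {
        starts <- c(starts, if (start_at == "onset") kin$t[i]
                    else kin$t[i] + profile$t_probe_start)
        in_probe <- TRUE
      }
    } else {
      if (!inz1[i] || stopcand[i]) {
        stops <- c(stops, kin$t[i])
        in_probe <- FALSE
      }
    }
  }
  if (in_probe) stops <- c(stops, dur)
  keep <- stops - starts > 1e-9      # "confirmed" starts can collapse a probe
  starts <- starts[keep]; stops <- stops[keep]

  gaps <- complement_intervals(starts, stops, dur)
  ev <- rbind(
    if (length(starts)) data.frame(start = starts, stop = stops, label = "probe"),
    if (nrow(gaps)) data.frame(start = gaps$start, stop = gaps$stop,
                               label = "non_probe"))
  event_stream(ev$start, ev$stop, ev$label, duration = dur)
}

#' Detect moving / not-moving states
#'
#' Simple two-threshold hysteresis with no dwell time: the subject starts
#' moving when smoothed speed exceeds `v_move_start` and stops moving when it
#' drops below `v_move_stop`. The initial state is taken from the first
#' sample with defined speed. Samples with undefined speed never switch the
#' state.
#'
#' @inheritParams detect_probes
#' @return An [event_stream()] of `moving`/`not_moving` intervals tiling the
#'   observation.
#' @export
detect_movement <- function(kin, profile) {
  stopifnot(inherits(kin, "aphid_kinematics"), inherits(profile, "species_profile"))
  n <- nrow(kin)
  if (n == 0) stop("empty kinematics series")
  dur <- attr(kin, "duration")
  v <- kin$speed
  if (all(is.na(v))) {
    warning("no valid detections in series; returning one not_moving interval")
    return(event_stream(0, dur, "not_moving", duration = dur))
  }
  first <- which(!is.na(v))[1]
  state <- if (v[first] > profile$v_move_start) "moving" else "not_moving"
  bounds <- numeric(0); labels <- character(0)
  seg_start <- 0
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    newstate <- state
    if (state == "not_moving" && v[i] > profile$v_move_start) newstate <- "moving"
    if (state == "moving" && v[i] < profile$v_move_stop) newstate <- "not_moving"
    if (newstate != state) {
      bounds <- c(bounds, kin$t[i]); labels <- c(labels, state)
      seg_start <- kin$t[i]
      state <- newstate
    }
  }
  starts <- c(0, bounds)
  stops <- c(bounds, dur)
  labs <- c(labels, state)
  keep <- stops > starts
  event_stream(starts[keep], stops[keep], labs[keep], duration = dur)
}

#' Filter zone-transition probe trains
#'
#' Removes (relabels as non-probe, merging neighbours) every probe shorter
#' than `max_filtered_probe` whose preceding non-probe bout lasted at most
#' `max_preceding_gap`. The rule is applied in one left-to-right pass with
#' gaps measured on the unfiltered stream, so a whole train of short probes
#' following a genuine probe is removed. A short probe at the very start of
#' the observation has no preceding non-probe bout and is retained.
#'
#' @param events an alternating `probe`/`non_probe` [event_stream()].
#' @param params a [filter_params()].
#' @return A filtered [event_stream()] tiling the same observation.
#' @export
filter_zone_transitions <- function(events, params = filter_params()) {
  stopifnot(inherits(events, "event_stream"), inherits(params, "filter_params"))
  if (!nrow(events)) return(events)
  dur <- attr(events, "duration")
  pr <- events_of(events, "probe")
  if (!nrow(pr)) return(events)
  np <- events_of(events, "non_probe")
  keep <- rep(TRUE, nrow(pr))
  for (k in seq_len(nrow(pr))) {
    plen <- pr$stop[k] - pr$start[k]
    if (plen >= params$max_filtered_probe) next
    gap_row <- which(abs(np$stop - pr$start[k]) < 1e-9)
    if (!length(gap_row)) next              # probe opens the observation
    gap <- np$stop[gap_row[1]] - np$start[gap_row[1]]
    if (gap <= params$max_preceding_gap) keep[k] <- FALSE
  }
  pr <- pr[keep, , drop = FALSE]
  gaps <- complement_intervals(pr$start, pr$stop, dur)
  ev <- rbind(
    if (nrow(pr)) data.frame(start = pr$start, stop = pr$stop, label = "probe"),
    if (nrow(gaps)) data.frame(start = gaps$start, stop = gaps$stop,
                               label = "non_probe"))
  event_stream(ev$start, ev$stop, ev$label, duration = dur)
}
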