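# Independent reference implementations used as oracles.
# These deliberately transcribe the event rules sample-by-sample with explicit
# window checks, unlike the package's precomputed-window implementation.

# naive probe automaton: explicit all() over each candidate window
oracle_probes <- function(speed, zone, dt, profile, duration = length(speed) * dt) {
  n <- length(speed)
  w1 <- round(profile$t_probe_start / dt)
  w2 <- round(profile$t_probe_stop / dt)
  t <- (seq_len(n) - 1) * dt
  ok <- function(v) !is.na(v)
  in_probe <- FALSE
  starts <- numeric(0); stops <- numeric(0)
  for (i in seq_len(n)) {
    if (!in_probe) {
      if (i + w1 - 1 <= n && ok(speed[i]) &&
          speed[i] < profile$v_probe_start && zone[i] == "zone1") {
        win <- i:(i + w1 - 1)
        if (all(!is.na(speed[win])) &&
            all(speed[win] < profile$v_probe_stop) &&
            all(zone[win] == "zone1")) {
          starts <- c(starts, t[i]); in_probe <- TRUE
        }
      }
    } else {
      if (zone[i] != "zone1") {
        stops <- c(stops, t[i]); in_probe <- FALSE
      } else if (i + w2 - 1 <= n && ok(speed[i]) &&
                 speed[i] > profile$v_probe_stop) {
        win <- i:(i + w2 - 1)
        if (all(!is.na(speed[win])) &&
            all(speed[win] >= profile$v_hysteresis)) {
          stops <- c(stops, t[i]); in_probe <- FALSE
        }
      }
    }
  }
  if (in_probe) stops <- c(stops, duration)
  data.frame(start = starts, stop = stops)
}

# naive two-threshold movement automaton
oracle_movement <- function(speed, dt, profile, duration = length(speed) * dt) {
  n <- length(speed)
  t <- (seq_len(n) - 1) * dt
  first <- which(!is.na(speed))[1]
  state <- if (speed[first] > profile$v_move_start) "moving" else "not_moving"
  starts <- 0; labs <- character(0); cur <- state
  bounds <- numeric(0)
  for (i in seq_len(n)) {
    if (is.na(speed[i])) next
    ns <- cur
    if (cur == "not_moving" && speed[i] > profile$v_move_start) ns <- "moving"
    if (cur == "moving" && speed[i] < profile$v_move_stop) ns <- "not_moving"
    if (ns != cur) { bounds <- c(bounds, t[i]); labs <- c(labs, cur); cur <- ns }
  }
  data.frame(start = c(0, bounds), stop = c(bounds, duration),
             label = c(labs, cur))
}

# random piecewise-constant speed series crossing the probe thresholds
random_speed_series <- function(n_blocks = 12, dt = 0.2) {
  lens <- sample(1:80, n_blocks, replace = TRUE)
  lvls <- sample(c(0, 0.005, 0.015, 0.05, 0.15, 0.25, 0.31, 0.5, 1.0),
                 n_blocks, replace = TRUE)
  rep(lvls, lens)
}

# brute-force interval accounting for observation summaries
oracle_summary_totals <- function(events, cats) {
  pr <- events[events$label == "probe", , drop = FALSE]
  d <- pr$stop - pr$start
  list(long_min = sum(d[d >= cats$long_min]) / 60,
       sustained_min = sum(d[d > cats$sustained_min]) / 60,
       other_min = sum(d[d < cats$long_min]) / 60,
       n_short = sum(d < cats$short_max),
       n_long = sum(d >= cats$long_min),
       non_probing_min = sum(with(events[events$label == "non_probe", ],
                                  stop - start)) / 60)
}

# sample-accumulation oracle for per-bin long-probe time
oracle_bin_long_time <- function(events, cats, bin_width, duration, dt = 0.01) {
  pr <- events[events$label == "probe", , drop = FALSE]
  d <- pr$stop - pr$start
  longs <- pr[d >= cats$long_min, , drop = FALSE]
  mid <- seq(dt / 2, duration, by = dt)
  inlong <- rep(FALSE, length(mid))
  for (k in seq_len(nrow(longs)))
    inlong <- inlong | (mid > longs$start[k] & mid < longs$stop[k])
  bins <- ceiling(mid / bin_width)
  as.numeric(tapply(inlong * dt, bins, sum))
}

# random alternating probe/non_probe stream tiling [0, duration)
random_event_stream <- function(duration = 7200, max_bouts = 20) {
  cuts <- sort(runif(sample(1:max_bouts, 1), 0, duration))
  edges <- unique(c(0, cuts, duration))
  labs <- rep(c("non_probe", "probe"), length.out = length(edges) - 1)
  if (runif(1) < 0.5) labs <- rev(labs)
  event_stream(edges[-length(edges)], edges[-1], labs, duration = duration)
}
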