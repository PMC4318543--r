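#' Generate a bout-structured behaviour schedule
#'
#' Builds a reproducible sequence of behaviour bouts emulating an aphid on a
#' leaf-disc arena: walking bouts, probing bouts (stillness with sub-threshold
#' jitter), and optional edge-dwell bouts (stillness exactly on the zone-1
#' boundary, which provokes the zone-flicker artifact). Bout kinds are drawn
#' from the given weights (never repeating the previous kind, so bouts are
#' maximal) and bout durations are exponential with the given means. Brief
#' confounding movement spikes — body movements during probing that must not
#' end a probe — are placed inside probing bouts as a Poisson process.
#'
#' The ground-truth probe stream marks every probing bout; spikes do not
#' split a probe, and edge dwells are not probes.
#'
#' @param params list of bout-mix parameters; defaults (see
#'   [schedule_params()]) describe an aphid on a susceptible host: probing
#'   dominates, with occasional walks.
#' @param duration observation duration in s.
#' @param seed integer seed.
#' @return object of class `behavior_schedule`: list with `bouts` (kind,
#'   start, duration), `spikes` (t, duration, peak), `ground_truth`
#'   ([event_stream()] of probe/non_probe), `params`, `duration`.
#' @export
generate_schedule <- function(params = schedule_params(), duration = 3600,
                              seed = 1L) {
  set.seed(seed)
  p <- params
  kinds <- c("walk", "probe", "edge_dwell")
  w <- c(p$p_walk, p$p_probe, p$p_edge)
  if (any(w < 0) || sum(w) <= 0) stop("invalid bout weights")
  means <- c(walk = p$mean_walk, probe = p$mean_probe, edge_dwell = p$mean_edge)

  bouts <- data.frame(kind = character(0), start = numeric(0),
                      duration = numeric(0))
  t <- 0; prev <- ""
  while (t < duration) {
    repeat {
      k <- sample(kinds, 1, prob = w)
      if (k != prev || sum(w > 0) == 1) break
    }
    d <- stats::rexp(1, 1 / means[[k]])
    d <- min(d, duration - t)
    bouts <- rbind(bouts, data.frame(kind = k, start = t, duration = d))
    t <- t + d; prev <- k
  }

  spikes <- data.frame(t = numeric(0), duration = numeric(0), peak = numeric(0))
  pb <- bouts[bouts$kind == "probe", , drop = FALSE]
  for (i in seq_len(nrow(pb))) {
    room <- pb$duration[i] - 2 * p$spike_margin
    if (room <= 0 || p$spike_rate <= 0) next
    k <- stats::rpois(1, p$spike_rate * room)
    if (k == 0) next
    spikes <- rbind(spikes, data.frame(
      t = pb$start[i] + p$spike_margin + sort(stats::runif(k, 0, room)),
      duration = p$spike_duration, peak = p$spike_peak))
  }

  gt_probe <- bouts[bouts$kind == "probe", , drop = FALSE]
  gaps <- complement_intervals(gt_probe$start, gt_probe$start + gt_probe$duration,
                               duration)
  gt <- rbind(
    if (nrow(gt_probe)) data.frame(start = gt_probe$start,
                                   stop = gt_probe$start + gt_probe$duration,
                                   label = "probe"),
    if (nrow(gaps)) data.frame(start = gaps$start, stop = gaps$stop,
                               label = "non_probe"))
  structure(list(bouts = bouts, spikes = spikes,
                 ground_truth = event_stream(gt$start, gt$stop, gt$label,
                                             duration = duration),
                 params = p, duration = duration, seed = seed),
            class = "behavior_schedule")
}

#' Bout-mix parameters for the schedule generator
#'
#' @param p_walk,p_probe,p_edge bout-kind weights.
#' @param mean_walk,mean_probe,mean_edge mean bout durations (s,
#'   exponential).
#' @param walk_speed walking speed (mm/s); well above the probe-stop
#'   threshold.
#' @param turn_sd turning-angle SD per frame (rad) of the correlated random
#'   walk.
#' @param jitter_sd positional jitter SD during probing (mm per frame); small
#'   enough that smoothed jitter speed stays below the probe-start threshold.
#' @param edge_jitter_sd stationary SD (mm) of the slow positional drift
#'   during edge dwells; any amplitude flickers the zone when the anchor sits
#'   on the boundary, while staying slow enough to register as stillness.
#' @param edge_tau correlation time (s) of the edge-dwell drift; sets the
#'   typical in-zone dwell length.
#' @param edge_offset radial offset (mm) of the edge anchor relative to the
#'   zone-1 boundary; slightly negative (centroid estimate marginally inside
#'   the rim) so out-of-zone excursions are brief.
#' @param spike_rate confounding-spike rate inside probes (per s).
#' @param spike_duration,spike_peak spike length (s) and peak speed (mm/s);
#'   shorter than the probe-stop dwell time so the hysteresis rule absorbs
#'   them.
#' @param spike_margin minimum distance of a spike from the bout edges (s).
#' @return named list of parameters.
#' @export
schedule_params <- function(p_walk = 0.5, p_probe = 0.5, p_edge = 0,
                            mean_walk = 60, mean_probe = 1800, mean_edge = 40,
                            walk_speed = 1.0, turn_sd = 0.4,
                            jitter_sd = 0.0008, edge_jitter_sd = 0.006,
                            edge_tau = 2, edge_offset = -0.005,
                            spike_rate = 1 / 600, spike_duration = 0.6,
                            spike_peak = 0.5, spike_margin = 5) {
  as.list(environment())
}

#' @export
print.behavior_schedule <- function(x, ...) {
  cat(sprintf("Behaviour schedule: %.0f s, %d bouts (%s), %d spikes\n",
              x$duration, nrow(x$bouts),
              paste(sprintf("%s:%d", names(table(x$bouts$kind)),
                            as.integer(table(x$bouts$kind))), collapse = ", "),
              nrow(x$spikes)))
  invisible(x)
}

#' Render a trajectory from a behaviour schedule
#'
#' Turns a schedule into a frame-rate centre-point track inside the arena.
#' Walking bouts are a correlated random walk at the set speed, confined to
#' the zone-1 interior (aphids stay on the leaf). Probing bouts render as a
#' fixed anchor plus Gaussian jitter. Edge-dwell bouts anchor exactly on the
#' zone-1 boundary so the assigned zone flickers with jitter. Confounding
#' spikes are brief out-and-back displacements along a random direction with
#' a triangular speed profile. Positions never leave the arena wall.
#'
#' @param schedule a [generate_schedule()] result.
#' @param arena an [arena_geometry()].
#' @param noise_sd extra white positional noise on every frame (mm),
#'   emulating centroid estimation error; 0 for a noise-free track.
#' @param frame_rate frames per s (default 25).
#' @param seed integer seed (independent of the schedule's).
#' @return an [trajectory()] object.
#' @export
render_trajectory <- function(schedule, arena, noise_sd = 0, frame_rate = 25,
                              seed = 1L) {
  stopifnot(inherits(schedule, "behavior_schedule"),
            inherits(arena, "arena_geometry"))
  set.seed(seed)
  p <- schedule$params
  n <- as.integer(round(schedule$duration * frame_rate))
  x <- numeric(n); y <- numeric(n)
  r1 <- arena$disc_radius - arena$zone1_margin
  walk_r <- r1 - 0.3                       # keep walks well inside zone 1
  cx <- arena$centre[1]; cy <- arena$centre[2]
  pos <- c(cx, cy)
  heading <- stats::runif(1, 0, 2 * pi)
  step <- p$walk_speed / frame_rate

  clamp_disc <- function(q, rmax) {
    d <- sqrt((q[1] - cx)^2 + (q[2] - cy)^2)
    if (d > rmax) c(cx, cy) + (q - c(cx, cy)) * (rmax / d) else q
  }

  for (b in seq_len(nrow(schedule$bouts))) {
    kind <- schedule$bouts$kind[b]
    i0 <- as.integer(round(schedule$bouts$start[b] * frame_rate)) + 1L
    i1 <- as.integer(round((schedule$bouts$start[b] +
                            schedule$bouts$duration[b]) * frame_rate))
    if (i1 < i0) next
    idx <- i0:min(i1, n)
    nf <- length(idx)
    if (kind == "walk") {
      turns <- stats::rnorm(nf, 0, p$turn_sd)
      for (k in seq_len(nf)) {
        heading <- heading + turns[k]
        cand <- pos + step * c(cos(heading), sin(heading))
        d <- sqrt((cand[1] - cx)^2 + (cand[2] - cy)^2)
        if (d > walk_r) {                  # bounce back towards the centre
          heading <- atan2(cy - pos[2], cx - pos[1]) + stats::rnorm(1, 0, 0.3)
          cand <- pos + step * c(cos(heading), sin(heading))
          cand <- clamp_disc(cand, walk_r)
        }
        pos <- cand
        x[idx[k]] <- pos[1]; y[idx[k]] <- pos[2]
      }
    } else if (kind == "probe") {
      anchor <- clamp_disc(pos, walk_r)
      jx <- stats::rnorm(nf, 0, p$jitter_sd)
      jy <- stats::rnorm(nf, 0, p$jitter_sd)
      x[idx] <- anchor[1] + jx; y[idx] <- anchor[2] + jy
      pos <- anchor
    } else if (kind == "edge_dwell") {
      # anchor exactly on the zone-1 boundary; the apparent position drifts
      # slowly (AR(1), correlation time edge_tau) so the assigned zone
      # alternates in dwells of seconds, as for an aphid straddling the edge
      th <- atan2(pos[2] - cy, pos[1] - cx)
      if (!is.finite(th) || (pos[1] == cx && pos[2] == cy))
        th <- stats::runif(1, 0, 2 * pi)
      anchor <- c(cx, cy) + (r1 + p$edge_offset) * c(cos(th), sin(th))
      rho <- exp(-1 / (frame_rate * p$edge_tau))
      inno <- p$edge_jitter_sd * sqrt(1 - rho^2)
      jr <- stats::filter(stats::rnorm(nf, 0, inno), rho, "recursive")
      jt <- stats::filter(stats::rnorm(nf, 0, inno), rho, "recursive")
      u <- c(cos(th), sin(th))                 # radial unit vector
      x[idx] <- anchor[1] + jr * u[1] - jt * u[2]
      y[idx] <- anchor[2] + jr * u[2] + jt * u[1]
      pos <- anchor
    }
  }

  # overlay confounding spikes (out-and-back, triangular speed profile)
  for (s in seq_len(nrow(schedule$spikes))) {
    sp <- schedule$spikes[s, ]
    j0 <- as.integer(round(sp$t * frame_rate)) + 1L
    nf <- max(2L, as.integer(round(sp$duration * frame_rate)))
    if (j0 + nf - 1L > n) next
    th <- stats::runif(1, 0, 2 * pi)
    u <- seq(0, 1, length.out = nf)
    excursion <- sp$peak * sp$duration / 2 * (1 - abs(2 * u - 1)) # mm
    jdx <- j0:(j0 + nf - 1L)
    x[jdx] <- x[jdx] + excursion * cos(th)
    y[jdx] <- y[jdx] + excursion * sin(th)
  }

  if (noise_sd > 0) {
    x <- x + stats::rnorm(n, 0, noise_sd)
    y <- y + stats::rnorm(n, 0, noise_sd)
  }
  # never exit the arena wall
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  over <- d > arena$wall_radius
  if (any(over)) {
    f <- arena$wall_radius / d[over]
    x[over] <- cx + (x[over] - cx) * f
    y[over] <- cy + (y[over] - cy) * f
  }
  trajectory(t = (seq_len(n) - 1) / frame_rate, x = x, y = y,
             frame_rate = frame_rate,
             arena_id = sprintf("synthetic_seed%d", schedule$seed))
}
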