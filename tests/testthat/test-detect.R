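prof <- species_profile("m_persicae")

test_that("a long stillness framed by movement yields one probe with stated timestamps", {
  # 60 s at 0.5 mm/s, 1200 s at 0.005 mm/s, 10 s at 0.4 mm/s (all zone 1)
  v <- c(rep(0.5, 300), rep(0.005, 6000), rep(0.4, 50))
  kin <- kinematics_series(v, "zone1")
  ev <- detect_probes(kin, prof)
  pr <- ev[ev$label == "probe", ]
  expect_equal(nrow(pr), 1)
  expect_equal(pr$start, 60)
  expect_equal(pr$stop, 1260)
})

test_that("a brief supra-threshold excursion during probing does not stop the probe", {
  # 1-s excursion to 0.32 mm/s returning below 0.1 mm/s within 2 s
  v <- c(rep(0.5, 300), rep(0.005, 3000), rep(0.32, 5), rep(0.005, 3000),
         rep(0.4, 50))
  kin <- kinematics_series(v, "zone1")
  ev <- detect_probes(kin, prof)
  pr <- ev[ev$label == "probe", ]
  expect_equal(nrow(pr), 1)
  expect_equal(pr$stop, 60 + (3000 + 5 + 3000) * 0.2)
})

test_that("a sustained excursion above hysteresis stops the probe at its onset", {
  v <- c(rep(0.005, 500), rep(0.35, 10), rep(0.15, 10), rep(0.005, 500))
  kin <- kinematics_series(v, "zone1")
  pr <- detect_probes(kin, prof)
  pr <- pr[pr$label == "probe", ]
  expect_equal(nrow(pr), 2)
  expect_equal(pr$stop[1], 100)    # onset of the 0.35 mm/s excursion
})

test_that("leaving zone 1 force-ends a probe", {
  v <- rep(0.005, 1000)
  zone <- c(rep("zone1", 600), rep("zone2", 400))
  kin <- kinematics_series(v, zone)
  pr <- detect_probes(kin, prof)
  pr <- pr[pr$label == "probe", ]
  expect_equal(nrow(pr), 1)
  expect_equal(pr$stop, 120)
})

test_that("all-undetected series yields one non_probe interval with a warning", {
  kin <- kinematics_series(rep(NA_real_, 100), "undetected")
  expect_warning(ev <- detect_probes(kin, prof), "no valid detections")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$label, "non_probe")
  expect_error(detect_probes(kinematics_series(numeric(0)), prof), "empty")
})

test_that("probe detection equals the naive per-sample automaton on random series", {
  set.seed(101)
  for (rep_i in 1:300) {
    v <- random_speed_series()
    zone <- if (runif(1) < 0.3)
      sample(c("zone1", "zone2"), length(v), replace = TRUE, prob = c(0.9, 0.1))
    else rep("zone1", length(v))
    kin <- kinematics_series(v, zone)
    got <- detect_probes(kin, prof)
    got <- got[got$label == "probe", c("start", "stop")]
    want <- oracle_probes(v, zone, 0.2, prof)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                 tolerance = 1e-12)
  }
})

test_that("movement detection matches its trivial cases and the naive automaton", {
  kin0 <- kinematics_series(rep(0, 100))
  ev0 <- detect_movement(kin0, prof)
  expect_equal(nrow(ev0), 1); expect_equal(ev0$label, "not_moving")
  kin1 <- kinematics_series(rep(0.5, 100))
  ev1 <- detect_movement(kin1, prof)
  expect_equal(nrow(ev1), 1); expect_equal(ev1$label, "moving")

  set.seed(202)
  for (rep_i in 1:200) {
    v <- random_speed_series()
    kin <- kinematics_series(v)
    got <- detect_movement(kin, prof)
    want <- oracle_movement(v, 0.2, prof)
    expect_equal(data.frame(start = got$start, stop = got$stop,
                            label = got$label), want, tolerance = 1e-12)
  }
})

test_that("probe and non-probe intervals tile the observation exactly", {
  set.seed(33)
  for (rep_i in 1:50) {
    v <- random_speed_series()
    kin <- kinematics_series(v)
    ev <- detect_probes(kin, prof)
    expect_equal(sum(ev$stop - ev$start), attr(kin, "duration"),
                 tolerance = 1e-9)
    mv <- detect_movement(kin, prof)
    expect_equal(sum(mv$stop - mv$start), attr(kin, "duration"),
                 tolerance = 1e-9)
  }
})

test_that("raising the stop velocity never increases the number of probe stops", {
  # The stop threshold also bounds the speeds allowed inside a probe-start
  # window, so the monotonicity of stop events is only well defined when the
  # start windows are unaffected by the threshold. Alternating long stillness
  # blocks (speeds far below every threshold) with activity blocks pins the
  # start events, leaving only the stop rule sensitive to the threshold.
  set.seed(44)
  for (rep_i in 1:30) {
    nb <- 8
    v <- unlist(lapply(seq_len(nb), function(b) {
      c(rep(sample(c(0, 0.005, 0.015), 1), sample(55:80, 1)),
        rep(sample(c(0.05, 0.15, 0.25, 0.31, 0.42, 0.5, 1.0), 1),
            sample(5:40, 1)))
    }))
    kin <- kinematics_series(v)
    stops <- vapply(c(0.3, 0.45, 0.6, 0.9), function(vs) {
      p <- species_profile("custom", v_probe_stop = vs)
      ev <- detect_probes(kin, p)
      sum(ev$label == "probe" & ev$stop < attr(kin, "duration"))
    }, numeric(1))
    expect_true(all(diff(stops) <= 0))
  }
})

test_that("the zone-transition filter removes short probes after short gaps", {
  # 2-s probe preceded by a 10-s non-probe: removed
  ev <- event_stream(c(0, 100, 110, 112), c(100, 110, 112, 200),
                     c("probe", "non_probe", "probe", "non_probe"),
                     duration = 200)
  out <- filter_zone_transitions(ev)
  expect_equal(sum(out$label == "probe"), 1)
  expect_equal(out$stop[out$label == "probe"], 100)

  # 2-s probe preceded by a 60-s non-probe: retained
  ev2 <- event_stream(c(0, 100, 160, 162), c(100, 160, 162, 200),
                      c("probe", "non_probe", "probe", "non_probe"),
                      duration = 200)
  out2 <- filter_zone_transitions(ev2)
  expect_equal(sum(out2$label == "probe"), 2)
})

test_that("a train of short probes after a long probe is removed wholesale", {
  # long probe, then 1-s probes separated by 2-s gaps
  starts <- c(0, 100 + (0:4) * 3 + 2)
  stops <- c(100, 100 + (0:4) * 3 + 3)
  labs <- c("probe", rep("probe", 5))
  pr <- data.frame(start = starts, stop = stops)
  gaps <- data.frame(start = pr$stop[-6], stop = pr$start[-1])
  ev <- event_stream(c(pr$start, gaps$start, 115), c(pr$stop, gaps$stop, 200),
                     c(labs, rep("non_probe", 5), "non_probe"),
                     duration = 200)
  out <- filter_zone_transitions(ev)
  pr_out <- out[out$label == "probe", ]
  expect_equal(nrow(pr_out), 1)
  expect_equal(pr_out$stop - pr_out$start, 100)
  # removed probes merge into the surrounding non-probe time
  expect_equal(sum(out$stop - out$start), 200)
  # a filtered stream passes through unchanged
  expect_equal(as.data.frame(filter_zone_transitions(out)), as.data.frame(out))
})

test_that("a short probe opening the observation is retained", {
  ev <- event_stream(c(0, 2), c(2, 100), c("probe", "non_probe"),
                     duration = 100)
  out <- filter_zone_transitions(ev)
  expect_equal(sum(out$label == "probe"), 1)
})

test_that("species profiles carry the published thresholds", {
  mp <- species_profile("m_persicae")
  nr <- species_profile("n_ribisnigri")
  expect_equal(mp$v_probe_stop, 0.3)
  expect_equal(nr$v_probe_stop, 0.35)
  expect_equal(mp$v_probe_start, 0.02)
  expect_equal(mp$t_probe_start, 10)
  expect_equal(mp$v_hysteresis, 0.1)
  expect_equal(mp$t_probe_stop, 2)
  expect_error(species_profile("custom", v_probe_stop = 0.05), "v_hysteresis")
})
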