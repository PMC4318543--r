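cats <- probe_categories()

test_that("probe categories follow the stated boundary semantics", {
  m <- categorize_probe(c(120, 1500, 2100, 2100.1), cats)
  expect_equal(m[1, ], c(short = TRUE, long = FALSE, sustained = FALSE,
                         other = TRUE))
  expect_equal(m[2, ], c(short = FALSE, long = TRUE, sustained = FALSE,
                         other = FALSE))               # >= 25 min is long
  expect_equal(m[3, ], c(short = FALSE, long = TRUE, sustained = FALSE,
                         other = FALSE))               # 35 min exactly: not sustained
  expect_equal(m[4, ], c(short = FALSE, long = TRUE, sustained = TRUE,
                         other = FALSE))
  expect_error(probe_categories(long_min = 100, short_max = 200), "short_max")
})

test_that("a single probe spanning the whole observation summarises degenerately", {
  D <- 8 * 3600
  ev <- event_stream(0, D, "probe", duration = D)
  mv <- event_stream(0, D, "not_moving", duration = D)
  s <- summarize_observation(ev, mv, kin = NULL, duration = D)
  expect_equal(s$n_long_probes, 1)
  expect_equal(s$mean_long_probe_min, 480)
  expect_equal(s$latency_first_long_min, 0)
  expect_equal(s$total_non_probing_min, 0)
})

test_that("an observation without probes leaves mean and latency absent, not zero", {
  D <- 3600
  ev <- event_stream(0, D, "non_probe", duration = D)
  mv <- event_stream(0, D, "moving", duration = D)
  s <- summarize_observation(ev, mv, kin = NULL, duration = D)
  expect_equal(s$total_long_probes_min, 0)
  expect_equal(s$n_long_probes, 0)
  expect_true(is.na(s$mean_long_probe_min))
  expect_true(is.na(s$latency_first_long_min))
})

test_that("summaries equal brute-force interval accounting on random streams", {
  set.seed(55)
  for (rep_i in 1:40) {
    ev <- random_event_stream()
    mv <- event_stream(0, 7200, "not_moving", duration = 7200)
    s <- summarize_observation(ev, mv, kin = NULL, duration = 7200)
    want <- oracle_summary_totals(as.data.frame(ev), cats)
    expect_equal(s$total_long_probes_min, want$long_min)
    expect_equal(s$total_sustained_probes_min, want$sustained_min)
    expect_equal(s$total_other_probes_min, want$other_min)
    expect_equal(s$n_short_probes, want$n_short)
    expect_equal(s$n_long_probes, want$n_long)
    expect_equal(s$total_non_probing_min, want$non_probing_min)
    # bookkeeping: non-probing + long + other = observation duration
    expect_equal(s$total_non_probing_min + s$total_long_probes_min +
                   s$total_other_probes_min, 120, tolerance = 1e-9)
  }
})

test_that("summaries are invariant to splitting a non-probe interval", {
  D <- 7200
  ev1 <- event_stream(c(0, 2000), c(2000, D), c("probe", "non_probe"),
                      duration = D)
  ev2 <- event_stream(c(0, 2000, 5000), c(2000, 5000, D),
                      c("probe", "non_probe", "non_probe"), duration = D)
  mv <- event_stream(0, D, "not_moving", duration = D)
  s1 <- summarize_observation(ev1, mv, NULL, duration = D)
  s2 <- summarize_observation(ev2, mv, NULL, duration = D)
  for (v in c("total_long_probes_min", "total_non_probing_min",
              "mean_long_probe_min", "latency_first_long_min"))
    expect_equal(s1[[v]], s2[[v]])
  # but the bout count reflects the split
  expect_equal(s2$n_non_probe_bouts, 2)
})

test_that("a duration mismatch is a validation error", {
  ev <- event_stream(0, 100, "probe", duration = 100)
  mv <- event_stream(0, 90, "not_moving", duration = 90)
  expect_error(summarize_observation(ev, mv, NULL, duration = 100),
               "does not tile")
})

test_that("a 90-min probe starting at 30 min splits pro rata across hour bins", {
  D <- 8 * 3600
  ev <- event_stream(c(0, 1800, 7200), c(1800, 7200, D),
                     c("non_probe", "probe", "non_probe"), duration = D)
  b <- summarize_bins(ev, kin = NULL, bin_width = 3600, duration = D)
  expect_equal(b$pct_long_probes[1], 50)
  expect_equal(b$pct_long_probes[2], 100)
  expect_equal(b$pct_long_probes[3:8], rep(0, 6))
})

test_that("per-bin long-probe time matches a per-sample accumulation oracle", {
  set.seed(66)
  for (rep_i in 1:10) {
    ev <- random_event_stream()
    b <- summarize_bins(ev, kin = NULL, bin_width = 1800, duration = 7200)
    want <- oracle_bin_long_time(as.data.frame(ev), cats, 1800, 7200)
    expect_equal(b$pct_long_probes, 100 * want / 1800, tolerance = 1e-3)
    # per-bin values sum to the whole-observation total
    s <- summarize_observation(ev, event_stream(0, 7200, "not_moving",
                                                duration = 7200),
                               NULL, duration = 7200)
    expect_equal(sum(b$pct_long_probes) * 1800 / 100 / 60,
                 s$total_long_probes_min, tolerance = 1e-9)
  }
})

test_that("uniform walking spreads distance equally over bins", {
  n <- 3600 * 5
  kin <- kinematics_series(rep(0.5, n))
  ev <- event_stream(0, 3600, "non_probe", duration = 3600)
  b <- summarize_bins(ev, kin, bin_width = 600, duration = 3600)
  expect_equal(b$distance_cm, rep(b$distance_cm[1], 6), tolerance = 0.02)
  expect_equal(sum(b$distance_cm), kin$cumulative_distance[n] / 10,
               tolerance = 1e-9)
})

test_that("qc partition separates observations by detected fraction", {
  mk <- function(f) {
    s <- summarize_observation(event_stream(0, 60, "non_probe", duration = 60),
                               event_stream(0, 60, "moving", duration = 60),
                               NULL, duration = 60)
    s$qc_detected_fraction <- f
    s
  }
  sums <- do.call(rbind, lapply(c(1.0, 0.95, 0.5, 0.0, NA), mk))
  part <- qc_exclude(sums, min_detected_fraction = 0.9)
  expect_equal(nrow(part$retained), 2)
  expect_equal(nrow(part$excluded), 3)
  expect_match(part$excluded$reason[1], "detected fraction")
  # partition sizes equal a brute-force count
  expect_equal(nrow(part$retained),
               sum(sums$qc_detected_fraction >= 0.9, na.rm = TRUE))
})
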