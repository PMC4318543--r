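test_that("rejection sampling honours the truncation bounds", {
  sp <- group_spec(62.8, sd = 31.3, lower = 25, upper = 480, label = "Co-2")
  pool <- simulate_group(sp, 5000, seed = 1)
  expect_length(pool, 5000)
  expect_true(all(pool >= 25 & pool <= 480))
})

test_that("se and n derive the group standard deviation", {
  sp <- group_spec(62.8, se = 7.0, n = 20)
  expect_equal(sp$sd, 7.0 * sqrt(20))
})

test_that("a vanishing sd gives an almost constant pool", {
  sp <- group_spec(100, sd = 1e-6, lower = 0, upper = 480)
  pool <- simulate_group(sp, 1000, seed = 2)
  expect_equal(mean(pool), 100, tolerance = 1e-6)
  expect_lt(sd(pool), 1e-5)
})

test_that("degenerate truncation is refused", {
  expect_error(simulate_group(group_spec(1000, sd = 10, lower = 0, upper = 480),
                              100), "degenerate")
})

test_that("pool moments match closed-form truncated-normal moments", {
  mu <- 62.8; s <- 31.3; lo <- 25; hi <- 480
  a <- (lo - mu) / s; b <- (hi - mu) / s
  Z <- pnorm(b) - pnorm(a)
  m_true <- mu + s * (dnorm(a) - dnorm(b)) / Z
  v_true <- s^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                     ((dnorm(a) - dnorm(b)) / Z)^2)
  n <- 2e4
  pool <- simulate_group(group_spec(mu, sd = s, lower = lo, upper = hi), n,
                         seed = 3)
  mc_se_mean <- sqrt(v_true / n)
  expect_lt(abs(mean(pool) - m_true), 3 * mc_se_mean)
  # variance of the sample variance ~ 2 sigma^4/(n-1) for near-normal data
  expect_lt(abs(var(pool) - v_true), 3 * sqrt(2) * v_true / sqrt(n - 1))
})

test_that("the family-wise null detection rate is 1 - (1 - alpha)^2", {
  sp <- group_spec(100, sd = 30, lower = 0, upper = 480)
  cfg <- power_config(list(list(group1 = sp, group2 = sp),
                           list(group1 = sp, group2 = sp)),
                      iterations = 2000, replicate_levels = 20,
                      alpha_per_test = 0.025, seed = 5)
  r <- detection_rate(cfg)
  want <- 100 * (1 - 0.975^2)               # 4.94%
  mc_se <- 100 * sqrt(want / 100 * (1 - want / 100) / 2000)
  expect_lt(abs(r$rates$detection_rate - want), 3 * mc_se)
})

test_that("widely separated groups saturate the detection rate", {
  g1 <- group_spec(100, sd = 10, lower = 0, upper = 1000)
  g2 <- group_spec(200, sd = 10, lower = 0, upper = 1000)
  cfg <- power_config(list(list(group1 = g1, group2 = g2)),
                      iterations = 200, replicate_levels = 20,
                      alpha_per_test = 0.025, seed = 6)
  expect_equal(detection_rate(cfg)$rates$detection_rate, 100)
})

test_that("detection rate is non-decreasing in the replicate level", {
  cfg <- power_config(arabidopsis_video_specs(), iterations = 400,
                      replicate_levels = c(10, 20, 40), seed = 7)
  r <- detection_rate(cfg)$rates
  expect_true(all(diff(r$detection_rate) > -3 * max(r$mc_se)))
})

test_that("type-I error stays at the nominal family-wise level and scales with alpha", {
  sp <- group_spec(150, sd = 50, lower = 0, upper = 480)
  two <- list(list(group1 = sp, group2 = sp), list(group1 = sp, group2 = sp))
  cfg25 <- power_config(two, iterations = 2000, replicate_levels = c(15, 20),
                        alpha_per_test = 0.025, seed = 8)
  r25 <- type1_rate(cfg25)$rates
  expect_true(all(abs(r25$detection_rate - 4.94) < 3 * r25$mc_se + 1e-9))

  one <- list(list(group1 = sp, group2 = sp))
  cfg05 <- power_config(one, iterations = 2000, replicate_levels = 20,
                        alpha_per_test = 0.05, seed = 9)
  cfg025 <- power_config(one, iterations = 2000, replicate_levels = 20,
                         alpha_per_test = 0.025, seed = 9)
  r05 <- type1_rate(cfg05)$rates$detection_rate
  r025 <- type1_rate(cfg025)$rates$detection_rate
  # halved alpha roughly halves the marginal false-positive rate
  expect_lt(abs(r025 - r05 / 2), 3 * 100 * sqrt(0.05 * 0.95 / 2000))
})

test_that("marginal power matches the analytic non-central t when truncation is negligible", {
  g1 <- group_spec(100, sd = 20, lower = 0, upper = 1000)
  g2 <- group_spec(115, sd = 20, lower = 0, upper = 1000)
  n <- 20
  cfg <- power_config(list(list(name = "v", group1 = g1, group2 = g2)),
                      iterations = 4000, replicate_levels = n,
                      alpha_per_test = 0.025, seed = 10)
  r <- detection_rate(cfg)
  pw <- function(delta) 100 * power.t.test(n = n, delta = delta, sd = 20,
                                           sig.level = 0.025)$power
  want <- pw(15)
  # iterations share one pool per group, so the pool-level error in the
  # realised group difference propagates into the rate
  se_delta <- sqrt(2 * 20^2 / cfg$n_draws)
  slope <- (pw(15 + 1) - pw(15 - 1)) / 2
  mc_se <- sqrt(want / 100 * (1 - want / 100) / 4000 * 100^2 +
                  (slope * se_delta)^2)
  expect_lt(abs(r$rates$rate_v - want), 3 * mc_se)
})

test_that("duration rescaling follows the stated default policy", {
  sp <- group_spec(62.8, sd = 31.3, lower = 25, upper = 480)
  expect_equal(duration_rescale(sp, 480, 480)[c("mean", "sd", "lower", "upper")],
               sp[c("mean", "sd", "lower", "upper")])
  half <- duration_rescale(sp, 240, 480)
  expect_equal(half$mean, 31.4)
  expect_equal(half$upper, 240)
  expect_equal(half$lower, 25)
})

test_that("alternative rescaling policies change the result reproducibly", {
  sp1 <- group_spec(276, se = 27, n = 20, lower = 0, upper = 480)
  sp2 <- group_spec(353, se = 19, n = 17, lower = 0, upper = 480)
  keep_sd <- function(s, r) group_spec(mean = s$mean * r, sd = s$sd,
                                       lower = s$lower, upper = s$upper * r,
                                       label = s$label)
  mk <- function(policy) {
    v <- list(list(group1 = duration_rescale(sp1, 240, 480, policy),
                   group2 = duration_rescale(sp2, 240, 480, policy)))
    detection_rate(power_config(v, iterations = 400, replicate_levels = 20,
                                alpha_per_test = 0.025,
                                seed = 11))$rates$detection_rate
  }
  r_default <- mk(NULL)
  r_keep_sd <- mk(keep_sd)
  # scaling the SD down preserves the effect size; keeping it dilutes it
  expect_gt(r_default, r_keep_sd)
})

test_that("results are reproducible bit-for-bit per seed", {
  cfg <- power_config(arabidopsis_video_specs(), iterations = 100,
                      replicate_levels = 20, seed = 12)
  expect_identical(detection_rate(cfg)$rates, detection_rate(cfg)$rates)
})
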