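#' Group specification for power simulation
#'
#' Describes the distribution of one response variable in one plant-line
#' group: a normal distribution with the group's mean and standard deviation,
#' truncated to the variable's feasible range (draws below zero or the probe
#' category's minimum duration, or above the maximum recording duration, are
#' rejected and redrawn). Published tables usually print the standard error;
#' supply `se` and `n` and the SD is derived as `se * sqrt(n)`.
#'
#' @param mean group mean (same units as the response variable, typically min).
#' @param sd group standard deviation; alternatively give `se` and `n`.
#' @param se,n standard error and sample size used to derive `sd`.
#' @param lower,upper truncation bounds (e.g. 25 and 480 min for the mean
#'   duration of long probes in an 8-h recording).
#' @param label plant-line label.
#' @return object of class `group_spec`.
#' @examples
#' group_spec(62.8, se = 7.0, n = 20, lower = 25, upper = 480, label = "Co-2")
#' @export
group_spec <- function(mean, sd = NULL, se = NULL, n = NULL,
                       lower = 0, upper = 480, label = "group") {
  if (is.null(sd)) {
    if (is.null(se) || is.null(n)) stop("give sd, or se and n")
    sd <- se * sqrt(n)
  }
  if (!(sd > 0)) stop("sd must be > 0")
  if (!(lower < upper)) stop("need lower < upper")
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper,
                 label = label, n_source = n),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("Group '%s': N(%.4g, sd %.4g) truncated to [%g, %g]\n",
              x$label, x$mean, x$sd, x$lower, x$upper))
  invisible(x)
}

#' Draw a truncated-normal sample pool
#'
#' Rejection sampling: normal draws outside `[lower, upper]` are discarded
#' and redrawn until `n_draws` values are accepted, so the pool size is
#' exact. Degenerate specifications whose acceptance probability is below 1%
#' are refused.
#'
#' @param spec a [group_spec()].
#' @param n_draws pool size (default 1e4).
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return numeric vector of length `n_draws`, all inside the bounds.
#' @export
simulate_group <- function(spec, n_draws = 1e4, seed = NULL) {
  stopifnot(inherits(spec, "group_spec"))
  if (!is.null(seed)) set.seed(seed)
  accept <- stats::pnorm(spec$upper, spec$mean, spec$sd) -
    stats::pnorm(spec$lower, spec$mean, spec$sd)
  if (accept < 0.01)
    stop(sprintf("degenerate spec '%s': truncation keeps %.2f%% of the mass",
                 spec$label, 100 * accept))
  out <- numeric(0)
  while (length(out) < n_draws) {
    want <- n_draws - length(out)
    cand <- stats::rnorm(ceiling(want / accept * 1.1) + 10, spec$mean, spec$sd)
    out <- c(out, cand[cand >= spec$lower & cand <= spec$upper])
  }
  out[seq_len(n_draws)]
}

#' Power-simulation configuration
#'
#' @param variables list of variables, each a list with elements `group1` and
#'   `group2` ([group_spec()]s) and optionally `name`.
#' @param n_draws pool size per group (default 1e4).
#' @param iterations Monte Carlo iterations per replicate level (default
#'   1000).
#' @param replicate_levels per-group sample sizes to evaluate.
#' @param alpha_per_test per-test significance level after Bonferroni
#'   correction (0.05 / number of variables; 0.025 for two video variables).
#' @param var_equal `TRUE` for Student's equal-variance t-test (the default);
#'   `FALSE` for Welch.
#' @param seed integer seed governing pools and subsampling.
#' @return object of class `power_config`.
#' @export
power_config <- function(variables, n_draws = 1e4, iterations = 1000,
                         replicate_levels = c(10, 15, 20, 25, 30, 35, 40),
                         alpha_per_test = 0.05 / length(variables),
                         var_equal = TRUE, seed = 1L) {
  stopifnot(length(variables) >= 1, all(replicate_levels >= 2),
            all(replicate_levels <= n_draws),
            alpha_per_test > 0, alpha_per_test < 1)
  for (v in variables)
    stopifnot(inherits(v$group1, "group_spec"), inherits(v$group2, "group_spec"))
  structure(list(variables = variables, n_draws = n_draws,
                 iterations = iterations, replicate_levels = replicate_levels,
                 alpha_per_test = alpha_per_test, var_equal = var_equal,
                 seed = as.integer(seed)),
            class = "power_config")
}

# two-sample t-test p-values on column-paired matrices (n x iterations)
t_test_cols <- function(x, y, var_equal = TRUE) {
  n1 <- nrow(x); n2 <- nrow(y)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- (colSums(x^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(y^2) - n2 * m2^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  2 * stats::pt(-abs(tt), df)
}

#' Detection rate of a simulated screening experiment
#'
#' For each replicate level and iteration, draws `n` replicates per group
#' without replacement from the truncated-normal pools of every variable and
#' runs a two-sample Student's t-test per variable. An iteration detects the
#' plant-line effect when any variable's p-value falls below
#' `alpha_per_test`. The detection rate is the percentage of detecting
#' iterations.
#'
#' @param config a [power_config()].
#' @return object of class `power_result`: data frame `rates` (per level:
#'   `detection_rate` %, Monte Carlo standard error `mc_se`, and one marginal
#'   rate column per variable), plus the config.
#' @export
detection_rate <- function(config) {
  stopifnot(inherits(config, "power_config"))
  set.seed(config$seed)
  nv <- length(config$variables)
  pools <- lapply(config$variables, function(v)
    list(g1 = simulate_group(v$group1, config$n_draws),
         g2 = simulate_group(v$group2, config$n_draws)))
  vnames <- vapply(seq_len(nv), function(i) {
    nm <- config$variables[[i]]$name
    if (is.null(nm)) paste0("var", i) else nm
  }, character(1))

  rows <- lapply(config$replicate_levels, function(n) {
    p <- matrix(NA_real_, config$iterations, nv)
    for (j in seq_len(nv)) {
      i1 <- vapply(seq_len(config$iterations),
                   function(k) sample.int(config$n_draws, n), integer(n))
      i2 <- vapply(seq_len(config$iterations),
                   function(k) sample.int(config$n_draws, n), integer(n))
      x <- matrix(pools[[j]]$g1[i1], n)
      y <- matrix(pools[[j]]$g2[i2], n)
      p[, j] <- t_test_cols(x, y, config$var_equal)
    }
    sig <- rowSums(p < config$alpha_per_test) > 0
    rate <- 100 * mean(sig)
    marg <- 100 * colMeans(p < config$alpha_per_test)
    out <- data.frame(n = n, detection_rate = rate,
                      mc_se = 100 * sqrt(mean(sig) * (1 - mean(sig)) /
                                           config$iterations))
    out[paste0("rate_", vnames)] <- as.list(marg)
    out
  })
  structure(list(rates = do.call(rbind, rows), config = config),
            class = "power_result")
}

#' Type-I error rate under the null
#'
#' Runs the same machinery with both groups drawn from one shared pool per
#' variable (built from `group1`), so any detection is a false positive.
#' Within an iteration the two groups are disjoint subsamples of the pool.
#'
#' @param config a [power_config()]; `group2` specs are ignored.
#' @return a `power_result` whose `detection_rate` column estimates the
#'   family-wise type-I error (%).
#' @export
type1_rate <- function(config) {
  stopifnot(inherits(config, "power_config"))
  set.seed(config$seed)
  nv <- length(config$variables)
  pools <- lapply(config$variables, function(v)
    simulate_group(v$group1, config$n_draws))

  rows <- lapply(config$replicate_levels, function(n) {
    p <- matrix(NA_real_, config$iterations, nv)
    for (j in seq_len(nv)) {
      idx <- vapply(seq_len(config$iterations),
                    function(k) sample.int(config$n_draws, 2 * n), integer(2 * n))
      x <- matrix(pools[[j]][idx[seq_len(n), ]], n)
      y <- matrix(pools[[j]][idx[n + seq_len(n), ]], n)
      p[, j] <- t_test_cols(x, y, config$var_equal)
    }
    sig <- rowSums(p < config$alpha_per_test) > 0
    data.frame(n = n, detection_rate = 100 * mean(sig),
               mc_se = 100 * sqrt(mean(sig) * (1 - mean(sig)) /
                                    config$iterations))
  })
  structure(list(rates = do.call(rbind, rows), config = config),
            class = "power_result")
}

#' Rescale a group specification to a shorter recording
#'
#' Emulates truncating the recording: under the default policy the mean, SD
#' and upper bound scale by `target_duration / source_duration`; the lower
#' bound (a probe-category minimum) is kept. The policy is pluggable for
#' sensitivity analysis.
#'
#' @param spec a [group_spec()].
#' @param target_duration,source_duration recording durations (min).
#' @param policy function `(spec, ratio) -> group_spec`; default as above.
#' @return a rescaled [group_spec()].
#' @export
duration_rescale <- function(spec, target_duration, source_duration = 480,
                             policy = NULL) {
  stopifnot(inherits(spec, "group_spec"), target_duration <= source_duration)
  ratio <- target_duration / source_duration
  if (is.null(policy))
    policy <- function(s, r)
      group_spec(mean = s$mean * r, sd = s$sd * r, lower = s$lower,
                 upper = s$upper * r, label = s$label)
  policy(spec, ratio)
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power simulation: %d variable(s), alpha = %g per test, %d iterations\n",
              length(x$config$variables), x$config$alpha_per_test,
              x$config$iterations))
  print(x$rates, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.power_result <- function(x, ...) {
  graphics::plot(x$rates$n, x$rates$detection_rate, type = "b", ylim = c(0, 100),
                 xlab = "replicates per group", ylab = "detection rate (%)", ...)
  graphics::abline(h = 80, lty = 2)
  invisible(x)
}

#' Published screening presets
#'
#' Variable pairs for the two case studies, parameterised from the printed
#' video-tracking group means and standard errors (SD derived as
#' `se * sqrt(n)`): the Arabidopsis contrast (accessions Co-2, resistant,
#' vs Sanna-2, susceptible; *M. persicae*) and the lettuce contrast
#' (cultivars Corbana, resistant, vs Terlana, susceptible; *N. ribisnigri*).
#' Both use the two probing variables of an 8-h recording: mean duration of
#' long probes (>= 25 min; bounds 25–480 min) and total duration of sustained
#' probes (> 35 min; bounds 0–480 min).
#'
#' @return list of two variables, each with `name`, `group1` (resistant) and
#'   `group2` (susceptible) [group_spec()]s.
#' @export
arabidopsis_video_specs <- function() {
  list(
    list(name = "mean_long_probe_dur",
         group1 = group_spec(62.8, se = 7.0, n = 20, lower = 25, upper = 480,
                             label = "Co-2"),
         group2 = group_spec(90.0, se = 9.8, n = 17, lower = 25, upper = 480,
                             label = "Sanna-2")),
    list(name = "total_sustained_dur",
         group1 = group_spec(276, se = 27, n = 20, lower = 0, upper = 480,
                             label = "Co-2"),
         group2 = group_spec(353, se = 19, n = 17, lower = 0, upper = 480,
                             label = "Sanna-2")))
}

#' @rdname arabidopsis_video_specs
#' @export
lettuce_video_specs <- function() {
  list(
    list(name = "mean_long_probe_dur",
         group1 = group_spec(72.4, se = 9.5, n = 21, lower = 25, upper = 480,
                             label = "Corbana"),
         group2 = group_spec(99.8, se = 11.2, n = 26, lower = 25, upper = 480,
                             label = "Terlana")),
    list(name = "total_sustained_dur",
         group1 = group_spec(132, se = 24, n = 27, lower = 0, upper = 480,
                             label = "Corbana"),
         group2 = group_spec(260, se = 25, n = 28, lower = 0, upper = 480,
                             label = "Terlana")))
}
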