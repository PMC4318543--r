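#' Match automated against manual probe annotations
#'
#' Two probes match when their intervals overlap at least partially
#' (intersection length strictly positive; touching endpoints do not match).
#' Each manual probe is `detected` when at least one automated probe overlaps
#' it, and `overrated` when two or more do (one true probe split by the
#' software). An automated probe overlapping two or more manual probes marks
#' those manual probes `underrated` (several true probes merged into one).
#' Start/stop/duration offsets (automated minus manual, s) are computed per
#' detected manual probe against the overlapping automated probe whose
#' duration is closest to the manual one (ties broken by earlier start).
#'
#' @param auto automated probe [event_stream()] (only `probe` intervals used).
#' @param manual manual reference probe [event_stream()].
#' @return An object of class `match_report`: list with data frames `manual`
#'   (status, multiplicity, underrated flag, offsets) and `auto` (status),
#'   plus counts `n_redundant` (extra automated probes on overrated manual
#'   probes) and `n_missed` (extra manual probes on underrating automated
#'   probes).
#' @export
match_events <- function(auto, manual) {
  a <- events_of(auto, "probe")
  m <- events_of(manual, "probe")
  na <- nrow(a); nm <- nrow(m)
  ov <- matrix(FALSE, nm, na)
  if (nm && na)
    for (i in seq_len(nm))
      ov[i, ] <- pmin(m$stop[i], a$stop) - pmax(m$start[i], a$start) > 0

  mult <- if (na) rowSums(ov) else rep(0L, nm)
  a_hits <- if (nm) colSums(ov) else rep(0L, na)

  man <- data.frame(start = m$start, stop = m$stop,
                    status = ifelse(mult >= 1, "detected", "undetected"),
                    multiplicity = mult,
                    underrated = if (na) apply(ov, 1, function(r) any(a_hits[r] >= 2))
                                 else rep(FALSE, nm),
                    start_offset = NA_real_, stop_offset = NA_real_,
                    duration_offset = NA_real_)
  for (i in which(mult >= 1)) {
    js <- which(ov[i, ])
    dm <- m$stop[i] - m$start[i]
    da <- a$stop[js] - a$start[js]
    j <- js[order(abs(da - dm), a$start[js])][1]
    man$start_offset[i] <- a$start[j] - m$start[i]
    man$stop_offset[i] <- a$stop[j] - m$stop[i]
    man$duration_offset[i] <- (a$stop[j] - a$start[j]) - dm
  }
  aut <- data.frame(start = a$start, stop = a$stop,
                    status = ifelse(a_hits >= 1, "matched", "false_positive"),
                    n_manual = a_hits)
  structure(list(manual = man, auto = aut,
                 n_redundant = sum(pmax(0, mult - 1)),
                 n_missed = sum(pmax(0, a_hits - 1))),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("Match report: %d manual probes (%d detected), %d automated (%d false positive)\n",
              nrow(x$manual), sum(x$manual$status == "detected"),
              nrow(x$auto), sum(x$auto$status == "false_positive")))
  cat(sprintf("  overrated manual probes: %d (redundant automated probes: %d); underrated: %d\n",
              sum(x$manual$multiplicity >= 2), x$n_redundant,
              sum(x$manual$underrated)))
  invisible(x)
}

#' Aggregate accuracy over matched observations
#'
#' Pools a list of match reports into the headline accuracy figures: the
#' percentage of manually scored probes detected by the software, counts of
#' undetected / false-positive / underrated / overrated probes, mean probe
#' duration per class, and mean start/stop/duration offsets with t-based 95%
#' confidence intervals.
#'
#' @param reports list of [match_events()] results.
#' @param conf confidence level for the offset intervals.
#' @return list with `n_manual`, `n_auto`, `pct_detected`, class counts, a
#'   data frame `offsets` (mean, lo, hi per offset type) and `mean_duration`
#'   per class (min).
#' @export
accuracy_summary <- function(reports, conf = 0.95) {
  if (!length(reports)) stop("no match reports supplied")
  man <- do.call(rbind, lapply(reports, `[[`, "manual"))
  aut <- do.call(rbind, lapply(reports, `[[`, "auto"))
  ci <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(mean = NA, lo = NA, hi = NA))
    mu <- mean(v)
    if (length(v) < 2 || stats::sd(v) == 0) return(c(mean = mu, lo = mu, hi = mu))
    hw <- stats::qt(1 - (1 - conf) / 2, length(v) - 1) * stats::sd(v) / sqrt(length(v))
    c(mean = mu, lo = mu - hw, hi = mu + hw)
  }
  offs <- rbind(start = ci(man$start_offset), stop = ci(man$stop_offset),
                duration = ci(man$duration_offset))
  mdur <- function(f) if (any(f)) mean((man$stop - man$start)[f]) / 60 else NA_real_
  list(n_manual = nrow(man), n_auto = nrow(aut),
       pct_detected = 100 * mean(man$status == "detected"),
       n_undetected = sum(man$status == "undetected"),
       n_false_positive = sum(aut$status == "false_positive"),
       n_underrated = sum(man$underrated),
       n_overrated = sum(man$multiplicity >= 2),
       offsets = as.data.frame(offs),
       mean_duration_min = c(detected = mdur(man$status == "detected"),
                             undetected = mdur(man$status == "undetected")))
}

#' Correlate automated and manual summary variables
#'
#' For each requested variable pair, tests the correlation between the
#' automated and the manual value across observations. Normality of both
#' vectors is checked with a Shapiro test; if both pass, a Pearson test is
#' used (`Pe`); otherwise, if both pass after log transform, Pearson on logs
#' (`Pl`); otherwise Spearman (`S`).
#'
#' @param auto,manual data frames with one row per observation (paired).
#' @param variables character vector of shared column names to correlate;
#'   default: all shared numeric columns.
#' @param alpha significance level of the Shapiro normality screen.
#' @return data frame with `variable`, `test` ("Pe"/"Pl"/"S"), `r2`,
#'   `p_value`, `n`, `degenerate` (TRUE when a vector is constant and the
#'   correlation is undefined).
#' @export
correlate_summaries <- function(auto, manual, variables = NULL, alpha = 0.05) {
  if (is.null(variables)) {
    shared <- intersect(names(auto), names(manual))
    variables <- shared[vapply(shared, function(v)
      is.numeric(auto[[v]]) && is.numeric(manual[[v]]), logical(1))]
  }
  if (nrow(auto) != nrow(manual)) stop("auto and manual must be paired")
  out <- lapply(variables, function(v) {
    x <- auto[[v]]; y <- manual[[v]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("fewer than 3 complete pairs for ", v)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(variable = v, test = NA_character_, r2 = NA_real_,
                        p_value = NA_real_, n = length(x), degenerate = TRUE))
    normal <- function(z) length(unique(z)) > 2 &&
      stats::shapiro.test(z)$p.value > alpha
    if (normal(x) && normal(y)) {
      ct <- stats::cor.test(x, y, method = "pearson"); test <- "Pe"
    } else if (all(x > 0) && all(y > 0) && normal(log(x)) && normal(log(y))) {
      ct <- stats::cor.test(log(x), log(y), method = "pearson"); test <- "Pl"
    } else {
      ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE); test <- "S"
    }
    data.frame(variable = v, test = test, r2 = unname(ct$estimate^2),
               p_value = ct$p.value, n = length(x), degenerate = FALSE)
  })
  do.call(rbind, out)
}
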