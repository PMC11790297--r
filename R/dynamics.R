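# recovery model: v(t) = baseline + (s0 - baseline) * 2^(-t/halfLife)
recoveryModel <- function(p, t) p[3] + (p[1] - p[3]) * 2^(-t / p[2])

recoveryFitCore <- function(t, v) {
  stopIfNot(length(t) >= 4, "need at least 4 points in the fitted segment")
  b0 <- min(v)
  a0 <- v[1] - b0
  # half-life init from the time the excess halves (fallback: span / 3)
  hl0 <- {
    below <- which((v - b0) <= a0 / 2)
    if (a0 > 0 && length(below)) max(t[below[1]], 20) else max(t) / 3
  }
  init <- c(v[1], min(max(hl0, 11), 9999), b0)
  resid <- function(p) v - recoveryModel(p, t)
  fit <- nls.lm(par = init, lower = c(-Inf, 10, -Inf),
                upper = c(Inf, 1e4, Inf), fn = resid,
                control = nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  p <- fit$par
  rss <- sum(fit$fvec^2)
  flags <- character()
  scale <- max(abs(v), 1e-12)
  if (abs(p[1] - p[3]) <= 1e-6 * scale) flags <- c(flags, "degenerate")
  if (p[2] <= 10 * (1 + 1e-6) || p[2] >= 1e4 * (1 - 1e-6))
    flags <- c(flags, "at_bound")
  # 95% CI from the asymptotic covariance (J'J scaled by residual variance)
  ci <- NA_real_
  if (length(t) > 3) {
    s2 <- rss / (length(t) - 3)
    cov <- tryCatch(solve(fit$hessian) * s2, error = function(e) NULL)
    if (!is.null(cov) && is.finite(cov[2, 2]) && cov[2, 2] >= 0)
      ci <- 1.96 * sqrt(cov[2, 2])
  }
  new("RecoveryFit", s0Post = p[1], halfLife = p[2], baseline = p[3],
      ci95HalfLife = ci, rss = rss,
      converged = fit$info %in% c(1, 2, 3, 4) && !length(flags),
      flags = flags)
}

#' Fit post-exercise recovery kinetics
#'
#' Three-parameter exponential recovery fit
#' `v(t) = baseline + (s0 - baseline) * 2^(-t/halfLife)` by bounded
#' nonlinear least squares, with the half-life constrained to (10, 1e4) s
#' and its 95% confidence interval taken from the asymptotic covariance.
#' With `fromPeak = TRUE` (the default, appropriate for the sodium
#' amplitude which rises for ~8 min before recovering) the fit starts at the
#' series peak (located as in [timeToPeak()]) and time is re-zeroed there; a
#' pure decay model cannot represent the initial rise. Degenerate fits
#' (amplitude term ~ 0) and half-lives at a bound are flagged.
#'
#' @param series a [DynamicSeries-class]
#' @param fromPeak start the fitted segment at the series peak
#' @return a [RecoveryFit-class]
#' @examples
#' s <- makeDynamicSeries(subjectTruth("HV"),
#'                        AcquisitionTimeline(postExerciseSpan = 3600),
#'                        "na_amplitude")
#' fitRecovery(s)
#' @export
fitRecovery <- function(series, fromPeak = TRUE) {
  stopIfNot(is(series, "DynamicSeries"), "series must be a DynamicSeries")
  t <- timestamps(series)
  v <- values(series)
  if (fromPeak) {
    tp <- timeToPeak(series)
    keep <- t >= tp
    t <- t[keep] - t[keep][1]
    v <- v[keep]
  }
  recoveryFitCore(t, v)
}

#' Fit the post-exercise water-T2 decline
#'
#' Monoexponential decline fit for the muscle water T2 time course, which
#' peaks at the first post-exercise timepoint: the same three-parameter
#' model as [fitRecovery()] with the segment always starting (and time
#' re-zeroed) at the first timepoint.
#'
#' @param series a [DynamicSeries-class]
#' @return a [RecoveryFit-class]
#' @export
fitT2Decline <- function(series) {
  stopIfNot(is(series, "DynamicSeries"), "series must be a DynamicSeries")
  t <- timestamps(series)
  recoveryFitCore(t - t[1], values(series))
}

#' Locate the post-exercise peak
#'
#' Timestamp of the series maximum after 3-point moving-average smoothing
#' (window truncated at the ends); ties resolve to the earliest timepoint.
#'
#' @param series a [DynamicSeries-class]
#' @return peak time, s
#' @export
timeToPeak <- function(series) {
  stopIfNot(is(series, "DynamicSeries"), "series must be a DynamicSeries")
  v <- values(series)
  n <- length(v)
  sm <- vapply(seq_len(n), function(i)
    mean(v[max(1, i - 1):min(n, i + 1)]), 0)
  timestamps(series)[which.max(sm)]
}

#' Per-timepoint deviation from baseline
#'
#' Two-tailed Wilcoxon signed-rank test of (value - subject baseline) at
#' each common timepoint across a cohort's series: exact null distribution
#' for n <= 25 with no ties or zeros, normal approximation with continuity
#' correction otherwise. All-zero differences give p = 1, flagged.
#'
#' @param seriesList list of [DynamicSeries-class], one per subject, sharing
#'   the acquisition cadence
#' @param alpha two-tailed significance level
#' @return data.frame with columns `timepoint`, `statistic`, `p_value`,
#'   `significant`, `flag`
#' @export
compareToBaseline <- function(seriesList, alpha = 0.05) {
  stopIfNot(length(seriesList) >= 5, "need at least 5 subjects")
  ts <- lapply(seriesList, timestamps)
  stopIfNot(all(vapply(ts, function(x)
    isTRUE(all.equal(x, ts[[1]])), TRUE)),
    "all subjects must share the acquisition timeline")
  diffs <- vapply(seriesList, function(s) values(s) - baselineValue(s),
                  numeric(length(ts[[1]])))
  out <- lapply(seq_along(ts[[1]]), function(i) {
    d <- diffs[i, ]
    if (all(d == 0))
      return(data.frame(timepoint = ts[[1]][i], statistic = NA_real_,
                        p_value = 1, significant = FALSE,
                        flag = "all_zero"))
    wt <- suppressWarnings(
      stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                         exact = length(d) <= 25, correct = TRUE))
    data.frame(timepoint = ts[[1]][i], statistic = unname(wt$statistic),
               p_value = wt$p.value, significant = wt$p.value < alpha,
               flag = "")
  })
  do.call(rbind, out)
}

#' Group-mean dynamic curve on a common grid
#'
#' Per-subject linear interpolation onto a shared time grid followed by
#' pointwise averaging, for cohorts whose cadences differ.
#'
#' @param seriesList list of [DynamicSeries-class]
#' @param grid time grid, s; defaults to the union range at the median
#'   cadence
#' @return a [DynamicSeries-class] holding the group mean (baseline = mean
#'   of subject baselines)
#' @export
groupMeanSeries <- function(seriesList, grid = NULL) {
  stopIfNot(length(seriesList) >= 1, "need at least one series")
  if (is.null(grid)) {
    lo <- max(vapply(seriesList, function(s) min(timestamps(s)), 0))
    hi <- min(vapply(seriesList, function(s) max(timestamps(s)), 0))
    npt <- round(stats::median(vapply(seriesList,
                                      function(s) length(timestamps(s)), 0)))
    grid <- seq(lo, hi, length.out = max(npt, 4))
  }
  vals <- vapply(seriesList, function(s)
    stats::approx(timestamps(s), values(s), xout = grid)$y,
    numeric(length(grid)))
  DynamicSeries(grid, rowMeans(vals), modality = modality(seriesList[[1]]),
                baselineValue = mean(vapply(seriesList, baselineValue, 0)),
                subject = "group_mean", group = seriesList[[1]]@group)
}
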