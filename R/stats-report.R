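#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples: the exact null
#' distribution is used when the smaller group has at most `exactMax`
#' observations and there are no ties, otherwise the normal approximation
#' with tie correction and continuity correction. Both the exact (where
#' computable) and the asymptotic p-value are reported.
#'
#' @param x,y numeric samples (>= 3 each)
#' @param variable label carried through to the output
#' @param exactMax largest min-group size for which the exact distribution
#'   is used
#' @return data.frame with group means/SDs, the U statistic, `p_two_tailed`
#'   (the value selected by the exact rule), `p_exact`, `p_asymptotic` and a
#'   `flag` column
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mannWhitney <- function(x, y, variable = "variable", exactMax = 8) {
  stopIfNot(length(x) >= 3 && length(y) >= 3,
            "need at least 3 observations per group")
  flag <- ""
  if (length(unique(c(x, y))) == 1L) {
    return(data.frame(variable = variable, mean_x = mean(x),
                      sd_x = stats::sd(x), mean_y = mean(y),
                      sd_y = stats::sd(y),
                      u = length(x) * length(y) / 2, p_two_tailed = 1,
                      p_exact = NA_real_, p_asymptotic = 1,
                      flag = "all_identical"))
  }
  ties <- any(duplicated(c(x, y)))
  useExact <- min(length(x), length(y)) <= exactMax && !ties
  pEx <- if (!ties)
    suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
  else NA_real_
  wAs <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  u <- unname(suppressWarnings(stats::wilcox.test(x, y,
                                                  exact = FALSE)$statistic))
  data.frame(variable = variable, mean_x = mean(x), sd_x = stats::sd(x),
             mean_y = mean(y), sd_y = stats::sd(y), u = u,
             p_two_tailed = if (useExact) pEx else wAs$p.value,
             p_exact = pEx, p_asymptotic = wAs$p.value, flag = flag)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-distribution approximation. Constant input is flagged (undefined
#' correlation).
#'
#' @param x,y paired samples (n >= 4)
#' @return data.frame with `r_s`, `p`, `n`, `flag`
#' @examples
#' spearmanCorrelation(1:4, c(2, 1, 4, 3))
#' @export
spearmanCorrelation <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must be paired")
  stopIfNot(length(x) >= 4, "need at least 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(r_s = NA_real_, p = NA_real_, n = length(x),
                      flag = "constant_input"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  data.frame(r_s = unname(ct$estimate), p = ct$p.value, n = length(x),
             flag = "")
}

#' Cohort summary table
#'
#' Per-variable group means, SDs, two-tailed Mann-Whitney p-values, and the
#' percent group difference `round(100 (mean_DP - mean_HV) / mean_HV)`.
#' Variables missing from either group are listed in the `missing`
#' attribute rather than silently dropped.
#'
#' @param results data.frame with one row per subject, a `group` column
#'   (`"HV"`/`"DP"`) and one numeric column per variable
#' @param variables variables to summarise; default all numeric columns
#' @return data.frame with columns `variable`, `mean_hv`, `sd_hv`,
#'   `mean_dp`, `sd_dp`, `percent_difference`, `u`, `p_two_tailed`,
#'   `p_exact`, `p_asymptotic`
#' @export
buildSummary <- function(results, variables = NULL) {
  stopIfNot(is.data.frame(results) && "group" %in% names(results),
            "results must be a data.frame with a 'group' column")
  stopIfNot(all(c("HV", "DP") %in% results$group),
            "need per-subject results for both groups")
  if (is.null(variables))
    variables <- setdiff(names(results)[vapply(results, is.numeric, TRUE)],
                         "group")
  missing <- character()
  rows <- list()
  for (v in variables) {
    if (!v %in% names(results)) { missing <- c(missing, v); next }
    hv <- results[[v]][results$group == "HV"]
    dp <- results[[v]][results$group == "DP"]
    hv <- hv[!is.na(hv)]; dp <- dp[!is.na(dp)]
    if (!length(hv) || !length(dp)) { missing <- c(missing, v); next }
    mw <- mannWhitney(dp, hv, variable = v)
    rows[[v]] <- data.frame(
      variable = v, mean_hv = mean(hv), sd_hv = stats::sd(hv),
      mean_dp = mean(dp), sd_dp = stats::sd(dp),
      percent_difference = round(100 * (mean(dp) - mean(hv)) / mean(hv)),
      u = mw$u, p_two_tailed = mw$p_two_tailed, p_exact = mw$p_exact,
      p_asymptotic = mw$p_asymptotic)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "missing") <- missing
  out
}
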