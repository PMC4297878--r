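#' Labeled-cell fraction with Wilson 95% confidence interval
#'
#' @param positive number of labeled cells.
#' @param total number of cells scored (> 0, >= positive).
#' @param decimals decimals the percent is rounded to (round-half-to-even).
#' @return list with `percent`, `lower`, `upper` (Wilson score interval at
#'   z = 1.96, as percentages), `positive`, `total`.
#' @export
labeled_fraction <- function(positive, total, decimals = 0) {
  if (total <= 0) stop("total must be positive")
  if (positive < 0 || positive > total)
    stop("positive must be in [0, total]")
  p <- positive / total
  z <- 1.96
  denom <- 1 + z^2 / total
  center <- (p + z^2 / (2 * total)) / denom
  half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / denom
  list(percent = round(100 * p, decimals),
       lower = max(0, 100 * (center - half)),
       upper = min(100, 100 * (center + half)),
       positive = positive, total = total)
}

#' Population composition in whole percents
#'
#' @param category_counts non-negative counts (optionally named), sum > 0.
#' @return named numeric vector of percentages rounded to whole percent;
#'   rounded values may not sum to exactly 100 and are reported as-is.
#' @export
composition <- function(category_counts) {
  if (any(category_counts < 0)) stop("counts must be non-negative")
  if (sum(category_counts) == 0) stop("all counts are zero")
  round(100 * category_counts / sum(category_counts))
}

#' Transcript-fraction partitioning
#'
#' Percent of the summed level attributable to each component (e.g.
#' endogenous vs viral transcript of the same gene measured in a common
#' unit), to one decimal.
#'
#' @param component_levels non-negative levels, sum > 0.
#' @return named numeric vector of percentages (one decimal).
#' @export
transcript_fractions <- function(component_levels) {
  if (any(component_levels < 0)) stop("levels must be non-negative")
  if (sum(component_levels) == 0) stop("zero total level")
  round(100 * component_levels / sum(component_levels), 1)
}

#' Doubling time from a cumulative growth series
#'
#' Least-squares slope `b` of `log2(count)` against time; doubling time is
#' `1 / b` hours. Non-growing series (slope <= 0) return `NA`.
#'
#' @param series data frame with `time_hr` (strictly increasing) and `count`
#'   (> 0), or two separate vectors via `time_hr` and `count`.
#' @param time_hr,count alternative vector interface.
#' @return doubling time in hours, or `NA_real_` if the fit is non-growing.
#' @export
doubling_time <- function(series = NULL, time_hr = series$time_hr,
                          count = series$count) {
  if (length(time_hr) < 2) stop("need >= 2 timepoints")
  if (any(diff(time_hr) <= 0)) stop("timepoints must be strictly increasing")
  if (any(count <= 0)) stop("counts must be positive")
  b <- coef(lm(log2(count) ~ time_hr))[["time_hr"]]
  if (b <= 1e-10) return(NA_real_)  # flat or shrinking: no doubling time
  1 / b
}
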