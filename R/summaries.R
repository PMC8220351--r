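# Survey-weighted cross-sectional summaries of health and social care
# utilisation by CFS category.

#' Survey-weighted mean with a normal-approximation confidence interval
#'
#' Point estimate `sum(w * x) / sum(w)` with a design-based standard error
#' from the standard ratio-estimator linearisation,
#' `SE^2 = sum(w_i^2 (x_i - xbar_w)^2) / (sum w_i)^2`, and a symmetric
#' z-interval. For a 0/1 indicator this is a weighted proportion.
#'
#' @param x Numeric values.
#' @param w Non-negative weights, same length as `x`.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `se`, `ci_low`, `ci_high`, `n` (unweighted).
#' @export
#' @examples
#' weighted_mean_ci(c(3, 99), c(1, 0))$estimate  # zero-weight exclusion
weighted_mean_ci <- function(x, w, conf = 0.95) {
  if (length(x) != length(w))
    stop("values and weights must have the same length", call. = FALSE)
  keep <- !is.na(x) & !is.na(w)
  x <- x[keep]; w <- w[keep]
  if (length(x) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(w) <= 0) stop("total weight must be positive", call. = FALSE)
  m <- sum(w * x) / sum(w)
  se <- sqrt(sum(w^2 * (x - m)^2)) / sum(w)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(estimate = m, se = se, ci_low = m - z * se, ci_high = m + z * se,
       n = length(x))
}

#' Count of community services received
#'
#' Number of `TRUE` flags among the 13 community-based allied healthcare
#' service indicators (see [cfs_services()]).
#'
#' @param flags Logical vector of length 13, or a matrix/data frame with 13
#'   columns (one row per respondent).
#' @return Integer count(s) in 0-13.
#' @export
services_count <- function(flags) {
  if (is.data.frame(flags)) flags <- as.matrix(flags)
  if (is.matrix(flags)) {
    if (ncol(flags) != 13L)
      stop("expected 13 service flags, got ", ncol(flags), call. = FALSE)
    return(as.integer(rowSums(flags)))
  }
  if (length(flags) != 13L)
    stop("expected 13 service flags, got ", length(flags), call. = FALSE)
  as.integer(sum(flags))
}

#' Monthly care hours from hours/day and days/month
#'
#' Hours of care per month for one provider type; totals across provider
#' types are sums of per-provider products.
#'
#' @param hours_per_day Non-negative numeric (at most 24).
#' @param days_per_month Numeric in `[0, 31]`.
#' @return `hours_per_day * days_per_month`, vectorised.
#' @export
#' @examples
#' monthly_care_hours(2, 10)  # 20 hours/month
monthly_care_hours <- function(hours_per_day, days_per_month) {
  if (any(hours_per_day < 0 | hours_per_day > 24, na.rm = TRUE))
    stop("hours_per_day must lie in [0, 24]", call. = FALSE)
  if (any(days_per_month < 0 | days_per_month > 31, na.rm = TRUE))
    stop("days_per_month must lie in [0, 31]", call. = FALSE)
  hours_per_day * days_per_month
}

#' Fold change between the highest and lowest CFS categories
#'
#' Ratio of the highest-category mean to the lowest-category mean of a
#' utilisation variable (by default CFS7 over CFS1).
#'
#' @param means Numeric vector of per-category means, named `"CFS1"` ...
#'   `"CFS7"` (or positionally indexed 1-7 when unnamed).
#' @param low,high Names (or indices) of the lowest and highest categories.
#' @return The ratio `means[high] / means[low]`.
#' @export
#' @examples
#' fold_change(c(CFS1 = 0.1, CFS2 = 0.2, CFS3 = 0.3, CFS4 = 0.4,
#'               CFS5 = 0.6, CFS6 = 0.8, CFS7 = 0.9))  # 9
fold_change <- function(means, low = "CFS1", high = "CFS7") {
  if (is.null(names(means))) names(means) <- paste0("CFS", seq_along(means))
  if (!low %in% names(means) || is.na(means[[low]]))
    stop("lowest-category mean ('", low, "') is absent", call. = FALSE)
  if (!high %in% names(means) || is.na(means[[high]]))
    stop("highest-category mean ('", high, "') is absent", call. = FALSE)
  if (means[[low]] == 0)
    stop("lowest-category mean is zero; fold change undefined", call. = FALSE)
  unname(means[[high]] / means[[low]])
}

#' Survey-weighted utilisation summaries by CFS category
#'
#' Computes, for each CFS category present at a wave, the weighted mean (with
#' design-based 95% CI) of one or more utilisation variables over respondents
#' observed at that wave. Two derived variables are available in addition to
#' panel columns: `services_total` (count of the 13 service flags) and
#' `<provider>_monthly_hours` for providers `informal`, `paid`, `formal`.
#'
#' @param panel Cohort panel.
#' @param variables Character vector of variable names.
#' @param wave Wave index to summarise (default: the last wave).
#' @param conf Confidence level.
#' @return Tidy data frame: `variable`, `cfs_category`, `estimate`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
utilisation_summary <- function(panel, variables,
                                wave = max(panel$wave_index), conf = 0.95) {
  cross <- panel[panel$wave_index == wave & panel$status == "observed", ]
  svc_cols <- paste0("svc_", cfs_services())
  get_var <- function(df, v) {
    if (v %in% names(df)) return(as.numeric(df[[v]]))
    if (v == "services_total")
      return(as.numeric(services_count(df[, svc_cols])))
    prov <- sub("_monthly_hours$", "", v)
    if (grepl("_monthly_hours$", v) &&
        all(paste0(prov, c("_hours_day", "_days_month")) %in% names(df)))
      return(monthly_care_hours(df[[paste0(prov, "_hours_day")]],
                                df[[paste0(prov, "_days_month")]]))
    stop("unknown utilisation variable '", v, "'", call. = FALSE)
  }
  out <- NULL
  for (v in variables) {
    vals <- get_var(cross, v)
    for (k in sort(unique(cross$cfs_category))) {
      idx <- cross$cfs_category == k
      est <- weighted_mean_ci(vals[idx], cross$weight[idx], conf = conf)
      out <- rbind(out, data.frame(
        variable = v, cfs_category = paste0("CFS", k),
        estimate = est$estimate, ci_low = est$ci_low, ci_high = est$ci_high,
        n = est$n, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Survey-weighted prevalence of CFS categories and states
#'
#' Weighted proportion of respondents at a wave in each CFS category and in
#' each collapsed state, with design-based confidence intervals.
#'
#' @inheritParams utilisation_summary
#' @return Tidy data frame: `level` (`"category"`/`"state"`), `group`,
#'   `prevalence` (percent), `ci_low`, `ci_high`, `n`.
#' @export
prevalence_summary <- function(panel, wave = max(panel$wave_index),
                               conf = 0.95) {
  cross <- panel[panel$wave_index == wave & panel$status == "observed", ]
  out <- NULL
  add <- function(level, group, ind) {
    est <- weighted_mean_ci(as.numeric(ind), cross$weight, conf = conf)
    rbind(out, data.frame(
      level = level, group = group, prevalence = 100 * est$estimate,
      ci_low = 100 * est$ci_low, ci_high = 100 * est$ci_high,
      n = sum(ind), stringsAsFactors = FALSE))
  }
  for (k in sort(unique(cross$cfs_category)))
    out <- add("category", paste0("CFS", k), cross$cfs_category == k)
  for (s in c("fit", "vulnerable", "frail"))
    out <- add("state", s, cross$cfs_state == s)
  rownames(out) <- NULL
  out
}
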