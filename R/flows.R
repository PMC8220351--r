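# Wave-to-wave flow counts between CFS categories or collapsed states --
# the numerical content of alluvial transition charts.

#' Tabulate wave-to-wave flows
#'
#' Counts, for each consecutive wave pair, how many subjects move from each
#' source label to each destination label. Labels are the CFS categories
#' (`CFS1`...`CFS9`) or the collapsed states (`fit`/`vulnerable`/`frail`),
#' plus `died` and `missing`. A subject without a record at a wave counts as
#' `missing` at that wave, so every wave boundary conserves the cohort.
#'
#' @param panel Cohort panel (see [simulate_cohort()]).
#' @param level `"state"` (collapse categories first) or `"category"`.
#' @return Data frame of class `"flow_table"` with columns `wave_from`,
#'   `wave_to`, `source`, `destination`, `count` (only non-zero flows), and
#'   an attribute `"wave_totals"` holding per-wave label counts.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 50, seed = 1, include_items = FALSE,
#'                   include_utilisation = FALSE)
#' head(flow_table(simulate_cohort(cfg)))
flow_table <- function(panel, level = c("state", "category")) {
  level <- match.arg(level)
  waves <- sort(unique(panel$wave_index))
  subjects <- sort(unique(panel$subject_id))
  lab <- matrix("missing", length(subjects), length(waves),
                dimnames = list(NULL, as.character(waves)))
  i <- match(panel$subject_id, subjects)
  j <- match(panel$wave_index, waves)
  lab[cbind(i, j)] <- ifelse(
    panel$status == "observed",
    if (level == "category") paste0("CFS", panel$cfs_category)
    else panel$cfs_state,
    panel$status
  )
  # died is absorbing in the labelling: propagate forward
  if (length(waves) > 1L) for (w in 2:length(waves))
    lab[lab[, w - 1L] == "died", w] <- "died"

  out <- NULL
  for (w in seq_len(length(waves) - 1L)) {
    tab <- table(source = lab[, w], destination = lab[, w + 1L])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    out <- rbind(out, data.frame(
      wave_from = waves[w], wave_to = waves[w + 1L],
      source = df$source, destination = df$destination,
      count = as.integer(df$Freq), stringsAsFactors = FALSE))
  }
  totals <- NULL
  for (w in seq_along(waves)) {
    tb <- table(lab[, w])
    totals <- rbind(totals, data.frame(
      wave_index = waves[w], label = names(tb), n = as.integer(tb),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "wave_totals") <- totals
  class(out) <- c("flow_table", "data.frame")
  out
}

#' Write a flow table as tidy CSV
#'
#' @param flows A [flow_table()] result.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_flow_table <- function(flows, path) {
  utils::write.csv(as.data.frame(flows), path, row.names = FALSE)
  invisible(path)
}
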