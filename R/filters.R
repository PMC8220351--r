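# Ordered exclusion filters with a sample-accounting ledger, mirroring how
# analytical samples are reported (initial n, n removed at each step,
# n remaining).

#' Apply ordered exclusion filters and record a sample-accounting ledger
#'
#' Each filter is a pure predicate: a function of the data frame returning a
#' logical keep-vector (one entry per row). Filters are applied in order and
#' the ledger records, per step, how many rows were removed and how many
#' remain. Because predicates are pure, the final row set is independent of
#' filter order (only the ledger's intermediate counts change).
#'
#' @param data Data frame of subject records (one row per subject).
#' @param filters Named list of predicate functions; names describe the
#'   exclusion step.
#' @return List with `data` (the retained rows) and `ledger` (data frame
#'   `step`, `description`, `n_removed`, `n_remaining`; step 0 is the initial
#'   count).
#' @export
#' @examples
#' cohort <- data.frame(age = c(70, 60, 80), has_cfs = c(TRUE, TRUE, FALSE))
#' apply_filters(cohort, list(
#'   "aged under 65" = function(d) d$age >= 65,
#'   "no CFS data" = function(d) d$has_cfs
#' ))$ledger
apply_filters <- function(data, filters = list()) {
  stopifnot(is.data.frame(data))
  if (length(filters) && is.null(names(filters)))
    names(filters) <- paste("filter", seq_along(filters))
  ledger <- data.frame(step = 0L, description = "initial sample",
                       n_removed = 0L, n_remaining = nrow(data),
                       stringsAsFactors = FALSE)
  for (i in seq_along(filters)) {
    keep <- filters[[i]](data)
    if (!is.logical(keep) || length(keep) != nrow(data) || anyNA(keep))
      stop("filter '", names(filters)[i],
           "' must return a complete logical keep-vector", call. = FALSE)
    removed <- sum(!keep)
    data <- data[keep, , drop = FALSE]
    ledger <- rbind(ledger, data.frame(
      step = i, description = names(filters)[i],
      n_removed = removed, n_remaining = nrow(data),
      stringsAsFactors = FALSE))
  }
  rownames(data) <- NULL
  list(data = data, ledger = ledger)
}
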