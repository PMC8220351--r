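# Questionnaire-derived items feeding the CFS classification tree.

#' Chronic and cardiovascular conditions counted for the CFS tree
#'
#' Returns the canonical names, in questionnaire order, of the 28 chronic and
#' cardiovascular conditions whose sum gives the `condition_count` item of the
#' CFS classification tree.
#'
#' @return Character vector of length 28.
#' @export
#' @examples
#' length(cfs_conditions())
cfs_conditions <- function() {
  c("hypertension", "angina", "heart_attack", "heart_failure", "diabetes",
    "stroke", "tia", "high_cholesterol", "heart_murmur", "abnormal_rhythm",
    "other_heart", "lung_disease", "asthma", "arthritis", "osteoporosis",
    "cancer", "parkinsons", "psychiatric", "alcohol_substance", "alzheimers",
    "dementia", "memory_impairment", "stomach_ulcers", "varicose_ulcers",
    "cirrhosis", "cataracts", "glaucoma", "macular_degeneration")
}

#' Canonical ordinal levels of the CFS tree items
#'
#' Self-rated health has five levels from best to worst; the effort item
#' ("everything I did was an effort" in the past week) has four frequency
#' levels from least to most frequent. Matching elsewhere in the package is
#' case-insensitive and accepts the full questionnaire phrasings as aliases
#' (e.g. "some or a little of the time" for `"some/little"`).
#'
#' @return Named list with components `self_rated_health` and
#'   `effort_frequency`, each a character vector ordered from lowest to
#'   highest rank.
#' @export
cfs_levels <- function() {
  list(
    self_rated_health = c("excellent", "very good", "good", "fair", "poor"),
    effort_frequency  = c("rarely/none", "some/little",
                          "occasionally/moderate", "all of the time")
  )
}

# Full questionnaire phrasings accepted as aliases for the short canonical
# effort labels.
.effort_aliases <- c(
  "rarely or none of the time"                = "rarely/none",
  "some or a little of the time"              = "some/little",
  "occasionally or a moderate amount of time" = "occasionally/moderate",
  "all of the time"                           = "all of the time"
)

# Canonicalise an ordinal value: case-insensitive, alias-aware.
# Returns the canonical label, or throws naming the offending value.
canonical_level <- function(x, item) {
  levels <- cfs_levels()[[item]]
  if (length(x) != 1L || is.na(x))
    stop("missing value for required item '", item, "'", call. = FALSE)
  key <- tolower(trimws(as.character(x)))
  hit <- match(key, tolower(levels))
  if (is.na(hit) && item == "effort_frequency") {
    alias <- match(key, tolower(names(.effort_aliases)))
    if (!is.na(alias)) hit <- match(.effort_aliases[[alias]], levels)
  }
  if (is.na(hit))
    stop("unknown level '", x, "' for item '", item, "'", call. = FALSE)
  levels[[hit]]
}

# Rank of an ordinal level (1 = lowest).
level_rank <- function(x, item) {
  match(canonical_level(x, item), cfs_levels()[[item]])
}

#' Construct and validate a CFS item vector
#'
#' The six inputs of the CFS classification tree for one participant-wave:
#' counts of basic and instrumental activities of daily living requiring help,
#' the chronic-condition count (0-28), self-rated health, the past-week effort
#' frequency, and whether the respondent was active (moderate or vigorous
#' activity on at least one day in the past week).
#'
#' @param badl_help_count,iadl_help_count Non-negative integer counts.
#' @param condition_count Integer in 0-28.
#' @param self_rated_health One of `cfs_levels()$self_rated_health`
#'   (case-insensitive).
#' @param effort_frequency One of `cfs_levels()$effort_frequency`
#'   (case-insensitive; full questionnaire phrasings accepted).
#' @param active_past_week Logical.
#' @return A one-row `data.frame` with the six canonical item columns.
#' @export
#' @examples
#' item_vector(0, 0, 2, "very good", "rarely/none", TRUE)
item_vector <- function(badl_help_count, iadl_help_count, condition_count,
                        self_rated_health, effort_frequency,
                        active_past_week) {
  chk_count <- function(x, name, max = Inf) {
    if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < 0 ||
        x != round(x) || x > max)
      stop("invalid value for item '", name, "': ", deparse(x), call. = FALSE)
    as.integer(x)
  }
  if (length(active_past_week) != 1L || is.na(active_past_week) ||
      !is.logical(active_past_week))
    stop("invalid value for item 'active_past_week'", call. = FALSE)
  data.frame(
    badl_help_count   = chk_count(badl_help_count, "badl_help_count"),
    iadl_help_count   = chk_count(iadl_help_count, "iadl_help_count"),
    condition_count   = chk_count(condition_count, "condition_count", 28L),
    self_rated_health = canonical_level(self_rated_health,
                                        "self_rated_health"),
    effort_frequency  = canonical_level(effort_frequency, "effort_frequency"),
    active_past_week  = active_past_week,
    stringsAsFactors  = FALSE
  )
}

#' Derive the six CFS tree items from raw questionnaire fields
#'
#' Sums per-activity and per-condition help/diagnosis flags into counts and
#' canonicalises the ordinal items. No imputation is performed: any missing
#' required field is an error.
#'
#' @param raw Named list or one-row data frame of raw questionnaire fields.
#' @param condition_items Names of the 28 condition flag fields, in
#'   questionnaire order. Defaults to `paste0("cond_", cfs_conditions())`.
#' @param badl_items,iadl_items Names of the basic / instrumental
#'   activities-of-daily-living help flag fields. The item lists are
#'   configurable; the defaults are the six Katz basic activities and the
#'   eight Lawton instrumental activities.
#' @param srh_field,effort_field,activity_field Field names of the self-rated
#'   health, effort-frequency and past-week activity items.
#' @return A one-row item-vector `data.frame` (see [item_vector()]).
#' @export
#' @examples
#' raw <- c(
#'   as.list(setNames(rep(FALSE, 28), paste0("cond_", cfs_conditions()))),
#'   as.list(setNames(rep(FALSE, 6), paste0("badl_", katz_badl()))),
#'   as.list(setNames(rep(FALSE, 8), paste0("iadl_", lawton_iadl()))),
#'   list(self_rated_health = "good", effort_frequency = "rarely/none",
#'        active_past_week = TRUE)
#' )
#' derive_item_vector(raw)
derive_item_vector <- function(raw,
                               condition_items = paste0("cond_",
                                                        cfs_conditions()),
                               badl_items = paste0("badl_", katz_badl()),
                               iadl_items = paste0("iadl_", lawton_iadl()),
                               srh_field = "self_rated_health",
                               effort_field = "effort_frequency",
                               activity_field = "active_past_week") {
  raw <- as.list(raw)
  if (length(condition_items) != 28L)
    stop("'condition_items' must name exactly 28 condition flags",
         call. = FALSE)
  flag_sum <- function(fields, what) {
    missing <- setdiff(fields, names(raw))
    if (length(missing))
      stop("missing required field(s) for ", what, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    vals <- vapply(raw[fields], function(v) {
      if (length(v) != 1L || is.na(v)) return(NA)
      if (is.logical(v)) return(v)
      if (is.numeric(v) && v %in% c(0, 1)) return(v == 1)
      NA
    }, logical(1))
    if (anyNA(vals))
      stop("non-boolean or missing flag value in ", what, ": ",
           paste(fields[is.na(vals)], collapse = ", "), call. = FALSE)
    sum(vals)
  }
  for (f in c(srh_field, effort_field, activity_field))
    if (!f %in% names(raw))
      stop("missing required field '", f, "'", call. = FALSE)
  item_vector(
    badl_help_count   = flag_sum(badl_items, "BADL items"),
    iadl_help_count   = flag_sum(iadl_items, "IADL items"),
    condition_count   = flag_sum(condition_items, "condition flags"),
    self_rated_health = raw[[srh_field]],
    effort_frequency  = raw[[effort_field]],
    active_past_week  = as.logical(raw[[activity_field]])
  )
}

#' Default basic / instrumental activities of daily living
#'
#' The BADL/IADL item lists are configurable in [derive_item_vector()]; only
#' the count semantics are fixed. These defaults follow the Katz basic and
#' Lawton instrumental activity sets.
#'
#' @return Character vector of activity names.
#' @export
katz_badl <- function() {
  c("bathing", "dressing", "toileting", "transferring", "continence",
    "feeding")
}

#' @rdname katz_badl
#' @export
lawton_iadl <- function() {
  c("telephone", "shopping", "preparing_meals", "housekeeping", "laundry",
    "transport", "medications", "finances")
}

#' Discretised domain of the CFS item vector
#'
#' The full cross-product of item values used for tree validation, preimage
#' enumeration and uniform item sampling. Counts are truncated at
#' configurable maxima (the ADL counts have no natural upper bound; the
#' condition count is capped at 28 by definition).
#'
#' @param badl_max,iadl_max Largest help counts enumerated.
#' @param condition_values Integer vector of condition counts enumerated
#'   (default `0:28`).
#' @return Data frame with one row per item-vector in the discretised domain.
#' @export
cfs_item_domain <- function(badl_max = 6L, iadl_max = 6L,
                            condition_values = 0:28) {
  lv <- cfs_levels()
  expand.grid(
    badl_help_count   = 0:badl_max,
    iadl_help_count   = 0:iadl_max,
    condition_count   = as.integer(condition_values),
    self_rated_health = lv$self_rated_health,
    effort_frequency  = lv$effort_frequency,
    active_past_week  = c(TRUE, FALSE),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
}
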