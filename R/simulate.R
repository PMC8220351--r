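# Synthetic cohort generator: a biennial multi-wave panel of adults aged 65+
# whose fit/vulnerable/frail/died dynamics follow a configured
# continuous-time generator, with wave-on-wave missingness, item vectors
# consistent with each assigned CFS category, and category-conditional
# utilisation variables. Everything downstream of the restricted study data
# is exercised against cohorts drawn from this module.

#' Published 2-year transition-probability matrix between frailty states
#'
#' The point estimates of the published 2-year fit/vulnerable/frail/died
#' transition matrix for community-dwelling adults aged 65 and over (rows may
#' not sum exactly to 1 because the published entries are rounded). Used as
#' the calibration input of the synthetic cohort generator via
#' [nearest_generator()].
#'
#' @return 4x4 numeric matrix with state dimnames.
#' @export
ref_transition_2yr <- function() {
  st <- msm_states()
  matrix(c(0.59, 0.34, 0.06, 0.02,
           0.22, 0.57, 0.16, 0.05,
           0.06, 0.17, 0.51, 0.25,
           0.00, 0.00, 0.00, 1.00),
         nrow = 4, byrow = TRUE, dimnames = list(st, st))
}

#' Published CFS category prevalence for adults aged 65 and over
#'
#' Percentage prevalence of CFS categories 1-7 in the community-dwelling
#' population aged 65+: the combined fit group (CFS1-3) is 73.6%, split
#' across CFS1-3 in the proportions 6:36:31; the vulnerable (CFS4) and frail
#' (CFS5-7) categories are 16%, 5.5%, 4.3% and 0.7%. Categories 8-9 were not
#' observed in community dwellers. The vector is returned as published (it
#' need not sum exactly to 100 because of rounding); normalise before using
#' it as a probability vector.
#'
#' @return Named numeric vector of length 7 (percent).
#' @export
ref_prevalence_wave5 <- function() {
  fit_split <- 73.6 * c(6, 36, 31) / 73
  stats::setNames(c(fit_split, 16, 5.5, 4.3, 0.7), paste0("CFS", 1:7))
}

#' Names of the 13 community-based allied healthcare services
#'
#' @return Character vector of length 13.
#' @export
cfs_services <- function() {
  c("physiotherapy", "ot", "phn", "dietician", "hearing", "dental",
    "optician", "counselling", "social_work", "speech_language", "chiropody",
    "day_centre", "respite")
}

#' Default category-conditional utilisation parameters
#'
#' Per-CFS-category distribution parameters of the utilisation variables the
#' generator draws: means of the five annual count variables (GP, outpatient
#' and ED visits, overnight admissions, hospital nights), Bernoulli
#' probabilities for the 13 community-service flags, and monthly-hour targets
#' for the three care provider types (unpaid informal, paid non-state, formal
#' state). Count means interpolate linearly between the published CFS1 and
#' CFS7 means; service probabilities are the published mean services count
#' spread evenly over the 13 services; care-hour means follow the published
#' per-category patterns. Counts are drawn Poisson by default
#' (`count_dispersion = Inf`) or negative-binomial for finite dispersion;
#' hours per day are gamma; days per month are binomial on 0-30.
#'
#' @return Named list of parameter matrices/vectors (7 categories each).
#' @export
default_utilisation_params <- function() {
  lin <- function(a, b) seq(a, b, length.out = 7)
  counts <- rbind(
    gp_visits = lin(2.5, 5.9),
    opd_visits = lin(0.7, 3.9),
    ed_visits = lin(0.1, 0.9),
    admissions = lin(0.2, 1.0),
    hospital_nights = lin(6.6, 26.1)
  )
  colnames(counts) <- paste0("CFS", 1:7)
  services <- matrix(rep(lin(0.3, 2.0) / 13, each = 13), nrow = 13,
                     dimnames = list(cfs_services(), paste0("CFS", 1:7)))
  care_monthly <- rbind(
    informal = c(1, 2, 4, 12, 60, 85.2, 150),
    paid = c(0, 0, 0.5, 3, 0, 34.8, 50),
    formal = c(1, 1.5, 2, 3.2, 22.4, 23.7, 16.9)
  )
  colnames(care_monthly) <- paste0("CFS", 1:7)
  list(counts = counts, count_dispersion = Inf, services = services,
       care_monthly = care_monthly, care_days_mean = 15, care_gamma_shape = 2)
}

#' Configure a synthetic cohort simulation
#'
#' Validates and assembles the full set of generating conditions: cohort
#' size, wave grid, baseline category mix, the ground-truth transition
#' generator, attrition, the scoring tree used to draw category-consistent
#' item vectors, utilisation distributions and the attrition-weight model.
#'
#' @param n_subjects Positive integer cohort size.
#' @param n_waves Number of waves (default 5).
#' @param wave_spacing Years between waves: a scalar (default 2) or a vector
#'   of `n_waves - 1` per-interval spacings.
#' @param baseline_category_probs Probability 7-vector over CFS1-7 at wave 0
#'   (default: the published prevalence, normalised).
#' @param baseline_state_probs Optional probability 3-vector over
#'   (fit, vulnerable, frail); must equal the collapsed category vector
#'   (it is derived from it when omitted).
#' @param generator Ground-truth 4x4 generator matrix (default: the generator
#'   calibrated to [ref_transition_2yr()] via [nearest_generator()]).
#' @param missing_hazard Per-wave probability in `[0, 1)` of a non-death
#'   missing observation (default 0.05); wave 0 is always observed and death
#'   is always ascertained.
#' @param tree Classification tree used to draw item vectors consistent with
#'   assigned categories.
#' @param utilisation_params See [default_utilisation_params()].
#' @param weight_model List `list(dist = "lognormal", sdlog = ...)`; attrition
#'   weights are drawn with mean 1.
#' @param include_items,include_utilisation Logical switches to skip drawing
#'   item vectors / utilisation variables (useful for large state-dynamics
#'   studies).
#' @param seed Optional integer seed; when supplied the simulation is fully
#'   reproducible.
#' @return Validated configuration object of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 3500L,
                       n_waves = 5L,
                       wave_spacing = 2,
                       baseline_category_probs = NULL,
                       baseline_state_probs = NULL,
                       generator = NULL,
                       missing_hazard = 0.05,
                       tree = cfs_tree(),
                       utilisation_params = default_utilisation_params(),
                       weight_model = list(dist = "lognormal", sdlog = 0.5),
                       include_items = TRUE,
                       include_utilisation = TRUE,
                       seed = NULL) {
  bad <- function(field, why) {
    stop("invalid '", field, "': ", why, call. = FALSE)
  }
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1 ||
      n_subjects != round(n_subjects))
    bad("n_subjects", "must be a positive integer")
  if (length(n_waves) != 1L || is.na(n_waves) || n_waves < 1 ||
      n_waves != round(n_waves))
    bad("n_waves", "must be a positive integer")
  if (length(wave_spacing) == 1L)
    wave_spacing <- rep(wave_spacing, max(0L, n_waves - 1L))
  if (n_waves > 1L && (length(wave_spacing) != n_waves - 1L ||
                       any(wave_spacing <= 0)))
    bad("wave_spacing", "needs n_waves - 1 positive spacings")
  if (is.null(baseline_category_probs)) {
    baseline_category_probs <- ref_prevalence_wave5()
    baseline_category_probs <- baseline_category_probs /
      sum(baseline_category_probs)
  }
  if (length(baseline_category_probs) != 7L ||
      any(baseline_category_probs < 0) ||
      abs(sum(baseline_category_probs) - 1) > 1e-12)
    bad("baseline_category_probs",
        "must be 7 non-negative probabilities summing to 1 (tol 1e-12)")
  collapsed <- c(sum(baseline_category_probs[1:3]),
                 baseline_category_probs[4],
                 sum(baseline_category_probs[5:7]))
  if (is.null(baseline_state_probs)) {
    baseline_state_probs <- collapsed
  } else if (length(baseline_state_probs) != 3L ||
             any(abs(baseline_state_probs - collapsed) > 1e-12)) {
    bad("baseline_state_probs",
        "must collapse exactly from baseline_category_probs")
  }
  if (is.null(generator))
    generator <- nearest_generator(ref_transition_2yr(), 2)$Q
  generator <- generator_matrix(generator)
  if (length(missing_hazard) != 1L || is.na(missing_hazard) ||
      missing_hazard < 0 || missing_hazard >= 1)
    bad("missing_hazard", "must lie in [0, 1)")
  if (!identical(weight_model$dist, "lognormal") ||
      !is.numeric(weight_model$sdlog) || weight_model$sdlog < 0)
    bad("weight_model", "supported model is list(dist = 'lognormal', sdlog)")
  if (include_items) {
    rep_ok <- validate_tree(tree)
    if (!rep_ok$valid)
      bad("tree", paste(rep_ok$issues, collapse = "; "))
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_waves = as.integer(n_waves),
    wave_spacing = wave_spacing,
    baseline_category_probs = unname(baseline_category_probs),
    baseline_state_probs = unname(baseline_state_probs),
    generator = generator, missing_hazard = missing_hazard, tree = tree,
    utilisation_params = utilisation_params, weight_model = weight_model,
    include_items = include_items, include_utilisation = include_utilisation,
    seed = seed
  ), class = "sim_config")
}

#' Sample item vectors consistent with a CFS category
#'
#' Draws item vectors uniformly from the preimage (leaf region) of a category
#' under a classification tree, by enumerating a discretised item domain.
#' Every returned vector classifies back to `category` by construction.
#'
#' @param category CFS category (scalar, 1-9).
#' @param tree Classification tree.
#' @param n Number of vectors to draw.
#' @param domain Discretised item domain (default [cfs_item_domain()]).
#' @param preimage Optional precomputed [tree_preimage()] for `tree` and
#'   `domain` (avoids re-enumeration in hot loops).
#' @return Data frame of `n` item vectors.
#' @export
generate_items <- function(category, tree = cfs_tree(), n = 1,
                           domain = cfs_item_domain(), preimage = NULL) {
  stopifnot(length(category) == 1L, category %in% 1:9)
  if (is.null(preimage)) preimage <- tree_preimage(tree, domain)
  rows <- preimage[[as.character(category)]]
  if (is.null(rows) || !length(rows))
    stop("category ", category,
         " has an empty preimage under this tree (unreachable)",
         call. = FALSE)
  domain <- attr(preimage, "domain")
  out <- domain[rows[sample.int(length(rows), n, replace = TRUE)], ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

# Draw one utilisation block for records with categories `cat` (integer vec).
draw_utilisation <- function(cat, params) {
  n <- length(cat)
  out <- list()
  for (v in rownames(params$counts)) {
    mu <- params$counts[v, cat]
    out[[v]] <- if (is.infinite(params$count_dispersion)) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, size = params$count_dispersion, mu = mu)
    }
  }
  for (s in rownames(params$services)) {
    out[[paste0("svc_", s)]] <- stats::runif(n) < params$services[s, cat]
  }
  for (p in rownames(params$care_monthly)) {
    monthly <- params$care_monthly[p, cat]
    days <- stats::rbinom(n, 30, params$care_days_mean / 30)
    mean_hours <- monthly / params$care_days_mean
    hours <- ifelse(mean_hours > 0,
                    stats::rgamma(n, shape = params$care_gamma_shape,
                                  scale = mean_hours /
                                    params$care_gamma_shape),
                    0)
    out[[paste0(p, "_hours_day")]] <- pmin(hours, 24)
    out[[paste0(p, "_days_month")]] <- days
  }
  as.data.frame(out)
}

#' Simulate a synthetic longitudinal cohort
#'
#' Generates the long-format panel the downstream analyses consume: one row
#' per subject per wave with status `observed` (carrying a CFS category, a
#' category-consistent item vector and utilisation variables), `died`
#' (absorbing; death is always ascertained) or `missing` (missing at random
#' with the configured per-wave hazard; subjects can return after a missing
#' wave). Between waves, states evolve by one multinomial draw per interval
#' from the interval law `exp(Q * spacing)` of the configured generator;
#' within-state categories are drawn from the baseline category mix
#' conditioned on the state.
#'
#' @param config A [sim_config()] object.
#' @return Data frame of class `"cohort_panel"` with `n_subjects * n_waves`
#'   rows and columns `subject_id`, `wave_index` (0-based), `time_years`,
#'   `status`, `cfs_category`, `cfs_state`, `weight`, the six item columns
#'   and the utilisation columns.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  W <- config$n_waves
  times <- cumsum(c(0, config$wave_spacing))
  cat_probs <- config$baseline_category_probs
  state_of_cat <- c(1L, 1L, 1L, 2L, 3L, 3L, 3L)
  # p(category | state), from the baseline category mix
  cond <- lapply(1:3, function(s) {
    p <- ifelse(state_of_cat == s, cat_probs, 0)
    if (sum(p) <= 0) stop("baseline category mass for state ", s,
                          " is zero but the state is reachable",
                          call. = FALSE)
    p / sum(p)
  })

  # state dynamics: 4-state matrix per wave interval
  state <- matrix(NA_integer_, n, W)
  state[, 1] <- sample.int(3L, n, replace = TRUE,
                           prob = config$baseline_state_probs)
  if (W > 1L) for (w in 2:W) {
    P <- pmat(config$generator, config$wave_spacing[w - 1L])
    for (s in 1:4) {
      idx <- which(state[, w - 1L] == s)
      if (length(idx))
        state[idx, w] <- sample.int(4L, length(idx), replace = TRUE,
                                    prob = P[s, ])
    }
  }

  # categories conditional on state
  categ <- matrix(NA_integer_, n, W)
  for (w in 1:W) for (s in 1:3) {
    idx <- which(state[, w] == s)
    if (length(idx))
      categ[idx, w] <- sample.int(7L, length(idx), replace = TRUE,
                                  prob = cond[[s]])
  }

  # missing at random (never at wave 0, never for the dead)
  miss <- matrix(stats::runif(n * W) < config$missing_hazard, n, W)
  miss[, 1] <- FALSE
  miss[state == 4L] <- FALSE

  weight <- stats::rlnorm(n, meanlog = -config$weight_model$sdlog^2 / 2,
                          sdlog = config$weight_model$sdlog)

  status <- matrix("observed", n, W)
  status[miss] <- "missing"
  status[state == 4L] <- "died"
  categ[status != "observed"] <- NA_integer_

  panel <- data.frame(
    subject_id = rep(seq_len(n), times = W),
    wave_index = rep(0:(W - 1L), each = n),
    time_years = rep(times, each = n),
    status = as.vector(status),
    cfs_category = as.vector(categ),
    stringsAsFactors = FALSE
  )
  panel$cfs_state <- ifelse(panel$status == "observed",
                            collapse_state(replace(panel$cfs_category,
                                                   is.na(panel$cfs_category),
                                                   1L)),
                            panel$status)
  panel$weight <- rep(weight, times = W)

  obs <- which(panel$status == "observed")
  if (config$include_items) {
    pre <- tree_preimage(config$tree)
    domain <- attr(pre, "domain")
    item_cols <- names(domain)
    for (col in item_cols) panel[[col]] <- domain[[col]][NA_integer_]
    for (k in 1:7) {
      rows <- obs[panel$cfs_category[obs] == k]
      if (!length(rows)) next
      drawn <- generate_items(k, config$tree, n = length(rows),
                              preimage = pre)
      for (col in item_cols) panel[[col]][rows] <- drawn[[col]]
    }
  }
  if (config$include_utilisation) {
    util <- draw_utilisation(panel$cfs_category[obs],
                             config$utilisation_params)
    for (col in names(util)) {
      panel[[col]] <- util[[col]][NA_integer_]
      panel[[col]][obs] <- util[[col]]
    }
  }
  panel <- panel[order(panel$subject_id, panel$wave_index), ]
  rownames(panel) <- NULL
  class(panel) <- c("cohort_panel", "data.frame")
  panel
}

#' Read or write a cohort panel as CSV
#'
#' UTF-8 CSV with a header row; missing cells are written as empty strings.
#'
#' @param panel Cohort panel data frame.
#' @param path CSV file path.
#' @return `read_cohort_csv` returns the panel; `write_cohort_csv` returns
#'   `path` invisibly.
#' @export
write_cohort_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                           fileEncoding = "UTF-8")
  if ("active_past_week" %in% names(panel))
    panel$active_past_week <- as.logical(panel$active_past_week)
  for (col in grep("^svc_", names(panel), value = TRUE))
    panel[[col]] <- as.logical(panel[[col]])
  class(panel) <- c("cohort_panel", "data.frame")
  panel
}

#' Read or write a simulation configuration as YAML or JSON
#'
#' Serialises the scalar and matrix fields of a [sim_config()]; the
#' classification tree is stored inline using the tree schema.
#'
#' @param config A [sim_config()] object.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `read_sim_config` returns a validated [sim_config()];
#'   `write_sim_config` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$generator <- unname(apply(x$generator, 1, as.numeric, simplify = FALSE))
  x$utilisation_params <- lapply(x$utilisation_params, function(m) {
    if (is.matrix(m)) {
      lst <- apply(m, 1, as.numeric, simplify = FALSE)
      lst
    } else m
  })
  if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 17)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
  gen <- do.call(rbind, lapply(x$generator, as.numeric))
  up <- default_utilisation_params()
  if (!is.null(x$utilisation_params)) {
    for (nm in names(x$utilisation_params)) {
      v <- x$utilisation_params[[nm]]
      if (is.list(v)) {
        m <- do.call(rbind, lapply(v, as.numeric))
        rownames(m) <- names(v)
        colnames(m) <- paste0("CFS", 1:7)
        up[[nm]] <- m
      } else {
        up[[nm]] <- v
      }
    }
  }
  sim_config(
    n_subjects = x$n_subjects, n_waves = x$n_waves,
    wave_spacing = unlist(x$wave_spacing),
    baseline_category_probs = unlist(x$baseline_category_probs),
    generator = gen, missing_hazard = x$missing_hazard,
    tree = if (is.null(x$tree)) cfs_tree() else normalise_tree(x$tree),
    utilisation_params = up,
    weight_model = x$weight_model,
    include_items = isTRUE(x$include_items),
    include_utilisation = isTRUE(x$include_utilisation),
    seed = x$seed
  )
}
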