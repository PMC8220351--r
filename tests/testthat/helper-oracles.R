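# Independent oracles and fixtures shared across the suite.

# Single-row tree walker: an independent re-implementation of tree scoring
# used to cross-check the vectorised classifier.
walk_classify <- function(row, tree) {
  lv <- cfs_levels()
  node <- tree
  repeat {
    if (!is.null(node$cfs)) return(as.integer(node$cfs))
    x <- row[[node$item]]
    if (node$item %in% names(lv)) {
      xr <- match(tolower(x), tolower(lv[[node$item]]))
      vr <- match(tolower(node$value), tolower(lv[[node$item]]))
    } else {
      xr <- as.numeric(x)
      vr <- as.numeric(node$value)
    }
    res <- switch(node$op,
      "<" = xr < vr, "<=" = xr <= vr, ">=" = xr >= vr, ">" = xr > vr,
      "==" = xr == vr, "in" = xr %in% vr)
    node <- if (res) node$yes else node$no
  }
}

# Event-time simulation of the continuous-time chain: exponential holding
# times and embedded-chain jumps, independent of the matrix exponential.
path_sim_ctmc <- function(Q, t, n, from) {
  state <- rep.int(from, n)
  tm <- numeric(n)
  repeat {
    rate <- -diag(Q)[state]
    active <- which(rate > 0 & tm < t)
    if (!length(active)) break
    tm[active] <- tm[active] + stats::rexp(length(active), rate[active])
    jumpers <- active[tm[active] <= t]
    pre <- state[jumpers]
    for (s in unique(pre)) {
      idx <- jumpers[pre == s]
      probs <- Q[s, ]
      probs[s] <- 0
      state[idx] <- sample.int(4L, length(idx), replace = TRUE,
                               prob = probs / sum(probs))
    }
  }
  state
}

# Fixture trees -------------------------------------------------------------

leaf_tree <- function(cat) list(cfs = cat)

badl_tree <- list(item = "badl_help_count", op = ">=", value = 1,
                  yes = list(cfs = 6), no = list(cfs = 2))

# Mixes ordinal, set and count splits; leaves span both fit and frail states.
mixed_tree <- list(
  item = "self_rated_health", op = "in", value = c("fair", "poor"),
  yes = list(item = "effort_frequency", op = ">=", value = "some/little",
             yes = list(cfs = 5), no = list(cfs = 4)),
  no = list(item = "condition_count", op = "<", value = 3,
            yes = list(item = "active_past_week", op = "==", value = TRUE,
                       yes = list(cfs = 1), no = list(cfs = 2)),
            no = list(cfs = 3))
)

# A small item domain that can be swept exhaustively against the walker.
coarse_domain <- function() {
  cfs_item_domain(badl_max = 3L, iadl_max = 2L,
                  condition_values = c(0L, 1L, 3L, 28L))
}

# Raw questionnaire record with every flag FALSE and benign ordinals.
blank_raw <- function() {
  c(as.list(stats::setNames(rep(FALSE, 28), paste0("cond_",
                                                   cfs_conditions()))),
    as.list(stats::setNames(rep(FALSE, 6), paste0("badl_", katz_badl()))),
    as.list(stats::setNames(rep(FALSE, 8), paste0("iadl_", lawton_iadl()))),
    list(self_rated_health = "excellent", effort_frequency = "rarely/none",
         active_past_week = TRUE))
}

# Random valid generator over the four frailty states.
rand_generator <- function(seed) {
  set.seed(seed)
  Q <- matrix(0, 4, 4)
  Q[1:3, ] <- stats::runif(12, 0.02, 0.5)
  diag(Q) <- 0
  Q[4, ] <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# Generator calibrated to the published 2-year matrix.
table2_generator <- function() nearest_generator(ref_transition_2yr(), 2)$Q

# Hand-built three-subject cohort panel: one stable, one death, one
# missing-then-return. Used by flow and likelihood tests.
toy_cohort <- function() {
  data.frame(
    subject_id = rep(1:3, each = 3),
    wave_index = rep(0:2, times = 3),
    time_years = rep(c(0, 2, 4), times = 3),
    status = c("observed", "observed", "observed",
               "observed", "died", "died",
               "observed", "missing", "observed"),
    cfs_category = c(2L, 3L, 2L, 1L, NA, NA, 4L, NA, 6L),
    cfs_state = c("fit", "fit", "fit",
                  "fit", "died", "died",
                  "vulnerable", "missing", "frail"),
    weight = 1,
    stringsAsFactors = FALSE
  )
}
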