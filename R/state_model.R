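# Continuous-time multi-state Markov model over the collapsed frailty states
# (fit, vulnerable, frail) with an absorbing death state, fitted by maximum
# likelihood to interval-censored panel observations.

#' State space of the frailty transition model
#'
#' @return Character vector `c("fit", "vulnerable", "frail", "died")`, in the
#'   fixed order used by all matrices in the package.
#' @export
msm_states <- function() c("fit", "vulnerable", "frail", "died")

# Matrix exponential by scaling-and-squaring with a truncated Taylor series.
# Intended for the small dense generators used here (4x4): after scaling the
# 1-norm below 1/2, 14 Taylor terms reach full double precision.
expm_ss <- function(A) {
  nrm <- max(rowSums(abs(A)))
  s <- if (nrm > 0.5) ceiling(log2(nrm)) + 1L else 0L
  As <- A / 2^s
  E <- diag(nrow(A))
  term <- E
  for (k in 1:14) {
    term <- term %*% As / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# exp(Q t) cleaned up to an exact stochastic matrix (clips the tiny negative
# round-off the series can leave and renormalises rows).
pmat <- function(Q, t) {
  M <- expm_ss(Q * t)
  M[M < 0] <- 0
  M / rowSums(M)
}

#' Build and validate a transition-intensity (generator) matrix
#'
#' A valid generator has non-negative off-diagonal intensities, rows summing
#' to zero, and an identically zero row for the absorbing death state.
#'
#' @param Q Numeric 4x4 matrix of instantaneous transition intensities
#'   (per year), states ordered as [msm_states()].
#' @param mask Optional logical 4x4 matrix of allowed instantaneous
#'   transitions; entries of `Q` outside the mask must be exactly zero.
#' @return `Q` with state dimnames, invisibly classed as checked.
#' @export
generator_matrix <- function(Q, mask = NULL) {
  st <- msm_states()
  Q <- as.matrix(Q)
  if (!is.numeric(Q) || any(dim(Q) != 4L) || anyNA(Q))
    stop("Q must be a numeric 4x4 matrix without missing values",
         call. = FALSE)
  off <- Q[row(Q) != col(Q)]
  if (any(off < 0))
    stop("generator has negative off-diagonal intensities", call. = FALSE)
  if (any(abs(rowSums(Q)) > 1e-10))
    stop("generator rows must sum to 0 (tolerance 1e-10)", call. = FALSE)
  if (any(Q[4L, ] != 0))
    stop("death state must be absorbing (zero generator row)", call. = FALSE)
  if (!is.null(mask) && any(Q[!mask & row(Q) != col(Q)] != 0))
    stop("generator has non-zero intensities outside the structure mask",
         call. = FALSE)
  dimnames(Q) <- list(st, st)
  Q
}

#' Default structure mask of allowed instantaneous transitions
#'
#' By default only adjacent severity moves (fit-vulnerable, vulnerable-frail)
#' plus death from every transient state are allowed instantaneously; direct
#' fit-frail jumps then arise in the interval law via two transitions. Set
#' `direct_fit_frail = TRUE` to also allow instantaneous fit-frail moves.
#'
#' @param direct_fit_frail Allow instantaneous fit->frail and frail->fit
#'   intensities.
#' @return Logical 4x4 matrix with state dimnames.
#' @export
msm_mask <- function(direct_fit_frail = FALSE) {
  st <- msm_states()
  m <- matrix(FALSE, 4, 4, dimnames = list(st, st))
  m["fit", "vulnerable"] <- m["vulnerable", "fit"] <- TRUE
  m["vulnerable", "frail"] <- m["frail", "vulnerable"] <- TRUE
  m[1:3, "died"] <- TRUE
  if (direct_fit_frail) m["fit", "frail"] <- m["frail", "fit"] <- TRUE
  m
}

#' Interval transition probabilities of a generator
#'
#' Evaluates the interval law `P(t) = exp(Q t)` of the continuous-time chain.
#'
#' @param Q Generator matrix (validated via [generator_matrix()]).
#' @param t Elapsed time in years (non-negative scalar).
#' @return Row-stochastic 4x4 matrix with state dimnames; the death row is
#'   `(0, 0, 0, 1)`.
#' @export
#' @examples
#' Q <- matrix(0, 4, 4)
#' Q[1, 2] <- 0.3; Q[1, 1] <- -0.3
#' transition_probability(Q, 2)
transition_probability <- function(Q, t) {
  Q <- generator_matrix(Q)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single non-negative number of years", call. = FALSE)
  P <- pmat(Q, t)
  dimnames(P) <- dimnames(Q)
  P
}

#' Nearest valid generator reproducing an interval matrix
#'
#' Computes the principal matrix logarithm of a row-stochastic interval
#' matrix, divides by the interval length, clips any negative off-diagonal
#' intensities to zero, zeroes the absorbing-death row and rebalances the
#' diagonal. The returned generator is exactly valid; the maximum entry-wise
#' error of `transition_probability(Q, t)` against the input is reported
#' alongside. Used to calibrate the synthetic cohort generator to a published
#' 2-year matrix.
#'
#' @param P Row-stochastic 4x4 matrix (rows are renormalised to sum exactly
#'   to 1 before the logarithm; printed matrices often carry rounding).
#' @param t Interval length in years the matrix refers to (positive).
#' @return List with `Q` (valid generator), `max_error` (max entry-wise
#'   reproduction error) and `t`.
#' @export
nearest_generator <- function(P, t) {
  P <- as.matrix(P)
  if (!is.numeric(P) || any(dim(P) != 4L) || anyNA(P) || any(P < 0))
    stop("P must be a non-negative numeric 4x4 matrix", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0)
    stop("t must be a single positive number of years", call. = FALSE)
  if (any(abs(rowSums(P) - 1) > 0.05))
    stop("P rows are too far from summing to 1 to be an interval matrix",
         call. = FALSE)
  P <- P / rowSums(P)
  ev <- eigen(P, only.values = TRUE)$values
  if (any(Re(ev) <= 0 & abs(Im(ev)) < 1e-12))
    stop("principal matrix logarithm undefined: P has an eigenvalue on the ",
         "closed negative real axis", call. = FALSE)
  L <- pracma::logm(P)
  if (is.complex(L)) {
    if (max(abs(Im(L))) > 1e-8)
      stop("matrix logarithm of P is not real", call. = FALSE)
    L <- Re(L)
  }
  Q <- L / t
  Q[row(Q) != col(Q) & Q < 0] <- 0
  Q[4L, ] <- 0
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- generator_matrix(Q)
  err <- max(abs(pmat(Q, t) - P))
  list(Q = Q, max_error = err, t = t)
}

# ---- panel handling ---------------------------------------------------------

#' Convert a simulated cohort to a state-observation panel
#'
#' Collapses observed CFS categories to the three transient states, keeps the
#' first death record per subject, and drops missing waves (the likelihood
#' skips over them by the Markov property, so they carry no information).
#'
#' @param cohort A cohort panel from [simulate_cohort()] (or any data frame
#'   with `subject_id`, `time_years` and either `status`/`cfs_category`
#'   columns or an `observation` column of state labels).
#' @return Data frame with columns `subject_id`, `time_years`, `observation`
#'   (levels of [msm_states()]).
#' @export
as_state_panel <- function(cohort) {
  if ("observation" %in% names(cohort)) {
    panel <- cohort[, c("subject_id", "time_years", "observation")]
  } else {
    obs <- ifelse(cohort$status == "observed",
                  collapse_state(replace(cohort$cfs_category,
                                         cohort$status != "observed", 1L)),
                  cohort$status)
    panel <- data.frame(subject_id = cohort$subject_id,
                        time_years = cohort$time_years,
                        observation = obs, stringsAsFactors = FALSE)
    panel <- panel[panel$observation != "missing", ]
  }
  panel <- panel[order(panel$subject_id, panel$time_years), ]
  # died is absorbing: keep only the first death record per subject
  split_idx <- split(seq_len(nrow(panel)), panel$subject_id)
  drop <- logical(nrow(panel))
  for (idx in split_idx) {
    d <- which(panel$observation[idx] == "died")
    if (length(d) > 1L) drop[idx[d[-1L]]] <- TRUE
    if (length(d) >= 1L && d[1L] < length(idx))
      drop[idx[(d[1L] + 1L):length(idx)]] <- TRUE
  }
  panel <- panel[!drop, ]
  rownames(panel) <- NULL
  validate_state_panel(panel)
  panel
}

validate_state_panel <- function(panel) {
  stopifnot(all(c("subject_id", "time_years", "observation") %in%
                  names(panel)))
  bad <- setdiff(unique(panel$observation), c(msm_states(), "missing"))
  if (length(bad))
    stop("unknown observation label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  panel <- panel[order(panel$subject_id, panel$time_years), ]
  for (idx in split(seq_len(nrow(panel)), panel$subject_id)) {
    tt <- panel$time_years[idx]
    if (is.unsorted(tt, strictly = TRUE))
      stop("times must be strictly increasing within subject ",
           panel$subject_id[idx[1]], call. = FALSE)
    d <- which(panel$observation[idx] == "died")
    if (length(d) && any(d < length(idx)))
      stop("observations follow a death record for subject ",
           panel$subject_id[idx[1]], call. = FALSE)
  }
  invisible(panel)
}

# Aggregate a panel into interval-transition counts: a data frame
# (from, to, dt, n). Missing observations are skipped (Markov property);
# records after death were removed upstream.
aggregate_intervals <- function(panel) {
  st <- msm_states()
  keys <- character(0)
  from <- to <- integer(0)
  dt <- numeric(0)
  counts <- new.env(parent = emptyenv())
  panel <- panel[panel$observation != "missing", ]
  panel <- panel[order(panel$subject_id, panel$time_years), ]
  sid <- panel$subject_id
  obs <- match(panel$observation, st)
  tt <- panel$time_years
  n <- nrow(panel)
  if (n < 2L)
    return(data.frame(from = integer(0), to = integer(0), dt = numeric(0),
                      n = integer(0)))
  same <- sid[-1L] == sid[-n]
  a <- obs[-n][same]
  b <- obs[-1L][same]
  d <- signif((tt[-1L] - tt[-n])[same], 10)
  du <- sort(unique(d))
  code <- (match(d, du) - 1L) * 16L + (a - 1L) * 4L + b
  cnt <- tabulate(code, nbins = 16L * length(du))
  hit <- which(cnt > 0L)
  data.frame(
    from = ((hit - 1L) %% 16L) %/% 4L + 1L,
    to = (hit - 1L) %% 4L + 1L,
    dt = du[(hit - 1L) %/% 16L + 1L],
    n = cnt[hit]
  )
}

# Reshape aggregated counts into one block per unique interval length, with
# the (from, to) index matrix prebuilt -- the likelihood hot path avoids any
# data-frame subsetting.
prep_counts <- function(agg) {
  lapply(split(seq_len(nrow(agg)), agg$dt), function(i)
    list(dt = agg$dt[i[1]], idx = cbind(agg$from[i], agg$to[i]),
         n = agg$n[i]))
}

loglik_from_blocks <- function(Q, blocks) {
  ll <- 0
  zero <- character(0)
  st <- msm_states()
  for (g in blocks) {
    P <- pmat(Q, g$dt)
    p <- P[g$idx]
    if (any(p <= 0)) {
      bad <- p <= 0
      zero <- c(zero, paste0(st[g$idx[bad, 1]], "->", st[g$idx[bad, 2]],
                             " over ", g$dt, "y"))
      next
    }
    ll <- ll + sum(g$n * log(p))
  }
  if (length(zero)) {
    ll <- -Inf
    attr(ll, "zero_transitions") <- zero
  }
  ll
}

loglik_from_counts <- function(Q, agg) {
  if (!nrow(agg)) return(0)
  loglik_from_blocks(Q, prep_counts(agg))
}

#' Log-likelihood of a generator for an interval-censored panel
#'
#' For consecutive observed states `a` at `t1` and `b` at `t2` the interval
#' contributes `log P(t2 - t1)[a, b]`. A death observation is treated as
#' interval-censored — the subject was alive in state `a` at `t1` and known
#' dead by `t2` — which is exactly the `[a, died]` entry of the interval
#' matrix (all paths into death are summed by the matrix exponential).
#' Missing observations are skipped by the Markov property. An empty panel
#' has log-likelihood 0; an observed transition that is impossible under
#' structural zeros yields `-Inf` with a diagnostic attribute
#' `"zero_transitions"`.
#'
#' @param Q Generator matrix.
#' @param panel State panel (see [as_state_panel()]).
#' @return Scalar log-likelihood.
#' @export
msm_loglik <- function(Q, panel) {
  Q <- generator_matrix(Q)
  if (!nrow(panel)) return(0)
  validate_state_panel(panel)
  loglik_from_counts(Q, aggregate_intervals(panel))
}

# Crude empirical initial intensities: observed a->b transition counts over
# person-time at risk in a (interval lengths attributed to the origin state).
crude_rates <- function(agg, mask) {
  init <- matrix(0.01, 4, 4)
  for (a in 1:3) {
    persontime <- sum(agg$n[agg$from == a] * agg$dt[agg$from == a])
    if (persontime <= 0) next
    for (b in 1:4) {
      if (b == a) next
      cnt <- sum(agg$n[agg$from == a & agg$to == b])
      init[a, b] <- max(cnt, 0.5) / persontime
    }
  }
  pmax(init[mask], 1e-4)
}

#' Fit the multi-state model by maximum likelihood
#'
#' Maximises the interval-censored panel likelihood over log-intensities
#' (the unconstrained parameterisation guarantees a valid generator) with
#' quasi-Newton (BFGS) iterations, starting from crude empirical rates.
#'
#' @param panel State panel (see [as_state_panel()]).
#' @param mask Logical 4x4 matrix of allowed instantaneous transitions
#'   (default [msm_mask()]).
#' @param init Optional numeric vector of initial log-intensities (length
#'   `sum(mask)`).
#' @param t Horizon (years) at which the fitted transition-probability matrix
#'   is reported (default 2, one wave interval).
#' @param control Passed to [stats::optim()]; defaults to
#'   `list(maxit = 500, reltol = 1e-10)`.
#' @return Object of class `"msm_fit"`: list with `Q` (fitted generator),
#'   `P` (fitted transition matrix at `t`), `log_likelihood`, `converged`,
#'   `t`, `mask`, `par` (log-intensities), `panel`, `ci` (`NULL` until
#'   [bootstrap_ci()] is run) and optimiser details.
#' @export
fit_msm <- function(panel, mask = msm_mask(), init = NULL, t = 2,
                    control = list()) {
  validate_state_panel(panel)
  agg <- aggregate_intervals(panel)
  if (!nrow(agg))
    stop("panel contains no observed transitions", call. = FALSE)
  mask <- mask & !diag(4) == 1
  mask[4L, ] <- FALSE
  npar <- sum(mask)
  # flag free intensities with no directly observed transition
  unobserved <- character(0)
  st <- msm_states()
  for (k in which(mask)) {
    a <- row(mask)[k]; b <- col(mask)[k]
    if (!sum(agg$n[agg$from == a & agg$to == b]))
      unobserved <- c(unobserved, paste0(st[a], "->", st[b]))
  }
  if (is.null(init)) init <- log(crude_rates(agg, mask))
  stopifnot(length(init) == npar)
  control <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
  build_Q <- function(lq) {
    Q <- matrix(0, 4, 4)
    Q[mask] <- exp(pmin(lq, 6))
    diag(Q) <- -rowSums(Q)
    Q
  }
  blocks <- prep_counts(agg)
  nll <- function(lq) {
    ll <- loglik_from_blocks(build_Q(lq), blocks)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  op <- stats::optim(init, nll, method = "BFGS", control = control)
  Q <- generator_matrix(build_Q(op$par), mask = mask)
  structure(list(
    Q = Q,
    P = transition_probability(Q, t),
    log_likelihood = -op$value,
    converged = op$convergence == 0L && is.finite(op$value),
    t = t,
    mask = mask,
    par = op$par,
    panel = panel,
    unobserved_intensities = unobserved,
    ci = NULL,
    optim = op[c("counts", "convergence", "message")]
  ), class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, digits = 3, ...) {
  cat("Multi-state Markov model fit (interval-censored panel)\n")
  cat("log-likelihood:", format(x$log_likelihood, digits = 8),
      " converged:", x$converged, "\n")
  if (length(x$unobserved_intensities))
    cat("note: no directly observed transitions for:",
        paste(x$unobserved_intensities, collapse = ", "), "\n")
  cat("\nTransition intensities (per year):\n")
  print(round(x$Q, digits))
  cat("\nTransition probabilities over", x$t, "years:\n")
  print(round(x$P, digits))
  if (!is.null(x$ci)) {
    cat("\n", 100 * x$ci$conf, "% bootstrap CI (", x$ci$B_used,
        " replicates):\n", sep = "")
    st <- msm_states()
    for (a in 1:3) {
      cat(st[a], ": ", paste0(
        st, " ", sprintf("%.2f (%.2f,%.2f)", x$P[a, ],
                         x$ci$lower[a, ], x$ci$upper[a, ]),
        collapse = "  "), "\n", sep = "")
    }
  }
  invisible(x)
}

# Precompute the ragged observation grid of a panel once: time and initial
# state matrices with one row per subject (NA-padded beyond each grid).
boot_grid <- function(panel) {
  st <- msm_states()
  panel <- panel[order(panel$subject_id, panel$time_years), ]
  idx <- split(seq_len(nrow(panel)), panel$subject_id)
  len <- lengths(idx)
  tmat <- matrix(NA_real_, length(idx), max(len))
  for (i in seq_along(idx))
    tmat[i, seq_len(len[i])] <- panel$time_years[idx[[i]]]
  s0 <- match(panel$observation[vapply(idx, `[`, integer(1), 1L)], st)
  list(tmat = tmat, s0 = s0)
}

# Simulate one parametric-bootstrap panel: each subject keeps their observed
# observation-time grid and initial state; later states are drawn from the
# interval law of Q; death truncates the grid. Vectorised by grouping
# subjects on (current state, interval length) at each grid slot.
simulate_boot_panel <- function(grid, Q) {
  st <- msm_states()
  tmat <- grid$tmat
  n <- nrow(tmat)
  smat <- matrix(NA_integer_, n, ncol(tmat))
  smat[, 1] <- grid$s0
  Pcache <- list()
  for (j in seq_len(ncol(tmat))[-1]) {
    active <- which(!is.na(tmat[, j]) & !is.na(smat[, j - 1L]) &
                      smat[, j - 1L] != 4L)
    if (!length(active)) next
    d <- tmat[active, j] - tmat[active, j - 1L]
    for (key in unique(signif(d, 10))) {
      k <- as.character(key)
      if (is.null(Pcache[[k]])) Pcache[[k]] <- pmat(Q, key)
      P <- Pcache[[k]]
      for (s in 1:3) {
        rows <- active[smat[active, j - 1L] == s & signif(d, 10) == key]
        if (length(rows))
          smat[rows, j] <- sample.int(4L, length(rows), replace = TRUE,
                                      prob = P[s, ])
      }
    }
  }
  keep <- which(!is.na(smat))
  data.frame(subject_id = as.integer(row(smat)[keep]),
             time_years = tmat[keep],
             observation = st[smat[keep]],
             stringsAsFactors = FALSE)[order(row(smat)[keep],
                                             tmat[keep]), ]
}

#' Parametric-bootstrap confidence intervals for transition probabilities
#'
#' Simulates `B` replicate panels from the fitted generator over each
#' subject's observed observation grid (conditioning on their first observed
#' state), refits the model to each, and returns percentile bounds for every
#' entry of the fitted transition-probability matrix. Bounds are expanded,
#' where needed, to contain the point estimate. Non-convergent replicates are
#' dropped and counted; more than 20% dropped is an error.
#'
#' @param fit An [fit_msm()] result (must have converged).
#' @param B Number of bootstrap replicates (>= 2); 500 is a reasonable
#'   production default.
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @param control Optimiser control for the refits; defaults to a slightly
#'   looser tolerance than the original fit.
#' @return The `fit` object with its `ci` field set to a list holding
#'   `lower` / `upper` 4x4 matrices, `conf`, `B_used` and `B_dropped`.
#' @export
bootstrap_ci <- function(fit, B = 500, conf = 0.95, seed = NULL,
                         control = list(maxit = 300, reltol = 1e-8)) {
  stopifnot(inherits(fit, "msm_fit"))
  if (!fit$converged)
    stop("bootstrap requires a converged fit", call. = FALSE)
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grid <- boot_grid(fit$panel)
  reps <- array(NA_real_, dim = c(4, 4, B))
  dropped <- 0L
  for (b in seq_len(B)) {
    bp <- simulate_boot_panel(grid, fit$Q)
    bf <- tryCatch(
      fit_msm(bp, mask = fit$mask, init = fit$par, t = fit$t,
              control = control),
      error = function(e) NULL)
    if (is.null(bf) || !bf$converged) {
      dropped <- dropped + 1L
      next
    }
    reps[, , b] <- bf$P
  }
  if (dropped > 0.2 * B)
    stop("more than 20% of bootstrap replicates failed to converge (",
         dropped, " of ", B, ")", call. = FALSE)
  alpha <- (1 - conf) / 2
  lower <- upper <- matrix(NA_real_, 4, 4, dimnames = dimnames(fit$P))
  for (a in 1:4) for (b2 in 1:4) {
    v <- reps[a, b2, ]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
    lower[a, b2] <- min(q[1], fit$P[a, b2])
    upper[a, b2] <- max(q[2], fit$P[a, b2])
  }
  fit$ci <- list(lower = lower, upper = upper, conf = conf,
                 B_used = B - dropped, B_dropped = dropped)
  fit
}

#' Read or write a state panel as CSV
#'
#' Plain-text interchange of panel observations with columns `subject_id`,
#' `time_years`, `observation`.
#'
#' @param panel State panel data frame.
#' @param path CSV file path.
#' @return `read_state_panel` returns the validated panel;
#'   `write_state_panel` returns `path` invisibly.
#' @export
write_state_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_state_panel
#' @export
read_state_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  validate_state_panel(panel)
  panel
}

#' Export a fitted transition matrix
#'
#' Writes the fitted 2-year transition-probability matrix (and bootstrap
#' bounds when present) as tidy CSV or JSON with the fixed state labels.
#'
#' @param fit An [fit_msm()] result.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_msm_fit <- function(fit, path) {
  st <- msm_states()
  tidy <- data.frame(
    from = rep(st, times = 4), to = rep(st, each = 4),
    probability = as.vector(fit$P),
    ci_low = if (is.null(fit$ci)) NA_real_ else as.vector(fit$ci$lower),
    ci_high = if (is.null(fit$ci)) NA_real_ else as.vector(fit$ci$upper)
  )
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(
      list(t_years = fit$t, states = st, transition_probabilities = tidy,
           intensities = as.data.frame(fit$Q),
           log_likelihood = fit$log_likelihood, converged = fit$converged),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(tidy, path, row.names = FALSE)
  }
  invisible(path)
}
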