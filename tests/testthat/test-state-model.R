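test_that("the interval law satisfies its closed forms and invariants", {
  I4 <- diag(4)
  dimnames(I4) <- list(msm_states(), msm_states())
  expect_equal(transition_probability(matrix(0, 4, 4), 3.7), I4)

  # single escape intensity: P(fit -> vulnerable over t) = 1 - exp(-lambda t)
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- 0.5
  diag(Q) <- -rowSums(Q)
  P <- transition_probability(Q, 2)
  expect_equal(P[1, 2], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(P[1, 1], exp(-1), tolerance = 1e-12)

  for (seed in 1:5) {
    Qr <- rand_generator(seed)
    P2 <- transition_probability(Qr, 2)
    P4 <- transition_probability(Qr, 4)
    expect_true(all(P2 >= 0 & P2 <= 1))
    expect_equal(unname(rowSums(P2)), rep(1, 4), tolerance = 1e-9)
    expect_equal(unname(P2[4, ]), c(0, 0, 0, 1))
    expect_equal(P4, P2 %*% P2, tolerance = 1e-8)           # Chapman-Kolmogorov
  }

  expect_error(transition_probability(Q, -1), "non-negative")
  badQ <- Q; badQ[1, 2] <- -0.1
  expect_error(transition_probability(badQ, 1), "negative off-diagonal")
  badQ2 <- matrix(0.1, 4, 4)
  expect_error(transition_probability(badQ2, 1), "sum to 0")
})

test_that("matrix exponential agrees with event-time path simulation", {
  Q <- table2_generator()
  P <- transition_probability(Q, 2)
  set.seed(41)
  n <- 100000
  for (from in 1:3) {
    end <- path_sim_ctmc(Q, 2, n, from)
    for (to in 1:4) {
      p <- P[from, to]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(end == to) - p), 3 * se)
    }
  }
})

test_that("nearest_generator projects interval matrices onto valid generators", {
  id <- diag(4)
  ng_id <- nearest_generator(id, 2)
  expect_equal(unname(ng_id$Q), matrix(0, 4, 4))
  expect_lt(ng_id$max_error, 1e-12)

  for (seed in 1:4) {
    Q <- rand_generator(seed) / 2
    P <- transition_probability(Q, 2)
    ng <- nearest_generator(P, 2)
    expect_equal(unname(ng$Q), unname(Q), tolerance = 1e-8)
    expect_lt(ng$max_error, 1e-8)
  }

  # a period-2 block has eigenvalue -1: no real principal logarithm
  swap <- diag(4)
  swap[1:2, 1:2] <- matrix(c(0, 1, 1, 0), 2)
  expect_error(nearest_generator(swap, 2), "logarithm")
})

test_that("log-likelihood equals hand-composed interval products", {
  Q <- table2_generator()
  empty <- data.frame(subject_id = integer(0), time_years = numeric(0),
                      observation = character(0))
  expect_identical(msm_loglik(Q, empty), 0)

  one <- data.frame(subject_id = 1, time_years = c(0, 2),
                    observation = c("fit", "fit"))
  expect_equal(msm_loglik(Q, one), log(transition_probability(Q, 2)[1, 1]))

  # three subjects incl. an interval-censored death and a skipped missing wave
  toy <- data.frame(
    subject_id = c(1, 1, 1, 2, 2, 3, 3, 3),
    time_years = c(0, 2, 4, 0, 2, 0, 2, 4),
    observation = c("fit", "vulnerable", "frail",
                    "fit", "died",
                    "vulnerable", "missing", "fit")
  )
  P2 <- transition_probability(Q, 2)
  P4 <- transition_probability(Q, 4)
  by_hand <- log(P2["fit", "vulnerable"]) + log(P2["vulnerable", "frail"]) +
    log(P2["fit", "died"]) + log(P4["vulnerable", "fit"])
  expect_equal(msm_loglik(Q, toy), by_hand, tolerance = 1e-12)

  # inserting missing rows never changes the likelihood (Markov skipping)
  toy_extra <- rbind(toy, data.frame(subject_id = 2, time_years = 1,
                                     observation = "missing"))
  expect_equal(msm_loglik(Q, toy_extra), by_hand, tolerance = 1e-12)

  # splitting a record at an observed wave preserves the total likelihood
  split2 <- data.frame(
    subject_id = c(1, 1, 4, 4, 2, 2, 3, 3),
    time_years = c(0, 2, 2, 4, 0, 2, 0, 4),
    observation = c("fit", "vulnerable", "vulnerable", "frail",
                    "fit", "died", "vulnerable", "fit")
  )
  expect_equal(msm_loglik(Q, split2), by_hand, tolerance = 1e-12)

  # structurally impossible observed transition
  Qz <- matrix(0, 4, 4)
  Qz[1, 2] <- 0.3
  diag(Qz) <- -rowSums(Qz)
  imposs <- data.frame(subject_id = 1, time_years = c(0, 2),
                       observation = c("fit", "frail"))
  ll <- msm_loglik(Qz, imposs)
  expect_identical(as.numeric(ll), -Inf)
  expect_match(attr(ll, "zero_transitions"), "fit->frail", all = FALSE)
})

test_that("maximum likelihood recovers interval probabilities", {
  # binomial closed form: single free intensity, k of n switch in one interval
  n <- 60; k <- 21
  panel <- data.frame(
    subject_id = rep(seq_len(n), each = 2),
    time_years = rep(c(0, 2), n),
    observation = c(rbind(rep("fit", n),
                          c(rep("vulnerable", k), rep("fit", n - k))))
  )
  mask <- matrix(FALSE, 4, 4)
  mask[1, 2] <- TRUE
  fit <- fit_msm(panel, mask = mask)
  expect_true(fit$converged)
  expect_equal(fit$P["fit", "vulnerable"], k / n, tolerance = 1e-6)

  # Monte-Carlo recovery from a known generator
  Q <- table2_generator()
  cfg <- sim_config(n_subjects = 2000, n_waves = 5, generator = Q,
                    missing_hazard = 0, include_items = FALSE,
                    include_utilisation = FALSE, seed = 1)
  sp <- as_state_panel(simulate_cohort(cfg))
  fit2 <- fit_msm(sp, mask = msm_mask(direct_fit_frail = TRUE))
  expect_true(fit2$converged)
  expect_lt(max(abs(fit2$P - transition_probability(Q, 2))), 0.03)

  # invariance to subject relabelling and record order
  sp_shuf <- sp
  relabel <- sample(max(sp$subject_id))
  sp_shuf$subject_id <- relabel[sp$subject_id]
  sp_shuf <- sp_shuf[sample(nrow(sp_shuf)), ]
  fit3 <- fit_msm(sp_shuf, mask = msm_mask(direct_fit_frail = TRUE))
  expect_equal(fit3$Q, fit2$Q, tolerance = 1e-8)

  # non-convergence is flagged, not silently returned
  fit4 <- fit_msm(sp, control = list(maxit = 1))
  expect_false(fit4$converged)
})

test_that("parametric-bootstrap intervals bracket estimates and shrink with n", {
  Q <- table2_generator()
  make_fit <- function(n, seed) {
    cfg <- sim_config(n_subjects = n, n_waves = 4, generator = Q,
                      missing_hazard = 0, include_items = FALSE,
                      include_utilisation = FALSE, seed = seed)
    fit_msm(as_state_panel(simulate_cohort(cfg)))
  }
  fit_small <- make_fit(400, 8)
  smoke <- bootstrap_ci(fit_small, B = 2, seed = 1)
  expect_true(all(smoke$ci$lower <= smoke$P + 1e-12))
  expect_true(all(smoke$ci$upper >= smoke$P - 1e-12))

  ci_small <- bootstrap_ci(fit_small, B = 99, seed = 2)$ci
  fit_big <- make_fit(1600, 8)
  ci_big <- bootstrap_ci(fit_big, B = 99, seed = 3)$ci
  trans <- cbind(rep(1:3, 4), rep(1:4, each = 3))
  w_small <- (ci_small$upper - ci_small$lower)[trans]
  w_big <- (ci_big$upper - ci_big$lower)[trans]
  ratio <- stats::median(w_big / w_small)
  expect_gt(ratio, 0.35)  # quadrupling n should roughly halve CI widths
  expect_lt(ratio, 0.65)

  bad <- fit_msm(as_state_panel(simulate_cohort(
    sim_config(n_subjects = 200, generator = Q, include_items = FALSE,
               include_utilisation = FALSE, seed = 4))),
    control = list(maxit = 1))
  expect_error(bootstrap_ci(bad, B = 2), "converged")
})

test_that("state panels convert, validate and round-trip", {
  pan <- toy_cohort()
  sp <- as_state_panel(pan)
  # missing waves dropped, only the first death record kept
  expect_equal(nrow(sp), 7)
  expect_equal(sp$observation[sp$subject_id == 2], c("fit", "died"))
  expect_equal(sp$observation[sp$subject_id == 3], c("vulnerable", "frail"))

  path <- tempfile(fileext = ".csv")
  write_state_panel(sp, path)
  expect_equal(read_state_panel(path), sp, ignore_attr = TRUE)
  unlink(path)

  bad <- data.frame(subject_id = 1, time_years = c(0, 2),
                    observation = c("died", "fit"))
  expect_error(msm_loglik(table2_generator(), bad), "follow a death")
})
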