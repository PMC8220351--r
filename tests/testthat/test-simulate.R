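test_that("simulation is seeded-reproducible and honours a frozen generator", {
  cfg <- sim_config(n_subjects = 120, seed = 5)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- sim_config(n_subjects = 120, seed = 6)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))

  frozen <- sim_config(n_subjects = 200, generator = matrix(0, 4, 4),
                       missing_hazard = 0, include_items = FALSE,
                       include_utilisation = FALSE, seed = 5)
  pan <- simulate_cohort(frozen)
  expect_equal(nrow(pan), 200 * 5)
  expect_true(all(pan$status == "observed"))
  st0 <- pan$cfs_state[pan$wave_index == 0]
  for (w in 1:4)
    expect_identical(pan$cfs_state[pan$wave_index == w], st0)
})

test_that("interval dynamics and baseline mix match the configured law", {
  Q <- table2_generator()
  cfg <- sim_config(n_subjects = 50000, n_waves = 2, generator = Q,
                    missing_hazard = 0, include_items = FALSE,
                    include_utilisation = FALSE, seed = 31)
  pan <- simulate_cohort(cfg)
  P <- transition_probability(Q, 2)

  fit0 <- pan$subject_id[pan$wave_index == 0 & pan$cfs_state == "fit"]
  next_state <- pan$cfs_state[pan$wave_index == 1][fit0]
  n <- length(fit0)
  p_emp <- mean(next_state == "vulnerable")
  p_true <- P["fit", "vulnerable"]
  expect_lt(abs(p_emp - p_true), 3 * sqrt(p_true * (1 - p_true) / n))

  # wave-0 marginal category frequencies converge to the baseline mix
  cat0 <- pan$cfs_category[pan$wave_index == 0]
  probs <- cfg$baseline_category_probs
  for (k in 1:7) {
    se <- sqrt(probs[k] * (1 - probs[k]) / 50000)
    expect_lt(abs(mean(cat0 == k) - probs[k]), 3 * se)
  }
})

test_that("death is absorbing and attrition behaves as configured", {
  cfg <- sim_config(n_subjects = 1500, seed = 9, include_items = FALSE,
                    include_utilisation = FALSE)
  pan <- simulate_cohort(cfg)
  expect_equal(nrow(pan), 1500 * 5)
  # no status other than died may follow a died record
  for (idx in split(seq_len(nrow(pan)), pan$subject_id)) {
    s <- pan$status[idx]
    d <- which(s == "died")
    if (length(d)) expect_true(all(s[d[1]:length(s)] == "died"))
  }
  cum_dead <- tapply(pan$status == "died", pan$wave_index, mean)
  expect_true(all(diff(cum_dead) >= 0))
  # wave 0 is always observed
  expect_true(all(pan$status[pan$wave_index == 0] == "observed"))

  none <- sim_config(n_subjects = 300, generator = matrix(0, 4, 4),
                     missing_hazard = 0, include_items = FALSE,
                     include_utilisation = FALSE, seed = 2)
  expect_true(all(table(simulate_cohort(none)$subject_id) == 5))
})

test_that("generated item vectors always classify back to their category", {
  tree <- cfs_tree()
  cfg <- sim_config(n_subjects = 400, seed = 13,
                    include_utilisation = FALSE)
  pan <- simulate_cohort(cfg)
  obs <- pan[pan$status == "observed", ]
  expect_identical(classify_cfs(obs[, names(cfs_item_domain())], tree),
                   obs$cfs_category)

  pre <- tree_preimage(tree)
  set.seed(1)
  for (k in 1:7) {
    drawn <- generate_items(k, tree, n = 1000, preimage = pre)
    expect_true(all(classify_cfs(drawn, tree) == k))
  }
  expect_error(generate_items(8, tree, preimage = pre), "empty preimage")

  # forced branch on a two-leaf fixture
  act <- list(item = "active_past_week", op = "==", value = TRUE,
              yes = list(cfs = 1), no = list(cfs = 2))
  set.seed(2)
  expect_true(all(generate_items(1, act, n = 50)$active_past_week))
})

test_that("preimage enumeration agrees with rejection-sampling support", {
  dom <- coarse_domain()
  pre <- tree_preimage(mixed_tree, dom)
  set.seed(7)
  draws <- sample.int(nrow(dom), 3000, replace = TRUE)
  cats <- classify_cfs(dom[draws, ], mixed_tree)
  for (k in as.integer(names(pre))) {
    # every rejection-sampled vector of category k lies in the enumerated
    # preimage, and every enumerated row classifies to k
    expect_true(all(draws[cats == k] %in% pre[[as.character(k)]]))
    expect_true(all(classify_cfs(dom[pre[[as.character(k)]], ],
                                 mixed_tree) == k))
  }
  expect_equal(unname(sort(unlist(pre))), seq_len(nrow(dom)))
})

test_that("utilisation draws and weights converge to configured parameters", {
  cfg <- sim_config(n_subjects = 20000, n_waves = 1, seed = 17,
                    include_items = FALSE)
  pan <- simulate_cohort(cfg)
  up <- cfg$utilisation_params
  for (k in c(1, 4, 7)) {
    rows <- pan[pan$cfs_category == k, ]
    n <- nrow(rows)
    mu <- up$counts["gp_visits", k]
    expect_lt(abs(mean(rows$gp_visits) - mu), 3 * stats::sd(rows$gp_visits) / sqrt(n))
    hrs <- monthly_care_hours(rows$informal_hours_day,
                              rows$informal_days_month)
    target <- up$care_monthly["informal", k]
    expect_lt(abs(mean(hrs) - target),
              max(3 * stats::sd(hrs) / sqrt(n), 1e-9))
    psvc <- up$services["respite", k]
    expect_lt(abs(mean(rows$svc_respite) - psvc),
              3 * sqrt(psvc * (1 - psvc) / n))
  }
  expect_lt(abs(mean(pan$weight[pan$wave_index == 0]) - 1),
            3 * stats::sd(pan$weight) / sqrt(20000))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(missing_hazard = 1), "missing_hazard")
  expect_error(sim_config(baseline_category_probs = rep(0.2, 7)),
               "baseline_category_probs")
  p <- rep(1 / 7, 7)
  expect_error(sim_config(baseline_category_probs = p,
                          baseline_state_probs = c(0.5, 0.3, 0.2)),
               "baseline_state_probs")
  expect_error(sim_config(wave_spacing = c(2, 2)), "wave_spacing")
  expect_error(sim_config(weight_model = list(dist = "uniform")),
               "weight_model")
})

test_that("cohort CSV and simulation config files round-trip", {
  cfg <- sim_config(n_subjects = 40, seed = 3)
  pan <- simulate_cohort(cfg)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(pan, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(pan), tolerance = 1e-12)
  unlink(path)

  cfg_path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, cfg_path)
  cfg_back <- read_sim_config(cfg_path)
  expect_identical(simulate_cohort(cfg_back), pan)
  unlink(cfg_path)
})
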