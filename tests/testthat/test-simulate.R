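test_that("identical config and seed give byte-identical output", {
  cfg <- simulation_config(n_initial_apps = 30, arrival_rate = 1,
                           span_days = 40, n_missing_days = 5,
                           search_window_k = 20, seed = 99)
  s1 <- simulate_marketplace(cfg)
  s2 <- simulate_marketplace(cfg)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$registry, s2$registry)
  s3 <- simulate_marketplace(simulation_config(
    n_initial_apps = 30, arrival_rate = 1, span_days = 40,
    n_missing_days = 5, search_window_k = 20, seed = 100))
  expect_false(identical(s1$panel$observations, s3$panel$observations))
})

test_that("without removals or truncation every app is always in search", {
  cfg <- simulation_config(n_initial_apps = 15, arrival_rate = 0,
                           removal_hazard = 0, span_days = 20,
                           n_missing_days = 0, search_window_k = 50,
                           seed = 3)
  sim <- simulate_marketplace(cfg)
  obs <- sim$panel$observations
  expect_true(all(obs$in_search))
  expect_true(all(obs$available))
  expect_equal(nrow(obs), 15 * 20)
  for (mode in c("search", "availability")) {
    s <- cohort_series(sim$panel, mode, start_day = 1)
    expect_equal(s$p, rep(1, 20))
  }
})

test_that("simulated panels respect conservation and truncation invariants", {
  cfg <- simulation_config(n_initial_apps = 40, arrival_rate = 1.5,
                           removal_hazard = 0.02, span_days = 50,
                           n_missing_days = 6, search_window_k = 25,
                           seed = 17)
  sim <- simulate_marketplace(cfg)
  obs <- sim$panel$observations
  truth <- sim$truth

  expect_true(all(obs$app_id %in% sim$registry$app_id))
  expect_identical(sim$registry$app_id, truth$app_id)

  # no observations outside [arrival, removal)
  m <- match(obs$app_id, truth$app_id)
  expect_true(all(obs$date >= truth$arrival_day[m]))
  removed <- !is.na(truth$removal_day[m])
  expect_true(all(obs$date[removed] < truth$removal_day[m][removed]))
  expect_true(all(is.na(truth$removal_day) |
                    truth$removal_day > truth$arrival_day))

  # per day, in-search count = min(K, alive count)
  for (d in sim$panel$observed_days) {
    alive <- sum(truth$arrival_day <= d &
                   (is.na(truth$removal_day) | d < truth$removal_day))
    expect_equal(sum(obs$in_search[obs$date == d]), min(25, alive))
  }

  # download buckets only appear on Android and are valid labels
  expect_true(all(!is.na(obs$download_bucket)))
  ios <- simulate_marketplace(simulation_config(
    n_initial_apps = 10, span_days = 10, n_missing_days = 0,
    platform = "ios", search_window_k = 200, seed = 5))
  expect_true(all(is.na(ios$panel$observations$download_bucket)))
})

test_that("constant-hazard survival matches the geometric law", {
  # n=1000, h=0.01, no arrivals: availability on day 200 ~ 0.99^199
  fractions <- vapply(1:10, function(seed) {
    sim <- simulate_marketplace(simulation_config(
      n_initial_apps = 1000, arrival_rate = 0, removal_hazard = 0.01,
      span_days = 200, n_missing_days = 0, search_window_k = 1000,
      review_rate = 0, download_rate = 0, seed = seed))
    obs <- sim$panel$observations
    sum(obs$date == 200) / 1000
  }, 0)
  expected <- 0.99^199
  mc_se <- sqrt(expected * (1 - expected) / 1000) / sqrt(10)
  expect_lt(abs(mean(fractions) - expected), 3 * mc_se)
})

test_that("empirical removal rate recovers the configured hazard", {
  h <- 0.02
  sim <- simulate_marketplace(simulation_config(
    n_initial_apps = 1500, arrival_rate = 0, removal_hazard = h,
    span_days = 60, n_missing_days = 0, search_window_k = 1500,
    review_rate = 0, download_rate = 0, seed = 21))
  truth <- sim$truth
  span <- 60
  removed <- !is.na(truth$removal_day) & truth$removal_day <= span + 1
  trials <- ifelse(removed, truth$removal_day - truth$arrival_day,
                   span - truth$arrival_day + 1)
  h_hat <- sum(removed) / sum(trials)
  se <- sqrt(h * (1 - h) / sum(trials))
  expect_lt(abs(h_hat - h), 3 * se)
})

test_that("masking removes exactly n days, never day 1, span unchanged", {
  cfg <- simulation_config(n_initial_apps = 8, arrival_rate = 0,
                           removal_hazard = 0, span_days = 246,
                           n_missing_days = 0, search_window_k = 10,
                           seed = 2)
  full <- simulate_marketplace(cfg)$panel

  expect_identical(mask_missing_days(full, 0), full)

  masked <- mask_missing_days(full, 35, seed = 8)
  expect_length(observed_days(masked), 211)
  expect_equal(masked$span_days, 246)
  expect_true(1L %in% observed_days(masked))

  # repeated masking under a seed is deterministic
  expect_identical(mask_missing_days(full, 35, seed = 8), masked)

  # boundary: all but day 1 masked
  small <- simulate_marketplace(simulation_config(
    n_initial_apps = 3, arrival_rate = 0, removal_hazard = 0,
    span_days = 6, n_missing_days = 0, search_window_k = 5, seed = 2))$panel
  only1 <- mask_missing_days(small, 5, seed = 1)
  expect_equal(observed_days(only1), 1L)
  expect_error(mask_missing_days(small, 6, seed = 1), "smaller")
})

test_that("generated descriptions carry claims at the configured rate", {
  base_cfg <- function(cf) simulation_config(
    n_initial_apps = 1000, arrival_rate = 0, removal_hazard = 0,
    span_days = 2, n_missing_days = 0, search_window_k = 1000,
    relevance_fraction = 1, claim_fraction = cf, review_rate = 0,
    download_rate = 0, seed = 31)

  all_claim <- simulate_marketplace(base_cfg(1))$registry
  all_claim <- screen_claims(all_claim)
  expect_true(all(all_claim$claim_match))
  expect_true(all(all_claim$claim_truth))

  none <- screen_claims(simulate_marketplace(base_cfg(0))$registry)
  expect_false(any(none$claim_match))

  some <- simulate_marketplace(base_cfg(0.3))$registry
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(mean(some$claim_truth) - 0.3), 3 * se)
  # filter agrees exactly with ground truth on synthetic text
  some <- screen_claims(some)
  expect_identical(some$claim_match, some$claim_truth)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(simulation_config(removal_hazard = 1.5), "removal_hazard")
  expect_error(simulation_config(relevance_fraction = -0.1),
               "relevance_fraction")
  expect_error(simulation_config(span_days = 0), "span_days")
  expect_error(simulation_config(n_missing_days = 246, span_days = 246),
               "n_missing_days")
  expect_error(simulation_config(removal_hazard = c(a = 0.1, b = 0.2)),
               "relevant")
})
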