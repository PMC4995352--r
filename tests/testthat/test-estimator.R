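test_that("cohort series reproduce the hand-counted worked example", {
  p <- fixture_f()
  s1 <- cohort_series(p, "search", start_day = 1)
  expect_equal(s1$baseline, c("a", "b", "c", "d"))
  expect_equal(s1$offsets, 1:6)
  expect_equal(s1$p, c(1, 0.75, 0.5, 0.5, 0.25, 0.25))

  s2 <- cohort_series(p, "search", start_day = 2)
  expect_equal(s2$baseline, c("a", "b", "c"))
  expect_equal(s2$p, c(1, 2/3, 2/3, 1/3, 1/3))

  # every fixture app stays downloadable, so availability mode is flat
  a1 <- cohort_series(p, "availability", start_day = 1)
  expect_equal(a1$p, rep(1, 6))
  expect_true(all(a1$p >= s1$p))

  expect_error(cohort_series(p, "search", start_day = 10),
               "not an observed day")
  empty_day <- panel_from_sets(list("a", character(0), "a"))
  expect_error(cohort_series(empty_day, "search", start_day = 2),
               "empty cohort")
})

test_that("averaging matches the hand-computed curve and support rule", {
  p <- fixture_f()
  series <- list(cohort_series(p, "search", 1),
                 cohort_series(p, "search", 2))
  cv <- average_series(series, min_series = 1)
  expect_equal(cv$offsets, 1:6)
  expect_equal(cv$p,
               c(1, (0.75 + 2/3) / 2, (0.5 + 2/3) / 2, (0.5 + 1/3) / 2,
                 (0.25 + 1/3) / 2, 0.25))
  expect_equal(round(cv$p, 4),
               c(1, 0.7083, 0.5833, 0.4167, 0.2917, 0.25))
  expect_equal(cv$support, c(2, 2, 2, 2, 2, 1))

  # support rule: offset 6 has one contributing series only
  cv2 <- average_series(series, min_series = 2)
  expect_equal(cv2$offsets, 1:5)

  # mean of identical series is the series itself
  cv3 <- average_series(rep(list(series[[1]]), 25), min_series = 20)
  expect_equal(cv3$p, series[[1]]$p)

  expect_error(average_series(list()), "at least one")
  mixed <- list(cohort_series(p, "search", 1),
                cohort_series(p, "availability", 1))
  expect_error(average_series(mixed), "one mode")
})

test_that("half-life is the first strict drop below 50%, else censored", {
  p <- fixture_f()
  cv <- average_series(list(cohort_series(p, "search", 1),
                            cohort_series(p, "search", 2)),
                       min_series = 1)
  hl <- half_life(cv)
  expect_false(hl$censored)
  expect_equal(hl$half_life_days, 4)
  expect_equal(hl$remaining_at_end, 0.25)
  expect_equal(hl$last_offset, 6)

  flat <- structure(list(mode = "search", offsets = 1:100,
                         p = rep(1, 100), support = rep(30L, 100),
                         min_series = 20L, n_series = 30L),
                    class = "averaged_curve")
  hl2 <- half_life(flat)
  expect_true(hl2$censored)
  expect_true(is.na(hl2$half_life_days))
  expect_equal(hl2$remaining_at_end, 1)

  # P(3) = 0.5 exactly does not cross; 0.49 at offset 4 does
  edge <- structure(list(mode = "search", offsets = 1:4,
                         p = c(1, 0.8, 0.5, 0.49), support = rep(20L, 4),
                         min_series = 20L, n_series = 20L),
                    class = "averaged_curve")
  expect_equal(half_life(edge)$half_life_days, 4)

  empty <- structure(list(mode = "search", offsets = integer(0),
                          p = numeric(0), support = integer(0),
                          min_series = 20L, n_series = 2L),
                     class = "averaged_curve")
  expect_error(half_life(empty), "no defined offsets")
})

test_that("estimator agrees exactly with brute-force enumeration", {
  for (seed in 1:6) {
    p <- random_panel(seed, n_apps = 8, n_days = 12)
    for (mode in c("search", "availability")) {
      for (ms in c(1, 3)) {
        got <- estimate_half_life(p, mode, min_series = ms)
        want <- oracle_estimate(p, mode, min_series = ms)
        expect_equal(got$curve$offsets, want$curve$offsets)
        expect_equal(got$curve$p, want$curve$p)
        expect_equal(got$curve$support, want$curve$support)
        expect_equal(got$half_life_days, want$half_life_days)
        expect_equal(got$censored, want$censored)
        expect_equal(got$remaining_at_end, want$remaining_at_end)
      }
    }
  }
})

test_that("averaged curve lies within the envelope of its series", {
  for (seed in 7:9) {
    p <- random_panel(seed, n_apps = 10, n_days = 14)
    mats_days <- observed_days(p)
    series <- list()
    for (s in mats_days) {
      sr <- tryCatch(cohort_series(p, "search", s),
                     error = function(e) NULL)
      if (!is.null(sr)) series[[length(series) + 1L]] <- sr
    }
    cv <- average_series(series, min_series = 1)
    for (i in seq_along(cv$offsets)) {
      t <- cv$offsets[i]
      vals <- unlist(lapply(series, function(sr) sr$p[sr$offsets == t]))
      expect_gte(cv$p[i], min(vals) - 1e-12)
      expect_lte(cv$p[i], max(vals) + 1e-12)
    }
    expect_equal(cv$p[1], 1)   # every cohort starts at exactly 1
  }
})

test_that("availability dominates search pointwise and in half-life", {
  for (seed in 1:5) {
    sim <- simulate_marketplace(simulation_config(
      n_initial_apps = 30, arrival_rate = 0.5, removal_hazard = 0.03,
      span_days = 40, n_missing_days = 4, search_window_k = 15,
      seed = seed))
    s <- estimate_half_life(sim$panel, "search", min_series = 5)
    a <- estimate_half_life(sim$panel, "availability", min_series = 5)
    common <- intersect(s$curve$offsets, a$curve$offsets)
    expect_true(all(
      a$curve$p[match(common, a$curve$offsets)] >=
        s$curve$p[match(common, s$curve$offsets)] - 1e-12))
    expect_gte(halflife_value(a), halflife_value(s))
  }
})

test_that("when the window never truncates, both modes coincide", {
  sim <- simulate_marketplace(simulation_config(
    n_initial_apps = 25, arrival_rate = 0.5, removal_hazard = 0.03,
    span_days = 30, n_missing_days = 0, search_window_k = 1000,
    seed = 12))
  s <- estimate_half_life(sim$panel, "search", min_series = 3)
  a <- estimate_half_life(sim$panel, "availability", min_series = 3)
  expect_equal(s$curve$p, a$curve$p)
  expect_equal(halflife_value(s), halflife_value(a))
})

test_that("absorbing mode never exceeds the per-day series", {
  p <- panel_from_sets(list(c("a", "b"), "a", c("a", "b"), "b"))
  free <- cohort_series(p, "search", 1)
  abs_ <- cohort_series(p, "search", 1, absorbing = TRUE)
  expect_equal(free$p, c(1, 0.5, 1, 0.5))
  expect_equal(abs_$p, c(1, 0.5, 0.5, 0))   # b re-enters, a is gone
  expect_true(all(abs_$p <= free$p))
  expect_true(all(diff(abs_$p) <= 0))
})

test_that("removal interval reproduces the published arithmetic", {
  expect_equal(removal_interval(197, 0.659, 246), 3.7)
  expect_equal(removal_interval(c(197, 150), c(0.659, 0.878), 246), 2.9)
  expect_equal(removal_interval(100, 0.5, 100), 2.0)
  expect_error(removal_interval(100, 1.0, 246), "no removals")
  expect_error(removal_interval(0, 0.5, 246), "positive")
  expect_error(removal_interval(100, 1.2, 246), "frac_remaining")
  expect_error(removal_interval(c(10, 10), 0.5, 100), "equal length")
})
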