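# Fixture builders shared across the suite. Everything is generated in
# code; no files are read.

# One observation row with sensible defaults.
obs_row <- function(date, app_id, platform = "ios", in_search = TRUE,
                    rank = if (in_search) 1L else NA_integer_,
                    available = TRUE, version = "1.0",
                    star_rating = NA_real_, n_reviews = 0L,
                    download_bucket = NA_character_) {
  data.frame(date = date, app_id = app_id, platform = platform,
             in_search = in_search, rank = rank, available = available,
             version = version, star_rating = star_rating,
             n_reviews = n_reviews, download_bucket = download_bucket,
             stringsAsFactors = FALSE)
}

# Build a panel from per-day search-result sets; every app in `apps` is
# available on every day (rows present), only set members are in search.
panel_from_sets <- function(sets, apps = sort(unique(unlist(sets))),
                            platform = "ios", keyword = "fixture") {
  rows <- do.call(rbind, lapply(seq_along(sets), function(d) {
    present <- apps %in% sets[[d]]
    obs_row(date = d, app_id = apps, platform = platform,
            in_search = present,
            rank = ifelse(present, match(apps, sets[[d]]), NA_integer_))
  }))
  snapshot_panel(rows, platform = platform, keyword = keyword)
}

# The six-day, four-app worked example used throughout the estimator
# tests: search sets shrink {a,b,c,d} -> {a} while all apps stay
# downloadable.
fixture_f <- function() {
  panel_from_sets(list(c("a", "b", "c", "d"), c("a", "b", "c"),
                       c("a", "b"), c("a", "b"), "a", "a"))
}

# Random small panel with valid invariants: each (app, day) is absent,
# available-only, or in the search results; some days may be unobserved.
random_panel <- function(seed, n_apps = 8, n_days = 12,
                         p_absent = 0.15, p_search = 0.6,
                         platform = "ios", drop_days = TRUE) {
  set.seed(seed)
  apps <- sprintf("app%02d", seq_len(n_apps))
  days <- seq_len(n_days)
  if (drop_days && n_days > 2) {
    days <- sort(c(1L, sample(2:n_days, max(1L, n_days - 1L -
                                              stats::rbinom(1, 2, 0.7)))))
  }
  rows <- list()
  for (d in days) {
    u <- stats::runif(n_apps)
    state <- ifelse(u < p_absent, "absent",
                    ifelse(u < p_absent + p_search, "search", "avail"))
    in_s <- which(state == "search")
    keep <- which(state != "absent")
    if (!length(keep)) next
    rank <- rep(NA_integer_, n_apps)
    rank[in_s] <- sample.int(length(in_s))
    rows[[length(rows) + 1L]] <-
      obs_row(date = d, app_id = apps[keep], platform = platform,
              in_search = state[keep] == "search", rank = rank[keep])
  }
  snapshot_panel(do.call(rbind, rows), platform = platform,
                 keyword = "random", observed_days = days,
                 span_days = n_days)
}

# Two-class marketplace built directly in code: `n_top` immortal apps
# that always hold the top ranks, plus `n_bottom` mortal apps with a
# constant per-day removal hazard. All alive apps are in the search
# results (no truncation).
two_class_panel <- function(seed, n_top = 25, n_bottom = 100,
                            hazard = 0.05, span = 25) {
  set.seed(seed)
  top_ids <- sprintf("top%03d", seq_len(n_top))
  bot_ids <- sprintf("zzz%03d", seq_len(n_bottom))
  bot_life <- 1L + stats::rgeom(n_bottom, hazard)   # alive days
  rows <- list()
  for (d in seq_len(span)) {
    alive_bot <- bot_ids[bot_life >= d]
    ids <- c(top_ids, alive_bot)
    rows[[d]] <- obs_row(date = d, app_id = ids, platform = "ios",
                         in_search = TRUE, rank = seq_along(ids))
  }
  snapshot_panel(do.call(rbind, rows), platform = "ios",
                 keyword = "two-class")
}

halflife_value <- function(res) {
  if (res$censored) Inf else res$half_life_days
}
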