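# Independent brute-force oracle for the shifted-cohort estimator.
# Works row-by-row on the raw observation table with naive loops and no
# shared code with the package implementation.

oracle_predicate <- function(obs, app, day, mode) {
  r <- obs[obs$app_id == app & obs$date == day, , drop = FALSE]
  if (nrow(r) == 0L) return(FALSE)
  if (mode == "search") isTRUE(r$in_search) else isTRUE(r$available)
}

# All cohort series of a panel: one per observed start day with a
# non-empty baseline.
oracle_series <- function(panel, mode) {
  obs <- panel$observations
  days <- sort(panel$observed_days)
  out <- list()
  for (s in days) {
    baseline <- obs$app_id[obs$date == s & obs$in_search]
    if (length(baseline) == 0L) next
    offsets <- integer(0)
    p <- numeric(0)
    for (d in days[days >= s]) {
      n_present <- 0L
      for (a in baseline) {
        if (oracle_predicate(obs, a, d, mode)) n_present <- n_present + 1L
      }
      offsets <- c(offsets, d - s + 1L)
      p <- c(p, n_present / length(baseline))
    }
    out[[length(out) + 1L]] <-
      list(start_day = s, offsets = offsets, p = p)
  }
  out
}

oracle_average <- function(series, min_series) {
  max_offset <- 0L
  for (s in series) max_offset <- max(max_offset, max(s$offsets))
  offsets <- integer(0)
  p <- numeric(0)
  support <- integer(0)
  for (t in seq_len(max_offset)) {
    vals <- numeric(0)
    for (s in series) {
      hit <- which(s$offsets == t)
      if (length(hit)) vals <- c(vals, s$p[hit])
    }
    if (length(vals) >= min_series) {
      offsets <- c(offsets, t)
      p <- c(p, mean(vals))
      support <- c(support, length(vals))
    }
  }
  list(offsets = offsets, p = p, support = support)
}

oracle_half_life <- function(avg) {
  hl <- NA_integer_
  for (i in seq_along(avg$offsets)) {
    if (avg$p[i] < 0.5) {
      hl <- avg$offsets[i]
      break
    }
  }
  list(half_life_days = hl, censored = is.na(hl),
       remaining_at_end = avg$p[length(avg$p)])
}

oracle_estimate <- function(panel, mode, min_series) {
  avg <- oracle_average(oracle_series(panel, mode), min_series)
  c(oracle_half_life(avg), list(curve = avg))
}
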