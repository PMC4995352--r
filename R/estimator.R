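# Shifted-cohort survival estimator for search-result and app half-lives.
#
# The estimator works on presence matrices (apps x observed days) so that
# every cohort reduces to column means of a row subset; the exported
# operations rebuild the matrices per call, while estimate_half_life()
# builds them once and reuses them across all start-day cohorts.

# Build logical (apps x observed days) matrices from a panel.
presence_matrices <- function(panel) {
  obs <- panel$observations
  days <- sort(panel$observed_days)
  apps <- sort(unique(obs$app_id))
  in_search <- matrix(FALSE, length(apps), length(days),
                      dimnames = list(apps, days))
  available <- in_search
  i <- match(obs$app_id, apps)
  j <- match(obs$date, days)
  in_search[cbind(i, j)] <- obs$in_search
  available[cbind(i, j)] <- obs$available
  list(apps = apps, days = days, in_search = in_search,
       available = available)
}

mode_matrix <- function(mats, mode) {
  switch(mode, search = mats$in_search, availability = mats$available)
}

# Core cohort computation shared by cohort_series() and
# estimate_half_life(): proportion of the baseline satisfying the mode
# predicate on each observed day >= start_day.
cohort_points <- function(mats, mode, start_day, absorbing = FALSE,
                          restrict_ids = NULL) {
  jstart <- match(start_day, mats$days)
  if (is.na(jstart)) {
    stop("start_day ", start_day, " is not an observed day", call. = FALSE)
  }
  baseline <- mats$apps[mats$in_search[, jstart]]
  if (!is.null(restrict_ids)) baseline <- intersect(baseline, restrict_ids)
  if (!length(baseline)) return(NULL)
  cols <- jstart:length(mats$days)
  sub <- mode_matrix(mats, mode)[match(baseline, mats$apps), cols,
                                 drop = FALSE]
  if (absorbing && ncol(sub) > 1L) {
    for (j in seq_len(ncol(sub))[-1L]) {
      sub[, j] <- sub[, j] & sub[, j - 1L]
    }
  }
  list(
    baseline = baseline,
    # offsets count calendar days: the start day is offset 1, and a
    # missing calendar day simply contributes no point
    offsets = mats$days[cols] - start_day + 1L,
    p = unname(colMeans(sub))
  )
}

#' Survival series of one start-day cohort
#'
#' The cohort of a start day s is the set of apps appearing in the keyword
#' search results on day s (the baseline). For every observed day at or
#' after s, the series records the proportion of the baseline still
#' satisfying the mode predicate: `"search"` counts apps still in the
#' search results, `"availability"` counts apps still available to
#' download (found either in the results or by the per-app fallback
#' search). Presence is evaluated day by day, so a series need not be
#' monotone: apps may drop out of the results and later re-enter.
#'
#' Offsets count calendar days with the start day as offset 1; unobserved
#' days contribute no point.
#'
#' @param panel a [snapshot_panel()].
#' @param mode `"search"` or `"availability"`.
#' @param start_day an observed study day with a non-empty baseline.
#' @param absorbing if `TRUE`, an app that once fails the predicate counts
#'   as absent ever after (once-gone-always-gone sensitivity analysis).
#' @return object of class `survival_series` with fields `start_day`,
#'   `mode`, `baseline`, `offsets`, `p`.
#' @export
cohort_series <- function(panel, mode = c("search", "availability"),
                          start_day, absorbing = FALSE) {
  stopifnot(inherits(panel, "snapshot_panel"))
  mode <- match.arg(mode)
  mats <- presence_matrices(panel)
  pts <- cohort_points(mats, mode, start_day, absorbing = absorbing)
  if (is.null(pts)) {
    stop("empty cohort: no apps in search results on day ", start_day,
         call. = FALSE)
  }
  structure(list(start_day = as.integer(start_day), mode = mode,
                 baseline = pts$baseline, offsets = pts$offsets,
                 p = pts$p),
            class = "survival_series")
}

#' @export
print.survival_series <- function(x, ...) {
  cat(sprintf(
    "<survival_series> mode=%s start_day=%d baseline=%d apps, %d points\n",
    x$mode, x$start_day, length(x$baseline), length(x$offsets)))
  invisible(x)
}

#' Average shifted cohort series
#'
#' Aligns every cohort series to a common origin (its start day becomes
#' offset 1) and takes, at each offset, the unweighted arithmetic mean of
#' the proportions over the series that have a point there. The mean is
#' reported only at offsets where at least `min_series` series contribute;
#' this minimum-support rule suppresses noisy tail averages built from a
#' handful of late cohorts.
#'
#' @param series_list list of [cohort_series()] results sharing one mode.
#' @param min_series minimum number of contributing series per offset
#'   (default 20).
#' @return object of class `averaged_curve` with defined `offsets`, mean
#'   proportions `p`, per-offset `support`, and `n_series`.
#' @export
average_series <- function(series_list, min_series = 20L) {
  if (!length(series_list)) {
    stop("series_list must contain at least one series", call. = FALSE)
  }
  if (min_series < 1L) stop("min_series must be >= 1", call. = FALSE)
  modes <- unique(vapply(series_list, `[[`, "", "mode"))
  if (length(modes) != 1L) {
    stop("all series must share one mode; got: ",
         paste(modes, collapse = ", "), call. = FALSE)
  }
  max_offset <- max(vapply(series_list,
                           function(s) as.integer(max(s$offsets)), 0L))
  total <- numeric(max_offset)
  support <- integer(max_offset)
  for (s in series_list) {
    total[s$offsets] <- total[s$offsets] + s$p
    support[s$offsets] <- support[s$offsets] + 1L
  }
  defined <- which(support >= min_series)
  structure(list(mode = modes, offsets = defined,
                 p = total[defined] / support[defined],
                 support = support[defined],
                 min_series = as.integer(min_series),
                 n_series = length(series_list)),
            class = "averaged_curve")
}

#' @export
print.averaged_curve <- function(x, ...) {
  cat(sprintf(
    "<averaged_curve> mode=%s: %d series, %d defined offsets (min_series=%d)\n",
    x$mode, x$n_series, length(x$offsets), x$min_series))
  invisible(x)
}

#' Half-life of an averaged survival curve
#'
#' The half-life is the smallest defined offset at which the averaged
#' proportion drops strictly below 50%. If the curve never does within the
#' defined range, the half-life is censored and reported as exceeding the
#' study span. The proportion remaining at the end of the study is the
#' curve's value at its largest defined offset.
#'
#' @param curve an [average_series()] result with at least one defined
#'   offset.
#' @return object of class `half_life_result` with fields `mode`,
#'   `half_life_days` (`NA` when censored), `censored`,
#'   `remaining_at_end`, `last_offset`, `n_series`.
#' @export
half_life <- function(curve) {
  stopifnot(inherits(curve, "averaged_curve"))
  if (!length(curve$offsets)) {
    stop("averaged curve has no defined offsets", call. = FALSE)
  }
  below <- which(curve$p < 0.5)
  censored <- !length(below)
  structure(list(
    mode = curve$mode,
    half_life_days = if (censored) NA_integer_ else
      curve$offsets[below[1L]],
    censored = censored,
    remaining_at_end = curve$p[length(curve$p)],
    last_offset = curve$offsets[length(curve$offsets)],
    n_series = curve$n_series
  ), class = "half_life_result")
}

#' @export
print.half_life_result <- function(x, ...) {
  hl <- if (x$censored) paste0("> ", x$last_offset, " days (censored)")
        else paste0(x$half_life_days, " days")
  cat(sprintf(
    "<half_life_result> mode=%s: t1/2 = %s, %.1f%% remaining at offset %d (%d series)\n",
    x$mode, hl, 100 * x$remaining_at_end, x$last_offset, x$n_series))
  invisible(x)
}

#' Estimate a half-life from a panel
#'
#' Runs the full shifted-cohort procedure: starts a cohort on every
#' observed day whose baseline (search results that day, optionally
#' intersected with `restrict_ids`) is non-empty, aligns and averages the
#' series with the minimum-support rule, and locates the 50% crossing.
#'
#' @inheritParams cohort_series
#' @param min_series minimum contributing series per offset (default 20).
#' @param restrict_ids optional app-id set; cohort baselines are
#'   intersected with it (used for relevance and subgroup stratification).
#' @param start_days observed days on which to start cohorts; defaults to
#'   all observed days. Days with an empty baseline are skipped.
#' @return a `half_life_result` with the averaged curve attached as
#'   `$curve`.
#' @export
estimate_half_life <- function(panel, mode = c("search", "availability"),
                               min_series = 20L, absorbing = FALSE,
                               restrict_ids = NULL, start_days = NULL) {
  stopifnot(inherits(panel, "snapshot_panel"))
  mode <- match.arg(mode)
  mats <- presence_matrices(panel)
  if (is.null(start_days)) start_days <- mats$days
  series <- vector("list", length(start_days))
  kept <- 0L
  for (s in start_days) {
    pts <- cohort_points(mats, mode, s, absorbing = absorbing,
                         restrict_ids = restrict_ids)
    if (is.null(pts)) next
    kept <- kept + 1L
    series[[kept]] <- list(start_day = s, mode = mode,
                           offsets = pts$offsets, p = pts$p)
  }
  if (!kept) {
    stop("no start day has a non-empty cohort baseline", call. = FALSE)
  }
  curve <- average_series(series[seq_len(kept)], min_series = min_series)
  result <- half_life(curve)
  result$curve <- curve
  result
}

#' Removal interval from end-of-study survival
#'
#' Converts end-of-study remaining proportions into the headline "one app
#' disappearing every N days" figure: the study span divided by the total
#' number of apps removed, `sum(n_apps * (1 - frac_remaining))`, rounded
#' to one decimal. Supplying several cohorts (e.g. the two platforms)
#' pools their removals over the same span.
#'
#' @param n_apps apps in each cohort at baseline.
#' @param frac_remaining proportion of each cohort still available at the
#'   end of the study (0..1).
#' @param span_days study span in days.
#' @return days per removal, rounded to one decimal.
#' @examples
#' removal_interval(197, 0.659, 246)            # one platform
#' removal_interval(c(197, 150), c(0.659, 0.878), 246)  # pooled
#' @export
removal_interval <- function(n_apps, frac_remaining, span_days) {
  if (length(n_apps) != length(frac_remaining)) {
    stop("n_apps and frac_remaining must have equal length", call. = FALSE)
  }
  if (span_days <= 0) stop("span_days must be positive", call. = FALSE)
  if (any(n_apps <= 0)) stop("each n_apps must be positive", call. = FALSE)
  if (any(frac_remaining < 0 | frac_remaining > 1)) {
    stop("frac_remaining must lie in [0, 1]", call. = FALSE)
  }
  removed <- sum(n_apps * (1 - frac_remaining))
  if (removed == 0) {
    stop("removal interval undefined: no removals observed", call. = FALSE)
  }
  round(span_days / removed, 1)
}
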