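# Top/bottom subgroup analyses by store-visible metrics.

#' Specify a top/bottom subgroup by a store-visible metric
#'
#' @param metric one of `"rank"`, `"n_reviews"`, `"star_rating"`,
#'   `"download_bucket"` (Android only).
#' @param which `"top"` or `"bottom"`.
#' @param size subgroup size (default 25).
#' @return list of class `subgroup_spec`.
#' @export
subgroup_spec <- function(metric = c("rank", "n_reviews", "star_rating",
                                     "download_bucket"),
                          which = c("top", "bottom"), size = 25L) {
  metric <- match.arg(metric)
  which <- match.arg(which)
  size <- as.integer(size)
  if (size < 1L) stop("size must be >= 1", call. = FALSE)
  structure(list(metric = metric, which = which, size = size),
            class = "subgroup_spec")
}

# Metric values for in-search rows of one day; higher value = "top",
# so rank is negated (rank 1 is the top of the results).
metric_values <- function(rows, metric) {
  switch(metric,
         rank = -as.numeric(rows$rank),
         n_reviews = as.numeric(rows$n_reviews),
         star_rating = rows$star_rating,
         download_bucket = as.numeric(
           factor(rows$download_bucket, levels = DOWNLOAD_BUCKET_LABELS)))
}

#' Select a subgroup of the search results on one day
#'
#' Takes the apps appearing in the search results on `anchor_day`, orders
#' them by the metric (rank ascending for the top; review count, star
#' rating and download bucket descending for the top), breaks ties by app
#' id, and returns the first `size` ids. Apps lacking the metric that day
#' are ineligible. If fewer than `size` qualify, all are returned with a
#' warning.
#'
#' @param panel a [snapshot_panel()].
#' @param spec a [subgroup_spec()].
#' @param anchor_day observed day at which membership is taken.
#' @return character vector of app ids.
#' @export
select_subgroup <- function(panel, spec, anchor_day = 1L) {
  stopifnot(inherits(panel, "snapshot_panel"),
            inherits(spec, "subgroup_spec"))
  if (!anchor_day %in% panel$observed_days) {
    stop("anchor_day ", anchor_day, " is not an observed day",
         call. = FALSE)
  }
  if (spec$metric == "download_bucket" && panel$platform != "android") {
    stop("download_bucket subgroups require an Android panel",
         call. = FALSE)
  }
  rows <- panel$observations[panel$observations$date == anchor_day &
                               panel$observations$in_search, , drop = FALSE]
  vals <- metric_values(rows, spec$metric)
  rows <- rows[!is.na(vals), , drop = FALSE]
  vals <- vals[!is.na(vals)]
  if (!nrow(rows)) {
    stop("empty subgroup: no app in the day-", anchor_day,
         " search results has metric `", spec$metric, "`", call. = FALSE)
  }
  if (spec$which == "bottom") vals <- -vals
  ord <- order(-vals, rows$app_id)
  if (nrow(rows) < spec$size) {
    warning("only ", nrow(rows), " eligible apps for subgroup of size ",
            spec$size, " on day ", anchor_day, "; returning all",
            call. = FALSE)
  }
  rows$app_id[ord[seq_len(min(spec$size, nrow(rows)))]]
}

#' Half-life of a metric-defined subgroup
#'
#' Re-runs the shifted-cohort estimator with each cohort's baseline
#' intersected with the subgroup. By default membership is re-anchored at
#' each cohort's own start day, so every averaged series compares
#' like-for-like snapshots (e.g. "the top 25 of that day's results");
#' passing `freeze_day` instead fixes membership at one day for all
#' cohorts. Start days where the intersection is empty simply contribute
#' no series.
#'
#' @inheritParams estimate_half_life
#' @param spec a [subgroup_spec()].
#' @param freeze_day if non-`NULL`, the single observed day at which
#'   membership is selected for every cohort.
#' @return a `half_life_result` (with `$curve`); its `n_series` records
#'   how many cohorts contributed.
#' @export
subgroup_halflife <- function(panel, spec,
                              mode = c("search", "availability"),
                              min_series = 20L, absorbing = FALSE,
                              freeze_day = NULL) {
  stopifnot(inherits(panel, "snapshot_panel"),
            inherits(spec, "subgroup_spec"))
  mode <- match.arg(mode)
  mats <- presence_matrices(panel)
  days <- mats$days
  frozen <- if (!is.null(freeze_day)) {
    select_subgroup(panel, spec, anchor_day = freeze_day)
  }
  series <- list()
  for (s in days) {
    members <- if (is.null(freeze_day)) {
      tryCatch(suppressWarnings(select_subgroup(panel, spec,
                                                anchor_day = s)),
               error = function(e) NULL)
    } else frozen
    if (is.null(members)) next
    pts <- cohort_points(mats, mode, s, absorbing = absorbing,
                         restrict_ids = members)
    if (is.null(pts)) next
    series[[length(series) + 1L]] <-
      list(start_day = s, mode = mode, offsets = pts$offsets, p = pts$p)
  }
  if (!length(series)) {
    stop("no start day yields a non-empty subgroup baseline",
         call. = FALSE)
  }
  curve <- average_series(series, min_series = min_series)
  result <- half_life(curve)
  result$curve <- curve
  result$subgroup <- spec
  result
}
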