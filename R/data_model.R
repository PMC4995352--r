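#' @keywords internal
"_PACKAGE"

# Column order of the panel CSV; fixed so files round-trip byte-stably.
PANEL_COLUMNS <- c(
  "date", "app_id", "platform", "in_search", "rank", "available",
  "version", "star_rating", "n_reviews", "download_bucket"
)

PLATFORMS <- c("android", "ios")

# Download count buckets reported by the Android store, as half-open
# intervals [lo, hi) so that boundary counts fall in exactly one bucket.
DOWNLOAD_BUCKET_BREAKS <- c(0, 50, 100, 500, 1000, 5000, 10000, 50000,
                            250000, Inf)
DOWNLOAD_BUCKET_LABELS <- c(
  "<50", "50-100", "100-500", "500-1000", "1000-5000", "5000-10000",
  "10000-50000", "50000-250000", ">250000"
)

#' Construct a validated daily snapshot panel
#'
#' A snapshot panel is the longitudinal observation table produced by
#' searching an app store for one keyword once per day: one row per
#' (study day, app) pair, recording whether the app appeared in the
#' keyword search results (and at what rank), whether it was still
#' available to download (established by a per-app fallback search when it
#' left the results), plus store-visible metadata (version, star rating,
#' review count, and on Android a download-count bucket).
#'
#' Days are 1-based integer study-day indices: the first search is day 1.
#' Days on which no data were collected are simply absent from
#' `observed_days`; the explicit manifest keeps "no data that day"
#' distinguishable from "no apps that day".
#'
#' @param observations data frame with columns `date`, `app_id`,
#'   `platform`, `in_search`, `rank`, `available`, `version`,
#'   `star_rating`, `n_reviews`, `download_bucket`. Absent values are `NA`.
#' @param platform `"android"` or `"ios"`.
#' @param keyword the search term the panel tracks.
#' @param observed_days integer vector of study days with data; defaults to
#'   the days present in `observations`.
#' @param span_days total calendar span of the study (observed plus
#'   missing days); defaults to `max(observed_days)`.
#' @return an object of class `snapshot_panel`.
#' @examples
#' obs <- data.frame(date = 1L, app_id = "a", platform = "android",
#'                   in_search = TRUE, rank = 1L, available = TRUE,
#'                   version = "1.0", star_rating = NA_real_,
#'                   n_reviews = 0L, download_bucket = NA_character_)
#' snapshot_panel(obs, platform = "android", keyword = "depression")
#' @export
snapshot_panel <- function(observations, platform, keyword = "",
                           observed_days = NULL, span_days = NULL) {
  observations <- as_observation_frame(observations)
  platform <- match.arg(platform, PLATFORMS)
  if (is.null(observed_days)) {
    observed_days <- sort(unique(observations$date))
  }
  observed_days <- as.integer(observed_days)
  if (is.null(span_days)) {
    span_days <- if (length(observed_days)) max(observed_days) else 0L
  }
  span_days <- as.integer(span_days)
  panel <- structure(
    list(
      observations = observations,
      platform = platform,
      keyword = as.character(keyword),
      observed_days = observed_days,
      span_days = span_days
    ),
    class = "snapshot_panel"
  )
  validate_panel(panel)
  panel
}

# Coerce a raw data frame to the canonical observation column types.
as_observation_frame <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(PANEL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    date = as.integer(df$date),
    app_id = as.character(df$app_id),
    platform = as.character(df$platform),
    in_search = as.logical(df$in_search),
    rank = as.integer(df$rank),
    available = as.logical(df$available),
    version = as.character(df$version),
    star_rating = as.numeric(df$star_rating),
    n_reviews = as.integer(df$n_reviews),
    download_bucket = as.character(df$download_bucket),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Validate a snapshot panel's invariants
#'
#' Checks every structural invariant of the panel: unique (date, app_id)
#' keys; observation dates within the observed-day manifest; search
#' presence implying download availability; ranks present exactly for
#' in-search rows and distinct within each day; star ratings in \[1, 5\];
#' non-negative review counts; download buckets only on Android.
#' Violations raise an error naming the offending rows; valid panels are
#' returned invisibly.
#'
#' @param panel a `snapshot_panel`.
#' @param k optional search-window size; if given, each day may contain at
#'   most `k` in-search rows and no rank may exceed `k`.
#' @return the panel, invisibly.
#' @export
validate_panel <- function(panel, k = NULL) {
  stopifnot(inherits(panel, "snapshot_panel"))
  obs <- panel$observations

  if (anyNA(obs$date) || any(obs$date < 1L)) {
    stop("observation dates must be positive study-day indices",
         call. = FALSE)
  }
  if (anyNA(obs$app_id) || any(!nzchar(obs$app_id))) {
    stop("app_id must be non-empty", call. = FALSE)
  }

  key <- paste(obs$date, obs$app_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (date, app_id) observation(s): ",
         paste(unique(sprintf("(day %d, %s)", obs$date[dup],
                              obs$app_id[dup])), collapse = ", "),
         call. = FALSE)
  }

  bad_day <- setdiff(unique(obs$date), panel$observed_days)
  if (length(bad_day)) {
    stop("observations on day(s) outside observed_days: ",
         paste(sort(bad_day), collapse = ", "), call. = FALSE)
  }
  if (any(panel$observed_days < 1L) ||
      any(panel$observed_days > panel$span_days)) {
    stop("observed_days must lie within 1..span_days", call. = FALSE)
  }
  if (anyDuplicated(panel$observed_days)) {
    stop("observed_days must be distinct", call. = FALSE)
  }

  bad_platform <- !obs$platform %in% PLATFORMS
  if (any(bad_platform)) {
    stop("unknown platform value(s): ",
         paste(unique(obs$platform[bad_platform]), collapse = ", "),
         call. = FALSE)
  }

  # An app in the search results is by definition downloadable.
  ghost <- obs$in_search & !obs$available
  if (any(ghost)) {
    stop("in_search=TRUE with available=FALSE for: ",
         paste(sprintf("(day %d, %s)", obs$date[ghost], obs$app_id[ghost]),
               collapse = ", "), call. = FALSE)
  }

  rank_mismatch <- xor(obs$in_search, !is.na(obs$rank))
  if (any(rank_mismatch)) {
    stop("rank must be present exactly when in_search=TRUE; offending: ",
         paste(sprintf("(day %d, %s)", obs$date[rank_mismatch],
                       obs$app_id[rank_mismatch]), collapse = ", "),
         call. = FALSE)
  }
  if (any(obs$rank < 1L, na.rm = TRUE)) {
    stop("ranks must be positive", call. = FALSE)
  }

  in_s <- obs[obs$in_search, , drop = FALSE]
  if (nrow(in_s)) {
    rank_key <- paste(in_s$date, in_s$rank, sep = "\r")
    if (anyDuplicated(rank_key)) {
      d <- in_s$date[duplicated(rank_key)]
      stop("duplicate ranks within day(s): ",
           paste(sort(unique(d)), collapse = ", "), call. = FALSE)
    }
  }

  if (!is.null(k)) {
    per_day <- table(in_s$date)
    if (any(per_day > k)) {
      stop("more than k=", k, " in-search apps on day(s): ",
           paste(names(per_day)[per_day > k], collapse = ", "),
           call. = FALSE)
    }
    if (any(in_s$rank > k)) {
      stop("rank exceeds search window k=", k, call. = FALSE)
    }
  }

  bad_rating <- !is.na(obs$star_rating) &
    (obs$star_rating < 1 | obs$star_rating > 5)
  if (any(bad_rating)) {
    stop("star_rating must lie in [1, 5]", call. = FALSE)
  }
  if (any(obs$n_reviews < 0L, na.rm = TRUE)) {
    stop("n_reviews must be non-negative", call. = FALSE)
  }

  bad_bucket_platform <- !is.na(obs$download_bucket) &
    obs$platform != "android"
  if (any(bad_bucket_platform)) {
    stop("download_bucket is recorded for Android apps only", call. = FALSE)
  }
  bad_bucket <- !is.na(obs$download_bucket) &
    !obs$download_bucket %in% DOWNLOAD_BUCKET_LABELS
  if (any(bad_bucket)) {
    stop("unknown download_bucket label(s): ",
         paste(unique(obs$download_bucket[bad_bucket]), collapse = ", "),
         call. = FALSE)
  }

  invisible(panel)
}

#' Study days with data
#'
#' Returns the ordered study-day indices on which the store was actually
#' observed. Days lost to collection failures are absent, so the length is
#' `span_days` minus the number of missing days.
#'
#' @param panel a `snapshot_panel`.
#' @return sorted integer vector of observed study days.
#' @export
observed_days <- function(panel) {
  stopifnot(inherits(panel, "snapshot_panel"))
  sort(panel$observed_days)
}

#' @export
print.snapshot_panel <- function(x, ...) {
  cat(sprintf(
    "<snapshot_panel> keyword=%s platform=%s\n  %d observations, %d apps, %d/%d days observed\n",
    if (nzchar(x$keyword)) dQuote(x$keyword, q = FALSE) else "<none>",
    x$platform, nrow(x$observations),
    length(unique(x$observations$app_id)),
    length(x$observed_days), x$span_days
  ))
  invisible(x)
}

#' Construct an app registry
#'
#' The registry carries per-app static metadata: the stable package/bundle
#' identifier (constant across renames), platform, dated display names,
#' the store description, optional dual-reviewer relevance labels with
#' consensus, and the result of the effectiveness-claim keyword filter.
#'
#' @param app_id character vector of unique, non-empty identifiers.
#' @param platform platform per app (recycled if length 1).
#' @param names list column: per app, a data frame with columns `date` and
#'   `name` ordered by date. Defaults to a single name equal to the id.
#' @param description store description text per app.
#' @param reviewer_labels optional list column of length-2 logical vectors
#'   (relevance per reviewer), `NULL` entries where unreviewed.
#' @param consensus_relevant optional logical vector (post-adjudication).
#' @param claim_match optional logical vector: matched the claim filter.
#' @param claim_keywords optional list column of matched keyword vectors.
#' @return data frame of class `app_registry`.
#' @export
app_registry <- function(app_id, platform,
                         names = NULL, description = NULL,
                         reviewer_labels = NULL,
                         consensus_relevant = NULL,
                         claim_match = NULL, claim_keywords = NULL) {
  app_id <- as.character(app_id)
  n <- length(app_id)
  if (anyNA(app_id) || any(!nzchar(app_id))) {
    stop("app_id must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(app_id)) {
    stop("app_id must be unique within a registry; duplicated: ",
         paste(unique(app_id[duplicated(app_id)]), collapse = ", "),
         call. = FALSE)
  }
  platform <- rep_len(as.character(platform), n)
  if (!all(platform %in% PLATFORMS)) {
    stop("platform must be one of: ", paste(PLATFORMS, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names)) {
    names <- lapply(app_id, function(id) {
      data.frame(date = 1L, name = id, stringsAsFactors = FALSE)
    })
  }
  names <- lapply(names, function(nm) {
    nm <- data.frame(date = as.integer(nm$date),
                     name = as.character(nm$name),
                     stringsAsFactors = FALSE)
    nm[order(nm$date), , drop = FALSE]
  })
  if (is.null(description)) description <- rep_len(NA_character_, n)
  if (is.null(reviewer_labels)) reviewer_labels <- rep_len(list(NULL), n)
  if (is.null(consensus_relevant)) consensus_relevant <- rep_len(NA, n)
  if (is.null(claim_match)) claim_match <- rep_len(NA, n)
  if (is.null(claim_keywords)) claim_keywords <- rep_len(list(NULL), n)

  out <- data.frame(app_id = app_id, platform = platform,
                    stringsAsFactors = FALSE)
  out$names <- names
  out$description <- as.character(description)
  out$reviewer_labels <- reviewer_labels
  out$consensus_relevant <- as.logical(consensus_relevant)
  out$claim_match <- as.logical(claim_match)
  out$claim_keywords <- claim_keywords
  class(out) <- c("app_registry", "data.frame")
  out
}

#' @export
print.app_registry <- function(x, ...) {
  cat(sprintf("<app_registry> %d apps (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$platform)),
                            table(x$platform)), collapse = ", ")))
  invisible(x)
}
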