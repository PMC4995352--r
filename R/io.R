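#' Read a snapshot panel from CSV
#'
#' The panel format is a UTF-8 CSV with fixed column order
#' `date, app_id, platform, in_search, rank, available, version,
#' star_rating, n_reviews, download_bucket`; absent values are empty
#' fields. A JSON sidecar (`<path>.meta.json`, written by [write_panel()])
#' carries the keyword, platform, span and the observed-day manifest; if it
#' is missing, observed days are inferred from the data.
#'
#' Rows violating a panel invariant cause an error (naming the rows); they
#' are never silently dropped.
#'
#' @param path path to the panel CSV.
#' @param meta_path path to the metadata sidecar; defaults to
#'   `<path>.meta.json`, ignored when absent.
#' @return a validated [snapshot_panel()].
#' @export
read_panel <- function(path, meta_path = paste0(path, ".meta.json")) {
  if (!file.exists(path)) {
    stop("panel file does not exist: ", path, call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(PANEL_COLUMNS, header)
  if (length(missing_cols)) {
    stop("panel CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(
                          date = "integer", app_id = "character",
                          platform = "character", in_search = "logical",
                          rank = "integer", available = "logical",
                          version = "character", star_rating = "numeric",
                          n_reviews = "integer",
                          download_bucket = "character"
                        ), na.strings = "")
  df <- df[, PANEL_COLUMNS, drop = FALSE]

  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    snapshot_panel(df,
                   platform = meta$platform,
                   keyword = meta$keyword,
                   observed_days = meta$observed_days,
                   span_days = meta$span_days)
  } else {
    platform <- if (nrow(df)) df$platform[[1L]] else "android"
    snapshot_panel(df, platform = platform)
  }
}

#' Write a snapshot panel to CSV
#'
#' Writes the observation table in the fixed column order with absent
#' values as empty fields, plus a JSON metadata sidecar recording keyword,
#' platform, span and the observed-day manifest. `read_panel()` of the
#' written files reproduces the panel field-for-field, and re-writing
#' produces byte-identical files.
#'
#' @param panel a validated [snapshot_panel()].
#' @param path output CSV path.
#' @param meta_path sidecar path; defaults to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, meta_path = paste0(path, ".meta.json")) {
  validate_panel(panel)
  obs <- panel$observations[, PANEL_COLUMNS, drop = FALSE]
  # stable row order for byte-identical re-writes
  obs <- obs[order(obs$date, obs$app_id), , drop = FALSE]
  utils::write.csv(obs, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  meta <- list(
    keyword = panel$keyword,
    platform = panel$platform,
    span_days = panel$span_days,
    observed_days = panel$observed_days
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             meta_path, useBytes = TRUE)
  invisible(path)
}

#' Read an app registry from JSON-lines
#'
#' One app per line; each line is a JSON object with fields `app_id`,
#' `platform`, `names` (array of `{date, name}`), `description`, and
#' optionally `reviewer_labels` (pair of booleans), `consensus_relevant`,
#' `claim_match` and `claim_keywords`.
#'
#' @param path path to the JSONL file.
#' @return an [app_registry()].
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) {
    stop("registry file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyDataFrame = TRUE)
  get1 <- function(r, field, default) {
    if (is.null(r[[field]]) || (length(r[[field]]) == 1 &&
                                is.na(r[[field]])[1])) default else r[[field]]
  }
  app_registry(
    app_id = vapply(recs, `[[`, "", "app_id"),
    platform = vapply(recs, `[[`, "", "platform"),
    names = lapply(recs, function(r) {
      nm <- r$names
      if (is.null(nm) || !length(nm)) {
        data.frame(date = 1L, name = r$app_id, stringsAsFactors = FALSE)
      } else {
        as.data.frame(nm, stringsAsFactors = FALSE)
      }
    }),
    description = vapply(recs, function(r) {
      as.character(get1(r, "description", NA_character_))
    }, ""),
    reviewer_labels = lapply(recs, function(r) {
      lab <- r$reviewer_labels
      if (is.null(lab)) NULL else as.logical(lab)
    }),
    consensus_relevant = vapply(recs, function(r) {
      as.logical(get1(r, "consensus_relevant", NA))
    }, NA),
    claim_match = vapply(recs, function(r) {
      as.logical(get1(r, "claim_match", NA))
    }, NA),
    claim_keywords = lapply(recs, function(r) {
      kw <- r$claim_keywords
      if (is.null(kw)) NULL else as.character(kw)
    })
  )
}

#' Write an app registry to JSON-lines
#'
#' @param registry an [app_registry()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "app_registry"))
  lines <- vapply(seq_len(nrow(registry)), function(i) {
    rec <- list(
      app_id = registry$app_id[[i]],
      platform = registry$platform[[i]],
      names = registry$names[[i]],
      description = registry$description[[i]]
    )
    if (!is.null(registry$reviewer_labels[[i]])) {
      rec$reviewer_labels <- registry$reviewer_labels[[i]]
    }
    if (!is.na(registry$consensus_relevant[[i]])) {
      rec$consensus_relevant <- registry$consensus_relevant[[i]]
    }
    if (!is.na(registry$claim_match[[i]])) {
      rec$claim_match <- registry$claim_match[[i]]
      rec$claim_keywords <- as.list(registry$claim_keywords[[i]])
    }
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
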