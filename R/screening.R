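# Effectiveness-claim keyword screening and dual-reviewer relevance merge.

#' The effectiveness-claim keyword set
#'
#' The fixed keyword list used to pre-screen store descriptions for claims
#' of clinical effectiveness. Two entries are prefix wildcards
#' (`effective*`, `evaluate*`); the rest match whole tokens only, so
#' "clinically" does not match `clinical`. Matching is case-insensitive
#' ("RCT" matches as a whole token).
#'
#' @param exact whole-token keywords.
#' @param prefix prefix keywords (match any token starting with them).
#' @return list of class `claim_keyword_set` with lowercase `exact` and
#'   `prefix` character vectors.
#' @export
claim_keywords <- function(exact = c("clinical", "study", "studies",
                                     "proven", "proof", "tested",
                                     "guaranteed", "evidence", "rct",
                                     "trial"),
                           prefix = c("effective", "evaluate")) {
  structure(list(exact = tolower(exact), prefix = tolower(prefix)),
            class = "claim_keyword_set")
}

#' Screen a description for effectiveness-claim keywords
#'
#' Tokenizes the text on non-alphanumeric boundaries, lowercases, and
#' matches each token against the keyword set: equality for exact
#' keywords, `startsWith` for prefix keywords. Prefix matches are reported
#' with a trailing `*` (e.g. `"effective*"` for the token "effectively").
#'
#' @param description text (may be empty or `NA`; both yield no match).
#' @param keywords a [claim_keywords()] set.
#' @return list with `matched` (logical) and `keywords` (character vector
#'   of matched keywords, empty when none).
#' @examples
#' claim_keyword_filter("An effective mood tracker")
#' claim_keyword_filter("Track your mood and sleep daily")
#' @export
claim_keyword_filter <- function(description, keywords = claim_keywords()) {
  stopifnot(inherits(keywords, "claim_keyword_set"))
  if (length(description) != 1L) {
    stop("description must be a single string", call. = FALSE)
  }
  if (is.na(description) || !nzchar(description)) {
    return(list(matched = FALSE, keywords = character(0)))
  }
  tokens <- tolower(strsplit(description, "[^[:alnum:]]+")[[1L]])
  tokens <- unique(tokens[nzchar(tokens)])
  hits <- character(0)
  for (kw in keywords$exact) {
    if (kw %in% tokens) hits <- c(hits, kw)
  }
  for (kw in keywords$prefix) {
    if (any(startsWith(tokens, kw))) hits <- c(hits, paste0(kw, "*"))
  }
  list(matched = length(hits) > 0L, keywords = hits)
}

#' Apply the claim filter across a registry
#'
#' @param registry an [app_registry()].
#' @param keywords a [claim_keywords()] set.
#' @return the registry with `claim_match` and `claim_keywords` filled.
#' @export
screen_claims <- function(registry, keywords = claim_keywords()) {
  stopifnot(inherits(registry, "app_registry"))
  res <- lapply(registry$description, claim_keyword_filter,
                keywords = keywords)
  registry$claim_match <- vapply(res, `[[`, NA, "matched")
  registry$claim_keywords <- lapply(res, `[[`, "keywords")
  registry
}

#' Merge two reviewers' relevance labels into a consensus
#'
#' Implements independent dual review with adjudication: where the two
#' reviewers agree the common label is the consensus; where they disagree
#' the supplied resolution (the outcome of discussion) is used.
#' Resolutions must cover exactly the disagreeing apps — a disagreement
#' without a resolution leaves consensus pending and is an error, as is a
#' resolution for an app the reviewers agreed on.
#'
#' @param labels1,labels2 named logical vectors (app id -> relevant),
#'   covering the same app set.
#' @param resolutions named logical vector for the disagreeing apps.
#' @return data frame of class `review_outcome` with columns `app_id`,
#'   `reviewer1`, `reviewer2`, `disagreement`, `consensus`.
#' @export
merge_dual_review <- function(labels1, labels2,
                              resolutions = logical(0)) {
  if (is.null(names(labels1)) || is.null(names(labels2))) {
    stop("labels must be named by app_id", call. = FALSE)
  }
  if (!setequal(names(labels1), names(labels2))) {
    stop("labels1 and labels2 must cover the same app set", call. = FALSE)
  }
  ids <- sort(names(labels1))
  l1 <- as.logical(labels1[ids])
  l2 <- as.logical(labels2[ids])
  if (anyNA(l1) || anyNA(l2)) {
    stop("labels must be TRUE/FALSE, not NA", call. = FALSE)
  }
  disagree <- l1 != l2
  need <- ids[disagree]
  missing_res <- setdiff(need, names(resolutions))
  if (length(missing_res)) {
    stop("consensus pending: no resolution for disagreeing app(s): ",
         paste(missing_res, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(resolutions), need)
  if (length(extra)) {
    stop("resolutions supplied for non-disagreeing app(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  consensus <- l1
  consensus[disagree] <- as.logical(resolutions[ids[disagree]])
  out <- data.frame(app_id = ids, reviewer1 = l1, reviewer2 = l2,
                    disagreement = disagree, consensus = consensus,
                    stringsAsFactors = FALSE)
  class(out) <- c("review_outcome", "data.frame")
  out
}

#' Pooled relevance proportion
#'
#' Percentage of screened apps judged clinically relevant, pooled over
#' strata (e.g. platforms): `100 * sum(n_relevant) / sum(n_total)`,
#' rounded to one decimal.
#'
#' @param n_relevant relevant apps per stratum.
#' @param n_total screened apps per stratum.
#' @return percentage, one decimal.
#' @examples
#' relevance_proportion(c(197, 150), c(623, 359))
#' @export
relevance_proportion <- function(n_relevant, n_total) {
  if (length(n_relevant) != length(n_total)) {
    stop("n_relevant and n_total must have equal length", call. = FALSE)
  }
  if (any(n_relevant < 0) || any(n_total < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(n_relevant > n_total)) {
    stop("n_relevant cannot exceed n_total", call. = FALSE)
  }
  if (sum(n_total) == 0) stop("total count is zero", call. = FALSE)
  round(100 * sum(n_relevant) / sum(n_total), 1)
}
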