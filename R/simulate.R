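#' Simulation configuration for the synthetic marketplace
#'
#' Bundles every generative parameter of the birth--death marketplace
#' simulator and checks their ranges. The defaults emulate the study
#' conditions of a 246-day daily keyword crawl of an Android store with a
#' 190-result search window and 35 days lost to collection failures;
#' removal hazards default to values whose 246-day survival matches the
#' availability proportions reported for clinically relevant
#' (about two-thirds remaining) and non-relevant (about five-sixths
#' remaining) apps.
#'
#' @param n_initial_apps apps present on day 1.
#' @param arrival_rate expected new apps per day (Poisson).
#' @param removal_hazard per-app, per-day removal probability. Either a
#'   single number or a named vector `c(relevant = , nonrelevant = )` for
#'   class-specific hazards.
#' @param relevance_fraction probability a new app is clinically relevant
#'   to the search condition.
#' @param claim_fraction probability a relevant app's description embeds an
#'   effectiveness-claim keyword.
#' @param search_window_k search-engine result cap K (190 Android /
#'   200 iOS); only the top K apps by ranking score appear in results.
#' @param popularity_meanlog,popularity_sdlog log-normal parameters of the
#'   initial popularity draw.
#' @param popularity_walk_sigma daily standard deviation of the
#'   multiplicative log-normal popularity random walk.
#' @param launch_boost multiplier applied to the initial popularity of apps
#'   arriving after day 1 (1 = no boost).
#' @param affinity_sdlog log-normal sd of the fixed per-app keyword
#'   affinity weight; ranking score = affinity x popularity.
#' @param quality_min,quality_max range of the uniform true-quality draw
#'   (star scale).
#' @param review_rate expected reviews per day per unit popularity.
#' @param review_sigma sd of review scores around true quality (clipped to
#'   \[1, 5\]).
#' @param download_rate expected downloads per day per unit popularity
#'   (Android bucket accumulation).
#' @param version_bump_prob per-day probability of a version increment.
#' @param span_days total study span in days.
#' @param n_missing_days days (other than day 1) masked as unobserved.
#' @param platform,keyword store platform and search term recorded on the
#'   panel.
#' @param seed integer seed; identical config and seed give byte-identical
#'   output.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_initial_apps = 300,
                              arrival_rate = 2,
                              removal_hazard = c(relevant = 0.0017,
                                                 nonrelevant = 0.0007),
                              relevance_fraction = 0.316,
                              claim_fraction = 0.38,
                              search_window_k = 190,
                              popularity_meanlog = 0,
                              popularity_sdlog = 1,
                              popularity_walk_sigma = 0.05,
                              launch_boost = 1,
                              affinity_sdlog = 1,
                              quality_min = 1.5,
                              quality_max = 5,
                              review_rate = 0.02,
                              review_sigma = 1,
                              download_rate = 5,
                              version_bump_prob = 0.01,
                              span_days = 246,
                              n_missing_days = 35,
                              platform = "android",
                              keyword = "depression",
                              seed = 1L) {
  config <- list(
    n_initial_apps = as.integer(n_initial_apps),
    arrival_rate = arrival_rate,
    removal_hazard = removal_hazard,
    relevance_fraction = relevance_fraction,
    claim_fraction = claim_fraction,
    search_window_k = as.integer(search_window_k),
    popularity_meanlog = popularity_meanlog,
    popularity_sdlog = popularity_sdlog,
    popularity_walk_sigma = popularity_walk_sigma,
    launch_boost = launch_boost,
    affinity_sdlog = affinity_sdlog,
    quality_min = quality_min,
    quality_max = quality_max,
    review_rate = review_rate,
    review_sigma = review_sigma,
    download_rate = download_rate,
    version_bump_prob = version_bump_prob,
    span_days = as.integer(span_days),
    n_missing_days = as.integer(n_missing_days),
    platform = match.arg(platform, PLATFORMS),
    keyword = as.character(keyword),
    seed = as.integer(seed)
  )
  class(config) <- "simulation_config"
  validate_config(config)
  config
}

validate_config <- function(config) {
  check_prob <- function(field) {
    v <- config[[field]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1)) {
      stop("invalid simulation config: `", field,
           "` must be a probability in [0, 1]", call. = FALSE)
    }
  }
  check_pos <- function(field, strict = TRUE) {
    v <- config[[field]]
    lo_ok <- if (strict) all(v > 0) else all(v >= 0)
    if (!is.numeric(v) || anyNA(v) || !lo_ok) {
      stop("invalid simulation config: `", field, "` must be ",
           if (strict) "positive" else "non-negative", call. = FALSE)
    }
  }
  for (f in c("removal_hazard", "relevance_fraction", "claim_fraction",
              "version_bump_prob")) check_prob(f)
  for (f in c("n_initial_apps", "search_window_k", "span_days",
              "launch_boost")) check_pos(f)
  for (f in c("arrival_rate", "n_missing_days", "popularity_sdlog",
              "popularity_walk_sigma", "affinity_sdlog", "review_rate",
              "review_sigma", "download_rate")) check_pos(f, strict = FALSE)
  if (length(config$removal_hazard) == 2 &&
      !setequal(names(config$removal_hazard),
                c("relevant", "nonrelevant"))) {
    stop("invalid simulation config: `removal_hazard` must be a scalar or ",
         "a vector named c(relevant=, nonrelevant=)", call. = FALSE)
  }
  if (config$n_missing_days >= config$span_days) {
    stop("invalid simulation config: `n_missing_days` must be smaller ",
         "than `span_days`", call. = FALSE)
  }
  if (config$quality_min < 1 || config$quality_max > 5 ||
      config$quality_min > config$quality_max) {
    stop("invalid simulation config: quality range must lie within [1, 5]",
         call. = FALSE)
  }
  invisible(config)
}

#' Simulate a daily-snapshot app marketplace
#'
#' Generates a complete synthetic study with known ground truth. Apps are
#' born (Poisson arrivals on top of an initial stock), carry a latent
#' popularity following a multiplicative log-normal random walk and a fixed
#' keyword affinity, and die according to a per-day removal hazard that may
#' differ between clinically relevant and non-relevant apps (removal is
#' absorbing: a removed app never re-lists). Each day every alive app is
#' available to download; only the top `min(K, n alive)` apps by
#' affinity x popularity appear in the keyword search results, ranked in
#' score order with ties broken by identifier. Reviews arrive at a
#' Poisson rate proportional to popularity, with scores normal around the
#' app's true quality and clipped to the 1--5 star scale; Android apps
#' accumulate downloads into the store's report buckets. Finally
#' `n_missing_days` observation days (never day 1) are masked, and store
#' descriptions with ground-truth claim keywords are attached via
#' [generate_descriptions()].
#'
#' @param config a [simulation_config()].
#' @return a list of class `marketplace_sim` with elements `panel`
#'   (a [snapshot_panel()]), `registry` (an [app_registry()] carrying
#'   ground-truth columns `relevant_truth` and `claim_truth`) and `truth`
#'   (per-app arrival/removal days, latent quality, affinity and the full
#'   popularity trajectory).
#' @examples
#' sim <- simulate_marketplace(simulation_config(
#'   n_initial_apps = 20, arrival_rate = 0.5, span_days = 30,
#'   n_missing_days = 3, search_window_k = 15, seed = 42))
#' sim$panel
#' @export
simulate_marketplace <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_config(config)
  set.seed(config$seed)
  span <- config$span_days

  # arrivals: initial stock on day 1, Poisson stream afterwards
  arrivals_per_day <- if (span > 1) {
    stats::rpois(span - 1L, config$arrival_rate)
  } else integer(0)
  arrival_day <- c(rep.int(1L, config$n_initial_apps),
                   rep(seq_len(span - 1L) + 1L, arrivals_per_day))
  n <- length(arrival_day)
  prefix <- if (config$platform == "android") "com.sim.app" else "sim.app"
  app_id <- sprintf("%s%05d", prefix, seq_len(n))

  relevant <- stats::runif(n) < config$relevance_fraction
  hazard <- per_app_hazard(config$removal_hazard, relevant)
  # lifetime: alive on arrival day, then survives each day w.p. (1 - h)
  alive_days <- rep.int(Inf, n)
  pos <- hazard > 0
  if (any(pos)) {
    alive_days[pos] <- 1 + stats::rgeom(sum(pos), hazard[pos])
  }
  removal_day <- arrival_day + alive_days   # first day NOT observed

  quality <- stats::runif(n, config$quality_min, config$quality_max)
  affinity <- stats::rlnorm(n, 0, config$affinity_sdlog)
  pop0 <- stats::rlnorm(n, config$popularity_meanlog,
                        config$popularity_sdlog)
  pop0[arrival_day > 1L] <- pop0[arrival_day > 1L] * config$launch_boost

  # popularity random walk, re-based so pop(arrival day) = pop0
  cumw <- matrix(stats::rnorm(n * span, sd = config$popularity_walk_sigma),
                 n, span)
  cumw[, 1L] <- 0
  for (d in seq_len(span)[-1L]) cumw[, d] <- cumw[, d - 1L] + cumw[, d]
  at_arrival <- cumw[cbind(seq_len(n), arrival_day)]
  pop <- exp(log(pop0) + cumw - at_arrival)

  n_reviews <- integer(n)
  sum_scores <- numeric(n)
  downloads <- numeric(n)
  version_minor <- integer(n)
  android <- config$platform == "android"

  day_rows <- vector("list", span)
  for (d in seq_len(span)) {
    alive <- which(arrival_day <= d & d < removal_day)
    n_alive <- length(alive)
    if (n_alive == 0L) next
    pop_d <- pop[alive, d]

    # review arrivals and score accumulation
    k <- stats::rpois(n_alive, config$review_rate * pop_d)
    has <- k > 0L
    if (any(has)) {
      who <- rep(alive[has], k[has])
      scores <- stats::rnorm(length(who), quality[who], config$review_sigma)
      scores <- pmin(5, pmax(1, scores))
      add <- rowsum(scores, who)
      idx <- as.integer(rownames(add))
      sum_scores[idx] <- sum_scores[idx] + add[, 1L]
      cnt <- rowsum(rep(1L, length(who)), who)
      n_reviews[idx] <- n_reviews[idx] + cnt[, 1L]
    }
    if (android) {
      downloads[alive] <- downloads[alive] +
        stats::rpois(n_alive, config$download_rate * pop_d)
    }
    version_minor[alive] <- version_minor[alive] +
      (stats::runif(n_alive) < config$version_bump_prob)

    # truncated top-K search results by affinity x popularity
    score <- affinity[alive] * pop_d
    ord <- order(-score, app_id[alive])
    m <- min(config$search_window_k, n_alive)
    rank <- rep.int(NA_integer_, n_alive)
    rank[ord[seq_len(m)]] <- seq_len(m)

    star <- ifelse(n_reviews[alive] > 0L,
                   sum_scores[alive] / n_reviews[alive], NA_real_)
    bucket <- if (android) {
      as.character(cut(downloads[alive], DOWNLOAD_BUCKET_BREAKS,
                       DOWNLOAD_BUCKET_LABELS, right = FALSE))
    } else rep.int(NA_character_, n_alive)

    day_rows[[d]] <- list(
      date = rep.int(d, n_alive),
      app_id = app_id[alive],
      in_search = !is.na(rank),
      rank = rank,
      version = sprintf("1.%d", version_minor[alive]),
      star_rating = star,
      n_reviews = n_reviews[alive],
      download_bucket = bucket
    )
  }

  pull <- function(field) unlist(lapply(day_rows, `[[`, field),
                                 use.names = FALSE)
  obs <- data.frame(
    date = pull("date"),
    app_id = pull("app_id"),
    platform = config$platform,
    in_search = pull("in_search"),
    rank = pull("rank"),
    available = TRUE,           # rows exist only for alive apps
    version = pull("version"),
    star_rating = round(pull("star_rating"), 6),
    n_reviews = pull("n_reviews"),
    download_bucket = pull("download_bucket"),
    stringsAsFactors = FALSE
  )
  panel <- snapshot_panel(obs, platform = config$platform,
                          keyword = config$keyword,
                          observed_days = seq_len(span),
                          span_days = span)
  if (config$n_missing_days > 0L) {
    panel <- mask_missing_days(panel, config$n_missing_days)
  }

  truth <- data.frame(
    app_id = app_id,
    relevant = relevant,
    claim = NA,                 # set by generate_descriptions()
    arrival_day = arrival_day,
    removal_day = ifelse(is.finite(removal_day),
                         as.integer(removal_day), NA_integer_),
    quality = quality,
    affinity = affinity,
    stringsAsFactors = FALSE
  )
  truth$popularity <- lapply(seq_len(n), function(i) {
    last <- min(span, removal_day[i] - 1L)
    if (last < arrival_day[i]) numeric(0) else pop[i, arrival_day[i]:last]
  })
  class(truth) <- c("ground_truth", "data.frame")

  registry <- app_registry(app_id = app_id, platform = config$platform,
                           names = make_display_names(app_id, relevant,
                                                      config$keyword))
  registry$relevant_truth <- relevant
  described <- generate_descriptions(registry, config)
  truth$claim <- described$claim_truth

  structure(list(panel = panel, registry = described, truth = truth,
                 config = config),
            class = "marketplace_sim")
}

per_app_hazard <- function(removal_hazard, relevant) {
  if (length(removal_hazard) == 1L) {
    rep_len(unname(removal_hazard), length(relevant))
  } else {
    unname(ifelse(relevant, removal_hazard[["relevant"]],
                  removal_hazard[["nonrelevant"]]))
  }
}

capitalize <- function(x) {
  paste0(toupper(substring(x, 1L, 1L)), substring(x, 2L))
}

make_display_names <- function(app_id, relevant, keyword) {
  nouns <- c("Tracker", "Diary", "Companion", "Coach", "Journal", "Helper")
  lapply(seq_along(app_id), function(i) {
    name <- if (relevant[i]) {
      paste(capitalize(keyword), nouns[(i %% length(nouns)) + 1L], i)
    } else {
      paste("App", nouns[(i %% length(nouns)) + 1L], i)
    }
    data.frame(date = 1L, name = name, stringsAsFactors = FALSE)
  })
}

# Description templates. The base templates are deliberately free of every
# effectiveness-claim keyword so that ground-truth claim status is exactly
# "a claim sentence was appended".
RELEVANT_TEMPLATES <- c(
  "Daily %s tracker with a mood diary, reminders and support resources.",
  "Manage %s symptoms with journaling, breathing exercises and tips.",
  "A companion app for people living with %s: track sleep, mood and habits.",
  "Self-help toolkit for %s with relaxation audio and a wellbeing planner."
)
NONRELEVANT_TEMPLATES <- c(
  "The great %s: a stock market history strategy game.",
  "Moody wallpaper pack with dark themes and lock screen art.",
  "Relaxing rain sounds and music playlists for sleep.",
  "Daily horoscope, quotes and fun quizzes for your free time."
)
CLAIM_SENTENCES <- c(
  "Proven to reduce symptoms in a randomized controlled trial.",
  "An effective program backed by scientific evidence.",
  "Evaluated in a clinical study with real users.",
  "Tested by researchers, results guaranteed."
)

#' Attach store descriptions with known claim status
#'
#' Gives every app a description: clinically relevant apps receive a
#' condition-phrased template and, with probability `claim_fraction`, an
#' appended effectiveness-claim sentence containing at least one keyword
#' from the claim filter's list; non-relevant apps receive unrelated
#' templates. All base templates are keyword-free, so the recorded
#' ground-truth flag (`claim_truth`) is exactly whether a claim sentence
#' was embedded.
#'
#' @param registry an [app_registry()]; relevance is taken from its
#'   `relevant_truth` column (as produced by [simulate_marketplace()]) or,
#'   failing that, `consensus_relevant`.
#' @param config a [simulation_config()] (uses `claim_fraction` and
#'   `keyword`).
#' @param seed optional seed; by default draws from the current RNG stream
#'   so that [simulate_marketplace()] output is reproducible from its
#'   single config seed.
#' @return the registry with `description` filled and a logical
#'   `claim_truth` column.
#' @export
generate_descriptions <- function(registry, config, seed = NULL) {
  stopifnot(inherits(registry, "app_registry"))
  if (!is.null(seed)) set.seed(seed)
  relevant <- registry$relevant_truth
  if (is.null(relevant)) relevant <- registry$consensus_relevant
  if (is.null(relevant) || anyNA(relevant)) {
    stop("registry must carry relevance (relevant_truth or ",
         "consensus_relevant) to generate descriptions", call. = FALSE)
  }
  n <- nrow(registry)
  base <- ifelse(
    relevant,
    sprintf(RELEVANT_TEMPLATES[sample.int(length(RELEVANT_TEMPLATES), n,
                                          replace = TRUE)],
            config$keyword),
    sprintf(NONRELEVANT_TEMPLATES[sample.int(length(NONRELEVANT_TEMPLATES),
                                             n, replace = TRUE)],
            config$keyword)
  )
  claim <- relevant & stats::runif(n) < config$claim_fraction
  sent <- CLAIM_SENTENCES[sample.int(length(CLAIM_SENTENCES), n,
                                     replace = TRUE)]
  registry$description <- ifelse(claim, paste(base, sent), base)
  registry$claim_truth <- claim
  registry
}

#' Mask observation days as missing
#'
#' Removes `n_missing` days (sampled uniformly among days 2..span; day 1,
#' the baseline search, is never masked) from the observed-day manifest and
#' drops all their rows. The calendar span is unchanged, so the panel
#' records "no data" rather than "no apps" for those days.
#'
#' @param panel a [snapshot_panel()].
#' @param n_missing number of days to mask; must be smaller than the
#'   current number of observed days.
#' @param seed optional seed; by default uses the current RNG stream.
#' @return the masked panel.
#' @export
mask_missing_days <- function(panel, n_missing, seed = NULL) {
  stopifnot(inherits(panel, "snapshot_panel"))
  n_missing <- as.integer(n_missing)
  if (n_missing < 0L) stop("n_missing must be non-negative", call. = FALSE)
  if (n_missing == 0L) return(panel)
  if (!is.null(seed)) set.seed(seed)
  candidates <- setdiff(panel$observed_days, 1L)
  if (n_missing >= length(panel$observed_days)) {
    stop("n_missing (", n_missing, ") must be smaller than the number of ",
         "observed days (", length(panel$observed_days), ")",
         call. = FALSE)
  }
  masked <- sort(candidates[sample.int(length(candidates), n_missing)])
  panel$observed_days <- setdiff(panel$observed_days, masked)
  panel$observations <-
    panel$observations[!panel$observations$date %in% masked, , drop = FALSE]
  rownames(panel$observations) <- NULL
  validate_panel(panel)
  panel
}

#' @export
print.marketplace_sim <- function(x, ...) {
  cat(sprintf("<marketplace_sim> %d apps, seed %d\n", nrow(x$registry),
              x$config$seed))
  print(x$panel)
  invisible(x)
}
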