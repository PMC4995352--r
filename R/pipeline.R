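# End-to-end pipeline: simulate -> estimate -> screen -> subgroup -> report.

#' Count unique apps on day 1 and over the whole study
#'
#' @param panel a [snapshot_panel()].
#' @return list with `day1_count` (apps in the search results on the first
#'   observed day) and `total_count` (distinct app ids ever appearing in
#'   the search results).
#' @export
count_unique_apps <- function(panel) {
  stopifnot(inherits(panel, "snapshot_panel"))
  obs <- panel$observations
  if (!nrow(obs)) stop("panel has no observations", call. = FALSE)
  first_day <- min(panel$observed_days)
  list(
    day1_count = sum(obs$in_search & obs$date == first_day),
    total_count = length(unique(obs$app_id[obs$in_search]))
  )
}

#' Configure the analysis pipeline
#'
#' @param simulation a [simulation_config()] used to generate the study
#'   data, or `NULL` when reading from files.
#' @param panel_path,registry_path input files used when `simulation` is
#'   `NULL`.
#' @param out_dir directory for the report bundle.
#' @param min_series minimum-support threshold for the averaged curves.
#' @param absorbing estimator sensitivity flag (once-gone-always-gone).
#' @param subgroup_specs list of [subgroup_spec()]s; each is estimated in
#'   both modes. `NULL` for none.
#' @param subgroup_min_series support threshold for subgroup curves
#'   (subgroup baselines are small, so the default is 5).
#' @param quiet suppress INFO logging to stderr.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            panel_path = NULL, registry_path = NULL,
                            out_dir = "storeflux-report",
                            min_series = 20L, absorbing = FALSE,
                            subgroup_specs = NULL,
                            subgroup_min_series = 5L,
                            quiet = FALSE) {
  if (is.null(simulation) &&
      (is.null(panel_path) || is.null(registry_path))) {
    stop("provide either a simulation config or panel and registry paths",
         call. = FALSE)
  }
  structure(list(simulation = simulation, panel_path = panel_path,
                 registry_path = registry_path, out_dir = out_dir,
                 min_series = as.integer(min_series),
                 absorbing = isTRUE(absorbing),
                 subgroup_specs = subgroup_specs,
                 subgroup_min_series = as.integer(subgroup_min_series),
                 quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level keys `out_dir`,
#' `min_series`, `absorbing`, `panel_path`, `registry_path`, a
#' `simulation:` block of [simulation_config()] arguments, and a
#' `subgroups:` list of `{metric, which, size}` entries.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$simulation)) {
    do.call(simulation_config, raw$simulation)
  }
  specs <- if (!is.null(raw$subgroups)) {
    lapply(raw$subgroups, function(sg) do.call(subgroup_spec, sg))
  }
  args <- raw[setdiff(names(raw), c("simulation", "subgroups"))]
  do.call(pipeline_config,
          c(list(simulation = sim, subgroup_specs = specs), args))
}

fmt_halflife <- function(res) {
  if (res$censored) sprintf("> %d days", res$last_offset)
  else sprintf("%d days", res$half_life_days)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulation (or file input), half-life estimation in both
#' modes, relevance stratification, claim screening, subgroup analyses and
#' removal-interval arithmetic, writing a report bundle of plain-text
#' artifacts to `out_dir`:
#'
#' * `table1.csv` — unique apps on day 1 and over the study;
#' * `table2.csv` — search-result half-life and % remaining;
#' * `table3.csv` — app (availability) half-life and % remaining;
#' * `table4.csv` — both measures stratified by clinical relevance;
#' * `claims.csv` — claim-filter counts among relevant apps;
#' * `subgroups.csv` — subgroup half-lives (when specs are given);
#' * `report.json` — everything above plus the averaged curves, the
#'   removal intervals, and the full configuration with its seed.
#'
#' Reruns with the same config are byte-identical. Any stage error aborts
#' the run with a stage-named message and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the report as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  info <- function(...) {
    if (!config$quiet) {
      message(sprintf("[storeflux %+6.1fs] ",
                      as.numeric(Sys.time() - t0, units = "secs")), ...)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(stage, err) {
    unlink(written)
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(err),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    info("stage: ", name)
    tryCatch(expr, error = function(e) on_fail(name, e))
  }
  emit_csv <- function(df, file) {
    path <- file.path(config$out_dir, file)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    written <<- c(written, path)
    path
  }

  # --- input -------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_marketplace(config$simulation))
    panel <- sim$panel
    registry <- sim$registry
    relevant_ids <- registry$app_id[registry$relevant_truth]
    seed <- config$simulation$seed
  } else {
    panel <- stage("load", read_panel(config$panel_path))
    registry <- stage("load", read_registry(config$registry_path))
    if (all(is.na(registry$consensus_relevant))) {
      stop("pipeline stage `load` failed: registry carries no consensus ",
           "relevance labels", call. = FALSE)
    }
    relevant_ids <- registry$app_id[registry$consensus_relevant %in% TRUE]
    seed <- NA_integer_
  }
  nonrelevant_ids <- setdiff(registry$app_id, relevant_ids)

  # --- table 1: unique apps ----------------------------------------------
  counts <- stage("count", count_unique_apps(panel))
  table1 <- data.frame(keyword = panel$keyword, platform = panel$platform,
                       apps_day1 = counts$day1_count,
                       apps_total = counts$total_count)
  emit_csv(table1, "table1.csv")

  # --- tables 2-3: half-lives per mode -----------------------------------
  estimates <- list()
  for (mode in c("search", "availability")) {
    estimates[[mode]] <- stage(
      paste0("estimate-", mode),
      estimate_half_life(panel, mode = mode,
                         min_series = config$min_series,
                         absorbing = config$absorbing))
  }
  mode_table <- function(res) {
    data.frame(keyword = panel$keyword, platform = panel$platform,
               half_life = fmt_halflife(res),
               censored = res$censored,
               remaining_at_end_pct = round(100 * res$remaining_at_end, 1),
               n_series = res$n_series)
  }
  emit_csv(mode_table(estimates$search), "table2.csv")
  emit_csv(mode_table(estimates$availability), "table3.csv")

  # --- table 4: stratified by relevance ----------------------------------
  strata <- list(all = NULL, relevant = relevant_ids,
                 not_relevant = nonrelevant_ids)
  table4_rows <- list()
  stratified <- list()
  for (sname in names(strata)) {
    row <- list(platform = panel$platform, subgroup = sname)
    for (mode in c("search", "availability")) {
      res <- stage(
        paste0("estimate-", mode, "-", sname),
        estimate_half_life(panel, mode = mode,
                           min_series = config$min_series,
                           absorbing = config$absorbing,
                           restrict_ids = strata[[sname]]))
      stratified[[paste(mode, sname, sep = ".")]] <- res
      row[[paste0(mode, "_half_life")]] <- fmt_halflife(res)
      row[[paste0(mode, "_remaining_pct")]] <-
        round(100 * res$remaining_at_end, 1)
    }
    table4_rows[[sname]] <- as.data.frame(row)
  }
  table4 <- do.call(rbind, table4_rows)
  rownames(table4) <- NULL
  emit_csv(table4, "table4.csv")

  # --- claim screening ---------------------------------------------------
  registry <- stage("screen", screen_claims(registry))
  rel_reg <- registry[registry$app_id %in% relevant_ids, , drop = FALSE]
  claims <- data.frame(
    n_relevant = nrow(rel_reg),
    n_claim_matched = sum(rel_reg$claim_match, na.rm = TRUE),
    claim_matched_pct = if (nrow(rel_reg)) {
      round(100 * sum(rel_reg$claim_match, na.rm = TRUE) / nrow(rel_reg), 1)
    } else NA_real_
  )
  emit_csv(claims, "claims.csv")

  # --- removal interval (relevant apps, availability mode) ---------------
  rel_avail <- stratified[["availability.relevant"]]
  removal <- tryCatch(
    removal_interval(length(relevant_ids), rel_avail$remaining_at_end,
                     panel$span_days),
    error = function(e) NA_real_)

  # --- subgroups ---------------------------------------------------------
  subgroup_rows <- list()
  for (spec in config$subgroup_specs) {
    for (mode in c("search", "availability")) {
      res <- stage(
        sprintf("subgroup-%s-%s-%s", spec$metric, spec$which, mode),
        subgroup_halflife(panel, spec, mode = mode,
                          min_series = config$subgroup_min_series,
                          absorbing = config$absorbing))
      subgroup_rows[[length(subgroup_rows) + 1L]] <- data.frame(
        metric = spec$metric, which = spec$which, size = spec$size,
        mode = mode, half_life = fmt_halflife(res),
        remaining_at_end_pct = round(100 * res$remaining_at_end, 1),
        n_series = res$n_series)
    }
  }
  if (length(subgroup_rows)) {
    emit_csv(do.call(rbind, subgroup_rows), "subgroups.csv")
  }

  # --- report bundle -----------------------------------------------------
  curve_json <- function(res) {
    list(mode = res$mode,
         half_life_days = if (res$censored) NULL else res$half_life_days,
         censored = res$censored,
         remaining_at_end = res$remaining_at_end,
         last_offset = res$last_offset, n_series = res$n_series,
         offsets = res$curve$offsets, p = res$curve$p,
         support = res$curve$support)
  }
  report <- list(
    seed = seed,
    config = list(min_series = config$min_series,
                  absorbing = config$absorbing),
    simulation = if (!is.null(config$simulation)) {
      unclass(config$simulation)
    },
    table1 = table1,
    estimates = lapply(stratified, curve_json),
    claims = claims,
    removal_interval_days = removal,
    subgroups = if (length(subgroup_rows)) do.call(rbind, subgroup_rows)
  )
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  written <- c(written, report_path)
  info("done: ", length(written), " artifacts in ", config$out_dir)
  invisible(report)
}
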