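## Config-driven end-to-end runs: simulate (or load) -> score -> build
## histories -> cost accounting -> fit -> estimate -> report.

#' Run configuration
#'
#' @param perspective `"uk"` or `"us"` (costing convention and default
#'   tariff).
#' @param scenario `"main"`, `"region_subset"` (UK participants for the
#'   UK perspective, North-American for the US), `"no_baseline"` (QoL
#'   model without the baseline-utility adjustment) or
#'   `"alternate_tariff"` (re-score QoL under the toy tariff).
#' @param sim a [cohort_config()] for simulate mode; exactly one of
#'   `sim` / `input_dir` must be supplied.
#' @param input_dir directory with a cohort bundle (see
#'   [write_cohort()]).
#' @param tariff optional tariff name or CSV path overriding the default.
#' @param B bootstrap resamples for incremental costs (>= 2, or 0 to
#'   skip).
#' @param seed seed for generation and bootstrap.
#' @param output_dir where tables, figures and the manifest are written
#'   (`NULL`: nothing persisted).
#' @param select run backward/forward covariate selection.
#' @param merge run temporal-category merging for every event type.
#' @param interactions screen event co-occurrence interactions in the
#'   cost model.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(perspective = c("uk", "us"),
                       scenario = c("main", "region_subset", "no_baseline",
                                    "alternate_tariff"),
                       sim = NULL, input_dir = NULL, tariff = NULL,
                       B = 1000, seed = 1L, output_dir = NULL,
                       select = FALSE, merge = FALSE,
                       interactions = TRUE) {
  perspective <- match.arg(perspective)
  scenario <- match.arg(scenario)
  if (is.null(sim) == is.null(input_dir))
    stop("supply exactly one of 'sim' (simulation config) or 'input_dir'",
         call. = FALSE)
  if (B != 0 && B < 2) stop("B must be 0 or >= 2", call. = FALSE)
  cfg <- list(perspective = perspective, scenario = scenario, sim = sim,
              input_dir = input_dir, tariff = tariff, B = B,
              seed = as.integer(seed), output_dir = output_dir,
              select = select, merge = merge, interactions = interactions)
  class(cfg) <- "run_config"
  cfg
}

resolve_tariff <- function(config) {
  if (!is.null(config$tariff)) {
    if (file.exists(config$tariff)) return(read_tariff(config$tariff))
    return(eq5d_tariff(config$tariff))
  }
  if (config$scenario == "alternate_tariff") return(eq5d_tariff("toy"))
  eq5d_tariff(paste0("synthetic_", config$perspective))
}

# merge + annualize all participants' episodes on one costing convention
annualize_all <- function(episodes, participants, inflation, uplift) {
  sp <- split(episodes, episodes$id)
  rows <- lapply(participants$id, function(pid) {
    e <- sp[[pid]]
    if (is.null(e)) e <- data.frame(admission_day = numeric(0),
                                    discharge_day = numeric(0),
                                    unit_cost = numeric(0))
    i <- match(pid, participants$id)
    a <- annualize(merge_overlapping(e),
                   death_day = participants$death_day[i],
                   followup_end = pmin(participants$followup_day[i],
                                       participants$death_day[i],
                                       na.rm = TRUE),
                   inflation = inflation, fee_uplift = uplift)
    a$id <- pid
    a
  })
  out <- do.call(rbind, rows)
  out[c("id", "period", "exposure", "cost", "any_cost", "death_period")]
}

#' Default cost-model formula
#'
#' Annual cost on age (centred at 67), sex and the cost-clock temporal
#' categories of all ten event types.
#'
#' @param types event types included.
#' @param covariates additional covariate columns.
#' @return A formula.
#' @export
cost_formula <- function(types = event_types(),
                         covariates = character(0)) {
  stats::as.formula(paste("cost ~",
                          paste(c("I(age - 67)", "female", covariates,
                                  paste0("cat_", types)),
                                collapse = " + ")))
}

default_cost_scenarios <- function(fit) {
  types <- sub("^cat_", "", grep("^cat_", fit_term_labels(fit),
                                 value = TRUE))
  sc <- lapply(types, function(tp) stats::setNames("y0", tp))
  names(sc) <- paste0(types, "_y0")
  if (length(fit$interactions) &&
      any(grepl("cat_mi", fit$interactions) &
            grepl("cat_ucrv", fit$interactions))) {
    sc$mi_with_ucrv_y0 <- c(mi = "y0", ucrv = "y0")
  }
  sc
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, scores EQ-5D profiles, builds the two
#' event-history clocks, reconstructs annual costs from hospital episodes
#' on the configured costing convention, fits the QoL and two-part cost
#' models (with optional covariate selection, temporal-category merging
#' and interaction screening), computes recycled-prediction incremental
#' costs with cluster-bootstrap intervals and the QoL decrement table,
#' and optionally persists all tables, figures and a manifest.
#'
#' @param config a [run_config()].
#' @return A list of class `pipeline_result`: `cohort`, `qol_fit`,
#'   `cost_fit`, `qol_decrements`, `incremental_costs`, `config`,
#'   `log` (stage row counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  stage <- function(name, ...) {
    msg <- sprintf(...)
    message("[", name, "] ", msg)
    log[[name]] <<- msg
  }

  cohort <- if (!is.null(config$input_dir)) read_cohort(config$input_dir)
            else generate_cohort(config$sim, seed = config$seed)
  check_cohort_schema(cohort)
  stage("simulate", "%d participants, %d events",
        nrow(cohort$participants), nrow(cohort$events))

  if (config$scenario == "region_subset") {
    keep_region <- if (config$perspective == "uk") "uk" else "north_am"
    ids <- cohort$participants$id[cohort$participants$region == keep_region]
    cohort$participants <- cohort$participants[
      cohort$participants$id %in% ids, , drop = FALSE]
    for (nm in c("events", "annual_costs", "profiles", "episodes"))
      cohort[[nm]] <- cohort[[nm]][cohort[[nm]]$id %in% ids, , drop = FALSE]
    stage("subset", "region %s: %d participants", keep_region, length(ids))
  }

  tariff <- resolve_tariff(config)

  ## quality of life
  qd <- build_qol_data(cohort, tariff)
  stage("score", "QoL analysis set n = %d (tariff %s)", nrow(qd),
        tariff$name)
  qf <- qol_formula(baseline = config$scenario != "no_baseline")
  qol_fit <- qol_lm(qf, qd)
  if (config$select) qol_fit <- select_covariates(qol_fit)
  if (config$merge)
    for (tp in sub("^cat_", "",
                   grep("^cat_", fit_term_labels(qol_fit), value = TRUE)))
      qol_fit <- merge_temporal_categories(qol_fit, tp)
  decr <- qol_decrement_table(qol_fit)

  ## costs
  p <- config$perspective
  eps <- cohort$episodes
  eps$unit_cost <- eps[[paste0("unit_cost_", p)]]
  pricing <- cohort$config$pricing
  ac <- annualize_all(eps, cohort$participants,
                      inflation = pricing[[paste0("inflation_", p)]],
                      uplift = pricing[[paste0("uplift_", p)]])
  py <- person_year_table(ac, cohort$events, cohort$participants)
  stage("costing", "%d person-periods, %.1f%% with any cost",
        nrow(py), 100 * mean(py$any_cost))
  cost_fit <- two_part_glm(cost_formula(), py, cluster = "id")
  if (config$select) cost_fit <- select_covariates(cost_fit)
  if (config$interactions) cost_fit <- add_interactions(cost_fit)
  if (config$merge)
    for (tp in sub("^cat_", "",
                   grep("^cat_", fit_term_labels(cost_fit), value = TRUE)))
      cost_fit <- merge_temporal_categories(cost_fit, tp)
  stage("fit", "two-part gamma/identity; QoL OLS n = %d",
        stats::nobs(qol_fit))

  inc <- incremental_costs(cost_fit, default_cost_scenarios(cost_fit),
                           B = config$B, seed = config$seed + 1L)
  stage("estimate", "%d incremental-cost scenarios, B = %d",
        nrow(inc), config$B)

  out <- list(cohort = cohort, qol_fit = qol_fit, cost_fit = cost_fit,
              qol_decrements = decr, incremental_costs = inc,
              config = config, log = log)
  class(out) <- "pipeline_result"
  if (!is.null(config$output_dir)) persist_results(out)
  out
}

check_cohort_schema <- function(cohort) {
  need <- list(
    participants = c("id", "age", "female", "region", "death_day",
                     "followup_day"),
    events = c("id", "type", "day"),
    annual_costs = c("id", "period", "exposure", "any_cost"),
    profiles = c("id", "visit", EQ5D_DIMENSIONS),
    episodes = c("id", "admission_day", "discharge_day"))
  for (nm in names(need)) {
    missing <- setdiff(need[[nm]], names(cohort[[nm]]))
    if (length(missing))
      stop("input table '", nm, "' lacks column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !cohort$events$type %in% event_types()
  if (any(bad))
    stop("events table: unknown event type(s) at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  invisible(cohort)
}

persist_results <- function(res) {
  dir <- res$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # intermediate analysis tables (QoL rows with last-occurrence
  # categories; person-years with first-occurrence categories)
  utils::write.csv(res$qol_fit$qol_data,
                   file.path(dir, "qol_analysis_set.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cost_fit$data[
    setdiff(names(res$cost_fit$data), ".any_cost")],
    file.path(dir, "person_years.csv"), row.names = FALSE)
  utils::write.csv(res$qol_decrements,
                   file.path(dir, "qol_decrements.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$incremental_costs),
                   file.path(dir, "incremental_costs.csv"),
                   row.names = FALSE)
  fits <- list(
    qol = list(coefficients = as.list(stats::coef(res$qol_fit)),
               se = as.list(sqrt(diag(vcov(res$qol_fit)))),
               merged_map = res$qol_fit$merged_map,
               selection = res$qol_fit$selection),
    cost = list(part1 = as.list(stats::coef(res$cost_fit$part1)),
                part2 = as.list(stats::coef(res$cost_fit$part2)),
                se_part2 = as.list(sqrt(diag(vcov(res$cost_fit, 2)))),
                shape = res$cost_fit$shape,
                merged_map = res$cost_fit$merged_map,
                interactions = res$cost_fit$interactions))
  jsonlite::write_json(fits, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- res$config
  cfg_json <- file.path(dir, "run_config.json")
  jsonlite::write_json(lapply(unclass(cfg), function(x)
    if (inherits(x, "cohort_config")) unclass(x) else x),
    cfg_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    package_version = as.character(utils::packageVersion("cvdimpact")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    log = res$log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  grDevices::png(file.path(dir, "qol_decrements.png"), width = 900,
                 height = 600)
  graphics::par(mar = c(4, 9, 1, 1))
  plot(res$qol_decrements)
  grDevices::dev.off()
  grDevices::png(file.path(dir, "incremental_costs.png"), width = 900,
                 height = 600)
  graphics::par(mar = c(4, 9, 1, 1))
  plot(res$incremental_costs)
  grDevices::dev.off()
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", x$config$perspective, "perspective, scenario",
      x$config$scenario, "\n")
  for (nm in names(x$log)) cat(sprintf("  %-9s %s\n", nm, x$log[[nm]]))
  invisible(x)
}
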