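## Final-visit quality-of-life model.
##
## QoL utility at the final study visit is modelled with a Gaussian
## linear model (OLS) adjusting for utility at randomization, demographic
## and clinical covariates, and last-occurrence temporal event-history
## categories.  Participants who died before the final QoL measurement or
## did not provide one are excluded upstream (see build_qol_data).  One
## row per participant, so classical OLS standard errors are the default;
## heteroscedasticity-robust SEs are available behind a flag.

#' Assemble the QoL analysis data set
#'
#' Scores baseline and final EQ-5D-5L profiles under a tariff, builds
#' last-occurrence temporal categories per event type relative to each
#' participant's QoL measurement day, and applies the analysis
#' exclusions (death before measurement; missing final profile), with
#' counts reported via `message()`.
#'
#' @param cohort a `cvd_cohort` (or any list with `participants`,
#'   `events`, `profiles` of the same shape).
#' @param tariff an `eq5d_tariff` (default: the tariff named in the
#'   cohort config).
#' @param types event types to build categories for (deaths are omitted:
#'   decedents are excluded from this analysis).
#' @return Data frame with one row per included participant: covariates,
#'   `baseline_u`, `final_u`, and `cat_<type>` factors.
#' @export
build_qol_data <- function(cohort, tariff = NULL,
                           types = setdiff(event_types(), death_types())) {
  if (is.null(tariff)) tariff <- eq5d_tariff(cohort$config$tariff)
  part <- cohort$participants
  prof <- cohort$profiles
  n <- nrow(part)
  bl <- prof[prof$visit == "baseline", ]
  fi <- prof[prof$visit == "final", ]
  bl_u <- score_eq5d(bl, tariff)[match(part$id, bl$id)]
  fi_u <- score_eq5d(fi, tariff)[match(part$id, fi$id)]

  dead <- !is.na(part$death_day)
  no_final <- !dead & is.na(fi_u)
  keep <- !dead & !no_final
  message(sprintf(
    "QoL analysis set: %d of %d participants (%.1f%%); excluded %d deaths, %d missing final QoL",
    sum(keep), n, 100 * sum(keep) / n, sum(dead), sum(no_final)))

  d <- part[keep, , drop = FALSE]
  d$baseline_u <- bl_u[keep]
  d$final_u <- fi_u[keep]
  qd <- d$qol_day; names(qd) <- d$id
  cats <- build_qol_categories(cohort$events, qd, types = types)
  stopifnot(identical(cats$id, d$id))
  cbind(d, cats[-1L])
}

#' Default QoL model formula
#'
#' Final utility on baseline utility (centred at 0.84, the cohort mean at
#' randomization, so the intercept is interpretable as the reference
#' patient's expected utility), age centred at 67, sex, and the standard
#' covariate and temporal-category blocks.
#'
#' @param types event types whose temporal categories enter the model.
#' @param baseline include the baseline-utility adjustment (turned off in
#'   the no-baseline scenario analysis).
#' @param covariates character vector of covariate column names.
#' @return A formula.
#' @export
qol_formula <- function(types = c("mi", "stroke", "ucrv", "ncrv", "hf",
                                  "ncr", "cancer", "diabetes"),
                        baseline = TRUE,
                        covariates = c("female", "region", "disease",
                                       "hf_hist", "af", "diab_hist", "sbp",
                                       "dbp", "bmi", "alcohol", "smoking",
                                       "egfr", "uacr")) {
  rhs <- c("I(age - 67)", covariates, paste0("cat_", types))
  if (baseline) rhs <- c("I(baseline_u - 0.84)", rhs)
  stats::as.formula(paste("final_u ~", paste(rhs, collapse = " + ")))
}

#' Fit the quality-of-life linear model
#'
#' Ordinary least squares on the final-visit utility.  The returned
#' object extends `lm`, so `coef()`, `predict()`, `confint()`,
#' `residuals()` etc. behave as usual; `vcov()` honours the `robust`
#' flag (HC1 sandwich).
#'
#' @param formula model formula (see [qol_formula()]).
#' @param data QoL analysis data (see [build_qol_data()]).
#' @param robust use heteroscedasticity-robust (HC1) standard errors
#'   instead of classical OLS ones.
#' @return An object of class `c("qol_fit", "lm")` with extra fields
#'   `merged_map` and `robust`.
#' @export
qol_lm <- function(formula, data, robust = FALSE) {
  labels <- attr(stats::terms(formula), "term.labels")
  pruned <- prune_constant_terms(labels, data)
  if (!identical(pruned, labels))
    formula <- stats::reformulate(if (length(pruned)) pruned else "1",
                                  response = deparse1(formula[[2L]]))
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient QoL design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit$robust <- robust
  fit$merged_map <- list()
  fit$qol_data <- data
  class(fit) <- c("qol_fit", "lm")
  fit
}

#' @export
vcov.qol_fit <- function(object, ...) {
  if (isTRUE(object$robust)) sandwich::vcovHC(object, type = "HC1")
  else { cls <- class(object); class(object) <- "lm"
         on.exit(class(object) <- cls); stats::vcov(object) }
}

#' @export
print.qol_fit <- function(x, ...) {
  cat("Quality-of-life linear model (final-visit utility)\n")
  cat(sprintf("  n = %d participants; %s SEs\n", stats::nobs(x),
              if (isTRUE(x$robust)) "robust (HC1)" else "classical OLS"))
  cat(sprintf("  intercept (reference patient): %.3f\n",
              unname(stats::coef(x)["(Intercept)"])))
  if (length(x$merged_map))
    cat("  merged temporal categories:",
        paste(names(x$merged_map), collapse = ", "), "\n")
  invisible(x)
}

#' Impute missing continuous covariates by cell means
#'
#' Continuous missing values are replaced by the mean within cells of
#' sex x smoking status x trial arm; if a cell is empty the overall mean
#' is used with a warning.  Categorical covariates are untouched (a
#' printed "missing" level is itself a category).
#'
#' @param participants baseline table.
#' @param vars columns to impute; defaults to all numeric columns with
#'   missing values.
#' @param by cell-defining columns.
#' @return The completed table.
#' @export
impute_covariates <- function(participants,
                              vars = NULL,
                              by = c("female", "smoking", "arm")) {
  if (!all(by %in% names(participants)))
    stop("imputation cell variable(s) missing: ",
         paste(setdiff(by, names(participants)), collapse = ", "),
         call. = FALSE)
  for (cl in by)
    if (anyNA(participants[[cl]]))
      stop("imputation cell variable '", cl, "' has missing values",
           call. = FALSE)
  if (is.null(vars)) {
    num <- vapply(participants, is.numeric, logical(1))
    vars <- names(participants)[num &
                                  vapply(participants, anyNA, logical(1))]
  }
  cell <- interaction(participants[by], drop = TRUE)
  for (v in vars) {
    x <- participants[[v]]
    if (!anyNA(x)) next
    cm <- stats::ave(x, cell, FUN = function(z) mean(z, na.rm = TRUE))
    empty <- is.na(x) & !is.finite(cm)
    if (any(empty)) {
      warning("empty imputation cell(s) for '", v,
              "': overall mean used for ", sum(empty), " value(s)",
              call. = FALSE)
      cm[empty] <- mean(x, na.rm = TRUE)
    }
    x[is.na(x)] <- cm[is.na(x)]
    participants[[v]] <- x
  }
  participants
}
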