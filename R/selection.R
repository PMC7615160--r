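## Model-building procedures shared by the QoL and cost models:
## Wald/F block tests, backward-then-forward covariate selection at the 1%
## level (age and sex always retained), backward F-test merging of
## adjacent temporal categories, interaction screening for co-occurring
## events, and the specification battery (modified Park test, Pregibon
## link test, AIC/BIC/RMSE/MAE) used to choose the cost GLM.

# tested "parts" of a fit: coefficient vector, covariance used for
# inference, and the term structure of the design
model_parts <- function(object) {
  if (inherits(object, "two_part")) {
    p <- function(fit, V) {
      tt <- stats::terms(fit)
      mm <- stats::model.matrix(fit)
      list(coef = stats::coef(fit), vcov = V,
           labels = attr(tt, "term.labels"), assign = attr(mm, "assign"))
    }
    list(p(object$part2, vcov.two_part(object, 2)),
         p(object$part1, vcov.two_part(object, 1)))
  } else {
    tt <- stats::terms(object)
    mm <- stats::model.matrix(object)
    list(list(coef = stats::coef(object), vcov = vcov(object),
              labels = attr(tt, "term.labels"), assign = attr(mm, "assign")))
  }
}

# Wald chi-square p-value that all coefficients of a term block are zero
block_p_value <- function(part, label) {
  k <- match(label, part$labels)
  if (is.na(k)) return(NA_real_)
  idx <- which(part$assign == k)
  b <- part$coef[idx]
  V <- part$vcov[idx, idx, drop = FALSE]
  ok <- is.finite(b) & diag(V) > 1e-300
  if (!any(ok)) return(NA_real_)
  b <- b[ok]; V <- V[ok, ok, drop = FALSE]
  stat <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  if (!is.finite(stat)) return(NA_real_)
  stats::pchisq(stat, df = length(b), lower.tail = FALSE)
}

# refit with a new right-hand side (term labels) and/or data
refit_with <- function(object, labels, data = NULL, interactions = NULL) {
  if (inherits(object, "two_part")) {
    if (is.null(data)) data <- object$data
    if (is.null(interactions)) interactions <- object$interactions
    f <- stats::reformulate(labels,
                            response = as.character(object$formula[[2L]]))
    two_part_glm(f, data, cluster = object$cluster,
                 family2 = object$family2,
                 exclude_certain = object$exclude_certain,
                 drop_incomplete = FALSE, interactions = interactions)
  } else {
    if (is.null(data)) data <- object$qol_data
    f <- stats::reformulate(labels, response = "final_u")
    qol_lm(f, data, robust = isTRUE(object$robust))
  }
}

# the shared right-hand side (part-2-only interaction terms excluded)
fit_term_labels <- function(object) {
  if (inherits(object, "two_part")) return(object$shared_labels)
  attr(stats::terms(object), "term.labels")
}

#' Backward-then-forward covariate selection at the 1% level
#'
#' Starting from the fitted model, repeatedly drops the least significant
#' non-forced covariate block (Wald test of the whole block; for the
#' two-part model a block is retained if significant in either part, with
#' cluster-robust covariances) while its p-value is at or above `alpha`,
#' then re-checks each dropped block by adding it back once.  Age and sex
#' (and the baseline-utility adjustment, where present) are always
#' retained.
#'
#' @param object a `qol_fit` or `two_part` fit.
#' @param forced term labels never dropped; defaults to the age, sex and
#'   baseline-utility terms present in the model.
#' @param alpha retention significance level (default 0.01).
#' @return The refitted object, with a `selection` element recording the
#'   kept and dropped blocks.
#' @export
select_covariates <- function(object, forced = NULL, alpha = 0.01) {
  labels <- fit_term_labels(object)
  if (is.null(forced))
    forced <- intersect(c("I(age - 67)", "age", "female", "sex",
                          "I(baseline_u - 0.84)", "baseline_u"), labels)
  stopifnot(all(forced %in% labels))
  fit <- object
  dropped <- character(0)
  repeat {
    cur <- fit_term_labels(fit)
    free <- setdiff(cur, forced)
    if (!length(free)) break
    parts <- model_parts(fit)
    pv <- vapply(free, function(lb) {
      ps <- vapply(parts, block_p_value, numeric(1), label = lb)
      if (all(is.na(ps))) 1 else min(ps, na.rm = TRUE)
    }, numeric(1))
    worst <- which.max(pv)
    if (pv[worst] < alpha) break
    dropped <- c(dropped, free[worst])
    fit <- refit_with(fit, setdiff(cur, free[worst]))
  }
  # forward re-check in original model order
  for (lb in intersect(labels, dropped)) {
    cand <- refit_with(fit, c(fit_term_labels(fit), lb))
    ps <- vapply(model_parts(cand), block_p_value, numeric(1), label = lb)
    if (any(ps < alpha, na.rm = TRUE)) {
      fit <- cand
      dropped <- setdiff(dropped, lb)
    }
  }
  fit$selection <- list(kept = fit_term_labels(fit), dropped = dropped,
                        forced = forced, alpha = alpha)
  fit
}

#' Merge adjacent temporal categories by backward F-tests
#'
#' Starting from the most distant pair (more than 3 years vs 2-3 years)
#' and moving towards the event year, tests equality of the two adjacent
#' category effects (Wald/F test at `alpha`, on the cost-magnitude part
#' for two-part fits, classical for the QoL model).  While the difference
#' is not significant the pair is combined into a single indicator and
#' the model refitted; the sweep stops at the first significant
#' difference.  The event-year category is never merged into `no_event`.
#'
#' @param object a `qol_fit` or `two_part` fit.
#' @param type event type, e.g. `"hf"`.
#' @param alpha significance level for the equality test.
#' @return The refitted object; `merged_map[[type]]` maps each original
#'   level to its (possibly merged) label.
#' @export
merge_temporal_categories <- function(object, type, alpha = 0.01) {
  cl <- paste0("cat_", type)
  data <- if (inherits(object, "two_part")) object$data else object$qol_data
  if (is.null(data[[cl]]))
    stop("no temporal-category column for type '", type, "'", call. = FALSE)
  base_lv <- c("y0", "y1_2", "y2_3", "gt3y")
  # only levels with an estimated effect in the tested (magnitude) part
  # can be compared and merged
  part0 <- model_parts(object)[[1L]]
  present <- base_lv[paste0(cl, base_lv) %in% names(part0$coef)]
  map <- stats::setNames(present, present)
  if (length(present) < 2L) {           # nothing to merge
    object$merged_map[[type]] <- map
    return(object)
  }
  groups <- as.list(match(present, base_lv))  # indices into base_lv
  fit <- object
  cur_label <- function(g) if (length(g) == 1L) base_lv[g]
                           else merged_label(min(g), max(g))
  i <- length(groups)
  while (i >= 2L) {
    la <- cur_label(groups[[i]]); lb <- cur_label(groups[[i - 1L]])
    parts <- model_parts(fit)
    part <- parts[[1L]]                 # magnitude / single part
    na_ <- paste0(cl, la); nb_ <- paste0(cl, lb)
    if (!(na_ %in% names(part$coef)) || !(nb_ %in% names(part$coef))) break
    d <- part$coef[na_] - part$coef[nb_]
    v <- part$vcov[na_, na_] + part$vcov[nb_, nb_] - 2 * part$vcov[na_, nb_]
    p <- stats::pchisq(d^2 / v, 1, lower.tail = FALSE)
    if (p < alpha) break                # first significant difference
    groups[[i - 1L]] <- c(groups[[i - 1L]], groups[[i]])
    groups[[i]] <- NULL
    new_lab <- cur_label(groups[[i - 1L]])
    x <- as.character(data[[cl]])
    x[x %in% c(la, lb)] <- new_lab
    lv_new <- c("no_event",
                vapply(groups, cur_label, character(1)))
    data[[cl]] <- factor(x, levels = lv_new)
    fit <- refit_with(fit, fit_term_labels(fit), data = data)
    i <- i - 1L
  }
  for (g in groups)
    map[base_lv[g]] <- cur_label(g)
  fit$merged_map <- object$merged_map
  fit$merged_map[[type]] <- map
  fit
}

# same-period event-year co-occurrence counts for a pair of types
co_occurrence <- function(data, a, b) {
  ya <- data[[paste0("cat_", a)]] == "y0"
  yb <- data[[paste0("cat_", b)]] == "y0"
  c(n_a = sum(ya), n_b = sum(yb), n_ab = sum(ya & yb))
}

#' Screen and retain interactions between co-occurring events
#'
#' For every pair of modelled event types whose same-period event-year
#' co-occurrences exceed `threshold` (5%) of the pair's combined number
#' of contributing event-years, an interaction indicator
#' (both categories in the event year) is tested at `alpha` and retained
#' if significant.  For two-part fits the interaction enters (and is
#' tested in) the cost-magnitude part with cluster-robust covariance.
#'
#' @param object a `qol_fit` or `two_part` fit.
#' @param alpha significance level (default 0.01).
#' @param threshold co-occurrence share triggering a test (default 0.05).
#' @return The refitted object; `interactions` holds the retained terms
#'   and `interaction_trace` the screening record.
#' @export
add_interactions <- function(object, alpha = 0.01, threshold = 0.05) {
  data <- if (inherits(object, "two_part")) object$data else object$qol_data
  labels <- fit_term_labels(object)
  types <- sub("^cat_", "", grep("^cat_", labels, value = TRUE))
  trace <- NULL
  kept <- character(0)
  fit <- object
  if (length(types) >= 2L) {
    pairs <- utils::combn(types, 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      co <- co_occurrence(data, a, b)
      eligible <- co["n_ab"] > 0 &&
        co["n_ab"] > threshold * (co["n_a"] + co["n_b"])
      p <- NA_real_
      if (eligible) {
        term <- sprintf('I(cat_%s == "y0" & cat_%s == "y0")', a, b)
        cand <- if (inherits(fit, "two_part"))
          refit_with(fit, fit_term_labels(fit),
                     interactions = c(fit$interactions, term))
        else refit_with(fit, c(fit_term_labels(fit), term))
        p <- block_p_value(model_parts(cand)[[1L]], term)
        if (is.finite(p) && p < alpha) {
          fit <- cand
          kept <- c(kept, term)
        }
      }
      trace <- rbind(trace, data.frame(
        type_a = a, type_b = b, n_a = co["n_a"], n_b = co["n_b"],
        n_co = co["n_ab"], tested = eligible, p = p,
        retained = eligible && is.finite(p) && p < alpha,
        row.names = NULL))
    }
  }
  fit$merged_map <- object$merged_map
  fit$interactions <- kept
  fit$interaction_trace <- trace
  fit
}

# ---- specification battery ----------------------------------------------

make_family <- function(family, link) {
  switch(family,
         gaussian = stats::gaussian(link = link),
         poisson = stats::quasipoisson(link = link),
         gamma = ,
         Gamma = stats::Gamma(link = link),
         stop("unknown family: ", family, call. = FALSE))
}

family_power <- function(family) {
  switch(family, gaussian = 0, poisson = 1, quasipoisson = 1,
         gamma = 2, Gamma = 2, NA_real_)
}

#' Modified Park test of the variance-mean relationship
#'
#' OLS regression of the log squared raw-scale residuals on the log
#' fitted means over positive fitted values.  A slope near 0 supports a
#' Gaussian (constant-variance) family, near 1 Poisson-type variance
#' proportional to the mean, near 2 a gamma family (variance
#' proportional to the squared mean).
#'
#' @param y observed outcomes.
#' @param mu fitted means.
#' @return List with `slope`, `se`, `nearest` (0, 1 or 2).
#' @export
park_test <- function(y, mu) {
  ok <- is.finite(mu) & mu > 0 & is.finite(y) & (y - mu)^2 > 0
  if (sum(ok) < 10L) return(list(slope = NA_real_, se = NA_real_,
                                 nearest = NA_real_))
  f <- stats::lm(log((y - mu)^2) ~ log(mu), subset = ok,
                 data = data.frame(y = y, mu = mu))
  sl <- unname(stats::coef(f)[2L])
  list(slope = sl, se = unname(sqrt(diag(stats::vcov(f)))[2L]),
       nearest = c(0, 1, 2)[which.min(abs(sl - c(0, 1, 2)))])
}

#' Pregibon-style link test
#'
#' Refits the magnitude model on its own linear predictor and its square;
#' a significant squared term indicates a misspecified link.
#'
#' @param fit a fitted `glm` (the cost-magnitude part).
#' @return p-value of the squared linear predictor (NA if the auxiliary
#'   fit fails).
#' @export
link_test <- function(fit) {
  lp <- stats::predict(fit, type = "link")
  d <- data.frame(y = fit$y, lp = lp)
  aux <- tryCatch(
    fit_glm_safe(y ~ lp + I(lp^2), d, fit$family),
    error = function(e) NULL)
  if (is.null(aux)) return(NA_real_)
  ct <- tryCatch(stats::coef(summary(aux)), error = function(e) NULL)
  if (is.null(ct) || !"I(lp^2)" %in% rownames(ct)) return(NA_real_)
  ct["I(lp^2)", 4L]
}

default_candidates <- function() {
  rbind(
    expand.grid(parts = 2L, family = c("gaussian", "poisson", "gamma"),
                link = c("identity", "log"), stringsAsFactors = FALSE),
    data.frame(parts = 1L, family = c("gaussian", "gaussian", "poisson"),
               link = c("identity", "log", "log"))
  )
}

#' Compare candidate cost-model specifications
#'
#' Fits each candidate (two-part with the given family/link in part 2, or
#' a single-equation GLM) and reports the modified Park-test slope, the
#' Pregibon link-test p-value, AIC/BIC and RMSE/MAE of predicted versus
#' observed cost.  A candidate is *admissible* when the Park slope is
#' nearest its family's variance power and the link test does not reject
#' at `alpha`; candidates are ranked admissible-first, then by RMSE, and
#' the best-ranked one is chosen.
#'
#' @param data person-year data.
#' @param formula cost-model formula.
#' @param cluster participant-id column.
#' @param candidates data frame with columns `parts`, `family`, `link`;
#'   defaults to the full battery.
#' @param alpha link-test level (default 0.01).
#' @return A list of class `spec_comparison`: `table` (ranked results)
#'   and `chosen` (row of the selected specification).
#' @export
compare_specifications <- function(data, formula, cluster = "id",
                                   candidates = default_candidates(),
                                   alpha = 0.01) {
  stopifnot(nrow(candidates) >= 1L)
  data <- data[data$exposure >= 1 - 1e-9 |
                 (if (is.null(data$death_period)) FALSE
                  else data$death_period), , drop = FALSE]
  resp <- as.character(formula[[2L]])
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    fam <- make_family(cand$family, cand$link)
    res <- tryCatch({
      if (cand$parts == 2L) {
        fit <- two_part_glm(formula, data, cluster = cluster,
                            family2 = fam, compute_vcov = FALSE,
                            drop_incomplete = FALSE)
        mag <- fit$part2
        ey <- predict.two_part(fit, type = "response")
        st <- fit_stats(fit)
      } else {
        fit <- fit_glm_safe(formula, data, fam)
        mag <- fit
        ey <- stats::fitted(fit)
        st <- fit_stats(fit)
      }
      y <- data[[resp]]
      pk <- park_test(mag$y, stats::fitted(mag))
      lt <- link_test(mag)
      adm <- is.finite(pk$slope) && is.finite(lt) &&
        pk$nearest == family_power(cand$family) && lt >= alpha
      data.frame(parts = cand$parts, family = cand$family,
                 link = cand$link, park_slope = pk$slope, link_p = lt,
                 aic = st["aic"], bic = st["bic"],
                 rmse = st["rmse"], mae = st["mae"],
                 admissible = adm, converged = TRUE, row.names = NULL)
    }, error = function(e)
      data.frame(parts = cand$parts, family = cand$family,
                 link = cand$link, park_slope = NA, link_p = NA,
                 aic = NA, bic = NA, rmse = NA, mae = NA,
                 admissible = FALSE, converged = FALSE, row.names = NULL))
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$converged))
    stop("no candidate specification converged", call. = FALSE)
  ord <- order(!tab$admissible, tab$rmse)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  out <- list(table = tab, chosen = tab[1L, ])
  class(out) <- "spec_comparison"
  out
}

#' @export
print.spec_comparison <- function(x, digits = 3, ...) {
  cat("Cost-model specification comparison (ranked):\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  cat(sprintf("\nchosen: %d-part %s / %s link\n", x$chosen$parts,
              x$chosen$family, x$chosen$link))
  invisible(x)
}
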