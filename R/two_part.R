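## Two-part annual hospital-cost model.
##
## Part 1: logistic regression for the probability of incurring any
## hospital cost in a person-year.  Periods in which an urgent/nonurgent
## coronary revascularisation or a heart-failure admission occurred are
## excluded from part-1 estimation: such events take place in hospital, so
## the probability of incurring cost is 1 by definition and is fixed at 1
## in prediction.  Part 2: GLM for cost magnitude conditional on any cost
## (default identity-link gamma).  Standard errors are cluster-robust by
## participant on both parts.

# collapse the event-year level of certain-admission event types: those
# person-years never enter part-1 estimation, so the level is empty there
collapse_certain_y0 <- function(data) {
  for (tp in certain_admission_types()) {
    cl <- paste0("cat_", tp)
    if (!is.null(data[[cl]])) {
      x <- as.character(data[[cl]])
      x[x == "y0"] <- "no_event"
      data[[cl]] <- factor(x, levels = setdiff(levels(data[[cl]]), "y0"))
    }
  }
  data
}

# drop bare-column terms that are constant in an estimation subsample
# (single-level factors crash model.matrix; constant numerics alias the
# intercept); their effects are implicitly zero
prune_constant_terms <- function(labels, data) {
  keep <- vapply(labels, function(lb) {
    x <- data[[lb]]
    if (is.null(x)) return(TRUE)          # expression terms stay
    if (is.factor(x)) nlevels(droplevels(x)) >= 2L
    else length(unique(x)) >= 2L
  }, logical(1))
  labels[keep]
}

# map factor levels absent from a fit's xlevels onto the reference level
# (their effect in that part is zero by construction)
align_levels <- function(fit, newdata) {
  for (v in names(fit$xlevels)) {
    x <- newdata[[v]]
    if (is.null(x) || !is.factor(x)) next
    known <- fit$xlevels[[v]]
    bad <- !(as.character(x) %in% known) & !is.na(x)
    if (any(bad)) {
      xc <- as.character(x)
      xc[bad] <- known[1L]
      newdata[[v]] <- factor(xc, levels = known)
    }
  }
  newdata
}

# TRUE where an admission is certain: any occurrence of a
# certain-admission event type in the period
certain_flag <- function(data) {
  occ <- paste0("occ_", certain_admission_types())
  have <- occ[occ %in% names(data)]
  if (length(have)) {
    flag <- rep(FALSE, nrow(data))
    for (cl in have) flag <- flag | data[[cl]]
    flag
  } else if (!is.null(data$certain_admission)) {
    data$certain_admission
  } else rep(FALSE, nrow(data))
}

# Gamma/identity (and other risky family-link pairs) can step outside the
# valid mean space during IRLS.  Try plain glm first; on failure run a
# damped IRLS with step-halving that keeps fitted means positive, then
# hand the solution back to glm as a starting value so the returned object
# is a genuine "glm".
fit_glm_safe <- function(formula, data, family, start = NULL,
                         weights = NULL) {
  fit <- tryCatch(
    suppressWarnings(stats::glm(formula, family = family, data = data,
                                start = start,
                                control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged) return(fit)
  mf <- stats::model.frame(formula, data, drop.unused.levels = TRUE)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  beta <- damped_irls(x, y, family)
  suppressWarnings(stats::glm(formula, family = family, data = data,
                              start = beta,
                              control = stats::glm.control(maxit = 3,
                                                           epsilon = 1e-10)))
}

damped_irls <- function(x, y, family, start = NULL, maxit = 60L,
                        tol = 1e-10, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(y))
  linkinv <- family$linkinv
  variance <- family$variance
  mu.eta <- family$mu.eta
  dev_fun <- function(mu) sum(family$dev.resids(y, mu, weights))
  ok_start <- FALSE
  if (!is.null(start) && length(start) == ncol(x) &&
      all(is.finite(start))) {
    beta <- start
    eta <- drop(x %*% beta)
    ok_start <- family$valideta(eta) && family$validmu(linkinv(eta))
  }
  if (!ok_start) {
    # valid cold start: intercept at the link of mean(y), slopes 0
    int <- which(colnames(x) == "(Intercept)")
    if (!length(int)) beta <- rep(0.1, ncol(x)) else {
      beta <- rep(0, ncol(x)); beta[int] <- family$linkfun(mean(y))
    }
    eta <- drop(x %*% beta)
  }
  dev <- dev_fun(linkinv(eta))
  for (it in seq_len(maxit)) {
    mu <- linkinv(eta)
    me <- mu.eta(eta)
    w <- weights * me^2 / variance(mu)
    z <- eta + (y - mu) / me
    sw <- sqrt(w)
    xw <- x * sw
    # normal equations with a Cholesky solve; QR fallback when singular
    beta_new <- tryCatch(
      drop(solve(crossprod(xw), crossprod(xw, z * sw))),
      error = function(e) NULL)
    if (is.null(beta_new)) {
      qrW <- stats::.lm.fit(xw, z * sw)
      cf <- qrW$coefficients
      if (qrW$rank < length(cf)) cf[(qrW$rank + 1L):length(cf)] <- 0
      cf[is.na(cf)] <- 0
      beta_new <- numeric(ncol(x))
      beta_new[qrW$pivot] <- cf         # undo pivoting
    }
    step <- 1
    repeat {
      b <- beta + step * (beta_new - beta)
      eta_b <- drop(x %*% b)
      mu_b <- linkinv(eta_b)
      ok <- all(is.finite(mu_b)) && all(variance(mu_b) > 0) &&
        family$valideta(eta_b) && family$validmu(mu_b)
      if (ok && (d <- dev_fun(mu_b)) <= dev + 1e-8) break
      step <- step / 2
      if (step < 1e-10) { b <- beta; d <- dev; break }
    }
    conv <- abs(d - dev) / (abs(dev) + 0.1) < tol
    beta <- b; eta <- drop(x %*% beta); dev <- d
    if (conv) break
  }
  if (any(!is.finite(beta)))
    stop("identity-link fit failed to find valid coefficients",
         call. = FALSE)
  beta
}

# coefficients that could not be identified (empty factor cells in a
# subsample) are set to zero so prediction stays defined
zero_na_coefs <- function(fit, label) {
  if (anyNA(stats::coef(fit))) {
    nas <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    warning(label, ": coefficient(s) not estimable, set to 0: ",
            paste(nas, collapse = ", "), call. = FALSE)
    fit$coefficients[is.na(fit$coefficients)] <- 0
    fit$aliased_coefs <- nas
  }
  fit
}

# cluster-robust sandwich covariance for a glm; equals sandwich::vcovCL
# (HC0 meat, G/(G-1) cluster adjustment) but tolerates aliased
# coefficients, whose rows/columns are returned as zero
robust_cluster_vcov <- function(fit, cluster) {
  if (is.null(fit$aliased_coefs))
    return(sandwich::vcovCL(fit, cluster = cluster))
  X <- stats::model.matrix(fit)
  keep <- !colnames(X) %in% fit$aliased_coefs
  Xk <- X[, keep, drop = FALSE]
  w <- fit$weights
  r <- fit$residuals                      # working residuals
  ef <- Xk * (w * r)
  Sg <- rowsum(ef, group = cluster)
  G <- nrow(Sg)
  B <- chol2inv(chol(crossprod(Xk * sqrt(w))))
  Vk <- B %*% (crossprod(Sg) * G / (G - 1)) %*% B
  p <- ncol(X)
  V <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  V[keep, keep] <- Vk
  V
}

#' Fit a two-part model for annual hospital costs
#'
#' @param formula model formula; the left-hand side is the annual cost,
#'   the right-hand side is shared by both parts (part 1 models
#'   `cost > 0` with a logit link on the same covariates).
#' @param data person-year data frame (see [person_year_table()]).  Rows
#'   with incomplete exposure that are not death periods are dropped from
#'   estimation (partial administrative-censoring years are not annual
#'   observations).
#' @param cluster name of the participant-id column used for
#'   cluster-robust covariances (default `"id"`).
#' @param family2 family/link for the conditional-magnitude part
#'   (default `Gamma(link = "identity")`, the specification retained for
#'   this analysis).
#' @param exclude_certain exclude certain-admission periods from part-1
#'   estimation (default `TRUE`; see Details).
#' @param compute_vcov compute cluster-robust covariances (skip inside
#'   bootstrap refits for speed).
#' @param start optional list with `p1` and `p2` starting coefficient
#'   vectors (warm starts for bootstrap refits).
#' @param drop_incomplete drop administratively censored partial years
#'   (default `TRUE`).
#' @param interactions character vector of extra terms (event
#'   co-occurrence indicators, see [add_interactions()]) entering the
#'   cost-magnitude part only.
#' @details Periods in which an urgent/nonurgent coronary
#'   revascularisation or heart-failure admission occurred always carry
#'   hospital cost; they are excluded from part-1 estimation and their
#'   predicted probability of any cost is fixed at 1.  Consequently the
#'   event-year level of those event types does not appear in part 1.
#' @return An object of class `two_part` with components `part1`, `part2`
#'   (glm fits), `vcov1`, `vcov2` (cluster-robust), `shape` (gamma shape
#'   from Pearson dispersion), `data`, `merged_map`, `interactions`.
#' @seealso [recycled_prediction()], [cluster_bootstrap()],
#'   [merge_temporal_categories()], [add_interactions()]
#' @export
two_part_glm <- function(formula, data, cluster = "id",
                         family2 = stats::Gamma(link = "identity"),
                         exclude_certain = TRUE, compute_vcov = TRUE,
                         start = NULL, drop_incomplete = TRUE,
                         interactions = character(0)) {
  if (is.character(family2)) family2 <- get(family2)()
  if (drop_incomplete && !is.null(data$exposure)) {
    dp <- if (is.null(data$death_period)) FALSE else data$death_period
    data <- data[data$exposure >= 1 - 1e-9 | dp, , drop = FALSE]
  }
  resp <- as.character(formula[[2L]])
  y <- data[[resp]]
  if (is.null(y)) stop("response '", resp, "' not found in data",
                       call. = FALSE)
  data$.any_cost <- as.integer(y > 0)
  cert <- certain_flag(data)

  shared <- attr(stats::terms(formula), "term.labels")

  d1 <- if (exclude_certain) data[!cert, , drop = FALSE] else data
  d1 <- collapse_certain_y0(d1)
  lab1 <- prune_constant_terms(shared, d1)
  f1 <- stats::reformulate(if (length(lab1)) lab1 else "1",
                           response = ".any_cost")
  part1 <- suppressWarnings(stats::glm(f1, family = stats::binomial(),
                                       data = d1, start = start$p1))
  part1 <- zero_na_coefs(part1, "part 1")

  d2 <- data[y > 0, , drop = FALSE]
  if (nrow(d2) == 0L)
    stop("no positive-cost observations: part 2 cannot be fitted",
         call. = FALSE)
  lab2 <- c(prune_constant_terms(shared, d2), interactions)
  f2 <- stats::reformulate(if (length(lab2)) lab2 else "1",
                           response = resp)
  part2 <- fit_glm_safe(f2, d2, family2, start = start$p2)
  part2 <- zero_na_coefs(part2, "part 2")

  pearson <- sum(stats::residuals(part2, type = "pearson")^2)
  dispersion <- pearson / part2$df.residual
  obj <- list(part1 = part1, part2 = part2,
              formula = formula, shared_labels = shared,
              cluster = cluster,
              family2 = family2,
              exclude_certain = exclude_certain,
              dispersion = dispersion,
              shape = 1 / dispersion,
              data = data,
              merged_map = list(),
              interactions = interactions,
              call = match.call())
  class(obj) <- "two_part"
  if (compute_vcov) {
    obj$vcov1 <- robust_cluster_vcov(part1, d1[[cluster]])
    obj$vcov2 <- robust_cluster_vcov(part2, d2[[cluster]])
  }
  obj
}

#' @export
print.two_part <- function(x, ...) {
  cat("Two-part annual-cost GLM",
      sprintf("(part 2: %s, %s link)\n", x$family2$family, x$family2$link))
  cat(sprintf("  %d person-years (%d with any cost, %.1f%%); %d clusters\n",
              nrow(x$data), sum(x$data$.any_cost),
              100 * mean(x$data$.any_cost),
              length(unique(x$data[[x$cluster]]))))
  if (x$exclude_certain)
    cat(sprintf("  part 1 excludes %d certain-admission period(s)\n",
                sum(certain_flag(x$data))))
  cat("  gamma shape (1/dispersion):", format(x$shape, digits = 3), "\n")
  if (length(x$merged_map))
    cat("  merged temporal categories:",
        paste(names(x$merged_map), collapse = ", "), "\n")
  if (length(x$interactions))
    cat("  retained interactions:",
        paste(x$interactions, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.two_part <- function(object, part = c("both", "1", "2"), ...) {
  part <- match.arg(as.character(part), c("both", "1", "2"))
  switch(part,
         "1" = stats::coef(object$part1),
         "2" = stats::coef(object$part2),
         list(part1 = stats::coef(object$part1),
              part2 = stats::coef(object$part2)))
}

#' @export
vcov.two_part <- function(object, part = 2, ...) {
  v <- if (as.character(part) == "1") object$vcov1 else object$vcov2
  if (is.null(v)) stop("covariances were not computed for this fit",
                       call. = FALSE)
  v
}

#' Predict from a two-part cost model
#'
#' @param object a `two_part` fit.
#' @param newdata person-year data; defaults to the estimation data.
#' @param type `"response"` (expected cost, probability x conditional
#'   mean), `"prob"` (part-1 probability, 1 for certain-admission
#'   periods) or `"cond"` (conditional magnitude).
#' @param ... unused.
#' @export
predict.two_part <- function(object, newdata = NULL,
                             type = c("response", "prob", "cond"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  if (type %in% c("response", "prob")) {
    nd1 <- align_levels(object$part1, collapse_certain_y0(newdata))
    p <- stats::predict(object$part1, newdata = nd1, type = "response")
    if (object$exclude_certain) p[certain_flag(newdata)] <- 1
    if (type == "prob") return(unname(p))
  }
  mu <- stats::predict(object$part2,
                       newdata = align_levels(object$part2, newdata),
                       type = "response")
  if (type == "cond") return(unname(mu))
  unname(p * mu)
}

#' @export
residuals.two_part <- function(object, type = "response", ...) {
  y <- object$data[[as.character(object$formula[[2L]])]]
  y - predict.two_part(object, type = "response")
}

#' @export
fitted.two_part <- function(object, ...) {
  predict.two_part(object, type = "response")
}

#' Simulate annual costs from a fitted two-part model
#'
#' Draws any-cost indicators from part 1 (with certain-admission periods
#' fixed at probability 1) and positive costs from the part-2 gamma with
#' the estimated shape.
#'
#' @param object a `two_part` fit.
#' @param nsim number of simulated cost vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns, one row per person-year.
#' @export
simulate.two_part <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict.two_part(object, type = "prob")
  mu <- pmax(predict.two_part(object, type = "cond"), 1e-8)
  shape <- object$shape
  out <- replicate(nsim, {
    any <- stats::runif(length(p)) < p
    ifelse(any, stats::rgamma(length(p), shape = shape, rate = shape / mu), 0)
  })
  as.data.frame(out)
}

#' @export
summary.two_part <- function(object, ...) {
  ctab <- function(fit, V) {
    b <- stats::coef(fit)
    se <- sqrt(diag(V))[names(b)]
    z <- b / se
    cbind(Estimate = b, `Cluster SE` = se, z = z,
          `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  }
  out <- list(part1 = ctab(object$part1, vcov.two_part(object, 1)),
              part2 = ctab(object$part2, vcov.two_part(object, 2)),
              shape = object$shape, family2 = object$family2,
              n = nrow(object$data),
              merged_map = object$merged_map,
              interactions = object$interactions,
              stats = fit_stats(object))
  class(out) <- "summary.two_part"
  out
}

#' @export
print.summary.two_part <- function(x, digits = 4, ...) {
  cat("Part 1 (logit, any cost; cluster-robust SEs):\n")
  stats::printCoefmat(x$part1, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nPart 2 (%s, %s link; cluster-robust SEs):\n",
              x$family2$family, x$family2$link))
  stats::printCoefmat(x$part2, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nshape %.3f | RMSE %.1f | MAE %.1f | AIC %.1f\n",
              x$shape, x$stats["rmse"], x$stats["mae"], x$stats["aic"]))
  invisible(x)
}

#' Fit statistics for cost-model candidates
#'
#' RMSE and MAE of predicted versus observed cost, and the summed AIC/BIC
#' of the parts (part-2 likelihood evaluated at the Pearson-estimated
#' gamma shape where applicable).
#'
#' @param object a `two_part` fit or a one-part `glm`.
#' @return Named numeric vector `rmse`, `mae`, `aic`, `bic`.
#' @export
fit_stats <- function(object) {
  if (inherits(object, "two_part")) {
    y <- object$data[[as.character(object$formula[[2L]])]]
    ey <- predict.two_part(object, type = "response")
    aic <- stats::AIC(object$part1) + stats::AIC(object$part2)
    bic <- stats::BIC(object$part1) + stats::BIC(object$part2)
  } else {
    y <- object$y
    if (is.null(y)) y <- stats::model.response(stats::model.frame(object))
    ey <- stats::fitted(object)
    aic <- tryCatch(stats::AIC(object), error = function(e) NA_real_)
    bic <- tryCatch(stats::BIC(object), error = function(e) NA_real_)
  }
  c(rmse = sqrt(mean((y - ey)^2)), mae = mean(abs(y - ey)),
    aic = aic, bic = bic)
}

#' @export
plot.two_part <- function(x, ...) {
  y <- x$data[[as.character(x$formula[[2L]])]]
  ey <- predict.two_part(x, type = "response")
  graphics::plot(ey, y, xlab = "predicted annual cost",
                 ylab = "observed annual cost", pch = 16,
                 col = grDevices::grey(0.4, 0.4), ...)
  graphics::abline(0, 1, col = 2)
  invisible(x)
}
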