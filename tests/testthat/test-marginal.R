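test_that("recycled prediction equals an explicit counterfactual-dataset
           oracle", {
  ch <- generate_cohort(cohort_config(n = 120, seed = 61))
  py <- py_of(ch, "uk")
  fit <- suppressWarnings(two_part_glm(cost_formula(), py))
  for (on in list(c(ncr = "y0"), c(stroke = "y1_2"),
                  c(mi = "y0", ucrv = "y0"))) {
    # oracle: build both counterfactual datasets explicitly and average
    # row-wise prediction differences using raw glm predictions
    build <- function(active) {
      d <- fit$data
      for (tp in names(on)) {
        d[[paste0("cat_", tp)]][] <- if (active) on[[tp]] else "no_event"
        if (tp %in% certain_admission_types())
          d[[paste0("occ_", tp)]] <- active && on[[tp]] == "y0"
      }
      d
    }
    # levels with no estimated effect in a part count as the reference
    align <- function(g, d) {
      for (v in names(g$xlevels)) {
        if (!is.factor(d[[v]])) next
        x <- as.character(d[[v]])
        x[!x %in% g$xlevels[[v]]] <- g$xlevels[[v]][1]
        d[[v]] <- factor(x, levels = g$xlevels[[v]])
      }
      d
    }
    expected_cost <- function(d) {
      d1 <- d
      for (tp in certain_admission_types()) {
        x <- as.character(d1[[paste0("cat_", tp)]])
        x[x == "y0"] <- "no_event"
        d1[[paste0("cat_", tp)]] <-
          factor(x, levels = setdiff(levels(d[[paste0("cat_", tp)]]),
                                     "y0"))
      }
      p <- stats::predict(fit$part1, newdata = align(fit$part1, d1),
                          type = "response")
      p[d$occ_ucrv | d$occ_ncrv | d$occ_hf] <- 1
      mu <- stats::predict(fit$part2, newdata = align(fit$part2, d),
                           type = "response")
      p * mu
    }
    oracle <- mean(expected_cost(build(TRUE)) -
                     expected_cost(build(FALSE)))
    expect_equal(as.numeric(recycled_prediction(fit, on = on)), oracle,
                 tolerance = 1e-12)
  }
})

test_that("with probability one the identity-link increment is the
           part-2 coefficient", {
  set.seed(62)
  n <- 900
  ev <- sample(c("no_event", "y0"), n, TRUE)
  d <- data.frame(id = seq_len(n), exposure = 1, death_period = FALSE,
                  cat_mi = factor(ev, levels = temporal_levels()))
  d$cost <- rgamma(n, 2, 2 / (800 + 2500 * (ev == "y0")))
  d$any_cost <- TRUE
  fit <- suppressWarnings(two_part_glm(cost ~ cat_mi, d))
  inc <- recycled_prediction(fit, on = c(mi = "y0"))
  expect_equal(as.numeric(inc), unname(coef(fit$part2)["cat_miy0"]),
               tolerance = 1e-4)
})

test_that("merged-away categories are resolved to their merged label", {
  set.seed(65)
  n_id <- 800; periods <- 5
  id <- rep(seq_len(n_id), each = periods)
  period <- rep(seq_len(periods) - 1L, n_id)
  ev_day <- ifelse(runif(n_id) < 0.6, runif(n_id, 0, 4.5 * 365.25), NA)
  cat_mi <- factor(cost_category(pmin(ev_day, periods * 365.25 - 1)[id],
                                 period), levels = temporal_levels())
  p <- plogis(-0.8 + 0.8 * (cat_mi != "no_event"))
  mu <- 1000 + 3000 * (cat_mi != "no_event")  # equal effect, all four
  any <- runif(length(id)) < p
  d <- data.frame(id = id, exposure = 1, death_period = FALSE,
                  cost = ifelse(any, rgamma(length(id), 0.5, 0.5 / mu), 0),
                  any_cost = any, cat_mi = cat_mi)
  fit <- suppressWarnings(two_part_glm(cost ~ cat_mi, d))
  fit <- suppressWarnings(merge_temporal_categories(fit, "mi"))
  lab <- fit$merged_map$mi[["y1_2"]]
  expect_false(lab == "y1_2")   # truly equal effects get merged
  expect_false("cat_miy1_2" %in% names(coef(fit$part2)))
  inc <- recycled_prediction(fit, on = c(mi = "y1_2"))
  expect_true(is.finite(as.numeric(inc)))
  expect_equal(as.numeric(inc),
               as.numeric(recycled_prediction(fit, on = setNames(lab, "mi"))))
  expect_error(recycled_prediction(fit, on = c(mi = "nonsense")),
               "unknown temporal category")
})

test_that("the cluster bootstrap is seeded, reproducible and collapses
           for degenerate data", {
  set.seed(63)
  d <- data.frame(id = rep(1:80, each = 3), x = rnorm(240))
  stat <- function(dd) c(m = mean(dd$x))
  b1 <- cluster_bootstrap(d, stat, B = 60, seed = 5)
  b2 <- cluster_bootstrap(d, stat, B = 60, seed = 5)
  expect_identical(b1$ci, b2$ci)
  b3 <- cluster_bootstrap(d, stat, B = 60, seed = 6)
  expect_false(identical(b1$ci, b3$ci))
  expect_true(b1$ci["m", "lower"] <= b1$estimate["m"])
  expect_true(b1$ci["m", "upper"] >= b1$estimate["m"])
  # identical participants: every resample gives the same statistic
  d0 <- data.frame(id = rep(1:40, each = 2), x = rep(c(1, 2), 40))
  b0 <- cluster_bootstrap(d0, stat, B = 30, seed = 7)
  expect_equal(unname(b0$se), 0)
})

test_that("bootstrap SE of a sample mean matches the closed form", {
  set.seed(64)
  d <- data.frame(id = seq_len(500), x = rnorm(500, 10, 3))
  b <- cluster_bootstrap(d, function(dd) c(m = mean(dd$x)), B = 400,
                         seed = 8)
  closed <- sd(d$x) / sqrt(nrow(d))
  expect_lt(abs(b$se["m"] - closed) / closed, 0.15)
})

test_that("bootstrap percentile intervals cover the generating increment
           at close to nominal rate", {
  # reduced design: one event type, analytic truth from the generating
  # two-part parameters on each replicate's own design
  covered <- 0L
  n_rep <- 50L
  for (s in seq_len(n_rep)) {
    set.seed(7000 + s)
    n_id <- 150; periods <- 3
    id <- rep(seq_len(n_id), each = periods)
    period <- rep(seq_len(periods) - 1L, n_id)
    ev_day <- ifelse(runif(n_id) < 0.5,
                     runif(n_id, 0, periods * 365.25), NA)
    cat_mi <- factor(cost_category(ev_day[id], period),
                     levels = temporal_levels())
    p <- plogis(-0.5 + 1.2 * (cat_mi == "y0"))
    mu <- 1000 + 2500 * (cat_mi == "y0") + 500 * (cat_mi %in%
                                                    c("y1_2", "y2_3"))
    any <- runif(length(id)) < p
    d <- data.frame(id = id, exposure = 1, death_period = FALSE,
                    cost = ifelse(any, rgamma(length(id), 0.5,
                                              0.5 / mu), 0),
                    any_cost = any, cat_mi = cat_mi)
    truth <- mean(plogis(-0.5 + 1.2) * (1000 + 2500) -
                    plogis(-0.5) * 1000)
    fit <- tryCatch(suppressWarnings(two_part_glm(cost ~ cat_mi, d,
                                                  compute_vcov = FALSE)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    inc <- suppressWarnings(
      incremental_costs(fit, list(mi = c(mi = "y0")), B = 200,
                        seed = s))
    covered <- covered + (inc$lower[1] <= truth && truth <= inc$upper[1])
  }
  expect_gte(covered / n_rep, 0.88)
  expect_lte(covered / n_rep, 1)
})

test_that("QoL decrements report at merged granularity and straddle zero
           under null effects", {
  qd <- tiny_qol()
  fit <- qol_lm(qol_formula(), qd)
  tab <- qol_decrement_table(fit)
  expect_true(all(tab$lower <= tab$estimate & tab$estimate <= tab$upper))
  expect_setequal(unique(tab$type),
                  c("mi", "stroke", "ucrv", "ncrv", "hf", "ncr",
                    "cancer", "diabetes"))
  # null-effect types (mi, ucrv, ncrv, diabetes) stay near zero
  null_rows <- tab[tab$type %in% c("mi", "ucrv", "ncrv", "diabetes"), ]
  expect_true(all(abs(null_rows$estimate) < 4.5 * null_rows$se))
  # after merging, the table reports merged labels
  fitm <- merge_temporal_categories(fit, "diabetes")
  tabm <- qol_decrement_table(fitm)
  expect_true(any(tabm$type == "diabetes" &
                    !tabm$category %in% c("y0", "y1_2", "y2_3", "gt3y")))
})
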