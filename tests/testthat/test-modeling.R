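# small two-part simulator with one event type (no certain-admission
# types), used for focused model checks
sim_tp <- function(n_id, periods = 3, p0 = -1, b_y0 = 1.5, mu0 = 1000,
                   delta = 3000, shape = 0.5, seed = 1) {
  set.seed(seed)
  id <- rep(seq_len(n_id), each = periods)
  period <- rep(seq_len(periods) - 1L, n_id)
  ev_day <- ifelse(runif(n_id) < 0.4,
                   runif(n_id, 0, periods * 365.25), NA)
  cat_mi <- factor(cost_category(ev_day[id], period),
                   levels = temporal_levels())
  p <- plogis(p0 + b_y0 * (cat_mi == "y0"))
  mu <- mu0 + delta * (cat_mi == "y0")
  any <- runif(length(id)) < p
  cost <- ifelse(any, rgamma(length(id), shape, rate = shape / mu), 0)
  data.frame(id = id, period = period, exposure = 1,
             death_period = FALSE, cost = cost, any_cost = any,
             cat_mi = cat_mi)
}

test_that("continuous covariates are imputed by sex x smoking x arm cell
           means", {
  d <- data.frame(female = rep(0:1, each = 6),
                  smoking = rep(c("never", "current"), 6),
                  arm = rep(c("A", "B"), 6),
                  bmi = c(24, 26, NA, 30, 31, 32, 25, NA, 27, 28, 29, 30))
  full <- d[!is.na(d$bmi), ]
  out <- impute_covariates(d, vars = "bmi")
  expect_false(anyNA(out$bmi))
  # untouched where complete
  expect_equal(out$bmi[!is.na(d$bmi)], d$bmi[!is.na(d$bmi)])
  # the imputed value is its cell's mean
  i <- which(is.na(d$bmi))[1]
  cell <- full$female == d$female[i] & full$smoking == d$smoking[i] &
    full$arm == d$arm[i]
  expect_equal(out$bmi[i], mean(full$bmi[cell]))
  # no missing values: table unchanged
  expect_identical(impute_covariates(full, vars = "bmi"), full)
  # an empty cell falls back to the overall mean with a warning
  d2 <- data.frame(female = c(0, 0, 1), smoking = "never", arm = "A",
                   bmi = c(NA, NA, 31))
  d2$female <- c(0, 0, 1)
  expect_warning(out2 <- impute_covariates(d2, vars = "bmi"),
                 "overall mean")
  expect_equal(out2$bmi[1:2], rep(31, 2))
})

test_that("the QoL model interpolates noise-free data exactly", {
  set.seed(21)
  n <- 400
  d <- data.frame(age = rnorm(n, 67, 8), female = rbinom(n, 1, 0.15),
                  baseline_u = runif(n, 0.5, 1),
                  cat_hf = factor(sample(temporal_levels(), n, TRUE),
                                  levels = temporal_levels()))
  d$final_u <- 0.9 - 0.001 * (d$age - 67) - 0.02 * d$female +
    0.3 * (d$baseline_u - 0.84) - 0.07 * (d$cat_hf == "y0") -
    0.01 * (d$cat_hf == "y1_2")
  f <- qol_lm(final_u ~ I(age - 67) + female + I(baseline_u - 0.84) +
                cat_hf, d)
  b <- coef(f)
  expect_equal(unname(b["(Intercept)"]), 0.9, tolerance = 1e-10)
  expect_equal(unname(b["cat_hfy0"]), -0.07, tolerance = 1e-10)
  expect_equal(unname(b["I(baseline_u - 0.84)"]), 0.3, tolerance = 1e-10)
  # collinear design errors with the offending column named
  d$dup <- d$female
  expect_error(qol_lm(final_u ~ female + dup, d), "dup")
})

test_that("with all costs positive part 1 degenerates and expected cost
           reduces to the part-2 mean", {
  d <- sim_tp(250, p0 = 30, seed = 2)      # p ~ 1 everywhere
  expect_true(all(d$any_cost))
  fit <- suppressWarnings(two_part_glm(cost ~ cat_mi, d))
  expect_true(all(predict(fit, type = "prob") > 0.999))
  expect_equal(predict(fit, type = "response"),
               predict(fit, type = "cond"), tolerance = 1e-3)
})

test_that("fitted two-part expectation decomposes the sample mean", {
  d <- sim_tp(800, seed = 3)
  fit <- two_part_glm(cost ~ cat_mi, d)
  expect_equal(mean(predict(fit, type = "response")), mean(d$cost),
               tolerance = 0.03)
  # simulate() reproduces the any-cost rate and mean cost
  sims <- simulate(fit, nsim = 20, seed = 4)
  expect_equal(mean(colMeans(sims > 0)), mean(d$any_cost),
               tolerance = 0.02)
  expect_equal(mean(colMeans(sims)), mean(d$cost), tolerance = 0.1)
})

test_that("certain-admission periods are excluded from part 1 without
           touching part 2", {
  py <- tiny_py("uk")
  fit <- two_part_glm(cost_formula(), py)
  cert <- py$certain_admission & (py$exposure >= 1 | py$death_period)
  keep <- py$exposure >= 1 | py$death_period
  expect_equal(nobs(fit$part1), sum(keep) - sum(cert))
  expect_equal(nobs(fit$part2), sum(py$cost[keep] > 0))
  # the event-year level of certain types is absent from part 1
  expect_false("cat_ucrvy0" %in% names(coef(fit$part1)))
  expect_true("cat_ucrvy0" %in% names(coef(fit$part2)))
  # dropping the rule changes part 1 but leaves part 2 identical
  fit_all <- two_part_glm(cost_formula(), py, exclude_certain = FALSE)
  expect_equal(coef(fit_all$part2), coef(fit$part2))
  expect_gt(nobs(fit_all$part1), nobs(fit$part1))
  # certain periods predict probability exactly 1
  expect_true(all(predict(fit, type = "prob")[
    certain_flag(fit$data)] == 1))
})

test_that("cluster-robust covariance reduces to the classical sandwich
           for singleton clusters", {
  d <- sim_tp(500, periods = 1, seed = 6)
  fit <- two_part_glm(cost ~ cat_mi, d)
  G1 <- nobs(fit$part1); G2 <- nobs(fit$part2)
  hc1 <- sandwich::vcovHC(fit$part1, type = "HC0") * G1 / (G1 - 1)
  hc2 <- sandwich::vcovHC(fit$part2, type = "HC0") * G2 / (G2 - 1)
  expect_equal(vcov(fit, 1), hc1, tolerance = 1e-8)
  expect_equal(vcov(fit, 2), hc2, tolerance = 1e-8)
})

test_that("the Park slope identifies the gamma variance power", {
  set.seed(8)
  n <- 4000
  mu <- 500 + 3000 * runif(n)
  y <- mu * rgamma(n, 0.5, 0.5)
  pk <- park_test(y, mu)
  expect_within(pk$slope, 2, 0.3)
  expect_equal(pk$nearest, 2)
  # constant-variance data points to the Gaussian family
  y0 <- mu + rnorm(n, 0, 100)
  expect_equal(park_test(y0, mu)$nearest, 0)
})

test_that("a single specification candidate is chosen trivially", {
  d <- sim_tp(300, seed = 9)
  one <- compare_specifications(d, cost ~ cat_mi,
                                candidates = data.frame(
                                  parts = 2, family = "gamma",
                                  link = "identity"))
  expect_equal(nrow(one$table), 1)
  expect_equal(one$chosen$family, "gamma")
})

test_that("backward/forward selection drops null blocks and keeps real
           and forced ones", {
  n_drop <- n_keep <- n_forced <- 0L
  for (s in 1:12) {
    set.seed(500 + s)
    n <- 1500
    d <- data.frame(age = rnorm(n, 67, 8), female = rbinom(n, 1, 0.15),
                    x_strong = rbinom(n, 1, 0.3),
                    x_null = rbinom(n, 1, 0.3),
                    baseline_u = runif(n, 0.6, 1))
    d$final_u <- 0.9 - 0.05 * d$x_strong +
      0.2 * (d$baseline_u - 0.84) + rnorm(n, 0, 0.15)
    fit <- qol_lm(final_u ~ I(age - 67) + female +
                    I(baseline_u - 0.84) + x_strong + x_null, d)
    sel <- select_covariates(fit)
    n_drop <- n_drop + ("x_null" %in% sel$selection$dropped)
    n_keep <- n_keep + ("x_strong" %in% sel$selection$kept)
    n_forced <- n_forced +
      all(c("I(age - 67)", "female") %in% sel$selection$kept)
  }
  expect_gte(n_drop, 10)    # ~99% per replicate at the 1% level
  expect_equal(n_keep, 12L) # ample power for the real effect
  expect_equal(n_forced, 12L)
})

test_that("generating coefficients fall inside their 95% confidence
           intervals at close to nominal rate", {
  keys <- c("cat_hfy0", "female", "I(baseline_u - 0.84)")
  truth <- c(-0.072, -0.025, 0.19)
  n_rep <- 50L
  covered <- matrix(FALSE, n_rep, length(keys))
  for (s in seq_len(n_rep)) {
    ch <- generate_cohort(cohort_config(n = 3000, seed = 5000 + s))
    qd <- suppressMessages(build_qol_data(ch))
    fit <- qol_lm(qol_formula(), qd)
    b <- coef(fit)[keys]
    se <- sqrt(diag(vcov(fit)))[keys]
    covered[s, ] <- abs(b - truth) <= qnorm(0.975) * se
  }
  for (j in seq_along(keys)) {
    expect_gte(mean(covered[, j]), 0.86)
    expect_lte(mean(covered[, j]), 1)
  }
})

test_that("temporal-category merging is a no-op for single-category
           types", {
  py <- tiny_py("uk")
  fit <- two_part_glm(cost_formula(), py)
  out <- merge_temporal_categories(fit, "vdeath")  # terminal: y0 only
  expect_equal(out$merged_map$vdeath, c(y0 = "y0"))
  expect_equal(coef(out$part2), coef(fit$part2))
})

test_that("interactions are only screened above the co-occurrence
           threshold", {
  d <- sim_tp(500, seed = 10)
  # a second event type that never co-occurs with the first in its
  # event year
  d$cat_stroke <- factor(ifelse(d$cat_mi == "no_event" & d$period == 2,
                                "y0", "no_event"),
                         levels = temporal_levels())
  fit <- two_part_glm(cost ~ cat_mi + cat_stroke, d)
  out <- add_interactions(fit)
  tr <- out$interaction_trace
  expect_equal(nrow(tr), 1)
  expect_equal(tr$n_co, 0)
  expect_false(tr$tested)
  expect_length(out$interactions, 0)
})
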