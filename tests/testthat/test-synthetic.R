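test_that("a degenerate configuration yields an event-free, cost-free
           cohort", {
  rates <- setNames(rep(0, 10), event_types())
  ct <- cvdimpact:::default_cost_truth()
  ct$part1$intercept <- -Inf
  cfg <- cohort_config(n = 60, seed = 4, event_rates = rates,
                       cost_truth = ct)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$events), 0)
  expect_true(all(ch$annual_costs$cost_uk == 0))
  expect_true(all(!ch$annual_costs$any_cost))
  py <- build_cost_categories(ch$annual_costs, ch$events)
  for (tp in event_types())
    expect_true(all(py[[paste0("cat_", tp)]] == "no_event"))
})

test_that("generation is byte-identical given the same seed", {
  c1 <- generate_cohort(cohort_config(n = 150, seed = 33))
  c2 <- generate_cohort(cohort_config(n = 150, seed = 33))
  for (nm in c("participants", "events", "annual_costs", "profiles",
               "episodes"))
    expect_identical(c1[[nm]], c2[[nm]])
  c3 <- generate_cohort(cohort_config(n = 150, seed = 34))
  expect_false(identical(c1$annual_costs, c3$annual_costs))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(event_rates = c(mi = 0.5)), "event_rates")
  er <- setNames(rep(0.02, 10), event_types()); er["mi"] <- 1.4
  expect_error(cohort_config(event_rates = er), "event_rates")
  expect_error(cohort_config(ucrv_given_mi = 2), "ucrv_given_mi")
  expect_error(cohort_config(followup_range = c(5, 4)), "followup_range")
  ct <- cvdimpact:::default_cost_truth(); ct$shape <- -1
  expect_error(cohort_config(cost_truth = ct), "cost_truth")
  expect_error(cohort_config(bogus_field = 1), "bogus_field")
})

test_that("generated marginals match the configured calibration", {
  ch <- generate_cohort(cohort_config(n = 6000, seed = 55))
  part <- ch$participants
  n <- nrow(part)
  # cumulative MI incidence near 4.5% (3 binomial SDs)
  mi <- mean(part$id %in% ch$events$id[ch$events$type == "mi"])
  expect_within(mi, 0.045, 3 * sqrt(0.045 * 0.955 / n))
  # female fraction near 14.3% (4 binomial SDs)
  expect_within(mean(part$female), 0.143, 4 * sqrt(0.143 * 0.857 / n))
  # any-cost share of person-years near 20%
  expect_within(mean(ch$annual_costs$any_cost), 0.20, 0.02)
})

test_that("every event falls inside its participant's follow-up window", {
  ch <- tiny_cohort()
  part <- ch$participants
  end <- pmin(part$followup_day, part$death_day, na.rm = TRUE)
  i <- match(ch$events$id, part$id)
  expect_true(all(ch$events$day >= 0))
  expect_true(all(ch$events$day <= end[i] + 1e-9))
  # death events occur exactly once and at the death day
  for (tp in death_types()) {
    de <- ch$events[ch$events$type == tp, ]
    expect_false(any(duplicated(de$id)))
    expect_equal(de$day, part$death_day[match(de$id, part$id)])
  }
})

test_that("empirical mean annual cost matches the analytic two-part
           oracle", {
  ch <- generate_cohort(cohort_config(n = 4000, seed = 77))
  cfg <- ch$config
  py <- build_cost_categories(ch$annual_costs, ch$events)
  partial <- py$exposure < 1 & !py$death_period
  p <- cvdimpact:::cost_truth_p(py, cfg$cost_truth$part1)
  p[partial] <- 1 - (1 - p[partial])^py$exposure[partial]
  mu <- cvdimpact:::cost_truth_mu(py, cfg$cost_truth$uk)
  scale_f <- ifelse(partial, py$exposure, 1)
  analytic <- sum(p * mu * scale_f) / sum(py$exposure)
  empirical <- sum(ch$annual_costs$cost_uk) / sum(ch$annual_costs$exposure)
  mc_se <- sd(ch$annual_costs$cost_uk) / sqrt(nrow(py)) *
    nrow(py) / sum(py$exposure)
  expect_within(empirical, analytic, 4 * mc_se)
})

test_that("baseline profiles reproduce the configured utility
           distribution", {
  ch <- full_cohort()
  tar <- eq5d_tariff("synthetic_uk")
  bl <- ch$profiles[ch$profiles$visit == "baseline", ]
  s <- summarize_utilities(bl, tar)
  expect_within(s$mean, 0.84, 0.01)
  expect_within(s$sd, 0.16, 0.01)
})

test_that("cohort bundles round-trip through CSV/JSON persistence", {
  dir <- tempfile("cohort")
  ch <- generate_cohort(cohort_config(n = 80, seed = 12))
  write_cohort(ch, dir)
  expect_true(all(file.exists(file.path(dir,
    c("participants.csv", "events.csv", "annual_costs.csv",
      "profiles.csv", "episodes.csv", "config.json", "manifest.json")))))
  back <- read_cohort(dir)
  expect_equal(back$participants$id, ch$participants$id)
  expect_equal(back$annual_costs$cost_uk, ch$annual_costs$cost_uk,
               tolerance = 1e-10)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 12)
  expect_equal(man$n_participants, 80)
})
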