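ep <- function(...) {
  m <- if (...length() == 0L) matrix(numeric(0), ncol = 3)
       else matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(admission_day = m[, 1], discharge_day = m[, 2],
             unit_cost = m[, 3])
}

test_that("overlapping episodes are combined with costs summed", {
  expect_equal(nrow(merge_overlapping(ep())), 0)
  m <- merge_overlapping(ep(0, 10, 100, 5, 15, 50))
  expect_equal(m$admission_day, 0)
  expect_equal(m$discharge_day, 15)
  expect_equal(m$unit_cost, 150)
  # abutting but disjoint stays separate; same-day readmission merges
  expect_equal(nrow(merge_overlapping(ep(0, 5, 10, 6, 8, 20))), 2)
  expect_equal(nrow(merge_overlapping(ep(0, 5, 10, 5, 8, 20))), 1)
  # containment and chains
  m2 <- merge_overlapping(ep(0, 20, 10, 3, 5, 5, 19, 30, 7, 40, 41, 1))
  expect_equal(m2$unit_cost, c(22, 1))
  expect_error(merge_overlapping(ep(5, 3, 10)), "discharge before")
})

test_that("merging is idempotent and conserves total cost", {
  set.seed(5)
  for (i in 1:20) {
    adm <- runif(15, 0, 300)
    e <- data.frame(admission_day = adm,
                    discharge_day = adm + rpois(15, 6),
                    unit_cost = rgamma(15, 1, 1 / 500))
    m1 <- merge_overlapping(e)
    expect_equal(merge_overlapping(m1), m1)
    expect_equal(sum(m1$unit_cost), sum(e$unit_cost))
    expect_true(all(m1$admission_day[-1] > m1$discharge_day[-nrow(m1)]))
  }
})

test_that("annualization assigns episodes to admission periods with
           price factors applied", {
  # 20% professional-fee uplift
  a <- annualize(ep(10, 12, 100), NA, followup_end = 4 * 365.25,
                 inflation = 1, fee_uplift = 1.2)
  expect_equal(a$cost, c(120, 0, 0, 0))
  expect_equal(a$exposure, rep(1, 4))
  expect_false(any(a$death_period))
  # no episodes: four zero-cost person-years
  a0 <- annualize(ep(), NA, followup_end = 4 * 365.25)
  expect_equal(a0$cost, rep(0, 4))
  expect_equal(a0$any_cost, rep(FALSE, 4))
  # inflation to the target price year; admission-day assignment
  a1 <- annualize(ep(400, 410, 500), NA, followup_end = 2 * 365.25,
                  inflation = 1.05)
  expect_equal(a1$cost, c(0, 525))
  # episode after the end of follow-up is an input error
  expect_error(annualize(ep(900, 905, 10), NA, followup_end = 800),
               "after end of follow-up")
})

test_that("death and administrative censoring truncate exposure", {
  a <- annualize(ep(), death_day = 500, followup_end = 4 * 365.25)
  expect_equal(nrow(a), 2)
  expect_equal(a$exposure, c(1, 500 / 365.25 - 1))
  expect_true(a$death_period[2])
  a2 <- annualize(ep(), NA, followup_end = 3.5 * 365.25)
  expect_equal(a2$exposure, c(1, 1, 1, 0.5))
  expect_false(any(a2$death_period))
})

test_that("costs are conserved from episodes through annual periods", {
  set.seed(9)
  adm <- runif(25, 0, 4 * 365.25 - 10)
  e <- data.frame(admission_day = adm, discharge_day = adm + rpois(25, 5),
                  unit_cost = rgamma(25, 1, 1 / 800))
  m <- merge_overlapping(e)
  a <- annualize(m, NA, followup_end = 4.6 * 365.25, inflation = 1.08,
                 fee_uplift = 1.2)
  expect_equal(sum(a$cost), sum(e$unit_cost) * 1.08 * 1.2)
})

test_that("the generator's episode table reproduces its annual costs", {
  ch <- tiny_cohort()
  pr <- ch$config$pricing
  eps <- ch$episodes
  eps$unit_cost <- eps$unit_cost_uk
  ids <- ch$participants$id[1:50]
  for (pid in ids) {
    e <- eps[eps$id == pid, , drop = FALSE]
    i <- match(pid, ch$participants$id)
    end <- min(ch$participants$followup_day[i],
               ch$participants$death_day[i], na.rm = TRUE)
    a <- annualize(merge_overlapping(e), ch$participants$death_day[i],
                   followup_end = end,
                   inflation = pr[["inflation_uk"]],
                   fee_uplift = pr[["uplift_uk"]])
    ref <- ch$annual_costs[ch$annual_costs$id == pid, ]
    expect_equal(a$cost, ref$cost_uk, tolerance = 1e-8)
    expect_equal(a$exposure, ref$exposure, tolerance = 1e-10)
  }
})

test_that("person-year table carries certain-admission flags and
           covariates", {
  py <- tiny_py("uk")
  expect_true(all(py$any_cost[py$certain_admission]))
  expect_true(all(c("age", "female", "region", "cat_mi", "occ_ucrv",
                    "certain_admission") %in% names(py)))
  # flag is exactly "any occurrence of ucrv/ncrv/hf in the period"
  expect_equal(py$certain_admission,
               py$occ_ucrv | py$occ_ncrv | py$occ_hf)
})
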