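# Shared fixtures, built in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# a small default-truth cohort for module tests
tiny_cohort <- function() memo("tiny", {
  generate_cohort(cohort_config(n = 800, seed = 101))
})

# full-size cohort for the calibration-surface acceptance checks
full_cohort <- function() memo("full", {
  generate_cohort(cohort_config(n = 21820, seed = 2024))
})

tiny_py <- function(perspective = "uk") memo(paste0("py_", perspective), {
  ch <- tiny_cohort()
  ac <- ch$annual_costs
  ac$cost <- ac[[paste0("cost_", perspective)]]
  person_year_table(ac, ch$events, ch$participants)
})

tiny_qol <- function() memo("qol", {
  suppressMessages(build_qol_data(tiny_cohort()))
})

# person-year table of a perspective for an arbitrary cohort
py_of <- function(ch, perspective = "uk") {
  ac <- ch$annual_costs
  ac$cost <- ac[[paste0("cost_", perspective)]]
  person_year_table(ac, ch$events, ch$participants)
}

expect_within <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("%.4f within %.4f of %.4f", x, tol, target))
}
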