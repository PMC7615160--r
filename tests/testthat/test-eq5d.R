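test_that("full health scores exactly 1 under any valid tariff", {
  fh <- eq5d_profile(1, 1, 1, 1, 1)
  for (nm in c("toy", "synthetic_uk", "synthetic_us"))
    expect_identical(score_eq5d(fh, eq5d_tariff(nm)), 1)
})

test_that("toy-tariff utilities are additive decrement arithmetic", {
  toy <- eq5d_tariff("toy")
  expect_equal(score_eq5d(eq5d_profile(2, 1, 1, 1, 1), toy), 0.95)
  expect_equal(score_eq5d(eq5d_profile(5, 5, 5, 5, 5), toy), 0)
  expect_equal(score_eq5d(eq5d_profile(3, 2, 1, 1, 1), toy),
               1 - 0.10 - 0.05)
})

test_that("profile and tariff validation rejects malformed input", {
  expect_error(eq5d_profile(0, 1, 1, 1, 1), "1..5")
  expect_error(eq5d_profile(6, 1, 1, 1, 1), "1..5")
  expect_error(validate_eq5d(data.frame(mobility = 1)), "lacks dimension")
  p <- eq5d_profile(c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  p$mobility[2] <- NA  # partially missing row
  expect_error(validate_eq5d(p), "partially missing")
  # tariff missing a cell / nonzero level-1 decrement
  tmp <- tempfile(fileext = ".csv")
  tab <- read.csv(system.file("extdata", "tariff_toy.csv",
                              package = "cvdimpact"))
  write.csv(tab[-3, ], tmp, row.names = FALSE)
  expect_error(read_tariff(tmp), "25")
  tab2 <- tab; tab2$decrement[tab2$level == 1][1] <- 0.01
  write.csv(tab2, tmp, row.names = FALSE)
  expect_error(read_tariff(tmp), "level 1")
})

test_that("worsening any single dimension never increases utility", {
  tar <- eq5d_tariff("synthetic_uk")
  set.seed(42)
  for (i in 1:50) {
    lv <- sample(1:5, 5, replace = TRUE)
    p <- eq5d_profile(lv[1], lv[2], lv[3], lv[4], lv[5])
    u <- score_eq5d(p, tar)
    d <- sample(1:5, 1)
    if (lv[d] < 5) {
      lv2 <- lv; lv2[d] <- lv[d] + 1
      p2 <- eq5d_profile(lv2[1], lv2[2], lv2[3], lv2[4], lv2[5])
      expect_lte(score_eq5d(p2, tar), u)
    }
  }
})

test_that("swapping tariffs changes utilities but not full-health fraction", {
  set.seed(7)
  lv <- matrix(sample(1:5, 250, replace = TRUE, prob = c(.6, .2, .1, .06, .04)),
               ncol = 5)
  p <- eq5d_profile(lv[, 1], lv[, 2], lv[, 3], lv[, 4], lv[, 5])
  s_uk <- summarize_utilities(p, eq5d_tariff("synthetic_uk"))
  s_us <- summarize_utilities(p, eq5d_tariff("synthetic_us"))
  expect_false(isTRUE(all.equal(s_uk$mean, s_us$mean)))
  expect_identical(s_uk$full_health_fraction, s_us$full_health_fraction)
})

test_that("utility summaries are simple arithmetic over scored profiles", {
  toy <- eq5d_tariff("toy")
  p <- eq5d_profile(c(1, 5), c(1, 3), c(1, 3), c(1, 2), c(1, 2))  # 1.0, 0.5
  s <- summarize_utilities(p, toy)
  expect_equal(s$mean, 0.75)
  expect_equal(s$full_health_fraction, 0.5)
  all_full <- eq5d_profile(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3),
                           rep(1, 3))
  s2 <- summarize_utilities(all_full, toy)
  expect_equal(s2$mean, 1)
  expect_equal(s2$full_health_fraction, 1)
  empty <- eq5d_profile(integer(0), integer(0), integer(0), integer(0),
                        integer(0))
  expect_error(summarize_utilities(empty, toy), "no non-missing")
})

test_that("nearest-profile inversion is consistent with scoring", {
  tar <- eq5d_tariff("synthetic_uk")
  grid_u <- sort(unique(score_eq5d(
    do.call(eq5d_profile, expand.grid(m = 1:5, s = 1:5, u = 1:5, p = 1:5,
                                      a = 1:5)), tar)))
  max_gap <- max(diff(grid_u))
  set.seed(3)
  targets <- runif(200, min(grid_u), 1)
  ach <- nearest_profile(targets, tar)$utility
  expect_true(all(abs(ach - targets) <= max_gap / 2 + 1e-12))
  # exact grid values invert to themselves
  expect_equal(nearest_profile(grid_u[10], tar)$utility, grid_u[10])
})

test_that("midpoint ties break to the lexicographically smallest profile", {
  toy <- eq5d_tariff("toy")  # grid is 0, 0.05, ..., 1
  # 0.975 is equidistant between 0.95 and 1.0; (1,1,1,1,1) is lex-smallest
  p <- nearest_profile(0.975, toy)
  expect_equal(unlist(p[1, 1:5], use.names = FALSE), rep(1L, 5))
})
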