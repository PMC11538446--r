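test_that("inherent precision is 2x the coefficient of variation", {
  expect_equal(inherent_precision(c(60, 60, 60, 60, 60)), 0)
  expect_equal(inherent_precision(c(60, 62, 58, 61, 59)),
               2 * sd(c(60, 62, 58, 61, 59)) / 60 * 100)
  expect_equal(inherent_precision(c(60, 62, 58, 61, 59)), 5.270463,
               tolerance = 1e-6)
  # scale invariance of the CV
  x <- c(55, 61, 58, 63, 59)
  expect_equal(inherent_precision(x), inherent_precision(3.7 * x))
  expect_error(inherent_precision(c(-5, 5)), "mean")
  expect_error(inherent_precision(60), "two repeats")
})

test_that("least significant change is precision times sqrt(2)", {
  expect_equal(least_significant_change(11), 16)
  expect_equal(least_significant_change(0), 0)
  expect_equal(least_significant_change(7.07), 10)
  expect_equal(least_significant_change(11, rounded = FALSE), 11 * sqrt(2))
  expect_error(least_significant_change(-1), "precision")
})

test_that("repeated-measures Bland-Altman handles exact-agreement cases", {
  ref <- c(50, 55, 60, 45, 52, 58)
  id <- c(1, 1, 1, 2, 2, 2)
  ba0 <- bland_altman_repeated(ref, ref, id)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_high - ba0$loa_low, 0)
  ba5 <- bland_altman_repeated(ref + 5, ref, id)
  expect_equal(ba5$bias, 5)
  expect_equal(ba5$sd_total, 0)
  expect_equal(ba5$n_pairs, 6L)
  expect_equal(ba5$n_animals, 2L)
})

test_that("variance decomposition matches an ANOVA oracle exactly", {
  set.seed(101)
  id <- rep(1:3, each = 5)
  d <- 2 + rnorm(3, 0, 3)[id] + rnorm(15, 0, 2)
  test <- 60 + d
  ref <- rep(60, 15)
  ba <- bland_altman_repeated(test, ref, id)

  fit <- stats::aov(d ~ factor(id))
  ms <- summary(fit)[[1]]$`Mean Sq`
  msb <- ms[1]; msw <- ms[2]
  n0 <- (15 - sum(table(id)^2) / 15) / (3 - 1)
  sd_oracle <- sqrt(max(0, (msb - msw) / n0) + msw)

  expect_equal(ba$bias, mean(d), tolerance = 1e-10)
  expect_equal(ba$sd_total, sd_oracle, tolerance = 1e-10)
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd_oracle, tolerance = 1e-10)
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd_oracle, tolerance = 1e-10)
})

test_that("Bland-Altman recovers injected bias and SD on seeded data", {
  set.seed(7)
  k <- 10; n <- 30
  sa <- 2; sw <- 4; b <- 3
  id <- rep(seq_len(k), each = n)
  d <- b + rnorm(k, 0, sa)[id] + rnorm(k * n, 0, sw)
  ba <- bland_altman_repeated(70 + d, rep(70, k * n), id)
  s_tot <- sqrt(sa^2 + sw^2)
  expect_lt(abs(ba$bias - b), 2 * s_tot / sqrt(k))
  expect_lt(abs(ba$sd_total - s_tot) / s_tot, 0.10)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
})

test_that("a single subject falls back to simple Bland-Altman with a warning", {
  expect_warning(
    ba <- bland_altman_repeated(c(50, 52, 55), c(49, 53, 54), c(1, 1, 1)),
    "single subject")
  expect_equal(ba$variant, "simple")
  expect_equal(ba$bias, mean(c(1, -1, 1)))
})

test_that("intervention extremes pair pre/post slots and skip incomplete ones", {
  rec <- data.frame(
    animal_id = rep("a1", 6),
    phase = c("fio2", "fio2", "fio2", "hemorrhage", "hemorrhage", "peep"),
    slot = c("pre", "mid1", "post", "pre", "post", "pre"),
    t_s = c(10, 20, 30, 40, 50, 60),
    method = "capno",
    svo2_pct = c(50, 55, 64, 60, 40, 52),
    stringsAsFactors = FALSE
  )
  d <- select_intervention_extremes(rec)
  expect_setequal(d$phase, c("fio2", "hemorrhage"))  # peep lacks a post
  expect_equal(d$delta[d$phase == "fio2"], 14)
  expect_equal(d$delta[d$phase == "hemorrhage"], -20)
})

test_that("extremes fall back to first/last timestamps without slots", {
  rec <- data.frame(
    animal_id = "a1", phase = "dobutamine", t_s = c(0, 300, 900),
    method = "capno", svo2_pct = c(50, 57, 65), stringsAsFactors = FALSE
  )
  d <- select_intervention_extremes(rec)
  expect_equal(d$delta, 15)
})

test_that("concordance reproduces the worked trending rates", {
  d_ref <- rep(c(12, -12), 35)
  d_test_68 <- d_ref
  d_test_68[c(1, 2)] <- -d_test_68[c(1, 2)]   # two discordant of 70
  c68 <- concordance(d_test_68, d_ref, exclusion_zone = 10)
  expect_equal(c68$n_outside, 70L)
  expect_equal(c68$n_concordant, 68L)
  expect_equal(round(c68$rate), 97)

  d_test_65 <- d_ref
  d_test_65[1:5] <- -d_test_65[1:5]           # five discordant of 70
  c65 <- concordance(d_test_65, d_ref, exclusion_zone = 10)
  expect_equal(round(c65$rate), 93)

  expect_equal(concordance(d_ref, d_ref, 10)$rate, 100)
})

test_that("the exclusion zone filters on the reference and is monotone", {
  set.seed(5)
  d_ref <- rnorm(200, 0, 8)
  d_test <- d_ref + rnorm(200, 0, 3)
  n_prev <- Inf
  for (z in c(0, 2, 5, 10, 15)) {
    cc <- concordance(d_test, d_ref, z)
    expect_lte(cc$n_outside, n_prev)
    n_prev <- cc$n_outside
    expect_equal(cc$n_outside, sum(abs(d_ref) > z))
  }
  # with no zone, the rate is symmetric in the two roles
  expect_equal(concordance(d_test, d_ref, 0)$rate,
               concordance(d_ref, d_test, 0)$rate)
  # empty retained set is an explicit empty result
  c_empty <- concordance(c(1, -1), c(0.5, -0.5), exclusion_zone = 10)
  expect_equal(c_empty$n_outside, 0L)
  expect_true(is.na(c_empty$rate))
})

test_that("the Wilson interval brackets the rate and respects [0, 100]", {
  cc <- concordance(rep(5, 70), rep(c(6, -6), 35), 0)
  expect_true(cc$rate_ci[1] <= cc$rate && cc$rate <= cc$rate_ci[2])
  c_all <- concordance(rep(5, 20), rep(5, 20), 0)
  expect_equal(c_all$rate, 100)
  expect_lte(c_all$rate_ci[2], 100)
  expect_lt(c_all$rate_ci[1], 100)
})

test_that("compare_methods assembles precision, LSC, zone, agreement and trending", {
  plan <- default_sampling_plan()
  base <- function(t) 55 + 10 * sin(t / 2500)
  rec <- make_recordings(c("a1", "a2", "a3"), plan, list(
    co_oximetry = base,
    capno = function(t) base(t) + 2,
    fiberoptic = function(t) base(t) - 3
  ))
  cmp <- compare_methods(rec, exclusion_zone = 0)
  expect_equal(unname(cmp$precision["co_oximetry"]),
               inherent_precision(base(plan$t_s[plan$phase == "baseline"])),
               tolerance = 1e-9)
  expect_equal(cmp$agreement$capno$bias, 2, tolerance = 1e-9)
  expect_equal(cmp$agreement$fiberoptic$bias, -3, tolerance = 1e-9)
  expect_equal(cmp$concordance$capno$rate, 100)
  expect_error(compare_methods(rec, reference = "thermodilution"),
               "no rows for reference")
})
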