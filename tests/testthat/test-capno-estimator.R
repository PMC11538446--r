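test_that("windowed VCO2 reproduces constant and single-breath rates", {
  br <- make_breaths(rep(8, 100), duration = 3)
  vc <- windowed_vco2(br, window = 1200)
  expect_equal(vc$vco2_mlpm, rep(160, 100))
  one <- make_breaths(6, duration = 2.4)
  expect_equal(windowed_vco2(one)$vco2_mlpm, 150)
  expect_error(windowed_vco2(make_breaths(6)[0, ]), "no breaths|empty")
})

test_that("windowed VCO2 matches a brute-force trailing-window oracle", {
  set.seed(42)
  br <- make_breaths(runif(200, 4, 10), duration = runif(200, 2.5, 4))
  w <- 120
  vc <- windowed_vco2(br, window = w)
  t_end <- br$t_start_s + br$duration_s
  oracle <- sapply(seq_len(nrow(br)), function(i) {
    j <- which(t_end > t_end[i] - w & t_end <= t_end[i])
    60 * sum(br$vtco2_ml[j]) / sum(br$duration_s[j])
  })
  expect_equal(vc$vco2_mlpm, oracle, tolerance = 1e-12)
})

test_that("windowed VCO2 moves monotonically toward a new level after a step", {
  br <- make_breaths(c(rep(6, 100), rep(12, 100)), duration = 3)
  vc <- windowed_vco2(br, window = 60)
  after <- vc$vco2_mlpm[101:200]
  expect_true(all(diff(after) >= -1e-12))
  expect_equal(after[100], 240)
})

test_that("VO2 conversion divides by the respiratory quotient", {
  expect_equal(vo2_from_vco2(200, 1.0), 200)
  expect_equal(vo2_from_vco2(194, 0.97), 200)
  expect_equal(vo2_from_vco2(0, 0.97), 0)
  expect_error(vo2_from_vco2(100, 0), "rq")
  expect_error(vo2_from_vco2(-5, 1), "vco2")
})

test_that("EPBF fit recovers the simulator truth on noise-free breaths", {
  k <- physio_constants()
  st <- constant_states(epbf = 3.5, duration_s = 300, constants = k)
  br <- synthesize_breaths(st)
  est <- estimate_capno_svo2(br, hb = 90, constants = k)
  e <- est$epbf_lpm[nrow(est)]
  expect_lt(abs(e - 3.5) / 3.5, 0.02)
})

test_that("doubling true EPBF doubles the estimate (noise-free)", {
  k <- physio_constants()
  est_at <- function(epbf) {
    st <- constant_states(epbf = epbf, duration_s = 300, constants = k)
    br <- synthesize_breaths(st)
    est <- estimate_capno_svo2(br, hb = 90, constants = k)
    est$epbf_lpm[nrow(est)]
  }
  expect_lt(abs(est_at(4.4) / est_at(2.2) - 2), 0.05 * 2)
})

test_that("a CO2-free uniform breath stream is flagged degenerate", {
  br <- make_breaths(rep(0, 30), duration = 4, fet = 0)
  est <- estimate_capno_svo2(br, hb = 90)
  expect_true(any(grepl("degenerate", est$quality_flag)))
  expect_true(all(is.na(est$epbf_lpm)))
})

test_that("the Fick chain reproduces CvO2 = CcO2 - VO2/EPBF with clamping", {
  k <- physio_constants()
  hb <- 120; fio2 <- 0.5; paco2 <- 40
  cco2 <- oxygen_content(hb, 1, alveolar_po2(fio2, paco2, k), k)
  res <- capno_svo2_chain(epbf = 4, vo2 = 200, fio2, paco2, hb, k)
  expect_equal(res$cvo2, cco2 - 50, tolerance = 1e-12)
  # huge flow: venous content approaches end-capillary content
  res_inf <- capno_svo2_chain(epbf = 1e6, vo2 = 200, fio2, paco2, hb, k)
  expect_equal(res_inf$cvo2, cco2, tolerance = 1e-3)
  expect_gt(res_inf$svo2, 0.999)
  # starved flow with low-capacity blood: clamped to zero and flagged
  res_low <- capno_svo2_chain(epbf = 1.0, vo2 = 200, fio2, paco2, hb = 50,
                              constants = k)
  expect_equal(res_low$svo2, 0)
  expect_match(res_low$quality_flag, "clamped_low")
  # zero flow: defined zero output with its own flag
  res_0 <- capno_svo2_chain(epbf = 0, vo2 = 200, fio2, paco2, hb, k)
  expect_equal(res_0$svo2, 0)
  expect_match(res_0$quality_flag, "no_flow")
})

test_that("capno SvO2 is monotone in EPBF and VO2", {
  k <- physio_constants()
  s_flow <- capno_svo2_chain(c(2, 3, 4, 5), 200, 0.3, 40, 100, k)$svo2
  expect_true(all(diff(s_flow) > 0))
  s_met <- capno_svo2_chain(4, c(120, 180, 240, 300), 0.3, 40, 100, k)$svo2
  expect_true(all(diff(s_met) < 0))
})

test_that("moving mean filter is exact on constants and matches a window oracle", {
  t <- seq(0, 199, by = 2)
  expect_equal(moving_mean_filter(t, rep(7, 100), 50), rep(7, 100))
  x <- c(rep(0, 50), rep(1, 50))
  filt <- moving_mean_filter(t, x, 50)
  oracle <- sapply(seq_along(t), function(i) {
    mean(x[t > t[i] - 50 & t <= t[i]])
  })
  expect_equal(filt, oracle)
  expect_true(all(diff(filt[50:80]) >= 0))       # ramp toward the step
  expect_equal(filt[77:100], rep(1, 24))          # completes after one window
  # degenerate window shorter than sample spacing: identity
  expect_equal(moving_mean_filter(t, x, 1), x)
})

test_that("filtered SvO2 lags the raw series and both converge", {
  k <- physio_constants()
  st <- constant_states(epbf = 3, duration_s = 500, constants = k)
  br <- synthesize_breaths(st)
  est <- estimate_capno_svo2(br, hb = 90, constants = k)
  tail_raw <- utils::tail(est$svo2_pct, 5)
  tail_f <- utils::tail(est$svo2_filt_pct, 5)
  expect_equal(mean(tail_raw), mean(tail_f), tolerance = 0.01)
})

test_that("malformed breath tables are rejected with the offending row", {
  br <- make_breaths(rep(6, 20), duration = 3)
  br$t_start_s[10] <- br$t_start_s[10] - 50
  expect_error(estimate_capno_svo2(br, hb = 90), "row 10")
  expect_error(estimate_capno_svo2(br[0, ], hb = 90), "empty")
  br2 <- make_breaths(rep(6, 5)); br2$vt_ml <- NULL
  expect_error(estimate_capno_svo2(br2, hb = 90), "missing columns")
})

test_that("end-to-end steady-state accuracy holds across the EPBF/VO2 grid", {
  k <- physio_constants()
  for (epbf in c(2, 4, 6)) {
    for (vo2 in c(100, 200, 300)) {
      st <- constant_states(epbf = epbf, vo2 = vo2, duration_s = 400,
                            constants = k)
      br <- synthesize_breaths(st)
      est <- estimate_capno_svo2(br, hb = 90, constants = k)
      got <- est$svo2_pct[nrow(est)] / 100
      truth <- st$svo2_true[nrow(st)]
      expect_lt(abs(got - truth), 0.02)
    }
  }
})
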