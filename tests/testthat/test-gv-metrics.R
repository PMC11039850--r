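test_that("mean/sd and J-index follow their closed forms", {
  tr <- make_trace(c(90, 100, 110))
  ms <- gv_mean_sd(tr)
  expect_equal(ms$mean_mg_dl, 100)
  expect_equal(ms$sd_mg_dl, 10)
  expect_equal(j_index_from_moments(100, 10), 12.1)
  expect_equal(gv_j_index(make_trace(rep(100, 10))), 10)
  # strictly increasing in both moments
  expect_gt(j_index_from_moments(101, 10), j_index_from_moments(100, 10))
  expect_gt(j_index_from_moments(100, 11), j_index_from_moments(100, 10))
})

test_that("CONGA matches the hand-computed lag-difference SD", {
  # 30-min spacing, 60-min lag: differences -10, -10, +10
  tr <- make_trace(c(100, 120, 90, 110, 100), cadence = 30)
  expect_equal(gv_conga(tr, 60), sd(c(-10, -10, 10)) / 18.016)
  expect_equal(gv_conga(tr, 60), 0.6409, tolerance = 1e-3)
  expect_equal(gv_conga(make_trace(rep(100, 20)), 60), 0)
  expect_error(gv_conga(make_trace(c(100, 110, 105), cadence = 15), 60),
               "shorter")
})

test_that("LI sums squared hourly swings per day of observation", {
  mmol <- 18.016
  tr <- make_trace(c(5, 6, 5) * mmol, cadence = 60)
  expect_equal(gv_li(tr, 60), 2.0)
  expect_equal(gv_li(make_trace(rep(100, 30), cadence = 60)), 0)
  # doubling deviations from the mean quadruples LI (vs brute force)
  g <- c(5, 6, 5.5, 4.5, 5) * mmol
  tr1 <- make_trace(g, cadence = 60)
  tr2 <- make_trace(mean(g) + 2 * (g - mean(g)), cadence = 60)
  expect_equal(gv_li(tr2), 4 * gv_li(tr1))
  tt <- as.numeric(tr2$time)
  expect_equal(gv_li(tr2), o_li(tt, tr2$glucose, 60, 60))
})

test_that("risk indices vanish at the transform root and split by level", {
  root <- exp(5.381^(1 / 1.084))
  expect_equal(root, 112.5, tolerance = 1e-2)
  b <- gv_bgi(make_trace(rep(root, 12)))
  expect_lt(b$lbgi + b$hbgi, 1e-3)

  b180 <- gv_bgi(make_trace(rep(180, 12)))
  expect_equal(b180$lbgi, 0)
  expect_equal(b180$hbgi, unname(o_bgi(rep(180, 12))["hbgi"]))
  expect_equal(b180$hbgi, 7.73, tolerance = 1e-2)

  b50 <- gv_bgi(make_trace(rep(50, 12)))
  expect_equal(b50$hbgi, 0)
  expect_equal(b50$lbgi, 22.51, tolerance = 1e-2)

  # monotone in a constant trace's level
  lv <- seq(50, 250, by = 20)
  hb <- vapply(lv, function(g) gv_bgi(make_trace(rep(g, 5)))$hbgi, numeric(1))
  lb <- vapply(lv, function(g) gv_bgi(make_trace(rep(g, 5)))$lbgi, numeric(1))
  expect_true(all(diff(hb) >= 0))
  expect_true(all(diff(lb) <= 0))
})

test_that("ADRR averages daily risk ranges over qualifying days", {
  day1 <- rep(50, 96); day2 <- rep(180, 96)
  tr <- make_trace(c(day1, day2), cadence = 15)
  expected <- mean(c(o_bgi(50)["lbgi"], o_bgi(180)["hbgi"]))
  expect_equal(gv_adrr(tr), expected)
  expect_equal(gv_adrr(tr), 15.12, tolerance = 1e-2)

  expect_equal(gv_adrr(make_trace(rep(112.5, 96))), 0, tolerance = 1e-3)

  # a day with fewer than 12 readings is excluded
  short_day <- make_trace(rep(250, 5), start = t0("2023-03-08 10:00:00"))
  joined <- glucose_trace("x", 0, c(tr$time, short_day$time),
                          c(tr$glucose, short_day$glucose))
  expect_equal(gv_adrr(joined), expected)

  # adding a reading equal to the day's max leaves ADRR unchanged
  plus <- glucose_trace("x", 0, c(tr$time, max(tr$time) + 60), c(tr$glucose, 180))
  expect_equal(gv_adrr(plus), expected)
})

test_that("GRADE evaluates the capped log-log penalty", {
  g55 <- 5.5 * 18.016
  expect_equal(as.numeric(gv_grade(make_trace(rep(g55, 10)))),
               425 * (log10(log10(5.5)) + 0.16)^2)
  expect_equal(as.numeric(gv_grade(make_trace(rep(g55, 10)))), 0.369,
               tolerance = 1e-2)
  # analytic minimum near 4.918 mmol/L
  gmin <- 10^(10^(-0.16)) * 18.016
  expect_equal(gmin / 18.016, 4.918, tolerance = 1e-3)
  expect_lt(as.numeric(gv_grade(make_trace(rep(gmin, 10)))), 1e-10)
  # cap at 50 for extreme hypoglycemia
  g2 <- 2 * 18.016
  expect_gt(425 * (log10(log10(2)) + 0.16)^2, 50)
  expect_equal(as.numeric(gv_grade(make_trace(rep(g2, 10)))), 50)
})

test_that("MAGE averages super-SD excursions between turning points", {
  expect_equal(as.numeric(gv_mage(make_trace(rep(100, 10)))), 0)
  expect_true(attr(gv_mage(make_trace(rep(100, 10))), "no_excursions"))

  osc <- make_trace(rep(c(90, 120, 150, 120), 6))
  expect_equal(as.numeric(gv_mage(osc)), 60 / 18.016)

  mono <- make_trace(seq(80, 180, by = 5))
  expect_equal(as.numeric(gv_mage(mono)), 0)
  expect_true(attr(gv_mage(mono), "no_excursions"))

  # plateaus collapse: repeated peak values are one turning point
  plat <- make_trace(rep(c(90, 120, 150, 150, 120), 6))
  expect_equal(as.numeric(gv_mage(plat)), as.numeric(o_mage(plat$glucose)))
})

test_that("MODD is the mean absolute 24-h difference", {
  one_day <- 100 + 10 * sin(2 * pi * (0:95) / 96)
  expect_equal(gv_modd(make_trace(c(one_day, one_day))), 0)
  expect_equal(gv_modd(make_trace(c(one_day, one_day + 18.016))), 1.0)
  expect_error(gv_modd(make_trace(rep(100, 80))), "24 h")
})

test_that("M-value is the cubed log-deviation from the reference", {
  expect_equal(gv_m_value(make_trace(rep(120, 10))), 0)
  expect_equal(gv_m_value(make_trace(rep(240, 10))), abs(10 * log10(2))^3)
  expect_equal(gv_m_value(make_trace(rep(240, 10))), 27.28, tolerance = 1e-2)
  # log-symmetry: halving and doubling the reference agree
  expect_equal(gv_m_value(make_trace(rep(60, 10))),
               gv_m_value(make_trace(rep(240, 10))))
})

test_that("metrics are invariant to a uniform time shift", {
  tr <- random_trace(11)
  sh <- glucose_trace(tr$participant_id, 0, tr$time + 86400 * 30 + 3600,
                      tr$glucose, tr$cadence_min)
  p1 <- gv_profile(tr); p2 <- gv_profile(sh)
  for (m in c("mean_glucose", "sd_glucose", "conga", "mage", "li",
              "j_index", "lbgi", "hbgi", "grade", "m_value", "modd"))
    expect_equal(p2[[m]], p1[[m]], info = m)
  # ADRR shifts day boundaries with the clock, so only a whole-day shift
  whole <- glucose_trace(tr$participant_id, 0, tr$time + 86400 * 30,
                         tr$glucose, tr$cadence_min)
  expect_equal(gv_profile(whole)$adrr, p1$adrr)
})

test_that("the profile collects the battery and flags short traces", {
  p <- gv_profile(random_trace(3, days = 3))
  expect_equal(p$n_readings, 288)
  expect_true(all(c("conga", "mage", "modd", "li", "adrr") %in% names(p)))
  expect_identical(p$notes, "")
  short <- gv_profile(make_trace(c(100, 120, 90, 110)))
  expect_true(is.na(short$modd))
  expect_match(short$notes, "modd")
})
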