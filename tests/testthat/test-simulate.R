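cfg0 <- function(...) sim_config(n_participants = 2, days_per_assessment = 3, ...)

test_that("config invariants are enforced", {
  expect_error(sim_config(cadence = 13), "cadence")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(sim_config(lge_propensity_range = c(-0.1, 0.5)), "propensity")
  expect_error(sim_config(days_per_assessment = 1), "day")
})

test_that("a trace with every variance source off is constant", {
  cfg <- cfg0(noise_sd = 0, circadian_amplitude = 0)
  tr <- simulate_trace(cfg, list(baseline = 100))
  expect_true(all(tr$glucose == 100))
  expect_equal(length(tr), 3 * 96)
  # and every dispersion metric downstream is exactly zero
  expect_equal(gv_mean_sd(tr)$sd_mg_dl, 0)
  expect_equal(gv_conga(tr), 0)
  expect_equal(gv_li(tr), 0)
  expect_equal(as.numeric(gv_mage(tr)), 0)
  expect_equal(gv_modd(tr), 0)
})

test_that("a single meal produces the kernel's excursion profile", {
  cfg <- cfg0(noise_sd = 0, circadian_amplitude = 0, meal_decay = 60)
  meal_t <- t0("2023-01-02 12:00:00")
  tr <- simulate_trace(cfg, list(
    baseline = 100, start = "2023-01-02 00:00:00",
    meals = data.frame(timestamp = meal_t, amplitude = 60)))
  within90 <- tr$glucose[tr$time > meal_t & tr$time <= meal_t + 90 * 60]
  rise <- max(within90) - 100
  expect_gte(rise, 45)
  expect_lte(rise, 60)
  # oracle: direct evaluation of the response kernel on the grid
  off <- as.numeric(tr$time - meal_t, units = "mins")
  kern <- ifelse(off < 0, 0,
                 ifelse(off <= 30, 60 * off / 30, 60 * exp(-(off - 30) / 60)))
  expect_equal(tr$glucose, 100 + kern)
})

test_that("trace simulation is deterministic in its seed", {
  cfg <- cfg0()
  p <- list(baseline = 95, seed = 77L)
  tr1 <- simulate_trace(cfg, p)
  tr2 <- simulate_trace(cfg, p)
  expect_identical(tr1$glucose, tr2$glucose)
  p2 <- p; p2$seed <- 78L
  expect_false(identical(simulate_trace(cfg, p2)$glucose, tr1$glucose))
})

test_that("propensity 1 with zero noise yields 100% low-glucose eating", {
  cfg <- cfg0(noise_sd = 0, snack_noise_fraction = 0)
  base <- simulate_trace(cfg, list(baseline = 92, participant_id = "A"))
  food <- simulate_meals(cfg, base, lge_propensity = 1, threshold = 93,
                         seed = 5L)
  truth <- attr(food, "meals")
  expect_gt(nrow(truth), 0)
  final <- simulate_trace(cfg, list(baseline = 92, participant_id = "A",
                                    meals = truth))
  ev <- match_preprandial(consolidate_events(food), resample_trace(final))
  expect_equal(compute_lge(ev, 93)$lge_percent, 100)
})

test_that("propensity 0 on a high-baseline trace yields LGE near zero", {
  cfg <- cfg0(noise_sd = 0, snack_noise_fraction = 0)
  base <- simulate_trace(cfg, list(baseline = 130, participant_id = "B"))
  food <- simulate_meals(cfg, base, lge_propensity = 0, threshold = 95,
                         seed = 6L)
  final <- simulate_trace(cfg, list(baseline = 130, participant_id = "B",
                                    meals = attr(food, "meals")))
  ev <- match_preprandial(consolidate_events(food), resample_trace(final))
  # brute recount: no matched preprandial value can be at or below 95
  expect_equal(sum(ev$preprandial_glucose[ev$matched] <= 95), 0)
  expect_equal(compute_lge(ev, 95)$lge_percent, 0)
})

test_that("snack-noise records are dropped by the 25-kcal filter", {
  cfg <- sim_config(n_participants = 2, days_per_assessment = 7,
                    snack_noise_fraction = 0.5, meals_per_day_range = c(4, 6))
  base <- simulate_trace(cfg, list(baseline = 95, seed = 2L))
  food <- simulate_meals(cfg, base, 0.2, 95, seed = 9L)
  kept <- consolidate_events(food)
  dropped_frac <- 1 - nrow(kept) / nrow(food)
  expect_gt(dropped_frac, 0.3)
  expect_lt(dropped_frac, 0.6)
  # recount after filter equals the number of true meals
  expect_equal(nrow(kept), nrow(attr(food, "meals")))
})

test_that("cohorts are complete, bounded, in-period and reproducible", {
  cfg <- sim_config(n_participants = 17, days_per_assessment = 3, seed = 12L)
  co <- simulate_cohort(cfg)
  expect_s3_class(co, "synthetic_cohort")
  for (tab in list(co$cgm, co$meals, co$anthro))
    expect_equal(sort(unique(tab$participant_id)), sprintf("P%02d", 1:17))
  expect_equal(nrow(co$truth), 17)
  expect_true(all(co$cgm$glucose_mg_dl >= 40))
  # every meal lies inside its participant-week wear period
  for (wk in c(0, 16)) for (id in c("P01", "P09")) {
    cg <- co$cgm[co$cgm$participant_id == id & co$cgm$week == wk, ]
    ml <- co$meals[co$meals$participant_id == id & co$meals$week == wk, ]
    expect_true(all(ml$timestamp >= min(cg$timestamp) &
                      ml$timestamp <= max(cg$timestamp)))
  }
  co2 <- simulate_cohort(cfg)
  expect_identical(co, co2)
  # and the CSV round trip preserves the tables byte-for-byte
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort_csv(co, d1); write_cohort_csv(co2, d2)
  for (f in c("cgm.csv", "meals.csv", "anthro.csv", "truth.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("the planted effect drives the truth-table correlation", {
  cfg <- sim_config(n_participants = 40, days_per_assessment = 3,
                    effect_size = -30, seed = 33L)
  tr <- simulate_cohort(cfg)$truth
  r_neg <- cor(tr$propensity_week16 - tr$propensity_week0,
               tr$meal_amp_week16 - tr$meal_amp_week0)
  expect_lt(r_neg, 0)

  # effect 0: correlation of the truth columns is null in expectation
  rs <- vapply(1:6, function(s) {
    tt <- simulate_cohort(sim_config(n_participants = 40,
                                     days_per_assessment = 3,
                                     effect_size = 0, seed = s))$truth
    cor(tt$propensity_week16 - tt$propensity_week0,
        tt$meal_amp_week16 - tt$meal_amp_week0)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.2)
  # and every null correlation is weaker than the planted one
  expect_true(all(rs > r_neg))
})
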