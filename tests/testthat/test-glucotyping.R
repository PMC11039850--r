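# three archetype traces with cleanly separated variability; wave periods
# divide the 150-min window so every window sees whole cycles and each
# archetype maps to a single point in feature space
archetype_windows <- function(days = 2) {
  flat <- wave_trace(0, 150, level = 100, days = days, id = "flat")
  slow <- wave_trace(0.5 * 18.016, 150, level = 100, days = days, id = "slow")
  fast <- wave_trace(3 * 18.016, 75, level = 100, days = days, id = "fast")
  list(flat = window_trace(flat), slow = window_trace(slow),
       fast = window_trace(fast))
}

test_that("windowing counts, features and gap handling are correct", {
  # 300 min of gap-free 5-min data: (300-150)/30 + 1 = 6 windows
  tr <- make_trace(100 + sin(0:60), cadence = 5)
  w <- window_trace(tr)
  expect_equal(nrow(w), 6)

  wc <- window_trace(make_trace(rep(100, 61), cadence = 5))
  expect_true(all(wc$sd == 0))
  expect_true(all(wc$range == 0))
  expect_true(all(wc$max_rate == 0))

  # windows overlapping a missing grid stretch are absent
  times <- t0() + c(0:30, 45:80) * 5 * 60
  gap_tr <- glucose_trace("g", 0, times, rep(100, length(times)), 5)
  wg <- window_trace(gap_tr)
  starts_min <- as.numeric(wg$start_time - t0(), units = "mins")
  expect_false(any(starts_min > 150 - 150 & starts_min < 45 * 5))
  expect_true(all(starts_min >= 225 | starts_min == 0))

  # shorter than one window: empty result
  expect_equal(nrow(window_trace(make_trace(rep(100, 10), cadence = 5))), 0)
})

test_that("archetypes separate into correctly ordered severity classes", {
  win <- archetype_windows()
  model <- fit_glucotypes(do.call(rbind, win), seed = 4L)
  expect_s3_class(model, "glucotype_model")
  expect_equal(rownames(model$centroids), c("low", "moderate", "severe"))
  expect_true(all(diff(model$centroids[, "sd"]) > 0))

  expect_equal(unname(classify_fractions(model, win$flat)), c(1, 0, 0))
  expect_equal(unname(classify_fractions(model, win$slow)), c(0, 1, 0))
  expect_equal(unname(classify_fractions(model, win$fast)), c(0, 0, 1))
})

test_that("fractions sum to one and ignore window order", {
  win <- archetype_windows()
  model <- fit_glucotypes(do.call(rbind, win), seed = 4L)
  mixed <- do.call(rbind, win)
  fr <- classify_fractions(model, mixed)
  expect_equal(sum(fr), 1)
  perm <- mixed[sample(nrow(mixed)), ]
  expect_equal(classify_fractions(model, perm), fr)
})

test_that("fitting is deterministic and robust to pool permutation/duplication", {
  win <- archetype_windows()
  pool <- do.call(rbind, win)
  m1 <- fit_glucotypes(pool, seed = 4L)
  m2 <- fit_glucotypes(pool[sample(nrow(pool)), ], seed = 4L)
  expect_equal(classify_fractions(m2, win$slow),
               classify_fractions(m1, win$slow))
  # duplication shifts the sample-SD standardization only marginally
  m3 <- fit_glucotypes(rbind(pool, pool), seed = 4L)
  expect_equal(m3$centroids, m1$centroids, tolerance = 0.05)
  for (a in names(win))
    expect_equal(classify_fractions(m3, win[[a]]),
                 classify_fractions(m1, win[[a]]))
  # a different seed may relabel internally but severity output is stable
  m4 <- fit_glucotypes(pool, seed = 99L)
  for (a in names(win))
    expect_equal(classify_fractions(m4, win[[a]]),
                 classify_fractions(m1, win[[a]]))
})

test_that("severe-fraction ranking follows the simulated amplitude", {
  amps <- seq(2, 60, length.out = 20)
  set.seed(10)
  traces <- lapply(seq_along(amps), function(i)
    wave_trace(amps[i], 180, level = 100 + rnorm(1, 0, 3), days = 1,
               id = sprintf("S%02d", i)))
  wins <- lapply(traces, window_trace)
  model <- fit_glucotypes(do.call(rbind, wins), seed = 4L)
  sev <- vapply(wins, function(w) classify_fractions(model, w)["severe"],
                numeric(1))
  expect_gte(cor(rank(amps), rank(sev)), 0.8)
})

test_that("degenerate pools are rejected", {
  win <- archetype_windows()
  expect_error(fit_glucotypes(win$flat[1:10, ]), "at least 30")
  const_pool <- do.call(rbind, replicate(40, win$flat[1, ], simplify = FALSE))
  expect_error(fit_glucotypes(const_pool), "distinct")
  model <- fit_glucotypes(do.call(rbind, win), seed = 4L)
  expect_error(classify_fractions(model, win$flat[0, ]), "no windows")
})
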