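# Builders for small fixture traces, constructed in code at test time.

t0 <- function(s = "2023-03-06 00:00:00") as.POSIXct(s, tz = "UTC")

# trace from a value vector on a regular cadence grid
make_trace <- function(values, start = t0(), cadence = 15,
                       id = "T1", week = 0) {
  glucose_trace(id, week, start + (seq_along(values) - 1) * cadence * 60,
                values, cadence_min = cadence)
}

# sinusoidal trace: amplitude mg/dL around a level, given period
wave_trace <- function(amplitude, period_min, level = 100, days = 1,
                       cadence = 5, start = t0(), id = "W1", week = 0) {
  n <- days * 1440 / cadence
  tmin <- (seq_len(n) - 1) * cadence
  make_trace(level + amplitude * sin(2 * pi * tmin / period_min),
             start = start, cadence = cadence, id = id, week = week)
}

# irregular-ish random trace for oracle-equivalence sweeps: smooth daily
# structure + AR-like noise, strictly above the 45 mg/dL mark
random_trace <- function(seed, days = 2, cadence = 15) {
  set.seed(seed)
  n <- days * 1440 / cadence
  tmin <- (seq_len(n) - 1) * cadence
  base <- runif(1, 85, 120)
  g <- base +
    runif(1, 0, 15) * sin(2 * pi * tmin / 1440 + runif(1, 0, 2 * pi)) +
    runif(1, 0, 30) * pmax(0, sin(2 * pi * tmin / runif(1, 180, 480)))^3 +
    as.numeric(stats::filter(rnorm(n, 0, 4), 0.5, method = "recursive"))
  make_trace(pmax(50, g), cadence = cadence, id = paste0("R", seed))
}

# meal-record data frame helper
meal_df <- function(times, kcal, id = "T1", week = 0, start = t0()) {
  data.frame(participant_id = id, week = week,
             timestamp = start + times * 60, kcal = kcal)
}
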