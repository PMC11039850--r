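# Synthetic two-timepoint CGM cohort generator.
#
# Emulates a small cohort of postmenopausal women without diabetes wearing a
# blinded 15-min CGM for several days at weeks 0 and 16, logging timestamped
# meals, with a plantable effect linking the change in low-glucose-eating
# propensity to the change in postprandial excursion size (and hence in
# glycemic variability).

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a 17-woman two-timepoint cohort,
#' 7 days of 15-min CGM per assessment, fasting thresholds near 85-110
#' mg/dL, 2-6 meals/day, and a negative planted effect of the change in
#' low-glucose-eating propensity on the change in meal-excursion amplitude.
#'
#' @param n_participants Cohort size.
#' @param days_per_assessment CGM days per assessment (3-10).
#' @param cadence Minutes between CGM readings; must divide 1440.
#' @param baseline_mean,baseline_sd Population mean/SD of the participant
#'   basal glucose level, mg/dL.
#' @param circadian_amplitude Amplitude of the 24-h sinusoid, mg/dL.
#' @param meal_amplitude_range Range of per-participant mean postprandial
#'   excursion amplitudes, mg/dL.
#' @param meal_decay Exponential decay time of the post-peak excursion, min.
#' @param ar_coefficient AR(1) coefficient of the sensor noise, in [0, 1).
#' @param noise_sd Marginal SD of the sensor noise, mg/dL.
#' @param lge_propensity_range Range of week-0 low-glucose-eating
#'   propensities, in [0, 1].
#' @param effect_size Planted slope (mg/dL of meal amplitude per unit change
#'   in propensity); negative values plant the negative
#'   delta-LGE/delta-GV association.
#' @param snack_noise_fraction Fraction of meals accompanied by a sub-25-kcal
#'   snack record (exercises the validity filter).
#' @param meals_per_day_range Integer range of meals per day.
#' @param threshold_range Range of personalized fasting thresholds, mg/dL.
#' @param seed Integer seed; identical configs give identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 17,
                       days_per_assessment = 7,
                       cadence = 15,
                       baseline_mean = 92,
                       baseline_sd = 7,
                       circadian_amplitude = 7,
                       meal_amplitude_range = c(30, 60),
                       meal_decay = 60,
                       ar_coefficient = 0.6,
                       noise_sd = 4,
                       lge_propensity_range = c(0, 0.6),
                       effect_size = -30,
                       snack_noise_fraction = 0.1,
                       meals_per_day_range = c(3, 6),
                       threshold_range = c(85, 110),
                       seed = 1L) {
  if (n_participants < 1) stop("invalid config: n_participants < 1")
  if (days_per_assessment <= 1) stop("invalid config: need more than 1 day")
  if (1440 %% cadence != 0) stop("invalid config: cadence must divide 1440")
  if (noise_sd < 0) stop("invalid config: negative noise_sd")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("invalid config: ar_coefficient outside [0, 1)")
  if (any(lge_propensity_range < 0) || any(lge_propensity_range > 1))
    stop("invalid config: propensity range outside [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

# linear 30-min rise then exponential decay; zero before the meal
meal_kernel <- function(offset_min, amplitude, decay_min, rise_min = 30) {
  ifelse(offset_min < 0, 0,
         ifelse(offset_min <= rise_min, amplitude * offset_min / rise_min,
                amplitude * exp(-(offset_min - rise_min) / decay_min)))
}

#' Simulate one CGM trace
#'
#' Glucose is a basal level plus a 24-h circadian sinusoid, postprandial
#' excursions (linear 30-min rise, exponential decay), and AR(1) sensor
#' noise, clipped at the 40 mg/dL reporting floor and sampled on the cadence
#' grid.
#'
#' @param config A [sim_config].
#' @param params List of participant parameters: `participant_id`, `week`,
#'   `start` (`POSIXct`), `baseline` (mg/dL), optional `circadian_amplitude`
#'   and `circadian_phase_h` (hour of the sinusoid's mean upcrossing, default
#'   10), optional `meals` (data frame with `timestamp`, `amplitude`),
#'   optional `seed`.
#' @return A [glucose_trace].
#' @export
simulate_trace <- function(config, params) {
  stopifnot(inherits(config, "sim_config"))
  n_days <- config$days_per_assessment
  if (n_days * 24 <= 24) stop("invalid config: trace duration must exceed 24 h")
  start <- parse_time(params$start %||% "2023-01-02 00:00:00")
  n <- as.integer(n_days * 1440 / config$cadence)
  tt <- as.numeric(start) + (seq_len(n) - 1L) * config$cadence * 60
  hour <- (tt / 3600) %% 24
  amp_c <- params$circadian_amplitude %||% config$circadian_amplitude
  phase <- params$circadian_phase_h %||% 10
  g <- params$baseline + amp_c * sin(2 * pi * (hour - phase) / 24)
  meals <- params$meals
  if (!is.null(meals) && nrow(meals)) {
    for (m in seq_len(nrow(meals))) {
      off <- (tt - as.numeric(meals$timestamp[m])) / 60
      g <- g + meal_kernel(off, meals$amplitude[m], config$meal_decay)
    }
  }
  noise <- numeric(n)
  if (config$noise_sd > 0) {
    noise <- with_seed(params$seed %||% NULL, {
      phi <- config$ar_coefficient
      innov <- stats::rnorm(n, 0, config$noise_sd * sqrt(1 - phi^2))
      e <- numeric(n)
      e[1] <- stats::rnorm(1, 0, config$noise_sd)
      for (i in seq_len(n - 1L)) e[i + 1L] <- phi * e[i] + innov[i + 1L]
      e
    })
  }
  glucose_trace(params$participant_id %||% "sim", params$week %||% 0,
                as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
                pmax(40, g + noise), cadence_min = config$cadence)
}

#' Simulate a food log against a trace
#'
#' Schedules 2-6 meals per day in the 06:00-21:00 window. With probability
#' `lge_propensity` a meal is placed at a (random) instant where the current
#' simulated glucose - the input trace plus the excursions of meals already
#' placed - is at or below the participant threshold (falling back to the
#' lowest-glucose instant when none qualifies); otherwise at a random
#' daytime instant. Meals are kept at least 45 min apart. A configurable
#' fraction of meals is accompanied by a sub-25-kcal snack record placed at
#' least 15 min from every other record, to exercise the validity filter.
#'
#' @param config A [sim_config].
#' @param trace A meal-free [glucose_trace] for the assessment.
#' @param lge_propensity Probability in [0, 1] of scheduling a meal low.
#' @param threshold Participant threshold, mg/dL.
#' @param meal_amplitude Participant-week mean excursion amplitude, mg/dL.
#' @param seed Optional integer seed.
#' @return Data frame `participant_id, week, timestamp, kcal` with attribute
#'   `"meals"` (timestamp, amplitude, scheduled_low) describing the true
#'   meals for trace regeneration.
#' @export
simulate_meals <- function(config, trace, lge_propensity, threshold,
                           meal_amplitude = mean(config$meal_amplitude_range),
                           seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(trace, "glucose_trace"))
  if (lge_propensity < 0 || lge_propensity > 1)
    stop("invalid config: lge_propensity outside [0, 1]")
  with_seed(seed, {
    tt <- as.numeric(trace$time)
    hour <- (tt / 3600) %% 24
    dayi <- as.integer(as.Date(trace$time, tz = "UTC"))
    cur <- trace$glucose
    placed <- numeric(0)       # meal times, seconds
    amps <- numeric(0); low_flag <- logical(0)
    for (d in unique(dayi)) {
      n_meals <- sample(seq(config$meals_per_day_range[1],
                            config$meals_per_day_range[2]), 1)
      last <- -Inf
      for (k in seq_len(n_meals)) {
        # chronological placement: each decision sees all earlier excursions
        go_low <- stats::runif(1) < lge_propensity
        # habitual meals fall in usual eating hours; deliberate low-glucose
        # meals may also use the early-morning window where glucose is low
        h_min <- if (go_low) 6 else 8
        cand <- which(dayi == d & hour >= h_min & hour < 21 & tt >= last + 45 * 60)
        if (!length(cand)) break
        if (go_low) {
          cand <- cand[cur[cand] <= threshold]
          if (!length(cand)) next  # no low instant left today: meal skipped
        }
        i <- cand[sample.int(length(cand), 1)]
        amp <- meal_amplitude * stats::runif(1, 0.7, 1.3)
        placed <- c(placed, tt[i]); amps <- c(amps, amp)
        low_flag <- c(low_flag, go_low)
        last <- tt[i]
        cur <- cur + meal_kernel((tt - tt[i]) / 60, amp, config$meal_decay)
      }
    }
    ord <- order(placed)
    placed <- placed[ord]; amps <- amps[ord]; low_flag <- low_flag[ord]
    kcal <- round(clamp(stats::rlnorm(length(placed), log(400), 0.4), 25, 1500))
    log_t <- placed
    log_k <- kcal
    # snack-noise records: sub-25 kcal, >= 15 min from everything, so that
    # snack_noise_fraction of the raw log is dropped by the validity filter
    f <- min(config$snack_noise_fraction, 0.9)
    n_snack <- round(f / (1 - f) * length(placed))
    if (n_snack > 0) {
      pool <- which(hour >= 6 & hour < 22)
      pool <- pool[vapply(tt[pool], function(x)
        all(abs(x - placed) >= 20 * 60), logical(1))]
      if (length(pool)) {
        pick <- pool[sample.int(length(pool), min(n_snack, length(pool)))]
        log_t <- c(log_t, tt[pick])
        log_k <- c(log_k, round(stats::runif(length(pick), 5, 24)))
      }
    }
    ord <- order(log_t)
    out <- data.frame(participant_id = trace$participant_id, week = trace$week,
                      timestamp = as.POSIXct(log_t[ord], origin = "1970-01-01",
                                             tz = "UTC"),
                      kcal = log_k[ord], stringsAsFactors = FALSE)
    attr(out, "meals") <- data.frame(
      timestamp = as.POSIXct(placed, origin = "1970-01-01", tz = "UTC"),
      amplitude = amps, scheduled_low = low_flag)
    out
  })
}

#' Simulate a full two-timepoint cohort
#'
#' Per participant: a basal glucose level, a fasting threshold near the basal
#' level, a week-0 low-glucose-eating propensity and meal-excursion
#' amplitude; the week-16 propensity adds a heterogeneous shift, and the
#' week-16 amplitude moves by `effect_size` times the propensity shift,
#' planting a negative association between the change in low-glucose eating
#' and the change in glycemic variability. Weight loss is generated
#' independently of the propensity shift. The planted per-participant values
#' are returned in the `truth` table.
#'
#' @param config A [sim_config].
#' @return Object of class `synthetic_cohort`: list with data frames `cgm`
#'   (`participant_id,week,timestamp,glucose_mg_dl`), `meals`
#'   (`participant_id,week,timestamp,kcal`), `anthro`
#'   (`participant_id,week,weight_kg,fasting1_mg_dl,fasting2_mg_dl`),
#'   `truth`, and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    cgm <- list(); meals <- list(); anthro <- list(); truth <- list()
    for (i in seq_len(config$n_participants)) {
      pid <- sprintf("P%02d", i)
      b0 <- clamp(stats::rnorm(1, config$baseline_mean, config$baseline_sd), 75, 115)
      # threshold tracks the basal level (morning fasting glucose), so the
      # chance a *random* daytime meal lands low is comparable across
      # participants and differences in computed LGE reflect propensity
      thr_true <- clamp(b0, config$threshold_range[1], config$threshold_range[2])
      p0 <- stats::runif(1, config$lge_propensity_range[1],
                         config$lge_propensity_range[2])
      p16 <- clamp(p0 + stats::runif(1, -0.4, 0.4), 0, 1)
      amp0 <- stats::runif(1, config$meal_amplitude_range[1],
                           config$meal_amplitude_range[2])
      amp16 <- clamp(amp0 + config$effect_size * (p16 - p0) +
                       stats::rnorm(1, 0, 3), 5, 120)
      w0 <- clamp(stats::rnorm(1, 92.5, 18.5), 55, 150)
      w16 <- w0 - stats::rnorm(1, 6.9, 4)
      for (wk in c(0, 16)) {
        base <- if (wk == 0) b0 else b0 + stats::rnorm(1, 0, 2)
        prop <- if (wk == 0) p0 else p16
        amp <- if (wk == 0) amp0 else amp16
        fasting <- pmax(60, thr_true + stats::rnorm(2, 0, 1))
        thr_used <- mean(fasting)
        s_trace <- (config$seed * 7919L + i * 104729L + wk * 13L) %% 2147483600L
        s_meals <- (s_trace + 7L) %% 2147483600L
        start <- sprintf("2023-%02d-02 00:00:00", if (wk == 0) 1 else 5)
        params <- list(participant_id = pid, week = wk, start = start,
                       baseline = base, seed = s_trace)
        base_trace <- simulate_trace(config, params)
        food <- simulate_meals(config, base_trace, prop, thr_used,
                               meal_amplitude = amp, seed = s_meals)
        params$meals <- attr(food, "meals")
        final <- simulate_trace(config, params)
        cgm[[length(cgm) + 1L]] <- data.frame(
          participant_id = pid, week = wk,
          timestamp = format_time(final$time), glucose_mg_dl = final$glucose)
        meals[[length(meals) + 1L]] <- data.frame(
          participant_id = pid, week = wk,
          timestamp = format_time(food$timestamp), kcal = food$kcal)
        anthro[[length(anthro) + 1L]] <- data.frame(
          participant_id = pid, week = wk,
          weight_kg = round(if (wk == 0) w0 else w16, 1),
          fasting1_mg_dl = round(fasting[1], 1),
          fasting2_mg_dl = round(fasting[2], 1))
      }
      truth[[i]] <- data.frame(
        participant_id = pid, threshold = thr_true, baseline = b0,
        propensity_week0 = p0, propensity_week16 = p16,
        meal_amp_week0 = amp0, meal_amp_week16 = amp16,
        weight_week0 = w0, weight_week16 = w16)
    }
    structure(list(cgm = do.call(rbind, cgm),
                   meals = do.call(rbind, meals),
                   anthro = do.call(rbind, anthro),
                   truth = do.call(rbind, truth),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants x 2 assessments, %d CGM rows, %d meal records\n",
              nrow(x$truth), nrow(x$cgm), nrow(x$meals)))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `cgm.csv`, `meals.csv`, `anthro.csv`, `truth.csv` into `dir`,
#' ISO-8601 timestamps without timezone offsets.
#'
#' @param cohort A [simulate_cohort] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("cgm", "meals", "anthro", "truth"))
    utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
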