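# Glycemic-variability metric battery.
#
# All metrics operate on a glucose_trace at its native cadence, in mg/dL
# internally; CONGA, MAGE, MODD are reported in mmol/L and LI in
# (mmol/L)^2 per hour, matching the scales conventional for these metrics.

# internal: nearest-reading lookup. For each target time (seconds), index of
# the nearest reading, NA when farther than tol seconds.
nearest_reading <- function(times, targets, tol) {
  lo <- findInterval(targets, times)
  hi <- pmin(lo + 1L, length(times))
  lo <- pmax(lo, 1L)
  d_lo <- abs(targets - times[lo])
  d_hi <- abs(targets - times[hi])
  idx <- ifelse(d_lo <= d_hi, lo, hi)
  d <- pmin(d_lo, d_hi)
  idx[d > tol] <- NA_integer_
  idx
}

#' Mean and standard deviation of a trace
#'
#' Arithmetic mean and sample (n-1) standard deviation in mg/dL.
#'
#' @param trace A [glucose_trace].
#' @return List with `mean_mg_dl`, `sd_mg_dl`.
#' @export
gv_mean_sd <- function(trace) {
  g <- trace$glucose
  if (length(g) < 2L) stop("need at least 2 readings for the sample SD")
  list(mean_mg_dl = mean(g), sd_mg_dl = stats::sd(g))
}

#' CONGA: continuous overlapping net glycemic action
#'
#' Sample standard deviation of differences between readings a fixed lag
#' apart (default 60 min), reported in mmol/L. A reading pairs with the
#' nearest earlier reading within half a cadence of the lag.
#'
#' @param trace A [glucose_trace].
#' @param lag_minutes Lag, default 60.
#' @return CONGA in mmol/L.
#' @export
gv_conga <- function(trace, lag_minutes = 60) {
  tt <- as.numeric(trace$time)
  if (trace_span_hours(trace) * 60 <= lag_minutes)
    stop("trace shorter than the CONGA lag")
  tol <- trace$cadence_min * 60 / 2
  idx <- nearest_reading(tt, tt - lag_minutes * 60, tol)
  ok <- !is.na(idx)
  d <- trace$glucose[ok] - trace$glucose[idx[ok]]
  if (length(d) < 2L) stop("fewer than 2 lag pairs for CONGA")
  stats::sd(d) / MGDL_PER_MMOL
}

#' LI: lability index
#'
#' Squared glucose changes (mmol/L) between readings on a fixed interval
#' grid (default 60 min), divided by the elapsed time in hours, summed, and
#' normalized per whole day of observation (span floored at one day).
#'
#' @param trace A [glucose_trace].
#' @param interval_minutes Grid interval, default 60.
#' @return LI in (mmol/L)^2 per hour, per day of observation.
#' @export
gv_li <- function(trace, interval_minutes = 60) {
  tt <- as.numeric(trace$time)
  grid <- seq(tt[1], tt[length(tt)], by = interval_minutes * 60)
  idx <- nearest_reading(tt, grid, trace$cadence_min * 60 / 2)
  idx <- unique(idx[!is.na(idx)])
  if (length(idx) < 2L) stop("fewer than 2 grid readings for LI")
  g <- trace$glucose[idx] / MGDL_PER_MMOL
  t_h <- tt[idx] / 3600
  days <- max(1, trace_span_hours(trace) / 24)
  sum(diff(g)^2 / diff(t_h)) / days
}

#' J-index
#'
#' `0.001 * (mean + sd)^2` with mean and SD in mg/dL.
#'
#' @param trace A [glucose_trace].
#' @return J-index (unitless).
#' @export
gv_j_index <- function(trace) {
  ms <- gv_mean_sd(trace)
  j_index_from_moments(ms$mean_mg_dl, ms$sd_mg_dl)
}

#' @rdname gv_j_index
#' @param mean_mg_dl,sd_mg_dl Trace moments in mg/dL.
#' @export
j_index_from_moments <- function(mean_mg_dl, sd_mg_dl) {
  0.001 * (mean_mg_dl + sd_mg_dl)^2
}

# internal: the symmetrizing risk transform behind LBGI/HBGI/ADRR.
# f(G) = 1.509 * ((ln G)^1.084 - 5.381), r = 10 f^2, split by sign of f.
risk_components <- function(g) {
  if (any(g <= 0)) stop("non-positive glucose in risk transform")
  f <- 1.509 * (log(g)^1.084 - 5.381)
  r <- 10 * f^2
  list(rl = ifelse(f < 0, r, 0), rh = ifelse(f > 0, r, 0))
}

#' LBGI and HBGI: low and high blood glucose indices
#'
#' Means of the low-side and high-side risk after the logarithmic
#' symmetrizing transform of glucose (mg/dL). The transform's root is near
#' 112.5 mg/dL, where both indices vanish.
#'
#' @param trace A [glucose_trace].
#' @return List with `lbgi`, `hbgi`.
#' @export
gv_bgi <- function(trace) {
  rc <- risk_components(trace$glucose)
  list(lbgi = mean(rc$rl), hbgi = mean(rc$rh))
}

#' ADRR: average daily risk range
#'
#' Per calendar day, the maximum low-side plus maximum high-side risk;
#' ADRR is the mean of the daily sums. Days with fewer than
#' `min_readings_per_day` readings are excluded as degenerate.
#'
#' @param trace A [glucose_trace].
#' @param min_readings_per_day Default 12.
#' @return ADRR (unitless).
#' @export
gv_adrr <- function(trace, min_readings_per_day = 12) {
  days <- split_days(trace)
  daily <- vapply(days, function(d) {
    if (length(d$glucose) < min_readings_per_day) return(NA_real_)
    rc <- risk_components(d$glucose)
    max(rc$rl) + max(rc$rh)
  }, numeric(1))
  daily <- daily[!is.na(daily)]
  if (!length(daily)) stop("no day with enough readings for ADRR")
  mean(daily)
}

#' GRADE: glycemic risk assessment diabetes equation
#'
#' Per reading, `425 * (log10(log10(G_mmol)) + 0.16)^2` capped at 50; GRADE
#' is the mean. Readings at or below 1 mmol/L (outside the log-log domain)
#' are excluded and counted in the `n_excluded` attribute.
#'
#' @param trace A [glucose_trace].
#' @param cap Per-reading cap, default 50.
#' @return GRADE (unitless) with attribute `n_excluded`.
#' @export
gv_grade <- function(trace, cap = 50) {
  g_mmol <- trace$glucose / MGDL_PER_MMOL
  bad <- g_mmol <= 1
  g_mmol <- g_mmol[!bad]
  if (!length(g_mmol)) stop("no readings in the GRADE domain (> 1 mmol/L)")
  h <- pmin(cap, 425 * (log10(log10(g_mmol)) + 0.16)^2)
  structure(mean(h), n_excluded = sum(bad))
}

#' MAGE: mean amplitude of glycemic excursions
#'
#' Turning points are interior local extrema of the reading sequence
#' (three-point rule after collapsing plateaus). Excursion amplitudes between
#' consecutive turning points qualify when they exceed the whole-trace sample
#' SD (mg/dL); MAGE is the mean qualifying amplitude in both directions,
#' reported in mmol/L. With no qualifying excursion the value is 0 with
#' attribute `no_excursions = TRUE`.
#'
#' @param trace A [glucose_trace].
#' @return MAGE in mmol/L.
#' @export
gv_mage <- function(trace) {
  g <- trace$glucose
  if (length(g) < 4L) stop("need at least 4 readings for MAGE")
  s <- stats::sd(g)
  # collapse plateaus, then three-point interior extrema
  keep <- c(TRUE, diff(g) != 0)
  gc <- g[keep]
  tp <- numeric(0)
  if (length(gc) >= 3L) {
    d <- sign(diff(gc))
    turn <- which(d[-1] != d[-length(d)]) + 1L
    tp <- gc[turn]
  }
  if (length(tp) < 2L)
    return(structure(0, no_excursions = TRUE))
  amp <- abs(diff(tp))
  amp <- amp[amp > s]
  if (!length(amp)) return(structure(0, no_excursions = TRUE))
  mean(amp) / MGDL_PER_MMOL
}

#' MODD: mean of daily differences
#'
#' Mean absolute difference between readings exactly 24 h apart (within half
#' a cadence), in mmol/L.
#'
#' @param trace A [glucose_trace].
#' @return MODD in mmol/L.
#' @export
gv_modd <- function(trace) {
  if (trace_span_hours(trace) <= 24)
    stop("trace must span more than 24 h for MODD")
  tt <- as.numeric(trace$time)
  idx <- nearest_reading(tt, tt + 24 * 3600, trace$cadence_min * 60 / 2)
  ok <- !is.na(idx)
  if (!any(ok)) stop("no 24-h reading pairs for MODD")
  mean(abs(trace$glucose[idx[ok]] - trace$glucose[ok])) / MGDL_PER_MMOL
}

#' M-value
#'
#' Mean of `|10 * log10(G / reference)|^3` over readings, reference 120
#' mg/dL by default. No sparse-sampling range correction is applied: CGM
#' series are dense.
#'
#' @param trace A [glucose_trace].
#' @param reference_mg_dl Reference glucose, default 120.
#' @return M-value (unitless).
#' @export
gv_m_value <- function(trace, reference_mg_dl = 120) {
  if (any(trace$glucose <= 0)) stop("non-positive glucose")
  mean(abs(10 * log10(trace$glucose / reference_mg_dl))^3)
}

#' Full glycemic-variability profile of one trace
#'
#' Computes the complete battery. Metrics whose preconditions fail on short
#' or degenerate traces are returned as `NA` with the failure noted in the
#' `notes` column.
#'
#' @param trace A [glucose_trace].
#' @param conga_lag_minutes,li_interval_minutes Lag and interval settings,
#'   both 60 min by default.
#' @param m_reference_mg_dl M-value reference, default 120 mg/dL.
#' @return One-row data frame: `participant_id`, `week`, `n_readings`,
#'   `mean_glucose`, `sd_glucose` (mg/dL), `conga`, `mage`, `modd` (mmol/L),
#'   `li`, `j_index`, `lbgi`, `hbgi`, `adrr`, `grade`, `m_value`, `notes`.
#' @export
gv_profile <- function(trace, conga_lag_minutes = 60, li_interval_minutes = 60,
                       m_reference_mg_dl = 120) {
  grab <- function(expr) tryCatch(as.numeric(expr), error = function(e) NA_real_)
  ms <- gv_mean_sd(trace)
  bgi <- gv_bgi(trace)
  vals <- data.frame(
    participant_id = trace$participant_id,
    week = trace$week,
    n_readings = length(trace$glucose),
    mean_glucose = ms$mean_mg_dl,
    sd_glucose = ms$sd_mg_dl,
    conga = grab(gv_conga(trace, conga_lag_minutes)),
    mage = grab(gv_mage(trace)),
    modd = grab(gv_modd(trace)),
    li = grab(gv_li(trace, li_interval_minutes)),
    j_index = j_index_from_moments(ms$mean_mg_dl, ms$sd_mg_dl),
    lbgi = bgi$lbgi,
    hbgi = bgi$hbgi,
    adrr = grab(gv_adrr(trace)),
    grade = grab(gv_grade(trace)),
    m_value = gv_m_value(trace, m_reference_mg_dl),
    stringsAsFactors = FALSE)
  miss <- names(vals)[vapply(vals, function(x) is.numeric(x) && is.na(x), logical(1))]
  vals$notes <- if (length(miss)) paste("insufficient data:", paste(miss, collapse = ",")) else ""
  vals
}
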