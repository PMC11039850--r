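#' Read a food log from CSV
#'
#' Expects columns `participant_id,week,timestamp,kcal` with optional
#' macronutrient columns `carb_g,fat_g,protein_g`.
#'
#' @param path CSV file path.
#' @return Data frame of meal records sorted by participant, week, time.
#' @export
read_meals_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "week", "timestamp", "kcal")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  raw$participant_id <- as.character(raw$participant_id)
  raw$timestamp <- parse_time(raw$timestamp)
  raw$kcal <- as.numeric(raw$kcal)
  ok <- !is.na(raw$timestamp) & is.finite(raw$kcal) & raw$kcal >= 0
  raw <- raw[ok, , drop = FALSE]
  raw[order(raw$participant_id, raw$week, raw$timestamp), , drop = FALSE]
}

#' Consolidate raw meal records into discrete eating events
#'
#' Records for one participant-week are chain-merged whenever consecutive
#' records are less than 15 minutes apart: energy (and macronutrients) are
#' summed and the merged event takes the earliest timestamp. After merging,
#' events below the 25 kcal validity floor are dropped. The chain rule merges
#' A, B, C when A-B and B-C are each under the gap even if A-C is not.
#'
#' @param records Data frame with columns `timestamp` (`POSIXct`) and `kcal`
#'   (plus optional `carb_g`, `fat_g`, `protein_g`), one participant-week,
#'   any order.
#' @param min_gap_minutes Merge gap, default 15.
#' @param min_kcal Validity floor applied after merging, default 25.
#' @return Data frame of events (`timestamp`, `kcal`, `n_records`, macros if
#'   present), sorted, pairwise at least `min_gap_minutes` apart, all at or
#'   above `min_kcal`.
#' @export
consolidate_events <- function(records, min_gap_minutes = 15, min_kcal = 25) {
  macro_cols <- intersect(c("carb_g", "fat_g", "protein_g"), names(records))
  if (nrow(records) == 0L) {
    out <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      kcal = numeric(), n_records = integer())
    for (m in macro_cols) out[[m]] <- numeric()
    return(out)
  }
  records <- records[order(records$timestamp), , drop = FALSE]
  gap <- c(Inf, diff(as.numeric(records$timestamp)) / 60)
  grp <- cumsum(gap >= min_gap_minutes)
  agg <- function(col) as.numeric(tapply(records[[col]], grp, sum))
  out <- data.frame(
    timestamp = as.POSIXct(as.numeric(tapply(as.numeric(records$timestamp), grp, min)),
                           origin = "1970-01-01", tz = "UTC"),
    kcal = agg("kcal"),
    n_records = as.integer(tapply(grp, grp, length)))
  for (m in macro_cols) out[[m]] <- agg(m)
  out <- out[out$kcal >= min_kcal, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match preprandial glucose to eating events
#'
#' Each event is assigned the glucose at the nearest instant of a resampled
#' trace within +/- `window_minutes`; ties prefer the instant at or before the
#' meal (preprandial semantics). Events with no candidate instant (e.g. during
#' an uninterpolated CGM gap) are flagged `matched = FALSE` and are excluded
#' from the low-glucose-eating denominator downstream.
#'
#' @param events Data frame from [consolidate_events].
#' @param trace A [glucose_trace], normally resampled to a 5-min grid via
#'   [resample_trace].
#' @param window_minutes Matching half-window, default 5.
#' @return `events` with added columns `preprandial_glucose`, `matched`.
#' @export
match_preprandial <- function(events, trace, window_minutes = 5) {
  stopifnot(inherits(trace, "glucose_trace"))
  tt <- as.numeric(trace$time)
  pre <- rep(NA_real_, nrow(events))
  matched <- rep(FALSE, nrow(events))
  for (i in seq_len(nrow(events))) {
    dt <- as.numeric(events$timestamp[i]) - tt  # positive: reading before meal
    cand <- which(abs(dt) <= window_minutes * 60 + 1e-9)
    if (!length(cand)) next
    best <- abs(dt[cand])
    sel <- cand[best <= min(best) + 1e-9]
    if (length(sel) > 1L) sel <- sel[dt[sel] >= 0]  # tie: at-or-before wins
    pre[i] <- trace$glucose[sel[1]]
    matched[i] <- TRUE
  }
  events$preprandial_glucose <- pre
  events$matched <- matched
  events
}

#' Per-day validity of eating records
#'
#' A calendar day is valid when it carries at least two matched eating events
#' and the trace as a whole passed the plausibility filter.
#'
#' @param events Data frame from [match_preprandial].
#' @param plausible Logical: trace-level plausibility from
#'   [assess_plausibility].
#' @param min_events Events needed per day, default 2.
#' @return Data frame with `date`, `n_matched_events`, `valid`.
#' @export
find_valid_days <- function(events, plausible, min_events = 2) {
  if (nrow(events) == 0L)
    return(data.frame(date = as.Date(character()), n_matched_events = integer(),
                      valid = logical()))
  day <- as.Date(events$timestamp, tz = "UTC")
  tab <- tapply(events$matched, day, sum)
  data.frame(date = as.Date(names(tab)),
             n_matched_events = as.integer(tab),
             valid = as.integer(tab) >= min_events & isTRUE(plausible),
             row.names = NULL)
}

#' Participant inclusion decision
#'
#' A participant enters the analytic dataset only with at least `min_days`
#' valid days at both assessments.
#'
#' @param valid_days_week0,valid_days_week16 Valid-day counts (`NA` if the
#'   assessment is missing).
#' @param min_days Minimum per week, default 3.
#' @return List with the counts, `included`, and a `reason` string when
#'   excluded.
#' @export
decide_inclusion <- function(valid_days_week0, valid_days_week16, min_days = 3) {
  miss <- is.na(valid_days_week0) || is.na(valid_days_week16)
  included <- !miss && valid_days_week0 >= min_days && valid_days_week16 >= min_days
  reason <- if (included) NA_character_
            else if (miss) "missing assessment"
            else sprintf("valid days %s/%s below %d", valid_days_week0,
                         valid_days_week16, min_days)
  list(valid_days_week0 = valid_days_week0,
       valid_days_week16 = valid_days_week16,
       included = included, reason = reason)
}
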