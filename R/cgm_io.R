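#' Construct a CGM glucose trace
#'
#' A `glucose_trace` holds one participant-assessment's time-ordered
#' interstitial glucose readings. Timestamps must be strictly increasing and
#' values positive and finite.
#'
#' @param participant_id Scalar identifier.
#' @param week Assessment label (typically 0 or 16).
#' @param time `POSIXct` vector (or ISO-8601 strings), strictly increasing.
#' @param glucose Numeric vector, mg/dL, positive finite, same length as
#'   `time`.
#' @param cadence_min Nominal minutes between readings (default 15, the
#'   FreeStyle Libre Pro cadence).
#' @return An object of class `glucose_trace`: a list with elements
#'   `participant_id`, `week`, `time`, `glucose`, `cadence_min`.
#' @export
glucose_trace <- function(participant_id, week, time, glucose, cadence_min = 15) {
  time <- parse_time(time)
  glucose <- as.numeric(glucose)
  if (length(time) != length(glucose))
    stop("time and glucose must have equal length")
  if (length(time) < 1L) stop("empty trace")
  if (anyNA(time)) stop("unparseable timestamps")
  if (any(!is.finite(glucose)) || any(glucose <= 0))
    stop("glucose values must be positive and finite")
  if (is.unsorted(as.numeric(time), strictly = TRUE))
    stop("timestamps must be strictly increasing")
  structure(
    list(participant_id = participant_id, week = week,
         time = time, glucose = glucose, cadence_min = cadence_min),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("<glucose_trace> participant %s, week %s: %d readings, %s to %s\n",
              x$participant_id, x$week, length(x$glucose),
              format_time(x$time[1]), format_time(x$time[length(x$time)])))
  cat(sprintf("  glucose %.1f-%.1f mg/dL (mean %.1f), cadence %g min\n",
              min(x$glucose), max(x$glucose), mean(x$glucose), x$cadence_min))
  invisible(x)
}

#' @export
length.glucose_trace <- function(x) length(x$glucose)

trace_span_hours <- function(trace) {
  as.numeric(difftime(trace$time[length(trace$time)], trace$time[1], units = "hours"))
}

#' Read CGM traces from CSV
#'
#' Expects columns `participant_id, week, timestamp, glucose_mg_dl` (names
#' remappable via `col_map`, e.g. for Libre Pro "Historic Glucose" exports).
#' Rows with unparseable timestamps or non-positive glucose are dropped and
#' counted; duplicate timestamps within a participant-week keep the first
#' occurrence.
#'
#' @param path CSV file path.
#' @param col_map Named character vector mapping the canonical names
#'   `participant_id`, `week`, `timestamp`, `glucose` to the file's column
#'   names.
#' @return A list of [glucose_trace] objects, one per participant-week, with
#'   attribute `"drop_log"` (a data frame counting dropped rows by reason).
#' @export
read_cgm_csv <- function(path,
                         col_map = c(participant_id = "participant_id",
                                     week = "week",
                                     timestamp = "timestamp",
                                     glucose = "glucose_mg_dl")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  df <- data.frame(participant_id = as.character(raw[[col_map[["participant_id"]]]]),
                   week = raw[[col_map[["week"]]]],
                   timestamp = parse_time(raw[[col_map[["timestamp"]]]]),
                   glucose = suppressWarnings(as.numeric(raw[[col_map[["glucose"]]]])))
  bad_time <- is.na(df$timestamp)
  bad_gluc <- !bad_time & (!is.finite(df$glucose) | df$glucose <= 0)
  keep <- !(bad_time | bad_gluc)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no parseable CGM rows in ", path)

  n_dup <- 0L
  traces <- list()
  for (key in unique(paste(df$participant_id, df$week, sep = "\r"))) {
    part <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- df[df$participant_id == part[1] & df$week == part[2], , drop = FALSE]
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    dup <- duplicated(sub$timestamp)
    n_dup <- n_dup + sum(dup)
    sub <- sub[!dup, , drop = FALSE]
    cad <- if (nrow(sub) > 1) stats::median(diff(as.numeric(sub$timestamp))) / 60 else 15
    traces[[key]] <- glucose_trace(part[1], part[2], sub$timestamp, sub$glucose,
                                   cadence_min = cad)
  }
  names(traces) <- vapply(traces, function(tr)
    paste(tr$participant_id, tr$week, sep = "_w"), character(1))
  attr(traces, "drop_log") <- data.frame(
    reason = c("unparseable_timestamp", "nonpositive_glucose", "duplicate_timestamp"),
    n = c(sum(bad_time), sum(bad_gluc), n_dup))
  traces
}

#' Assess CGM plausibility
#'
#' A trace is plausible if strictly more than 95% of its readings are at or
#' above the physiologic floor of 70 mg/dL (readings are evenly spaced, so the
#' count fraction proxies the wear-time fraction).
#'
#' @param trace A [glucose_trace].
#' @param floor_mg_dl Physiologic floor, default 70 mg/dL.
#' @param min_fraction Plausibility cut, default 0.95 (strict inequality).
#' @return A list with `fraction_in_physiologic_range`, `plausible`,
#'   `n_readings`.
#' @export
assess_plausibility <- function(trace, floor_mg_dl = 70, min_fraction = 0.95) {
  stopifnot(inherits(trace, "glucose_trace"))
  n <- length(trace$glucose)
  if (n == 0L) stop("empty trace")
  frac <- sum(trace$glucose >= floor_mg_dl) / n
  list(fraction_in_physiologic_range = frac,
       plausible = frac > min_fraction,
       n_readings = n)
}

#' Resample a trace onto a regular grid
#'
#' Linear interpolation onto a grid anchored at the first reading. No values
#' are synthesized across raw gaps longer than `max_gap_minutes`: grid points
#' strictly inside such gaps are absent from the output.
#'
#' @param trace A [glucose_trace].
#' @param grid_minutes Grid step, default 5 min (guarantees a candidate within
#'   the +/-5 min meal-matching window on 15-min data).
#' @param max_gap_minutes Longest raw gap to interpolate across, default 60.
#' @return A [glucose_trace] on the regular grid (cadence = `grid_minutes`).
#' @export
resample_trace <- function(trace, grid_minutes = 5, max_gap_minutes = 60) {
  stopifnot(inherits(trace, "glucose_trace"), grid_minutes >= 1)
  t0 <- as.numeric(trace$time)
  if (length(t0) < 2L) stop("need at least 2 readings to resample")
  grid <- seq(t0[1], t0[length(t0)], by = grid_minutes * 60)
  val <- stats::approx(t0, trace$glucose, xout = grid, method = "linear")$y
  # mask grid points strictly inside raw gaps that exceed max_gap
  gaps <- which(diff(t0) > max_gap_minutes * 60)
  keep <- rep(TRUE, length(grid))
  for (g in gaps) keep <- keep & !(grid > t0[g] & grid < t0[g + 1])
  glucose_trace(trace$participant_id, trace$week,
                as.POSIXct(grid[keep], origin = "1970-01-01", tz = "UTC"),
                val[keep], cadence_min = grid_minutes)
}

#' Split a trace into calendar-day sub-traces
#'
#' Partition by local calendar date (midnight boundaries, single implicit
#' timezone). The concatenation of the parts reproduces the input exactly.
#'
#' @param trace A [glucose_trace].
#' @return Named list of `glucose_trace` objects, one per calendar date.
#' @export
split_days <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  day <- as.Date(trace$time, tz = "UTC")
  idx <- split(seq_along(day), day)
  lapply(idx, function(i)
    glucose_trace(trace$participant_id, trace$week, trace$time[i],
                  trace$glucose[i], cadence_min = trace$cadence_min))
}

#' Write CGM traces to CSV
#'
#' Inverse of [read_cgm_csv] for the canonical column layout.
#'
#' @param traces List of [glucose_trace] objects (or a single trace).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(traces, path) {
  if (inherits(traces, "glucose_trace")) traces <- list(traces)
  rows <- do.call(rbind, lapply(traces, function(tr)
    data.frame(participant_id = tr$participant_id, week = tr$week,
               timestamp = format_time(tr$time),
               glucose_mg_dl = tr$glucose)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
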