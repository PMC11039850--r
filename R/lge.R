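#' Personalized glucose threshold from morning fasting readings
#'
#' The threshold is the unrounded arithmetic mean of exactly two morning
#' fasting glucose readings; a single value is never silently accepted.
#'
#' @param fasting_values Numeric vector of exactly two positive mg/dL values.
#' @return List with `threshold` (mg/dL) and `source_values`.
#' @examples
#' derive_threshold(c(95, 105))$threshold # 100
#' @export
derive_threshold <- function(fasting_values) {
  fasting_values <- as.numeric(fasting_values)
  if (length(fasting_values) != 2L || any(!is.finite(fasting_values)) ||
      any(fasting_values <= 0))
    stop("exactly two positive fasting values are required")
  list(threshold = mean(fasting_values), source_values = fasting_values)
}

#' Classify eating events as low-glucose
#'
#' An event is a low-glucose eating (LGE) event when its matched preprandial
#' glucose is at or below the personalized threshold (inclusive).
#'
#' @param preprandial_glucose Numeric mg/dL (no `NA`: events must be matched).
#' @param threshold Personalized threshold, mg/dL.
#' @return Logical vector `is_lge`.
#' @export
classify_lge <- function(preprandial_glucose, threshold) {
  if (anyNA(preprandial_glucose))
    stop("unmatched events cannot be classified; filter on matched first")
  preprandial_glucose <= threshold
}

#' Low-glucose eating percentage for one assessment
#'
#' LGE is the percentage of included (matched) eating events whose
#' preprandial glucose is at or below the threshold. Unmatched events are
#' removed from numerator and denominator alike.
#'
#' @param events Data frame from [match_preprandial] (columns
#'   `preprandial_glucose`, `matched`).
#' @param threshold Personalized threshold, mg/dL.
#' @return List with `n_events_included`, `n_events_lge`, `lge_percent`.
#' @export
compute_lge <- function(events, threshold) {
  inc <- events[events$matched, , drop = FALSE]
  if (nrow(inc) == 0L)
    stop("no included (matched) eating events; LGE undefined for this assessment")
  is_lge <- classify_lge(inc$preprandial_glucose, threshold)
  list(n_events_included = nrow(inc),
       n_events_lge = sum(is_lge),
       lge_percent = 100 * sum(is_lge) / nrow(inc))
}
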