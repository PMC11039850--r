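#' Unit conversion between mg/dL and mmol/L
#'
#' The canonical internal unit throughout the package is mg/dL; metrics
#' conventionally reported in mmol/L (CONGA, MAGE, MODD, LI) are converted on
#' output with the constant 18.016 mg/dL per mmol/L.
#'
#' @param x Numeric vector of glucose values.
#' @return Converted numeric vector.
#' @examples
#' mgdl_to_mmol(180.16) # 10
#' @export
mgdl_to_mmol <- function(x) x / MGDL_PER_MMOL

#' @rdname mgdl_to_mmol
#' @export
mmol_to_mgdl <- function(x) x * MGDL_PER_MMOL

#' @rdname mgdl_to_mmol
#' @format `MGDL_PER_MMOL` is the scalar 18.016.
#' @export
MGDL_PER_MMOL <- 18.016

# internal: parse/format ISO-8601 timestamps, single implicit timezone (UTC);
# element-wise so one malformed row does not poison the vector
parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  out
}

format_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a
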