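# Change-score association analysis: week-16 minus week-0 changes in
# low-glucose eating vs percent changes in glycemic variability, by Pearson
# correlation and weight-adjusted ordinary least squares.

#' Change scores between the two assessments
#'
#' Per participant present at both weeks: change in LGE (percentage points),
#' change in body weight (kg), and for each glycemic-variability measure the
#' percent change `100 * (post - pre) / pre` and the absolute change.
#' Percent change is flagged undefined (`NA`) when the week-0 value is 0.
#' Unpaired participants are excluded and listed in the `"excluded"`
#' attribute.
#'
#' @param lge Data frame with `participant_id`, `week`, `lge_percent`.
#' @param gv Data frame with `participant_id`, `week`, and one column per GV
#'   measure (e.g. from [gv_profile]).
#' @param anthro Data frame with `participant_id`, `week`, `weight_kg`.
#' @param measures Character vector of GV columns to difference; default is
#'   every numeric column of `gv` except bookkeeping columns.
#' @return Data frame with `participant_id`, `delta_lge`, `delta_weight`,
#'   and per measure `pct_<measure>` and `abs_<measure>`.
#' @export
compute_changes <- function(lge, gv, anthro, measures = NULL) {
  if (is.null(measures)) {
    num <- vapply(gv, is.numeric, logical(1))
    measures <- setdiff(names(gv)[num], c("week", "n_readings"))
  }
  ids <- sort(unique(lge$participant_id))
  rows <- list(); excluded <- character(0)
  for (id in ids) {
    l0 <- lge[lge$participant_id == id & lge$week == 0, , drop = FALSE]
    l16 <- lge[lge$participant_id == id & lge$week == 16, , drop = FALSE]
    g0 <- gv[gv$participant_id == id & gv$week == 0, , drop = FALSE]
    g16 <- gv[gv$participant_id == id & gv$week == 16, , drop = FALSE]
    a0 <- anthro[anthro$participant_id == id & anthro$week == 0, , drop = FALSE]
    a16 <- anthro[anthro$participant_id == id & anthro$week == 16, , drop = FALSE]
    if (!all(c(nrow(l0), nrow(l16), nrow(g0), nrow(g16), nrow(a0), nrow(a16)) == 1L)) {
      excluded <- c(excluded, id)
      next
    }
    row <- data.frame(participant_id = id,
                      delta_lge = l16$lge_percent - l0$lge_percent,
                      delta_weight = a16$weight_kg - a0$weight_kg)
    for (m in measures) {
      pre <- g0[[m]]; post <- g16[[m]]
      row[[paste0("pct_", m)]] <-
        if (is.na(pre) || is.na(post) || pre == 0) NA_real_
        else 100 * (post - pre) / pre
      row[[paste0("abs_", m)]] <- post - pre
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  attr(out, "measures") <- measures
  out
}

#' Pearson product-moment correlation with t-based p-value
#'
#' Thin wrapper over [stats::cor.test]: `r` and the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors (pairs with `NA` are dropped).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Weight-adjusted regression of a GV change on the LGE change
#'
#' Ordinary least squares of the percent change in one GV measure on the
#' change in LGE (percentage points) and the concurrent change in body
#' weight (kg), with intercept. Reports per-coefficient two-sided t-tests,
#' adjusted R-squared, and the per-10-percentage-point LGE effect
#' (`10 * beta_lge`).
#'
#' @param delta_gv Numeric outcome (normally `pct_<measure>`).
#' @param delta_lge,delta_weight Numeric predictors.
#' @return List with `beta_lge`, `p_lge`, `beta_weight`, `p_weight`,
#'   `intercept`, `adjusted_r2`, `per_10pp_effect`, `n`, and the underlying
#'   `lm` fit.
#' @export
adjusted_regression <- function(delta_gv, delta_lge, delta_weight) {
  ok <- is.finite(delta_gv) & is.finite(delta_lge) & is.finite(delta_weight)
  d <- data.frame(y = delta_gv[ok], lge = delta_lge[ok], wt = delta_weight[ok])
  if (nrow(d) < 4L) stop("need at least 4 complete cases")
  # a constant weight change carries no information: collapse to the simple
  # regression (whose slope t-test matches the Pearson test on the pair)
  use_wt <- stats::sd(d$wt) > 0
  if (use_wt && qr(cbind(1, d$lge, d$wt))$rank < 3L)
    stop("singular design: collinear predictors")
  if (stats::sd(d$lge) == 0) stop("singular design: constant LGE change")
  fit <- if (use_wt) stats::lm(y ~ lge + wt, data = d) else
    stats::lm(y ~ lge, data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  list(beta_lge = co["lge", 1], p_lge = co["lge", 4],
       beta_weight = if (use_wt) co["wt", 1] else NA_real_,
       p_weight = if (use_wt) co["wt", 4] else NA_real_,
       intercept = co["(Intercept)", 1],
       adjusted_r2 = sm$adj.r.squared,
       per_10pp_effect = 10 * co["lge", 1],
       n = nrow(d), fit = fit)
}

#' Associations between the LGE change and every GV measure
#'
#' Runs [pearson_assoc] and [adjusted_regression] for each measure in a
#' change-score table and assembles the per-measure association table,
#' including a Benjamini-Hochberg column alongside the unadjusted p-values
#' (the analysis itself is exploratory and uncorrected).
#'
#' @param changes Data frame from [compute_changes].
#' @param scale `"percent"` (default, `pct_` columns) or `"absolute"`.
#' @return Data frame, one row per measure: `measure`, `n`, `pearson_r`,
#'   `r_p_value`, `r_p_bh`, `beta_lge`, `p_lge`, `beta_weight`, `p_weight`,
#'   `adjusted_r2`, `per_10pp_effect`; attribute `"fits"` holds the `lm`
#'   objects.
#' @export
associate_changes <- function(changes, scale = c("percent", "absolute")) {
  scale <- match.arg(scale)
  prefix <- if (scale == "percent") "pct_" else "abs_"
  measures <- attr(changes, "measures") %||%
    sub(prefix, "", grep(paste0("^", prefix), names(changes), value = TRUE))
  rows <- list(); fits <- list()
  for (m in measures) {
    y <- changes[[paste0(prefix, m)]]
    res <- tryCatch({
      pe <- pearson_assoc(changes$delta_lge, y)
      re <- adjusted_regression(y, changes$delta_lge, changes$delta_weight)
      data.frame(measure = m, n = pe$n, pearson_r = pe$r, r_p_value = pe$p,
                 beta_lge = re$beta_lge, p_lge = re$p_lge,
                 beta_weight = re$beta_weight, p_weight = re$p_weight,
                 adjusted_r2 = re$adjusted_r2,
                 per_10pp_effect = re$per_10pp_effect)
    }, error = function(e) NULL)
    if (is.null(res)) next
    fits[[m]] <- adjusted_regression(y, changes$delta_lge, changes$delta_weight)$fit
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out)) {
    out$r_p_bh <- stats::p.adjust(out$r_p_value, method = "BH")
    out <- out[, c("measure", "n", "pearson_r", "r_p_value", "r_p_bh",
                   "beta_lge", "p_lge", "beta_weight", "p_weight",
                   "adjusted_r2", "per_10pp_effect")]
    rownames(out) <- NULL
  }
  attr(out, "fits") <- fits
  out
}
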