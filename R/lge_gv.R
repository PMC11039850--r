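# Top-level fit: runs the whole pipeline from raw tables to the change-score
# association analysis and returns a classed result.

traces_from_df <- function(cgm) {
  cgm$participant_id <- as.character(cgm$participant_id)
  cgm$timestamp <- parse_time(cgm$timestamp)
  ok <- !is.na(cgm$timestamp) & is.finite(cgm$glucose_mg_dl) & cgm$glucose_mg_dl > 0
  cgm <- cgm[ok, , drop = FALSE]
  keys <- unique(cgm[, c("participant_id", "week")])
  traces <- list()
  for (r in seq_len(nrow(keys))) {
    sub <- cgm[cgm$participant_id == keys$participant_id[r] &
                 cgm$week == keys$week[r], , drop = FALSE]
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    sub <- sub[!duplicated(sub$timestamp), , drop = FALSE]
    cad <- if (nrow(sub) > 1) stats::median(diff(as.numeric(sub$timestamp))) / 60 else 15
    traces[[paste(keys$participant_id[r], keys$week[r], sep = "_w")]] <-
      glucose_trace(keys$participant_id[r], keys$week[r], sub$timestamp,
                    sub$glucose_mg_dl, cadence_min = cad)
  }
  traces
}

#' Fit the low-glucose-eating / glycemic-variability association model
#'
#' Runs the full pipeline: trace validation and plausibility, eating-event
#' consolidation and preprandial matching, valid-day and inclusion rules,
#' personalized thresholds and LGE scoring, the glycemic-variability metric
#' battery, glucotype time fractions, and the change-score Pearson and
#' weight-adjusted regression analyses.
#'
#' @param cgm CGM table (`participant_id,week,timestamp,glucose_mg_dl`), a
#'   CSV path, or a [simulate_cohort] object (in which case `meals` and
#'   `anthro` are taken from it).
#' @param meals Food-log table (`participant_id,week,timestamp,kcal`) or CSV
#'   path.
#' @param anthro Anthropometrics table
#'   (`participant_id,week,weight_kg,fasting1_mg_dl,fasting2_mg_dl`) or CSV
#'   path.
#' @param threshold_mode `"carry_forward"` (default: the week-0 threshold is
#'   reused at week 16) or `"per_assessment"` (week-16 fasting values, when
#'   present, re-derive the threshold).
#' @param glucotypes Logical: fit glucotype fractions (default `TRUE`).
#' @param seed Integer seed for the glucotype clustering step.
#' @param min_valid_days,min_events_per_day Inclusion rules (defaults 3 and
#'   2).
#' @param grid_minutes,max_gap_minutes Resampling used for meal matching and
#'   windowing.
#' @param window_minutes,step_minutes Glucotype window geometry.
#' @return An object of class `lge_gv` with components `inclusion`, `lge`,
#'   `gv`, `glucotype_model`, `changes`, `associations`, `n_included`.
#'   Methods: `print`, `summary`, `coef`, `plot`, `residuals`, `fitted`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 6, seed = 42))
#' fit <- lge_gv(cohort, glucotypes = FALSE)
#' summary(fit)
#' @export
lge_gv <- function(cgm, meals = NULL, anthro = NULL,
                   threshold_mode = c("carry_forward", "per_assessment"),
                   glucotypes = TRUE, seed = 1L,
                   min_valid_days = 3, min_events_per_day = 2,
                   grid_minutes = 5, max_gap_minutes = 60,
                   window_minutes = 150, step_minutes = 30) {
  threshold_mode <- match.arg(threshold_mode)
  if (inherits(cgm, "synthetic_cohort")) {
    meals <- cgm$meals; anthro <- cgm$anthro; cgm <- cgm$cgm
  }
  if (is.character(cgm)) cgm <- utils::read.csv(cgm, stringsAsFactors = FALSE)
  if (is.character(meals)) meals <- read_meals_csv(meals)
  else { meals$participant_id <- as.character(meals$participant_id)
         meals$timestamp <- parse_time(meals$timestamp) }
  if (is.character(anthro)) anthro <- utils::read.csv(anthro, stringsAsFactors = FALSE)
  anthro$participant_id <- as.character(anthro$participant_id)

  traces <- traces_from_df(cgm)
  ids <- sort(unique(vapply(traces, function(tr) tr$participant_id, character(1))))

  per_week <- list()   # per participant-week intermediates
  for (key in names(traces)) {
    tr <- traces[[key]]
    plaus <- assess_plausibility(tr)
    res <- resample_trace(tr, grid_minutes, max_gap_minutes)
    rec <- meals[meals$participant_id == tr$participant_id &
                   meals$week == tr$week, , drop = FALSE]
    ev <- consolidate_events(rec)
    ev <- match_preprandial(ev, res, window_minutes = 5)
    vd <- find_valid_days(ev, plaus$plausible, min_events = min_events_per_day)
    per_week[[key]] <- list(trace = tr, resampled = res, events = ev,
                            plausible = plaus$plausible,
                            valid_days = sum(vd$valid))
  }

  inclusion <- do.call(rbind, lapply(ids, function(id) {
    k0 <- paste(id, 0, sep = "_w"); k16 <- paste(id, 16, sep = "_w")
    d0 <- if (k0 %in% names(per_week)) per_week[[k0]]$valid_days else NA_integer_
    d16 <- if (k16 %in% names(per_week)) per_week[[k16]]$valid_days else NA_integer_
    dec <- decide_inclusion(d0, d16, min_days = min_valid_days)
    data.frame(participant_id = id, valid_days_week0 = d0,
               valid_days_week16 = d16, included = dec$included,
               reason = dec$reason %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  included_ids <- inclusion$participant_id[inclusion$included]
  if (length(included_ids) < 3L)
    stop("fewer than 3 included participants; association analysis undefined")

  threshold_for <- function(id, wk) {
    row <- anthro[anthro$participant_id == id & anthro$week == wk, , drop = FALSE]
    if (wk == 16 && threshold_mode == "carry_forward") return(threshold_for(id, 0))
    if (nrow(row) != 1L || is.na(row$fasting1_mg_dl) || is.na(row$fasting2_mg_dl)) {
      if (wk == 16) return(threshold_for(id, 0))
      stop("no fasting values for participant ", id, " week ", wk)
    }
    derive_threshold(c(row$fasting1_mg_dl, row$fasting2_mg_dl))$threshold
  }

  lge_rows <- list(); gv_rows <- list()
  for (id in included_ids) for (wk in c(0, 16)) {
    pw <- per_week[[paste(id, wk, sep = "_w")]]
    thr <- threshold_for(id, wk)
    lr <- compute_lge(pw$events, thr)
    lge_rows[[length(lge_rows) + 1L]] <- data.frame(
      participant_id = id, week = wk, threshold = thr,
      n_events_included = lr$n_events_included,
      n_events_lge = lr$n_events_lge, lge_percent = lr$lge_percent)
    gv_rows[[length(gv_rows) + 1L]] <- gv_profile(pw$trace)
  }
  lge_tab <- do.call(rbind, lge_rows)
  gv_tab <- do.call(rbind, gv_rows)

  gt_model <- NULL
  if (glucotypes) {
    win_list <- lapply(included_ids, function(id) lapply(c(0, 16), function(wk)
      window_trace(per_week[[paste(id, wk, sep = "_w")]]$resampled,
                   window_minutes, step_minutes)))
    all_win <- do.call(rbind, unlist(win_list, recursive = FALSE))
    gt_model <- fit_glucotypes(all_win, seed = seed)
    fr <- t(vapply(seq_len(nrow(gv_tab)), function(r) {
      w <- win_list[[match(gv_tab$participant_id[r], included_ids)]][[
        match(gv_tab$week[r], c(0, 16))]]
      classify_fractions(gt_model, w)
    }, numeric(3)))
    gv_tab$gt_low <- fr[, 1]; gv_tab$gt_moderate <- fr[, 2]
    gv_tab$gt_severe <- fr[, 3]
  }

  changes <- compute_changes(lge_tab, gv_tab, anthro)
  associations <- associate_changes(changes)

  structure(list(inclusion = inclusion, lge = lge_tab, gv = gv_tab,
                 glucotype_model = gt_model, changes = changes,
                 associations = associations,
                 n_included = length(included_ids),
                 call = match.call()),
            class = "lge_gv")
}

#' @export
print.lge_gv <- function(x, ...) {
  cat(sprintf("<lge_gv> %d of %d participants included\n",
              x$n_included, nrow(x$inclusion)))
  cat(sprintf("  week-0 LGE %.1f%%, week-16 LGE %.1f%% (cohort means)\n",
              mean(x$lge$lge_percent[x$lge$week == 0]),
              mean(x$lge$lge_percent[x$lge$week == 16])))
  cat(sprintf("  %d GV measures analysed; use summary() for the association table\n",
              nrow(x$associations)))
  invisible(x)
}

#' @export
summary.lge_gv <- function(object, ...) {
  structure(list(inclusion = object$inclusion,
                 associations = object$associations,
                 n_included = object$n_included),
            class = "summary.lge_gv")
}

#' @export
print.summary.lge_gv <- function(x, ...) {
  cat(sprintf("Change-score associations (n = %d participants)\n", x$n_included))
  cat("Pearson r of delta-LGE (pp) vs delta-GV (%), and weight-adjusted OLS:\n\n")
  tab <- x$associations
  tab[] <- lapply(tab, function(c) if (is.numeric(c)) signif(c, 3) else c)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.lge_gv <- function(object, ...) {
  a <- object$associations
  out <- cbind(beta_lge = a$beta_lge, beta_weight = a$beta_weight,
               per_10pp_effect = a$per_10pp_effect)
  rownames(out) <- a$measure
  out
}

#' @export
residuals.lge_gv <- function(object, ...) {
  lapply(attr(object$associations, "fits"), stats::residuals)
}

#' @export
fitted.lge_gv <- function(object, ...) {
  lapply(attr(object$associations, "fits"), stats::fitted)
}

#' Scatter panels of GV changes against the LGE change
#'
#' One panel per measure: percent change in the GV measure against the
#' change in LGE (percentage points), with the fitted simple regression
#' line.
#'
#' @param x An [lge_gv] fit.
#' @param measures Measures to draw (default: the first 9 analysed).
#' @param ... Passed to [graphics::plot].
#' @export
plot.lge_gv <- function(x, measures = utils::head(x$associations$measure, 9), ...) {
  n <- length(measures)
  mf <- c(ceiling(n / 3), min(n, 3))
  old <- graphics::par(mfrow = mf, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in measures) {
    y <- x$changes[[paste0("pct_", m)]]
    r <- x$associations$pearson_r[x$associations$measure == m]
    graphics::plot(x$changes$delta_lge, y,
                   xlab = expression(Delta ~ "LGE (pp)"),
                   ylab = expression(Delta ~ "GV (%)"),
                   main = sprintf("%s (r = %.2f)", m, r), pch = 19, ...)
    ok <- is.finite(y)
    if (sum(ok) >= 3)
      graphics::abline(stats::lm(y[ok] ~ x$changes$delta_lge[ok]),
                       col = "darkorange", lwd = 2)
  }
  invisible(x)
}
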