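# Glucotyping: classify CGM time windows into low / moderate / severe
# glycemic-variability patterns by spectral clustering of window features,
# and report per-participant time fractions in each pattern.

#' Cut a trace into overlapping fixed-length windows
#'
#' Windows are taken on the trace's regular grid (resample first). Windows
#' overlapping any gap (missing grid point) are dropped. Per-window features:
#' mean, SD, range (mg/dL) and maximum absolute rate of change (mg/dL per
#' hour).
#'
#' @param trace A [glucose_trace] on a regular grid (see [resample_trace]).
#' @param window_minutes Window length, default 150 (2.5 h).
#' @param step_minutes Step between window starts, default 30.
#' @return Data frame, one row per window: `participant_id`, `week`,
#'   `start_time`, `mean`, `sd`, `range`, `max_rate`, plus the window values
#'   in attribute `"values"` (a matrix, one row per window).
#' @export
window_trace <- function(trace, window_minutes = 150, step_minutes = 30) {
  stopifnot(inherits(trace, "glucose_trace"))
  cad <- trace$cadence_min
  n_per <- as.integer(window_minutes / cad)   # half-open: offsets 0..window-cad
  step <- as.integer(step_minutes / cad)
  tt <- as.numeric(trace$time)
  # index positions on the full ideal grid to detect gaps
  pos <- as.integer(round((tt - tt[1]) / (cad * 60)))
  grid_len <- pos[length(pos)] + 1L
  present <- logical(grid_len)
  present[pos + 1L] <- TRUE
  vals <- rep(NA_real_, grid_len)
  vals[pos + 1L] <- trace$glucose

  starts <- if (grid_len < n_per) integer(0) else
    seq(1L, grid_len - n_per + 1L, by = step)
  mat <- matrix(NA_real_, length(starts), n_per)
  for (j in seq_len(n_per)) mat[, j] <- vals[starts + j - 1L]
  ok <- !apply(mat, 1L, anyNA)
  mat <- mat[ok, , drop = FALSE]
  starts <- starts[ok]
  if (!length(starts)) {
    out <- data.frame(participant_id = character(), week = character(),
                      start_time = as.POSIXct(character(), tz = "UTC"),
                      mean = numeric(), sd = numeric(), range = numeric(),
                      max_rate = numeric())
    attr(out, "values") <- matrix(numeric(), 0, n_per)
    return(out)
  }
  steps <- abs(mat[, -1L, drop = FALSE] - mat[, -n_per, drop = FALSE])
  out <- data.frame(
    participant_id = trace$participant_id, week = trace$week,
    start_time = as.POSIXct(tt[1] + (starts - 1L) * cad * 60,
                            origin = "1970-01-01", tz = "UTC"),
    mean = rowMeans(mat),
    sd = apply(mat, 1L, stats::sd),
    range = apply(mat, 1L, max) - apply(mat, 1L, min),
    max_rate = apply(steps, 1L, max) / (cad / 60),
    stringsAsFactors = FALSE)
  attr(out, "values") <- mat
  out
}

# internal: spectral clustering (Ng-Jordan-Weiss) on a feature matrix.
# RBF affinity with bandwidth = median pairwise distance, normalized
# Laplacian, k leading eigenvectors row-normalized, k-means.
spectral_cluster <- function(x, k, seed) {
  d <- as.matrix(stats::dist(x))
  sigma <- stats::median(d[upper.tri(d)][d[upper.tri(d)] > 0])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  # self-affinity stays exp(0) = 1: duplicate points then have identical
  # affinity rows, hence identical spectral embeddings
  w <- exp(-d^2 / (2 * sigma^2))
  dg <- pmax(rowSums(w), .Machine$double.eps)
  s <- w / sqrt(outer(dg, dg))           # D^{-1/2} W D^{-1/2}
  ev <- eigen(s, symmetric = TRUE)
  u <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(u^2))
  u <- u / ifelse(nrm > 0, nrm, 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  km <- stats::kmeans(u, centers = k, nstart = 25, iter.max = 100)
  km$cluster
}

#' Fit a three-class glucotype model
#'
#' Spectral clustering of standardized window features (mean, sd, range,
#' max_rate) into k = 3 clusters, relabeled low < moderate < severe by
#' ascending centroid window-SD. The training pool is normally all windows of
#' all participants in a run (self-trained).
#'
#' @param windows Data frame from [window_trace] (rows from several traces
#'   may be `rbind`-ed; at least 30 windows, at least 3 distinct feature
#'   vectors).
#' @param seed Integer seed making the k-means step deterministic.
#' @param max_train Cap on the spectral training-pool size (the dense
#'   affinity eigendecomposition is quadratic in it). Larger pools are
#'   thinned by a deterministic even stride before clustering; every window
#'   is still assigned by nearest centroid afterwards.
#' @return Object of class `glucotype_model`: feature centering/scaling,
#'   per-class centroids in standardized feature space, severity order, seed.
#' @export
fit_glucotypes <- function(windows, seed = 1L, max_train = 1200L) {
  feat <- as.matrix(windows[, c("mean", "sd", "range", "max_rate")])
  if (nrow(feat) < 30L) stop("need at least 30 windows to fit glucotypes")
  if (nrow(unique(feat)) < 3L) stop("fewer than 3 distinct feature vectors")
  center <- colMeans(feat)
  scale <- apply(feat, 2, stats::sd)
  # a feature whose spread is numerical dust (< 1e-8 mg/dL) carries no
  # information; leave it unscaled rather than amplify rounding noise
  scale[scale < 1e-8] <- 1
  z <- sweep(sweep(feat, 2, center), 2, scale, "/")
  train <- seq_len(nrow(z))
  if (length(train) > max_train)
    train <- unique(as.integer(round(seq(1L, nrow(z), length.out = max_train))))
  z <- z[train, , drop = FALSE]
  cl <- spectral_cluster(z, k = 3L, seed = seed)
  cent <- t(vapply(1:3, function(k) colMeans(z[cl == k, , drop = FALSE]),
                   numeric(ncol(z))))
  ord <- order(cent[, "sd"])               # severity = ascending window SD
  cent <- cent[ord, , drop = FALSE]
  rownames(cent) <- c("low", "moderate", "severe")
  structure(list(center = center, scale = scale, centroids = cent,
                 assignments = match(cl, ord), n_windows = nrow(feat),
                 n_train = nrow(z), seed = seed),
            class = "glucotype_model")
}

#' @export
print.glucotype_model <- function(x, ...) {
  cat(sprintf("<glucotype_model> 3 classes fit on %d windows (seed %d)\n",
              x$n_windows, x$seed))
  cat("standardized centroids (ordered by window SD):\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' Glucotype time fractions for one participant-week
#'
#' Each window is assigned to the nearest model centroid in standardized
#' feature space; fractions are window counts over the total and sum to 1.
#'
#' @param model A [fit_glucotypes] model.
#' @param windows Data frame from [window_trace] for one participant-week.
#' @return Named numeric vector `c(low=, moderate=, severe=)`.
#' @export
classify_fractions <- function(model, windows) {
  stopifnot(inherits(model, "glucotype_model"))
  if (nrow(windows) == 0L) stop("no windows to classify")
  feat <- as.matrix(windows[, c("mean", "sd", "range", "max_rate")])
  z <- sweep(sweep(feat, 2, model$center), 2, model$scale, "/")
  d2 <- vapply(1:3, function(k)
    rowSums(sweep(z, 2, model$centroids[k, ])^2), numeric(nrow(z)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
  cls <- max.col(-d2, ties.method = "first")
  out <- tabulate(cls, 3) / nrow(z)
  names(out) <- rownames(model$centroids)
  out
}
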