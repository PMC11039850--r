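# Independent brute-force oracles: naive loops written straight from the
# metric definitions, sharing no code with the package internals.

K_ORACLE <- 18.016

o_mean <- function(g) sum(g) / length(g)

o_sd <- function(g) {
  m <- o_mean(g)
  sqrt(sum((g - m)^2) / (length(g) - 1))
}

# nearest reading to a target time, NA if beyond tol (seconds); linear scan
o_nearest <- function(tt, target, tol) {
  best <- NA_integer_; bestd <- Inf
  for (j in seq_along(tt)) {
    d <- abs(tt[j] - target)
    if (d < bestd) { bestd <- d; best <- j }
  }
  if (bestd <= tol) best else NA_integer_
}

o_conga <- function(tt, g, lag_min, cad_min) {
  d <- c()
  for (i in seq_along(tt)) {
    j <- o_nearest(tt, tt[i] - lag_min * 60, cad_min * 60 / 2)
    if (!is.na(j)) d <- c(d, g[i] - g[j])
  }
  if (length(d) < 2) return(NA_real_)
  o_sd(d) / K_ORACLE
}

o_li <- function(tt, g, interval_min, cad_min) {
  grid <- seq(tt[1], tt[length(tt)], by = interval_min * 60)
  idx <- c()
  for (tg in grid) {
    j <- o_nearest(tt, tg, cad_min * 60 / 2)
    if (!is.na(j) && !(j %in% idx)) idx <- c(idx, j)
  }
  if (length(idx) < 2) return(NA_real_)
  s <- 0
  for (k in seq_len(length(idx) - 1)) {
    g1 <- g[idx[k]] / K_ORACLE; g2 <- g[idx[k + 1]] / K_ORACLE
    dt_h <- (tt[idx[k + 1]] - tt[idx[k]]) / 3600
    s <- s + (g2 - g1)^2 / dt_h
  }
  days <- max(1, (tt[length(tt)] - tt[1]) / 86400)
  s / days
}

o_risk <- function(g) {
  f <- 1.509 * (log(g)^1.084 - 5.381)
  c(rl = if (f < 0) 10 * f^2 else 0, rh = if (f > 0) 10 * f^2 else 0)
}

o_bgi <- function(g) {
  rl <- 0; rh <- 0
  for (x in g) { r <- o_risk(x); rl <- rl + r["rl"]; rh <- rh + r["rh"] }
  c(lbgi = unname(rl) / length(g), hbgi = unname(rh) / length(g))
}

o_adrr <- function(times_posix, g, min_per_day = 12) {
  dates <- as.Date(times_posix, tz = "UTC")
  daily <- c()
  for (d in unique(dates)) {
    gi <- g[dates == d]
    if (length(gi) < min_per_day) next
    lr <- 0; hr <- 0
    for (x in gi) { r <- o_risk(x); lr <- max(lr, r["rl"]); hr <- max(hr, r["rh"]) }
    daily <- c(daily, lr + hr)
  }
  if (!length(daily)) return(NA_real_)
  o_mean(daily)
}

o_grade <- function(g, cap = 50) {
  hs <- c()
  for (x in g) {
    gm <- x / K_ORACLE
    if (gm <= 1) next
    hs <- c(hs, min(cap, 425 * (log10(log10(gm)) + 0.16)^2))
  }
  o_mean(hs)
}

o_mage <- function(g) {
  s <- o_sd(g)
  gc <- g[1]
  for (x in g[-1]) if (x != gc[length(gc)]) gc <- c(gc, x)
  tp <- c()
  if (length(gc) >= 3)
    for (i in 2:(length(gc) - 1))
      if ((gc[i] > gc[i - 1] && gc[i] > gc[i + 1]) ||
          (gc[i] < gc[i - 1] && gc[i] < gc[i + 1]))
        tp <- c(tp, gc[i])
  if (length(tp) < 2) return(0)
  amps <- abs(diff(tp))
  amps <- amps[amps > s]
  if (!length(amps)) return(0)
  o_mean(amps) / K_ORACLE
}

o_modd <- function(tt, g, cad_min) {
  d <- c()
  for (i in seq_along(tt)) {
    j <- o_nearest(tt, tt[i] + 24 * 3600, cad_min * 60 / 2)
    if (!is.na(j)) d <- c(d, abs(g[j] - g[i]))
  }
  if (!length(d)) return(NA_real_)
  o_mean(d) / K_ORACLE
}

o_m_value <- function(g, ref = 120) o_mean(abs(10 * log10(g / ref))^3)

# Pearson r and two-sided p from the covariance definition and the
# t-distribution, no cor()/cor.test()
o_pearson <- function(x, y) {
  n <- length(x)
  mx <- o_mean(x); my <- o_mean(y)
  r <- sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# OLS with intercept by explicit normal equations, coefficient t-tests and
# adjusted R^2 from the closed forms
o_ols <- function(y, x1, x2) {
  X <- cbind(1, x1, x2)
  n <- nrow(X); p <- ncol(X)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(xtx_inv) * sigma2)
  tstat <- beta / se
  pvals <- 2 * stats::pt(-abs(tstat), n - p)
  r2 <- 1 - sum(res^2) / sum((y - o_mean(y))^2)
  list(beta = as.numeric(beta), p = as.numeric(pvals),
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p))
}
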