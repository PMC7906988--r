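#' Lap-to-lap variance-mean relation
#'
#' For each spatial bin, the mean and unbiased variance of the per-lap
#' activity rate across the complete laps that visited the bin. Bins visited
#' in fewer than two laps are dropped (variance undefined).
#'
#' @param lapmat A [per_lap_maps()] result.
#' @param complete_only Use complete laps only (default).
#' @return Data frame with `bin`, `mean`, `var`, `n_laps`.
#' @export
variance_mean_relation <- function(lapmat, complete_only = TRUE) {
  rate <- lapmat$rate
  if (complete_only) rate <- rate[lapmat$complete, , drop = FALSE]
  if (nrow(rate) < 2L)
    stop("variance-mean relation requires >= 2 complete laps", call. = FALSE)
  n_laps <- colSums(!is.na(rate))
  mu <- colMeans(rate, na.rm = TRUE)
  va <- apply(rate, 2, stats::var, na.rm = TRUE)
  keep <- n_laps >= 2L
  data.frame(bin = which(keep), mean = mu[keep], var = va[keep],
             n_laps = n_laps[keep])
}

#' Total-least-squares power-law fit
#'
#' Fits y = a x^beta by total least squares in (log mean, log variance)
#' space: beta is the slope of the first principal direction of the centered
#' log-log scatter and a = exp of the intercept. Points with non-positive
#' mean or variance are excluded before the log transform.
#'
#' @param points Data frame with `mean` and `var` (e.g. from
#'   [variance_mean_relation()]), or two numeric vectors via `mean`/`var`
#'   columns.
#' @return Object of class `power_law_fit` with `a`, `beta`, `n_points` and
#'   `residual` (root-mean-square orthogonal distance in log space).
#' @export
fit_power_law_tls <- function(points) {
  x <- log(points$mean)
  y <- log(points$var)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    stop("fit error: need >= 3 positive (mean, var) points", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  S <- cbind(c(sum(xc^2), sum(xc * yc)), c(sum(xc * yc), sum(yc^2))) / (n - 1)
  if (S[1, 1] <= 0 || sum(diag(S)) <= 0)
    stop("fit error: zero spread in log space", call. = FALSE)
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (abs(v[1]) < 1e-14)
    stop("fit error: degenerate (vertical) principal direction", call. = FALSE)
  beta <- v[2] / v[1]
  intercept <- mean(y) - beta * mean(x)
  resid <- sqrt(mean((yc - beta * xc)^2) / (1 + beta^2))
  structure(list(a = exp(intercept), beta = beta, n_points = n,
                 residual = resid),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> var = %.3g * mean^%.3f (n = %d, resid %.3g)\n",
              x$a, x$beta, x$n_points, x$residual))
  invisible(x)
}

#' Per-cell variance-mean exponents for a session
#'
#' Convenience wrapper: per-lap maps, variance-mean relation and TLS fit for
#' each requested cell.
#'
#' @param session Circular-track [aligned_session()].
#' @param cells Cell indices.
#' @return Data frame with `cell`, `a`, `beta`, `n_points`; cells whose fit
#'   is undefined yield `NA`.
#' @export
reliability_exponents <- function(session, cells = seq_len(session$n_cells)) {
  rows <- lapply(cells, function(j) {
    fit <- tryCatch({
      lm <- per_lap_maps(session, j)
      fit_power_law_tls(variance_mean_relation(lm))
    }, error = function(e) NULL)
    if (is.null(fit))
      data.frame(cell = j, a = NA_real_, beta = NA_real_, n_points = 0L)
    else
      data.frame(cell = j, a = fit$a, beta = fit$beta,
                 n_points = fit$n_points)
  })
  do.call(rbind, rows)
}

#' Activity and event-rate summaries
#'
#' Per-cell event rate (events/s) and activity rate (dF/F per s) over moving
#' frames, with group summaries: mean with standard error for event rates,
#' and for the (approximately log-normal) activity rates the mean of the
#' log-normal model with its 90% confidence interval by Cox's method
#' (exp(m + s^2/2) with CI m + s^2/2 +/- z sqrt(s^2/n + s^4/(2(n-1))) on the
#' log scale, over cells with positive activity).
#'
#' @param session An [aligned_session()].
#' @param groups Optional factor/character per cell (e.g. place vs non-place)
#'   used to split the summaries.
#' @param conf_level Confidence level for the activity-rate interval.
#' @return Object of class `rate_summary`: `cells` (per-cell data frame) and
#'   `groups` (per-group summary data frame).
#' @export
rate_summary <- function(session, groups = NULL, conf_level = 0.90) {
  mov <- session$moving
  t_mov <- sum(mov) / session$frame_rate_hz
  if (t_mov <= 0) stop("no moving time in session", call. = FALSE)
  A <- session$activity[mov, , drop = FALSE]
  event_rate <- colSums(A > 0) / t_mov
  activity_rate <- colSums(A) / t_mov
  cells <- data.frame(cell = seq_len(ncol(A)),
                      event_rate = event_rate,
                      activity_rate = activity_rate)
  if (is.null(groups)) groups <- rep("all", ncol(A))
  cells$group <- as.character(groups)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  summ <- lapply(split(cells, cells$group), function(d) {
    n <- nrow(d)
    er_mean <- mean(d$event_rate)
    er_sem <- stats::sd(d$event_rate) / sqrt(n)
    pos <- d$activity_rate[d$activity_rate > 0]
    ar <- if (length(pos) >= 2L) cox_lognormal_ci(pos, z)
          else c(NA_real_, NA_real_, NA_real_)
    data.frame(group = d$group[1], n = n,
               event_rate_mean = er_mean, event_rate_sem = er_sem,
               activity_rate_mean = ar[1],
               activity_rate_ci_lo = ar[2], activity_rate_ci_hi = ar[3])
  })
  structure(list(cells = cells, groups = do.call(rbind, summ),
                 conf_level = conf_level),
            class = "rate_summary")
}

# Cox's interval for the mean of a log-normal sample: point estimate
# exp(m + s^2/2), limits exp(m + s^2/2 -/+ z sqrt(s^2/n + s^4/(2(n-1)))).
# Returns c(mean, lower, upper).
cox_lognormal_ci <- function(x, z) {
  lx <- log(x)
  m <- mean(lx); s2 <- stats::var(lx); k <- length(lx)
  center <- m + s2 / 2
  half <- z * sqrt(s2 / k + s2^2 / (2 * (k - 1)))
  exp(c(center, center - half, center + half))
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("<rate_summary>\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}
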