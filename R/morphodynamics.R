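#' Fit a polynomial to a mean-eccentricity time course
#'
#' Ordinary least squares on the mean-over-wells eccentricity against time
#' rescaled to `[0, 1]` over the fitted window (the rescaling makes the fit
#' equivariant under affine changes of the time axis and keeps the normal
#' equations well conditioned).
#'
#' @param trace data.frame with columns `time_min`, `well`,
#'   `mean_eccentricity` (and optionally `line`); missing values are dropped.
#' @param degree polynomial degree (default 6; >= 4 so that three interior
#'   turning points are representable).
#' @param window length-2 numeric restricting the fitted time range (minutes);
#'   `NULL` fits all observed times.
#' @return Object of class `poly_fit`: degree, `coefficients` (ascending
#'   powers of scaled time), time-scaling constants `t0`/`t1`, the fitted
#'   grid, and residual RMSE.
#' @export
fit_polynomial <- function(trace, degree = 6L, window = NULL) {
  stopifnot(all(c("time_min", "mean_eccentricity") %in% names(trace)),
            degree >= 4L)
  agg <- stats::aggregate(mean_eccentricity ~ time_min, trace, mean,
                          na.rm = TRUE, na.action = stats::na.pass)
  agg <- agg[is.finite(agg$mean_eccentricity), ]
  if (!is.null(window))
    agg <- agg[agg$time_min >= window[1] & agg$time_min <= window[2], ]
  t <- agg$time_min; y <- agg$mean_eccentricity
  if (length(unique(t)) < degree + 1L)
    stop("fit_polynomial: need at least degree + 1 distinct time points (",
         degree + 1L, "), got ", length(unique(t)))
  t0 <- min(t); t1 <- max(t)
  s <- (t - t0) / (t1 - t0)
  X <- outer(s, 0:degree, "^")
  qrx <- qr(X)
  if (qrx$rank < degree + 1L)
    stop("fit_polynomial: rank-deficient design (too few distinct times)")
  cf <- qr.coef(qrx, y)
  fitted <- drop(X %*% cf)
  structure(list(degree = as.integer(degree), coefficients = unname(cf),
                 t0 = t0, t1 = t1, time_min = t, observed = y,
                 fitted = fitted,
                 rmse = sqrt(mean((y - fitted)^2)),
                 line = if ("line" %in% names(trace))
                   as.character(trace$line[1]) else NA_character_),
            class = "poly_fit")
}

#' Evaluate a fitted polynomial trajectory
#' @param object a `poly_fit`.
#' @param newdata times in minutes (default: the fitted grid).
#' @param ... unused.
#' @return Fitted eccentricities.
#' @export
predict.poly_fit <- function(object, newdata = object$time_min, ...) {
  s <- (newdata - object$t0) / (object$t1 - object$t0)
  drop(outer(s, 0:object$degree, "^") %*% object$coefficients)
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("poly_fit: degree %d over [%g, %g] min (%d points, RMSE %.2g)\n",
              x$degree, x$t0, x$t1, length(x$time_min), x$rmse))
  tp <- turning_points(x)
  if (nrow(tp)) {
    cat("turning points:\n")
    print(tp, row.names = FALSE)
  } else cat("no interior turning points\n")
  invisible(x)
}

#' Turning points of a fitted trajectory
#'
#' Real roots of the fitted derivative inside `window` at which the derivative
#' changes sign, classified as maxima or minima by the second-derivative sign
#' (with a first-derivative sign-change fallback when the second derivative
#' vanishes), returned sorted in time.
#'
#' @param fit a [fit_polynomial()] result.
#' @param window length-2 time window in minutes (default: the fitted range).
#' @return data.frame with `time_min` and `type` (`"max"`/`"min"`); zero rows
#'   when the fit is monotone in the window.
#' @export
turning_points <- function(fit, window = c(fit$t0, fit$t1)) {
  stopifnot(inherits(fit, "poly_fit"), length(window) == 2L)
  cf <- fit$coefficients
  scale <- max(abs(cf), 1e-300)
  dcf <- cf[-1] * seq_len(fit$degree)
  while (length(dcf) > 1 && abs(dcf[length(dcf)]) <= 1e-11 * scale)
    dcf <- dcf[-length(dcf)]
  # constant (or numerically zero) derivative: no interior turning points
  if (length(dcf) <= 1 || all(abs(dcf) <= 1e-11 * scale))
    return(data.frame(time_min = numeric(), type = character()))
  r <- polyroot(dcf)
  r <- Re(r[abs(Im(r)) < 1e-7 * pmax(1, Mod(r))])
  span <- fit$t1 - fit$t0
  tmin <- sort(unique(r)) * span + fit$t0
  tmin <- tmin[tmin > max(window[1], fit$t0) & tmin < min(window[2], fit$t1)]
  if (!length(tmin))
    return(data.frame(time_min = numeric(), type = character()))
  d2cf <- dcf[-1] * seq_len(length(dcf) - 1)
  evalp <- function(co, s) drop(outer(s, seq_along(co) - 1, "^") %*% co)
  s <- (tmin - fit$t0) / span
  d2 <- if (length(d2cf)) evalp(d2cf, s) else rep(0, length(s))
  eps <- 1e-6
  d1l <- evalp(dcf, s - eps); d1r <- evalp(dcf, s + eps)
  type <- ifelse(d2 < -1e-10, "max",
          ifelse(d2 > 1e-10, "min",
          ifelse(d1l > 0 & d1r < 0, "max",
          ifelse(d1l < 0 & d1r > 0, "min", NA_character_))))
  keep <- !is.na(type) & (sign(d1l) != sign(d1r))
  data.frame(time_min = tmin[keep], type = type[keep])
}

# Newton solve of trigamma(x) = y, as used for the method-of-moments prior
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

# method-of-moments fit of the scaled-inverse-chi-square variance prior:
# log s^2 is matched to the moments of log(s0^2 * F(d, d0)); returns the
# prior df d0 (possibly Inf) and prior variance s0^2
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2L) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes differential eccentricity between two cell lines
#'
#' Per time point, the two lines' replicate wells are compared with a
#' two-sample t-statistic whose pooled residual variance is moderated by
#' empirical-Bayes shrinkage: the per-time-point variances `s_t^2` (residual
#' df `d = nA + nB - 2`) are shrunk towards a prior variance `s0^2` with prior
#' df `d0`, both estimated across time points by the method of moments on
#' `log s_t^2`. The moderated variance is `(d0 s0^2 + d s_t^2) / (d0 + d)`
#' and the moderated t is referred to a t distribution on `d0 + d` df.
#' Both raw and Benjamini-Hochberg adjusted two-sided p-values are reported.
#'
#' @param trace_a,trace_b long data.frames (`time_min`, `well`,
#'   `mean_eccentricity`) for the two lines, on a common time grid.
#' @param prior optional fixed prior, a list with `d0` and `s02`, bypassing
#'   estimation (useful for studying limits; `d0 = Inf` reduces the moderated
#'   t to the ordinary pooled t computed with the common variance `s02`).
#' @return Object of class `diff_ecc`: a `table` data.frame (time_min,
#'   mean_diff, s2_pooled, df, s2_moderated, t_moderated, p_value, p_bh,
#'   skipped) and the estimated prior (`d0`, `s02`). Time points with fewer
#'   than two wells in either line are skipped and flagged.
#' @export
eb_differential <- function(trace_a, trace_b, prior = NULL) {
  need <- c("time_min", "well", "mean_eccentricity")
  stopifnot(all(need %in% names(trace_a)), all(need %in% names(trace_b)))
  grid_a <- sort(unique(trace_a$time_min))
  grid_b <- sort(unique(trace_b$time_min))
  if (!identical(grid_a, grid_b))
    stop("eb_differential: the two traces must share a common time grid")
  stat1 <- function(tr) {
    v <- tr$mean_eccentricity[is.finite(tr$mean_eccentricity)]
    c(n = length(v), m = mean(v), ss = sum((v - mean(v))^2))
  }
  sa <- vapply(split(trace_a, trace_a$time_min), stat1, numeric(3))
  sb <- vapply(split(trace_b, trace_b$time_min), stat1, numeric(3))
  tm <- as.numeric(colnames(sa))
  o <- order(tm); sa <- sa[, o, drop = FALSE]; sb <- sb[, o, drop = FALSE]
  tm <- tm[o]
  nA <- sa["n", ]; nB <- sb["n", ]
  skipped <- nA < 2 | nB < 2
  d <- nA + nB - 2
  diff <- sa["m", ] - sb["m", ]
  s2 <- (sa["ss", ] + sb["ss", ]) / d
  s2[skipped] <- NA_real_
  if (is.null(prior))
    prior <- fit_variance_prior(s2[!skipped & s2 > 0], d[!skipped & s2 > 0])
  stopifnot(is.list(prior), all(c("d0", "s02") %in% names(prior)))
  s2mod <- if (is.infinite(prior$d0)) rep(prior$s02, length(s2))
           else (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
  s2mod[skipped] <- NA_real_
  se <- sqrt(s2mod * (1 / nA + 1 / nB))
  tstat <- ifelse(diff == 0, 0, diff / se)
  dftot <- prior$d0 + d
  p <- 2 * stats::pt(abs(tstat), df = dftot, lower.tail = FALSE)
  p[skipped] <- NA_real_
  tstat[skipped] <- NA_real_
  pbh <- rep(NA_real_, length(p))
  pbh[!skipped] <- stats::p.adjust(p[!skipped], method = "BH")
  structure(list(
    table = data.frame(time_min = tm, mean_diff = diff, s2_pooled = s2,
                       df = d, s2_moderated = s2mod, t_moderated = tstat,
                       p_value = p, p_bh = pbh, skipped = skipped,
                       row.names = NULL),
    d0 = prior$d0, s02 = prior$s02), class = "diff_ecc")
}

#' @export
print.diff_ecc <- function(x, ...) {
  nt <- sum(!x$table$skipped)
  cat(sprintf(
    "diff_ecc: %d time points tested (prior df %.3g, prior var %.3g)\n",
    nt, x$d0, x$s02))
  cat(sprintf("  raw p < 0.05: %d;  BH p < 0.05: %d\n",
              sum(x$table$p_value < 0.05, na.rm = TRUE),
              sum(x$table$p_bh < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Select nodal time points from two fitted trajectories
#'
#' The sorted union of both lines' windowed turning points plus the start and
#' end times; values closer than `tol` minutes are merged keeping the earlier
#' one. These are the times at which transcriptomes are sampled.
#'
#' @param fit_a,fit_b [fit_polynomial()] results, or numeric vectors of
#'   turning times (minutes).
#' @param t_start,t_end endpoints (minutes).
#' @param window window passed to [turning_points()] when fits are given
#'   (default `c(t_start, t_end)`).
#' @param tol merge tolerance in minutes (default 5).
#' @return Sorted numeric vector of nodal times.
#' @export
select_nodal_timepoints <- function(fit_a, fit_b, t_start, t_end,
                                    window = c(t_start, t_end), tol = 5) {
  get_tp <- function(x) {
    if (inherits(x, "poly_fit")) turning_points(x, window)$time_min
    else as.numeric(x)
  }
  times <- sort(c(t_start, get_tp(fit_a), get_tp(fit_b), t_end))
  out <- times[1]
  for (t in times[-1]) if (t - out[length(out)] > tol) out <- c(out, t)
  out
}

#' Read an eccentricity trace CSV
#'
#' Expected columns: `time_min`, `well`, `line`, `mean_eccentricity`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_traces <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "well", "line", "mean_eccentricity")
  if (!all(need %in% names(tr)))
    stop("read_traces: missing columns: ",
         paste(setdiff(need, names(tr)), collapse = ", "))
  tr
}
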