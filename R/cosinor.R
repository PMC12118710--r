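#' Fit a single-component cosinor model
#'
#' Least-squares fit of a fixed-period cosine to a time series sampled at
#' zeitgeber times `t`:
#' \deqn{y = M + \beta_s \sin(2\pi t/\tau) + \beta_c \cos(2\pi t/\tau) + \epsilon}
#' The rhythm parameters are the mesor \eqn{M} (baseline), the amplitude
#' \eqn{A = \sqrt{\beta_s^2 + \beta_c^2}} (half the peak-to-trough span)
#' and the acrophase \eqn{\phi = (\tau/2\pi)\,\mathrm{atan2}(\beta_s,
#' \beta_c) \bmod \tau} (clock time of the fitted peak). Rhythmicity is
#' tested by the F-test of the two harmonic terms against the
#' intercept-only model.
#'
#' @param y numeric response (abundance, typically on a log scale).
#' @param t zeitgeber times in hours; replicates at a time point enter as
#'   independent observations.
#' @param period fixed period in hours (default 24).
#' @return an object of class `cosinor` with components `mesor`,
#'   `amplitude`, `acrophase`, `p_rhythm`, `r2`, `residual_df`,
#'   `coefficients` (intercept, sin, cos), `vcov`, `sigma2`, `fitted`,
#'   `residuals`, `y`, `t`, `period`, and `perfect_fit` (TRUE when the
#'   harmonic fit is exact so the F statistic is unbounded).
#' @examples
#' t <- rep(c(2, 6, 10, 14, 18, 22), each = 3)
#' y <- 3 + 2 * cos(2 * pi * (t - 8) / 24) + rnorm(length(t), sd = 0.3)
#' fit <- fit_cosinor(y, t)
#' coef(fit)
#' @export
fit_cosinor <- function(y, t, period = 24) {
  if (length(y) != length(t)) stop("'y' and 't' lengths differ", call. = FALSE)
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  if (length(y) < 4) stop("need at least 4 finite observations", call. = FALSE)
  if (length(unique(t %% period)) < 2)
    stop("degenerate design: all observations at a single time", call. = FALSE)
  w <- 2 * pi / period
  X <- cbind(`(Intercept)` = 1, sin = sin(w * t), cos = cos(w * t))
  fit <- lm.fit(X, y)
  b <- fit$coefficients
  res <- fit$residuals
  df <- length(y) - fit$rank
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- if (df > 0) rss / df else NA_real_

  amplitude <- sqrt(b["sin"]^2 + b["cos"]^2)
  acrophase <- wrap_phase((period / (2 * pi)) * atan2(b["sin"], b["cos"]), period)

  perfect <- FALSE
  if (df > 0 && tss > 0) {
    if (rss <= tss * 1e-12 && tss - rss > 0) {
      p_rhythm <- .Machine$double.xmin
      perfect <- TRUE
    } else {
      f <- ((tss - rss) / 2) / (rss / df)
      p_rhythm <- pf(f, 2, df, lower.tail = FALSE)
    }
  } else {
    p_rhythm <- 1
  }
  if (tss == 0) p_rhythm <- 1                       # constant series
  r2 <- if (tss > 0) 1 - rss / tss else 0

  vc <- if (df > 0 && is.finite(sigma2)) {
    XtXi <- chol2inv(chol(crossprod(X)))
    dimnames(XtXi) <- list(colnames(X), colnames(X))
    sigma2 * XtXi
  } else NULL

  structure(list(
    mesor = unname(b["(Intercept)"]),
    amplitude = unname(amplitude),
    acrophase = unname(acrophase),
    p_rhythm = unname(p_rhythm),
    r2 = r2,
    residual_df = df,
    coefficients = b,
    vcov = vc,
    sigma2 = sigma2,
    fitted = fit$fitted.values,
    residuals = res,
    y = y, t = t, period = period,
    perfect_fit = perfect
  ), class = "cosinor")
}

#' @export
print.cosinor <- function(x, digits = 4, ...) {
  cat(sprintf("cosinor fit (period %g h, n = %d)\n", x$period, length(x$y)))
  cat(sprintf("  mesor %.4g  amplitude %.4g  acrophase %.4g h\n",
              x$mesor, x$amplitude, x$acrophase))
  cat(sprintf("  rhythmicity p = %.3g (F-test, df 2/%d), R^2 = %.3f\n",
              x$p_rhythm, x$residual_df, x$r2))
  invisible(x)
}

#' @export
coef.cosinor <- function(object, ...) {
  c(mesor = object$mesor, amplitude = object$amplitude,
    acrophase = object$acrophase)
}

#' @export
fitted.cosinor <- function(object, ...) object$fitted

#' @export
residuals.cosinor <- function(object, ...) object$residuals

#' @export
predict.cosinor <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$t
       else if (is.list(newdata)) newdata$t else newdata
  object$mesor + object$amplitude *
    cos(2 * pi * (t - object$acrophase) / object$period)
}

#' @export
summary.cosinor <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else rep(NA_real_, 3)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se)
  structure(list(coefficients = tab, fit = object), class = "summary.cosinor")
}

#' @export
print.summary.cosinor <- function(x, ...) {
  print(x$fit)
  cat("\nlinear coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
plot.cosinor <- function(x, ...) {
  plot(x$t, x$y, xlab = "zeitgeber time (h)", ylab = "abundance",
       xlim = c(0, x$period), ...)
  tt <- seq(0, x$period, length.out = 200)
  lines(tt, predict(x, tt), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Simulate responses from a fitted cosinor model
#'
#' Draws Gaussian noise at the fitted residual variance around the fitted
#' curve, at the original sampling times.
#'
#' @param object a `cosinor` fit.
#' @param nsim number of response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.cosinor <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$t)
  sd <- sqrt(max(object$sigma2, 0))
  out <- as.data.frame(replicate(nsim, predict(object) + rnorm(n, 0, sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
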