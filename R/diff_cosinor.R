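#' Compare rhythm parameters between two groups for one feature
#'
#' Joint nonlinear least-squares fit of a two-group cosinor with a group
#' indicator \eqn{G \in \{0, 1\}}:
#' \deqn{y = (M + \Delta M\,G) + (A + \Delta A\,G)\,
#'       \cos\!\big(2\pi\,(t - (\phi + \Delta\phi\,G))/\tau\big) + \epsilon}
#' so that \eqn{\Delta M}, \eqn{\Delta A} and \eqn{\Delta\phi} are the
#' between-group differences in mesor, amplitude and acrophase
#' (group 2 minus group 1; positive \eqn{\Delta\phi} means group 2 peaks
#' later). The fit is initialised from per-group linear cosinor fits and
#' Wald tests on the three contrasts use the asymptotic covariance of the
#' converged fit. A sine curve is always fitted, whether or not either
#' group passes a rhythmicity threshold; gating against rhythmicity calls
#' happens in [compare_rhythms()].
#'
#' @param y1,t1 series and zeitgeber times for group 1.
#' @param y2,t2 series and zeitgeber times for group 2.
#' @param period fixed period in hours (default 24).
#' @param fix_dphi if TRUE the phase difference is constrained to zero
#'   (shared acrophase), leaving mesor and amplitude contrasts only.
#' @param max_restarts extra phase-jittered starts tried on non-convergence.
#' @return an object of class `cosinor_diff` with per-group parameters
#'   (`mesor1`, `amplitude1`, `acrophase1`, `mesor2`, ...), contrasts
#'   `delta_mesor`, `delta_amplitude`, `delta_phase` (hours, wrapped to
#'   (-12, 12\]), their standard errors, p-values `p_mesor`, `p_amplitude`,
#'   `p_phase` (NA when the phase is unidentifiable because an amplitude is
#'   ~0), `converged`, `residual_df`.
#' @export
fit_differential_cosinor <- function(y1, t1, y2, t2, period = 24,
                                     fix_dphi = FALSE, max_restarts = 5) {
  f1 <- fit_cosinor(y1, t1, period)
  f2 <- fit_cosinor(y2, t2, period)
  y <- c(y1, y2); t <- c(t1, t2)
  G <- c(rep(0, length(y1)), rep(1, length(y2)))
  dat <- data.frame(y = y, t = t, G = G)

  start0 <- list(M = f1$mesor, dM = f2$mesor - f1$mesor,
                 A = f1$amplitude, dA = f2$amplitude - f1$amplitude,
                 phi = f1$acrophase,
                 dphi = wrap_diff(f2$acrophase - f1$acrophase, period))
  if (fix_dphi) start0$dphi <- NULL
  form <- if (fix_dphi)
    y ~ (M + dM * G) + (A + dA * G) * cos(2 * pi * (t - phi) / period)
  else
    y ~ (M + dM * G) + (A + dA * G) * cos(2 * pi * (t - (phi + dphi * G)) / period)

  # a start exactly at the per-group optimum can trip the Levenberg-
  # Marquardt QR ("singular gradient at initial estimates"); jittered and
  # phase-shifted starts serve as fallbacks
  starts <- list(start0)
  for (k in seq_len(max_restarts)) {
    s <- start0
    s$dM <- s$dM + 1e-3 * k
    s$dA <- s$dA + 1e-3 * k
    s$phi <- wrap_phase(start0$phi + (k - 1) * period / max_restarts, period)
    if (!fix_dphi) s$dphi <- 1e-2 * k
    starts[[k + 1]] <- s
  }
  fit <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }

  res <- list(fit1 = f1, fit2 = f2, period = period, converged = !is.null(fit))
  if (is.null(fit)) {
    # report per-group linear estimates and raw differences, no tests
    res <- c(res, list(
      mesor1 = f1$mesor, amplitude1 = f1$amplitude, acrophase1 = f1$acrophase,
      mesor2 = f2$mesor, amplitude2 = f2$amplitude, acrophase2 = f2$acrophase,
      delta_mesor = f2$mesor - f1$mesor,
      delta_amplitude = f2$amplitude - f1$amplitude,
      delta_phase = if (fix_dphi) 0
                    else wrap_diff(f2$acrophase - f1$acrophase, period),
      se = c(dM = NA_real_, dA = NA_real_, dphi = NA_real_),
      p_mesor = NA_real_, p_amplitude = NA_real_, p_phase = NA_real_,
      residual_df = length(y) - 6L))
    class(res) <- "cosinor_diff"
    return(res)
  }

  cf <- coef(fit)
  # normalize the sign/phase gauge: amplitudes reported non-negative
  norm_group <- function(A, phi) {
    if (A < 0) list(A = -A, phi = wrap_phase(phi + period / 2, period))
    else list(A = A, phi = wrap_phase(phi, period))
  }
  A1 <- cf["A"]; phi1 <- cf["phi"]
  A2 <- cf["A"] + cf[if (fix_dphi) "dA" else "dA"]
  phi2 <- if (fix_dphi) cf["phi"] else cf["phi"] + cf["dphi"]
  g1 <- norm_group(A1, phi1); g2 <- norm_group(A2, phi2)

  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else
    setNames(rep(NA_real_, length(cf)), names(cf))
  df <- length(y) - length(cf)

  wald_p <- function(est, s) {
    if (!is.finite(s)) return(NA_real_)
    if (s == 0) return(if (abs(est) < 1e-12) 1 else .Machine$double.xmin)
    2 * pt(abs(est) / s, df, lower.tail = FALSE)
  }
  amp_small <- min(g1$A, g2$A) < 1e-8
  dphi_est <- if (fix_dphi) 0 else wrap_diff(g2$phi - g1$phi, period)

  res <- c(res, list(
    mesor1 = unname(cf["M"]), amplitude1 = unname(g1$A),
    acrophase1 = unname(g1$phi),
    mesor2 = unname(cf["M"] + cf["dM"]), amplitude2 = unname(g2$A),
    acrophase2 = unname(g2$phi),
    delta_mesor = unname(cf["dM"]),
    delta_amplitude = unname(g2$A - g1$A),
    delta_phase = unname(dphi_est),
    se = c(dM = unname(se["dM"]), dA = unname(se["dA"]),
           dphi = if (fix_dphi) NA_real_ else unname(se["dphi"])),
    p_mesor = unname(wald_p(cf["dM"], se["dM"])),
    p_amplitude = unname(wald_p(cf["dA"], se["dA"])),
    p_phase = if (fix_dphi || amp_small) NA_real_
              else unname(wald_p(cf["dphi"], se["dphi"])),
    residual_df = df,
    nls_fit = fit))
  class(res) <- "cosinor_diff"
  res
}

#' @export
print.cosinor_diff <- function(x, ...) {
  cat(sprintf("two-group cosinor comparison (period %g h)%s\n", x$period,
              if (x$converged) "" else "  [did not converge]"))
  cat(sprintf("  group 1: M %.4g  A %.4g  phi %.4g h\n",
              x$mesor1, x$amplitude1, x$acrophase1))
  cat(sprintf("  group 2: M %.4g  A %.4g  phi %.4g h\n",
              x$mesor2, x$amplitude2, x$acrophase2))
  cat(sprintf("  dM %.4g (p %.3g)  dA %.4g (p %.3g)  dphi %.4g h (p %.3g)\n",
              x$delta_mesor, x$p_mesor, x$delta_amplitude, x$p_amplitude,
              x$delta_phase, x$p_phase))
  invisible(x)
}

#' @export
coef.cosinor_diff <- function(object, ...) {
  c(delta_mesor = object$delta_mesor,
    delta_amplitude = object$delta_amplitude,
    delta_phase = object$delta_phase)
}

#' @export
summary.cosinor_diff <- function(object, ...) {
  tab <- cbind(Estimate = coef(object),
               `Std. Error` = unname(object$se),
               `p value` = c(object$p_mesor, object$p_amplitude,
                             object$p_phase))
  structure(list(coefficients = tab, fit = object), class = "summary.cosinor_diff")
}

#' @export
print.summary.cosinor_diff <- function(x, ...) {
  print(x$fit)
  cat("\ncontrasts:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
predict.cosinor_diff <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- data.frame(
      t = c(object$fit1$t, object$fit2$t),
      G = rep(0:1, c(length(object$fit1$t), length(object$fit2$t))))
  M <- ifelse(newdata$G == 0, object$mesor1, object$mesor2)
  A <- ifelse(newdata$G == 0, object$amplitude1, object$amplitude2)
  phi <- ifelse(newdata$G == 0, object$acrophase1, object$acrophase2)
  M + A * cos(2 * pi * (newdata$t - phi) / object$period)
}

#' Compare rhythms for every eligible feature of a timed matrix
#'
#' Applies [fit_differential_cosinor()] feature-wise, gated by consensus
#' rhythmicity calls: mesor and amplitude contrasts are reported for
#' features rhythmic in at least one group, while the phase contrast is
#' reported only for features rhythmic in both groups ("robustly
#' rhythmic"). Significant contrasts (raw p below `alpha`, no
#' multiple-testing correction by default, mirroring common practice for
#' this comparison; set `adjust = "BH"` to add FDR-adjusted gating) are
#' translated into differential-rhythm classes: `mesor_up`/`mesor_down`,
#' `amp_up`/`amp_down`, `phase_delay`/`phase_advance` (delay = group 2
#' peaks later).
#'
#' @param x a [timed_matrix]; the matrix the calls were computed on.
#' @param calls a `rhythm_calls` table from [detect_rhythms()] with exactly
#'   two groups.
#' @param alpha significance threshold for each contrast (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`; with BH, class assignment
#'   uses the adjusted p-values.
#' @param period period in hours.
#' @param group_order optional character vector of the two group labels,
#'   fixing which is the reference (group 1); defaults to order of
#'   appearance in the sample sheet. Reversing it negates every contrast
#'   and mirrors the up/down and delay/advance classes.
#' @return data.frame of class `diff_rhythm_table`, one row per feature
#'   rhythmic in at least one group.
#' @export
compare_rhythms <- function(x, calls, alpha = 0.05, adjust = c("none", "BH"),
                            period = 24, group_order = NULL) {
  stopifnot(inherits(x, "timed_matrix"))
  adjust <- match.arg(adjust)
  groups <- group_order %||% unique(x$meta$group)
  if (length(groups) != 2 || !all(groups %in% x$meta$group))
    stop("compare_rhythms() needs exactly two groups", call. = FALSE)
  g1 <- groups[1]; g2 <- groups[2]
  c1 <- calls[calls$group == g1, ]
  c2 <- calls[calls$group == g2, ]
  r1 <- setNames(c1$consensus, c1$feature)
  r2 <- setNames(c2$consensus, c2$feature)
  feats <- rownames(x$values)
  eligible <- feats[r1[feats] | r2[feats]]
  eligible <- eligible[!is.na(eligible)]

  sel1 <- x$meta$group == g1; sel2 <- x$meta$group == g2
  t1 <- x$meta$time[sel1]; t2 <- x$meta$time[sel2]

  rows <- lapply(eligible, function(f) {
    fd <- tryCatch(
      fit_differential_cosinor(x$values[f, sel1], t1, x$values[f, sel2], t2,
                               period = period),
      error = function(e) NULL)
    if (is.null(fd))
      return(data.frame(feature = f, mesor1 = NA_real_, amplitude1 = NA_real_,
                        acrophase1 = NA_real_, mesor2 = NA_real_,
                        amplitude2 = NA_real_, acrophase2 = NA_real_,
                        delta_mesor = NA_real_, delta_amplitude = NA_real_,
                        delta_phase = NA_real_, p_mesor = NA_real_,
                        p_amplitude = NA_real_, p_phase = NA_real_,
                        rhythmic_g1 = unname(r1[f]), rhythmic_g2 = unname(r2[f]),
                        converged = FALSE, stringsAsFactors = FALSE))
    both <- isTRUE(r1[f]) && isTRUE(r2[f])
    data.frame(feature = f,
               mesor1 = fd$mesor1, amplitude1 = fd$amplitude1,
               acrophase1 = fd$acrophase1,
               mesor2 = fd$mesor2, amplitude2 = fd$amplitude2,
               acrophase2 = fd$acrophase2,
               delta_mesor = fd$delta_mesor,
               delta_amplitude = fd$delta_amplitude,
               delta_phase = if (both) fd$delta_phase else NA_real_,
               p_mesor = fd$p_mesor, p_amplitude = fd$p_amplitude,
               p_phase = if (both) fd$p_phase else NA_real_,
               rhythmic_g1 = unname(r1[f]), rhythmic_g2 = unname(r2[f]),
               converged = fd$converged, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(0), mesor1 = numeric(0),
               amplitude1 = numeric(0), acrophase1 = numeric(0),
               mesor2 = numeric(0), amplitude2 = numeric(0),
               acrophase2 = numeric(0), delta_mesor = numeric(0),
               delta_amplitude = numeric(0), delta_phase = numeric(0),
               p_mesor = numeric(0), p_amplitude = numeric(0),
               p_phase = numeric(0), rhythmic_g1 = logical(0),
               rhythmic_g2 = logical(0), converged = logical(0),
               stringsAsFactors = FALSE)

  pm <- out$p_mesor; pa <- out$p_amplitude; pp <- out$p_phase
  if (adjust == "BH") {
    pm <- p.adjust(pm, "BH"); pa <- p.adjust(pa, "BH"); pp <- p.adjust(pp, "BH")
  }
  cls <- character(nrow(out))
  add <- function(cls, hit, label) ifelse(hit & !is.na(hit),
                                          paste0(cls, ifelse(nzchar(cls), "+", ""), label), cls)
  cls <- add(cls, pm < alpha & out$delta_mesor > 0, "mesor_up")
  cls <- add(cls, pm < alpha & out$delta_mesor < 0, "mesor_down")
  cls <- add(cls, pa < alpha & out$delta_amplitude > 0, "amp_up")
  cls <- add(cls, pa < alpha & out$delta_amplitude < 0, "amp_down")
  cls <- add(cls, pp < alpha & out$delta_phase > 0, "phase_delay")
  cls <- add(cls, pp < alpha & out$delta_phase < 0, "phase_advance")
  out$classes <- cls
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- c(g1, g2)
  class(out) <- c("diff_rhythm_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Count differentially rhythmic features per class combination
#'
#' UpSet-style tally: one row per non-empty combination of
#' differential-rhythm classes.
#'
#' @param table a `diff_rhythm_table` from [compare_rhythms()].
#' @return data.frame with columns `combination` and `n`, plus attribute
#'   `per_class` (total per single class).
#' @export
summarize_drg <- function(table) {
  cls <- table$classes[nzchar(table$classes)]
  if (!length(cls)) {
    out <- data.frame(combination = character(0), n = integer(0))
    attr(out, "per_class") <- integer(0)
    return(out)
  }
  tab <- table(cls)
  out <- data.frame(combination = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$n, out$combination), , drop = FALSE]
  singles <- unlist(strsplit(cls, "+", fixed = TRUE))
  attr(out, "per_class") <- table(singles)
  rownames(out) <- NULL
  out
}

#' Mean acrophase shift across robustly rhythmic features
#'
#' Arithmetic mean of the wrapped phase differences (group 2 minus group 1,
#' hours in (-12, 12\]) with a one-sample test against zero. The linear
#' test is appropriate because the shifts of interest are small relative
#' to the 24-h cycle; a Wilcoxon alternative is provided.
#'
#' @param x a `diff_rhythm_table` or a numeric vector of phase differences
#'   in hours.
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @return list with `mean` (hours; positive = group 2 delayed), `n`, and
#'   `p` (NA when fewer than 2 values are available).
#' @export
mean_phase_shift <- function(x, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  d <- if (is.data.frame(x)) x$delta_phase else x
  d <- d[!is.na(d)]
  d <- wrap_diff(d)
  if (!length(d)) return(list(mean = NA_real_, n = 0L, p = NA_real_))
  if (length(d) < 2 || sd(d) == 0)
    return(list(mean = mean(d), n = length(d),
                p = if (length(d) >= 2 && all(d == 0)) 1 else NA_real_))
  p <- if (test == "t") t.test(d, mu = 0)$p.value
       else wilcox.test(d, mu = 0)$p.value
  list(mean = mean(d), n = length(d), p = p)
}
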