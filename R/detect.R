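# --- JTK-style Kendall-tau template test ------------------------------------

# Null distribution of Kendall's S (#concordant - #discordant) for n untied
# observations against an untied reference: inversion-count (Mahonian)
# recursion. Returns P(S >= s) as a function.
kendall_exact_tail <- function(n) {
  # counts[k+1] = number of permutations of 1..n with k inversions
  counts <- 1
  for (i in 2:n) {
    m <- length(counts) + i - 1
    cs <- c(0, cumsum(counts))
    new <- numeric(m)
    for (k in 0:(m - 1)) {
      lo <- max(0, k - i + 1)
      hi <- min(k, length(counts) - 1)
      new[k + 1] <- cs[hi + 2] - cs[lo + 1]
    }
    counts <- new
  }
  total <- sum(counts)
  npair <- n * (n - 1) / 2
  function(s) {
    # S = npair - 2 * inversions  =>  S >= s  <=>  inv <= (npair - s)/2
    kmax <- floor((npair - s) / 2)
    if (kmax < 0) return(0)
    sum(counts[seq_len(min(kmax + 1, length(counts)))]) / total
  }
}

# Kendall S and its tie-corrected null variance between x and y.
kendall_s <- function(x, y) {
  n <- length(x)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sx <- sign(x[ij[, 2]] - x[ij[, 1]])
  sy <- sign(y[ij[, 2]] - y[ij[, 1]])
  S <- sum(sx * sy)
  tie_terms <- function(v) {
    tt <- table(v)
    tt <- as.numeric(tt[tt > 1])
    c(t1 = sum(tt * (tt - 1) * (2 * tt + 5)),
      t2 = sum(tt * (tt - 1)),
      t3 = sum(tt * (tt - 1) * (tt - 2)))
  }
  tx <- tie_terms(x); ty <- tie_terms(y)
  v0 <- n * (n - 1) * (2 * n + 5)
  vS <- (v0 - tx["t1"] - ty["t1"]) / 18 +
    tx["t2"] * ty["t2"] / (2 * n * (n - 1)) +
    tx["t3"] * ty["t3"] / (9 * n * (n - 1) * (n - 2))
  list(S = S, var = unname(vS),
       tied = tx["t2"] > 0 || ty["t2"] > 0, n = n)
}

jtk_one_lag <- function(y, ref, exact_tail = NULL) {
  ks <- kendall_s(y, ref)
  if (ks$var <= 0) return(1)
  if (!ks$tied && ks$n <= 10) {
    if (is.null(exact_tail)) exact_tail <- kendall_exact_tail(ks$n)
    exact_tail(ks$S)
  } else {
    # one-sided upper tail, continuity-corrected normal approximation
    pnorm((ks$S - 1) / sqrt(ks$var), lower.tail = FALSE)
  }
}

#' JTK-style nonparametric rhythmicity test
#'
#' Correlates the series, by Kendall's tau, with cosine reference templates
#' of fixed period peaking at each candidate lag, and reports the
#' Bonferroni-adjusted one-sided tail probability of the best-matching lag.
#' The tau null tail is exact (inversion-count enumeration) for untied data
#' with n <= 10 and a tie-corrected normal approximation otherwise.
#'
#' @param y numeric series.
#' @param t zeitgeber times in hours.
#' @param period period in hours (default 24).
#' @param lag_grid candidate peak lags in hours; defaults to the distinct
#'   sampling times.
#' @return p-value in \[0, 1\]; constant series give 1.
#' @export
jtk_test <- function(y, t, period = 24, lag_grid = NULL) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  if (length(y) < 6) stop("need at least 6 observations", call. = FALSE)
  if (max(y) == min(y)) return(1)
  if (is.null(lag_grid)) lag_grid <- sort(unique(t %% period))
  exact_tail <- if (length(y) <= 10) kendall_exact_tail(length(y)) else NULL
  w <- 2 * pi / period
  p_lags <- vapply(lag_grid, function(L)
    jtk_one_lag(y, cos(w * (t - L)), exact_tail), numeric(1))
  min(1, min(p_lags) * length(lag_grid))
}

# --- Lomb-Scargle periodogram test ------------------------------------------

# Normalized Lomb-Scargle power at one frequency plus the exact Gaussian
# tail for sample-variance normalization: P(Z > z) = (1 - 2z/(n-1))^((n-3)/2),
# which tends to exp(-z) for large n.
ls_power <- function(y, t, period) {
  w <- 2 * pi / period
  y <- y - mean(y)
  tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
  ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
  0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
}

#' Lomb-Scargle rhythmicity test at a single frequency
#'
#' Computes the normalized Lomb-Scargle periodogram power at frequency
#' 1/`period` and converts it to a p-value using the exact null tail for
#' sample-variance-normalized power under Gaussian noise,
#' \eqn{(1 - 2z/(n-1))^{(n-3)/2}}. No multiple-frequency correction is
#' applied because the period is fixed a priori.
#'
#' @inheritParams jtk_test
#' @return p-value in \[0, 1\]; constant series give 1.
#' @export
lomb_scargle_test <- function(y, t, period = 24) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  n <- length(y)
  if (n < 6) stop("need at least 6 observations", call. = FALSE)
  s2 <- var(y)
  if (s2 == 0) return(1)
  z <- ls_power(y, t, period) / s2
  u <- 1 - 2 * z / (n - 1)
  if (u <= 0) return(0)
  min(1, u^((n - 3) / 2))
}

# --- consensus and matrix-level driver --------------------------------------

#' Consensus rhythmicity call over several detectors
#'
#' @param p matrix (or data.frame) of per-method p-values, features in rows.
#' @param alpha per-method significance threshold (default 0.01).
#' @param rule `"any"` (rhythmic if at least one method is significant — the
#'   default), `"majority"`, or `"all"`.
#' @return logical vector of consensus flags; NA-only rows give FALSE.
#' @export
consensus_rhythmicity <- function(p, alpha = 0.01, rule = c("any", "majority", "all")) {
  rule <- match.arg(rule)
  p <- as.matrix(p)
  hit <- p < alpha
  n_avail <- rowSums(!is.na(hit))
  n_hit <- rowSums(hit, na.rm = TRUE)
  out <- switch(rule,
    any = n_hit >= 1,
    majority = n_hit > n_avail / 2,
    all = n_avail > 0 & n_hit == n_avail)
  out & n_avail > 0
}

#' Detect rhythmic features per group
#'
#' Runs the selected detectors on every feature of a timed matrix,
#' independently within each sample group, and applies the consensus rule.
#' Cosinor fits additionally report mesor, amplitude, acrophase and R^2.
#' For lipid-style matrices the convention of this framework is the same
#' detector set minus any detector you drop via `methods`.
#'
#' @param x a [timed_matrix] (typically log-scale continuous values).
#' @param methods subset of `c("cosinor", "jtk", "ls")`.
#' @param alpha per-method threshold for the consensus call (default 0.01).
#' @param rule consensus rule, see [consensus_rhythmicity()].
#' @param period period in hours (default 24).
#' @return data.frame of class `rhythm_calls`: one row per feature per
#'   group with columns `feature`, `group`, `p_cosinor`, `p_jtk`, `p_ls`
#'   (NA when a method was not run or failed), `mesor`, `amplitude`,
#'   `acrophase`, `r2`, `consensus`, `status`.
#' @export
detect_rhythms <- function(x, methods = c("cosinor", "jtk", "ls"),
                           alpha = 0.01, rule = "any", period = 24) {
  stopifnot(inherits(x, "timed_matrix"))
  methods <- match.arg(methods, c("cosinor", "jtk", "ls"), several.ok = TRUE)
  groups <- unique(x$meta$group)
  res <- lapply(groups, function(g) {
    sel <- x$meta$group == g
    detect_group(x$values[, sel, drop = FALSE], x$meta$time[sel],
                 methods, period)
  })
  out <- do.call(rbind, Map(function(df, g) {
    df$group <- rep(g, nrow(df))
    df
  }, res, groups))
  pm <- as.matrix(out[, paste0("p_", methods), drop = FALSE])
  out$consensus <- consensus_rhythmicity(pm, alpha = alpha, rule = rule)
  attr(out, "alpha") <- alpha
  attr(out, "rule") <- rule
  attr(out, "methods") <- methods
  class(out) <- c("rhythm_calls", "data.frame")
  rownames(out) <- NULL
  out[, c("feature", "group", "p_cosinor", "p_jtk", "p_ls",
          "mesor", "amplitude", "acrophase", "r2", "consensus", "status")]
}

# vectorized single-group detection; t is shared across features
detect_group <- function(Y, t, methods, period) {
  nf <- nrow(Y)
  out <- data.frame(feature = if (nf) rownames(Y) %||% as.character(seq_len(nf))
                              else character(0),
                    p_cosinor = rep(NA_real_, nf), p_jtk = rep(NA_real_, nf),
                    p_ls = rep(NA_real_, nf),
                    mesor = rep(NA_real_, nf), amplitude = rep(NA_real_, nf),
                    acrophase = rep(NA_real_, nf), r2 = rep(NA_real_, nf),
                    status = rep("ok", nf), stringsAsFactors = FALSE)
  if (nf == 0) return(out)
  bad <- !apply(is.finite(Y), 1, all)
  out$status[bad] <- "non-finite values"
  okY <- Y[!bad, , drop = FALSE]
  if (nrow(okY)) {
    if ("cosinor" %in% methods) {
      cz <- cosinor_matrix(okY, t, period)
      out[!bad, c("p_cosinor", "mesor", "amplitude", "acrophase", "r2")] <-
        cz[, c("p", "mesor", "amplitude", "acrophase", "r2")]
    }
    if ("jtk" %in% methods) {
      lag_grid <- sort(unique(t %% period))
      exact_tail <- if (ncol(okY) <= 10) kendall_exact_tail(ncol(okY)) else NULL
      w <- 2 * pi / period
      refs <- lapply(lag_grid, function(L) cos(w * (t - L)))
      out$p_jtk[!bad] <- apply(okY, 1, function(y) {
        if (max(y) == min(y)) return(1)
        min(1, min(vapply(refs, function(r) jtk_one_lag(y, r, exact_tail),
                          numeric(1))) * length(refs))
      })
    }
    if ("ls" %in% methods) {
      out$p_ls[!bad] <- apply(okY, 1, function(y)
        lomb_scargle_test(y, t, period))
    }
  }
  out
}

# whole-matrix cosinor via one multi-response least-squares solve
cosinor_matrix <- function(Y, t, period) {
  w <- 2 * pi / period
  X <- cbind(1, sin(w * t), cos(w * t))
  fit <- lm.fit(X, t(Y))
  B <- t(fit$coefficients)                    # features x 3
  R <- t(fit$residuals)
  rss <- rowSums(R^2)
  tss <- rowSums((Y - rowMeans(Y))^2)
  df <- ncol(Y) - fit$rank
  amplitude <- sqrt(B[, 2]^2 + B[, 3]^2)
  acrophase <- wrap_phase((period / (2 * pi)) * atan2(B[, 2], B[, 3]), period)
  p <- rep(1, nrow(Y))
  pos <- tss > 0
  perfect <- pos & rss <= tss * 1e-12
  f <- ((tss - rss) / 2) / (rss / df)
  p[pos] <- pf(f[pos], 2, df, lower.tail = FALSE)
  p[perfect] <- .Machine$double.xmin
  r2 <- ifelse(pos, 1 - rss / tss, 0)
  cbind(p = p, mesor = B[, 1], amplitude = amplitude,
        acrophase = acrophase, r2 = r2)
}
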