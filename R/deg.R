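# Simplified negative-binomial differential expression.
#
# Dispersions are estimated per feature by method of moments on
# size-factor-normalized counts (pooled within groups), a mean-dispersion
# trend a0 + a1/mu is fitted across features, and feature dispersions are
# shrunk toward the trend in log space. Tests then use a fixed-dispersion
# NB GLM: Wald on the group coefficient (global mode) or a likelihood-ratio
# test of group on top of categorical time (time-adjusted mode). This is a
# deliberately lightweight approach: no Cox-Reid adjusted profile
# likelihood, no fold-change shrinkage, no independent filtering.

# cells: the factor whose within-cell variance is the model residual —
# group for the time-pooled Wald test, group x time for the LRT, so each
# test's dispersion reflects the variability its model leaves unexplained
estimate_dispersions <- function(counts, sf, cells) {
  q <- sweep(counts, 2, sf, "/")
  cells <- as.factor(cells)
  mu <- rowMeans(q)
  xim <- mean(1 / sf)
  # pooled within-cell method-of-moments: var(q) ~ mu/sf + alpha mu^2
  resvar <- rep(0, nrow(counts))
  for (g in levels(cells)) {
    sel <- cells == g
    if (sum(sel) < 2) next
    vg <- apply(q[, sel, drop = FALSE], 1, var)
    resvar <- resvar + (sum(sel) - 1) * vg
  }
  vpool <- resvar / (length(cells) - nlevels(cells))
  alpha_mom <- (vpool - xim * mu) / mu^2
  alpha_mom[!is.finite(alpha_mom)] <- NA_real_
  floor_a <- 1e-8
  a_use <- pmax(alpha_mom, floor_a)
  # parametric trend alpha(mu) = a0 + a1/mu, fitted on features with a
  # positive raw estimate
  fitok <- which(is.finite(alpha_mom) & alpha_mom > 0 & mu > 0)
  if (length(fitok) >= 10) {
    tr <- lm.fit(cbind(1, 1 / mu[fitok]), a_use[fitok])
    a0 <- max(tr$coefficients[1], 1e-6); a1 <- max(tr$coefficients[2], 0)
  } else {
    a0 <- max(mean(a_use, na.rm = TRUE), 1e-6); a1 <- 0
  }
  trend <- a0 + a1 / pmax(mu, 1e-8)
  # log-space shrinkage toward the trend
  shrunk <- exp(0.5 * log(pmax(a_use, floor_a)) + 0.5 * log(trend))
  shrunk[is.na(alpha_mom)] <- trend[is.na(alpha_mom)]
  pmax(shrunk, floor_a)
}

nb_fit_tables <- function(x, group_order = NULL,
                          cells = c("group", "group_time")) {
  if (x$value_kind != "counts")
    stop("differential expression requires count data", call. = FALSE)
  cells <- match.arg(cells)
  groups <- group_order %||% unique(x$meta$group)
  if (length(groups) != 2 || !all(groups %in% x$meta$group))
    stop("need exactly two groups", call. = FALSE)
  counts <- x$values
  keep <- rowSums(counts) > 0
  sf <- size_factors(counts[keep, , drop = FALSE])
  cellfac <- if (cells == "group") x$meta$group
             else interaction(x$meta$group, x$meta$time, drop = TRUE)
  disp <- rep(NA_real_, nrow(counts))
  disp[keep] <- estimate_dispersions(counts[keep, , drop = FALSE], sf, cellfac)
  list(counts = counts, keep = keep, sf = sf, disp = disp,
       group = factor(x$meta$group, levels = groups),
       time = factor(x$meta$time))
}

deg_frame <- function(feature, lfc, p, alpha) {
  fdr <- p.adjust(p, "BH")
  direction <- rep("ns", length(p))
  direction[!is.na(fdr) & fdr < alpha & lfc > 0] <- "up"
  direction[!is.na(fdr) & fdr < alpha & lfc < 0] <- "down"
  out <- data.frame(feature = feature, log2_fold_change = lfc, p = p,
                    fdr = fdr, direction = direction,
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Global differential expression, pooling sampling times
#'
#' Negative-binomial GLM per feature with the group factor only (all
#' sampling times pooled), Wald test on the group coefficient, and
#' Benjamini-Hochberg FDR across features. A feature is called up- or
#' down-regulated when its FDR is below `alpha` and the log2 fold change is
#' above or below zero — no fold-change threshold beyond the sign.
#'
#' @param x a [timed_matrix] of counts with exactly two groups.
#' @param alpha FDR threshold for the direction call (default 0.05).
#' @param group_order optional two group labels fixing the reference
#'   (group 1); defaults to order of appearance.
#' @return data.frame of class `deg_table`: `feature`, `log2_fold_change`
#'   (group 2 vs group 1), `p`, `fdr`, `direction` (`up`/`down`/`ns`);
#'   all-zero features carry NA statistics.
#' @export
nb_global_test <- function(x, alpha = 0.05, group_order = NULL) {
  ft <- nb_fit_tables(x, group_order)
  n <- nrow(ft$counts)
  lfc <- rep(NA_real_, n); p <- rep(NA_real_, n)
  off <- log(ft$sf)
  for (i in which(ft$keep)) {
    yi <- ft$counts[i, ]
    fam <- MASS::negative.binomial(theta = 1 / ft$disp[i])
    fit <- tryCatch(glm(yi ~ ft$group + offset(off), family = fam),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit))
      fit <- tryCatch(suppressWarnings(glm(yi ~ ft$group + offset(off),
                                           family = fam)),
                      error = function(e) NULL)
    if (is.null(fit)) next
    sm <- summary(fit, dispersion = 1)
    co <- sm$coefficients
    if (nrow(co) < 2) next
    lfc[i] <- co[2, "Estimate"] / log(2)
    p[i] <- 2 * pnorm(abs(co[2, "Estimate"] / co[2, "Std. Error"]),
                      lower.tail = FALSE)
  }
  deg_frame(rownames(ft$counts), lfc, p, alpha)
}

#' Time-adjusted differential expression (likelihood-ratio test)
#'
#' Negative-binomial GLM with categorical sampling time plus group, tested
#' against the time-only model by a likelihood-ratio (deviance) test with
#' one degree of freedom — the group effect given time.
#'
#' @inheritParams nb_global_test
#' @return data.frame of class `deg_table` as in [nb_global_test()].
#' @export
nb_time_adjusted_test <- function(x, alpha = 0.05, group_order = NULL) {
  ft <- nb_fit_tables(x, group_order, cells = "group_time")
  tg <- table(ft$time, ft$group)
  missing <- rownames(tg)[apply(tg == 0, 1, any)]
  if (length(missing))
    stop("timepoint(s) present in one group only: ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- nrow(ft$counts)
  lfc <- rep(NA_real_, n); p <- rep(NA_real_, n)
  off <- log(ft$sf)
  for (i in which(ft$keep)) {
    yi <- ft$counts[i, ]
    fam <- MASS::negative.binomial(theta = 1 / ft$disp[i])
    full <- tryCatch(suppressWarnings(
      glm(yi ~ ft$time + ft$group + offset(off), family = fam)),
      error = function(e) NULL)
    red <- tryCatch(suppressWarnings(
      glm(yi ~ ft$time + offset(off), family = fam)),
      error = function(e) NULL)
    if (is.null(full) || is.null(red)) next
    stat <- max(0, red$deviance - full$deviance)
    p[i] <- pchisq(stat, df = 1, lower.tail = FALSE)
    cf <- coef(full)
    lfc[i] <- cf[length(cf)] / log(2)
  }
  deg_frame(rownames(ft$counts), lfc, p, alpha)
}

#' Hormone-responsive, receptor-insensitive gene sets
#'
#' Set algebra for isolating features that respond to a stimulus in both
#' directions of perturbation yet are unchanged when the candidate receptor
#' is removed: the intersection `up_in_high` with `down_in_low` with
#' `unchanged_in_ko`, alongside the full seven-region partition of the
#' three sets.
#'
#' @param up_in_high,down_in_low,unchanged_in_ko character vectors over a
#'   shared feature universe.
#' @return list with `responsive_insensitive` (the triple intersection) and
#'   `partition` (named list over the 7 non-empty membership patterns,
#'   labels like `"up_in_high+down_in_low"`).
#' @export
responsive_insensitive_sets <- function(up_in_high, down_in_low, unchanged_in_ko) {
  u <- unique(up_in_high); d <- unique(down_in_low); k <- unique(unchanged_in_ko)
  core <- intersect(intersect(u, d), k)
  universe <- union(union(u, d), k)
  member <- cbind(up_in_high = universe %in% u,
                  down_in_low = universe %in% d,
                  unchanged_in_ko = universe %in% k)
  pat <- apply(member, 1, function(m)
    paste(colnames(member)[m], collapse = "+"))
  partition <- split(universe, pat)
  list(responsive_insensitive = sort(core), partition = partition)
}
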