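# Circular helpers on the 24-h clock ------------------------------------------

#' Circular mean of clock hours
#'
#' @param h hours in \[0, 24).
#' @param period cycle length (default 24).
#' @return mean direction in \[0, period).
#' @export
circular_mean_hours <- function(h, period = 24) {
  a <- 2 * pi * h / period
  wrap_phase(atan2(mean(sin(a)), mean(cos(a))) * period / (2 * pi), period)
}

#' Circular median of clock hours
#'
#' The member value minimising the summed circular absolute deviation
#' (shortest arc distance); ties are broken by the smaller hour.
#'
#' @inheritParams circular_mean_hours
#' @return median hour in \[0, period).
#' @export
circular_median_hours <- function(h, period = 24) {
  if (!length(h)) stop("empty phase vector", call. = FALSE)
  h <- wrap_phase(h, period)
  cand <- sort(unique(h))
  dev <- vapply(cand, function(c0) {
    d <- abs(wrap_diff(h - c0, period))
    sum(pmin(d, period - d))
  }, numeric(1))
  cand[which.min(dev)]      # which.min takes the first (smallest hour) on ties
}

#' Acrophase histogram
#'
#' Counts phases in consecutive bins of `bin_hours` partitioning \[0, 24).
#'
#' @param phases hours in \[0, 24).
#' @param bin_hours bin width; must divide 24.
#' @return integer vector of counts named by bin, summing to `length(phases)`.
#' @export
phase_histogram <- function(phases, bin_hours = 4) {
  if (!length(phases)) stop("empty phase vector", call. = FALSE)
  if (24 %% bin_hours != 0)
    stop("bin width must divide 24 hours", call. = FALSE)
  phases <- wrap_phase(phases)
  k <- 24 / bin_hours
  idx <- floor(phases / bin_hours) + 1
  counts <- tabulate(idx, nbins = k)
  names(counts) <- sprintf("[%g,%g)", (seq_len(k) - 1) * bin_hours,
                           seq_len(k) * bin_hours)
  counts
}

# Two-sample Kuiper test ------------------------------------------------------

#' Two-sample Kuiper test on circular phases
#'
#' Rotation-invariant two-sample test: V = D+ + D- between the empirical
#' distributions of the two samples, with the asymptotic Kuiper tail
#' (Stephens' effective-sample-size correction) for the p-value.
#'
#' @param x,y numeric samples (hours; any common rotation leaves the result
#'   unchanged).
#' @param period cycle length used only to wrap inputs (default 24).
#' @return list with `statistic` (V) and `p.value`.
#' @export
kuiper_two_sample <- function(x, y, period = 24) {
  x <- wrap_phase(x, period); y <- wrap_phase(y, period)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per sample", call. = FALSE)
  pooled <- sort(unique(c(x, y)))
  F1 <- findInterval(pooled, sort(x)) / n1
  F2 <- findInterval(pooled, sort(y)) / n2
  V <- max(F1 - F2) + max(F2 - F1)
  ne <- n1 * n2 / (n1 + n2)
  lam <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  j <- 1:100
  p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
  list(statistic = V, p.value = min(1, max(0, p)))
}

#' Phase set enrichment analysis (PSEA)
#'
#' For each gene set, tests whether the acrophases of its members are
#' distributed differently from the background phases (all rhythmic
#' features) using the two-sample Kuiper test; set members are removed
#' from the background sample for the comparison so the two samples are
#' disjoint. Each reported set also carries its summary phase, the
#' circular median of member acrophases.
#'
#' @param phases named numeric vector: feature -> acrophase hours in
#'   \[0, 24). These are the background.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param min_genes minimum set members with a phase (default 10); smaller
#'   sets are reported with `status = "skipped"` and no p-value.
#' @param alpha significance threshold recorded in the `significant` column
#'   (default 0.01).
#' @param round_phases if TRUE (default), phases are rounded half-up to
#'   integer hours before testing, matching the convention of feeding
#'   whole-hour peak times into PSEA.
#' @return data.frame of class `psea_result`: `set`, `description`, `n`,
#'   `p`, `set_phase` (circular median, hours), `significant`, `status`.
#' @export
psea_kuiper <- function(phases, sets, min_genes = 10, alpha = 0.01,
                        round_phases = TRUE) {
  if (is.null(names(phases))) stop("'phases' must be named by feature", call. = FALSE)
  ph <- if (round_phases) wrap_phase(floor(phases + 0.5)) else wrap_phase(phases)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], names(ph))
    desc <- attr(sets[[nm]], "description") %||% ""
    if (length(members) < min_genes)
      return(data.frame(set = nm, description = desc, n = length(members),
                        p = NA_real_, set_phase = NA_real_,
                        significant = FALSE, status = "skipped: too few members",
                        stringsAsFactors = FALSE))
    sp <- ph[members]
    bg <- ph[setdiff(names(ph), members)]
    kt <- kuiper_two_sample(sp, bg)
    data.frame(set = nm, description = desc, n = length(members),
               p = kt$p.value, set_phase = circular_median_hours(sp),
               significant = kt$p.value < alpha, status = "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("psea_result", "data.frame")
  out
}

#' Merge enriched processes into broader categories
#'
#' Given per-set summary phases and a manual mapping of set ids to broader
#' biological categories, returns the circular mean phase per category
#' (wrap-aware averaging; 23 h and 1 h average to 0 h, not 12 h).
#'
#' @param results a data.frame with columns `set` and `set_phase`
#'   (e.g. a `psea_result`).
#' @param mapping data.frame with columns `set` and `category`.
#' @return named numeric vector: category -> mean phase (hours).
#' @export
merge_categories <- function(results, mapping) {
  stopifnot(all(c("set", "category") %in% names(mapping)))
  known <- mapping$set %in% results$set
  if (any(!known))
    warning("sets absent from results, skipped: ",
            paste(mapping$set[!known], collapse = ", "))
  mapping <- mapping[known, , drop = FALSE]
  if (!nrow(mapping)) return(setNames(numeric(0), character(0)))
  ph <- setNames(results$set_phase, results$set)[mapping$set]
  keep <- !is.na(ph)
  mapping <- mapping[keep, , drop = FALSE]; ph <- ph[keep]
  if (!nrow(mapping)) return(setNames(numeric(0), character(0)))
  vapply(split(ph, mapping$category), circular_mean_hours, numeric(1))
}

#' Between-group phase difference per category
#'
#' @param g1,g2 named numeric vectors (category -> phase hours) for the two
#'   groups, e.g. two [merge_categories()] outputs.
#' @return named numeric vector over the categories present in both groups:
#'   wrapped difference in (-12, 12\], positive = group 2 later.
#' @export
category_phase_difference <- function(g1, g2) {
  common <- intersect(names(g1), names(g2))
  missing <- union(setdiff(names(g1), common), setdiff(names(g2), common))
  if (length(missing))
    warning("categories present in one group only, omitted: ",
            paste(missing, collapse = ", "))
  setNames(wrap_diff(g2[common] - g1[common]), common)
}

#' Over-representation analysis by the hypergeometric test
#'
#' One-sided upper-tail hypergeometric (Fisher) test of the overlap between
#' a hit list and each gene set, against a stated background universe.
#' Sets overlapping the hits in fewer than `min_genes` features are not
#' reported.
#'
#' @param hits character vector of significant features; must be a subset
#'   of `background`.
#' @param background character vector, the tested universe.
#' @param sets named list of character vectors.
#' @param min_genes minimum hit overlap for a set to be reported (default 3).
#' @param alpha threshold recorded in the `significant` column (default 0.05).
#' @return data.frame of class `ora_result` sorted by p: `set`,
#'   `description`, `n_set` (set size within background), `n_overlap`, `p`,
#'   `fdr` (Benjamini-Hochberg over reported sets), `significant`.
#' @export
ora_fisher <- function(hits, background, sets, min_genes = 3, alpha = 0.05) {
  hits <- unique(hits); background <- unique(background)
  stray <- setdiff(hits, background)
  if (length(stray))
    stop("hits not in background: ", paste(stray, collapse = ", "), call. = FALSE)
  N <- length(background); n <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], background)
    K <- length(members)
    ov <- length(intersect(members, hits))
    if (ov < min_genes) return(NULL)
    p <- phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, description = attr(sets[[nm]], "description") %||% "",
               n_set = K, n_overlap = ov, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(set = character(0), description = character(0),
                      n_set = integer(0), n_overlap = integer(0),
                      p = numeric(0), fdr = numeric(0), significant = logical(0))
    class(out) <- c("ora_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}
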