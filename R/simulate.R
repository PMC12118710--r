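# Synthetic two-group diurnal omics data with known ground truth.
#
# The default design mirrors a standard around-the-clock mouse study:
# samples every 4 h across 24 h (6 timepoints), 3 independent replicates per
# timepoint per group, two groups (control and perturbed). Rhythmic signal
# is defined on the log scale, mean = exp(mesor + amplitude *
# cos(2*pi*(t - acrophase)/24)), so cosinor fits to log-transformed values
# are well specified. Count noise is negative binomial; lipid-style noise
# is multiplicative log-normal.

#' Zeitgeber-time sampling grids
#'
#' The 4-hourly grid across 24 h, anchored either at ZT0 or at ZT2 (both
#' anchors occur in around-the-clock designs; the anchor does not affect
#' any downstream method, only the printed times).
#'
#' @param anchor `"ZT2"` (default; 2, 6, ..., 22) or `"ZT0"` (0, 4, ..., 20).
#' @return numeric vector of 6 hours.
#' @export
zt_grid <- function(anchor = c("ZT2", "ZT0")) {
  anchor <- match.arg(anchor)
  if (anchor == "ZT2") seq(2, 22, by = 4) else seq(0, 20, by = 4)
}

#' Negative-binomial noise specification
#' @param dispersion NB dispersion alpha > 0 (variance = mu + alpha mu^2);
#'   0 is allowed and means Poisson.
#' @return noise spec for [sim_config()].
#' @export
noise_nb <- function(dispersion = 0.05) {
  if (dispersion < 0) stop_field("dispersion", "must be >= 0")
  list(type = "nb", dispersion = dispersion)
}

#' Log-normal noise specification
#' @param sigma standard deviation of the additive log-scale noise; >= 0.
#' @return noise spec for [sim_config()].
#' @export
noise_lognormal <- function(sigma = 0.2) {
  if (sigma < 0) stop_field("sigma", "must be >= 0")
  list(type = "lognormal", sigma = sigma)
}

#' Simulation configuration
#'
#' Parameter distributions are given either as a single number (fixed for
#' every feature) or as a list: `list(min=, max=)` for uniform draws,
#' `list(mean=, sd=)` for Gaussian draws, or `list(values=, prob=)` for a
#' discrete mixture (e.g. balanced up/down effects). All rhythm parameters live on the
#' log-abundance scale; `acrophase` and `delta_phase` are hours.
#' `delta_*` values are the group-2 minus group-1 effects: `delta_mesor`
#' applies to every feature, while `delta_amplitude` and `delta_phase`
#' apply to rhythmic features only (non-rhythmic features keep amplitude
#' exactly 0 in both groups, giving a clean null). A positive `delta_phase`
#' delays the group-2 peak: acrophase2 = (acrophase1 + delta) mod 24.
#'
#' @param n_features number of features.
#' @param fraction_rhythmic proportion of rhythmic features in \[0, 1\].
#' @param timepoints zeitgeber hours in \[0, 24).
#' @param n_replicates replicates per timepoint per group (default 3).
#' @param group_labels two group identifiers (default control, knockout).
#' @param mesor,amplitude,acrophase per-feature parameter specs (log scale;
#'   defaults: mesor ~ N(log 500, 1); amplitude ~ U(0.3, 1.5) for rhythmic
#'   features; acrophase ~ U(0, 24)).
#' @param delta_mesor,delta_amplitude,delta_phase group-2 effect specs
#'   (defaults 0).
#' @param fraction_affected proportion of features that receive the group-2
#'   deltas (default 1). Values below 1 emulate the realistic situation
#'   where only a subset of the transcriptome responds to the perturbation;
#'   note that a mesor shift applied to every feature is compositional and
#'   is absorbed by median-of-ratios size factors downstream.
#' @param noise [noise_nb()] or [noise_lognormal()].
#' @param seed integer master seed; per-feature substreams are derived from
#'   it so results do not depend on feature order.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_features = 2000, fraction_rhythmic = 0.5,
                       timepoints = zt_grid("ZT2"), n_replicates = 3,
                       group_labels = c("WT", "KO"),
                       mesor = list(mean = log(500), sd = 1),
                       amplitude = list(min = 0.3, max = 1.5),
                       acrophase = list(min = 0, max = 24),
                       delta_mesor = 0, delta_amplitude = 0, delta_phase = 0,
                       fraction_affected = 1,
                       noise = noise_nb(0.05), seed = 1) {
  if (!is.numeric(n_features) || n_features < 1)
    stop_field("n_features", "must be a positive count")
  if (!is.numeric(fraction_rhythmic) ||
      fraction_rhythmic < 0 || fraction_rhythmic > 1)
    stop_field("fraction_rhythmic", "must lie in [0, 1]")
  if (!length(timepoints) || any(timepoints < 0 | timepoints >= 24))
    stop_field("timepoints", "must be non-empty hours in [0, 24)")
  if (!is.numeric(n_replicates) || n_replicates < 1)
    stop_field("n_replicates", "must be a positive count")
  if (length(group_labels) != 2 || anyDuplicated(group_labels))
    stop_field("group_labels", "must be two distinct identifiers")
  if (!is.numeric(fraction_affected) ||
      fraction_affected < 0 || fraction_affected > 1)
    stop_field("fraction_affected", "must lie in [0, 1]")
  if (!is.list(noise) || !noise$type %in% c("nb", "lognormal"))
    stop_field("noise", "must be noise_nb() or noise_lognormal()")
  structure(list(
    n_features = as.integer(n_features),
    fraction_rhythmic = fraction_rhythmic,
    timepoints = as.numeric(timepoints),
    n_replicates = as.integer(n_replicates),
    group_labels = as.character(group_labels),
    mesor = mesor, amplitude = amplitude, acrophase = acrophase,
    delta_mesor = delta_mesor, delta_amplitude = delta_amplitude,
    delta_phase = delta_phase, fraction_affected = fraction_affected,
    noise = noise, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d features (%.0f%% rhythmic), %d timepoints x %d replicates x 2 groups, %s noise, seed %d\n",
    x$n_features, 100 * x$fraction_rhythmic, length(x$timepoints),
    x$n_replicates, x$noise$type, x$seed))
  invisible(x)
}

draw_param <- function(spec, n = 1) {
  if (is.numeric(spec) && length(spec) == 1) return(rep(spec, n))
  if (is.list(spec) && all(c("min", "max") %in% names(spec)))
    return(runif(n, spec$min, spec$max))
  if (is.list(spec) && all(c("mean", "sd") %in% names(spec)))
    return(rnorm(n, spec$mean, spec$sd))
  if (is.list(spec) && !is.null(spec$values))   # discrete mixture, e.g. +/- lfc
    return(sample(spec$values, n, replace = TRUE, prob = spec$prob))
  stop_field("parameter spec",
             "must be a number, list(min,max), list(mean,sd) or list(values,prob)")
}

sim_sample_sheet <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      time = config$timepoints,
                      group = config$group_labels,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("group", "time", "replicate")]
  grid$sample <- paste0(grid$group, "_T", format(grid$time, trim = TRUE),
                        "_R", grid$replicate)
  grid[, c("sample", "group", "time", "replicate")]
}

# Per-feature true parameters, drawn from independent substreams of the
# master seed so the truth for feature i does not depend on n_features
# ordering quirks elsewhere.
sim_truth <- function(config) {
  set.seed(config$seed)
  feature_seeds <- sample.int(.Machine$integer.max - 1, config$n_features)
  g1 <- config$group_labels[1]; g2 <- config$group_labels[2]
  rows <- vector("list", config$n_features)
  for (i in seq_len(config$n_features)) {
    set.seed(feature_seeds[i])
    rhythmic <- runif(1) < config$fraction_rhythmic
    affected <- runif(1) < (config$fraction_affected %||% 1)
    m <- draw_param(config$mesor)
    a <- if (rhythmic) abs(draw_param(config$amplitude)) else 0
    phi <- if (rhythmic) wrap_phase(draw_param(config$acrophase)) else 0
    dm <- if (affected) draw_param(config$delta_mesor) else 0
    da <- if (rhythmic && affected) draw_param(config$delta_amplitude) else 0
    dp <- if (rhythmic && affected) draw_param(config$delta_phase) else 0
    a2 <- max(0, a + da)
    rows[[i]] <- data.frame(
      feature = NA_character_,
      group = c(g1, g2),
      is_rhythmic = c(rhythmic && a > 0, rhythmic && a2 > 0),
      mesor = c(m, m + dm),
      amplitude = c(a, a2),
      acrophase = c(phi, if (rhythmic) wrap_phase(phi + dp) else 0),
      feature_seed = feature_seeds[i],
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth
}

sim_means <- function(truth, sheet, period = 24) {
  # log-scale curve per feature per sample
  feats <- unique(truth$feature)
  mu <- matrix(NA_real_, length(feats), nrow(sheet),
               dimnames = list(feats, sheet$sample))
  for (g in unique(sheet$group)) {
    sel <- sheet$group == g
    tg <- truth[truth$group == g, ]
    tg <- tg[match(feats, tg$feature), ]
    curve <- outer(seq_along(feats), which(sel), function(i, j)
      tg$mesor[i] + tg$amplitude[i] *
        cos(2 * pi * (sheet$time[j] - tg$acrophase[i]) / period))
    mu[, sel] <- exp(curve)
  }
  mu
}

#' Simulate a two-group diurnal count dataset
#'
#' Draws negative-binomial counts around log-scale cosinor mean curves with
#' the configured design. The per-sample mean for feature i in group g at
#' time t is `exp(mesor + amplitude * cos(2*pi*(t - acrophase)/24))` with
#' the group's true parameters. Identical configs (same seed) give
#' bit-identical output.
#'
#' @param config a [sim_config()] with negative-binomial noise.
#' @return list with `matrix` (a counts [timed_matrix]), `truth` (the
#'   ground-truth data.frame, class `ground_truth`: one row per feature per
#'   group with `is_rhythmic`, `mesor`, `amplitude`, `acrophase`,
#'   `noise_param`) and `config`.
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$noise$type != "nb")
    stop_field("noise", "generate_counts() requires negative-binomial noise")
  truth <- sim_truth(config)
  feats <- sprintf("gene_%05d", seq_len(config$n_features))
  truth$feature <- rep(feats, each = 2)
  sheet <- sim_sample_sheet(config)
  mu <- sim_means(truth, sheet)
  disp <- config$noise$dispersion
  vals <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  for (i in seq_len(nrow(mu))) {
    set.seed(truth$feature_seed[2 * i] + 1L)      # sampling substream
    vals[i, ] <- if (disp > 0)
      rnbinom(ncol(mu), mu = mu[i, ], size = 1 / disp)
    else rpois(ncol(mu), lambda = mu[i, ])
  }
  truth$noise_param <- disp
  truth$feature_seed <- NULL
  class(truth) <- c("ground_truth", "data.frame")
  list(matrix = timed_matrix(vals, sheet, "counts"),
       truth = truth, config = config)
}

#' Simulate a two-group diurnal lipidome dataset
#'
#' Positive continuous abundances with multiplicative log-normal noise:
#' `value = exp(curve + eps)`, `eps ~ N(0, sigma)`, where `curve` is the
#' log-scale cosinor curve. Feature names are valid shorthand lipid species
#' drawn from `class_palette` (every generated name survives a parser
#' round trip). With `sigma = 0` each value equals the noiseless curve.
#'
#' @param config a [sim_config()] with log-normal noise; the default size
#'   (285 features) matches a typical untargeted liver lipidomics run.
#' @param class_palette lipid class tokens used to draw species names.
#' @return as [generate_counts()], with a continuous [timed_matrix].
#' @export
generate_lipidome <- function(config = sim_config(n_features = 285,
                                                  mesor = list(mean = 0, sd = 1),
                                                  noise = noise_lognormal(0.2)),
                              class_palette = c("TG", "DG", "PC", "PE", "PG",
                                                "PI", "Cer", "SM", "CE", "ST",
                                                "FFA")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$noise$type != "lognormal")
    stop_field("noise", "generate_lipidome() requires log-normal noise")
  if (!length(class_palette))
    stop_field("class_palette", "must be non-empty")
  for (cl in class_palette)                       # validate against the grammar
    parse_lipid_name(paste(cl, "16:0"))

  truth <- sim_truth(config)
  set.seed(config$seed + 1L)
  feats <- character(0)
  while (length(feats) < config$n_features) {
    feats <- unique(c(feats, replicate(config$n_features,
                                       random_lipid_name(class_palette))))
  }
  feats <- feats[seq_len(config$n_features)]
  truth$feature <- rep(feats, each = 2)
  sheet <- sim_sample_sheet(config)
  mu <- sim_means(truth, sheet)                   # natural-scale curve
  sigma <- config$noise$sigma
  vals <- mu
  for (i in seq_len(nrow(mu))) {
    set.seed(truth$feature_seed[2 * i] + 1L)
    vals[i, ] <- mu[i, ] * exp(rnorm(ncol(mu), 0, sigma))
  }
  truth$noise_param <- sigma
  truth$feature_seed <- NULL
  class(truth) <- c("ground_truth", "data.frame")
  list(matrix = timed_matrix(vals, sheet, "continuous"),
       truth = truth, config = config)
}

#' Write / read ground truth tables
#'
#' TSV with one row per feature per group; [read_ground_truth()] restores
#' an identical table.
#'
#' @param truth a `ground_truth` data.frame.
#' @param path file path.
#' @return the path (write) or the table (read).
#' @export
write_ground_truth <- function(truth, path) {
  cols <- c("feature", "group", "is_rhythmic", "mesor", "amplitude",
            "acrophase", "noise_param")
  df <- as.data.frame(truth)[, cols, drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$is_rhythmic <- as.logical(df$is_rhythmic)
  class(df) <- c("ground_truth", "data.frame")
  df
}
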