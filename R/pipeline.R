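# End-to-end orchestration: simulate/load -> preprocess -> detect -> compare
# -> phase statistics -> enrichment -> differential expression -> report.
# Every stage writes a TSV into the run directory and the run manifest
# records row counts, the seed and a hash of the effective configuration,
# so a rerun with the same config and seed reproduces byte-identical tables.

#' Pipeline configuration
#'
#' Either `simulate` (a [sim_config()]) or both `matrix_path` and
#' `sample_sheet_path` must be given.
#'
#' @param simulate optional [sim_config()]; when set, input data are
#'   generated rather than read.
#' @param matrix_path,sample_sheet_path input TSVs (used when `simulate`
#'   is NULL).
#' @param value_kind `"counts"` or `"continuous"` for file input.
#' @param gmt_path optional GMT file enabling PSEA and ORA.
#' @param category_map_path optional TSV (`set`, `category`) for merging
#'   enriched processes into broader categories.
#' @param min_total low-count filter threshold (counts only; default 100).
#' @param methods detector set (default cosinor, jtk, ls).
#' @param rule consensus rule (default `"any"`).
#' @param detection_alpha per-method rhythmicity threshold (default 0.01).
#' @param comparison_alpha threshold for rhythm-parameter contrasts
#'   (default 0.05).
#' @param psea_min_genes,psea_alpha PSEA cutoffs (defaults 10, 0.01).
#' @param ora_min_genes,ora_alpha ORA cutoffs (defaults 3, 0.05).
#' @param deg_alpha FDR threshold for expression direction calls (0.05).
#' @param seed integer seed for the whole run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, matrix_path = NULL,
                            sample_sheet_path = NULL,
                            value_kind = c("counts", "continuous"),
                            gmt_path = NULL, category_map_path = NULL,
                            min_total = 100,
                            methods = c("cosinor", "jtk", "ls"),
                            rule = "any",
                            detection_alpha = 0.01, comparison_alpha = 0.05,
                            psea_min_genes = 10, psea_alpha = 0.01,
                            ora_min_genes = 3, ora_alpha = 0.05,
                            deg_alpha = 0.05, seed = 1) {
  value_kind <- match.arg(value_kind)
  if (is.null(simulate) && (is.null(matrix_path) || is.null(sample_sheet_path)))
    stop_field("input", "need either 'simulate' or matrix and sample sheet paths")
  for (a in c(detection_alpha, comparison_alpha, psea_alpha, ora_alpha, deg_alpha))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      stop_field("alpha", "thresholds must lie in (0, 1)")
  structure(list(simulate = simulate, matrix_path = matrix_path,
                 sample_sheet_path = sample_sheet_path,
                 value_kind = value_kind, gmt_path = gmt_path,
                 category_map_path = category_map_path,
                 min_total = min_total, methods = methods, rule = rule,
                 detection_alpha = detection_alpha,
                 comparison_alpha = comparison_alpha,
                 psea_min_genes = psea_min_genes, psea_alpha = psea_alpha,
                 ora_min_genes = ora_min_genes, ora_alpha = ora_alpha,
                 deg_alpha = deg_alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; a `simulate` block
#' holds [sim_config()] arguments, with `noise: {type: nb, dispersion: x}`
#' or `{type: lognormal, sigma: x}`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    s <- y$simulate
    if (!is.null(s$noise)) {
      s$noise <- if (identical(s$noise$type, "lognormal"))
        noise_lognormal(s$noise$sigma) else noise_nb(s$noise$dispersion)
    }
    y$simulate <- do.call(sim_config, s)
  }
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate or load the matrix; (2) preprocess (low-count
#' filter and median-ratio log2 transform for counts; log2 for positive
#' continuous data); (3) rhythm detection per group with the consensus
#' rule; (4) differential-rhythm comparison with gating and class
#' assignment; (5) phase statistics (acrophase histograms, mean phase
#' shift); (6) PSEA and ORA when a GMT is supplied; (7) global and
#' time-adjusted differential expression for count data; (8) manifest.
#' Any stage failure stops with the stage name; completed stage outputs
#' are retained.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param out_dir run directory, created if needed.
#' @return the run directory, invisibly; side effect: stage TSVs plus
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  counts_mode <- FALSE
  rowcount <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # -- input
  x <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- if (config$simulate$noise$type == "nb")
        generate_counts(config$simulate) else generate_lipidome(config$simulate)
      write_timed_matrix(sim$matrix, file.path(out_dir, "matrix.tsv"),
                         file.path(out_dir, "samples.tsv"))
      rowcount$truth <- write_tsv(as.data.frame(sim$truth)[
        , c("feature", "group", "is_rhythmic", "mesor", "amplitude",
            "acrophase", "noise_param")],
        file.path(out_dir, "ground_truth.tsv"))
      sim$matrix
    } else {
      read_timed_matrix(config$matrix_path, config$sample_sheet_path,
                        config$value_kind)
    }
  })
  counts_mode <- x$value_kind == "counts"
  rowcount$input <- nrow(x$values)

  # -- preprocess
  xt <- stage("preprocess", {
    if (counts_mode) {
      xf <- filter_low_counts(x, config$min_total)
      normalize_log(xf)
    } else if (all(x$values > 0)) {
      timed_matrix(log2(x$values), x$meta, "continuous")
    } else x
  })
  rowcount$preprocess <- nrow(xt$values)
  stage("preprocess", write_timed_matrix(
    xt, file.path(out_dir, "matrix_transformed.tsv"),
    file.path(out_dir, "samples.tsv")))

  # -- detection
  calls <- stage("detect", detect_rhythms(
    xt, methods = config$methods, alpha = config$detection_alpha,
    rule = config$rule))
  rowcount$detect <- write_tsv(as.data.frame(calls),
                               file.path(out_dir, "rhythm_calls.tsv"))

  # -- differential rhythm
  drg <- stage("compare", compare_rhythms(
    xt, calls, alpha = config$comparison_alpha))
  rowcount$compare <- write_tsv(as.data.frame(drg),
                                file.path(out_dir, "diff_rhythm.tsv"))

  # -- phase statistics
  stage("phase_stats", {
    shift <- mean_phase_shift(drg)
    write_tsv(data.frame(mean_delta_phase_h = shift$mean, n = shift$n,
                         p = shift$p),
              file.path(out_dir, "phase_shift.tsv"))
    groups <- unique(calls$group)
    hist_tab <- do.call(rbind, lapply(groups, function(g) {
      ph <- calls$acrophase[calls$group == g & calls$consensus &
                              !is.na(calls$acrophase)]
      if (!length(ph)) return(NULL)
      h <- phase_histogram(ph, 4)
      data.frame(group = g, bin = names(h), n = as.integer(h))
    }))
    if (!is.null(hist_tab))
      write_tsv(hist_tab, file.path(out_dir, "phase_histogram.tsv"))
  })

  # -- enrichment
  if (!is.null(config$gmt_path)) {
    stage("enrichment", {
      if (!file.exists(config$gmt_path))
        stop("missing GMT file: ", config$gmt_path)
      sets <- read_gmt(config$gmt_path)
      groups <- unique(calls$group)
      psea_all <- do.call(rbind, lapply(groups, function(g) {
        sub <- calls[calls$group == g & calls$consensus &
                       !is.na(calls$acrophase), ]
        if (!nrow(sub)) return(NULL)
        res <- psea_kuiper(setNames(sub$acrophase, sub$feature), sets,
                           min_genes = config$psea_min_genes,
                           alpha = config$psea_alpha)
        cbind(group = g, res)
      }))
      if (!is.null(psea_all))
        rowcount$psea <- write_tsv(psea_all, file.path(out_dir, "psea.tsv"))
      if (!is.null(config$category_map_path) && !is.null(psea_all)) {
        mapping <- read.delim(config$category_map_path,
                              stringsAsFactors = FALSE)
        cats <- lapply(groups, function(g)
          merge_categories(psea_all[psea_all$group == g &
                                      psea_all$status == "ok", ], mapping))
        names(cats) <- groups
        if (length(groups) == 2) {
          dd <- category_phase_difference(cats[[1]], cats[[2]])
          write_tsv(data.frame(category = names(dd), delta_phase_h = dd),
                    file.path(out_dir, "category_phase_diff.tsv"))
        }
      }
      hits <- unique(drg$feature[nzchar(drg$classes)])
      bg <- rownames(xt$values)
      if (length(hits))
        rowcount$ora <- write_tsv(
          ora_fisher(hits, bg, sets, min_genes = config$ora_min_genes,
                     alpha = config$ora_alpha),
          file.path(out_dir, "ora.tsv"))
    })
  }

  # -- differential expression (counts only)
  if (counts_mode) {
    stage("deg", {
      xf <- filter_low_counts(x, config$min_total)
      rowcount$deg_global <- write_tsv(
        as.data.frame(nb_global_test(xf, alpha = config$deg_alpha)),
        file.path(out_dir, "deg_global.tsv"))
      rowcount$deg_lrt <- write_tsv(
        as.data.frame(nb_time_adjusted_test(xf, alpha = config$deg_alpha)),
        file.path(out_dir, "deg_time_adjusted.tsv"))
    })
  }

  # -- manifest
  stage("manifest", {
    cfg <- config
    cfg$simulate <- if (is.null(cfg$simulate)) NULL else unclass(cfg$simulate)
    cfg_yaml <- yaml::as.yaml(unclass(cfg))
    writeLines(cfg_yaml, file.path(out_dir, "config.yaml"))
    manifest <- list(
      package = "rhythmdiff",
      version = as.character(utils::packageVersion("rhythmdiff")),
      seed = config$seed,
      config_hash = unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
      rows = rowcount)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(out_dir)
}

#' Summarise a completed pipeline run
#'
#' Reads the stage outputs in a run directory and writes figure-style
#' summary tables: rhythmic counts per group with the Venn partition,
#' differential-rhythm class counts, the phase-shift summary and — when
#' the feature names parse as shorthand lipid species — the lipid class
#' distribution. Missing stages are skipped with a note in the returned
#' list.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return named list of the summary data frames (invisible); side effect:
#'   `report_*.tsv` files in `run_dir`.
#' @export
make_report <- function(run_dir) {
  out <- list()
  gaps <- character(0)
  calls_path <- file.path(run_dir, "rhythm_calls.tsv")
  if (file.exists(calls_path)) {
    calls <- read.delim(calls_path, stringsAsFactors = FALSE)
    groups <- unique(calls$group)
    rhythmic <- lapply(groups, function(g)
      calls$feature[calls$group == g & calls$consensus])
    names(rhythmic) <- groups
    venn <- if (length(groups) == 2) {
      both <- intersect(rhythmic[[1]], rhythmic[[2]])
      data.frame(group = c(groups, "both", "union"),
                 n_rhythmic = c(lengths(rhythmic),
                                length(both),
                                length(union(rhythmic[[1]], rhythmic[[2]]))))
    } else {
      data.frame(group = groups, n_rhythmic = lengths(rhythmic))
    }
    write_tsv(venn, file.path(run_dir, "report_rhythmic_counts.tsv"))
    out$rhythmic_counts <- venn

    # lipid class distribution, if names belong to the shorthand grammar
    g1 <- groups[1]
    nm <- calls$feature[calls$group == g1]
    parsed <- tryCatch({
      lipid_class_distribution(nm, calls$consensus[calls$group == g1])
    }, error = function(e) NULL)
    if (!is.null(parsed)) {
      write_tsv(parsed, file.path(run_dir, "report_lipid_classes.tsv"))
      out$lipid_classes <- parsed
    }
  } else gaps <- c(gaps, "rhythm_calls")

  drg_path <- file.path(run_dir, "diff_rhythm.tsv")
  if (file.exists(drg_path)) {
    drg <- read.delim(drg_path, stringsAsFactors = FALSE)
    drg$classes[is.na(drg$classes)] <- ""
    summ <- summarize_drg(drg)
    write_tsv(summ, file.path(run_dir, "report_drg_classes.tsv"))
    out$drg_classes <- summ
  } else gaps <- c(gaps, "diff_rhythm")

  shift_path <- file.path(run_dir, "phase_shift.tsv")
  if (file.exists(shift_path)) {
    out$phase_shift <- read.delim(shift_path, stringsAsFactors = FALSE)
  } else gaps <- c(gaps, "phase_shift")

  for (f in c("psea", "ora", "deg_global", "deg_time_adjusted")) {
    p <- file.path(run_dir, paste0(f, ".tsv"))
    if (file.exists(p)) out[[f]] <- read.delim(p, stringsAsFactors = FALSE)
  }
  if (length(gaps)) out$gaps <- gaps
  invisible(out)
}
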