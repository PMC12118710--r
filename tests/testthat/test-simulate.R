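test_that("configs validate their fields with informative messages", {
  expect_error(sim_config(fraction_rhythmic = 1.2), "fraction_rhythmic")
  expect_error(sim_config(timepoints = c(2, 25)), "timepoints")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
  expect_error(sim_config(group_labels = c("A", "A")), "group_labels")
  expect_error(noise_nb(-1), "dispersion")
  expect_error(noise_lognormal(-0.1), "sigma")
  expect_error(sim_config(fraction_affected = 2), "fraction_affected")
  expect_equal(zt_grid("ZT0"), seq(0, 20, 4))
  expect_equal(zt_grid(), seq(2, 22, 4))
})

test_that("fraction_rhythmic = 0 gives amplitude 0 everywhere", {
  sim <- generate_counts(sim_config(n_features = 100, fraction_rhythmic = 0,
                                    seed = 71))
  expect_true(all(sim$truth$amplitude == 0))
  expect_true(all(!sim$truth$is_rhythmic))
})

test_that("same config and seed reproduce bit-identical output", {
  cfg <- sim_config(n_features = 50, fraction_rhythmic = 0.4, seed = 72,
                    delta_phase = 2)
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  d <- generate_counts(sim_config(n_features = 50, fraction_rhythmic = 0.4,
                                  seed = 73, delta_phase = 2))
  expect_false(identical(a$matrix$values, d$matrix$values))
})

test_that("sample means track the ground-truth curve at low dispersion", {
  cfg <- sim_config(n_features = 4, fraction_rhythmic = 1, amplitude = 1,
                    n_replicates = 400, noise = noise_nb(1e-4), seed = 74)
  sim <- generate_counts(cfg)
  x <- sim$matrix; truth <- sim$truth
  for (f in rownames(x$values)[1:2]) {
    tw <- truth[truth$feature == f & truth$group == "WT", ]
    sel <- x$meta$group == "WT"
    means <- tapply(x$values[f, sel], x$meta$time[sel], mean)
    expected <- exp(tw$mesor + tw$amplitude *
                      cos(2 * pi * (as.numeric(names(means)) - tw$acrophase) / 24))
    expect_true(all(abs(means / expected - 1) < 0.02), info = f)
  }
})

test_that("negative-binomial noise has the right mean-variance relation", {
  cfg <- sim_config(n_features = 300, fraction_rhythmic = 0,
                    mesor = log(200), noise = noise_nb(0.1),
                    n_replicates = 6, seed = 75)
  sim <- generate_counts(cfg)
  v <- as.numeric(sim$matrix$values)
  mu <- mean(v)
  expect_equal(mu, 200, tolerance = 0.05)
  expect_equal(var(v), mu + 0.1 * mu^2, tolerance = 0.15)
})

test_that("noiseless data reproduce generator parameters through a cosinor fit", {
  cfg <- sim_config(n_features = 20, fraction_rhythmic = 1,
                    amplitude = list(min = 0.5, max = 1.5),
                    mesor = list(mean = 1, sd = 0.5),
                    noise = noise_lognormal(0), seed = 76)
  sim <- generate_lipidome(cfg)
  x <- sim$matrix; truth <- sim$truth
  sel <- x$meta$group == "WT"
  for (f in rownames(x$values)[1:10]) {
    tw <- truth[truth$feature == f & truth$group == "WT", ]
    fit <- fit_cosinor(log(x$values[f, sel]), x$meta$time[sel])
    expect_equal(fit$mesor, tw$mesor, tolerance = 1e-6, info = f)
    expect_equal(fit$amplitude, tw$amplitude, tolerance = 1e-6, info = f)
    dphi <- abs(((fit$acrophase - tw$acrophase + 12) %% 24) - 12)
    expect_lt(dphi, 1e-6)
  }
  # and the values equal the noiseless curve exactly
  tw <- truth[truth$feature == rownames(x$values)[1] & truth$group == "WT", ]
  expected <- exp(tw$mesor + tw$amplitude *
                    cos(2 * pi * (x$meta$time[sel] - tw$acrophase) / 24))
  expect_equal(unname(x$values[1, sel]), expected, tolerance = 1e-12)
})

test_that("lipidome features are valid names from the palette, 285 by default", {
  palette <- c("TG", "DG", "PC", "Cer")
  cfg <- sim_config(n_features = 285, mesor = list(mean = 0, sd = 1),
                    noise = noise_lognormal(0.2), seed = 77)
  sim <- generate_lipidome(cfg, class_palette = palette)
  expect_equal(nrow(sim$matrix$values), 285)
  classes <- vapply(rownames(sim$matrix$values),
                    function(nm) parse_lipid_name(nm)$lipid_class, character(1))
  expect_true(all(classes %in% palette))
  expect_true(all(sim$matrix$values > 0))
  expect_error(generate_lipidome(cfg, class_palette = character(0)),
               "class_palette")
  expect_error(generate_lipidome(sim_config(noise = noise_nb(0.1))), "noise")
})

test_that("ground truth tables round trip through TSV", {
  sim <- generate_counts(sim_config(n_features = 15, seed = 78))
  p <- tempfile(fileext = ".tsv")
  write_ground_truth(sim$truth, p)
  back <- read_ground_truth(p)
  expect_equal(back$feature, sim$truth$feature)
  expect_equal(back$is_rhythmic, sim$truth$is_rhythmic)
  expect_equal(back$mesor, sim$truth$mesor, tolerance = 1e-12)
  expect_equal(back$acrophase, sim$truth$acrophase, tolerance = 1e-12)
  # fixed schema width
  expect_equal(ncol(read.delim(p)), 7)
  # empty truth -> header-only file
  write_ground_truth(sim$truth[0, ], p)
  expect_equal(length(readLines(p)), 1)
})

test_that("truth invariants hold across random configs", {
  set.seed(79)
  for (i in 1:5) {
    cfg <- sim_config(n_features = 40, fraction_rhythmic = runif(1),
                      delta_phase = list(min = -3, max = 3),
                      delta_amplitude = list(mean = 0, sd = 0.3),
                      seed = 80 + i)
    truth <- generate_counts(cfg)$truth
    expect_true(all(truth$acrophase >= 0 & truth$acrophase < 24))
    expect_true(all(truth$amplitude >= 0))
    # amplitude 0 implies not rhythmic
    expect_true(all(!truth$is_rhythmic[truth$amplitude == 0]))
  }
})
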