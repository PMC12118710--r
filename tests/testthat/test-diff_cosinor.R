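curve24 <- function(t, M, A, phi) M + A * cos(2 * pi * (t - phi) / 24)

test_that("identical groups give zero contrasts and null p-values", {
  set.seed(21)
  t <- design_t()
  y <- curve24(t, 3, 2, 8) + rnorm(18, 0, 0.3)
  fd <- fit_differential_cosinor(y, t, y, t)
  expect_equal(fd$delta_mesor, 0, tolerance = 1e-4)
  expect_equal(fd$delta_amplitude, 0, tolerance = 1e-4)
  expect_equal(fd$delta_phase, 0, tolerance = 1e-4)
  expect_gt(fd$p_mesor, 0.99)
  expect_gt(fd$p_amplitude, 0.99)
  expect_gt(fd$p_phase, 0.99)
})

test_that("a constructed mesor difference is isolated in the mesor contrast", {
  t <- design_t()
  set.seed(22)
  eps <- rnorm(18, 0, 1e-8)
  y1 <- curve24(t, 3, 2, 8) + eps
  y2 <- curve24(t, 4, 2, 8) + eps
  fd <- fit_differential_cosinor(y1, t, y2, t)
  expect_equal(fd$delta_mesor, 1, tolerance = 1e-6)
  expect_equal(fd$delta_amplitude, 0, tolerance = 1e-6)
  expect_equal(fd$delta_phase, 0, tolerance = 1e-6)
  expect_lt(fd$p_mesor, 1e-10)
})

test_that("joint fit matches the separate-fits + delta-method oracle", {
  set.seed(23)
  t <- design_t()
  for (i in 1:6) {
    y1 <- curve24(t, 3, 2, 8) + rnorm(18, 0, 0.4)
    y2 <- curve24(t, 3.5, 2.5, 12) + rnorm(18, 0, 0.4)
    fd <- fit_differential_cosinor(y1, t, y2, t)
    oracle <- separate_fits_oracle(y1, t, y2, t)
    expect_equal(fd$delta_mesor, oracle$dM, tolerance = 1e-5)
    expect_equal(fd$delta_amplitude, oracle$dA, tolerance = 1e-4)
    expect_equal(fd$delta_phase, oracle$dphi, tolerance = 1e-4)
    expect_equal(unname(fd$se["dM"]), oracle$se_dM, tolerance = 0.05)
    expect_equal(unname(fd$se["dphi"]), oracle$se_dphi, tolerance = 0.05)
  }
})

test_that("a 4-hour phase delay is recovered within its confidence interval", {
  set.seed(24)
  t <- design_t()
  hits <- 0
  ests <- replicate(40, {
    y1 <- curve24(t, 3, 2, 6) + rnorm(18, 0, 0.4)
    y2 <- curve24(t, 3, 2, 10) + rnorm(18, 0, 0.4)
    fd <- fit_differential_cosinor(y1, t, y2, t)
    fd$delta_phase
  })
  expect_equal(mean(ests), 4, tolerance = 0.2)
  expect_lt(sd(ests), 1)
})

test_that("phase contrast is suppressed when an amplitude is ~0", {
  set.seed(25)
  t <- design_t()
  y1 <- rep(3, 18) + rnorm(18, 0, 1e-10)   # flat group
  y2 <- curve24(t, 3, 2, 8)
  fd <- fit_differential_cosinor(y1, t, y2, t)
  expect_true(is.na(fd$p_phase) || fd$amplitude1 > 1e-8)
})

test_that("with the phase difference fixed at zero the linear limit holds", {
  # equal true phases: the constrained joint fit reduces to per-group
  # linear cosinor fits on a balanced grid
  t <- design_t()
  y1 <- curve24(t, 3, 2, 8)
  y2 <- curve24(t, 4.2, 1.1, 8)
  fd <- fit_differential_cosinor(y1, t, y2, t, fix_dphi = TRUE)
  f1 <- fit_cosinor(y1, t); f2 <- fit_cosinor(y2, t)
  expect_equal(fd$delta_mesor, f2$mesor - f1$mesor, tolerance = 1e-6)
  expect_equal(fd$delta_amplitude, f2$amplitude - f1$amplitude, tolerance = 1e-6)
  expect_equal(fd$delta_phase, 0)
})

test_that("compare_rhythms gates contrasts by rhythmicity calls", {
  set.seed(26)
  cfg <- sim_config(n_features = 60, fraction_rhythmic = 0.5,
                    amplitude = list(min = 1, max = 2),
                    delta_phase = 2, fraction_affected = 1, seed = 41)
  sim <- generate_counts(cfg)
  xt <- normalize_log(sim$matrix)
  calls <- detect_rhythms(xt)
  drg <- compare_rhythms(xt, calls)

  # only features rhythmic in >= 1 group are present
  rtab <- with(calls, tapply(consensus, feature, any))
  expect_true(all(rtab[drg$feature]))
  # phase contrast only for features rhythmic in both groups
  both <- with(calls, tapply(consensus, feature, all))
  expect_true(all(is.na(drg$delta_phase[!both[drg$feature]])))
  # no phase class without both-group rhythmicity
  phase_classed <- grepl("phase", drg$classes)
  expect_true(all(both[drg$feature][phase_classed]))
  # all reported phase differences wrapped into (-12, 12]
  dp <- drg$delta_phase[!is.na(drg$delta_phase)]
  expect_true(all(dp > -12 & dp <= 12))
})

test_that("swapping group labels negates contrasts and mirrors classes", {
  set.seed(27)
  cfg <- sim_config(n_features = 30, fraction_rhythmic = 1,
                    amplitude = list(min = 1, max = 2),
                    delta_mesor = 0.5, fraction_affected = 1, seed = 55)
  sim <- generate_counts(cfg)
  xt <- normalize_log(sim$matrix)
  calls <- detect_rhythms(xt)
  drg <- compare_rhythms(xt, calls)

  # same data, reference group reversed
  drg2 <- compare_rhythms(xt, calls, group_order = c("KO", "WT"))
  m <- match(drg$feature, drg2$feature)
  expect_equal(drg2$delta_mesor[m], -drg$delta_mesor, tolerance = 1e-4)
  expect_equal(drg2$delta_amplitude[m], -drg$delta_amplitude, tolerance = 1e-4)
  up1 <- grepl("mesor_up", drg$classes)
  down2 <- grepl("mesor_down", drg2$classes[m])
  expect_equal(up1, down2)
})

test_that("DRG summary counts class combinations consistently", {
  tab <- data.frame(feature = c("a", "b", "c"),
                    classes = c("mesor_up", "mesor_up+phase_delay", ""),
                    stringsAsFactors = FALSE)
  s <- summarize_drg(tab)
  expect_equal(s$n[s$combination == "mesor_up"], 1)
  expect_equal(s$n[s$combination == "mesor_up+phase_delay"], 1)
  expect_equal(sum(s$n), 2)
  per <- attr(s, "per_class")
  expect_equal(unname(per["mesor_up"]), 2)   # appears in two combinations
  expect_equal(nrow(summarize_drg(tab[3, , drop = FALSE])), 0)
})

test_that("mean phase shift wraps, averages and tests against zero", {
  expect_equal(mean_phase_shift(rep(0.4, 5))$mean, 0.4)
  # wrap: 23.9 -> 0.1 is +0.2, not -23.8
  expect_equal(mean_phase_shift(0.1 - 23.9)$mean, 0.2, tolerance = 1e-12)
  sym <- mean_phase_shift(c(-1.5, 1.5, -0.7, 0.7))
  expect_equal(sym$mean, 0, tolerance = 1e-12)
  expect_gt(sym$p, 0.95)
  expect_true(is.na(mean_phase_shift(numeric(0))$p))
  one <- mean_phase_shift(2.5)
  expect_equal(one$mean, 2.5)
  expect_true(is.na(one$p))
  w <- mean_phase_shift(c(0.5, 0.3, 0.6, 0.4, 0.2), test = "wilcoxon")
  expect_lt(w$p, 0.1)
})
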