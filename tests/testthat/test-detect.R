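test_that("JTK-style test: perfect concordance, anti-phase, constants", {
  t <- rep(c(0, 4, 8, 12, 16, 20), each = 3)
  y <- cos(2 * pi * (t - 8) / 24)
  p_in <- jtk_test(y + rnorm(18, 0, 1e-6), t)
  expect_lt(p_in, 0.001)
  # anti-phase cosine scores the same because the lag grid covers the cycle
  p_anti <- jtk_test(-y + rnorm(18, 0, 1e-6), t)
  expect_lt(p_anti, 0.001)
  expect_equal(jtk_test(rep(2, 18), t), 1)
  expect_error(jtk_test(rnorm(4), c(0, 6, 12, 18)), "at least 6")
})

test_that("JTK exact null matches full permutation enumeration at n = 6", {
  # distinct times whose cosine reference values are untied
  t <- c(0, 3, 7, 11, 16, 21)
  ref <- cos(2 * pi * (t - 0) / 24)
  expect_equal(length(unique(ref)), 6)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  # exact tail from the package's enumeration
  tail_fn <- rhythmdiff:::kendall_exact_tail(6)
  # brute force: distribution of Kendall S over all 720 permutations
  S_all <- apply(perms, 1, function(pr) {
    s <- 0
    for (i in 1:5) for (j in (i + 1):6)
      s <- s + sign(pr[j] - pr[i]) * sign(ref[j] - ref[i])
    s
  })
  for (s in sort(unique(S_all)))
    expect_equal(tail_fn(s), mean(S_all >= s), tolerance = 1e-12,
                 info = paste("S =", s))
})

test_that("single-lag exact p-values are uniform on their attainable support", {
  t <- c(0, 3, 7, 11, 16, 21)
  ref <- cos(2 * pi * t / 24)
  tail_fn <- rhythmdiff:::kendall_exact_tail(6)
  set.seed(5)
  p <- replicate(3000, {
    y <- sample(6)
    ks <- rhythmdiff:::kendall_s(y, ref)
    tail_fn(ks$S)
  })
  # each attainable p-value q occurs with probability q - next smaller q
  support <- sort(unique(p))
  cum <- vapply(support, function(q) mean(p <= q), numeric(1))
  expect_lt(max(abs(cum - support)), 0.03)
})

test_that("Lomb-Scargle test: signal, centering invariance, null calibration", {
  t <- design_t()
  y <- cos(2 * pi * (t - 3) / 24)
  expect_lt(lomb_scargle_test(y, t), 1e-8)
  yn <- y + rnorm(18, 0, 0.2)
  expect_equal(lomb_scargle_test(yn, t), lomb_scargle_test(yn + 100, t),
               tolerance = 1e-12)
  expect_equal(lomb_scargle_test(rep(1, 18), t), 1)
  set.seed(404)
  p <- replicate(3000, lomb_scargle_test(rnorm(18), t))
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
  expect_lt(abs(mean(p < 0.01) - 0.01), 0.008)
})

test_that("consensus rules apply thresholds and stay monotone", {
  p <- rbind(c(0.005, 0.5, 0.5),
             c(0.02, 0.02, 0.02),
             c(0.5, 0.5, 0.5))
  expect_equal(consensus_rhythmicity(p, alpha = 0.01, rule = "any"),
               c(TRUE, FALSE, FALSE))
  expect_equal(consensus_rhythmicity(p, alpha = 0.05, rule = "majority"),
               c(FALSE, TRUE, FALSE))
  expect_equal(consensus_rhythmicity(p, alpha = 0.05, rule = "all"),
               c(FALSE, TRUE, FALSE))
  # adding a method never shrinks the "any" rhythmic set
  set.seed(1)
  p2 <- matrix(runif(300), 100, 3)
  before <- consensus_rhythmicity(p2[, 1:2], alpha = 0.05, rule = "any")
  after <- consensus_rhythmicity(p2, alpha = 0.05, rule = "any")
  expect_true(all(after[before]))
  # NA-only rows are not rhythmic
  expect_false(consensus_rhythmicity(matrix(NA_real_, 1, 3), 0.01, "any"))
})

test_that("detect_rhythms runs per group, flags bad rows, and handles empties", {
  set.seed(9)
  cfg <- sim_config(n_features = 40, fraction_rhythmic = 0.5,
                    amplitude = list(min = 1.5, max = 2), seed = 33)
  sim <- generate_counts(cfg)
  xt <- normalize_log(sim$matrix)
  calls <- detect_rhythms(xt, alpha = 0.01)
  expect_equal(nrow(calls), 80)   # 40 features x 2 groups
  expect_setequal(unique(calls$group), c("WT", "KO"))

  # strong rhythmic features are detected at high rate
  truth <- sim$truth
  rhy <- truth$feature[truth$group == "WT" & truth$is_rhythmic]
  hit <- calls$consensus[calls$group == "WT" & calls$feature %in% rhy]
  expect_gt(mean(hit), 0.9)

  # non-finite feature rows are flagged, not fatal
  xt$values[3, 2] <- NA   # sample 2 belongs to the first group
  g_bad <- xt$meta$group[2]
  calls2 <- detect_rhythms(xt)
  bad <- calls2[calls2$feature == rownames(xt$values)[3] &
                  calls2$group == g_bad, ]
  expect_true(all(bad$status == "non-finite values"))
  expect_true(all(is.na(bad$p_cosinor)))
  expect_false(any(bad$consensus))

  # empty matrix -> empty table
  empty <- timed_matrix(xt$values[0, , drop = FALSE], xt$meta, "continuous")
  expect_equal(nrow(detect_rhythms(empty)), 0)
})

test_that("detector p-values are unchanged by time rotation and scaling", {
  set.seed(77)
  t <- design_t()
  y <- 2 + cos(2 * pi * (t - 10) / 24) + rnorm(18, 0, 0.5)
  delta <- 4    # a rotation that maps the sampling grid onto itself
  expect_equal(jtk_test(y, (t + delta) %% 24), jtk_test(y, t), tolerance = 1e-12)
  expect_equal(lomb_scargle_test(y, (t + delta) %% 24), lomb_scargle_test(y, t),
               tolerance = 1e-9)
  expect_equal(jtk_test(5 * y, t), jtk_test(y, t), tolerance = 1e-12)
  expect_equal(lomb_scargle_test(5 * y, t), lomb_scargle_test(y, t),
               tolerance = 1e-12)
})
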