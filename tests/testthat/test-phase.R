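test_that("phase histogram partitions [0,24) and conserves counts", {
  h <- phase_histogram(c(1, 2, 3), 4)
  expect_equal(unname(h["[0,4)"]), 3)
  expect_equal(sum(h), 3)
  h24 <- phase_histogram(0:23, 4)
  expect_true(all(h24 == 4))
  expect_equal(sum(phase_histogram(runif(57, 0, 24), 6)), 57)
  expect_error(phase_histogram(c(1, 2), 5), "divide")
})

test_that("circular median matches the exhaustive-scan oracle", {
  expect_equal(circular_median_hours(c(2, 4, 6)), 4)
  expect_equal(circular_median_hours(c(23, 0, 1)), 0)   # wrap-aware, not 8
  set.seed(31)
  for (i in 1:50) {
    h <- runif(sample(3:15, 1), 0, 24)
    got <- circular_median_hours(h)
    # oracle: brute-force over member candidates with circular distance
    dev <- vapply(h, function(c0)
      sum(pmin(abs(h - c0), 24 - abs(h - c0))), numeric(1))
    best <- min(dev)
    cands <- sort(h[dev <= best + 1e-12])
    expect_equal(got, cands[1], info = paste("case", i))
  }
})

test_that("circular mean averages on the circle", {
  expect_equal(circular_mean_hours(c(4, 6)), 5, tolerance = 1e-12)
  expect_equal(circular_mean_hours(c(23, 1)), 0, tolerance = 1e-12)
})

test_that("Kuiper test detects concentration and is rotation invariant", {
  set.seed(32)
  bg <- runif(5000, 0, 24)
  tight <- runif(50, 10, 12)
  expect_lt(kuiper_two_sample(tight, bg)$p.value, 1e-6)
  # rotation invariance of the statistic
  v0 <- kuiper_two_sample(tight, bg)$statistic
  for (delta in c(3.3, 11, 17.8))
    expect_equal(kuiper_two_sample((tight + delta) %% 24, (bg + delta) %% 24)$statistic,
                 v0, tolerance = 1e-12)
  # symmetric in the two samples
  expect_equal(kuiper_two_sample(bg, tight)$statistic, v0, tolerance = 1e-12)
})

test_that("Kuiper p-values are roughly uniform for random subsamples", {
  set.seed(33)
  p <- replicate(400, {
    bg <- runif(800, 0, 24)
    idx <- sample(800, 40)
    kuiper_two_sample(bg[idx], bg[-idx])$p.value
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.035)
  expect_gt(mean(p), 0.4)
})

test_that("PSEA reports set phases, skips small sets and flags enrichment", {
  set.seed(34)
  features <- sprintf("g%03d", 1:400)
  phases <- setNames(runif(400, 0, 24), features)
  phases[1:30] <- rnorm(30, 6, 0.5) %% 24       # concentrated set
  sets <- list(focal = features[1:30],
               random = features[sample(31:400, 50)],
               tiny = features[1:4])
  attr(sets$focal, "description") <- "concentrated at ZT6"
  res <- psea_kuiper(phases, sets, min_genes = 10, alpha = 0.01)
  expect_true(res$significant[res$set == "focal"])
  expect_identical(res$status[res$set == "tiny"], "skipped: too few members")
  expect_true(is.na(res$p[res$set == "tiny"]))
  expect_false(res$significant[res$set == "random"])
  # set phase is the circular median of (rounded) member phases
  sp <- res$set_phase[res$set == "focal"]
  expect_lt(abs(((sp - 6 + 12) %% 24) - 12), 1.5)
})

test_that("category merging uses circular means and warns on unknown sets", {
  res <- data.frame(set = c("p1", "p2", "p3"),
                    set_phase = c(4, 6, 23), stringsAsFactors = FALSE)
  mapping <- data.frame(set = c("p1", "p2", "p3", "ghost"),
                        category = c("metabolism", "metabolism", "immune", "immune"),
                        stringsAsFactors = FALSE)
  expect_warning(cats <- merge_categories(res, mapping), "ghost")
  expect_equal(unname(cats["metabolism"]), 5, tolerance = 1e-12)
  expect_equal(unname(cats["immune"]), 23, tolerance = 1e-12)
  # wrap-aware average
  res2 <- data.frame(set = c("a", "b"), set_phase = c(23, 1))
  cats2 <- merge_categories(res2, data.frame(set = c("a", "b"), category = "c"))
  expect_equal(unname(cats2["c"]), 0, tolerance = 1e-12)
  expect_length(merge_categories(res, mapping[0, ]), 0)
})

test_that("category phase differences wrap and omit unshared categories", {
  g1 <- c(metabolism = 10, immune = 6, lost = 2)
  g2 <- c(metabolism = 13.5, immune = 0)
  expect_warning(d <- category_phase_difference(g1, g2), "lost")
  expect_equal(unname(d["metabolism"]), 3.5)   # delay
  expect_equal(unname(d["immune"]), -6)        # advance
  expect_equal(unname(category_phase_difference(c(x = 7), c(x = 7))["x"]), 0)
})

test_that("hypergeometric ORA equals exact tail enumeration", {
  # N=20 universe, set of 5, 4 hits, overlap 3 -> 155/4845
  bg <- sprintf("f%02d", 1:20)
  sets <- list(s = bg[1:5])
  hits <- c(bg[1:3], bg[10])
  res <- ora_fisher(hits, bg, sets, min_genes = 3)
  expect_equal(res$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(res$p, hyper_tail_enum(3, 5, 20, 4), tolerance = 1e-12)

  # random toy instances with universe <= 30 against the enumeration oracle
  set.seed(36)
  for (i in 1:25) {
    N <- sample(10:30, 1)
    bgU <- sprintf("u%02d", 1:N)
    K <- sample(3:(N - 2), 1)
    n <- sample(3:(N - 2), 1)
    st <- list(s = sample(bgU, K))
    ht <- sample(bgU, n)
    ov <- length(intersect(st$s, ht))
    res <- ora_fisher(ht, bgU, st, min_genes = 0)
    if (nrow(res))
      expect_equal(res$p, hyper_tail_enum(ov, K, N, n), tolerance = 1e-10,
                   info = sprintf("N=%d K=%d n=%d ov=%d", N, K, n, ov))
  }

  # cutoff: overlap below min_genes is not reported
  expect_equal(nrow(ora_fisher(bg[10:12], bg, list(s = bg[1:5]), min_genes = 3)), 0)
  # saturation: hits = background -> p = 1 for every set
  sat <- ora_fisher(bg, bg, list(s = bg[1:5]), min_genes = 3)
  expect_equal(sat$p, 1)
  # hits outside the background are an error naming the offenders
  expect_error(ora_fisher(c("zz", bg[1:3]), bg, sets), "zz")
})
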