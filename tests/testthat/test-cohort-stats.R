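test_that("normality gate routes clearly non-normal and normal samples", {
  withr::with_seed(1, u <- runif(500))
  expect_equal(shapiro_wilk_gate(u)$verdict, "non_normal")
  withr::with_seed(2, g <- rnorm(500))
  expect_equal(shapiro_wilk_gate(g)$verdict, "normal")
  expect_error(shapiro_wilk_gate(c(1, 2)), class = "ctces_error_sample_size")
  expect_error(shapiro_wilk_gate(rep(3, 10)), class = "ctces_error_degenerate")
})

test_that("Mann-Whitney matches exact enumeration and is symmetric", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$u, 0)
  expect_equal(sep$method, "exact")

  withr::with_seed(5, {
    a <- round(rnorm(5), 3)
    b <- round(rnorm(6) + 0.8, 3)
  })
  got <- mann_whitney(a, b)
  want <- oracle_mw(a, b)
  # wilcox.test's W counts wins of the first sample: a > b pairs
  expect_equal(got$u, sum(outer(a, b, `>`)))
  expect_equal(got$p, want$p, tolerance = 1e-12)

  swapped <- mann_whitney(b, a)
  expect_equal(swapped$u, length(a) * length(b) - got$u)
  expect_equal(swapped$p, got$p)

  big <- mann_whitney(rnorm(20), rnorm(20))
  expect_equal(big$method, "normal_approx")
  expect_error(mann_whitney(numeric(), 1:3), class = "ctces_error_sample_size")
})

test_that("Kruskal-Wallis is rank-based with chi-square reference", {
  same <- kruskal_wallis(list(1:5, 1:5, 1:5))
  expect_equal(same$h, 0, tolerance = 1e-12)

  withr::with_seed(7, {
    a <- rnorm(200)
    b <- rnorm(200) + 0.3
  })
  kw <- kruskal_wallis(list(a, b))
  mw <- mann_whitney(a, b)
  expect_equal(kw$p, mw$p, tolerance = 0.02)

  g <- list(rexp(30), rexp(30) * 2, rexp(30))
  expect_equal(kruskal_wallis(g)$h,
               kruskal_wallis(lapply(g, log))$h)  # monotone invariance
  expect_error(kruskal_wallis(list(1:3)), class = "ctces_error_sample_size")
  expect_error(kruskal_wallis(list(1:3, numeric())),
               class = "ctces_error_sample_size")
})

test_that("per-bin scan finds constructed bands and stays quiet under the null", {
  co <- simulate_cohort(cohort_spec(seed = 11))
  scan <- per_bin_scan(co$subjects[co$manifest$group == "severe", ],
                       co$subjects[co$manifest$group == "mild", ])
  best <- primary_band(scan)
  expect_true(best$lo <= 24 && best$hi >= 17)
  # bands are disjoint, sorted, maximal, and only contain significant bins
  if (nrow(scan$bands) > 1) {
    expect_true(all(diff(scan$bands$lo) > 0))
    expect_true(all(scan$bands$lo[-1] > scan$bands$hi[-nrow(scan$bands)] + 1))
  }
  sig <- scan$p_values$p < scan$alpha
  for (i in seq_len(nrow(scan$bands))) {
    expect_true(all(sig[(scan$bands$lo[i]:scan$bands$hi[i]) + 1L]))
  }

  null_long <- vapply(1:10, function(s) {
    con <- simulate_cohort(cohort_spec(band_mass_shift = 0, seed = 100 + s))
    sc <- per_bin_scan(con$subjects[31:60, ], con$subjects[1:30, ])
    if (nrow(sc$bands)) max(sc$bands$width) else 0L
  }, numeric(1))
  expect_gte(mean(null_long <= 3), 0.9)

  expect_equal(nrow(per_bin_scan(co$subjects[1:30, ], co$subjects[31:60, ],
                                 alpha = 0)$bands), 0L)
  expect_error(per_bin_scan(co$subjects[1, , drop = FALSE], co$subjects[3:9, ]),
               class = "ctces_error_sample_size")
})

test_that("ROC curve is the empirical >= classifier sweep", {
  roc <- roc_curve(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc$auc, 1)

  withr::with_seed(21, {
    s <- rnorm(1000)
    l <- rbinom(1000, 1, 0.5)
  })
  expect_equal(roc_curve(s, l)$auc, 0.5, tolerance = 0.05)

  # AUC equals the Mann-Whitney concordance U/(n1*n2) on tie-free scores
  withr::with_seed(22, {
    s2 <- rnorm(60)
    l2 <- rep(c(TRUE, FALSE), 30)
  })
  u <- mann_whitney(s2[l2], s2[!l2])$u
  expect_equal(roc_curve(s2, l2)$auc, u / (30 * 30), tolerance = 1e-12)

  # invariance under strictly monotone transform
  expect_equal(roc_curve(exp(s2), l2)$auc, roc_curve(s2, l2)$auc)

  # cross-check against an independent ROC implementation
  ref <- suppressMessages(pROC::roc(l2, s2, direction = "<", quiet = TRUE))
  expect_equal(roc_curve(s2, l2)$auc, as.numeric(ref$auc), tolerance = 1e-12)

  expect_error(roc_curve(1:5, rep(TRUE, 5)), class = "ctces_error_single_class")
})

test_that("cutoff selection maximises Youden J with deterministic tie-breaks", {
  perfect <- roc_curve(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  best <- select_cutoff(perfect)
  expect_equal(best$j, 1)
  expect_equal(best$sensitivity, 1)
  expect_equal(best$specificity, 1)

  for (s in 1:8) {
    withr::with_seed(300 + s, {
      sc <- round(rnorm(40), 2)
      lb <- rbinom(40, 1, 0.5) == 1
    })
    if (!any(lb) || all(lb)) next
    got <- select_cutoff(roc_curve(sc, lb))
    want <- oracle_best_cutoff(sc, lb)
    expect_equal(got$cutoff, unname(want["cutoff"]))
    expect_equal(got$sensitivity, unname(want["sensitivity"]))
    expect_equal(got$specificity, unname(want["specificity"]))
  }

  flat <- select_cutoff(roc_curve(rep(4, 10), rep(c(TRUE, FALSE), 5)))
  expect_equal(flat$j, 0)
  expect_equal(flat$cutoff, 4)
})

test_that("predictive values tally the confusion matrix at >= cutoff", {
  pv <- predictive_values(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE), 5)
  expect_equal(pv$ppv, 1)
  expect_equal(pv$npv, 1)

  withr::with_seed(31, {
    sc <- runif(50)
    lb <- rbinom(50, 1, 0.3) == 1
  })
  got <- predictive_values(sc, lb, 0.4)
  want <- oracle_confusion(sc, lb, 0.4)
  expect_equal(c(got$tp, got$fp, got$tn, got$fn), unname(want))

  # low prevalence with a weak score: high NPV, low PPV
  withr::with_seed(32, {
    lab <- c(rep(TRUE, 8), rep(FALSE, 37))
    sco <- rnorm(45) + 0.8 * lab
  })
  cut <- select_cutoff(roc_curve(sco, lab))$cutoff
  pv2 <- predictive_values(sco, lab, cut)
  expect_gt(pv2$npv, pv2$ppv)

  none <- predictive_values(c(1, 2), c(TRUE, FALSE), 10)
  expect_true(is.na(none$ppv))
  expect_error(predictive_values(1:4, rep(FALSE, 4), 2),
               class = "ctces_error_single_class")
})

test_that("categorical tests pick Fisher for sparse tables, chi-square otherwise", {
  extreme <- categorical_test(matrix(c(10, 0, 0, 10), 2))
  expect_lt(extreme$p, 0.001)

  # perfectly balanced table: no association, p = 1 (expected counts sit
  # exactly on the Fisher/chi-square boundary and route to chi-square)
  indep <- categorical_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(indep$p, 1)
  sparse <- categorical_test(matrix(c(2, 5, 6, 1), 2))
  expect_equal(sparse$method, "fisher")

  for (s in 1:5) {
    withr::with_seed(400 + s, tab <- matrix(rpois(4, 3), 2))
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- categorical_test(tab)
    if (got$method == "fisher") {
      expect_equal(got$p, oracle_fisher_2x2(tab), tolerance = 1e-9)
    }
  }

  big <- matrix(c(30, 20, 20, 30), 2)
  expect_equal(categorical_test(big)$method, "chi_square")
  expect_equal(categorical_test(big)$statistic,
               unname(chisq.test(big, correct = FALSE)$statistic))
  expect_error(categorical_test(matrix(0, 2, 2)),
               class = "ctces_error_degenerate")
})
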