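test_that("roc_auc handles separation, ties, and the 7/9 worked case", {
  expect_equal(roc_auc(c(1, 2, 3, 4, 5, 6),
                       rep(c("normal", "glaucoma"), each = 3)), 1)
  expect_equal(roc_auc(rep(2, 10), rep(c("normal", "glaucoma"), 5)), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 2, 3, 4),
                       rep(c("normal", "glaucoma"), each = 3)), 7 / 9)
  expect_error(roc_auc(1:5, rep("normal", 5)), "both classes")
})

test_that("roc_auc equals the exhaustive pairwise oracle and is rank-invariant", {
  set.seed(61)
  for (i in 1:25) {
    n0 <- sample(5:60, 1); n1 <- sample(5:60, 1)
    scores <- c(sample(1:8, n1, TRUE) + runif(n1) * (i %% 2),
                sample(1:8, n0, TRUE) + runif(n0) * (i %% 2))
    labels <- rep(c("glaucoma", "normal"), c(n1, n0))
    a <- roc_auc(scores, labels)
    expect_equal(a, auc_oracle(scores, labels), tolerance = 1e-12)
    # strictly increasing transform leaves the AUC untouched
    expect_equal(roc_auc(exp(scores / 3), labels), a, tolerance = 1e-12)
    expect_equal(roc_auc(rank(scores, ties.method = "average"), labels), a,
                 tolerance = 1e-12)
  }
})

test_that("delong_test agrees with pROC and respects invariances", {
  set.seed(62)
  n <- 60
  labels <- rep(c("normal", "glaucoma"), each = n)
  a <- c(rnorm(n), rnorm(n, 1))
  b <- 0.6 * a + 0.8 * c(rnorm(n), rnorm(n, 0.5))
  dl <- delong_test(a, b, labels)
  r1 <- pROC::roc(labels, a, levels = c("normal", "glaucoma"),
                  direction = "<", quiet = TRUE)
  r2 <- pROC::roc(labels, b, levels = c("normal", "glaucoma"),
                  direction = "<", quiet = TRUE)
  pp <- pROC::roc.test(r1, r2, method = "delong")
  expect_equal(dl$p_value, pp$p.value, tolerance = 1e-9)
  expect_equal(dl$auc_a, as.numeric(pROC::auc(r1)), tolerance = 1e-12)

  # identical scores and monotone transforms of them: difference 0, p = 1
  same <- delong_test(a, a, labels)
  expect_equal(same$diff, 0); expect_equal(same$p_value, 1)
  lin <- delong_test(a, 2 * a + 7, labels)
  expect_equal(lin$diff, 0); expect_equal(lin$p_value, 1)

  expect_error(delong_test(a, b[1:10], labels), "paired")
})

test_that("delong_se matches pROC's variance for a single AUC", {
  set.seed(63)
  labels <- rep(c("normal", "glaucoma"), each = 40)
  s <- c(rnorm(40), rnorm(40, 0.8))
  ours <- delong_se(s, labels)
  r <- pROC::roc(labels, s, levels = c("normal", "glaucoma"),
                 direction = "<", quiet = TRUE)
  expect_equal(unname(ours["se"]^2), pROC::var(r), tolerance = 1e-12)
})

test_that("sensitivity_at_specificity uses the conservative empirical cut", {
  labels <- rep(c("normal", "glaucoma"), each = 100)
  scores <- c(seq_len(100), seq_len(100) + 200)   # perfect separation
  expect_equal(as.numeric(sensitivity_at_specificity(scores, labels, 0.95)), 1)
  expect_equal(as.numeric(sensitivity_at_specificity(scores, labels, 0.99)), 1)
  # cases distributed as the normals: sensitivity ~ 1 - spec on average
  set.seed(64)
  sens_null <- replicate(20, {
    s0 <- c(rnorm(100), rnorm(100))
    as.numeric(sensitivity_at_specificity(s0, labels, 0.95))
  })
  expect_lt(abs(mean(sens_null) - 0.05), 0.03)
  s0 <- c(rnorm(100), rnorm(100))
  # monotone: the stricter specificity can never have higher sensitivity
  for (i in 1:10) {
    s <- c(rnorm(100), rnorm(100, runif(1, 0, 2)))
    expect_lte(as.numeric(sensitivity_at_specificity(s, labels, 0.99)),
               as.numeric(sensitivity_at_specificity(s, labels, 0.95)))
  }
  expect_error(sensitivity_at_specificity(s0, labels, 1.2), "in \\(0, 1\\)")
})

test_that("combine_indices averages sign-aligned z-scores", {
  set.seed(65)
  normals <- tibble::tibble(TCV = rnorm(50, 5, 1), PSDr = rnorm(50, 2, 0.5))
  stats <- reference_cohort_stats(normals, c("TCV", "PSDr"))
  mt <- stats$mean[1]; st <- stats$sd[1]
  mp <- stats$mean[2]; sp <- stats$sd[2]
  rec <- tibble::tibble(TCV = mt + st, PSDr = mp + 3 * sp)
  out <- combine_indices(rec, c("TCV", "PSDr"), stats)
  expect_equal(out$combined_z, 2)        # mean of z = (1, 3)
  expect_equal(combine_indices(rec, "TCV", stats)$combined_z, 1)
  # duplicated index collapses to the single z
  expect_equal(combine_indices(rec, c("TCV", "TCV"), stats)$combined_z, 1)
  # missing handling
  rec2 <- tibble::tibble(TCV = NA_real_, PSDr = mp + sp)
  expect_equal(combine_indices(rec2, c("TCV", "PSDr"), stats)$combined_z, 1)
  expect_true(is.na(combine_indices(rec2, c("TCV", "PSDr"), stats,
                                    na_policy = "strict")$combined_z))
})

test_that("cohort_roc reports AUC/CI/sensitivities per index and combination", {
  co <- make_cohort(cohort_spec(150, 120, d = c(2, 1), rho = 0.3,
                                indices = c("GDF", "TCV"), seed = 66))
  roc <- cohort_roc(co, c("GDF", "TCV"),
                    combinations = list(`GDF+TCV` = c("GDF", "TCV")))
  expect_equal(roc$index, c("GDF", "TCV", "GDF+TCV"))
  expect_true(all(roc$auc >= 0 & roc$auc <= 1))
  expect_true(all(roc$ci_lo <= roc$auc & roc$auc <= roc$ci_hi))
  expect_true(all(roc$sens99 <= roc$sens95))
  expect_gt(roc$auc[roc$index == "GDF"], roc$auc[roc$index == "TCV"])
  g <- glance(roc)
  expect_equal(g$n_indices, 3)
  td <- tidy(roc)
  expect_false(inherits(td, "onhe_roc"))
})

test_that("compare_dependent_correlations: Steiger test and permutation agree", {
  set.seed(67)
  x <- rnorm(120); y1 <- x + rnorm(120); y2 <- 0.6 * x + rnorm(120)
  st <- compare_dependent_correlations(x, y1, y2)
  pm <- compare_dependent_correlations(x, y1, y2, method = "permutation",
                                       n_perm = 3000, seed = 1)
  expect_equal(st$p_value, pm$p_value, tolerance = 0.03)
  # y2 == y1 -> equal correlations, p = 1
  eq <- compare_dependent_correlations(x, y1, y1)
  expect_equal(eq$r1, eq$r2); expect_equal(eq$p_value, 1)
  # degenerate direction: y1 = x exactly
  dg <- compare_dependent_correlations(x, x, rnorm(120))
  expect_equal(dg$r1, 1)
  expect_lt(dg$p_value, 1e-6)
  expect_error(compare_dependent_correlations(x, rep(1, 120), y2),
               "zero variance")
  expect_error(compare_dependent_correlations(x[1:5], y1[1:5], y2[1:5]),
               "at least 10")
})

test_that("classify_case applies the confirmed/suspect/normal rules", {
  expect_equal(classify_case(list(md = 2, gdf = 3), iop = 15), "confirmed")
  expect_equal(classify_case(list(psd = 2, md = 50, gdf = 60, rim_area = 3),
                             iop = 15), "confirmed")
  expect_equal(classify_case(list(psd = 50, md = 50, gdf = 50, rim_area = 50),
                             iop = 26), "suspect")
  expect_equal(classify_case(list(psd = 50, md = 50, gdf = 50, rim_area = 50),
                             iop = 23, cct = 480), "suspect")
  expect_equal(classify_case(list(psd = 50, md = 50, gdf = 50, rim_area = 50),
                             iop = 23, cct = 550), "normal")
  expect_equal(classify_case(list(psd = 50, md = 50, gdf = 50, rim_area = 50),
                             iop = 22, risk_flags = "family_history"),
               "suspect")
  expect_equal(classify_case(list(psd = 50, md = 50, gdf = 50, rim_area = 50),
                             iop = 15), "normal")
  # one abnormal branch alone is not confirmation
  expect_equal(classify_case(list(psd = 2, md = 50, gdf = 60, rim_area = 50),
                             iop = 15), "normal")
  expect_error(classify_case(list(psd = 50, gdf = 50)),
               class = "hbdisc_insufficient_data")
  expect_error(classify_case(list(psd = 2)), "structural")
})
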