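# Statistics layer: Spearman vs a brute-force rank oracle, dendrogram
# structure, ROC against pROC and closed forms, ICC against aov() and the
# bias closed form, Friedman against full enumeration.

test_that("Spearman handles monotone transforms, reversals and ties", {
  x <- seq(0.1, 2, length.out = 20)
  tab <- data.frame(dn2 = exp(x), crit = x)
  expect_equal(spearman_vs_dn2(tab, "crit")$rho, 1)
  tab2 <- data.frame(dn2 = -x, crit = x)
  expect_equal(spearman_vs_dn2(tab2, "crit")$rho, -1)
  tab3 <- data.frame(dn2 = c(2, 1, 4, 3, 5), crit = 1:5)
  s <- spearman_vs_dn2(tab3, "crit")
  expect_equal(s$rho, 0.8) # 1 - 6*4/(5*24)
  expect_equal(s$rho, spearman_brute(tab3$crit, tab3$dn2))
  set.seed(1)
  xt <- sample(1:5, 30, replace = TRUE) # heavy ties
  yt <- xt + sample(0:2, 30, replace = TRUE)
  tab4 <- data.frame(dn2 = yt, crit = xt)
  expect_equal(spearman_vs_dn2(tab4, "crit")$rho, spearman_brute(xt, yt),
               tolerance = 1e-12)
  expect_error(spearman_vs_dn2(data.frame(dn2 = 1:6, crit = rep(1, 6)),
                               "crit"), "constant")
})

test_that("the dendrogram merges by correlation distance", {
  set.seed(7)
  n <- 30
  a <- rnorm(n)
  tab <- data.frame(dn2 = a + rnorm(n, 0, 0.1), # near-copy of a
                    crit1 = a,
                    crit2 = rnorm(n))
  d <- build_dendrogram(tab, c("dn2", "crit1", "crit2"))
  # the strongly correlated pair merges first
  first <- sort(d$hclust$labels[-d$hclust$merge[1, ]])
  expect_equal(first, c("crit1", "dn2"))
  expect_true(all(diff(d$hclust$height) >= 0))
  expect_true(all(d$hclust$height >= 0 & d$hclust$height <= 1))
  expect_setequal(d$hclust$labels, c("dn2", "crit1", "crit2"))
  # identical variables merge at height 0
  tab$crit3 <- tab$crit1
  d2 <- build_dendrogram(tab, c("dn2", "crit1", "crit2", "crit3"))
  expect_equal(min(d2$hclust$height), 0)
  expect_error(build_dendrogram(cbind(tab, flatc = 1),
                                c("dn2", "crit1", "flatc")), "constant")
})

test_that("the strongest-linked criterion sits among dN2's close branches", {
  hits <- 0L
  for (s in 1:100) {
    tab <- generate_cohort(cohort_spec(n_subjects = 50, seed = 7000 + s))
    d <- build_dendrogram(tab, c("dn2",
                                 paste0(airtrap_criteria()$criterion,
                                        "_mean")))
    hits <- hits + ("e_over_i_mld_mean" %in%
                      names(d$closest_to_dn2)[1:3])
  }
  expect_gte(hits, 95)
})

test_that("ROC handles separation, transforms and direction duality", {
  vals <- c(1:5, 11:15)
  labs <- rep(c(FALSE, TRUE), each = 5)
  r <- roc_analysis(vals, labs)
  expect_equal(r$auc, 1)
  expect_gt(r$best_threshold, 5)
  expect_lte(r$best_threshold, 11)
  expect_equal(c(r$sensitivity, r$specificity), c(1, 1))
  # monotone transform invariance
  set.seed(3)
  v <- rnorm(200)
  l <- v + rnorm(200) > 0
  r1 <- roc_analysis(v, l)
  r2 <- roc_analysis(exp(v), l)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$curve$sensitivity, r2$curve$sensitivity)
  # duality under fixed directions
  rh <- roc_analysis(v, l, direction = "higher")
  rl <- roc_analysis(v, l, direction = "lower")
  expect_equal(rh$auc, 1 - rl$auc, tolerance = 1e-12)
  # auto direction flips a negatively oriented criterion
  rneg <- roc_analysis(-v, l)
  expect_equal(rneg$direction, "lower")
  expect_equal(rneg$auc, rh$auc)
  expect_error(roc_analysis(v, rep(TRUE, 200)), "both classes")
})

test_that("AUC and DeLong CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(11)
  v <- c(rnorm(80, 0.8), rnorm(120, 0))
  l <- rep(c(TRUE, FALSE), c(80, 120))
  r <- roc_analysis(v, l)
  pr <- pROC::roc(l, v, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$auc_ci, ci[c(1, 3)], tolerance = 1e-9)
})

test_that("Youden ties resolve towards higher specificity", {
  # thresholds >=2 (sens 1, spec .5) and >=5 (sens .5, spec 1) tie at J=.5
  r <- roc_analysis(c(1, 2, 4, 5), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(r$youden, 0.5)
  expect_equal(r$specificity, 1)
  expect_equal(r$best_threshold, 5)
})

test_that("ICC(2,1) matches aov() decomposition and closed forms", {
  set.seed(5)
  rp <- generate_reader_pair(rnorm(60, 50, 3), error_sd = c(2, 2), seed = 8)
  r <- icc_two_readers(rp$reader_a, rp$reader_b)
  expect_equal(r$icc, icc_aov_oracle(rp$reader_a, rp$reader_b),
               tolerance = 1e-12)
  # identical readers: exactly 1
  a <- rnorm(30)
  expect_equal(icc_two_readers(a, a)$icc, 1)
  # pure bias: icc = 2 var(s) / (2 var(s) + bias^2)
  s <- rnorm(100, 0, 2)
  rb <- icc_two_readers(s, s + 10)
  expect_equal(rb$icc, 2 * var(s) / (2 * var(s) + 100), tolerance = 1e-12)
  expect_lt(rb$icc, 1)
  # zero total variance: flagged undefined
  z <- icc_two_readers(rep(1, 10), rep(1, 10))
  expect_true(is.na(z$icc))
  expect_true(z$undefined)
})

test_that("ICC estimates converge to the variance-component truth", {
  for (setting in list(c(4, 1), c(1, 1), c(9, 1))) {
    rp <- generate_reader_pair(rep(0, 4000), subject_sd = sqrt(setting[1]),
                               error_sd = rep(sqrt(setting[2]), 2),
                               seed = 31 + setting[1])
    truth <- setting[1] / sum(setting)
    expect_lt(abs(icc_two_readers(rp$reader_a, rp$reader_b)$icc - truth),
              0.03)
  }
})

test_that("Friedman heterogeneity test matches enumeration and extremes", {
  # fully tied: statistic 0, p 1
  x0 <- matrix(5, 8, 4)
  r0 <- level_heterogeneity_test(x0, exact = FALSE)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # one level strongly shifted: tiny p
  set.seed(2)
  x1 <- matrix(rnorm(80), 20, 4)
  x1[, 2] <- x1[, 2] + 50
  expect_lt(level_heterogeneity_test(x1, exact = FALSE)$p_value, 0.001)
  # exact enumeration equals the brute-force permutation oracle
  for (s in 1:3) {
    set.seed(s)
    x <- matrix(rnorm(12), 4, 3)
    if (s == 3) x[1, ] <- c(1, 1, 2) # ties
    r <- level_heterogeneity_test(x, exact = TRUE)
    expect_equal(r$p_value, friedman_perm_oracle(x))
  }
  # chi-square path agrees with stats::friedman.test on tie-free data
  set.seed(9)
  xf <- matrix(rnorm(60), 15, 4)
  r <- level_heterogeneity_test(xf, exact = FALSE)
  ft <- friedman.test(xf)
  expect_equal(r$statistic, unname(ft$statistic))
  expect_equal(r$p_value, ft$p.value)
  # missing levels drop subjects and are reported
  xna <- rbind(xf, c(NA, 1, 2, 3))
  expect_equal(level_heterogeneity_test(xna, exact = FALSE)$n_dropped, 1L)
})

test_that("run_comparison mirrors the correlate-cluster-ROC workflow", {
  tab <- generate_cohort(cohort_spec(n_subjects = 40, seed = 17))
  rep <- run_comparison(tab)
  expect_equal(rep$prevalence, mean(tab$dn2 > 2.5))
  expect_equal(nrow(rep$spearman), 9L)
  expect_equal(length(rep$branches), 3L)
  expect_equal(rep$top_criterion, names(rep$roc)[1])
  aucs <- vapply(rep$roc, `[[`, numeric(1), "auc")
  expect_true(all(diff(aucs) <= 0)) # ranked by AUC
  # single-class cohorts skip ROC with a message
  tab1 <- tab
  tab1$dn2 <- abs(tab1$dn2) + 3 # everyone obstructed
  rep1 <- run_comparison(tab1)
  expect_null(rep1$roc)
  expect_match(rep1$roc_note, "single-class")
})
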