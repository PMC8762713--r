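test_that("pair-counting AUC matches brute force and its worked example", {
  expect_equal(mann_whitney_auc(c(2, 3), c(1, 2)), 0.875)
  expect_equal(pair_auc_oracle(c(2, 3), c(1, 2)), 0.875)
  x <- c(1, 2, 3)
  expect_equal(mann_whitney_auc(x, x), 0.5)
  expect_equal(mann_whitney_auc(c(10, 11), c(1, 2)), 1)
  expect_error(mann_whitney_auc(numeric(0), 1), "non-empty")
  withr::local_seed(31)
  for (rep in 1:20) {
    d <- sample(1:6, sample(2:8, 1), TRUE)   # ties likely
    h <- sample(1:6, sample(2:8, 1), TRUE)
    expect_equal(mann_whitney_auc(d, h), pair_auc_oracle(d, h))
  }
})

test_that("the empirical ROC trapezoid equals the pair-counting AUC exactly", {
  withr::local_seed(32)
  for (rep in 1:100) {
    d <- round(rnorm(sample(2:10, 1)), sample(0:1, 1))
    h <- round(rnorm(sample(2:10, 1)), sample(0:1, 1))
    r <- roc_curve(d, h)
    expect_equal(r$auc, mann_whitney_auc(d, h))
  }
})

test_that("ROC direction reversal and monotone invariance hold", {
  withr::local_seed(33)
  d <- rnorm(12, 1); h <- rnorm(15)
  expect_equal(roc_curve(d, h, "low")$auc, 1 - roc_curve(d, h, "high")$auc)
  expect_equal(mann_whitney_auc(exp(d), exp(h)), mann_whitney_auc(d, h))
  expect_equal(mann_whitney_auc(atan(d), atan(h)), mann_whitney_auc(d, h))
  # agreement with an independent ROC implementation
  pr <- pROC::roc(controls = h, cases = d, direction = "<", quiet = TRUE)
  expect_equal(roc_curve(d, h)$auc, as.numeric(pROC::auc(pr)))
})

test_that("the Youden cutoff follows enumeration and its conventions", {
  r <- roc_curve(c(2, 3), c(1, 2))
  # enumeration: J = 0.5 at both gaps; the more specific point wins
  expect_gt(r$cutoff, 2); expect_lt(r$cutoff, 3)
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 1.0)
  expect_equal(youden_cutoff(r), r$cutoff)
  # perfect separation: midpoint of the separating gap
  r2 <- roc_curve(c(5, 6), c(1, 2))
  expect_equal(r2$cutoff, 3.5)
  # indistinguishable groups: lowest candidate
  r3 <- roc_curve(c(1, 2), c(1, 2))
  expect_equal(r3$cutoff, 0)
  expect_equal(r3$sensitivity + r3$specificity, 1)
  # tidy/glance accessors
  expect_named(glance(r), c("auc", "cutoff", "sensitivity", "specificity",
                            "direction"))
  expect_true(all(c("threshold", "sensitivity", "specificity") %in%
                    names(tidy(r))))
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("binormal AUC matches its closed form and antisymmetry", {
  expect_equal(binormal_auc(1, 1, 1, 1), 0.5)
  # CSC vs healthy vessel volume under the SE-to-SD completion
  sd1 <- 0.23 * sqrt(34); sd0 <- 0.11 * sqrt(77)
  auc <- binormal_auc(4.68, sd1, 3.17, sd0)
  expect_equal(auc, pnorm(1.51 / sqrt(sd0^2 + sd1^2)))
  expect_equal(auc, 0.8197, tolerance = 2e-4)
  expect_equal(binormal_auc(3.17, sd0, 4.68, sd1), 1 - auc)
  expect_error(binormal_auc(1, 0, 0, 1), "> 0")
})

test_that("cohort simulation is seeded, unbiased, and partitions at cutoffs", {
  cs <- reference_cohorts()
  di <- cs[cs$label == "CSC" & cs$metric == "vessel_volume", ]
  he <- cs[cs$label == "healthy" & cs$metric == "vessel_volume", ]
  s1 <- simulate_cohorts(di, he, n_reps = 2000, seed = 42, cutoff = 4.14)
  s2 <- simulate_cohorts(di, he, n_reps = 2000, seed = 42, cutoff = 4.14)
  expect_identical(s1$reps, s2$reps)
  g <- glance(s1)
  expect_lt(abs(g$auc_mc_mean - s1$auc_closed_form), 3 * g$auc_mc_se)
  # same summary in both arms: AUC centres on 1/2
  s0 <- simulate_cohorts(he, he, n_reps = 2000, seed = 1)
  g0 <- glance(s0)
  expect_lt(abs(g0$auc_mc_mean - 0.5), 3 * g0$auc_mc_se)
  # specificity at the cutoff equals the healthy fraction <= cutoff
  sd0 <- he$se * sqrt(he$n)
  expect_equal(g$specificity, pnorm((4.14 - he$mean) / sd0), tolerance = 0.01)
  expect_error(simulate_cohorts(list(mean = 1, se = 0, n = 10), he), "invalid")
})

test_that("cohort summaries validate and ship the study groups", {
  expect_error(cohort_summary("x", "m", 1, 0, 10), "se")
  expect_error(cohort_summary("x", "m", 1, 0.1, 1), "n")
  cs <- reference_cohorts()
  expect_equal(nrow(cs), 9)
  expect_setequal(unique(cs$label), c("healthy", "CSC", "VKH"))
  expect_equal(cs$sd, cs$se * sqrt(cs$n))
  expect_equal(cs$n[cs$label == "healthy"], rep(77L, 3))
})

test_that("group comparison wraps Kruskal-Wallis with pairwise tests", {
  withr::local_seed(34)
  sc <- list(healthy = rnorm(30, 3.2, 1), CSC = rnorm(20, 4.7, 1.3),
             VKH = rnorm(20, 3.8, 1))
  out <- compare_groups(sc)
  expect_s3_class(out$kruskal, "htest")
  expect_equal(nrow(out$pairwise), 3)
  expect_true(all(out$pairwise$p_adj >= 0 & out$pairwise$p_adj <= 1))
})
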