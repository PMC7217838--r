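test_that("Fisher 2x2 reports the crude cross-product OR and exact p", {
  ft <- fisherExact2x2(matrix(c(21, 1, 20, 12), 2, byrow = TRUE))
  expect_equal(ft$odds_ratio, 12.6)
  expect_false(ft$degenerate)

  bal <- fisherExact2x2(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(bal$odds_ratio, 1)
  expect_equal(bal$p_value, 1)

  deg <- fisherExact2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("Fisher p matches exhaustive hypergeometric enumeration (N <= 60)", {
  set.seed(12)
  for (i in 1:150) {
    N <- sample(4:60, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    c_ <- sample(0:(N - a - b), 1); d <- N - a - b - c_
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    ft <- fisherExact2x2(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    expect_equal(ft$p_value, enumFisherP(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("Mann-Whitney matches enumeration and handles ties", {
  tied <- mannWhitney(rep(3, 5), rep(3, 7))
  expect_equal(tied$auc_equivalent, 0.5)
  expect_equal(tied$p_value, 1)

  sep <- mannWhitney(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sep$auc_equivalent, 1)

  set.seed(19)
  for (i in 1:20) {
    x <- sample(1:1000, 5); y <- sample(2000:3000, 5) / 7
    mw <- mannWhitney(x, y)
    expect_equal(mw$p_value, enumMwuP(x, y), tolerance = 1e-9)
    expect_equal(mw$auc_equivalent, aucPairs(x, y))
  }
})

test_that("ROC cutoff maximizes Youden J with the sensitive tie-break", {
  roc <- rocAndCutoff(c(10, 9, 1, 2), c("early", "early", "late", "late"))
  expect_equal(roc$auc, 1)
  expect_equal(roc$chosen_cutoff, 2)
  expect_equal(roc$youden_at_cutoff, 1)
  # dichotomization at the chosen cutoff is the "load > cutoff" rule
  expect_equal(dichotomizeLoad(c(10, 9, 1, 2), roc$chosen_cutoff),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_error(rocAndCutoff(1:4, rep("early", 4)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney identity on random data", {
  set.seed(23)
  for (i in 1:100) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    # integer loads force ties, exercising the half-credit convention
    pos <- sample(0:15, n1, replace = TRUE)
    neg <- sample(0:15, n2, replace = TRUE)
    roc <- rocAndCutoff(c(pos, neg), rep(c("early", "late"), c(n1, n2)))
    expect_equal(roc$auc, aucPairs(pos, neg), tolerance = 1e-12)
  }
  # label-noise null: AUC near 1/2 for large n
  set.seed(24)
  loads <- rnorm(2000)
  grp <- sample(rep(c("early", "late"), 1000))
  roc <- rocAndCutoff(loads, grp)
  expect_lt(abs(roc$auc - 0.5), 3 * sqrt((1000 + 1000 + 1) / (12 * 1e6)))
})

test_that("logistic OR for a lone binary covariate equals the 2x2 cross-product", {
  counts <- list(c(30, 20, 25, 45), c(12, 30, 22, 18), c(40, 5, 18, 30))
  for (ct in counts) {
    prof <- data.frame(
      onset_group = rep(c("early", "early", "late", "late"), ct),
      high_load = rep(c(TRUE, FALSE, TRUE, FALSE), ct),
      gender = "female", education_years = 6, apoe_e4 = FALSE,
      baseline_cdr = 1)
    fit <- fitLogistic(prof, formula = early ~ high_load)
    or <- fit$table$odds_ratio[fit$table$term == "high_load"]
    expect_equal(or, crossOR(ct[1], ct[2], ct[3], ct[4]), tolerance = 1e-6)
    expect_false(fit$separation)
  }
})

test_that("logistic Wald intervals are calibrated under the null", {
  set.seed(31)
  cover <- vapply(1:200, function(i) {
    n <- 2000
    prof <- data.frame(
      onset_group = sample(c("early", "late"), n, replace = TRUE),
      high_load = sample(c(TRUE, FALSE), n, replace = TRUE),
      gender = "female", education_years = 6, apoe_e4 = FALSE,
      baseline_cdr = 1)
    t <- fitLogistic(prof, formula = early ~ high_load)$table
    t$ci_lower[2] <= 1 && 1 <= t$ci_upper[2]
  }, logical(1))
  expect_lt(abs(mean(cover) - 0.95), 3 * sqrt(0.95 * 0.05 / 200))
})

test_that("complete separation is flagged, not silently estimated", {
  prof <- data.frame(
    onset_group = rep(c("early", "late"), each = 20),
    high_load = rep(c(TRUE, FALSE), each = 20),
    gender = "female", education_years = 6, apoe_e4 = FALSE,
    baseline_cdr = 1)
  fit <- fitLogistic(prof, formula = early ~ high_load)
  expect_true(fit$separation)
})

test_that("simulated power is null-calibrated and monotone in effect size", {
  null <- powerBySimulation(22, 32, alpha = 0.05, baseline_proportion = 0.5,
                            odds_ratio = 1, replicates = 4000, seed = 2)
  expect_lte(null$power, 0.05 + 3 * null$mc_se)

  p1 <- powerBySimulation(22, 32, 0.02, 0.625, 12.6, replicates = 4000,
                          seed = 3)
  p2 <- powerBySimulation(22, 32, 0.02, 0.625, 200, replicates = 4000,
                          seed = 3)
  expect_gt(p2$power, p1$power)
})

test_that("the group summary table has the study's structure and consistent tests", {
  set.seed(37)
  m <- tinyLoads(tinyCohortConfig(seed = 37, mean_early = 6, mean_late = 3))
  m$high_load <- dichotomizeLoad(m$self_antigen_load,
                                 median(m$self_antigen_load))
  t1 <- table1Summary(m)
  expect_equal(dim(t1), c(7L, 3L))
  expect_equal(rownames(t1)[1], "n")
  # categorical p-values agree with fisherExact2x2 called directly
  e <- m[m$onset_group == "early", ]; l <- m[m$onset_group == "late", ]
  ft <- fisherExact2x2(matrix(c(sum(e$apoe_e4), sum(!e$apoe_e4),
                                sum(l$apoe_e4), sum(!l$apoe_e4)),
                              2, byrow = TRUE))
  expect_equal(t1["ApoE (e4+)", "p_value"], ft$p_value)
  mw <- mannWhitney(e$self_antigen_load, l$self_antigen_load)
  expect_equal(t1["Self-antigen load", "p_value"], mw$p_value)

  m2 <- m; m2$apoe_e4[3] <- NA
  expect_error(table1Summary(m2), "missing apoe_e4")
})
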