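test_that("pearson_by_cohort reproduces perfect and inverted relations", {
  d <- data.frame(cohort = "test", true_fraction = seq(0.1, 0.5, 0.1),
                  predicted_fraction = seq(0.1, 0.5, 0.1))
  r <- pearson_by_cohort(d)
  expect_equal(r$r, 1)
  d$predicted_fraction <- 1 - d$true_fraction
  expect_equal(pearson_by_cohort(d)$r, -1)
  d$predicted_fraction <- rep(0.3, 5)
  expect_warning(rz <- pearson_by_cohort(d), "zero variance")
  expect_true(is.na(rz$r))
  expect_error(pearson_by_cohort(d[1:2, ]), "fewer than 3")
})

test_that("pearson matches the covariance-formula oracle on random pairs", {
  set.seed(81)
  tf <- runif(10); pf <- 0.4 * tf + rnorm(10, sd = 0.1)
  d <- data.frame(cohort = "train", true_fraction = tf, predicted_fraction = pf)
  res <- pearson_by_cohort(d)
  r_hand <- sum((tf - mean(tf)) * (pf - mean(pf))) /
    sqrt(sum((tf - mean(tf))^2) * sum((pf - mean(pf))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  b_hand <- sum((tf - mean(tf)) * (pf - mean(pf))) / sum((tf - mean(tf))^2)
  expect_equal(res$slope, b_hand, tolerance = 1e-12)
  expect_equal(res$intercept, mean(pf) - b_hand * mean(tf), tolerance = 1e-12)
})

test_that("AUROC handles separation, ties and matches the pairwise oracle", {
  sep <- data.frame(pre_therapy_fraction = c(0.1, 0.2, 0.6, 0.7),
                    responder = c(0, 0, 1, 1))
  expect_equal(auroc(sep), 1)
  tied <- data.frame(pre_therapy_fraction = rep(0.3, 6),
                     responder = c(0, 1, 0, 1, 0, 1))
  expect_equal(auroc(tied), 0.5)
  expect_error(auroc(data.frame(pre_therapy_fraction = 1:3,
                                responder = c(1, 1, 1))), "both")
  set.seed(82)
  for (rep in 1:100) {
    n <- sample(6:14, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # ties likely
    y <- as.integer(runif(n) < 0.5)
    if (length(unique(y)) < 2) next
    d <- data.frame(pre_therapy_fraction = sc, responder = y)
    expect_equal(auroc(d), oracle_auroc(sc, y), tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone transforms of the scores", {
  set.seed(83)
  sc <- runif(12); y <- rep(0:1, 6)
  d1 <- data.frame(pre_therapy_fraction = sc, responder = y)
  d2 <- data.frame(pre_therapy_fraction = exp(3 * sc) - 1, responder = y)
  expect_equal(auroc(d1), auroc(d2))
})

test_that("youden_cutoff separates classes and matches the exhaustive scan", {
  d <- data.frame(pre_therapy_fraction = c(0.1, 0.2, 0.6, 0.7),
                  responder = c(0, 0, 1, 1))
  yc <- youden_cutoff(d)
  expect_gt(yc$cutoff, 0.2); expect_lte(yc$cutoff, 0.6)
  expect_equal(yc$youden, 1)
  expect_equal(yc$sensitivity, 1); expect_equal(yc$specificity, 1)
  expect_error(youden_cutoff(data.frame(pre_therapy_fraction = 1:3,
                                        responder = c(1, 1, 1))), "both")
  set.seed(84)
  for (rep in 1:100) {
    sc <- sample(seq(0, 1, 0.1), 12, replace = TRUE)
    y <- as.integer(runif(12) < 0.5)
    if (length(unique(y)) < 2) next
    d2 <- data.frame(pre_therapy_fraction = sc, responder = y)
    got <- youden_cutoff(d2)
    want <- oracle_youden(sc, y)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden, want$J, tolerance = 1e-12)
  }
})

test_that("rank AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(85)
  sc <- runif(30); y <- as.integer(runif(30) < 0.4)
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  d <- data.frame(pre_therapy_fraction = sc, responder = y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(auroc(d), ref, tolerance = 1e-12)
})

test_that("responder dichotomization and the longitudinal table behave", {
  expect_equal(responder_from_survival(c(5, 14, 15, 40)), c(0L, 0L, 1L, 1L))
  expect_error(responder_from_survival(c(-1, 3)), "non-negative")
  df <- data.frame(subject = c(1, 1, 1, 2), day = c(0, 7, 12, 0),
                   hypoxia_fraction = c(0.20, 0.25, 0.51, 0.10))
  lt <- longitudinal_table(df)
  expect_equal(lt$delta, c(0, 0.05, 0.31, 0))    # +31% pre-therapy to day 12
  expect_equal(lt$day, c(0, 7, 12, 0))
  single <- longitudinal_table(data.frame(subject = 9, day = 3,
                                          hypoxia_fraction = 0.4))
  expect_equal(single$delta, 0)
})
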