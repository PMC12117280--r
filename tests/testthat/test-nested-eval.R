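test_that("rank AUC equals brute-force concordant-pair counting", {
  expect_identical(auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_identical(auc_rank(rep(0.3, 6), rep(c(0, 1), 3)), 0.5)
  expect_identical(auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc_rank(1:4, rep(1, 4)), "both classes")
  set.seed(1)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    s <- round(runif(n), 2)  # force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc_rank(s, y), auc_brute_force(s, y), tolerance = 1e-12)
  }
})

test_that("confusion metrics satisfy their defining identities", {
  scores <- c(rep(0.9, 50), rep(0.1, 50), rep(0.9, 17), rep(0.1, 83))
  labels <- rep(c(1, 0), c(100, 100))
  m <- classification_metrics(scores, labels)
  expect_equal(m$sensitivity, 0.50)
  expect_equal(m$specificity, 0.83)
  expect_equal(m$bac, 0.665)
  expect_equal(m$f1, 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity))
  perfect <- classification_metrics(labels, labels)
  for (col in c("auc", "accuracy", "bac", "sensitivity", "specificity",
                "ppv", "f1", "auprc")) {
    expect_equal(perfect[[col]], 1)
  }
  # harmonic-mean fixed point: precision = recall => F1 equals both
  set.seed(2)
  for (i in 1:20) {
    mm <- classification_metrics(runif(80), rbinom(80, 1, 0.5))
    expect_equal(mm$bac, (mm$sensitivity + mm$specificity) / 2,
                 tolerance = 1e-9)
    expect_true(all(unlist(mm[c("auc", "accuracy", "bac", "sensitivity",
                                "specificity", "ppv", "f1", "auprc")])
                    >= 0))
  }
})

test_that("step-integrated AUPRC matches a hand computation", {
  # scores desc: 0.9(pos) 0.8(neg) 0.7(pos) 0.6(neg)
  s <- c(0.9, 0.8, 0.7, 0.6)
  y <- c(1, 0, 1, 0)
  # recall steps: 0.5 at precision 1; 1.0 at precision 2/3
  expect_equal(prescriptr:::auprc_step(s, y), 0.5 * 1 + 0.5 * (2 / 3),
               tolerance = 1e-12)
})

test_that("calibration effect converts r to d and flags degeneracies", {
  # closed-form conversion at r = 0.2
  set.seed(3)
  ce <- calibration_effect(c(0.1, 0.9, 0.1, 0.9), c(0, 1, 0, 1))
  expect_identical(ce$flag, "infinite")
  # build data with a target correlation by rounding a bivariate pair
  p <- runif(500)
  y <- rbinom(500, 1, 0.5)
  c0 <- calibration_effect(p, y)
  expect_lt(abs(c0$r), 0.12)
  expect_equal(calibration_effect(p, y)$d,
               2 * c0$r / sqrt(1 - c0$r^2), tolerance = 1e-12)
  r <- 0.2
  expect_equal(2 * r / sqrt(1 - r^2), 0.408248, tolerance = 1e-5)
  cc <- calibration_effect(rep(0.4, 10), rbinom(10, 1, 0.5))
  expect_identical(cc$flag, "degenerate")
})

test_that("DeLong test handles identical and rank-equivalent scores", {
  set.seed(4)
  s <- runif(60)
  y <- rbinom(60, 1, 0.4)
  same <- delong_test(s, s, y)
  expect_identical(same$z, 0)
  expect_identical(same$p_value, 1)
  mono <- delong_test(s, plogis(3 * s - 1), y)
  expect_equal(mono$auc_a, mono$auc_b, tolerance = 1e-12)
  expect_identical(mono$z, 0)
  expect_error(delong_test(s[-1], s, y), "align")
})

test_that("DeLong agrees with pROC and is calibrated under the null", {
  set.seed(5)
  y <- rbinom(100, 1, 0.5)
  a <- runif(100) + 0.5 * y
  b <- runif(100) + 0.3 * y
  got <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  expect_equal(abs(got$z), abs(unname(ref$statistic)), tolerance = 1e-8)
  # independent score vectors: z is approximately standard normal
  zs <- vapply(1:200, function(i) {
    yy <- rep(c(0, 1), each = 30)
    delong_test(rnorm(60), rnorm(60), yy)$z
  }, numeric(1))
  expect_lt(abs(sd(zs) - 1), 0.25)
  expect_lt(abs(mean(zs)), 0.2)
})

test_that("nested cross-validation is bit-reproducible under a fixed seed", {
  d <- small_trial(n = 100, seed = 6, missing_rate = 0.05)
  set.seed(7)
  x <- as.numeric(scale(d$trait_mindfulness))
  x[is.na(x)] <- 0
  y <- rbinom(100, 1, plogis(x))
  specs <- list(model_spec("random_forest", num_trees = 100),
                model_spec("logistic_reference"))
  r1 <- run_nested_cv(d, y, specs, n_outer = 4, n_inner = 3,
                      n_repeats = 2, seed = 8)
  r2 <- run_nested_cv(d, y, specs, n_outer = 4, n_inner = 3,
                      n_repeats = 2, seed = 8)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$final_predictors, r2$final_predictors)
  # report identities hold on every emitted row
  pf <- r1$per_fold
  expect_equal(pf$bac, (pf$sensitivity + pf$specificity) / 2,
               tolerance = 1e-9)
  expect_true(all(pf$auc >= 0 & pf$auc <= 1, na.rm = TRUE))
  expect_length(r1$final_predictors, 10)
  expect_named(r1$delong, "random_forest")
})

test_that("outer-test labels never influence the fitted fold models", {
  d <- small_trial(n = 90, seed = 9)
  set.seed(10)
  y <- rbinom(90, 1, 0.5)
  pred_df <- as.data.frame(d)[, predictor_names()]
  train_idx <- 1:60
  test_idx <- 61:90
  opts <- list(screening = TRUE, top_k = 5, smote = TRUE, smote_k = 3,
               n_inner = 3, impute_trees = 50)
  specs <- list(model_spec("random_forest", num_trees = 100))
  f1 <- prescriptr:::fit_outer_fold(pred_df, y, train_idx, test_idx,
                                    specs, opts, seed = 11)
  y_perm <- y
  y_perm[test_idx] <- sample(y[test_idx])
  f2 <- prescriptr:::fit_outer_fold(pred_df, y_perm, train_idx, test_idx,
                                    specs, opts, seed = 11)
  expect_identical(f1$models$random_forest$scores,
                   f2$models$random_forest$scores)
  expect_identical(f1$models$random_forest$best_params,
                   f2$models$random_forest$best_params)
})

test_that("SVM scores come from a deterministic monotone decision mapping", {
  X <- random_features(120, 4, seed = 12)
  set.seed(13)
  y <- rbinom(120, 1, plogis(X[, 1] + X[, 2]))
  m1 <- prescriptr:::fit_learner("svm_rbf", X, y,
                                 params = list(cost = 1, gamma = 0.25))
  m2 <- prescriptr:::fit_learner("svm_rbf", X, y,
                                 params = list(cost = 1, gamma = 0.25))
  p1 <- prescriptr:::predict_learner(m1, X)
  expect_identical(p1, prescriptr:::predict_learner(m2, X))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_gt(auc_rank(p1, y), 0.6)
})
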