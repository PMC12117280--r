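test_that("fold plans partition cases with balanced, stratified folds", {
  set.seed(1)
  y <- rbinom(191, 1, 0.4)
  plan <- make_fold_plan(y, n_outer = 10, n_repeats = 3, seed = 2)
  for (r in 1:3) {
    f <- plan$assignments[, r]
    sizes <- table(f)
    expect_identical(sum(sizes), 191L)
    expect_lte(diff(range(sizes)), 1)
    pos <- table(f[y == 1])
    expect_lte(diff(range(pos)), 1)
  }
  expect_identical(make_fold_plan(y, seed = 5)$assignments,
                   make_fold_plan(y, seed = 5)$assignments)
  expect_false(identical(plan$assignments[, 1], plan$assignments[, 2]))
})

test_that("a 30/161 label split yields 3 +/- 1 positives per fold", {
  y <- rep(c(1, 0), c(30, 161))
  f <- stratified_folds(y, 10, seed = 3)
  pos <- table(f[y == 1])
  expect_true(all(pos >= 2 & pos <= 4))
  expect_true(all(pos %in% c(3, 3 - 1, 3 + 1)))
  expect_error(stratified_folds(rep(c(1, 0), c(5, 50)), 10), "folds")
})

test_that("forest imputation preserves observed cells and handles edge cases", {
  d <- as.data.frame(small_trial(n = 60, seed = 6))[, predictor_names()]
  d$age[c(3, 10)] <- NA
  d$ethnicity[5] <- NA
  imp <- rf_impute_fit(d, seed = 7)
  out <- rf_impute_apply(imp, d)
  expect_false(anyNA(out))
  obs <- !is.na(d$age)
  expect_identical(out$age[obs], d$age[obs])
  expect_identical(out$ethnicity[-5], d$ethnicity[-5])
  # no missing cells: identity
  full <- as.data.frame(small_trial(n = 30, seed = 8))[, predictor_names()]
  imp2 <- rf_impute_fit(full, seed = 9)
  expect_identical(rf_impute_apply(imp2, full), full)
  # constant column: imputed value is the constant
  cc <- data.frame(a = c(5, 5, 5, 5, NA), b = c(1, 2, 3, 4, 5))
  impc <- rf_impute_fit(cc, seed = 1)
  expect_identical(rf_impute_apply(impc, cc)$a, rep(5, 5))
  expect_error(rf_impute_fit(data.frame(a = c(NA, NA, 1), b = 1:3)),
               ">= 2")
})

test_that("forest imputation beats column-mean fill on correlated data", {
  set.seed(10)
  n <- 300
  z <- rnorm(n)
  truth <- data.frame(x1 = z + rnorm(n, 0, 0.3),
                      x2 = -z + rnorm(n, 0, 0.3),
                      x3 = 2 * z + rnorm(n, 0, 0.3),
                      x4 = rnorm(n))
  masked <- truth
  holes <- matrix(runif(n * 4) < 0.1, n, 4)
  masked[holes] <- NA
  imp <- rf_impute_fit(masked, seed = 11)
  filled <- rf_impute_apply(imp, masked)
  rmse <- function(est) {
    sqrt(mean((as.matrix(est)[holes] - as.matrix(truth)[holes])^2))
  }
  mean_fill <- masked
  for (j in 1:4) {
    mean_fill[[j]][is.na(mean_fill[[j]])] <- mean(masked[[j]], na.rm = TRUE)
  }
  expect_lt(rmse(filled), rmse(mean_fill))
})

test_that("standardization and encoding are fitted on training rows only", {
  d <- as.data.frame(small_trial(n = 80, seed = 12))[, predictor_names()]
  state <- preprocess_fit(d, seed = 13)
  X <- standardize_and_encode(state, d)
  for (nm in c("age", "sad_severity", "self_compassion")) {
    expect_equal(mean(X[, nm]), 0, tolerance = 1e-9)
    expect_equal(sd(X[, nm]), 1, tolerance = 1e-9)
  }
  # a test value equal to the training mean maps to exactly zero
  probe <- d[1, ]
  probe$age <- state$center$age
  expect_identical(standardize_and_encode(state, probe)[1, "age"], 0)
  # four registered ethnicity levels -> four indicators summing to one
  eth <- grep("^ethnicity\\.", colnames(X))
  expect_length(eth, 4)
  expect_true(all(rowSums(X[, eth]) == 1))
  # binary predictors stay single 0/1 columns
  expect_true(all(X[, "psychotropic_medication"] %in% c(0, 1)))
  # unseen level: all-zero indicators plus a warning
  odd <- d[1, ]
  odd$ethnicity <- factor("martian", levels = c(levels(d$ethnicity),
                                                "martian"))
  expect_warning(Xo <- standardize_and_encode(state, odd), "unseen")
  expect_identical(unname(rowSums(Xo[, eth, drop = FALSE])), 0)
  # schema error for unknown columns
  bad <- d; bad$extra <- 1
  expect_error(standardize_and_encode(state, bad), "absent")
})

test_that("transforming held-out rows never mutates the fitted state", {
  d <- as.data.frame(small_trial(n = 80, seed = 14,
                                 missing_rate = 0.1))[, predictor_names()]
  state <- preprocess_fit(d[1:60, ], seed = 15, partition_id = "train")
  before <- serialize(state, NULL)
  invisible(standardize_and_encode(state, d[61:80, ]))
  expect_identical(serialize(state, NULL), before)
  expect_identical(state$fitted_on, "train")
})

test_that("SMOTE synthetic points are convex combinations of minority neighbours", {
  X <- rbind(matrix(rnorm(60, 0), 30, 2), c(0, 0), c(1, 1))
  y <- rep(c(0, 1), c(30, 2))
  expect_warning(r <- smote_rebalance(X, y, k_neighbors = 5, seed = 16),
                 "reduced")
  synth <- r$features[r$synthetic, , drop = FALSE]
  # with minority (0,0) and (1,1) and k = 1 every synthetic point is
  # (lambda, lambda) on the connecting segment
  expect_true(all(abs(synth[, 1] - synth[, 2]) < 1e-12))
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 1))
  expect_identical(sum(r$labels == 1), sum(r$labels == 0))
})

test_that("SMOTE hits the midpoint-then-parity counts exactly", {
  X <- random_features(100, 3, seed = 17)
  y <- rep(c(1, 0), c(20, 80))
  r <- smote_rebalance(X, y, seed = 18)
  expect_identical(sum(r$labels == 0), 50L)  # majority to the midpoint
  expect_identical(sum(r$labels == 1), 50L)  # minority to parity
  expect_identical(sum(r$synthetic), 30L)
  expect_true(all(!r$synthetic[seq_len(sum(!r$synthetic))]))
  # balanced input is a no-op
  yb <- rep(c(0, 1), 50)
  rb <- smote_rebalance(X, yb, seed = 19)
  expect_identical(rb$features, X)
  expect_identical(sum(rb$synthetic), 0L)
  expect_error(smote_rebalance(X, rep(c(1, 0), c(1, 99))), ">= 2")
})
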