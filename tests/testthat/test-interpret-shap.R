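test_that("a constant model receives zero attributions and its base value", {
  f <- function(X) rep(0.42, nrow(X))
  bg <- random_features(30, 5, seed = 1)
  sh <- kernel_shap(f, bg, bg[1:4, ], seed = 2)
  expect_equal(unname(sh$base_value), 0.42)
  expect_lt(max(abs(sh$attributions)), 1e-8)
  rk <- rank_and_sign(sh, k = 5)
  expect_identical(rk$predictor, paste0("x", 1:5))  # tie-break order
  expect_true(all(rk$direction == "null"))
})

test_that("kernel SHAP recovers the closed-form linear attribution", {
  set.seed(3)
  p <- 6
  bg <- matrix(rnorm(200 * p), 200, p,
               dimnames = list(NULL, paste0("x", 1:p)))
  w <- c(1.5, -2, 0.8, 0, 0.3, -1)
  f <- function(X) as.numeric(X %*% w)
  inst <- matrix(rnorm(4 * p), 4, p, dimnames = list(NULL, paste0("x", 1:p)))
  sh <- kernel_shap(f, bg, inst, n_coalitions = 8 * p, seed = 4)
  expected <- sweep(inst, 2, colMeans(bg)) %*% diag(w)
  denom <- pmax(abs(expected), 0.05)
  expect_lt(max(abs(sh$attributions - expected) / denom), 0.02)
  # additivity holds exactly per instance
  expect_lt(max(abs(rowSums(sh$attributions) + sh$base_value - sh$fx)),
            1e-6)
})

test_that("duplicated features in a symmetric model share attribution", {
  set.seed(5)
  bg <- matrix(rnorm(150), 75, 2, dimnames = list(NULL, c("a", "b")))
  bg[, 2] <- bg[, 1]  # identical columns
  f <- function(X) X[, 1] + X[, 2]
  inst <- matrix(c(1.3, 1.3, -0.7, -0.7), 2, 2, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b")))
  sh <- kernel_shap(f, bg, inst, n_coalitions = 64, seed = 6)
  expect_lt(max(abs(sh$attributions[, "a"] - sh$attributions[, "b"])),
            0.05)
})

test_that("more coalitions means lower attribution sampling error", {
  set.seed(7)
  p <- 8
  bg <- matrix(rnorm(60 * p), 60, p, dimnames = list(NULL, paste0("x", 1:p)))
  f <- function(X) as.numeric(tanh(X[, 1]) + X[, 2] * X[, 3])
  inst <- matrix(rnorm(p), 1, p, dimnames = list(NULL, paste0("x", 1:p)))
  spread <- vapply(c(2L, 8L, 32L) * p, function(M) {
    phis <- vapply(1:6, function(s) {
      kernel_shap(f, bg, inst, n_coalitions = M, seed = s)$attributions[1, 1]
    }, numeric(1))
    sd(phis)
  }, numeric(1))
  expect_lt(spread[3], spread[1])
})

test_that("one-hot blocks aggregate to predictor level, order-invariantly", {
  set.seed(8)
  n <- 120
  X <- cbind(g.a = rbinom(n, 1, 0.5), x1 = rnorm(n))
  X <- cbind(X, g.b = 1 - X[, "g.a"])
  fmap <- c(g.a = "g", x1 = "x1", g.b = "g")
  f <- function(M) 0.8 * M[, "g.a"] - 0.8 * M[, "g.b"] + 0.5 * M[, "x1"]
  inst <- X[1:6, ]
  sh <- kernel_shap(f, X, inst, n_coalitions = 400, seed = 9,
                    feature_map = fmap)
  expect_setequal(colnames(sh$attributions), c("g", "x1"))
  # permuting the indicator columns leaves aggregated attributions intact
  perm <- c("x1", "g.b", "g.a")
  sh2 <- kernel_shap(function(M) f(M), X[, perm], inst[, perm],
                     n_coalitions = 400, seed = 10, feature_map = fmap[perm])
  expect_equal(sh$attributions[, c("g", "x1")],
               sh2$attributions[, c("g", "x1")], tolerance = 0.05)
})

test_that("ranking clamps k, orders by importance and signs directions", {
  d <- small_trial(n = 250, seed = 11, missing_rate = 0)
  pred <- as.data.frame(d)[, predictor_names()]
  st <- preprocess_fit(pred, seed = 12, impute = FALSE)
  X <- standardize_and_encode(st, pred)
  y <- as.integer(d$true_ite_post > 0)
  fm <- final_model(d, y, screening = FALSE, num_trees = 200, seed = 13)
  Xf <- fm$features
  sub <- function(i) {
    o <- Xf[i, , drop = FALSE]
    attr(o, "feature_map") <- attr(Xf, "feature_map")
    o
  }
  sh <- kernel_shap(fm, sub(1:60), sub(1:60), seed = 14)
  rk <- rank_and_sign(sh, k = 10)
  expect_identical(nrow(rk), 10L)
  expect_identical(rk$rank, 1:10)
  expect_true(all(diff(rk$importance) <= 1e-12))
  expect_warning(rk_all <- rank_and_sign(sh, k = 99), "clamped")
  expect_identical(nrow(rk_all), 17L)
  # the planted moderators dominate and carry their planted signs
  top3 <- rk$predictor[1:3]
  expect_setequal(top3, c("trait_mindfulness", "sad_severity",
                          "gad_severity"))
  expect_identical(rk$direction[rk$predictor == "trait_mindfulness"],
                   "positive")
  expect_identical(rk$direction[rk$predictor == "sad_severity"],
                   "negative")
  cons <- direction_consistency(rk, rk)
  expect_true(all(cons$consistent[cons$direction_a != "null"]))
})
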