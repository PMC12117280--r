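test_that("optimization labelling follows the strict probability contrast", {
  est <- label_optimization(c(0.8, 0.4, 0.2), c(0.3, 0.4, 0.6))
  expect_equal(est$ite, c(0.5, 0, -0.4), tolerance = 1e-12)
  expect_identical(est$optimized, c(1L, 0L, 0L))  # ties are not optimized
  expect_error(label_optimization(1.2, 0.5), "\\[0, 1\\]")
  # prevalence identity: label prevalence equals the strictly-positive
  # ITE fraction
  set.seed(1)
  p1 <- runif(200); p0 <- runif(200)
  e <- label_optimization(p1, p0)
  expect_identical(mean(e$optimized), mean(e$ite > 0))
  # antisymmetry of the contrast under arm swap
  swapped <- label_optimization(p0, p1)
  expect_equal(swapped$ite, -e$ite, tolerance = 1e-12)
})

test_that("cross-fit predictions are deterministic and track the base rate", {
  d <- small_trial(n = 160, seed = 2, moderation = 0, signal = 0)
  est1 <- fit_arm_models(d, "post", n_folds = 4, num_trees = 150, seed = 3)
  est2 <- fit_arm_models(d, "post", n_folds = 4, num_trees = 150, seed = 3)
  expect_identical(est1$p_memi, est2$p_memi)
  expect_identical(est1$p_sm, est2$p_sm)
  expect_equal(est1$ite, est1$p_memi - est1$p_sm, tolerance = 1e-12)
  # with no predictor signal, same-arm predictions hover near the arm's
  # remission base rate
  for (a in c(1, 0)) {
    sel <- d$arm == a
    base <- mean(classify_remission(d$spdq_post[sel]))
    p_same <- ifelse(est1$arm == 1, est1$p_memi, est1$p_sm)[sel]
    expect_lt(abs(mean(p_same) - base), 0.06)
  }
  # cross-fit bookkeeping: every trained participant carries a fold id
  expect_true(all(!is.na(est1$cf_fold)))
  expect_true(all(est1$cf_fold %in% 1:4))
})

test_that("a near-separable outcome is recovered by the arm models", {
  d <- small_trial(n = 600, seed = 4, moderation = 0)
  # deterministic outcome in both arms: remission iff high GAD severity
  d$spdq_post <- ifelse(d$gad_severity > 7.5, 0, 30)
  est <- fit_arm_models(d, "post", n_folds = 5, num_trees = 300, seed = 5)
  y <- classify_remission(d$spdq_post)
  p_same <- ifelse(est$arm == 1, est$p_memi, est$p_sm)
  for (a in c(1, 0)) {
    sel <- d$arm == a
    expect_gte(auc_rank(p_same[sel], y[sel]), 0.95)
  }
})

test_that("single-class arms are rejected", {
  d <- small_trial(n = 60, seed = 6)
  d$spdq_post <- 30  # nobody remits anywhere
  expect_error(suppressWarnings(fit_arm_models(d, "post", seed = 7)),
               "single outcome class")
})

test_that("recovery diagnostics match identity and null expectations", {
  d <- small_trial(n = 50, seed = 8)
  perfect <- label_optimization(
    p_memi = (d$true_ite_post + 1) / 2, p_sm = rep(0.5, 50),
    participant_id = d$participant_id, time_point = "post")
  rec <- recovery_report(perfect, d)
  expect_identical(rec$sign_agreement, 1)
  expect_equal(rec$rank_correlation, 1, tolerance = 1e-12)
  # no planted moderation: agreement is a coin flip
  d0 <- small_trial(n = 1000, seed = 9, moderation = 0)
  set.seed(10)
  noise <- label_optimization(runif(1000), runif(1000),
                              participant_id = d0$participant_id,
                              time_point = "post")
  rec0 <- recovery_report(noise, d0)
  expect_gt(rec0$sign_agreement, 0.45)
  expect_lt(rec0$sign_agreement, 0.55)
  # real-data mode (no latent truth) is refused
  d_real <- d
  d_real$true_ite_post <- NULL
  d_real$true_ite_1mfu <- NULL
  expect_error(recovery_report(perfect, d_real), "latent truth")
})

test_that("planted moderation is recovered as ITE sign agreement", {
  # binomial null band at n = 1200 is 0.5 +/- 0.028; recovery must clear
  # it decisively and rank-order the latent effects
  d <- small_trial(n = 1200, seed = 11, missing_rate = 0)
  est <- fit_arm_models(d, "post", n_folds = 5, num_trees = 300, seed = 12)
  rec <- recovery_report(est, d)
  expect_gte(rec$sign_agreement, 0.60)
  expect_gte(rec$rank_correlation, 0.5)
})
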