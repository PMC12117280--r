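test_that("permuted-block randomization balances arms within complete blocks", {
  # fixed block size: every multiple of the block length is exactly balanced
  for (b in c(2L, 4L, 6L)) {
    arm <- permuted_block_randomize(10L * b, block_sizes = b, seed = 7)
    cum_diff <- cumsum(ifelse(arm == 1, 1, -1))
    expect_identical(cum_diff[seq(b, length(arm), by = b)],
                     rep(0, 10))
  }
  expect_identical(permuted_block_randomize(12, c(2), seed = 3),
                   permuted_block_randomize(12, c(2), seed = 3))
  expect_false(identical(permuted_block_randomize(50, c(2, 4), seed = 1),
                         permuted_block_randomize(50, c(2, 4), seed = 2)))
  expect_error(permuted_block_randomize(10, c(3)), "even")
})

test_that("arm imbalance never exceeds half the largest block", {
  # a trailing partial block of size 6 can leave at most a 3-arm surplus
  diffs <- vapply(1:50, function(s) {
    arm <- permuted_block_randomize(191, c(2, 4, 6), seed = s)
    abs(sum(arm == 1) - sum(arm == 0))
  }, numeric(1))
  expect_true(all(diffs <= 3))
  expect_true(any(diffs == 1))  # the 96/95 split is attainable
})

test_that("generator reproduces configured predictor moments", {
  cfg <- generator_config(n_participants = 10000, missing_rate = 0,
                          seed = 42)
  d <- generate_trial(cfg)
  for (nm in names(cfg$predictor_specs)) {
    sp <- cfg$predictor_specs[[nm]]
    if (sp$type == "continuous") {
      se <- sp$sd / sqrt(10000)
      expect_lt(abs(mean(d[[nm]]) - sp$mean), 3 * se)
      expect_lt(abs(sd(d[[nm]]) - sp$sd), 3 * se)
    } else if (sp$type == "binary") {
      se <- sqrt(sp$p * (1 - sp$p) / 10000)
      expect_lt(abs(mean(d[[nm]]) - sp$p), 3.5 * se)
    }
  }
  expect_true(all(d$prompts_completed >= 0 & d$prompts_completed <= 70))
})

test_that("marginal remission rates match their calibration targets", {
  d <- generate_trial(generator_config(n_participants = 20000,
                                       missing_rate = 0, seed = 5))
  expect_lt(abs(mean(classify_remission(d$spdq_post)) - 0.18), 0.03)
  expect_lt(abs(mean(classify_remission(d$spdq_1mfu)) - 0.26), 0.03)
})

test_that("zero interaction weights yield a homogeneous treatment effect", {
  d <- small_trial(n = 2000, seed = 9, moderation = 0)
  expect_identical(var(d$true_ite_post), 0)
  expect_identical(var(d$true_ite_1mfu), 0)
})

test_that("planted moderator signs show up in the latent treatment effect", {
  d <- small_trial(n = 5000, seed = 11)
  # positive mindfulness moderation: high-mindfulness participants gain more
  hi <- d$trait_mindfulness > median(d$trait_mindfulness)
  expect_gt(mean(d$true_ite_post[hi]), mean(d$true_ite_post[!hi]))
  # negative severity moderation: high-severity participants gain less
  hi_sev <- d$sad_severity > median(d$sad_severity)
  expect_lt(mean(d$true_ite_post[hi_sev]), mean(d$true_ite_post[!hi_sev]))
})

test_that("missingness masks the exact cell count and never touches arm", {
  d <- generate_trial(generator_config(n_participants = 191,
                                       missing_rate = 0, seed = 1))
  masked <- apply_missingness(d, 0.10, seed = 2)
  # the 18-column analysis matrix has 191 x 18 = 3438 cells
  expect_identical(attr(masked, "masked_cells"), 344L)
  expect_identical(sum(is.na(analysis_matrix(masked, "post"))), 344L)
  expect_false(anyNA(masked$arm))
  expect_identical(apply_missingness(d, 0), d, ignore_attr = TRUE)
  m2 <- apply_missingness(d, 0.10, seed = 2)
  expect_identical(which(is.na(as.data.frame(masked))),
                   which(is.na(as.data.frame(m2))))
  m3 <- apply_missingness(d, 0.10, seed = 3)
  expect_false(identical(which(is.na(as.data.frame(masked))),
                         which(is.na(as.data.frame(m3)))))
  expect_error(apply_missingness(d, 1.0), "rate")
})

test_that("MAR mechanism spares the driver and loads missingness on high GAD", {
  d <- generate_trial(generator_config(n_participants = 2000,
                                       missing_rate = 0, seed = 3))
  m <- apply_missingness(d, 0.15, seed = 4, mechanism = "mar")
  expect_false(anyNA(m$gad_severity))
  n_miss <- rowSums(is.na(as.data.frame(m)[, predictor_names()]))
  hi <- d$gad_severity > median(d$gad_severity)
  expect_gt(mean(n_miss[hi]), mean(n_miss[!hi]))
})

test_that("trial CSV round-trips with sidecar truth", {
  d <- small_trial(n = 40, seed = 8, missing_rate = 0.1)
  path <- tempfile(fileext = ".csv")
  write_trial_csv(d, path)
  back <- read_trial_csv(path)
  expect_identical(nrow(back), 40L)
  expect_false("true_ite_post" %in%
                 names(read.csv(path)))  # truth only in the sidecar
  expect_equal(back$true_ite_post, d$true_ite_post, tolerance = 1e-12)
  expect_equal(back$spdq_post, d$spdq_post, tolerance = 1e-12)
  expect_identical(levels(back$ethnicity), levels(d$ethnicity))
  unlink(c(path, paste0(path, ".json")))
})
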