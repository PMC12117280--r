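# Synthetic two-arm RCT generator.
#
# Emulates a 191-participant randomized trial of a mindfulness ecological
# momentary intervention (MEMI, arm = 1) versus a self-monitoring app
# (SM, arm = 0) for social anxiety disorder: permuted-block randomization,
# 17 baseline predictors with calibrated marginals, a logistic remission
# model with configurable arm-by-predictor moderation, severity scores
# back-filled around the remission cut-off, and exact-count MCAR/MAR
# missingness. Latent per-person treatment effects are retained so that
# downstream stages can be recovery-tested against ground truth.

SPDQ_REMISSION_CUTOFF <- 12.13

#' Default remission outcome model
#'
#' Logistic model on the remission scale for the two assessment waves
#' (posttreatment and one-month follow-up). Weights are on the standardized
#' predictor scale (log-odds per SD). Defaults plant three strong
#' treatment-effect moderators -- trait mindfulness (+), baseline SAD
#' severity (-), and GAD severity (+) -- consistent with
#' capitalization/compensation accounts of who benefits more from the
#' mindfulness arm, plus modest prognostic main effects. The arm main
#' effect is 0 so that marginal remission rates are equal across arms, and
#' target marginal rates default to 18% at posttreatment and 26% at
#' follow-up.
#'
#' @param moderation Multiplier on the planted interaction weights; `0`
#'   yields a no-moderation (null heterogeneity) trial.
#' @param signal Multiplier on the prognostic main-effect weights.
#' @return List with elements `post` and `1mfu`, each holding
#'   `target_rate`, `arm_effect`, `main`, and `interaction` weights.
#' @export
default_outcome_model <- function(moderation = 1, signal = 1) {
  main <- c(sad_severity = -0.4, depression_severity = -0.3,
            trait_mindfulness = 0.3) * signal
  interaction <- c(trait_mindfulness = 1.5, sad_severity = -1.5,
                   gad_severity = 1.0) * moderation
  list(
    post = list(target_rate = 0.18, intercept = NULL, arm_effect = 0,
                main = main, interaction = interaction),
    "1mfu" = list(target_rate = 0.26, intercept = NULL, arm_effect = 0,
                  main = main, interaction = interaction)
  )
}

#' Build and validate a synthetic-trial generator configuration
#'
#' @param n_participants Number of participants (default 191, the
#'   motivating trial's sample size).
#' @param block_sizes Permuted-block sizes for randomization; all must be
#'   even so complete blocks allocate arms equally. Default `c(2, 4, 6)`.
#' @param predictor_specs Per-predictor marginal specifications, as
#'   returned by [canonical_predictors()].
#' @param outcome_model Remission model, as returned by
#'   [default_outcome_model()]. Intercepts left `NULL` are calibrated by
#'   Monte Carlo so the marginal remission rate hits `target_rate`.
#' @param missing_rate Fraction of analysis cells to mask, in `[0, 1)`.
#'   Default 0.10 (the trial reported 10% missing cells).
#' @param missing_mechanism `"mcar"` (default) or `"mar"` (mask probability
#'   increasing with observed GAD severity).
#' @param spdq_gap_sd Half-normal SDs of the severity-score gap below
#'   (remitters) and above (non-remitters) the remission cut-off.
#' @param prompts Mean/SD of completed prompts out of 70 (engagement was
#'   ~85%, i.e. 60 of 70 prompts, SD ~12).
#' @param seed Integer master seed.
#' @return Object of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_participants = 50, seed = 1)
#' cfg$outcome_model$post$intercept  # calibrated to the 18% target rate
generator_config <- function(n_participants = 191,
                             block_sizes = c(2, 4, 6),
                             predictor_specs = canonical_predictors(),
                             outcome_model = default_outcome_model(),
                             missing_rate = 0.10,
                             missing_mechanism = c("mcar", "mar"),
                             spdq_gap_sd = c(remit = 4, nonremit = 15),
                             prompts = list(mean = 60, sd = 12),
                             seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  assert_that(length(n_participants) == 1 && n_participants >= 1,
              "n_participants must be a positive count")
  assert_that(length(block_sizes) >= 1 && all(block_sizes > 0) &&
                all(block_sizes %% 2 == 0),
              "block_sizes must be positive even integers")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must lie in [0, 1)")
  for (nm in names(predictor_specs)) {
    sp <- predictor_specs[[nm]]
    if (identical(sp$type, "categorical")) {
      assert_that(abs(sum(sp$probs) - 1) <= 1e-9,
                  sprintf("level probabilities for '%s' must sum to 1", nm))
    }
  }
  for (tp in names(outcome_model)) {
    om <- outcome_model[[tp]]
    wn <- c(names(om$main), names(om$interaction))
    bad <- wn[!vapply(predictor_specs[wn], function(s)
      s$type %in% c("continuous", "binary"), logical(1))]
    assert_that(length(bad) == 0, paste0(
      "outcome-model weights must reference continuous or binary ",
      "predictors: ", paste(bad, collapse = ", ")))
    if (is.null(om$intercept)) {
      cal <- calibrate_intercept(om, predictor_specs)
      outcome_model[[tp]]$intercept <- cal$intercept
      outcome_model[[tp]]$arm_offset <- cal$arm_offset
    } else if (is.null(om$arm_offset)) {
      outcome_model[[tp]]$arm_offset <- 0
    }
  }
  structure(list(n_participants = as.integer(n_participants),
                 block_sizes = as.integer(block_sizes),
                 predictor_specs = predictor_specs,
                 outcome_model = outcome_model,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism,
                 spdq_gap_sd = spdq_gap_sd,
                 prompts = prompts,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Calibrate the outcome model by Monte Carlo over the standardized
# predictor distribution (fixed internal stream: the result depends only
# on the configuration, never on the generation seed). The intercept
# pins the control arm's marginal remission rate to target_rate; the arm
# offset then pins the treated arm's marginal rate to the same target,
# which the interaction spread would otherwise inflate (the sigmoid is
# convex below its midpoint, so E[plogis(a + G)] > plogis(a) for
# symmetric G). A user-specified arm_effect adds a genuine average
# effect on top of this equalization.
calibrate_intercept <- function(om, specs, n_mc = 2e5) {
  nms <- union(names(om$main), names(om$interaction))
  with_seed(760519, {
    z <- vapply(nms, function(nm) {
      sp <- specs[[nm]]
      if (sp$type == "continuous") rnorm(n_mc)
      else (rbinom(n_mc, 1, sp$p) - sp$p) / sqrt(sp$p * (1 - sp$p))
    }, numeric(n_mc))
    if (length(nms) == 0) z <- matrix(0, n_mc, 0)
    B <- as.numeric(z %*% weight_vector(om$main, nms))
    G <- as.numeric(z %*% weight_vector(om$interaction, nms))
    a <- uniroot(function(a) mean(plogis(a + B)) - om$target_rate,
                 c(-25, 25), tol = 1e-8)$root
    tau <- if (all(G == 0)) 0 else {
      uniroot(function(tau) {
        mean(plogis(a + tau + B + G)) - om$target_rate
      }, c(-25, 25), tol = 1e-8)$root
    }
    list(intercept = a, arm_offset = tau)
  })
}

weight_vector <- function(w, nms) {
  out <- setNames(numeric(length(nms)), nms)
  out[names(w)] <- w
  out
}

#' Permuted-block randomization
#'
#' Draws a sequence of block sizes uniformly with replacement from
#' `block_sizes`; within each complete block exactly half the assignments
#' go to each arm in a uniformly shuffled order. A final partial block is
#' a shuffled prefix of a balanced block, so the worst-case arm imbalance
#' is `max(block_sizes) / 2`.
#'
#' @param n Number of participants to allocate.
#' @param block_sizes Even positive block sizes (default `c(2, 4, 6)`).
#' @param seed Integer seed.
#' @return Integer vector of length `n` with values 1 (treatment) / 0
#'   (control).
#' @export
#' @examples
#' table(permuted_block_randomize(191, c(2, 4, 6), seed = 7))
permuted_block_randomize <- function(n, block_sizes = c(2, 4, 6), seed = 1L) {
  assert_that(n >= 1, "n must be >= 1")
  assert_that(length(block_sizes) >= 1 && all(block_sizes > 0),
              "block_sizes must be nonempty and positive")
  assert_that(all(block_sizes %% 2 == 0),
              "block_sizes must all be even (balanced blocks)")
  with_seed(seed, {
    arm <- integer(0)
    while (length(arm) < n) {
      b <- block_sizes[[sample.int(length(block_sizes), 1)]]
      block <- sample(rep(c(1L, 0L), each = b / 2))
      arm <- c(arm, block)
    }
    arm[seq_len(n)]
  })
}

#' Generate a synthetic two-arm trial dataset
#'
#' Draws the 17 baseline predictors from their configured marginals,
#' allocates arms by permuted blocks, draws remission at both waves from
#' the logistic outcome model, back-fills severity scores around the
#' remission cut-off (cut-off minus/plus a half-normal gap), draws prompt
#' completion counts, stores each participant's latent true individual
#' treatment effect (risk difference), and finally applies the configured
#' missingness.
#'
#' @param config A [generator_config()].
#' @return A `trial_dataset`: a data.frame with `participant_id`, `arm`
#'   (1 = treatment/MEMI, 0 = control/SM), the 17 predictors, `spdq_post`,
#'   `spdq_1mfu`, `prompts_completed`, and generator-only columns
#'   `true_ite_post` / `true_ite_1mfu`. The config is attached as an
#'   attribute.
#' @export
#' @examples
#' d <- generate_trial(generator_config(n_participants = 60, seed = 3))
#' table(d$arm)
generate_trial <- function(config) {
  assert_that(inherits(config, "generator_config"),
              "config must be a generator_config")
  n <- config$n_participants
  specs <- config$predictor_specs

  pred <- with_seed(derive_seed(config$seed, "predictors"), {
    out <- list()
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      out[[nm]] <- switch(sp$type,
        continuous = rnorm(n, sp$mean, sp$sd),
        binary = rbinom(n, 1, sp$p),
        categorical = factor(sample(names(sp$probs), n, replace = TRUE,
                                    prob = sp$probs),
                             levels = names(sp$probs)))
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })

  arm <- permuted_block_randomize(n, config$block_sizes,
                                  seed = derive_seed(config$seed, "arm"))

  # standardized contributions for the outcome model
  zcol <- function(nm) {
    sp <- specs[[nm]]
    if (sp$type == "continuous") (pred[[nm]] - sp$mean) / sp$sd
    else (pred[[nm]] - sp$p) / sqrt(sp$p * (1 - sp$p))
  }

  data <- data.frame(participant_id = sprintf("P%04d", seq_len(n)),
                     arm = arm, pred, stringsAsFactors = FALSE)

  for (tp in c("post", "1mfu")) {
    om <- config$outcome_model[[tp]]
    nms <- union(names(om$main), names(om$interaction))
    z <- if (length(nms)) vapply(nms, zcol, numeric(n)) else matrix(0, n, 0)
    if (n == 1) z <- matrix(z, nrow = 1)
    B <- as.numeric(z %*% weight_vector(om$main, nms))
    G <- as.numeric(z %*% weight_vector(om$interaction, nms))
    p1 <- plogis(om$intercept + om$arm_offset + om$arm_effect + B + G)
    p0 <- plogis(om$intercept + B)
    p_obs <- ifelse(arm == 1, p1, p0)
    remit <- with_seed(derive_seed(config$seed, "remit", tp),
                       rbinom(n, 1, p_obs))
    spdq <- with_seed(derive_seed(config$seed, "spdq", tp), {
      gap_r <- pmax(pmin(abs(rnorm(n, 0, config$spdq_gap_sd[["remit"]])),
                         SPDQ_REMISSION_CUTOFF - 0.01), 0.01)
      gap_n <- abs(rnorm(n, 0, config$spdq_gap_sd[["nonremit"]]))
      ifelse(remit == 1, SPDQ_REMISSION_CUTOFF - gap_r,
             SPDQ_REMISSION_CUTOFF + gap_n)
    })
    data[[paste0("spdq_", tp)]] <- spdq
    data[[paste0("true_ite_", tp)]] <- p1 - p0
  }

  data$prompts_completed <- with_seed(
    derive_seed(config$seed, "prompts"),
    pmin(70L, pmax(0L, as.integer(round(
      rnorm(n, config$prompts$mean, config$prompts$sd))))))

  data <- as_trial_dataset(data, config)
  if (config$missing_rate > 0) {
    data <- apply_missingness(data, config$missing_rate,
                              seed = derive_seed(config$seed, "missing"),
                              mechanism = config$missing_mechanism)
  }
  data
}

as_trial_dataset <- function(data, config = NULL) {
  structure(data, config = config,
            class = c("trial_dataset", "data.frame"))
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d participants (%d treatment / %d control)\n",
              nrow(x), sum(x$arm == 1), sum(x$arm == 0)))
  n_miss <- attr(x, "masked_cells")
  if (!is.null(n_miss)) cat(sprintf("  masked cells: %d\n", n_miss))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

# Default columns eligible for masking: the 18-column analysis matrix
# (17 predictors + posttreatment outcome). Follow-up outcomes are left
# observed; attrition processes are out of scope for the generator.
default_missing_columns <- function(data) {
  intersect(c(predictor_names(), "spdq_post"), names(data))
}

#' Mask cells of a trial dataset
#'
#' Masks exactly `round(rate * n_cells)` cells of the analysis columns
#' (by default the 17 predictors plus the posttreatment severity score, so
#' a 191-row dataset at rate 0.10 has exactly 344 masked cells). Arm and
#' identifier columns are never masked. Under `"mar"` the per-row masking
#' probability increases with observed GAD severity (which is then itself
#' exempt from masking so the mechanism stays observable).
#'
#' @param data A `trial_dataset` (or plain data.frame).
#' @param rate Fraction of cells to mask, in `[0, 1)`.
#' @param seed Integer seed.
#' @param columns Columns eligible for masking.
#' @param mechanism `"mcar"` (default) or `"mar"`.
#' @return The dataset with masked cells set to `NA`; the number of masked
#'   cells is recorded in the `masked_cells` attribute.
#' @export
#' @examples
#' d <- generate_trial(generator_config(n_participants = 191,
#'                                      missing_rate = 0, seed = 1))
#' attr(apply_missingness(d, 0.10, seed = 2), "masked_cells")  # 344
apply_missingness <- function(data, rate, seed = 1L,
                              columns = default_missing_columns(data),
                              mechanism = c("mcar", "mar")) {
  mechanism <- match.arg(mechanism)
  assert_that(rate >= 0 && rate < 1, "rate must lie in [0, 1)")
  assert_that(!"arm" %in% columns, "the arm column must never be masked")
  if (mechanism == "mar") columns <- setdiff(columns, "gad_severity")
  n <- nrow(data)
  n_cells <- n * length(columns)
  n_mask <- round(rate * n_cells)
  if (n_mask > 0) {
    idx <- with_seed(seed, {
      if (mechanism == "mar") {
        g <- data[["gad_severity"]]
        g[is.na(g)] <- mean(g, na.rm = TRUE)
        w <- rep(plogis(as.numeric(scale(g))), length(columns))
        sample.int(n_cells, n_mask, prob = w)
      } else {
        sample.int(n_cells, n_mask)
      }
    })
    row_i <- (idx - 1L) %% n + 1L
    col_i <- (idx - 1L) %/% n + 1L
    for (j in unique(col_i)) {
      data[row_i[col_i == j], columns[[j]]] <- NA
    }
  }
  attr(data, "masked_cells") <- as.integer(n_mask)
  data
}

#' Per-time-point analysis matrix
#'
#' The 18-column view used by the fold-based analyses: the 17 baseline
#' predictors plus the severity outcome of one assessment wave.
#'
#' @param data A `trial_dataset`.
#' @param time_point `"post"` or `"1mfu"`.
#' @return Data frame with 18 columns.
#' @export
analysis_matrix <- function(data, time_point = c("post", "1mfu")) {
  time_point <- match.arg(time_point)
  data[, c(predictor_names(), paste0("spdq_", time_point))]
}

#' Write / read a trial dataset as CSV plus JSON sidecar
#'
#' The CSV holds one row per participant (missing cells as empty fields);
#' the sidecar holds the generator configuration, seed, and the latent
#' true treatment effects, which are generator-only and never part of the
#' analysis table.
#'
#' @param data A `trial_dataset`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns a `trial_dataset` (with latent truth re-attached when the
#'   sidecar is present).
#' @export
write_trial_csv <- function(data, path) {
  truth_cols <- grep("^true_ite_", names(data), value = TRUE)
  out <- as.data.frame(data)[, setdiff(names(data), truth_cols)]
  write.csv(out, path, row.names = FALSE, na = "")
  cfg <- attr(data, "config")
  sidecar <- list(
    config = if (!is.null(cfg)) unclass(cfg) else NULL,
    seed = if (!is.null(cfg)) cfg$seed else NULL,
    masked_cells = attr(data, "masked_cells"),
    latent_truth = if (length(truth_cols))
      data.frame(participant_id = data$participant_id,
                 as.data.frame(data)[, truth_cols, drop = FALSE])
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trial_csv
#' @param sidecar Whether to look for the JSON sidecar.
#' @export
read_trial_csv <- function(path, sidecar = TRUE) {
  data <- read.csv(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  specs <- canonical_predictors()
  for (nm in intersect(names(specs), names(data))) {
    if (specs[[nm]]$type == "categorical") {
      data[[nm]] <- factor(data[[nm]], levels = names(specs[[nm]]$probs))
    }
  }
  side_path <- paste0(path, ".json")
  masked <- NULL
  if (sidecar && file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$latent_truth) && length(side$latent_truth)) {
      lt <- as.data.frame(side$latent_truth)
      data <- merge(data, lt, by = "participant_id", sort = FALSE)
    }
    masked <- side$masked_cells
  }
  data <- as_trial_dataset(data)
  attr(data, "masked_cells") <- masked
  data
}
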