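# T-learner counterfactual estimation. Arm-specific random-forest outcome
# models predict each participant's remission probability under both
# treatments: the same-arm probability comes from a model whose training
# data excluded that participant's fold (within-arm cross-fitting, which
# removes self-prediction optimism), the counterfactual probability from
# the full model of the opposite arm, which never saw the participant.
# A participant is labelled "optimized" to the treatment arm when the
# imputed remission probability is strictly higher under treatment.

#' Construct counterfactual estimates and the optimization label
#'
#' @param p_memi,p_sm Imputed remission probabilities under the treatment
#'   (MEMI) and control (SM) arms, in `[0, 1]`.
#' @param participant_id Optional identifiers.
#' @param time_point Optional time-point tag.
#' @return Data frame of class `counterfactual_estimates` with `ite`
#'   (`p_memi - p_sm`) and `optimized` (1 exactly when
#'   `p_memi > p_sm`; ties are labelled 0, per the strict "higher than"
#'   definition).
#' @export
#' @examples
#' label_optimization(c(0.8, 0.4, 0.2), c(0.3, 0.4, 0.6))
label_optimization <- function(p_memi, p_sm, participant_id = NULL,
                               time_point = NULL) {
  assert_that(all(p_memi >= 0 & p_memi <= 1) && all(p_sm >= 0 & p_sm <= 1),
              "probabilities must lie in [0, 1]")
  assert_that(length(p_memi) == length(p_sm),
              "probability vectors must align")
  out <- data.frame(
    participant_id = participant_id %||% seq_along(p_memi),
    p_memi = p_memi, p_sm = p_sm,
    ite = p_memi - p_sm,
    optimized = as.integer(p_memi > p_sm),
    stringsAsFactors = FALSE)
  if (!is.null(time_point)) out$time_point <- time_point
  class(out) <- c("counterfactual_estimates", "data.frame")
  out
}

#' Fit arm-specific outcome models and derive counterfactual estimates
#'
#' Trains random-forest remission models separately in each arm.
#' Same-arm probabilities are cross-fitted: each participant's prediction
#' comes from the model trained with their fold held out (stratified
#' within-arm folds), with preprocessing (imputation, standardization,
#' encoding) refit inside every cross-fit training split. Counterfactual
#' probabilities come from the full model of the opposite arm.
#' Participants with a missing outcome are excluded from training and
#' predicted by the full models of both arms.
#'
#' @param data A `trial_dataset`.
#' @param time_point `"post"` or `"1mfu"`.
#' @param n_folds Within-arm cross-fit folds (default 10; reduced with a
#'   warning when an arm's minority outcome class is smaller).
#' @param num_trees Trees per outcome forest (default 500).
#' @param impute_trees Trees per imputation forest.
#' @param seed Integer seed.
#' @return A `counterfactual_estimates` data frame (one row per
#'   participant: `p_memi`, `p_sm`, `ite`, `optimized`, plus arm and
#'   cross-fit fold bookkeeping). The fitted full models and preprocessor
#'   states are attached as the `models` attribute.
#' @export
fit_arm_models <- function(data, time_point = c("post", "1mfu"),
                           n_folds = 10L, num_trees = 500L,
                           impute_trees = 100L, seed = 1L) {
  time_point <- match.arg(time_point)
  outcome <- classify_remission(data[[paste0("spdq_", time_point)]])
  pred_df <- as.data.frame(data)[, predictor_names()]
  n <- nrow(data)
  p_same <- rep(NA_real_, n)
  p_other <- rep(NA_real_, n)
  cf_fold <- rep(NA_integer_, n)
  models <- list()

  for (a in c(1L, 0L)) {
    in_arm <- which(data$arm == a)
    trainable <- in_arm[!is.na(outcome[in_arm])]
    y <- outcome[trainable]
    if (length(unique(y)) < 2) {
      stop(sprintf(
        "arm %d has a single outcome class; arm-specific model cannot be fit",
        a), call. = FALSE)
    }
    arm_tag <- if (a == 1L) "memi" else "sm"
    # full-arm model: used for counterfactual (other-arm) predictions and
    # for arm members without an observed outcome
    state_full <- preprocess_fit(pred_df[trainable, , drop = FALSE],
                                 seed = derive_seed(seed, arm_tag, "prep"),
                                 num_trees = impute_trees,
                                 partition_id = paste0("arm-", arm_tag))
    X_full <- standardize_and_encode(state_full,
                                     pred_df[trainable, , drop = FALSE])
    model_full <- fit_learner("random_forest", X_full, y,
                              params = list(num_trees = num_trees),
                              seed = derive_seed(seed, arm_tag, "full"))
    models[[arm_tag]] <- list(state = state_full, model = model_full)

    k <- min(n_folds, min(table(y)))
    if (k < n_folds) {
      warning(sprintf("arm %d: cross-fit folds reduced to %d", a, k))
    }
    folds <- stratified_folds(y, k, seed = derive_seed(seed, arm_tag,
                                                       "folds"))
    cf_fold[trainable] <- folds
    for (f in seq_len(k)) {
      tr <- trainable[folds != f]
      te <- trainable[folds == f]
      state_f <- preprocess_fit(pred_df[tr, , drop = FALSE],
                                seed = derive_seed(seed, arm_tag, "prep", f),
                                num_trees = impute_trees,
                                partition_id = sprintf("arm-%s-cf%d",
                                                       arm_tag, f))
      Xtr <- standardize_and_encode(state_f, pred_df[tr, , drop = FALSE])
      m_f <- fit_learner("random_forest", Xtr, outcome[tr],
                         params = list(num_trees = num_trees),
                         seed = derive_seed(seed, arm_tag, "cf", f))
      Xte <- standardize_and_encode(state_f, pred_df[te, , drop = FALSE])
      p_same[te] <- predict_learner(m_f, Xte)
    }
    # arm members without an observed outcome: full same-arm model
    rest <- setdiff(in_arm, trainable)
    if (length(rest)) {
      Xr <- standardize_and_encode(state_full,
                                   pred_df[rest, , drop = FALSE])
      p_same[rest] <- predict_learner(model_full, Xr)
    }
  }

  for (a in c(1L, 0L)) {
    in_arm <- which(data$arm == a)
    other <- models[[if (a == 1L) "sm" else "memi"]]
    Xo <- standardize_and_encode(other$state,
                                 pred_df[in_arm, , drop = FALSE])
    p_other[in_arm] <- predict_learner(other$model, Xo)
  }

  p_memi <- ifelse(data$arm == 1, p_same, p_other)
  p_sm <- ifelse(data$arm == 1, p_other, p_same)
  est <- label_optimization(p_memi, p_sm,
                            participant_id = data$participant_id,
                            time_point = time_point)
  est$arm <- data$arm
  est$cf_fold <- cf_fold
  attr(est, "models") <- models
  est
}

#' Recovery diagnostics against latent generator truth
#'
#' Compares estimated individual treatment effects with the generator's
#' latent true effects: the fraction of participants whose estimated ITE
#' falls on the correct side of zero, and the Spearman rank correlation
#' between estimated and true effects.
#'
#' @param estimates A `counterfactual_estimates` data frame.
#' @param data The generating `trial_dataset` (must carry
#'   `true_ite_<time_point>`).
#' @return List with `sign_agreement`, `rank_correlation`, and `n`.
#' @export
recovery_report <- function(estimates, data) {
  tp <- estimates$time_point[1] %||% "post"
  truth_col <- paste0("true_ite_", tp)
  if (!truth_col %in% names(data)) {
    stop("dataset carries no latent truth (real-data mode); ",
         "recovery diagnostics need a synthetic trial", call. = FALSE)
  }
  truth <- data[[truth_col]][match(estimates$participant_id,
                                   data$participant_id)]
  agree <- mean((estimates$ite > 0) == (truth > 0))
  rc <- if (sd(truth) > 0 && sd(estimates$ite) > 0) {
    cor(estimates$ite, truth, method = "spearman")
  } else NA_real_
  list(sign_agreement = agree, rank_correlation = rc,
       n = nrow(estimates))
}
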