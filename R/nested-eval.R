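# Nested repeated cross-validated evaluation of optimization-label
# classifiers. Outer folds give unbiased test estimates; inner folds do
# hyperparameter selection; preprocessing, screening and SMOTE are all
# fitted strictly inside the outer-training partition. Metrics: rank AUC
# with percentile CI, accuracy, balanced accuracy, sensitivity,
# specificity, PPV, F1, AUPRC, and a point-biserial calibration effect
# size, plus DeLong comparisons of correlated AUCs against the logistic
# reference.

#' Rank (Mann-Whitney) AUC
#'
#' Probability that a uniformly random positive case outranks a uniformly
#' random negative case, ties counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0,
              "AUC is undefined unless both classes are present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve by step integration (average
# precision): sum over descending score thresholds of precision times the
# recall increment. No trapezoids, so precision spikes are not
# interpolated away.
auprc_step <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  if (P == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # collapse tied thresholds
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / P
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Point-biserial calibration effect size
#'
#' Correlation between predicted probabilities and the realized binary
#' outcome, converted to a Cohen-d-style effect via
#' `d = 2 r / sqrt(1 - r^2)`.
#'
#' @param probabilities Predicted probabilities in `[0, 1]`.
#' @param labels Binary outcomes.
#' @return List with `r`, `d`, and `flag` (`"ok"`, `"degenerate"` for
#'   zero-variance predictions, `"infinite"` for `|r|` at 1).
#' @export
#' @examples
#' calibration_effect(c(0.9, 0.8, 0.2, 0.4), c(1, 1, 0, 0))
calibration_effect <- function(probabilities, labels) {
  assert_that(all(probabilities >= 0 & probabilities <= 1),
              "probabilities must lie in [0, 1]")
  labels <- as.integer(labels)
  if (sd(probabilities) == 0 || sd(labels) == 0) {
    return(list(r = NA_real_, d = NA_real_, flag = "degenerate"))
  }
  r <- cor(probabilities, labels)
  if (abs(r) >= 1 - 1e-12) {
    return(list(r = r, d = Inf * sign(r), flag = "infinite"))
  }
  list(r = r, d = 2 * r / sqrt(1 - r^2), flag = "ok")
}

#' Threshold and ranking metrics for one evaluation
#'
#' Confusion-matrix metrics at a probability threshold, plus rank AUC,
#' step-integrated AUPRC, and the calibration effect. The reported
#' `calibration_d` is the magnitude of the effect; `calibration_r`
#' carries its sign.
#'
#' @param scores Predicted probabilities.
#' @param labels Binary labels.
#' @param threshold Classification threshold (default 0.5).
#' @return One-row data frame: auc, accuracy, bac, sensitivity,
#'   specificity, ppv, f1, auprc, calibration_r, calibration_d.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  assert_that(length(scores) == length(labels) && length(labels) > 0,
              "scores and labels must be nonempty and aligned")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && ppv + sens > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  both <- length(unique(labels)) == 2
  cal <- calibration_effect(pmin(pmax(scores, 0), 1), labels)
  data.frame(
    auc = if (both) auc_rank(scores, labels) else NA_real_,
    accuracy = (tp + tn) / length(labels),
    bac = (sens + spec) / 2,
    sensitivity = sens, specificity = spec, ppv = ppv, f1 = f1,
    auprc = if (both) auprc_step(scores, labels) else NA_real_,
    calibration_r = cal$r,
    calibration_d = abs(cal$d))
}

#' DeLong test for two correlated AUCs
#'
#' Fast placement-value formulation: per-case placement values give the
#' AUCs and their covariance across the two paired score vectors; the
#' AUC difference is referred to a standard normal.
#'
#' @param scores_a,scores_b Paired score vectors on the same cases.
#' @param labels Binary labels.
#' @return List with `auc_a`, `auc_b`, `z`, and two-sided `p_value`.
#'   Identical (or rank-identical) score vectors give `z = 0`, `p = 1`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  assert_that(length(scores_a) == length(scores_b) &&
                length(scores_a) == length(labels),
              "paired scores and labels must align")
  pos <- labels == 1; neg <- labels == 0
  m <- sum(pos); n <- sum(neg)
  assert_that(m > 0 && n > 0, "both classes must be present")
  placements <- function(s) {
    X <- s[pos]; Y <- s[neg]
    v10 <- vapply(X, function(x) mean((x > Y) + 0.5 * (x == Y)), numeric(1))
    v01 <- vapply(Y, function(y) mean((X > y) + 0.5 * (X == y)), numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(v) || v < 1e-14) {
    z <- 0
  } else {
    z <- (pa$auc - pb$auc) / sqrt(v)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Model specification for the nested evaluation
#'
#' @param algorithm `"random_forest"`, `"svm_rbf"`, or
#'   `"logistic_reference"`.
#' @param grid Optional explicit hyperparameter grid (data frame); by
#'   default the grid is built from the post-screening feature count `p`:
#'   RF uses 500 trees with variables-per-split in
#'   `{floor(sqrt(p)/2), floor(sqrt(p)), 2 floor(sqrt(p))}`; the RBF SVM
#'   uses cost in `{0.25, 1, 4, 16}` and kernel width in
#'   `{1/(2p), 1/p, 2/p}`; the logistic reference has no grid.
#' @param num_trees Trees for random forests.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("random_forest", "svm_rbf",
                                     "logistic_reference"),
                       grid = NULL, num_trees = 500L) {
  algorithm <- match.arg(algorithm)
  if (!is.null(grid)) {
    assert_that(nrow(grid) >= 1, "an explicit grid must be nonempty")
  }
  structure(list(algorithm = algorithm, grid = grid,
                 num_trees = as.integer(num_trees)),
            class = "model_spec")
}

default_grid <- function(algorithm, p, num_trees = 500L) {
  switch(algorithm,
    random_forest = {
      base <- floor(sqrt(p))
      data.frame(num_trees = num_trees,
                 mtry = unique(pmax(1L, c(floor(base / 2), base, 2L * base))))
    },
    svm_rbf = expand.grid(cost = c(0.25, 1, 4, 16),
                          gamma = c(1 / (2 * p), 1 / p, 2 / p)),
    logistic_reference = data.frame(dummy = 0))
}

# Fit everything for one outer fold: preprocessing, screening, SMOTE,
# inner grid search, and final per-model fits; score the untouched outer
# test rows. Outer-test labels are never read -- the leakage sentinel
# tests rely on that.
fit_outer_fold <- function(pred_df, labels, train_idx, test_idx, specs,
                           opts, seed) {
  y_tr <- labels[train_idx]
  state <- preprocess_fit(pred_df[train_idx, , drop = FALSE],
                          seed = derive_seed(seed, "prep"),
                          num_trees = opts$impute_trees,
                          max_iter = opts$impute_max_iter %||% 10L,
                          partition_id = "outer-train")
  X_tr <- standardize_and_encode(state, pred_df[train_idx, , drop = FALSE])
  X_te <- standardize_and_encode(state, pred_df[test_idx, , drop = FALSE])
  screen <- NULL
  if (opts$screening) {
    screen <- elastic_net_screen(X_tr, y_tr, k = opts$top_k,
                                 n_inner = opts$n_inner,
                                 seed = derive_seed(seed, "screen"))
    fmap <- feature_map(X_tr)
    keep <- names(fmap)[fmap %in% screen$selected]
    sub <- function(X) {
      out <- X[, keep, drop = FALSE]
      attr(out, "feature_map") <- fmap[keep]
      out
    }
    X_tr <- sub(X_tr); X_te <- sub(X_te)
  }
  k_inner <- min(opts$n_inner, min(table(y_tr)))
  inner <- stratified_folds(y_tr, k_inner,
                            seed = derive_seed(seed, "inner"))
  rebalance <- function(X, y, tag) {
    if (!opts$smote) {
      return(list(features = X, labels = y))
    }
    smote_rebalance(X, y, k_neighbors = opts$smote_k,
                    target_ratio = opts$smote_ratio %||% 1.0,
                    seed = derive_seed(seed, "smote", tag))
  }
  out <- list()
  for (spec in specs) {
    grid <- spec$grid %||% default_grid(spec$algorithm, ncol(X_tr),
                                        spec$num_trees)
    best_i <- 1L
    if (nrow(grid) > 1) {
      grid_auc <- matrix(NA_real_, k_inner, nrow(grid))
      for (f in seq_len(k_inner)) {
        tr2 <- inner != f
        va2 <- inner == f
        if (length(unique(y_tr[va2])) < 2) next
        reb <- rebalance(X_tr[tr2, , drop = FALSE], y_tr[tr2],
                         tag = paste0("inner", f))
        for (g in seq_len(nrow(grid))) {
          m <- fit_learner(spec$algorithm, reb$features, reb$labels,
                           params = as.list(grid[g, , drop = FALSE]),
                           seed = derive_seed(seed, spec$algorithm, f, g))
          sc <- predict_learner(m, X_tr[va2, , drop = FALSE])
          grid_auc[f, g] <- auc_rank(sc, y_tr[va2])
        }
      }
      mean_auc <- colMeans(grid_auc, na.rm = TRUE)
      best_i <- which.max(mean_auc)  # first maximum: deterministic
    }
    reb <- rebalance(X_tr, y_tr, tag = "outer")
    model <- fit_learner(spec$algorithm, reb$features, reb$labels,
                         params = as.list(grid[best_i, , drop = FALSE]),
                         seed = derive_seed(seed, spec$algorithm, "final"))
    stopifnot(!any(reb$synthetic %||% FALSE) || opts$smote)
    out[[spec$algorithm]] <- list(
      scores = predict_learner(model, X_te),
      best_params = as.list(grid[best_i, , drop = FALSE]),
      model = model)
  }
  list(models = out, screen = screen, state = state)
}

#' Nested repeated cross-validated evaluation
#'
#' For every repeat and outer fold: fit preprocessing, elastic-net
#' screening, SMOTE and the inner grid search strictly on the
#' outer-training partition, then evaluate once on the untouched outer
#' test partition. Metrics are averaged over all repeat-by-fold
#' evaluations; the AUC confidence interval is the percentile interval of
#' repeat-level mean AUCs. Per-participant scores (averaged across
#' repeats) feed paired DeLong comparisons against the logistic
#' reference.
#'
#' @param data A `trial_dataset` or a data frame of baseline predictors.
#' @param labels Binary optimization labels (from [fit_arm_models()]).
#' @param model_specs List of [model_spec()] objects.
#' @param plan Optional [make_fold_plan()]; built from the sizes below
#'   when `NULL`.
#' @param n_outer,n_inner,n_repeats Fold-plan sizes (defaults 10/10/10).
#' @param screening Apply fold-internal elastic-net screening?
#' @param top_k Predictors retained by screening (default 10).
#' @param smote Apply fold-internal SMOTE rebalancing?
#' @param smote_k SMOTE neighbour count.
#' @param smote_ratio Target minority/majority ratio after rebalancing.
#' @param threshold Classification threshold for confusion metrics.
#' @param impute_trees Trees per imputation forest.
#' @param impute_max_iter Maximum chained imputation sweeps.
#' @param seed Master seed; the run is bit-reproducible given the seed.
#' @return Object of class `nested_cv_result`: `summary` (per-model
#'   aggregated metrics with AUC CI), `per_fold` metrics, `delong`
#'   comparisons, `final_predictors` (modal screening selection),
#'   `scores` (participants x models, averaged over repeats), and the
#'   fold `plan`.
#' @export
run_nested_cv <- function(data, labels,
                          model_specs = list(model_spec("random_forest"),
                                             model_spec("svm_rbf"),
                                             model_spec("logistic_reference")),
                          plan = NULL, n_outer = 10L, n_inner = 10L,
                          n_repeats = 10L, screening = TRUE, top_k = 10L,
                          smote = TRUE, smote_k = 5L, smote_ratio = 1.0,
                          threshold = 0.5, impute_trees = 100L,
                          impute_max_iter = 10L, seed = 1L) {
  pred_df <- if (inherits(data, "trial_dataset")) {
    as.data.frame(data)[, predictor_names()]
  } else {
    as.data.frame(data)
  }
  labels <- as.integer(labels)
  assert_that(nrow(pred_df) == length(labels),
              "labels must align with the predictor rows")
  plan <- plan %||% make_fold_plan(labels, n_outer, n_inner, n_repeats,
                                   seed = derive_seed(seed, "plan"))
  opts <- list(screening = screening, top_k = top_k, smote = smote,
               smote_k = smote_k, smote_ratio = smote_ratio,
               n_inner = plan$n_inner, impute_trees = impute_trees,
               impute_max_iter = impute_max_iter)
  algs <- vapply(model_specs, function(s) s$algorithm, character(1))
  per_fold <- list()
  screens <- list()
  score_sum <- matrix(0, nrow(pred_df), length(algs),
                      dimnames = list(NULL, algs))
  for (r in seq_len(plan$n_repeats)) {
    folds <- plan$assignments[, r]
    for (f in seq_len(plan$n_outer)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      fit <- fit_outer_fold(pred_df, labels, train_idx, test_idx,
                            model_specs, opts,
                            seed = derive_seed(seed, "r", r, "f", f))
      if (!is.null(fit$screen)) screens[[length(screens) + 1]] <- fit$screen
      for (alg in algs) {
        sc <- fit$models[[alg]]$scores
        score_sum[test_idx, alg] <- score_sum[test_idx, alg] + sc
        row <- classification_metrics(sc, labels[test_idx], threshold)
        row <- cbind(data.frame(model = alg, repeat_id = r, fold = f,
                                stringsAsFactors = FALSE), row)
        row$best_params <- paste(names(fit$models[[alg]]$best_params),
                                 unlist(fit$models[[alg]]$best_params),
                                 sep = "=", collapse = ";")
        per_fold[[length(per_fold) + 1]] <- row
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)
  scores <- score_sum / plan$n_repeats

  metric_cols <- c("auc", "accuracy", "bac", "sensitivity", "specificity",
                   "ppv", "f1", "auprc", "calibration_r", "calibration_d")
  summary <- do.call(rbind, lapply(algs, function(alg) {
    rows <- per_fold[per_fold$model == alg, ]
    means <- colMeans(rows[, metric_cols], na.rm = TRUE)
    rep_auc <- tapply(rows$auc, rows$repeat_id,
                      function(x) mean(x, na.rm = TRUE))
    ci <- quantile(rep_auc, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    cbind(data.frame(model = alg, stringsAsFactors = FALSE),
          as.data.frame(as.list(means)),
          data.frame(auc_lci = ci[1], auc_uci = ci[2]))
  }))

  delong <- list()
  if ("logistic_reference" %in% algs) {
    for (alg in setdiff(algs, "logistic_reference")) {
      delong[[alg]] <- delong_test(scores[, alg],
                                   scores[, "logistic_reference"], labels)
    }
  }
  final_predictors <- if (length(screens)) {
    modal_selection(screens, top_k)
  } else {
    character(0)
  }
  structure(list(summary = summary, per_fold = per_fold, delong = delong,
                 final_predictors = final_predictors, scores = scores,
                 labels = labels, plan = plan, seed = seed,
                 settings = opts),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("<nested_cv_result> %d repeats x %d outer folds, %d cases\n",
              x$plan$n_repeats, x$plan$n_outer, length(x$labels)))
  print(x$summary[, c("model", "auc", "auc_lci", "auc_uci", "accuracy",
                      "bac", "sensitivity", "specificity", "ppv", "f1",
                      "auprc")],
        row.names = FALSE, digits = 3)
  if (length(x$final_predictors)) {
    cat("final predictors:", paste(x$final_predictors, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Table of aggregated metrics in report shape
#'
#' @param result A `nested_cv_result`.
#' @param configuration Label for the predictor configuration (for
#'   example `"initial"` or `"final"`).
#' @param time_point Label for the assessment wave.
#' @return Data frame, one row per model.
#' @export
metrics_table <- function(result, configuration = "initial",
                          time_point = "post") {
  cbind(data.frame(time_point = time_point,
                   configuration = configuration,
                   stringsAsFactors = FALSE),
        result$summary)
}
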