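# Kernel SHAP attribution. Model-agnostic Shapley values estimated by a
# constrained least-squares fit over coalitions sampled from the Shapley
# kernel: masked-out features are integrated over a background sample,
# and the additivity constraint (base value + attributions = prediction)
# is enforced exactly per explained instance. One-hot indicator blocks
# are re-aggregated to their source predictor by summation.

#' Kernel SHAP attributions
#'
#' @param model A predict-probability function taking a numeric feature
#'   matrix, or an internal learner object.
#' @param background Numeric background feature matrix (the reference
#'   distribution missing features are integrated over).
#' @param instances Numeric feature matrix of instances to explain
#'   (same columns as `background`).
#' @param n_coalitions Number of sampled coalitions (default `8 p`,
#'   minimum `p + 2`); coalition sizes are drawn from the Shapley kernel
#'   and each coalition is paired with its complement.
#' @param seed Integer seed for coalition sampling.
#' @param feature_map Optional column-to-predictor map; defaults to the
#'   `feature_map` attribute of `instances`.
#' @return Object of class `shap_summary`: `attributions` (instances x
#'   predictors, one-hot blocks summed), `column_attributions`,
#'   `base_value` (mean background prediction), `fx` (per-instance model
#'   predictions), and the instance feature `values`.
#' @export
kernel_shap <- function(model, background, instances, n_coalitions = NULL,
                        seed = 1L, feature_map = NULL) {
  predict_fun <- if (is.function(model)) {
    model
  } else if (inherits(model, "prescriptr_learner")) {
    function(X) predict_learner(model, X)
  } else if (inherits(model, "prescriptr_model")) {
    model$predict_encoded
  } else {
    stop("model must be a function or a fitted learner", call. = FALSE)
  }
  background <- as.matrix(background)
  instances <- as.matrix(instances)
  p <- ncol(instances)
  assert_that(nrow(background) >= 1, "background must be nonempty")
  assert_that(ncol(background) == p,
              "background and instances must share columns")
  fmap <- feature_map %||% attr(instances, "feature_map") %||%
    setNames(colnames(instances), colnames(instances))
  M <- n_coalitions %||% max(8L * p, p + 2L)
  assert_that(M >= p + 2, "n_coalitions must be at least p + 2")

  base_value <- mean(predict_fun(background))
  fx <- as.numeric(predict_fun(instances))
  if (p == 1) {
    # single feature: the whole gap is its attribution
    col_attr <- matrix(fx - base_value, ncol = 1,
                       dimnames = list(NULL, colnames(instances)))
    return(new_shap_summary(col_attr, fmap, base_value, fx, instances))
  }

  Z <- with_seed(derive_seed(seed, "coalitions"), {
    sizes <- seq_len(p - 1)
    w <- (p - 1) / (sizes * (p - sizes))  # kernel mass per coalition size
    half <- ceiling(M / 2)
    s_draw <- sample(sizes, half, replace = TRUE, prob = w / sum(w))
    Zh <- t(vapply(s_draw, function(s) {
      z <- numeric(p)
      z[sample.int(p, s)] <- 1
      z
    }, numeric(p)))
    rbind(Zh, 1 - Zh)[seq_len(2 * half), , drop = FALSE]
  })

  A <- crossprod(Z) + diag(1e-8, p)
  K <- rbind(cbind(A, rep(1, p)), c(rep(1, p), 0))
  nb <- nrow(background)
  rhs <- matrix(0, p + 1, nrow(instances))
  for (i in seq_len(nrow(instances))) {
    x <- instances[i, ]
    # each coalition row: background rows with coalition features set to x
    masked <- background[rep(seq_len(nb), times = nrow(Z)), , drop = FALSE]
    on <- Z[rep(seq_len(nrow(Z)), each = nb), , drop = FALSE] == 1
    xrep <- matrix(x, nrow(masked), p, byrow = TRUE)
    masked[on] <- xrep[on]
    v <- colMeans(matrix(predict_fun(masked), nrow = nb))
    rhs[, i] <- c(crossprod(Z, v - base_value), fx[i] - base_value)
  }
  phi <- solve(K, rhs)[seq_len(p), , drop = FALSE]
  col_attr <- t(phi)
  colnames(col_attr) <- colnames(instances)
  new_shap_summary(col_attr, fmap, base_value, fx, instances)
}

new_shap_summary <- function(col_attr, fmap, base_value, fx, values) {
  predictors <- unique(unname(fmap))
  agg <- vapply(predictors, function(pr) {
    cols <- names(fmap)[fmap == pr]
    rowSums(col_attr[, cols, drop = FALSE])
  }, numeric(nrow(col_attr)))
  if (nrow(col_attr) == 1) agg <- matrix(agg, nrow = 1,
                                         dimnames = list(NULL, predictors))
  structure(list(attributions = agg, column_attributions = col_attr,
                 base_value = base_value, fx = fx, values = values,
                 feature_map = fmap),
            class = "shap_summary")
}

#' @export
print.shap_summary <- function(x, ...) {
  cat(sprintf("<shap_summary> %d instances, %d predictors, base value %.3f\n",
              nrow(x$attributions), ncol(x$attributions), x$base_value))
  imp <- sort(colMeans(abs(x$attributions)), decreasing = TRUE)
  print(round(head(imp, 10), 4))
  invisible(x)
}

#' Rank predictors by SHAP importance with signed direction
#'
#' Importance is the mean absolute aggregated attribution; ranks are
#' 1..p with deterministic ties broken by canonical predictor-name
#' order. Direction is the sign of the Spearman correlation between a
#' predictor's value and its attribution (for a multi-level nominal
#' block, the indicator column with the largest mean absolute
#' attribution represents the block); predictors with zero importance or
#' undefined correlation get direction `"null"`.
#'
#' @param summary A [kernel_shap()] result.
#' @param k Number of top predictors to return (default 10; clamped with
#'   a warning when `k > p`).
#' @return Data frame of class `shap_ranking`: predictor, importance,
#'   rank, direction -- top-k rows.
#' @export
rank_and_sign <- function(summary, k = 10L) {
  assert_that(inherits(summary, "shap_summary"),
              "summary must come from kernel_shap()")
  agg <- summary$attributions
  predictors <- colnames(agg)
  if (k > length(predictors)) {
    warning(sprintf("k = %d exceeds %d predictors; clamped", k,
                    length(predictors)))
    k <- length(predictors)
  }
  importance <- colMeans(abs(agg))
  fmap <- summary$feature_map
  direction <- vapply(predictors, function(pr) {
    if (importance[[pr]] <= 1e-12) return("null")
    cols <- names(fmap)[fmap == pr]
    rep_col <- if (length(cols) == 1) cols else {
      cols[which.max(colMeans(abs(
        summary$column_attributions[, cols, drop = FALSE])))]
    }
    val <- summary$values[, rep_col]
    if (sd(val) == 0) return("null")
    s <- suppressWarnings(cor(val, agg[, pr], method = "spearman"))
    if (!is.finite(s) || s == 0) "null" else if (s > 0) "positive"
    else "negative"
  }, character(1))
  ord <- order(-importance, match(predictors, predictors))
  out <- data.frame(predictor = predictors[ord],
                    importance = unname(importance[ord]),
                    rank = seq_along(predictors),
                    direction = unname(direction[ord]),
                    stringsAsFactors = FALSE)
  out <- head(out, k)
  class(out) <- c("shap_ranking", "data.frame")
  out
}

#' Cross-time-point direction consistency
#'
#' Flags predictors whose attribution direction flips between two
#' rankings (for example posttreatment vs one-month follow-up models).
#'
#' @param ranking_a,ranking_b Two [rank_and_sign()] results.
#' @return Data frame: predictor, direction in each ranking, and a
#'   `consistent` flag (directions equal and non-null).
#' @export
direction_consistency <- function(ranking_a, ranking_b) {
  shared <- intersect(ranking_a$predictor, ranking_b$predictor)
  da <- ranking_a$direction[match(shared, ranking_a$predictor)]
  db <- ranking_b$direction[match(shared, ranking_b$predictor)]
  data.frame(predictor = shared, direction_a = da, direction_b = db,
             consistent = da == db & da != "null",
             stringsAsFactors = FALSE)
}

#' Beeswarm-style SHAP summary plot
#'
#' Jittered per-instance attributions per predictor, coloured by the
#' (scaled) predictor value, predictors ordered by importance.
#'
#' @param summary A [kernel_shap()] result.
#' @param k Predictors shown.
#' @return A ggplot object.
#' @export
plot_shap_summary <- function(summary, k = 10L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_shap_summary() needs the ggplot2 package", call. = FALSE)
  }
  ranking <- rank_and_sign(summary, k = k)
  fmap <- summary$feature_map
  rows <- lapply(ranking$predictor, function(pr) {
    cols <- names(fmap)[fmap == pr]
    rep_col <- if (length(cols) == 1) cols else {
      cols[which.max(colMeans(abs(
        summary$column_attributions[, cols, drop = FALSE])))]
    }
    val <- summary$values[, rep_col]
    rng <- range(val)
    scaled <- if (diff(rng) > 0) (val - rng[1]) / diff(rng) else 0.5
    data.frame(predictor = pr, attribution = summary$attributions[, pr],
               value = scaled, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$predictor <- factor(df$predictor, levels = rev(ranking$predictor))
  ggplot2::ggplot(df, ggplot2::aes(x = attribution, y = predictor,
                                   colour = value)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.7, size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_colour_gradient(low = "#3b4cc0", high = "#b40426",
                                   name = "value") +
    ggplot2::labs(x = "SHAP attribution (probability scale)", y = NULL)
}

#' Fit a final model on one partition for interpretation
#'
#' Convenience wrapper used by the reporting stage: preprocesses the
#' data, optionally screens to the top-k predictors, fits the learner,
#' and returns an object whose encoded design and predict function plug
#' straight into [kernel_shap()].
#'
#' @param data A `trial_dataset` or predictor data frame.
#' @param labels Binary optimization labels.
#' @param algorithm Learner (default random forest).
#' @param screening Screen to `top_k` predictors first?
#' @param top_k Predictors retained.
#' @param num_trees Forest size.
#' @param impute_trees Trees per imputation forest.
#' @param seed Integer seed.
#' @return Object of class `prescriptr_model` with elements `features`
#'   (encoded matrix), `predict_encoded`, `screen`, `state`, `learner`.
#' @export
final_model <- function(data, labels, algorithm = "random_forest",
                        screening = TRUE, top_k = 10L, num_trees = 500L,
                        impute_trees = 100L, seed = 1L) {
  pred_df <- if (inherits(data, "trial_dataset")) {
    as.data.frame(data)[, predictor_names()]
  } else {
    as.data.frame(data)
  }
  labels <- as.integer(labels)
  state <- preprocess_fit(pred_df, seed = derive_seed(seed, "prep"),
                          num_trees = impute_trees,
                          partition_id = "final")
  X <- standardize_and_encode(state, pred_df)
  screen <- NULL
  if (screening) {
    screen <- elastic_net_screen(X, labels, k = top_k,
                                 seed = derive_seed(seed, "screen"))
    fmap <- feature_map(X)
    keep <- names(fmap)[fmap %in% screen$selected]
    X <- X[, keep, drop = FALSE]
    attr(X, "feature_map") <- fmap[keep]
  }
  learner <- fit_learner(algorithm, X, labels,
                         params = list(num_trees = num_trees),
                         seed = derive_seed(seed, "fit"))
  structure(list(features = X, state = state, screen = screen,
                 learner = learner,
                 predict_encoded = function(M) predict_learner(learner, M)),
            class = "prescriptr_model")
}
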