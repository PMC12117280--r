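# Fold-aware preprocessing: stratified repeated fold plans, iterative
# chained random-forest imputation, training-partition standardization and
# one-hot encoding, and SMOTE class rebalancing. Every state object here is
# fitted strictly on a training partition and applied, frozen, to held-out
# rows -- this module is the leakage-control layer of the pipeline.

#' Stratified fold assignment for one repeat
#'
#' Assigns each case to one of `k` folds so that fold sizes differ by at
#' most one and per-class counts per fold differ by at most one.
#'
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts > 0 & counts < k)) {
    stop(sprintf(
      "a class has fewer members (%d) than folds (%d); reduce the number of folds",
      min(counts[counts > 0]), k), call. = FALSE)
  }
  with_seed(seed, {
    fold <- integer(n)
    # class 1 first: shuffled balanced deal, random folds get the extras
    extras1 <- integer(0)
    for (cl in c(1L, 0L)) {
      idx <- sample(which(labels == cl))
      m <- length(idx)
      if (m == 0) next
      base <- m %/% k
      e <- m %% k
      if (cl == 1L) {
        extra_folds <- sample.int(k, e)
        extras1 <- extra_folds
      } else {
        # prefer folds that did not receive a class-1 extra, so total fold
        # sizes still differ by at most one
        pool <- sample(setdiff(seq_len(k), extras1))
        pool <- c(pool, sample(extras1))
        extra_folds <- pool[seq_len(e)]
      }
      sizes <- rep(base, k)
      sizes[extra_folds] <- sizes[extra_folds] + 1L
      fold[idx] <- rep(seq_len(k), times = sizes)
    }
    fold
  })
}

#' Build a repeated stratified outer-fold plan
#'
#' @param labels Binary label vector to stratify on.
#' @param n_outer,n_inner,n_repeats Fold counts (defaults 10/10/10).
#' @param seed Master seed; each repeat uses a distinct derived seed.
#' @return Object of class `fold_plan` with an `assignments` matrix
#'   (cases x repeats).
#' @export
#' @examples
#' plan <- make_fold_plan(rbinom(191, 1, 0.5), n_repeats = 2, seed = 1)
#' table(plan$assignments[, 1])
make_fold_plan <- function(labels, n_outer = 10L, n_inner = 10L,
                           n_repeats = 10L, seed = 1L) {
  assignments <- vapply(seq_len(n_repeats), function(r) {
    stratified_folds(labels, n_outer, seed = derive_seed(seed, "repeat", r))
  }, integer(length(labels)))
  if (length(labels) == 1) assignments <- matrix(assignments, nrow = 1)
  structure(list(n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner),
                 n_repeats = as.integer(n_repeats),
                 assignments = assignments, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d outer x %d inner folds, %d repeats, %d cases\n",
              x$n_outer, x$n_inner, x$n_repeats, nrow(x$assignments)))
  invisible(x)
}

# ---- iterative random-forest imputation ------------------------------------

impute_init <- function(x, schema) {
  if (schema$type == "continuous") mean(x, na.rm = TRUE)
  else {
    tab <- sort(table(x), decreasing = TRUE)
    val <- names(tab)[1]
    if (schema$type == "binary") as.numeric(val) else val
  }
}

fill_initial <- function(data, init) {
  for (nm in names(init)) {
    miss <- is.na(data[[nm]])
    if (any(miss)) {
      if (is.factor(data[[nm]])) data[[nm]][miss] <- factor(init[[nm]],
        levels = levels(data[[nm]]))
      else data[[nm]][miss] <- init[[nm]]
    }
  }
  data
}

#' Fit an iterative chained random-forest imputer
#'
#' Missing cells are first filled with the training mean/mode; then each
#' incomplete variable in turn (ordered by increasing missingness) is
#' regressed (continuous) or classified (binary/categorical) on all other
#' variables with a random forest, and its missing cells replaced by the
#' forest's predictions. Iteration stops when the mean out-of-bag error of
#' the chained forests stops improving, or after `max_iter` sweeps.
#' Observed cells are never altered.
#'
#' @param data Data frame of predictors with missing cells (training
#'   partition only).
#' @param seed Integer seed.
#' @param max_iter Maximum chained sweeps (default 10).
#' @param num_trees Trees per imputation forest (default 100).
#' @param schema Variable schema; inferred when `NULL`.
#' @return Object of class `rf_imputer` holding the fitted forests, the
#'   initial fill values and the training sweep count; apply with
#'   [rf_impute_apply()].
#' @export
rf_impute_fit <- function(data, seed = 1L, max_iter = 10L, num_trees = 100L,
                          schema = NULL) {
  data <- as.data.frame(data)
  schema <- schema %||% infer_schema(data)
  for (nm in names(data)) {
    assert_that(sum(!is.na(data[[nm]])) >= 2,
                sprintf("variable '%s' must be observed in >= 2 rows", nm))
  }
  miss_frac <- vapply(data, function(x) mean(is.na(x)), numeric(1))
  targets <- names(sort(miss_frac[miss_frac > 0]))
  init <- lapply(names(data), function(nm) impute_init(data[[nm]],
                                                       schema[[nm]]))
  names(init) <- names(data)
  state <- list(schema = schema, init = init, columns = names(data),
                forests = list(), n_iter = 0L, targets = targets)
  class(state) <- "rf_imputer"
  if (length(targets) == 0) return(state)

  work <- fill_initial(data, init)
  # coerce types for forest fitting: binary as factor responses
  best_err <- Inf
  best_forests <- list()
  for (iter in seq_len(max_iter)) {
    errs <- numeric(0)
    forests <- list()
    for (nm in targets) {
      obs <- !is.na(data[[nm]])
      y <- data[[nm]][obs]
      sch <- schema[[nm]]
      classif <- sch$type %in% c("binary", "categorical")
      if (length(unique(y)) < 2) {
        forests[[nm]] <- list(constant = y[[1]])
        work[[nm]][!obs] <- y[[1]]
        next
      }
      ytrain <- if (classif) factor(y) else y
      xtrain <- work[obs, setdiff(names(work), nm), drop = FALSE]
      fit <- ranger::ranger(
        x = xtrain, y = ytrain, num.trees = num_trees,
        seed = derive_seed(seed, "impute", nm, iter),
        num.threads = 1, respect.unordered.factors = "order",
        verbose = FALSE)
      errs <- c(errs, fit$prediction.error)
      # predict.ranger draws a tie-break seed from the session RNG unless
      # one is supplied; fix it so imputation is state-independent
      pred <- predict(fit, data = work[!obs, setdiff(names(work), nm),
                                       drop = FALSE],
                      num.threads = 1,
                      seed = derive_seed(seed, "predict", nm, iter)
                      )$predictions
      if (classif) {
        pred <- as.character(pred)
        if (sch$type == "binary") pred <- as.numeric(pred)
        if (is.factor(work[[nm]]))
          pred <- factor(pred, levels = levels(work[[nm]]))
      }
      work[[nm]][!obs] <- pred
      forests[[nm]] <- list(fit = fit)
    }
    err <- if (length(errs)) mean(errs) else 0
    if (err < best_err - 1e-10) {
      best_err <- err
      best_forests <- forests
      state$n_iter <- iter
    } else {
      break
    }
  }
  state$forests <- best_forests
  state
}

#' Apply a fitted imputer to new rows
#'
#' Missing cells are initialized with the training fill values, then each
#' incomplete target variable is predicted from the stored forests, with
#' as many sweeps as the imputer used in training. Observed cells are
#' returned unchanged; no statistic of the imputer is updated.
#'
#' @param state An `rf_imputer`.
#' @param data Rows to impute (same columns as the training partition).
#' @return `data` with missing cells imputed.
#' @export
rf_impute_apply <- function(state, data) {
  assert_that(inherits(state, "rf_imputer"), "state must be an rf_imputer")
  data <- as.data.frame(data)
  missing_cols <- setdiff(state$columns, names(data))
  assert_that(length(missing_cols) == 0,
              paste("columns absent from data:",
                    paste(missing_cols, collapse = ", ")))
  orig_na <- lapply(data, is.na)
  if (!any(vapply(orig_na, any, logical(1)))) return(data)
  work <- fill_initial(data, state$init)
  for (sweep in seq_len(max(1L, state$n_iter))) {
    for (nm in names(state$forests)) {
      miss <- orig_na[[nm]]
      if (!any(miss)) next
      f <- state$forests[[nm]]
      if (!is.null(f$constant)) {
        work[[nm]][miss] <- f$constant
        next
      }
      pred <- predict(f$fit,
                      data = work[miss, setdiff(names(work), nm),
                                  drop = FALSE],
                      num.threads = 1, seed = 1L)$predictions
      sch <- state$schema[[nm]]
      if (sch$type %in% c("binary", "categorical")) {
        pred <- as.character(pred)
        if (sch$type == "binary") pred <- as.numeric(pred)
        if (is.factor(work[[nm]]))
          pred <- factor(pred, levels = levels(work[[nm]]))
      }
      work[[nm]][miss] <- pred
    }
  }
  work
}

# ---- standardization + one-hot encoding ------------------------------------

#' Fit the fold preprocessor (imputation + scaling + encoding registry)
#'
#' Fits, strictly on one training partition: the chained random-forest
#' imputer, per-column means and SDs for continuous predictors, and the
#' category level registry for nominal predictors. Binary predictors pass
#' through as single 0/1 indicators; nominal predictors are expanded to
#' one indicator per registered level (full one-hot).
#'
#' @param data Training-partition predictor rows.
#' @param seed Integer seed (for the imputation forests).
#' @param impute Fit the imputer? Set `FALSE` for complete data.
#' @param max_iter,num_trees Imputer settings, see [rf_impute_fit()].
#' @param schema Optional explicit schema.
#' @param partition_id Identifier of the fitting partition, recorded in
#'   the state for leakage audits.
#' @return Object of class `preprocessor_state`.
#' @export
preprocess_fit <- function(data, seed = 1L, impute = TRUE, max_iter = 10L,
                           num_trees = 100L, schema = NULL,
                           partition_id = "training") {
  data <- as.data.frame(data)
  schema <- schema %||% infer_schema(data)
  imputer <- NULL
  if (impute && any(is.na(data))) {
    imputer <- rf_impute_fit(data, seed = seed, max_iter = max_iter,
                             num_trees = num_trees, schema = schema)
    data <- rf_impute_apply(imputer, data)
  }
  center <- list(); scale_ <- list(); levels_ <- list()
  for (nm in names(data)) {
    sch <- schema[[nm]]
    if (sch$type == "continuous") {
      center[[nm]] <- mean(data[[nm]], na.rm = TRUE)
      s <- sd(data[[nm]], na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        warning(sprintf("constant continuous column '%s'; SD set to 1", nm))
        s <- 1
      }
      scale_[[nm]] <- s
    } else if (sch$type == "categorical") {
      lev <- sch$levels %||% sort(unique(as.character(data[[nm]])))
      levels_[[nm]] <- lev
    }
  }
  structure(list(schema = schema, imputer = imputer, center = center,
                 scale = scale_, levels = levels_, columns = names(data),
                 fitted_on = partition_id),
            class = "preprocessor_state")
}

#' Transform rows into the numeric feature matrix
#'
#' Applies a fitted [preprocess_fit()] state: imputes missing cells with
#' the stored forests, standardizes continuous columns with the
#' training-partition mean/SD, and one-hot encodes nominal columns against
#' the registered levels. A test level never seen in training yields
#' all-zero indicators with a warning. The state is never modified.
#'
#' @param state A `preprocessor_state`.
#' @param data Rows to transform (training or held-out).
#' @return Numeric matrix; the `feature_map` attribute maps each column
#'   back to its source predictor.
#' @export
standardize_and_encode <- function(state, data) {
  assert_that(inherits(state, "preprocessor_state"),
              "state must come from preprocess_fit()")
  data <- as.data.frame(data)
  extra <- setdiff(names(data), state$columns)
  assert_that(length(extra) == 0,
              paste("columns absent from preprocessor state:",
                    paste(extra, collapse = ", ")))
  data <- data[, state$columns, drop = FALSE]
  if (!is.null(state$imputer) && any(is.na(data))) {
    data <- rf_impute_apply(state$imputer, data)
  }
  cols <- list(); map <- character(0)
  for (nm in state$columns) {
    sch <- state$schema[[nm]]
    if (sch$type == "continuous") {
      cols[[nm]] <- (data[[nm]] - state$center[[nm]]) / state$scale[[nm]]
      map <- c(map, setNames(nm, nm))
    } else if (sch$type == "binary") {
      cols[[nm]] <- as.numeric(data[[nm]])
      map <- c(map, setNames(nm, nm))
    } else {
      lev <- state$levels[[nm]]
      vals <- as.character(data[[nm]])
      unseen <- !is.na(vals) & !vals %in% lev
      if (any(unseen)) {
        warning(sprintf(
          "column '%s': %d row(s) with unseen level(s) %s encoded as all-zero",
          nm, sum(unseen),
          paste(sQuote(unique(vals[unseen])), collapse = ", ")))
      }
      for (lv in lev) {
        cn <- paste(nm, lv, sep = ".")
        cols[[cn]] <- as.numeric(!is.na(vals) & vals == lv)
        map <- c(map, setNames(nm, cn))
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(data)
  attr(X, "feature_map") <- map
  X
}

feature_map <- function(X) {
  fm <- attr(X, "feature_map")
  fm %||% setNames(colnames(X), colnames(X))
}

# ---- SMOTE -----------------------------------------------------------------

#' SMOTE rebalancing of a training sample
#'
#' Two-sided scheme: the majority class is first randomly undersampled to
#' the midpoint between the original class counts, then the minority class
#' is augmented with synthetic points until the class counts satisfy
#' `target_ratio` exactly. Each synthetic point is a uniform convex
#' combination of a minority point and one of its `k` nearest minority
#' neighbours (Euclidean distance, applied after standardization).
#' Synthetic rows carry a provenance flag and must never reach an
#' evaluation partition.
#'
#' @param features Numeric feature matrix (training partition only).
#' @param labels Binary labels.
#' @param k_neighbors Number of minority neighbours (default 5); reduced
#'   with a warning when the minority class is smaller than `k + 1`.
#' @param target_ratio Target minority/majority count ratio (default 1).
#' @param seed Integer seed.
#' @return List of class `rebalanced_sample` with `features`, `labels`,
#'   logical `synthetic` provenance flags, and `k_used`.
#' @export
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(8, 3), 4))
#' r <- smote_rebalance(X, rep(c(0, 1), c(20, 4)), seed = 1)
#' table(r$labels)
smote_rebalance <- function(features, labels, k_neighbors = 5L,
                            target_ratio = 1.0, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  assert_that(nrow(features) == length(labels),
              "features and labels must align")
  counts <- table(factor(labels, levels = c(0, 1)))
  if (counts[["0"]] == counts[["1"]]) {
    return(structure(list(features = features, labels = labels,
                          synthetic = rep(FALSE, length(labels)),
                          k_used = 0L),
                     class = "rebalanced_sample"))
  }
  minority <- if (counts[["1"]] < counts[["0"]]) 1L else 0L
  majority <- 1L - minority
  n_min <- sum(labels == minority)
  n_maj <- sum(labels == majority)
  assert_that(n_min >= 2, "minority class must have >= 2 members")
  k <- k_neighbors
  if (k > n_min - 1) {
    warning(sprintf("k_neighbors reduced from %d to %d (minority size %d)",
                    k, n_min - 1, n_min))
    k <- n_min - 1L
  }
  with_seed(seed, {
    maj_target <- floor((n_min + n_maj) / 2)
    maj_idx <- which(labels == majority)
    keep_maj <- sample(maj_idx, maj_target)
    min_idx <- which(labels == minority)
    min_target <- round(maj_target * target_ratio)
    n_synth <- max(0L, min_target - n_min)
    Xmin <- features[min_idx, , drop = FALSE]
    synth <- NULL
    if (n_synth > 0) {
      D <- as.matrix(dist(Xmin))
      diag(D) <- Inf
      nn <- do.call(rbind, lapply(seq_len(n_min),
                                  function(i) order(D[i, ])[seq_len(k)]))
      base_i <- sample.int(n_min, n_synth, replace = TRUE)
      nb_i <- vapply(base_i, function(i) nn[i, sample.int(k, 1)], integer(1))
      lambda <- runif(n_synth)
      synth <- Xmin[base_i, , drop = FALSE] +
        lambda * (Xmin[nb_i, , drop = FALSE] - Xmin[base_i, , drop = FALSE])
    }
    keep <- sort(c(keep_maj, min_idx))
    out_X <- rbind(features[keep, , drop = FALSE], synth)
    out_y <- c(labels[keep], rep(minority, n_synth))
    attr(out_X, "feature_map") <- attr(features, "feature_map")
    structure(list(features = out_X, labels = out_y,
                   synthetic = c(rep(FALSE, length(keep)),
                                 rep(TRUE, n_synth)),
                   k_used = if (n_synth > 0) as.integer(k) else 0L),
              class = "rebalanced_sample")
  })
}
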