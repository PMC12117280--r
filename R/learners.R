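# Internal fit/predict-probability contract shared by the T-learner and
# the nested evaluation: random forest (ranger), RBF-kernel SVM (e1071,
# with deterministic Platt-style mapping of decision values to
# probabilities), and a maximum-likelihood logistic reference. A training
# partition with a single outcome class degenerates to a constant model.

fit_learner <- function(algorithm, X, y, params = list(), seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    return(structure(list(type = "constant", value = mean(y)),
                     class = "prescriptr_learner"))
  }
  obj <- switch(algorithm,
    random_forest = {
      fit <- ranger::ranger(
        x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
        num.trees = params$num_trees %||% 500L,
        mtry = params$mtry %||% max(1L, floor(sqrt(ncol(X)))),
        seed = seed, num.threads = 1, verbose = FALSE)
      list(type = "random_forest", fit = fit)
    },
    svm_rbf = {
      fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                        kernel = "radial",
                        cost = params$cost %||% 1,
                        gamma = params$gamma %||% (1 / ncol(X)),
                        scale = FALSE)
      dv <- as.numeric(attr(predict(fit, X, decision.values = TRUE),
                            "decision.values"))
      platt <- suppressWarnings(
        glm(y ~ dv, family = binomial(), data = data.frame(y = y, dv = dv)))
      co <- coef(platt)
      co[!is.finite(co)] <- 0
      list(type = "svm_rbf", fit = fit, platt = co)
    },
    logistic_reference = {
      fit <- suppressWarnings(
        glm.fit(cbind(`(Intercept)` = 1, X), y, family = binomial()))
      beta <- fit$coefficients
      beta[!is.finite(beta)] <- 0
      list(type = "logistic_reference", beta = beta)
    },
    stop("unknown algorithm: ", algorithm)
  )
  structure(obj, class = "prescriptr_learner")
}

predict_learner <- function(object, X) {
  X <- as.matrix(X)
  switch(object$type,
    constant = rep(object$value, nrow(X)),
    random_forest = {
      pr <- predict(object$fit, data = X, num.threads = 1,
                    seed = 1L)$predictions
      as.numeric(pr[, "1"])
    },
    svm_rbf = {
      dv <- as.numeric(attr(predict(object$fit, X, decision.values = TRUE),
                            "decision.values"))
      as.numeric(plogis(object$platt[1] + object$platt[2] * dv))
    },
    logistic_reference = {
      as.numeric(plogis(cbind(1, X) %*% object$beta))
    })
}

#' @importFrom stats glm.fit
NULL
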