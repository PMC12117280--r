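# Orchestration: one call runs generate -> trial statistics -> T-learner
# -> nested evaluation -> SHAP, writing a reproducible report bundle
# (CSV/JSON artifacts plus a manifest of content hashes). Every
# stochastic stage receives a seed derived deterministically from the
# master seed, so a repeated run yields an identical bundle.

#' Validate a participant-level input table
#'
#' Checks the canonical schema: the 17 baseline predictor columns, arm
#' coding (`0`/`1` or `SM`/`MEMI`), severity outcome columns, prompt
#' counts in `[0, 70]`, unique participant ids; reports per-column
#' missingness.
#'
#' @param x Path to a CSV or a data frame.
#' @return List of class `schema_report` with `ok`, `problems`
#'   (character vector), and `missingness` (per-column fraction).
#' @export
validate_input <- function(x) {
  data <- if (is.character(x)) read_trial_csv(x) else as.data.frame(x)
  problems <- character(0)
  missing_cols <- setdiff(predictor_names(), names(data))
  if (length(missing_cols)) {
    problems <- c(problems, paste("missing predictor column(s):",
                                  paste(missing_cols, collapse = ", ")))
  }
  for (nm in c("participant_id", "arm", "spdq_post", "spdq_1mfu")) {
    if (!nm %in% names(data)) {
      problems <- c(problems, paste("missing column:", nm))
    }
  }
  if ("participant_id" %in% names(data) &&
      anyDuplicated(data$participant_id)) {
    problems <- c(problems, "duplicate participant ids")
  }
  if ("arm" %in% names(data)) {
    ok_arm <- data$arm %in% c(0, 1, "0", "1", "MEMI", "SM")
    if (!all(ok_arm)) {
      problems <- c(problems, sprintf(
        "arm values outside {0, 1, MEMI, SM}: %s",
        paste(unique(data$arm[!ok_arm]), collapse = ", ")))
    }
    if (any(is.na(data$arm))) {
      problems <- c(problems, "arm must never be missing")
    }
  }
  if ("prompts_completed" %in% names(data)) {
    bad <- !is.na(data$prompts_completed) &
      (data$prompts_completed < 0 | data$prompts_completed > 70)
    if (any(bad)) {
      problems <- c(problems, sprintf(
        "prompt counts outside [0, 70] in %d row(s)", sum(bad)))
    }
  }
  present <- intersect(c(predictor_names(), "spdq_post", "spdq_1mfu"),
                       names(data))
  missingness <- vapply(data[present], function(col) mean(is.na(col)),
                        numeric(1))
  structure(list(ok = length(problems) == 0, problems = problems,
                 missingness = missingness, n = nrow(data)),
            class = "schema_report")
}

#' @export
print.schema_report <- function(x, ...) {
  cat(sprintf("<schema_report> %d rows: %s\n", x$n,
              if (x$ok) "PASS" else "FAIL"))
  for (p in x$problems) cat("  problem:", p, "\n")
  invisible(x)
}

# Normalize arm coding to 1 = treatment (MEMI), 0 = control (SM).
normalize_arm <- function(arm) {
  if (is.character(arm) || is.factor(arm)) {
    arm <- as.character(arm)
    assert_that(all(arm %in% c("MEMI", "SM", "0", "1")),
                "arm values must be MEMI/SM or 0/1")
    as.integer(arm == "MEMI" | arm == "1")
  } else {
    assert_that(all(arm %in% c(0, 1)), "numeric arm values must be 0/1")
    as.integer(arm)
  }
}

#' Default run configuration
#'
#' @param n_participants Generator sample size (ignored when `input_csv`
#'   is given).
#' @param seed Master seed.
#' @param outdir Output directory for the report bundle.
#' @param input_csv Optional participant CSV; when `NULL` a synthetic
#'   trial is generated.
#' @param time_point Assessment wave analysed.
#' @param models Algorithms evaluated.
#' @param folds List with `outer`, `inner`, `repeats`.
#' @param smote List with `enabled`, `k`, `target_ratio`.
#' @param impute List with `max_iter` (imputation sweeps).
#' @param screen List with `enabled`, `top_k`.
#' @param shap List with `enabled`, `n_instances`, `n_background`,
#'   `n_coalitions`.
#' @param tlearner List with `n_folds`, `num_trees`.
#' @param stages Named logical toggles (`trial_stats`, `tlearner`,
#'   `nested_cv`, `shap`).
#' @return List of class `run_config`.
#' @export
run_config <- function(n_participants = 191L, seed = 1L,
                       outdir = tempfile("prescriptr-run-"),
                       input_csv = NULL,
                       time_point = "post",
                       models = c("random_forest", "svm_rbf",
                                  "logistic_reference"),
                       folds = list(outer = 10L, inner = 10L,
                                    repeats = 10L),
                       smote = list(enabled = TRUE, k = 5L,
                                    target_ratio = 1.0),
                       impute = list(max_iter = 10L),
                       screen = list(enabled = TRUE, top_k = 10L),
                       shap = list(enabled = TRUE, n_instances = 100L,
                                   n_background = 100L,
                                   n_coalitions = NULL),
                       tlearner = list(n_folds = 10L, num_trees = 500L),
                       stages = list(trial_stats = TRUE, tlearner = TRUE,
                                     nested_cv = TRUE, shap = TRUE)) {
  count <- function(x) if (is.null(x)) x else as.integer(round(x))
  folds <- lapply(folds, count)
  smote$k <- count(smote$k)
  impute$max_iter <- count(impute$max_iter)
  screen$top_k <- count(screen$top_k)
  shap[c("n_instances", "n_background", "n_coalitions")] <-
    lapply(shap[c("n_instances", "n_background", "n_coalitions")], count)
  tlearner$n_folds <- count(tlearner$n_folds)
  tlearner$num_trees <- count(tlearner$num_trees)
  structure(list(n_participants = count(n_participants),
                 seed = count(seed),
                 outdir = outdir, input_csv = input_csv,
                 time_point = time_point, models = models, folds = folds,
                 smote = smote, impute = impute, screen = screen,
                 shap = shap, tlearner = tlearner, stages = stages),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the [run_config()]
#' defaults. The configuration round-trips unchanged through
#' serialize/parse.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- run_config()
  unknown <- setdiff(names(raw), names(defaults))
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg <- modifyList(unclass(defaults), raw)
  do.call(run_config, cfg)  # re-validate and normalize types
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  path
}

#' Run the full experiment pipeline
#'
#' Executes the configured stages in order -- data (generate or load),
#' trial statistics, T-learner labelling, nested cross-validated
#' evaluation, kernel SHAP ranking -- writing each stage's artifact into
#' the output directory together with a manifest of MD5 content hashes.
#'
#' @param config A [run_config()] (or path readable by
#'   [read_run_config()]).
#' @return List of class `run_result` with the in-memory stage results
#'   and the `manifest`.
#' @export
run_experiment <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_lines <- list()
  log_stage <- function(stage, ...) {
    entry <- list(stage = stage, ...)
    log_lines[[length(log_lines) + 1]] <<- entry
    entry
  }

  # ---- data ----
  if (!is.null(config$input_csv)) {
    data <- read_trial_csv(config$input_csv)
    report <- validate_input(data)
    if (!report$ok) {
      stop(paste(c("input failed schema validation:", report$problems),
                 collapse = "\n  "), call. = FALSE)
    }
    data$arm <- normalize_arm(data$arm)
  } else {
    gen_cfg <- generator_config(n_participants = config$n_participants,
                                seed = derive_seed(seed, "generate"))
    data <- generate_trial(gen_cfg)
  }
  snapshot <- file.path(config$outdir, "dataset.csv")
  write_trial_csv(data, snapshot)
  masked <- attr(data, "masked_cells") %||%
    sum(is.na(data[, default_missing_columns(data)]))
  log_stage("data", n = nrow(data), masked_cells = masked,
            seed = derive_seed(seed, "generate"))

  result <- list(config = config, data = data, masked_cells = masked)

  # ---- trial statistics ----
  if (isTRUE(config$stages$trial_stats)) {
    stats <- remission_report(data)
    write_json_artifact(stats, file.path(config$outdir, "trial_stats.json"))
    result$trial_stats <- stats
    log_stage("trial_stats")
  }

  # ---- T-learner ----
  labels <- NULL
  if (isTRUE(config$stages$tlearner)) {
    est <- fit_arm_models(data, time_point = config$time_point,
                          n_folds = config$tlearner$n_folds,
                          num_trees = config$tlearner$num_trees,
                          seed = derive_seed(seed, "tlearner"))
    write.csv(as.data.frame(est)[, c("participant_id", "p_memi", "p_sm",
                                     "ite", "optimized", "time_point")],
              file.path(config$outdir, "counterfactuals.csv"),
              row.names = FALSE)
    result$counterfactuals <- est
    labels <- est$optimized
    log_stage("tlearner", positive = sum(labels),
              seed = derive_seed(seed, "tlearner"))
  }

  # ---- nested evaluation ----
  if (isTRUE(config$stages$nested_cv) && !is.null(labels)) {
    specs <- lapply(config$models, model_spec)
    cv <- run_nested_cv(data, labels, model_specs = specs,
                        n_outer = config$folds$outer,
                        n_inner = config$folds$inner,
                        n_repeats = config$folds$repeats,
                        screening = isTRUE(config$screen$enabled),
                        top_k = config$screen$top_k,
                        smote = isTRUE(config$smote$enabled),
                        smote_k = config$smote$k,
                        smote_ratio = config$smote$target_ratio %||% 1.0,
                        impute_max_iter = config$impute$max_iter %||% 10L,
                        seed = derive_seed(seed, "nested"))
    write.csv(metrics_table(cv, configuration = "final",
                            time_point = config$time_point),
              file.path(config$outdir, "metrics.csv"), row.names = FALSE)
    write_json_artifact(
      list(final_predictors = cv$final_predictors,
           delong = cv$delong,
           per_fold_params = cv$per_fold[, c("model", "repeat_id", "fold",
                                             "best_params")]),
      file.path(config$outdir, "model_ledger.json"))
    result$nested_cv <- cv
    log_stage("nested_cv", seed = derive_seed(seed, "nested"))
  }

  # ---- SHAP ----
  if (isTRUE(config$stages$shap) && !is.null(labels)) {
    fm <- final_model(data, labels,
                      screening = isTRUE(config$screen$enabled),
                      top_k = config$screen$top_k,
                      num_trees = config$tlearner$num_trees,
                      seed = derive_seed(seed, "final-model"))
    X <- fm$features
    n_inst <- min(config$shap$n_instances, nrow(X))
    n_bg <- min(config$shap$n_background, nrow(X))
    idx <- with_seed(derive_seed(seed, "shap-rows"), {
      list(inst = sample.int(nrow(X), n_inst),
           bg = sample.int(nrow(X), n_bg))
    })
    sub <- function(i) {
      out <- X[i, , drop = FALSE]
      attr(out, "feature_map") <- attr(X, "feature_map")
      out
    }
    shap <- kernel_shap(fm, sub(idx$bg), sub(idx$inst),
                        n_coalitions = config$shap$n_coalitions,
                        seed = derive_seed(seed, "shap"))
    ranking <- rank_and_sign(shap, k = config$screen$top_k)
    write.csv(as.data.frame(ranking),
              file.path(config$outdir, "shap_ranking.csv"),
              row.names = FALSE)
    result$shap <- shap
    result$shap_ranking <- ranking
    log_stage("shap", seed = derive_seed(seed, "shap"))
  }

  # ---- manifest ----
  write_json_artifact(log_lines, file.path(config$outdir, "log.json"))
  artifacts <- sort(setdiff(list.files(config$outdir, full.names = TRUE),
                            file.path(config$outdir, "manifest.json")))
  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         stringsAsFactors = FALSE)
  write_json_artifact(manifest, file.path(config$outdir, "manifest.json"))
  result$manifest <- manifest
  class(result) <- "run_result"
  result
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> n=%d, masked cells=%d, outdir=%s\n",
              nrow(x$data), x$masked_cells, x$config$outdir))
  if (!is.null(x$nested_cv)) print(x$nested_cv)
  if (!is.null(x$shap_ranking)) {
    cat("top predictors:",
        paste(x$shap_ranking$predictor, collapse = ", "), "\n")
  }
  invisible(x)
}
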