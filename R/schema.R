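# Canonical baseline predictor set for the two-arm trial analyses.
#
# Seventeen pre-randomization predictors: sociodemographics, treatment
# credibility/expectancy, symptom severities, clinical history, and trait
# measures (attentional control, emotion dysregulation, mindfulness,
# perseverative cognition, self-compassion).

#' Canonical predictor specifications
#'
#' Returns the specification list for the 17 baseline predictors used
#' throughout the package: name, variable type, and default marginal
#' distribution for the synthetic generator. Continuous predictors carry a
#' mean and SD; binary predictors a success probability; categorical
#' predictors a named probability vector over levels.
#'
#' Default marginals emulate the motivating trial sample (N=191 adults with
#' probable social anxiety disorder in Singapore): age 21.84 (SD 3.37),
#' ~78% female, ~86% Chinese, 17.8% university-educated, 5.24% on
#' psychotropic medication, 15.71% with prior psychotherapy. Trait and
#' severity scales use plausible values on each instrument's raw metric
#' (their outcome-model contribution is always standardized, so only the
#' location/scale pairs matter for downstream behaviour).
#'
#' @return Named list of per-predictor specification lists.
#' @export
#' @examples
#' names(canonical_predictors())
canonical_predictors <- function() {
  list(
    age = list(type = "continuous", mean = 21.84, sd = 3.37),
    gender = list(type = "categorical",
                  probs = c(male = 0.2147, female = 0.7801, other = 0.0052)),
    ethnicity = list(type = "categorical",
                     probs = c(chinese = 0.8639, malay = 0.0209,
                               indian = 0.0628, other = 0.0524)),
    education = list(type = "binary", p = 0.178),
    credibility = list(type = "continuous", mean = 18, sd = 4),
    expectancy = list(type = "continuous", mean = 15, sd = 5),
    sad_severity = list(type = "continuous", mean = 34, sd = 8),
    depression_severity = list(type = "continuous", mean = 18, sd = 10),
    gad_severity = list(type = "continuous", mean = 7.5, sd = 3),
    clinician_diagnosis = list(type = "binary", p = 0.15),
    current_psychotherapy = list(type = "binary", p = 0.1571),
    psychotropic_medication = list(type = "binary", p = 0.0524),
    attentional_control = list(type = "continuous", mean = 47, sd = 8),
    emotion_dysregulation = list(type = "continuous", mean = 100, sd = 20),
    trait_mindfulness = list(type = "continuous", mean = 110, sd = 15),
    perseverative_cognition = list(type = "continuous", mean = 120, sd = 30),
    self_compassion = list(type = "continuous", mean = 2.8, sd = 0.6)
  )
}

#' Canonical predictor names
#'
#' @return Character vector of the 17 baseline predictor column names, in
#'   canonical order (also the deterministic tie-break order used by the
#'   screening and SHAP ranking stages).
#' @export
predictor_names <- function() names(canonical_predictors())

# Infer a schema (name -> type/levels) for a predictor table, using the
# canonical specs where column names match and falling back to class-based
# detection for extra columns.
infer_schema <- function(data, specs = canonical_predictors()) {
  out <- list()
  for (nm in names(data)) {
    x <- data[[nm]]
    if (!is.null(specs[[nm]])) {
      sp <- specs[[nm]]
      lev <- if (identical(sp$type, "categorical")) names(sp$probs) else NULL
      out[[nm]] <- list(type = sp$type, levels = lev)
    } else if (is.factor(x) || is.character(x)) {
      out[[nm]] <- list(type = "categorical",
                        levels = sort(unique(as.character(x[!is.na(x)]))))
    } else if (is_binary01(x)) {
      out[[nm]] <- list(type = "binary", levels = NULL)
    } else {
      out[[nm]] <- list(type = "continuous", levels = NULL)
    }
  }
  out
}
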