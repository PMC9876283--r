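# Pluggable registry of VO2max prediction equations.

#' Construct a prediction-model specification
#'
#' @param model_id Unique identifier string.
#' @param source_label Human-readable source, typically author-year.
#' @param sex Applicable sexes, subset of `c("male", "female")`.
#' @param modality Applicable testing modalities, subset of
#'   `c("TE", "CE")`.
#' @param output_unit Native output unit of the equation; see
#'   [vo2_units()].
#' @param predictors Character vector of the CPET record fields the
#'   equation reads (non-empty).
#' @param fun Pure function `cohort -> numeric` returning predictions in
#'   `output_unit` for each row.
#' @param notes Optional free-text note (derivation population, caveats).
#' @return Object of class `vo2_model`.
#' @export
#' @examples
#' m <- vo2_model("const40", "toy", c("male", "female"), c("TE", "CE"),
#'                "ml_kg_min", "age", function(d) rep(40, nrow(d)))
vo2_model <- function(model_id, source_label, sex, modality, output_unit,
                      predictors, fun, notes = "") {
  stopifnot(is.character(model_id), length(model_id) == 1L,
            is.function(fun), length(predictors) >= 1L)
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  modality <- match.arg(modality, c("TE", "CE"), several.ok = TRUE)
  output_unit <- match.arg(output_unit, vo2_units())
  structure(
    list(model_id = model_id, source_label = source_label, sex = sex,
         modality = modality, output_unit = output_unit,
         predictors = predictors, fun = fun, notes = notes),
    class = "vo2_model"
  )
}

#' @export
print.vo2_model <- function(x, ...) {
  cat(sprintf("<vo2_model %s> %s\n", x$model_id, x$source_label))
  cat("  sexes:     ", paste(x$sex, collapse = ", "), "\n")
  cat("  modalities:", paste(x$modality, collapse = ", "), "\n")
  cat("  unit:      ", x$output_unit, "\n")
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a prediction model on CPET records
#'
#' @param object A [vo2_model()].
#' @param cohort CPET cohort rows.
#' @param ... Unused.
#' @return Numeric predictions in the model's native unit.
#' @export
predict.vo2_model <- function(object, cohort, ...) {
  missing_p <- setdiff(object$predictors, names(cohort))
  if (length(missing_p)) {
    .stop("model '", object$model_id, "' requires missing predictor(s): ",
          paste(missing_p, collapse = ", "))
  }
  as.numeric(object$fun(cohort))
}

#' Create a model registry
#'
#' @param models Named starting set; defaults to [builtin_models()].
#' @return Object of class `vo2_registry`.
#' @export
model_registry <- function(models = builtin_models()) {
  ids <- vapply(models, `[[`, "", "model_id")
  names(models) <- ids
  structure(list(models = models), class = "vo2_registry")
}

#' Register an additional prediction model
#'
#' @param registry A [model_registry()].
#' @param model A [vo2_model()] whose id is not yet taken.
#' @return The extended registry (the built-in set is untouched).
#' @export
register <- function(registry, model) {
  stopifnot(inherits(registry, "vo2_registry"), inherits(model, "vo2_model"))
  if (model$model_id %in% names(registry$models)) {
    .stop("model id '", model$model_id, "' is already registered")
  }
  registry$models[[model$model_id]] <- model
  registry
}

#' Models applicable to a sex and modality
#'
#' @param sex `"male"` or `"female"`.
#' @param modality `"TE"` or `"CE"`.
#' @param registry A [model_registry()], a list of [vo2_model()]s, or
#'   `NULL` for the built-in set.
#' @return Named list of applicable `vo2_model`s.
#' @export
applicable_models <- function(sex, modality, registry = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  modality <- match.arg(modality, c("TE", "CE"))
  models <- if (is.null(registry)) {
    builtin_models()
  } else if (inherits(registry, "vo2_registry")) {
    registry$models
  } else {
    registry
  }
  Filter(function(m) sex %in% m$sex && modality %in% m$modality, models)
}

#' Build a long-format prediction table
#'
#' Evaluates every model on every record.  Non-applicable (sex, modality)
#' cells are flagged (`applicable = FALSE`, `predicted = NA`), never
#' zero-filled.  The observed VO2max is converted to each model's native
#' output unit via body mass so observed and predicted columns always
#' share the unit tag.
#'
#' @param cohort CPET cohort.
#' @param models List of [vo2_model()]s or a [model_registry()]; defaults
#'   to the built-in set.
#' @return Data frame with columns `subject_id`, `model_id`, `unit`,
#'   `sex`, `modality`, `applicable`, `observed`, `predicted`, `flag`.
#' @export
predict_cohort <- function(cohort, models = builtin_models()) {
  if (inherits(models, "vo2_registry")) models <- models$models
  if (inherits(models, "vo2_model")) models <- list(models)
  chk <- validate_cohort(cohort)
  if (!all(chk$valid)) {
    .stop("cohort contains ", sum(!chk$valid), " invalid record(s)")
  }
  blocks <- lapply(models, function(m) {
    applicable <- cohort$sex %in% m$sex & cohort$modality %in% m$modality
    predicted <- rep(NA_real_, nrow(cohort))
    flag <- ifelse(applicable, "", "not_applicable")
    if (any(applicable)) {
      p <- predict(m, cohort[applicable, , drop = FALSE])
      bad <- !is.finite(p)
      flag[applicable][bad] <- "nonfinite_prediction"
      p[bad] <- NA_real_
      predicted[applicable] <- p
    }
    data.frame(
      subject_id = cohort$subject_id,
      model_id = m$model_id,
      unit = m$output_unit,
      sex = cohort$sex,
      modality = cohort$modality,
      applicable = applicable,
      observed = convert_vo2(cohort$vo2max_rel, "ml_kg_min", m$output_unit,
                             cohort$body_mass),
      predicted = predicted,
      flag = flag,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Build a linear prediction model from declarative coefficients
#'
#' Convenience constructor for simple linear equations, usable from a
#' coefficient file: `intercept + sum(coef_i * field_i)`, with the
#' pseudo-fields `female` and `male` available as 0/1 indicators.
#'
#' @param model_id,source_label,sex,modality,output_unit See
#'   [vo2_model()].
#' @param intercept Numeric intercept.
#' @param terms Named numeric vector of slopes on record fields (and/or
#'   `female`/`male` indicators).
#' @return A [vo2_model()].
#' @export
#' @examples
#' m <- linear_vo2_model("toy", "toy linear", c("male", "female"),
#'                       c("TE", "CE"), "ml_kg_min", 60, c(age = -0.5))
linear_vo2_model <- function(model_id, source_label, sex, modality,
                             output_unit, intercept, terms) {
  stopifnot(is.numeric(terms), !is.null(names(terms)), all(names(terms) != ""))
  predictors <- setdiff(names(terms), c("female", "male"))
  if (!length(predictors)) predictors <- "sex"
  force(intercept); force(terms)
  fun <- function(cohort) {
    acc <- rep(intercept, nrow(cohort))
    for (nm in names(terms)) {
      x <- switch(nm,
        female = as.numeric(cohort$sex == "female"),
        male = as.numeric(cohort$sex == "male"),
        cohort[[nm]]
      )
      acc <- acc + terms[[nm]] * x
    }
    acc
  }
  vo2_model(model_id, source_label, sex, modality, output_unit,
            predictors = unique(c(predictors,
                                  if (any(names(terms) %in% c("female", "male"))) "sex")),
            fun = fun)
}
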