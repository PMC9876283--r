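# Per-model, per-subgroup external validation.

#' Validate prediction models across subgroups
#'
#' Computes one calibration result plus mean difference per model x sex x
#' modality x subgroup, in the model's native unit.  On the endurance
#' axis the "transition" class is excluded from validation panels; the
#' whole-population axis keeps it.  Degenerate cells are emitted with an
#' explicit status marker (`"empty"` for n = 0, `"degenerate"` for n < 3
#' or constant predictions), never dropped silently.
#'
#' @param cohort A CPET cohort; stratification columns are added with
#'   [stratify()] when missing.
#' @param models List of [vo2_model()]s, a [model_registry()], or the
#'   default built-in set.
#' @param axis `"endurance"`, `"age"` or `"whole"`.
#' @param convention Calibration-in-the-large convention reported in the
#'   `c1` column; see [calibration_in_the_large()].
#' @param min_n Reliability threshold for the `reliable` flag
#'   (default 100).
#' @return Data frame with one row per model x sex x modality x subgroup:
#'   identification columns, `n`, `reliable`, `status`, and the metric
#'   columns `r2_adj`, `rmse`, `c1`, `c2`, `p_slope`, `p_c1`,
#'   `effect_size_class`, `mean_diff`, `ci_low`, `ci_high`, `p_meandiff`.
#' @export
validate_models <- function(cohort, models = builtin_models(),
                            axis = c("endurance", "age", "whole"),
                            convention = c("free_intercept",
                                           "mean_difference"),
                            min_n = 100) {
  axis <- match.arg(axis)
  convention <- match.arg(convention)
  if (inherits(models, "vo2_registry")) models <- models$models
  if (inherits(models, "vo2_model")) models <- list(models)
  if (is.null(cohort$endurance_group) || is.null(cohort$age_group)) {
    cohort <- stratify(cohort)
  }
  subgroups <- switch(axis,
    endurance = c("HTEA", "REA", "LTEA"),
    age = age_group_levels(),
    whole = "all"
  )
  sub_of <- switch(axis,
    endurance = as.character(cohort$endurance_group),
    age = as.character(cohort$age_group),
    whole = rep("all", nrow(cohort))
  )

  na_row <- function(model, sx, md, sub, n, status) {
    data.frame(
      model_id = model$model_id, source_label = model$source_label,
      unit = model$output_unit, sex = sx, modality = md, axis = axis,
      subgroup = sub, n = n, reliable = n >= min_n, status = status,
      r2_adj = NA_real_, rmse = NA_real_, c1 = NA_real_, c2 = NA_real_,
      p_slope = NA_real_, p_c1 = NA_real_,
      effect_size_class = NA_character_,
      mean_diff = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      p_meandiff = NA_real_, stringsAsFactors = FALSE
    )
  }

  rows <- list()
  for (sx in c("male", "female")) {
    for (md in c("TE", "CE")) {
      panel <- applicable_models(sx, md, models)
      base_i <- cohort$sex == sx & cohort$modality == md
      for (sub in subgroups) {
        i <- base_i & sub_of == sub
        slice <- cohort[i, , drop = FALSE]
        for (m in panel) {
          n <- nrow(slice)
          if (n == 0) {
            rows[[length(rows) + 1L]] <- na_row(m, sx, md, sub, 0L, "empty")
            next
          }
          predicted <- predict(m, slice)
          observed <- convert_vo2(slice$vo2max_rel, "ml_kg_min",
                                  m$output_unit, slice$body_mass)
          if (n < 3 || sd(predicted) == 0) {
            rows[[length(rows) + 1L]] <- na_row(m, sx, md, sub, n, "degenerate")
            next
          }
          cal <- fit_calibration(observed, predicted)
          md_res <- mean_difference(observed, predicted)
          c1_val <- if (convention == "free_intercept") cal$c1 else
            mean(observed) - mean(predicted)
          rows[[length(rows) + 1L]] <- data.frame(
            model_id = m$model_id, source_label = m$source_label,
            unit = m$output_unit, sex = sx, modality = md, axis = axis,
            subgroup = sub, n = n, reliable = n >= min_n, status = "ok",
            r2_adj = cal$r2_adj, rmse = cal$rmse, c1 = c1_val, c2 = cal$c2,
            p_slope = cal$p_slope, p_c1 = cal$p_c1,
            effect_size_class = cal$effect_size_class,
            mean_diff = md_res$mean_diff, ci_low = md_res$ci_low,
            ci_high = md_res$ci_high, p_meandiff = md_res$p,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "c1_convention") <- convention
  out
}
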