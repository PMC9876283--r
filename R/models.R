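# Built-in VO2max prediction equations.
#
# Thirteen equations from eight publications, each with its applicability
# (sex, testing modality) and native output unit.  Sex-specific variants
# of the same publication are separate registry entries so that
# applicability filtering stays declarative.  The registry contract --
# identifiers, applicability sets, units, predictor lists -- is the
# stable surface; coefficient values are transcriptions of the cited
# equations and should be audited against the primary sources before any
# clinical use (see the methods vignette).  `register()` and
# `linear_vo2_model()` exist precisely so a corrected or additional
# equation can be swapped in without touching the validation engine.

#' Built-in prediction equations
#'
#' Returns the 13 built-in model specifications:
#' * Wilson (male-only meta-analysis of endurance-trained men; relative
#'   units; TE and CE),
#' * Fitzgerald (female-only meta-analysis of endurance-trained women;
#'   relative units; TE and CE),
#' * Wasserman male and female equations (absolute mL·min^-1; TE and CE),
#' * Kokkinos cycle-ergometer equations x3 (male, female, combined;
#'   relative units),
#' * Mylius cycle-ergometer reference equation (absolute mL·min^-1),
#' * Myers treadmill reference equation (relative units),
#' * Nevill treadmill equations x2 (allometric and additive; relative
#'   units),
#' * Petek athlete equations x2 (treadmill and cycle ergometer;
#'   L·min^-1).
#'
#' @return Named list of [vo2_model()] objects, length 13.
#' @export
#' @examples
#' length(builtin_models())
#' names(builtin_models())
builtin_models <- function() {
  lb_per_kg <- 2.2046226

  models <- list(
    vo2_model(
      "wilson", "Wilson et al. (meta-analysis, endurance-trained men)",
      sex = "male", modality = c("TE", "CE"), output_unit = "ml_kg_min",
      predictors = "age",
      fun = function(d) 75.4 - 0.46 * d$age
    ),
    vo2_model(
      "fitzgerald", "Fitzgerald et al. (meta-analysis, endurance-trained women)",
      sex = "female", modality = c("TE", "CE"), output_unit = "ml_kg_min",
      predictors = "age",
      fun = function(d) 72.9 - 0.62 * d$age
    ),
    vo2_model(
      "wasserman_male", "Wasserman et al. (men)",
      sex = "male", modality = c("TE", "CE"), output_unit = "ml_min",
      predictors = c("age", "body_mass"),
      fun = function(d) d$body_mass * (50.72 - 0.372 * d$age)
    ),
    vo2_model(
      "wasserman_female", "Wasserman et al. (women)",
      sex = "female", modality = c("TE", "CE"), output_unit = "ml_min",
      predictors = c("age", "body_mass"),
      fun = function(d) (d$body_mass + 43) * (22.78 - 0.17 * d$age)
    ),
    vo2_model(
      "kokkinos_ce_male", "Kokkinos et al. (1, cycle ergometry, men)",
      sex = "male", modality = "CE", output_unit = "ml_kg_min",
      predictors = "age",
      fun = function(d) 60.4 - 0.40 * d$age
    ),
    vo2_model(
      "kokkinos_ce_female", "Kokkinos et al. (2, cycle ergometry, women)",
      sex = "female", modality = "CE", output_unit = "ml_kg_min",
      predictors = "age",
      fun = function(d) 58.2 - 0.40 * d$age
    ),
    vo2_model(
      "kokkinos_ce_combined", "Kokkinos et al. (3, cycle ergometry, combined)",
      sex = c("male", "female"), modality = "CE", output_unit = "ml_kg_min",
      predictors = c("age", "sex"),
      fun = function(d) 58.6 - 0.40 * d$age - 3.0 * (d$sex == "female")
    ),
    vo2_model(
      "mylius_ce", "Mylius et al. (cycle ergometry reference)",
      sex = c("male", "female"), modality = "CE", output_unit = "ml_min",
      predictors = c("age", "height", "body_mass", "sex"),
      fun = function(d) {
        -273 + 18 * d$body_mass + 12 * d$height - 26 * d$age +
          636 * (d$sex == "male")
      }
    ),
    vo2_model(
      "myers_te", "Myers et al. (treadmill reference)",
      sex = c("male", "female"), modality = "TE", output_unit = "ml_kg_min",
      predictors = c("age", "body_mass", "sex"),
      fun = function(d) {
        79.9 - 0.39 * d$age - 13.7 * (d$sex == "female") -
          0.127 * d$body_mass * lb_per_kg
      }
    ),
    vo2_model(
      "nevill_te_allometric", "Nevill et al. (1, treadmill, allometric)",
      sex = c("male", "female"), modality = "TE", output_unit = "ml_kg_min",
      predictors = c("age", "body_mass", "sex"),
      fun = function(d) {
        222.1 * d$body_mass^(-1 / 3) * exp(-0.004 * d$age) *
          ifelse(d$sex == "female", 0.699, 1)
      }
    ),
    vo2_model(
      "nevill_te_additive", "Nevill et al. (2, treadmill, additive)",
      sex = c("male", "female"), modality = "TE", output_unit = "ml_kg_min",
      predictors = c("age", "body_mass", "sex"),
      fun = function(d) {
        72.9 - 0.36 * d$age - 0.20 * d$body_mass -
          13.8 * (d$sex == "female")
      }
    ),
    vo2_model(
      "petek_te", "Petek et al. (treadmill, endurance athletes)",
      sex = c("male", "female"), modality = "TE", output_unit = "l_min",
      predictors = c("age", "body_mass", "sex"),
      fun = function(d) {
        0.054 * d$body_mass - 0.0245 * d$age + 0.87 -
          0.45 * (d$sex == "female")
      }
    ),
    vo2_model(
      "petek_ce", "Petek et al. (cycle ergometry, endurance athletes)",
      sex = c("male", "female"), modality = "CE", output_unit = "l_min",
      predictors = c("age", "body_mass", "sex"),
      fun = function(d) {
        0.054 * d$body_mass - 0.0245 * d$age + 0.68 -
          0.45 * (d$sex == "female")
      }
    )
  )
  names(models) <- vapply(models, `[[`, "", "model_id")
  models
}
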