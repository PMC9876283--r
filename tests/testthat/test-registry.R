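test_that("built-in registry reproduces the validated model structure", {
  models <- builtin_models()
  expect_length(models, 13)
  expect_equal(anyDuplicated(names(models)), 0)

  expect_equal(models$wilson$sex, "male")
  expect_equal(models$fitzgerald$sex, "female")
  expect_setequal(models$wilson$modality, c("TE", "CE"))

  kok <- models[grep("^kokkinos", names(models))]
  expect_length(kok, 3)
  expect_true(all(vapply(kok, function(m) identical(m$modality, "CE"), TRUE)))
  expect_true(all(vapply(kok, `[[`, "", "output_unit") == "ml_kg_min"))

  nev <- models[grep("^nevill", names(models))]
  expect_length(nev, 2)
  expect_true(all(vapply(nev, function(m) identical(m$modality, "TE"), TRUE)))

  expect_equal(models$petek_te$output_unit, "l_min")
  expect_equal(models$petek_ce$output_unit, "l_min")
  expect_equal(models$wasserman_male$output_unit, "ml_min")
  expect_equal(models$mylius_ce$modality, "CE")
  expect_equal(models$myers_te$modality, "TE")

  for (m in models) {
    expect_gte(length(m$predictors), 1)
    expect_true(all(m$sex %in% c("male", "female")))
  }
})

test_that("applicability filtering matches the published panel structure", {
  fce <- applicable_models("female", "CE")
  expect_false("wilson" %in% names(fce))
  expect_true("fitzgerald" %in% names(fce))
  expect_true("kokkinos_ce_female" %in% names(fce))
  expect_false("kokkinos_ce_male" %in% names(fce))

  mte <- applicable_models("male", "TE")
  expect_true(all(c("nevill_te_allometric", "nevill_te_additive") %in% names(mte)))
  expect_false("myers_te" %in% names(applicable_models("male", "CE")))
  expect_false("fitzgerald" %in% names(mte))
})

test_that("built-in equations match independent hand evaluation", {
  male <- make_record(age = 35, body_mass = 77, height = 180)
  female <- make_record(sex = "female", age = 32, body_mass = 60,
                        height = 167, modality = "CE")
  models <- builtin_models()

  expect_equal(predict(models$wilson, male), 75.4 - 0.46 * 35)
  expect_equal(predict(models$fitzgerald, female), 72.9 - 0.62 * 32)
  expect_equal(predict(models$wasserman_male, male), 77 * (50.72 - 0.372 * 35))
  expect_equal(predict(models$wasserman_female, female),
               (60 + 43) * (22.78 - 0.17 * 32))
  expect_equal(predict(models$kokkinos_ce_male, male), 60.4 - 0.40 * 35)
  expect_equal(predict(models$kokkinos_ce_combined, female),
               58.6 - 0.40 * 32 - 3.0)
  expect_equal(predict(models$mylius_ce, female),
               -273 + 18 * 60 + 12 * 167 - 26 * 32)
  expect_equal(predict(models$myers_te, male),
               79.9 - 0.39 * 35 - 0.127 * 77 * 2.2046226)
  expect_equal(predict(models$nevill_te_allometric, male),
               222.1 * 77^(-1 / 3) * exp(-0.004 * 35))
  expect_equal(predict(models$nevill_te_additive, female),
               72.9 - 0.36 * 32 - 0.20 * 60 - 13.8)
  expect_equal(predict(models$petek_te, male),
               0.054 * 77 - 0.0245 * 35 + 0.87)
  expect_equal(predict(models$petek_ce, female),
               0.054 * 60 - 0.0245 * 32 + 0.68 - 0.45)
})

test_that("registration is id-unique and custom models evaluate", {
  reg <- model_registry()
  toy <- vo2_model("const40", "toy", c("male", "female"), c("TE", "CE"),
                   "ml_kg_min", "age", function(d) rep(40, nrow(d)))
  reg2 <- register(reg, toy)
  expect_true("const40" %in% names(reg2$models))
  expect_length(reg$models, 13)      # original registry untouched
  expect_error(register(reg2, toy), "already registered")

  lin <- linear_vo2_model("agelin", "toy linear", c("male", "female"),
                          c("TE", "CE"), "ml_kg_min", 60, c(age = -0.5))
  expect_equal(predict(lin, make_record(age = 40)), 40.0)
})

test_that("prediction table respects applicability and unit discipline", {
  co <- generate_cohort(default_config(120, seed = 111))
  toy <- vo2_model("const40", "toy", c("male", "female"), c("TE", "CE"),
                   "ml_kg_min", "age", function(d) rep(40, nrow(d)))
  tab <- predict_cohort(co, list(toy))
  expect_true(all(tab$predicted == 40))
  expect_true(all(tab$applicable))

  full <- predict_cohort(co)
  expect_equal(nrow(full), 120 * 13)
  # never a prediction outside the applicability sets
  expect_true(all(is.na(full$predicted[!full$applicable])))
  expect_true(all(full$flag[!full$applicable] == "not_applicable"))
  wil <- full[full$model_id == "wilson", ]
  expect_true(all(!wil$applicable[wil$sex == "female"]))

  # observed column in the model's native unit: L/min for Petek
  pet <- full[full$model_id == "petek_te", ]
  i <- match(pet$subject_id, co$subject_id)
  expect_equal(pet$observed, co$vo2max_rel[i] * co$body_mass[i] / 1000)

  # purity: same records -> same predictions, regardless of order
  shuffled <- co[rev(seq_len(nrow(co))), ]
  tab2 <- predict_cohort(shuffled)
  key <- paste(tab2$subject_id, tab2$model_id)
  ord <- match(paste(full$subject_id, full$model_id), key)
  expect_equal(full$predicted, tab2$predicted[ord])
})
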