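test_that("perfect and affine agreement give the textbook calibration identities", {
  set.seed(121)
  x <- rnorm(60, 50, 6)
  id <- fit_calibration(x, x)
  expect_equal(id$c2, 1)
  expect_equal(id$c1, 0, tolerance = 1e-12)
  expect_equal(id$r2_adj, 1)
  expect_equal(id$rmse, 0, tolerance = 1e-10)

  dbl <- fit_calibration(2 * x, x)
  expect_equal(dbl$c2, 2)
  expect_equal(dbl$c1, 0, tolerance = 1e-12)
  expect_equal(dbl$rmse, 0, tolerance = 1e-10)

  expect_error(fit_calibration(x, rep(1, 60)), "constant")
  expect_error(fit_calibration(x[1:2], x[1:2]), "at least 3")
})

test_that("calibration fit agrees with the closed-form OLS oracle", {
  set.seed(131)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    x <- rnorm(n, 45, 8)
    y <- 5 + 0.9 * x + rnorm(n, 0, sample(c(0.5, 3, 10), 1))
    cal <- fit_calibration(y, x)
    o <- ols_oracle(y, x)
    expect_equal(cal$slope, o$slope, tolerance = 1e-10)
    expect_equal(cal$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(cal$r2_adj, o$r2_adj, tolerance = 1e-10)
    expect_equal(cal$rmse, o$rmse, tolerance = 1e-10)
    expect_equal(cal$p_slope, o$p_slope, tolerance = 1e-9)
    # r2 equals the squared Pearson correlation
    expect_equal(cal$r2, cor(y, x)^2, tolerance = 1e-12)
  }
})

test_that("adjusted R2 can go negative on uncorrelated pairs", {
  set.seed(141)
  neg <- replicate(50, {
    y <- rnorm(20); x <- rnorm(20)
    fit_calibration(y, x)$r2_adj
  })
  expect_true(any(neg < 0))
})

test_that("calibration-in-the-large honours both conventions", {
  set.seed(151)
  x <- rnorm(80, 50, 5)
  both0 <- c(calibration_in_the_large(x, x, "free_intercept"),
             calibration_in_the_large(x, x, "mean_difference"))
  expect_equal(unname(both0), c(0, 0), tolerance = 1e-10)

  md <- calibration_in_the_large(x, x - 5, "mean_difference")
  expect_equal(as.numeric(md), 5)
  expect_equal(attr(md, "convention"), "mean_difference")

  co <- generate_cohort(default_config(10000, seed = 151))
  pr <- inject_predictions(co, c0 = 10, c1 = 0.8, noise_sd = 2, seed = 152)
  fi <- calibration_in_the_large(pr$observed, pr$predicted, "free_intercept")
  expect_lt(abs(as.numeric(fi) - 10), 0.5)
  expect_lt(abs(fit_calibration(pr$observed, pr$predicted)$c2 - 0.8), 0.02)
})

test_that("mean differences carry t-based intervals with sane edge cases", {
  md <- mean_difference(c(50, 52), c(48, 50))
  expect_equal(md$mean_diff, -2)           # underestimation
  expect_equal(md$ci_low, md$ci_high)      # zero-variance differences
  expect_true(is.na(md$p))                 # undefined for constant non-zero

  same <- mean_difference(c(50, 52, 54), c(50, 52, 54))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)

  set.seed(161)
  o <- rnorm(40, 50, 5); p <- o + rnorm(40, 1, 2)
  got <- mean_difference(o, p)
  d <- p - o
  half <- qt(0.975, 39) * sd(d) / sqrt(40)
  expect_equal(got$mean_diff, mean(d))
  expect_equal(got$ci_low, mean(d) - half, tolerance = 1e-12)
  expect_equal(got$ci_high, mean(d) + half, tolerance = 1e-12)
  expect_true(got$ci_low <= got$mean_diff && got$mean_diff <= got$ci_high)
})

test_that("metrics are invariant to record order", {
  set.seed(171)
  y <- rnorm(50, 50, 5); x <- y + rnorm(50)
  a <- fit_calibration(y, x)
  i <- sample(50)
  b <- fit_calibration(y[i], x[i])
  expect_equal(a$c1, b$c1)
  expect_equal(a$c2, b$c2)
  expect_equal(a$rmse, b$rmse)
})

test_that("subgroup validation covers panels, excludes transition, marks degenerates", {
  co <- stratify(apply_inclusion(generate_cohort(default_config(3000, seed = 181)))$cohort)
  met <- validate_models(co, axis = "endurance")
  expect_false("transition" %in% met$subgroup)
  expect_setequal(unique(met$subgroup), c("HTEA", "REA", "LTEA"))

  # row count: applicable models x 3 subgroups per sex x modality panel
  expected_rows <- 0
  for (sx in c("male", "female")) for (md in c("TE", "CE")) {
    expected_rows <- expected_rows + 3 * length(applicable_models(sx, md))
  }
  expect_equal(nrow(met), expected_rows)
  expect_equal(met$reliable, met$n >= 100)

  whole <- validate_models(co, axis = "whole")
  expect_equal(unique(whole$subgroup), "all")
  # whole-population panels keep the transition records
  n_mte <- sum(co$sex == "male" & co$modality == "TE")
  expect_equal(unique(whole$n[whole$sex == "male" & whole$modality == "TE"]),
               n_mte)

  # a perfect custom model validates with the identity metrics
  perfect <- vo2_model("oracle", "perfect", c("male", "female"),
                       c("TE", "CE"), "ml_kg_min", "vo2max_rel",
                       function(d) d$vo2max_rel)
  pm <- validate_models(co, list(perfect), axis = "whole")
  expect_equal(pm$r2_adj, rep(1, nrow(pm)))
  expect_equal(pm$c2, rep(1, nrow(pm)))
  expect_equal(pm$c1, rep(0, nrow(pm)), tolerance = 1e-10)

  # degenerate subgroups are marked, not dropped
  tiny <- co[co$sex == "male" & co$modality == "TE", ][1:2, ]
  tiny_met <- validate_models(tiny, list(perfect), axis = "whole")
  expect_true("degenerate" %in% tiny_met$status[tiny_met$n > 0])
  expect_true(all(tiny_met$status[tiny_met$n == 0] == "empty"))
})
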