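test_that("unit conversions match hand arithmetic and form a group action", {
  expect_equal(convert_vo2(4000, "ml_min", "l_min"), 4.0)
  expect_equal(convert_vo2(4000, "ml_min", "ml_kg_min", body_mass = 80), 50)
  expect_equal(convert_vo2(52.97, "ml_kg_min", "ml_min", body_mass = 70),
               3707.9)
  expect_error(convert_vo2(50, "ml_kg_min", "ml_min"), "body_mass")
  expect_error(convert_vo2(50, "ml_kg_min", "ml_min", body_mass = -1),
               "positive")

  # any cycle of conversions returns the start value within 1e-9 relative
  set.seed(42)
  units <- vo2_units()
  for (i in 1:50) {
    v0 <- runif(1, 20, 90)
    mass <- runif(1, 45, 110)
    path <- sample(units, 5, replace = TRUE)
    v <- v0
    from <- "ml_kg_min"
    for (u in c(path, "ml_kg_min")) {
      v <- convert_vo2(v, from, u, body_mass = mass)
      from <- u
    }
    expect_equal(v, v0, tolerance = 1e-9)
  }
})

test_that("absolute VO2 derivation is consistent with conversion", {
  co <- generate_cohort(default_config(50, seed = 3))
  expect_equal(derive_absolute_vo2(co), co$vo2max_rel * co$body_mass)
  expect_equal(derive_absolute_vo2(co),
               convert_vo2(co$vo2max_rel, "ml_kg_min", "ml_min", co$body_mass))
})

test_that("15-s VO2max handles constant, plateau-block, and short series", {
  t_reg <- seq(0, 60, by = 2)
  expect_equal(vo2max_15s(t_reg, rep(4000, length(t_reg))), 4000)

  # 3000 everywhere except one clean 15-s block at 4000
  v <- rep(3000, length(t_reg))
  v[t_reg >= 30 & t_reg < 45] <- 4000
  expect_equal(vo2max_15s(t_reg, v), 4000)

  expect_error(vo2max_15s(c(0, 5, 10), c(1, 1, 1) * 3000), "15")
  expect_error(vo2max_15s(c(0, 3, 2), c(1, 1, 1) * 3000), "increasing")
})

test_that("15-s VO2max equals an exhaustive sliding-window oracle on a ramp", {
  # irregular breath spacing, linear ramp 2000 -> 4000 over 600 s
  set.seed(11)
  t <- sort(runif(400, 0, 600))
  t <- c(0, t, 600)
  v <- 2000 + (4000 - 2000) * t / 600

  # oracle: dense enumeration of window starts, trapezoid-free step integral
  step_mean <- function(s) {
    e <- s + 15
    idx <- which(t >= s & t <= e)
    knots <- unique(c(s, t[idx], e))
    vals <- v[findInterval(knots[-length(knots)], t)]
    sum(vals * diff(knots)) / 15
  }
  starts <- seq(0, 585, length.out = 4000)
  oracle <- max(vapply(starts, step_mean, 0))
  expect_equal(vo2max_15s(t, v), oracle, tolerance = 1e-6)
})

test_that("15-s VO2max is monotone and ignores lower leading baseline", {
  set.seed(12)
  for (i in 1:20) {
    t <- sort(runif(80, 0, 120))
    v1 <- runif(80, 2000, 4000)
    v2 <- v1 + runif(80, 0, 500)   # pointwise larger
    expect_gte(vo2max_15s(t, v2), vo2max_15s(t, v1))
  }
  t <- seq(0, 60, by = 1.5)
  v <- 3000 + 10 * t
  peak <- vo2max_15s(t, v)
  lead_t <- seq(-30, -1, by = 2)
  expect_equal(vo2max_15s(c(lead_t, t), c(rep(1000, length(lead_t)), v)), peak)
})

test_that("cohort CSV round trip is lossless and bad rows are rejected", {
  co <- generate_cohort(default_config(100, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 100)
  for (cl in names(co)) {
    expect_equal(back[[cl]], co[[cl]], tolerance = 1e-12, label = cl)
  }

  # height = 0 makes the BMI invariant unverifiable -> row rejected
  bad <- co
  bad$height[3] <- 0
  bad$vo2max_rel[7] <- -1
  write_cohort(bad, path)
  expect_message(back2 <- read_cohort(path), "rejected")
  expect_equal(nrow(back2), 98)
  diag <- attr(back2, "diagnostics")
  expect_setequal(unique(diag$row), c(3, 7))

  # a missing required column is a format error naming the column
  trunc <- co[, setdiff(names(co), "borg_peak")]
  write.csv(trunc, path, row.names = FALSE)
  expect_error(read_cohort(path), "borg_peak")

  # non-numeric field in a numeric column -> row error, not a crash
  write_cohort(co[1:3, ], path)
  lines <- readLines(path)
  fields <- strsplit(lines[2], ",")[[1]]
  fields[3] <- "notanumber"   # age column
  lines[2] <- paste(fields, collapse = ",")
  writeLines(lines, path)
  expect_message(back3 <- read_cohort(path), "rejected")
  expect_equal(nrow(back3), 2)
})

test_that("breath-series reader enforces ordering and sign", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,vo2", "0,3000", "2,3100", "4,3200"), path)
  bs <- read_breath_series(path)
  expect_equal(bs$vo2, c(3000, 3100, 3200))
  writeLines(c("time,vo2", "0,3000", "2,-5"), path)
  expect_error(read_breath_series(path), "non-negative")
  writeLines(c("time,vo2", "0,3000", "0,3100"), path)
  expect_error(read_breath_series(path), "increasing")
})
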