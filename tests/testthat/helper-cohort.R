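# In-code fixtures shared across test files.

# A single fully specified CPET record that passes every inclusion and
# exertion criterion; fields can be overridden per test.
make_record <- function(...) {
  rec <- data.frame(
    subject_id = "T0001",
    sex = "male",
    age = 35,
    height = 180,
    body_mass = 77,
    bmi = 77 / 1.8^2,
    body_fat_pct = 15,
    ffm = 77 * 0.85,
    modality = "TE",
    vo2max_rel = 54,
    rer_peak = 1.15,
    la_peak = 10,
    fr_peak = 55,
    borg_peak = 19,
    hr_peak = 180,
    plateau_observed = TRUE,
    rcp_speed = 14.5,
    rcp_power_rel = NA_real_,
    post_rcp_gain_pct = 15,
    training_months = 48,
    has_condition = FALSE,
    on_medication = FALSE,
    smoker = FALSE,
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  # keep derived fields consistent unless explicitly overridden
  if (!"bmi" %in% names(dots)) {
    rec$bmi <- rec$body_mass / (rec$height / 100)^2
  }
  if (!"ffm" %in% names(dots)) {
    rec$ffm <- rec$body_mass * (1 - rec$body_fat_pct / 100)
  }
  if (!any(c("rcp_speed", "rcp_power_rel") %in% names(dots)) &&
      rec$modality == "CE") {
    rec$rcp_speed <- NA_real_
    rec$rcp_power_rel <- 3.4
  }
  rec
}

# Bind several records into a small cohort.
make_cohort <- function(n = 6, ...) {
  rows <- lapply(seq_len(n), function(i) {
    make_record(subject_id = sprintf("T%04d", i), ...)
  })
  do.call(rbind, rows)
}

# A record built from a logical vector over the seven exertion criteria
# (order: rer, plateau, fr, borg, lactate, post_rcp_gain, hr_proximity).
# Met criteria sit exactly on the inclusive boundary so boundary handling
# is exercised constantly.
record_with_criteria <- function(met) {
  stopifnot(length(met) == 7)
  make_record(
    rer_peak = if (met[1]) 1.10 else 1.05,
    plateau_observed = met[2],
    fr_peak = if (met[3]) 45 else 40,
    borg_peak = if (met[4]) 18 else 15,
    la_peak = if (met[5]) 8 else 6,
    post_rcp_gain_pct = if (met[6]) 10 else 5,
    hr_peak = if (met[7]) (220 - 35) - 15 else (220 - 35) - 25
  )
}

# Closed-form two-pass OLS of y on x: the independent oracle for the
# calibration fit.
ols_oracle <- function(y, x) {
  n <- length(y)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum((y - my)^2)
  r2 <- 1 - sse / sst
  sigma2 <- sse / (n - 2)
  se_slope <- sqrt(sigma2 / sxx)
  se_int <- sqrt(sigma2 * (1 / n + mx^2 / sxx))
  list(
    intercept = intercept, slope = slope, r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
    rmse = sqrt(sse / n),
    p_slope = 2 * stats::pt(abs(slope / se_slope), df = n - 2, lower.tail = FALSE),
    p_int = 2 * stats::pt(abs(intercept / se_int), df = n - 2, lower.tail = FALSE)
  )
}
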