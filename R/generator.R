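# Synthetic CPET cohort generator.
#
# The generator emulates the statistical structure the validation pipeline
# assumes: per-sex anthropometric marginals, a sex x modality mix, stratum
# specific VO2max marginals, an age-fitness dependence and a respiratory
# compensation point (RCP) variable correlated with VO2max, plus
# effort-variable distributions that make most records pass the
# maximal-exertion screen.  Dependence is induced through a Gaussian copula
# so configured marginal means are honoured exactly (truncated margins are
# location-corrected; see the methods vignette).

#' Default generator configuration
#'
#' Returns the configuration describing the reference population of adult
#' endurance athletes the package emulates: 84.76% male; male age
#' 35.04 (9.58) years, height 179.42 (6.60) cm, mass 77.23 (10.32) kg,
#' body fat 15.68 (4.55)%; female age 32.25 (8.99), height 167.19 (6.88),
#' mass 60.60 (8.73), body fat 22.04 (5.46); treadmill probability
#' 3330/4459 (male) and 671/801 (female); VO2max 54.10 (6.93) male-TE,
#' 51.92 (8.05) male-CE, 48.79 (6.67) female-TE, 49.05 (6.64) female-CE
#' mL·min^-1·kg^-1.  Fat-free mass is always computed as
#' `mass * (1 - bf/100)`, consistent in expectation with the reference
#' fat-free mass values.
#'
#' Dependence defaults (age-VO2max correlation -0.4, RCP-VO2max
#' correlation 0.9 within sex x modality) and the effort-variable
#' distributions are generator conventions, configurable through the
#' returned list.
#'
#' @param n Cohort size (default 1000).
#' @param seed Integer seed stored in the config; [generate_cohort()] uses
#'   it unless overridden.
#' @return A list of class `vo2_generator_config`.
#' @export
default_config <- function(n = 1000, seed = 1L) {
  cfg <- list(
    n = as.integer(n),
    seed = as.integer(seed),
    male_fraction = 0.8476,
    te_probability = c(male = 3330 / 4459, female = 671 / 801),
    anthropometrics = list(
      male = list(
        age = c(mean = 35.04, sd = 9.58),
        height = c(mean = 179.42, sd = 6.60),
        body_mass = c(mean = 77.23, sd = 10.32),
        body_fat_pct = c(mean = 15.68, sd = 4.55)
      ),
      female = list(
        age = c(mean = 32.25, sd = 8.99),
        height = c(mean = 167.19, sd = 6.88),
        body_mass = c(mean = 60.60, sd = 8.73),
        body_fat_pct = c(mean = 22.04, sd = 5.46)
      )
    ),
    vo2max = list(
      male_TE = c(mean = 54.10, sd = 6.93),
      male_CE = c(mean = 51.92, sd = 8.05),
      female_TE = c(mean = 48.79, sd = 6.67),
      female_CE = c(mean = 49.05, sd = 6.64)
    ),
    age_vo2_cor = -0.4,
    rcp_vo2_cor = 0.9,
    # RCP variable scale: running speed (km/h) on the treadmill, relative
    # power (W/kg) on the cycle ergometer.
    rcp = list(
      TE = c(mean = 14.5, sd = 2.0),
      CE = c(mean = 3.4, sd = 0.6)
    ),
    height_mass_cor = 0.5,
    effort = list(
      rer = c(mean = 1.14, sd = 0.04),
      lactate = c(mean = 10, sd = 2),
      fr = c(mean = 55, sd = 8),
      borg_levels = 18:20,
      hr_margin = c(mean = 5, sd = 5),      # |N| bpm below predicted HRmax
      post_rcp_gain = c(mean = 15, sd = 3), # % beyond RCP
      plateau_prob = 0.95
    ),
    training_months = c(mean = 48, sd = 30, min = 3),
    truncation = list(
      age_min = 18,
      height_min = 140,
      body_mass_min = 35,
      body_fat_range = c(3, 45)
    )
  )
  class(cfg) <- "vo2_generator_config"
  cfg
}

#' @keywords internal
validate_config <- function(config) {
  stopifnot(inherits(config, "vo2_generator_config"))
  probs <- c(config$male_fraction, config$te_probability,
             config$effort$plateau_prob)
  if (any(probs < 0 | probs > 1)) .stop("probabilities must lie in [0, 1]")
  sds <- c(
    vapply(config$anthropometrics, function(s) vapply(s, `[[`, 0, "sd"), numeric(4)),
    vapply(config$vo2max, `[[`, 0, "sd"),
    vapply(config$rcp, `[[`, 0, "sd")
  )
  if (any(sds <= 0)) .stop("all SDs must be positive")
  if (config$truncation$age_min < 18) .stop("age truncation must keep age >= 18")
  invisible(config)
}

# Location parameter such that a normal truncated to [lo, hi] with scale
# `sd` has mean `target`.
.trunc_location <- function(target, sd, lo = -Inf, hi = Inf) {
  if (!is.finite(lo) && !is.finite(hi)) return(target)
  f <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a)) - target
  }
  uniroot(f, c(target - 6 * sd, target + 6 * sd), tol = 1e-10)$root
}

# Truncated-normal quantile, driven by a uniform from the copula.
.qtrunc <- function(u, mu, sd, lo = -Inf, hi = Inf) {
  pa <- pnorm(lo, mu, sd)
  pb <- pnorm(hi, mu, sd)
  qnorm(pa + u * (pb - pa), mu, sd)
}

#' Generate a synthetic CPET cohort
#'
#' Deterministic for a fixed `(config, seed)` pair.  Marginal sample means
#' of age, height, mass, body fat and of VO2max per sex x modality stratum
#' converge to the configured values as n grows; the RCP variable carries
#' the configured correlation with relative VO2max within each sex x
#' modality stratum; every generated record satisfies the CPET record
#' invariants.
#'
#' @param config A [default_config()]-style configuration.
#' @param n Number of records (defaults to `config$n`).
#' @param seed Random seed (defaults to `config$seed`).
#' @return A `cpet_cohort` data frame.
#' @export
generate_cohort <- function(config = default_config(), n = config$n,
                            seed = config$seed) {
  validate_config(config)
  n <- as.integer(n)
  if (is.na(n) || n <= 0) .stop("n must be a positive integer")
  set.seed(as.integer(seed))
  tr <- config$truncation

  sex <- ifelse(runif(n) < config$male_fraction, "male", "female")
  modality <- ifelse(runif(n) < config$te_probability[sex], "TE", "CE")
  stratum <- paste(sex, modality, sep = "_")

  # Gaussian copula: age and latent fitness share correlation age_vo2_cor;
  # the RCP variable loads on latent fitness with rcp_vo2_cor.
  rho_af <- config$age_vo2_cor
  rho_rf <- config$rcp_vo2_cor
  z_age <- rnorm(n)
  z_fit <- rho_af * z_age + sqrt(1 - rho_af^2) * rnorm(n)
  z_rcp <- rho_rf * z_fit + sqrt(1 - rho_rf^2) * rnorm(n)

  par_of <- function(field) {
    m <- vapply(config$anthropometrics, function(s) s[[field]]["mean"], 0)
    s <- vapply(config$anthropometrics, function(s) s[[field]]["sd"], 0)
    list(mean = unname(m[sex]), sd = unname(s[sex]))
  }

  trunc_draw <- function(u, pars, lo = -Inf, hi = Inf) {
    out <- numeric(n)
    for (sx in c("male", "female")) {
      i <- sex == sx
      if (!any(i)) next
      mu0 <- pars$mean[i][1]
      sd0 <- pars$sd[i][1]
      mu <- .trunc_location(mu0, sd0, lo, hi)
      out[i] <- .qtrunc(u[i], mu, sd0, lo, hi)
    }
    out
  }

  age <- trunc_draw(pnorm(z_age), par_of("age"), lo = tr$age_min)

  vo2_mean <- vapply(config$vo2max, `[[`, 0, "mean")[stratum]
  vo2_sd <- vapply(config$vo2max, `[[`, 0, "sd")[stratum]
  vo2max_rel <- unname(vo2_mean + vo2_sd * z_fit)

  rcp_mean <- vapply(config$rcp, `[[`, 0, "mean")[modality]
  rcp_sd <- vapply(config$rcp, `[[`, 0, "sd")[modality]
  rcp_value <- unname(rcp_mean + rcp_sd * z_rcp)

  rho_hm <- config$height_mass_cor
  z_h <- rnorm(n)
  z_m <- rho_hm * z_h + sqrt(1 - rho_hm^2) * rnorm(n)
  height <- trunc_draw(pnorm(z_h), par_of("height"), lo = tr$height_min)
  body_mass <- trunc_draw(pnorm(z_m), par_of("body_mass"), lo = tr$body_mass_min)
  bf <- trunc_draw(pnorm(rnorm(n)), par_of("body_fat_pct"),
                   lo = tr$body_fat_range[1], hi = tr$body_fat_range[2])

  ef <- config$effort
  rer <- rnorm(n, ef$rer["mean"], ef$rer["sd"])
  la <- rnorm(n, ef$lactate["mean"], ef$lactate["sd"])
  fr <- rnorm(n, ef$fr["mean"], ef$fr["sd"])
  borg <- sample(ef$borg_levels, n, replace = TRUE)
  hr_deficit <- abs(rnorm(n, ef$hr_margin["mean"], ef$hr_margin["sd"]))
  gain <- rnorm(n, ef$post_rcp_gain["mean"], ef$post_rcp_gain["sd"])
  plateau <- runif(n) < ef$plateau_prob
  tm <- config$training_months
  training <- pmax(tm["min"], round(rnorm(n, tm["mean"], tm["sd"])))

  out <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    sex = sex,
    age = age,
    height = height,
    body_mass = body_mass,
    bmi = body_mass / (height / 100)^2,
    body_fat_pct = bf,
    ffm = body_mass * (1 - bf / 100),
    modality = modality,
    vo2max_rel = pmax(vo2max_rel, 1),
    rer_peak = rer,
    la_peak = la,
    fr_peak = fr,
    borg_peak = borg,
    hr_peak = (220 - age) - hr_deficit,
    plateau_observed = plateau,
    rcp_speed = ifelse(modality == "TE", rcp_value, NA_real_),
    rcp_power_rel = ifelse(modality == "CE", rcp_value, NA_real_),
    post_rcp_gain_pct = gain,
    training_months = unname(training),
    has_condition = rep(FALSE, n),
    on_medication = rep(FALSE, n),
    smoker = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cpet_cohort", "data.frame")
  out
}

#' Pair observed values with defect-injected predictions
#'
#' Builds a pseudo prediction model with a known calibration defect:
#' `observed = c0 + c1 * predicted + e`, `e ~ N(0, noise_sd)`.  The
#' cohort's relative VO2max acts as the error-free linear predictor
#' (`predicted = (vo2max_rel - c0) / c1`) and the measurement noise is
#' drawn independently of it, so ordinary least squares of observed on
#' predicted is consistent for `(c0, c1)` and metric recovery is
#' testable.  With `noise_sd = 0` the observed vector is exactly the
#' cohort's VO2max.
#'
#' @param cohort CPET cohort; `vo2max_rel` anchors the pairs.
#' @param c0 Intercept of the injected defect, observed units.
#' @param c1 Slope of the injected defect (non-zero).
#' @param noise_sd Residual SD in observed units (>= 0).
#' @param seed Optional seed for the noise draw.
#' @return Data frame with columns `observed`, `predicted`.
#' @export
inject_predictions <- function(cohort, c0 = 0, c1 = 1, noise_sd = 0,
                               seed = NULL) {
  if (nrow(cohort) == 0) .stop("cohort is empty")
  if (c1 == 0) .stop("c1 must be non-zero: a zero slope leaves the calibration regression without a recovery target")
  if (noise_sd < 0) .stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  predicted <- (cohort$vo2max_rel - c0) / c1
  e <- if (noise_sd > 0) rnorm(length(predicted), 0, noise_sd) else 0
  observed <- c0 + c1 * predicted + e
  data.frame(observed = observed, predicted = predicted)
}

#' Named eligibility defects the contaminator can inject
#'
#' One entry per inclusion or maximal-exertion criterion that
#' [contaminate()] can violate.
#'
#' @return Character vector of defect codes.
#' @export
contamination_reasons <- function() {
  c("age", "smoker", "rer", "borg", "lactate", "fr",
    "hr_proximity", "plateau", "post_rcp_gain", "outlier")
}

#' Inject eligibility violations into a cohort
#'
#' Modifies a requested fraction of records so each violates exactly one
#' named inclusion or maximal-exertion criterion; the modifications are
#' logged in the `"contamination_log"` attribute.  Note that a single
#' unmet exertion criterion does not by itself fail the >=6-of-7 effort
#' rule, so effort-type defects are guaranteed to be visible in the
#' per-criterion effort assessment rather than in the final
#' include/exclude decision.
#'
#' @param cohort CPET cohort.
#' @param fraction Fraction of records to contaminate, in `[0, 1]`.
#' @param seed Seed controlling which records and defects are drawn.
#' @param reasons Candidate defect types; see [contamination_reasons()].
#' @return The modified cohort with attribute `"contamination_log"`
#'   (data frame `row`, `subject_id`, `reason`).
#' @export
contaminate <- function(cohort, fraction, seed = 1L,
                        reasons = contamination_reasons()) {
  if (fraction < 0 || fraction > 1) .stop("fraction must lie in [0, 1]")
  reasons <- match.arg(reasons, contamination_reasons(), several.ok = TRUE)
  n <- nrow(cohort)
  k <- round(fraction * n)
  log <- data.frame(row = integer(), subject_id = character(),
                    reason = character())
  if (k > 0) {
    set.seed(as.integer(seed))
    rows <- sample.int(n, k)
    why <- rep_len(reasons, k)[sample.int(k)]
    # outlier magnitude fixed from the pre-modification cohort moments
    v_mean <- mean(cohort$vo2max_rel)
    v_sd <- sd(cohort$vo2max_rel)
    for (j in seq_len(k)) {
      i <- rows[j]
      switch(why[j],
        age = { cohort$age[i] <- 17 },
        smoker = { cohort$smoker[i] <- TRUE },
        rer = { cohort$rer_peak[i] <- 1.04 },
        borg = { cohort$borg_peak[i] <- 15 },
        lactate = { cohort$la_peak[i] <- 6 },
        fr = { cohort$fr_peak[i] <- 40 },
        hr_proximity = { cohort$hr_peak[i] <- 220 - cohort$age[i] - 25 },
        plateau = { cohort$plateau_observed[i] <- FALSE },
        post_rcp_gain = { cohort$post_rcp_gain_pct[i] <- 5 },
        outlier = { cohort$vo2max_rel[i] <- v_mean + 4 * v_sd }
      )
    }
    log <- data.frame(row = rows, subject_id = cohort$subject_id[rows],
                      reason = why, stringsAsFactors = FALSE)
    log <- log[order(log$row), , drop = FALSE]
    rownames(log) <- NULL
  }
  attr(cohort, "contamination_log") <- log
  cohort
}
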