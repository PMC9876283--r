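# Age and endurance stratification.
#
# Endurance classes are defined by SD bands of the respiratory
# compensation point (RCP) variable -- running speed (km/h) on the
# treadmill, relative power (W/kg) on the cycle ergometer -- standardized
# within sex x modality.  Speed and W/kg are incommensurable, so pooling
# modalities is impossible; standardizing within modality as well as sex
# keeps the bands meaningful.

#' @keywords internal
age_group_levels <- function() c("18-30", "31-45", "46-60", "61+")

#' @keywords internal
endurance_levels <- function() c("HTEA", "REA", "LTEA", "transition")

#' Assign age groups
#'
#' Ages are truncated to completed years and then bucketed into 18-30,
#' 31-45, 46-60 and >= 61.
#'
#' @param age Age in years, all >= 18 (younger records are excluded
#'   upstream by [apply_inclusion()]).
#' @return Factor with levels `18-30`, `31-45`, `46-60`, `61+`.
#' @export
#' @examples
#' age_group(c(30.9, 31, 61))
age_group <- function(age) {
  if (any(is.na(age)) || any(age < 18)) {
    .stop("age_group requires age >= 18; younger records are excluded upstream")
  }
  yrs <- floor(age)
  cut(yrs, breaks = c(18, 31, 46, 61, Inf), right = FALSE,
      labels = age_group_levels())
}

#' Endurance z-scores at the respiratory compensation point
#'
#' Standardizes the RCP variable (`rcp_speed` for treadmill records,
#' `rcp_power_rel` for cycle-ergometer records) to z-scores with mean and
#' SD computed within each sex x modality stratum.
#'
#' @param cohort CPET cohort; every sex x modality stratum needs >= 2
#'   records and non-zero spread.
#' @return Numeric vector of z-scores, aligned with `cohort` rows.
#' @export
endurance_zscores <- function(cohort) {
  value <- ifelse(cohort$modality == "TE", cohort$rcp_speed,
                  cohort$rcp_power_rel)
  stratum <- paste(cohort$sex, cohort$modality, sep = " x ")
  z <- rep(NA_real_, nrow(cohort))
  for (g in unique(stratum)) {
    i <- stratum == g
    if (sum(i) < 2) .stop("stratum '", g, "' has fewer than 2 records")
    m <- mean(value[i])
    s <- sd(value[i])
    if (is.na(s) || s == 0) .stop("stratum '", g, "' has zero SD of the RCP variable")
    z[i] <- (value[i] - m) / s
  }
  z
}

#' Endurance group of a z-score
#'
#' High-trained (HTEA) strictly above +1.5 SD, low-trained (LTEA) strictly
#' below -1.5 SD, recreational (REA) strictly within +/-0.5 SD; the bands
#' 0.5 <= |z| <= 1.5 form the "transition" class, so the boundaries
#' +/-0.5 and +/-1.5 themselves belong to transition.
#'
#' @param z Finite numeric z-scores.
#' @return Factor with levels `HTEA`, `REA`, `LTEA`, `transition`.
#' @export
#' @examples
#' endurance_group(c(1.5, 1.6, 0, -1.6))
endurance_group <- function(z) {
  if (any(!is.finite(z))) .stop("z must be finite")
  lab <- ifelse(z > 1.5, "HTEA",
         ifelse(z < -1.5, "LTEA",
         ifelse(abs(z) < 0.5, "REA", "transition")))
  factor(lab, levels = endurance_levels())
}

#' Stratify a cohort by age and endurance level
#'
#' Annotates the cohort with `age_group`, `endurance_z` and
#' `endurance_group` columns.  Each axis partitions the cohort:
#' every record gets exactly one label per axis.
#'
#' @param cohort CPET cohort (post-inclusion, so all ages >= 18).
#' @return The annotated cohort.
#' @seealso [subgroup_sizes()] for subgroup sizes and reliability flags.
#' @export
stratify <- function(cohort) {
  cohort$age_group <- age_group(cohort$age)
  cohort$endurance_z <- endurance_zscores(cohort)
  cohort$endurance_group <- endurance_group(cohort$endurance_z)
  class(cohort) <- unique(c("cpet_cohort", class(cohort)))
  cohort
}

#' Subgroup sizes and reliability flags
#'
#' Counts records per sex x modality x subgroup for one stratification
#' axis and flags each subgroup as reliable when it reaches the n >= 100
#' external-validation sample-size guideline.
#'
#' @param cohort A [stratify()]-annotated cohort.
#' @param axis `"endurance"`, `"age"` or `"whole"`.
#' @param min_n Reliability threshold (default 100).
#' @return Data frame with `sex`, `modality`, `subgroup`, `n`, `reliable`.
#' @export
subgroup_sizes <- function(cohort, axis = c("endurance", "age", "whole"),
                           min_n = 100) {
  axis <- match.arg(axis)
  subs <- switch(axis,
    endurance = as.character(cohort$endurance_group),
    age = as.character(cohort$age_group),
    whole = rep("all", nrow(cohort))
  )
  key <- data.frame(sex = cohort$sex, modality = cohort$modality,
                    subgroup = subs, stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n = seq_len(nrow(key))), key, FUN = length)
  agg$reliable <- agg$n >= min_n
  agg[order(agg$sex, agg$modality, agg$subgroup), , drop = FALSE]
}
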