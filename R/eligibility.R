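# Inclusion/exclusion pipeline: six inclusion rules plus the >=6-of-7
# maximal-exertion rule.

#' Predicted maximal heart rate
#'
#' The exertion criterion referencing predicted maximal heart rate does
#' not fix a formula; the classical 220 - age is the default, with
#' Tanaka's 208 - 0.7*age available as an alternative.
#'
#' @param age Age in years.
#' @param formula `"fox"` (220 - age, default) or `"tanaka"`
#'   (208 - 0.7 * age).
#' @return Predicted HRmax in bpm.
#' @export
hrmax_predicted <- function(age, formula = c("fox", "tanaka")) {
  formula <- match.arg(formula)
  switch(formula, fox = 220 - age, tanaka = 208 - 0.7 * age)
}

#' @keywords internal
effort_criteria <- function() {
  c("rer", "plateau", "fr", "borg", "lactate", "post_rcp_gain",
    "hr_proximity")
}

#' Assess the seven maximal-exertion criteria
#'
#' A CPET counts as maximal exertion when at least 6 of 7 criteria hold:
#' RER >= 1.10; a VO2 plateau; breathing frequency >= 45 breaths·min^-1;
#' Borg rating >= 18; blood lactate >= 8 mmol·L^-1; speed/power gain
#' beyond the respiratory compensation point >= 10%; and peak heart rate
#' within 15 bpm of predicted maximum (HR_peak >= HRmax_pred - 15).  All
#' comparisons are inclusive at the boundary.  A missing criterion field
#' counts as not met and is flagged in `missing_any`, it does not raise an
#' error.
#'
#' @param cohort CPET cohort (one or more rows).
#' @param hrmax_formula Passed to [hrmax_predicted()].
#' @return Data frame with one logical column per criterion plus
#'   `met_count`, `passed` (met_count >= 6) and `missing_any`.
#' @export
assess_max_effort <- function(cohort, hrmax_formula = c("fox", "tanaka")) {
  hrmax_formula <- match.arg(hrmax_formula)
  met <- data.frame(
    rer = cohort$rer_peak >= 1.10,
    plateau = cohort$plateau_observed,
    fr = cohort$fr_peak >= 45,
    borg = cohort$borg_peak >= 18,
    lactate = cohort$la_peak >= 8,
    post_rcp_gain = cohort$post_rcp_gain_pct >= 10,
    hr_proximity = cohort$hr_peak >= hrmax_predicted(cohort$age, hrmax_formula) - 15
  )
  missing_any <- Reduce(`|`, lapply(met, is.na))
  met[] <- lapply(met, function(x) !is.na(x) & x)
  met$met_count <- rowSums(met)
  met$passed <- met$met_count >= 6
  met$missing_any <- missing_any
  cbind(subject_id = cohort$subject_id, met)
}

#' Detect a VO2 plateau from per-stage values
#'
#' A plateau is present when VO2 grows by less than 100 mL·min^-1 from the
#' penultimate to the final stage despite the increased running or cycling
#' intensity.
#'
#' @param stage_vo2 Ordered per-stage VO2 values, mL·min^-1 (at least 2).
#' @param threshold Growth threshold, mL·min^-1 (default 100).
#' @return Logical scalar.
#' @export
#' @examples
#' detect_plateau(c(3800, 3890))  # TRUE, growth 90
#' detect_plateau(c(3800, 3950))  # FALSE
detect_plateau <- function(stage_vo2, threshold = 100) {
  if (length(stage_vo2) < 2) .stop("at least two stages are required")
  n <- length(stage_vo2)
  (stage_vo2[n] - stage_vo2[n - 1]) < threshold
}

#' Default variable set for the extreme-outlier screen
#'
#' @return Character vector of the testing variables screened by default.
#' @export
outlier_default_variables <- function() {
  c("vo2max_rel", "rer_peak", "la_peak", "fr_peak", "hr_peak",
    "height", "body_mass", "bmi")
}

#' Screen for extreme outliers
#'
#' Flags a record when any listed variable lies strictly outside
#' mean +/- k*SD, with the moments computed once on the input cohort in a
#' single (non-iterative) pass, within `by` groups (sex by default).
#' Zero-variance variables are skipped with a warning.
#'
#' @param cohort CPET cohort (>= 2 rows per group).
#' @param variables Variables screened; default
#'   [outlier_default_variables()].
#' @param k SD multiplier (default 3).
#' @param by Grouping column for the moments, or `NULL` to pool; default
#'   `"sex"`.
#' @param stats Optional moment table from a previous screen (the
#'   `"stats"` attribute of an earlier result), reused instead of
#'   recomputing; this is what makes repeated filtering idempotent.
#' @return Logical vector of flags with attributes `"stats"` (the moment
#'   table) and `"details"` (row, variable, z for each flagged value).
#' @export
outlier_screen <- function(cohort, variables = outlier_default_variables(),
                           k = 3, by = "sex", stats = NULL) {
  if (nrow(cohort) < 2) .stop("outlier screen needs at least 2 records")
  groups <- if (is.null(by)) rep("all", nrow(cohort)) else as.character(cohort[[by]])
  if (is.null(stats)) {
    stats <- do.call(rbind, lapply(unique(groups), function(g) {
      i <- groups == g
      do.call(rbind, lapply(variables, function(v) {
        data.frame(group = g, variable = v,
                   mean = mean(cohort[[v]][i], na.rm = TRUE),
                   sd = sd(cohort[[v]][i], na.rm = TRUE))
      }))
    }))
  }
  flags <- rep(FALSE, nrow(cohort))
  details <- list()
  for (r in seq_len(nrow(stats))) {
    g <- stats$group[r]; v <- stats$variable[r]
    if (is.na(stats$sd[r]) || stats$sd[r] == 0) {
      warning("variable '", v, "' has zero variance in group '", g,
              "'; skipped", call. = FALSE)
      next
    }
    i <- which(groups == g)
    z <- (cohort[[v]][i] - stats$mean[r]) / stats$sd[r]
    hit <- !is.na(z) & abs(z) > k
    if (any(hit)) {
      flags[i[hit]] <- TRUE
      details[[length(details) + 1L]] <-
        data.frame(row = i[hit], variable = v, z = z[hit])
    }
  }
  attr(flags, "stats") <- stats
  attr(flags, "details") <- if (length(details)) do.call(rbind, details) else
    data.frame(row = integer(), variable = character(), z = numeric())
  flags
}

#' Apply the full inclusion/exclusion pipeline
#'
#' Excludes records failing any of: training experience >= 3 months,
#' age >= 18 years, the extreme-outlier screen, clear medical /
#' medication / smoker flags, and the >=6-of-7 maximal-exertion rule.
#' Every failure reason is recorded per record in the exclusion ledger.
#'
#' @param cohort CPET cohort.
#' @param k,outlier_variables,outlier_stats Passed to [outlier_screen()].
#' @param hrmax_formula Passed to [assess_max_effort()].
#' @param run_outlier_screen Set to `FALSE` to skip the outlier screen
#'   (for instance on an already-screened cohort).
#' @return A list of class `inclusion_result`: `cohort` (included
#'   records), and `ledger` with per-record reasons, per-rule counts,
#'   input/output sizes, the full effort assessment and the outlier
#'   moment table.
#' @export
apply_inclusion <- function(cohort, k = 3,
                            outlier_variables = outlier_default_variables(),
                            hrmax_formula = c("fox", "tanaka"),
                            outlier_stats = NULL,
                            run_outlier_screen = TRUE) {
  if (nrow(cohort) == 0) .stop("cohort is empty")
  hrmax_formula <- match.arg(hrmax_formula)
  effort <- assess_max_effort(cohort, hrmax_formula)
  out_flags <- if (run_outlier_screen) {
    outlier_screen(cohort, outlier_variables, k = k, stats = outlier_stats)
  } else {
    rep(FALSE, nrow(cohort))
  }

  fails <- list(
    training = cohort$training_months < 3,
    age = cohort$age < 18,
    outlier = as.logical(out_flags),
    medical = cohort$has_condition | cohort$on_medication,
    smoker = cohort$smoker,
    effort = !effort$passed
  )
  fails <- lapply(fails, function(x) !is.na(x) & x)
  fail_any <- Reduce(`|`, fails)

  reason_of <- function(i) {
    names(fails)[vapply(fails, `[`, logical(1), i)]
  }
  excluded <- which(fail_any)
  per_record <- if (length(excluded)) {
    do.call(rbind, lapply(excluded, function(i) {
      data.frame(row = i, subject_id = cohort$subject_id[i],
                 reason = reason_of(i), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(row = integer(), subject_id = character(), reason = character())
  }

  included <- cohort[!fail_any, , drop = FALSE]
  rownames(included) <- NULL
  class(included) <- c("cpet_cohort", "data.frame")
  ledger <- list(
    n_input = nrow(cohort),
    n_included = nrow(included),
    counts = vapply(fails, sum, integer(1)),
    per_record = per_record,
    effort_assessment = effort,
    outlier_stats = attr(out_flags, "stats")
  )
  class(ledger) <- "exclusion_ledger"
  structure(list(cohort = included, ledger = ledger),
            class = "inclusion_result")
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("CPET exclusion ledger\n")
  cat("  input records:   ", x$n_input, "\n")
  cat("  included records:", x$n_included, "\n")
  cat("  failures by rule:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("    %-10s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
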