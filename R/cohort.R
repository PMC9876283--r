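#' @keywords internal
cohort_columns <- function() {
  c(
    subject_id = "character",
    sex = "character",            # "male" / "female"
    age = "numeric",              # years
    height = "numeric",           # cm
    body_mass = "numeric",        # kg
    bmi = "numeric",              # kg m^-2
    body_fat_pct = "numeric",     # %
    ffm = "numeric",              # kg, fat-free mass
    modality = "character",       # "TE" treadmill / "CE" cycle ergometer
    vo2max_rel = "numeric",       # mL min^-1 kg^-1
    rer_peak = "numeric",
    la_peak = "numeric",          # mmol L^-1
    fr_peak = "numeric",          # breaths min^-1
    borg_peak = "numeric",        # 6-20 scale
    hr_peak = "numeric",          # bpm
    plateau_observed = "logical",
    rcp_speed = "numeric",        # km h^-1, TE only
    rcp_power_rel = "numeric",    # W kg^-1, CE only
    post_rcp_gain_pct = "numeric",# % of RCP speed/power achieved beyond RCP
    training_months = "numeric",
    has_condition = "logical",
    on_medication = "logical",
    smoker = "logical"
  )
}

#' Validate rows of a CPET cohort
#'
#' Checks every row against the record invariants: recognised sex and
#' modality labels, positive height/mass, internally consistent BMI
#' (|bmi - mass/(height/100)^2| <= 0.1), positive relative VO2max, fat-free
#' mass not exceeding body mass, Borg rating within 6-20, and exactly one
#' respiratory-compensation-point variable present, matching the modality
#' (`rcp_speed` for treadmill, `rcp_power_rel` for cycle ergometer).
#'
#' @param df Data frame with the columns of [cohort_template()].
#' @return A list with `valid` (logical per row) and `diagnostics`
#'   (data frame of `row`, `problem` for every failed check).
#' @export
validate_cohort <- function(df) {
  n <- nrow(df)
  problems <- list()
  note <- function(rows, what) {
    if (any(rows, na.rm = TRUE)) {
      idx <- which(rows)
      problems[[length(problems) + 1L]] <<- data.frame(row = idx, problem = what)
    }
  }

  num_cols <- names(cohort_columns())[cohort_columns() == "numeric"]
  for (cl in num_cols) {
    if (!cl %in% c("rcp_speed", "rcp_power_rel")) {
      note(is.na(df[[cl]]), paste0("non-numeric or missing ", cl))
    }
  }
  note(!df$sex %in% c("male", "female"), "sex must be 'male' or 'female'")
  note(!df$modality %in% c("TE", "CE"), "modality must be 'TE' or 'CE'")
  bad_h <- is.na(df$height) | df$height <= 0
  note(bad_h, "height must be positive")
  bad_m <- is.na(df$body_mass) | df$body_mass <= 0
  note(bad_m, "body_mass must be positive")
  bmi_chk <- !bad_h & !bad_m & !is.na(df$bmi) &
    abs(df$bmi - df$body_mass / (df$height / 100)^2) > 0.1
  note(bmi_chk, "bmi inconsistent with body_mass/height")
  note(!is.na(df$vo2max_rel) & df$vo2max_rel <= 0, "vo2max_rel must be positive")
  note(!is.na(df$ffm) & !is.na(df$body_mass) & df$ffm > df$body_mass,
       "ffm exceeds body_mass")
  note(!is.na(df$borg_peak) & (df$borg_peak < 6 | df$borg_peak > 20),
       "borg_peak outside 6-20")
  te <- df$modality == "TE"
  note(te & (is.na(df$rcp_speed) | !is.na(df$rcp_power_rel)),
       "TE record must carry rcp_speed only")
  note(!te & df$modality == "CE" & (is.na(df$rcp_power_rel) | !is.na(df$rcp_speed)),
       "CE record must carry rcp_power_rel only")

  diagnostics <- if (length(problems)) {
    out <- do.call(rbind, problems)
    out[order(out$row), , drop = FALSE]
  } else {
    data.frame(row = integer(), problem = character())
  }
  valid <- rep(TRUE, n)
  valid[unique(diagnostics$row)] <- FALSE
  list(valid = valid, diagnostics = diagnostics)
}

#' Empty CPET cohort template
#'
#' @return Zero-row data frame carrying the canonical column set and types;
#'   the documented CSV exchange schema is exactly these columns.
#' @export
cohort_template <- function() {
  cols <- cohort_columns()
  out <- lapply(cols, function(tp) vector(tp, 0L))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a CPET cohort from CSV
#'
#' The CSV must contain every column of [cohort_template()] (extra columns
#' are preserved).  Rows violating the record invariants are rejected and
#' reported through the `"diagnostics"` attribute of the returned data
#' frame, indexed by input row number.
#'
#' @param path Path to a CSV file.
#' @return Validated cohort data frame of class `cpet_cohort`, with
#'   attribute `"diagnostics"`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) .stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- cohort_columns()
  missing_cols <- setdiff(names(cols), names(raw))
  if (length(missing_cols)) {
    .stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (cl in names(cols)) {
    raw[[cl]] <- switch(cols[[cl]],
      character = as.character(raw[[cl]]),
      numeric = suppressWarnings(as.numeric(raw[[cl]])),
      logical = {
        v <- raw[[cl]]
        if (is.logical(v)) v else as.logical(toupper(as.character(v)) %in% c("TRUE", "1", "T"))
      }
    )
  }
  chk <- validate_cohort(raw)
  if (nrow(chk$diagnostics)) {
    message(sum(!chk$valid), " row(s) rejected; see attr(, 'diagnostics')")
  }
  out <- raw[chk$valid, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpet_cohort", "data.frame")
  attr(out, "diagnostics") <- chk$diagnostics
  out
}

#' Write a CPET cohort to CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path; UTF-8, full numeric precision.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a breath-by-breath VO2 series
#'
#' Two-column CSV: time in seconds, VO2 in mL·min^-1.  Times must be
#' strictly increasing and VO2 non-negative.
#'
#' @param path CSV path.
#' @return Data frame with columns `time`, `vo2`.
#' @export
read_breath_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stop("breath series needs two columns (time, vo2)")
  names(df)[1:2] <- c("time", "vo2")
  df <- df[, c("time", "vo2")]
  if (any(diff(df$time) <= 0)) .stop("breath times must be strictly increasing")
  if (any(df$vo2 < 0)) .stop("vo2 must be non-negative")
  df
}

#' 15-second averaged VO2max from a breath-by-breath series
#'
#' Reduces an irregularly sampled breath-by-breath VO2 series to the test
#' VO2max: the maximum over all windows of `window` seconds of the
#' time-weighted mean VO2.  Each breath's value is held until the next
#' breath (step interpolation), so the windowed mean is an exact integral
#' of the step function divided by the window length.  Because that
#' integral is piecewise linear in the window start, the maximum is
#' attained with a window edge at a breath time; only those candidate
#' starts are evaluated.
#'
#' @param time Breath timestamps in seconds, strictly increasing.  May also
#'   be a two-column data frame as returned by [read_breath_series()].
#' @param vo2 VO2 per breath, mL·min^-1 (ignored when `time` is a data
#'   frame).
#' @param window Averaging window in seconds (default 15).
#' @return Scalar VO2max in mL·min^-1.
#' @export
#' @examples
#' t <- seq(0, 60, by = 2)
#' vo2max_15s(t, rep(4000, length(t)))  # 4000
vo2max_15s <- function(time, vo2 = NULL, window = 15) {
  if (is.data.frame(time)) {
    vo2 <- time$vo2
    time <- time$time
  }
  if (length(time) != length(vo2)) .stop("time and vo2 lengths differ")
  if (any(diff(time) <= 0)) .stop("breath times must be strictly increasing")
  if (any(vo2 < 0)) .stop("vo2 must be non-negative")
  span <- time[length(time)] - time[1]
  if (span < window) {
    .stop("series spans ", round(span, 3), " s; at least ", window, " s required")
  }
  # cumulative integral of the step function at each breath time
  dt <- diff(time)
  cum <- c(0, cumsum(vo2[-length(vo2)] * dt))
  integral_at <- function(x) {
    # piecewise-linear interpolation of the cumulative integral
    i <- findInterval(x, time)
    cum[i] + vo2[i] * (x - time[i])
  }
  starts <- c(time, time - window)
  starts <- sort(unique(pmin(pmax(starts, time[1]), time[length(time)] - window)))
  means <- (integral_at(starts + window) - integral_at(starts)) / window
  max(means)
}
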