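#' Oxygen-uptake units
#'
#' The three units in which published VO2max prediction equations report
#' their output: relative uptake in mL·min^-1·kg^-1 (`"ml_kg_min"`),
#' absolute uptake in mL·min^-1 (`"ml_min"`) and absolute uptake in
#' L·min^-1 (`"l_min"`).  Conversion between any pair is exact algebra
#' given body mass.
#'
#' @return Character vector of the recognised unit tags.
#' @export
#' @examples
#' vo2_units()
vo2_units <- function() c("ml_kg_min", "ml_min", "l_min")

#' Convert an oxygen-uptake value between units
#'
#' @param value Numeric vector of VO2 values expressed in `from` units.
#' @param from,to Unit tags; see [vo2_units()].
#' @param body_mass Body mass in kg.  Required whenever a relative unit
#'   (`"ml_kg_min"`) is involved; recycled against `value`.
#'
#' @return Numeric vector in `to` units.
#' @export
#' @examples
#' convert_vo2(4000, "ml_min", "l_min")            # 4.0
#' convert_vo2(4000, "ml_min", "ml_kg_min", 80)    # 50
convert_vo2 <- function(value, from, to, body_mass = NULL) {
  from <- match.arg(from, vo2_units())
  to <- match.arg(to, vo2_units())
  if (from == to) return(value)
  needs_mass <- "ml_kg_min" %in% c(from, to)
  if (needs_mass) {
    if (is.null(body_mass)) {
      .stop("body_mass is required to convert between relative and absolute VO2 units")
    }
    if (any(!is.na(body_mass) & body_mass <= 0)) {
      .stop("body_mass must be positive")
    }
  }
  # pivot through mL/min
  abs_ml <- switch(from,
    ml_min    = value,
    l_min     = value * 1000,
    ml_kg_min = value * body_mass
  )
  switch(to,
    ml_min    = abs_ml,
    l_min     = abs_ml / 1000,
    ml_kg_min = abs_ml / body_mass
  )
}

#' Absolute VO2max of a CPET record
#'
#' Records store relative VO2max (mL·min^-1·kg^-1) as the primary value;
#' the absolute uptake is always derived from it and body mass, never
#' stored, so the two can not drift apart.
#'
#' @param cohort A CPET cohort data frame (or any data frame with
#'   `vo2max_rel` and `body_mass` columns).
#' @return Numeric vector, mL·min^-1.
#' @export
derive_absolute_vo2 <- function(cohort) {
  convert_vo2(cohort$vo2max_rel, "ml_kg_min", "ml_min", cohort$body_mass)
}
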