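#' Exposure parameter realization
#'
#' One concrete set of exposure parameters — fixed values or one Monte
#' Carlo draw — for which the chronic daily intake equations are evaluated.
#' All fields accept vectors of a common length, so a realization can carry
#' a whole simulation's draws at once. The averaging time `at` must already
#' be the route-appropriate one (non-cancer or cancer): selecting it is the
#' caller's job, which keeps the intake formulas pure.
#'
#' @param ir Ingestion rate, L/day.
#' @param ef Exposure frequency, days/year (`<= 366`).
#' @param ed Exposure duration, years.
#' @param bw Body weight, kg.
#' @param at Averaging time, days.
#' @param sa Skin surface area, cm^2.
#' @param t_event Exposure duration per event, h/event.
#' @param ev Event frequency, events/day.
#' @param population Optional population tag.
#' @return A `wetrisk_realization` list.
#' @export
exposure_realization <- function(ir, ef, ed, bw, at, sa, t_event, ev,
                                 population = NA_character_) {
  vals <- list(ir = ir, ef = ef, ed = ed, bw = bw, at = at,
               sa = sa, t_event = t_event, ev = ev)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(is.na(v)) || any(v <= 0)) {
      stop_invalid("exposure realization: '%s' must be strictly positive", nm)
    }
  }
  if (any(ef > 366)) stop_invalid("exposure realization: 'ef' cannot exceed 366 days/year")
  structure(c(vals, list(population = population)), class = "wetrisk_realization")
}

#' Collapse an exposure profile to a point realization
#'
#' The deterministic evaluation mode: distribution specs are collapsed via
#' [dist_point()] (normal to its mean, triangular to its mode — so the
#' default exposure frequency collapses to 350 days/year), fixed fields are
#' taken as-is, and the averaging time matching the requested assessment is
#' selected.
#'
#' @param profile A `wetrisk_profile` (an element of `registry$exposure`).
#' @param assessment `"noncancer"` or `"cancer"`; picks the averaging time.
#' @return A `wetrisk_realization`.
#' @examples
#' reg <- default_registry()
#' point_realization(reg$exposure$adults, "cancer")
#' @export
point_realization <- function(profile, assessment = c("noncancer", "cancer")) {
  assessment <- match.arg(assessment)
  stopifnot(inherits(profile, "wetrisk_profile"))
  exposure_realization(
    ir = dist_point(profile$ir),
    ef = dist_point(profile$ef),
    ed = profile$ed,
    bw = dist_point(profile$bw),
    at = if (assessment == "cancer") profile$at_cancer else profile$at_noncancer,
    sa = profile$sa,
    t_event = profile$t_event,
    ev = profile$ev,
    population = profile$population
  )
}

#' Chronic daily intake, oral ingestion route
#'
#' `CDI_ing = C * IR * EF * ED / (BW * AT)`, in ug/kg/d for concentrations
#' in ug/L. Linear in the concentration.
#'
#' @param concentration Concentration in ug/L, `>= 0`.
#' @param realization A [exposure_realization()] (or any list with fields
#'   `ir`, `ef`, `ed`, `bw`, `at`).
#' @return Intake in ug/kg/d.
#' @examples
#' r <- point_realization(default_registry()$exposure$adults, "cancer")
#' cdi_ingestion(4.15, r)  # 0.041175
#' @export
cdi_ingestion <- function(concentration, realization) {
  check_conc(concentration)
  r <- realization
  concentration * r$ir * r$ef * r$ed / (r$bw * r$at)
}

#' Chronic daily intake, dermal contact route
#'
#' `CDI_derm = C * SA * Kp * T_event * EV * EF * ED * 1e-3 / (BW * AT)`,
#' in ug/kg/d. The `1e-3` factor converts the permeated volume from cm^3
#' to L (1 cm^3 = 1e-3 L) so that ug/L concentrations yield ug intakes.
#'
#' @param concentration Concentration in ug/L, `>= 0`.
#' @param kp Dermal permeability coefficient, cm/h, `> 0`.
#' @param realization A [exposure_realization()].
#' @return Intake in ug/kg/d.
#' @export
cdi_dermal <- function(concentration, kp, realization) {
  check_conc(concentration)
  if (!is.numeric(kp) || any(is.na(kp)) || any(kp <= 0)) {
    stop_invalid("'kp' must be strictly positive")
  }
  r <- realization
  concentration * r$sa * kp * r$t_event * r$ev * r$ef * r$ed * 1e-3 / (r$bw * r$at)
}

check_conc <- function(concentration) {
  if (!is.numeric(concentration) || any(is.na(concentration)) || any(concentration < 0)) {
    stop_invalid("'concentration' must be nonnegative")
  }
}
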