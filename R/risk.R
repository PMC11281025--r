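#' Hazard quotient for one metal
#'
#' Non-carcinogenic risk ratio summed over the two exposure routes:
#' `HQ = CDI_ing / RfD_ing + CDI_derm / RfD_derm`. A value above 1 flags a
#' potential non-carcinogenic health risk.
#'
#' @param cdi_ing,cdi_derm Route-specific chronic daily intakes, ug/kg/d.
#' @param rfd_ing,rfd_derm Route-specific reference doses, ug/kg/d, `> 0`.
#' @return Dimensionless hazard quotient.
#' @export
hazard_quotient <- function(cdi_ing, cdi_derm, rfd_ing, rfd_derm) {
  if (any(is.na(rfd_ing)) || any(is.na(rfd_derm)) ||
      any(rfd_ing <= 0) || any(rfd_derm <= 0)) {
    stop_invalid("reference doses must be present and positive; metals without RfDs are excluded upstream")
  }
  cdi_ing / rfd_ing + cdi_derm / rfd_derm
}

#' Total hazard index
#'
#' Sum of the per-metal hazard quotients. Values above 1 indicate a
#' potential non-carcinogenic health risk.
#'
#' @param hq Numeric vector of hazard quotients (one per metal).
#' @return The sum.
#' @export
total_hazard_index <- function(hq) {
  if (length(hq) < 1) stop_invalid("need at least one hazard quotient")
  sum(hq)
}

#' Cancer risk for one metal
#'
#' Incremental lifetime cancer probability from linear slope factors:
#' `CR = CDI_ing * SF_ing + CDI_derm * SF_derm`. Only metals with slope
#' factors for both routes are carcinogenic-assessable; calling this for a
#' metal without slope factors is an error, not an imputation.
#'
#' @param cdi_ing,cdi_derm Route-specific chronic daily intakes (computed
#'   with the cancer averaging time), ug/kg/d.
#' @param sf_ing,sf_derm Route-specific slope factors, (ug/kg/d)^-1, `> 0`.
#' @return Dimensionless cancer risk.
#' @export
cancer_risk <- function(cdi_ing, cdi_derm, sf_ing, sf_derm) {
  if (any(is.na(sf_ing)) || any(is.na(sf_derm)) ||
      any(sf_ing <= 0) || any(sf_derm <= 0)) {
    stop_invalid("slope factors must be present and positive; this metal is not carcinogenic-assessable")
  }
  cdi_ing * sf_ing + cdi_derm * sf_derm
}

#' Total cancer risk
#'
#' @param cr Numeric vector of per-metal cancer risks.
#' @return The sum.
#' @export
total_cancer_risk <- function(cr) {
  if (length(cr) < 1) stop_invalid("need at least one cancer risk")
  sum(cr)
}

#' Percentage contribution of each component to a total
#'
#' @param values Nonnegative per-component values.
#' @param total The total; defaults to `sum(values)`.
#' @return Percentages summing to 100 (or `NA` with a warning when the
#'   total is zero).
#' @export
contribution_shares <- function(values, total = sum(values)) {
  if (any(values < 0)) stop_invalid("'values' must be nonnegative")
  if (total <= 0) {
    warn("total is zero; contribution shares are undefined")
    return(rep(NA_real_, length(values)))
  }
  100 * values / total
}

## Vectorized core shared by the point assessment and the Monte Carlo
## engine: takes per-metal concentration vectors and (possibly vector)
## parameter draws, returns per-metal HQ/CR vectors plus totals. One
## parameter draw is shared across metals, which is what makes the
## downstream sensitivity analysis meaningful.
risk_components <- function(conc, registry, profile, ir, ef, bw) {
  mtbl <- registry$metals
  real_nc <- list(ir = ir, ef = ef, ed = profile$ed, bw = bw,
                  at = profile$at_noncancer, sa = profile$sa,
                  t_event = profile$t_event, ev = profile$ev)
  real_ca <- modifyList(real_nc, list(at = profile$at_cancer))
  hq <- list()
  cr <- list()
  for (i in seq_len(nrow(mtbl))) {
    m <- mtbl[i, ]
    cm <- conc[[m$metal]]
    if (is.null(cm)) stop_invalid("no concentration supplied for metal '%s'", m$metal)
    if (!is.na(m$rfd_ing) && !is.na(m$rfd_derm)) {
      hq[[m$metal]] <- hazard_quotient(
        cdi_ingestion(cm, real_nc), cdi_dermal(cm, m$kp, real_nc),
        m$rfd_ing, m$rfd_derm)
    }
    if (!is.na(m$sf_ing) && !is.na(m$sf_derm)) {
      cr[[m$metal]] <- cancer_risk(
        cdi_ingestion(cm, real_ca), cdi_dermal(cm, m$kp, real_ca),
        m$sf_ing, m$sf_derm)
    }
  }
  list(hq = hq, cr = cr,
       thi = Reduce(`+`, hq), tcr = Reduce(`+`, cr))
}

#' Point-estimate health risk assessment
#'
#' Evaluates the full intake-to-risk chain deterministically: every
#' exposure distribution is collapsed to its point value (mean for normal,
#' mode for triangular — so exposure frequency is 350 days/year) and
#' group-mean concentrations are used. Metals lacking toxicity values for a
#' pathway are skipped and listed in the result.
#'
#' @param concentrations Either a per-sample tibble (averaged to group
#'   means), a tibble with columns `group`, `metal`, `concentration`, or a
#'   named numeric vector of concentrations in ug/L (treated as one group
#'   `"all"`).
#' @param registry A `wetrisk_registry`.
#' @param populations Populations to assess (default: all in the registry).
#' @return A `wetrisk_risk` object: `$by_metal` (tibble `population`,
#'   `group`, `metal`, `concentration`, `hq`, `cr`, `hq_share`, `cr_share`;
#'   shares in percent, `NA` where a pathway does not apply) and `$totals`
#'   (tibble `population`, `group`, `thi`, `thi_class`, `tcr`, `tcr_class`).
#' @examples
#' reg <- default_registry()
#' means <- dplyr::mutate(group_profiles(reg), concentration = mean)
#' assess_risk(means, reg)
#' @export
assess_risk <- function(concentrations, registry = default_registry(),
                        populations = names(registry$exposure)) {
  conc_tbl <- normalize_concentrations(concentrations, registry)
  cr_scheme <- registry$schemes$cancer_risk
  skipped_nc <- setdiff(registry$metals$metal, noncarcinogenic_metals(registry))
  skipped_ca <- setdiff(registry$metals$metal, carcinogenic_metals(registry))

  rows <- list()
  totals <- list()
  for (pop in populations) {
    profile <- registry$exposure[[pop]]
    if (is.null(profile)) stop_invalid("unknown population '%s'", pop)
    ir <- dist_point(profile$ir); ef <- dist_point(profile$ef)
    bw <- dist_point(profile$bw)
    for (grp in unique(conc_tbl$group)) {
      d <- filter(conc_tbl, .data$group == grp)
      conc <- as.list(setNames(d$concentration, d$metal))
      comp <- risk_components(conc, registry, profile, ir, ef, bw)
      hq <- unname(map_dbl(d$metal, ~ comp$hq[[.x]] %||% NA_real_))
      cr <- unname(map_dbl(d$metal, ~ comp$cr[[.x]] %||% NA_real_))
      rows[[paste(pop, grp)]] <- tibble(
        population = pop, group = grp, metal = d$metal,
        concentration = d$concentration, hq = hq, cr = cr,
        hq_share = ifelse(is.na(hq), NA_real_, 100 * hq / comp$thi),
        cr_share = ifelse(is.na(cr), NA_real_, 100 * cr / comp$tcr)
      )
      totals[[paste(pop, grp)]] <- tibble(
        population = pop, group = grp,
        thi = comp$thi,
        thi_class = ifelse(comp$thi > 1, "potential risk", "acceptable"),
        tcr = comp$tcr,
        tcr_class = as.character(classify(comp$tcr, cr_scheme))
      )
    }
  }
  structure(
    list(by_metal = list_rbind(rows), totals = list_rbind(totals),
         skipped = list(noncancer = skipped_nc, cancer = skipped_ca)),
    class = "wetrisk_risk"
  )
}

## Accepts the three concentration input shapes described in assess_risk().
normalize_concentrations <- function(concentrations, registry) {
  metals <- registry$metals$metal
  if (is.numeric(concentrations) && !is.null(names(concentrations))) {
    missing <- setdiff(metals, names(concentrations))
    if (length(missing) > 0) {
      stop_invalid("missing concentration(s) for: %s", paste(missing, collapse = ", "))
    }
    return(tibble(group = "all", metal = metals,
                  concentration = as.numeric(concentrations[metals])))
  }
  if (is.data.frame(concentrations)) {
    if (all(c("metal", "concentration") %in% names(concentrations))) {
      out <- concentrations
      if (!"group" %in% names(out)) out$group <- "all"
      missing <- setdiff(metals, unique(out$metal))
      if (length(missing) > 0) {
        stop_invalid("missing concentration(s) for: %s", paste(missing, collapse = ", "))
      }
      return(select(out, "group", "metal", "concentration"))
    }
    ## per-sample wide table: reduce to group means
    return(samples_long(concentrations, registry) |>
             group_by(.data$group, .data$metal) |>
             summarise(concentration = mean(.data$concentration), .groups = "drop"))
  }
  stop_invalid("'concentrations' must be a named vector or a data frame")
}

#' @export
print.wetrisk_risk <- function(x, ...) {
  cat("<wetrisk point risk assessment>\n")
  if (length(x$skipped$cancer) > 0) {
    cat("  metals without slope factors (skipped for cancer risk):",
        paste(x$skipped$cancer, collapse = ", "), "\n")
  }
  print(x$totals)
  invisible(x)
}

#' @describeIn assess_risk Per-metal hazard quotients and cancer risks as a
#'   tibble.
#' @param x A `wetrisk_risk`.
#' @param ... Unused.
#' @export
tidy.wetrisk_risk <- function(x, ...) x$by_metal

#' @describeIn assess_risk Totals (THI, TCR and their classes) as a tibble.
#' @export
glance.wetrisk_risk <- function(x, ...) x$totals
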