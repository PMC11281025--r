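#' Constant registry: thresholds, toxicity values, exposure parameters
#'
#' The registry bundles every constant the assessment needs: per-metal
#' regulatory thresholds (surface-water Class II limits, `S_i`), analytical
#' detection limits, dermal permeability coefficients (`Kp`), reference
#' doses and cancer slope factors per exposure route, the exposure-parameter
#' profiles for children and adults, the contamination and cancer-risk
#' classification schemes, and the published group-level summary statistics
#' that drive the synthetic sample generator. All values live in a single
#' human-editable YAML file; `default_registry()` loads the copy shipped
#' with the package and `load_registry()` loads a user-edited one, applying
#' the same validation.
#'
#' Units are fixed package-wide: concentrations and thresholds in ug/L,
#' chronic daily intakes and reference doses in ug/kg/d, slope factors in
#' (ug/kg/d)^-1, Kp in cm/h. No automatic unit conversion is performed.
#'
#' @return A `wetrisk_registry`: a list with elements `metals` (tibble, one
#'   row per metal), `exposure` (named list of exposure profiles), `schemes`
#'   (classification schemes), `groups` (sampling-group summary profiles),
#'   `published_indices` (tibble of published group-average single-factor
#'   indices), `ph_range` and `ec_range`.
#' @examples
#' reg <- default_registry()
#' reg$metals
#' @export
default_registry <- function() {
  load_registry(system.file("extdata", "registry.yaml", package = "wetrisk"))
}

#' @rdname default_registry
#' @param path Path to a registry YAML file.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("registry file not found: %s", path), class = "wetrisk_io_error")
  }
  raw <- yaml::read_yaml(path)
  registry_from_list(raw)
}

num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

registry_from_list <- function(raw) {
  for (part in c("metals", "exposure", "schemes")) {
    if (is.null(raw[[part]])) stop_invalid("registry is missing section '%s'", part)
  }
  metals <- imap(raw$metals, function(m, sym) {
    tibble(
      metal = sym,
      class2_threshold = num_or_na(m$class2_threshold),
      detection_limit = num_or_na(m$detection_limit),
      kp = num_or_na(m$kp),
      rfd_ing = num_or_na(m$rfd_ing),
      rfd_derm = num_or_na(m$rfd_derm),
      sf_ing = num_or_na(m$sf_ing),
      sf_derm = num_or_na(m$sf_derm)
    )
  }) |> list_rbind()

  exposure <- imap(raw$exposure, function(p, pop) {
    prof <- list(
      population = pop,
      ir = do.call(dist_spec, p$ir),
      ef = do.call(dist_spec, p$ef),
      ed = as.numeric(p$ed),
      bw = do.call(dist_spec, p$bw),
      at_noncancer = as.numeric(p$at_noncancer),
      at_cancer = as.numeric(p$at_cancer),
      sa = as.numeric(p$sa),
      t_event = as.numeric(p$t_event),
      ev = as.numeric(p$ev)
    )
    structure(prof, class = "wetrisk_profile")
  })

  schemes <- imap(raw$schemes, function(s, nm) {
    new_scheme(nm, cuts = as.numeric(s$cuts), labels = as.character(s$labels),
               boundary = s$boundary)
  })

  groups <- imap(raw$groups %||% list(), function(g, nm) {
    list(
      group = nm,
      n_samples = as.integer(g$n_samples),
      stats = imap(g$stats, function(st, sym) {
        tibble(metal = sym, mean = as.numeric(st$mean), sd = as.numeric(st$sd),
               min = as.numeric(st$min), max = as.numeric(st$max))
      }) |> list_rbind()
    )
  })

  published <- imap(raw$published_indices %||% list(), function(p, grp) {
    tibble(group = grp, metal = names(p), p_i = as.numeric(unlist(p)))
  }) |> list_rbind()

  reg <- structure(
    list(
      metals = metals,
      exposure = exposure,
      schemes = schemes,
      groups = groups,
      published_indices = published,
      ph_range = as.numeric(raw$ph_range %||% c(NA, NA)),
      ec_range = as.numeric(raw$ec_range %||% c(NA, NA))
    ),
    class = "wetrisk_registry"
  )
  validate_registry(reg)
}

validate_registry <- function(reg) {
  m <- reg$metals
  for (col in c("class2_threshold", "detection_limit", "kp")) {
    bad <- is.na(m[[col]]) | m[[col]] <= 0
    if (any(bad)) {
      stop_invalid("metal '%s': field '%s' must be a positive number",
                   m$metal[bad][1], col)
    }
  }
  for (col in c("rfd_ing", "rfd_derm", "sf_ing", "sf_derm")) {
    bad <- !is.na(m[[col]]) & m[[col]] <= 0
    if (any(bad)) {
      stop_invalid("metal '%s': field '%s' must be positive when present",
                   m$metal[bad][1], col)
    }
  }
  for (prof in reg$exposure) {
    for (fld in c("ed", "at_noncancer", "at_cancer", "sa", "t_event", "ev")) {
      v <- prof[[fld]]
      if (!is.numeric(v) || is.na(v) || v <= 0) {
        stop_invalid("exposure profile '%s': field '%s' must be a positive number",
                     prof$population, fld)
      }
    }
  }
  for (g in reg$groups) {
    st <- g$stats
    if (g$n_samples < 2) stop_invalid("group '%s': n_samples must be >= 2", g$group)
    bad <- !(st$min <= st$mean & st$mean <= st$max) | st$sd < 0
    if (any(bad)) {
      stop_invalid("group '%s', metal '%s': requires min <= mean <= max and sd >= 0",
                   g$group, st$metal[bad][1])
    }
  }
  reg
}

#' Write a registry back to YAML
#'
#' Round-trips through [load_registry()]: re-reading the written file
#' reproduces every constant exactly.
#'
#' @param registry A `wetrisk_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "wetrisk_registry"))
  dist_to_list <- function(d) {
    out <- d[setdiff(names(d), "lower")]
    if (!is.null(d$lower)) out$lower <- d$lower
    class(out) <- NULL
    out
  }
  metals <- registry$metals
  raw <- list(
    metals = setNames(lapply(seq_len(nrow(metals)), function(i) {
      row <- as.list(metals[i, -1])
      lapply(row, function(v) if (is.na(v)) NULL else v)
    }), metals$metal),
    exposure = lapply(registry$exposure, function(p) {
      list(ir = dist_to_list(p$ir), ef = dist_to_list(p$ef), ed = p$ed,
           bw = dist_to_list(p$bw), at_noncancer = p$at_noncancer,
           at_cancer = p$at_cancer, sa = p$sa, t_event = p$t_event, ev = p$ev)
    }),
    schemes = lapply(registry$schemes, function(s) {
      list(cuts = s$cuts, labels = s$labels, boundary = s$boundary)
    }),
    groups = lapply(registry$groups, function(g) {
      list(n_samples = g$n_samples,
           stats = setNames(lapply(seq_len(nrow(g$stats)), function(i) {
             as.list(g$stats[i, -1])
           }), g$stats$metal))
    }),
    published_indices = {
      pub <- registry$published_indices
      if (nrow(pub) == 0) NULL
      else lapply(setNames(nm = unique(pub$group)), function(g) {
        as.list(setNames(pub$p_i[pub$group == g], pub$metal[pub$group == g]))
      })
    },
    ph_range = registry$ph_range,
    ec_range = registry$ec_range
  )
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' @export
print.wetrisk_registry <- function(x, ...) {
  cat("<wetrisk registry>\n")
  cat("  metals:", paste(x$metals$metal, collapse = ", "), "\n")
  cat("  carcinogenic-assessable:", paste(carcinogenic_metals(x), collapse = ", "), "\n")
  cat("  populations:", paste(names(x$exposure), collapse = ", "), "\n")
  cat("  groups:", paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Metals assessable for each risk pathway
#'
#' A metal is carcinogenic-assessable when slope factors are defined for
#' both exposure routes, and non-carcinogenic-assessable when reference
#' doses are defined for both routes. Metals lacking toxicity values for a
#' pathway are skipped by that pathway, never imputed.
#'
#' @param registry A `wetrisk_registry`.
#' @return A character vector of metal symbols.
#' @export
carcinogenic_metals <- function(registry) {
  m <- registry$metals
  m$metal[!is.na(m$sf_ing) & !is.na(m$sf_derm)]
}

#' @rdname carcinogenic_metals
#' @export
noncarcinogenic_metals <- function(registry) {
  m <- registry$metals
  m$metal[!is.na(m$rfd_ing) & !is.na(m$rfd_derm)]
}

#' Group summary profiles as a tidy tibble
#'
#' @param registry A `wetrisk_registry`.
#' @return A tibble with one row per group and metal: `group`, `n_samples`,
#'   `metal`, `mean`, `sd`, `min`, `max` (concentrations in ug/L).
#' @export
group_profiles <- function(registry) {
  map(registry$groups, function(g) {
    mutate(g$stats, group = g$group, n_samples = g$n_samples,
           .before = 1)
  }) |> list_rbind()
}

#' Published group-average single-factor pollution indices
#'
#' The study's reported group-average `P_i` values, shipped for validation
#' and reporting. These were computed by the original authors from the raw
#' per-sample data (unavailable), so they differ in the second decimal from
#' indices recomputed from the rounded group-mean concentrations.
#'
#' @param registry A `wetrisk_registry`.
#' @return A tibble `group`, `metal`, `p_i`.
#' @export
published_pollution_indices <- function(registry) {
  registry$published_indices
}

## ---- classification schemes -------------------------------------------

new_scheme <- function(name, cuts, labels, boundary = c("lower", "upper")) {
  boundary <- match.arg(boundary)
  if (length(labels) != length(cuts) + 1) {
    stop_invalid("scheme '%s': needs one more label than cut points", name)
  }
  if (is.unsorted(cuts, strictly = TRUE)) {
    stop_invalid("scheme '%s': cut points must be strictly increasing", name)
  }
  structure(list(name = name, cuts = cuts, labels = labels, boundary = boundary),
            class = "wetrisk_scheme")
}

#' @export
print.wetrisk_scheme <- function(x, ...) {
  cat("<scheme ", x$name, ": ", paste(x$labels, collapse = " | "),
      " at cuts ", paste(format(x$cuts), collapse = ", "),
      " (", x$boundary, "-closed)>\n", sep = "")
  invisible(x)
}

#' Classify values against a severity scheme
#'
#' Maps each nonnegative value to the unique severity label whose interval
#' contains it. The contamination scheme closes intervals on the right (a
#' value exactly on a cut joins the less severe class); the cancer-risk
#' scheme uses half-open `[cut, next)` intervals (a value on a cut joins
#' the more severe class). Labels are returned as an ordered factor so that
#' severity comparisons are meaningful.
#'
#' @param value Numeric vector, all `>= 0`.
#' @param scheme A `wetrisk_scheme` (an element of `registry$schemes`).
#' @return An ordered factor of labels, same length as `value`.
#' @examples
#' reg <- default_registry()
#' classify(c(0.5, 2.31, 3.58), reg$schemes$contamination)
#' classify(5e-5, reg$schemes$cancer_risk)
#' @export
classify <- function(value, scheme) {
  stopifnot(inherits(scheme, "wetrisk_scheme"))
  if (!is.numeric(value) || anyNA(value)) stop_invalid("'value' must be numeric, no NA")
  if (any(value < 0)) stop_invalid("cannot classify negative values")
  idx <- if (scheme$boundary == "lower") {
    rowSums(outer(value, scheme$cuts, `>`))
  } else {
    rowSums(outer(value, scheme$cuts, `>=`))
  }
  factor(scheme$labels[idx + 1L], levels = scheme$labels, ordered = TRUE)
}
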