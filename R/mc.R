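#' Draw one set of exposure-parameter realizations
#'
#' Samples the uncertain exposure parameters of a profile: ingestion rate
#' and body weight from their normal specifications truncated below at a
#' positive floor (1% of the mean), and exposure frequency from its
#' triangular specification. Exposure duration, skin surface area, event
#' time and event frequency are fixed at their point values.
#'
#' @param profile A `wetrisk_profile`.
#' @param n Number of draws.
#' @param assessment Which averaging time to attach (`"noncancer"` or
#'   `"cancer"`).
#' @param fix_ef Hold exposure frequency at its point value (the triangular
#'   mode, 350 days/year by default) instead of sampling it.
#' @return A `wetrisk_realization` whose `ir`, `ef`, `bw` fields are
#'   vectors of length `n`.
#' @export
sample_realization <- function(profile, n = 1,
                               assessment = c("noncancer", "cancer"),
                               fix_ef = FALSE) {
  assessment <- match.arg(assessment)
  stopifnot(inherits(profile, "wetrisk_profile"))
  d <- draw_parameters(profile, n, fix_ef = fix_ef)
  exposure_realization(
    ir = d$ir, ef = d$ef, ed = rep(profile$ed, n), bw = d$bw,
    at = rep(if (assessment == "cancer") profile$at_cancer else profile$at_noncancer, n),
    sa = rep(profile$sa, n), t_event = rep(profile$t_event, n),
    ev = rep(profile$ev, n), population = profile$population
  )
}

## IR and BW get a truncation floor at 1% of their point value so draws
## stay strictly positive; EF's triangular support already lies in
## (0, 366].
draw_parameters <- function(profile, n, fix_ef = FALSE) {
  floor_spec <- function(spec) {
    if (spec$family %in% c("normal", "lognormal") && is.null(spec$lower)) {
      spec$lower <- 0.01 * dist_point(spec)
    }
    spec
  }
  list(
    ir = dist_sample(floor_spec(profile$ir), n),
    ef = if (fix_ef) rep(dist_point(profile$ef), n) else dist_sample(profile$ef, n),
    bw = dist_sample(floor_spec(profile$bw), n)
  )
}

#' Monte Carlo propagation of exposure and concentration uncertainty
#'
#' Repeatedly samples the uncertain inputs — one exposure-parameter
#' realization per population and one concentration vector per group, per
#' iteration — and evaluates the full intake-to-risk chain for each draw,
#' yielding probability distributions for per-metal hazard quotients and
#' cancer risks, the total hazard index and the total cancer risk.
#'
#' Concentrations enter in one of three modes:
#' * `"distribution"` (default): each metal drawn independently from a
#'   lognormal moment-fitted to the group's summary statistics, truncated
#'   below at its detection limit;
#' * `"empirical"`: whole sample rows resampled with replacement from a
#'   supplied per-sample table (preserves inter-metal correlation);
#' * `"fixed"`: concentrations held at the group means.
#'
#' Randomness is fully seeded; each population's parameter stream and each
#' group's concentration stream is derived deterministically from `seed`,
#' so adding a group or population never perturbs the others' draws, and
#' reruns with an identical configuration reproduce every draw exactly.
#' Within an iteration the same parameter realization is shared across all
#' metals (one simulated person), which is what makes the sensitivity
#' analysis meaningful.
#'
#' @param registry A `wetrisk_registry`.
#' @param groups Sampling groups to simulate.
#' @param populations Populations to simulate.
#' @param n_iterations Number of Monte Carlo iterations (>= 100; default
#'   10000).
#' @param seed Integer seed; required.
#' @param concentration_mode See above.
#' @param samples Per-sample table, required for `"empirical"` mode.
#' @param fix_ef Hold exposure frequency at its point value in every
#'   iteration.
#' @return A `wetrisk_mc` object: `$draws` (one row per group, population
#'   and iteration with the sampled inputs `ir`, `ef`, `bw`,
#'   `conc_<metal>` and outputs `hq_<metal>`, `cr_<metal>`, `thi`, `tcr`),
#'   `$summary` (mean, sd and the 1/5/25/50/75/95/99 percentiles of every
#'   output), and `$config` (the echoed configuration, including the
#'   seed).
#' @examples
#' mc <- run_mc(default_registry(), groups = "rural",
#'              populations = "adults", n_iterations = 500, seed = 1)
#' dplyr::filter(mc$summary, output == "tcr")
#' @export
run_mc <- function(registry = default_registry(),
                   groups = names(registry$groups),
                   populations = names(registry$exposure),
                   n_iterations = 10000,
                   seed,
                   concentration_mode = c("distribution", "empirical", "fixed"),
                   samples = NULL,
                   fix_ef = FALSE) {
  concentration_mode <- match.arg(concentration_mode)
  if (missing(seed) || is.null(seed)) {
    stop_invalid("'seed' is required: Monte Carlo runs must be reproducible")
  }
  if (n_iterations < 100) stop_invalid("'n_iterations' must be >= 100")
  if (concentration_mode == "empirical" && is.null(samples)) {
    stop_invalid("empirical concentration mode requires a 'samples' table")
  }
  n <- as.integer(n_iterations)
  dl <- setNames(registry$metals$detection_limit, registry$metals$metal)
  metals <- registry$metals$metal

  params <- map(setNames(populations, populations), function(pop) {
    profile <- registry$exposure[[pop]]
    if (is.null(profile)) stop_invalid("unknown population '%s'", pop)
    withr_seed(stream_seed(seed, paste0("mc/params/", pop)))
    draw_parameters(profile, n, fix_ef = fix_ef)
  })

  conc <- map(setNames(groups, groups), function(grp) {
    g <- registry$groups[[grp]]
    if (is.null(g) && concentration_mode != "empirical") {
      stop_invalid("unknown group '%s'", grp)
    }
    withr_seed(stream_seed(seed, paste0("mc/conc/", grp)))
    switch(concentration_mode,
      distribution = map(setNames(metals, metals), function(sym) {
        st <- g$stats[g$stats$metal == sym, ]
        dist_sample(fit_lognormal_moments(st$mean, st$sd, lower = dl[[sym]]), n)
      }),
      fixed = map(setNames(metals, metals), function(sym) {
        rep(g$stats$mean[g$stats$metal == sym], n)
      }),
      empirical = {
        d <- filter(samples, .data$group == grp)
        if (nrow(d) == 0) stop_invalid("no samples for group '%s'", grp)
        idx <- sample.int(nrow(d), n, replace = TRUE)
        map(setNames(metals, metals), function(sym) d[[sym]][idx])
      })
  })

  draws <- list()
  for (grp in groups) {
    for (pop in populations) {
      profile <- registry$exposure[[pop]]
      p <- params[[pop]]
      comp <- risk_components(conc[[grp]], registry, profile, p$ir, p$ef, p$bw)
      row <- tibble(
        group = grp, population = pop, iteration = seq_len(n),
        ir = p$ir, ef = p$ef, bw = p$bw
      )
      for (sym in metals) row[[paste0("conc_", sym)]] <- conc[[grp]][[sym]]
      for (sym in names(comp$hq)) row[[paste0("hq_", sym)]] <- comp$hq[[sym]]
      for (sym in names(comp$cr)) row[[paste0("cr_", sym)]] <- comp$cr[[sym]]
      row$thi <- comp$thi
      row$tcr <- comp$tcr
      draws[[paste(grp, pop)]] <- row
    }
  }
  draws <- list_rbind(draws)

  config <- list(
    n_iterations = n, seed = seed, concentration_mode = concentration_mode,
    groups = groups, populations = populations, fix_ef = fix_ef,
    generated_at = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  structure(list(draws = draws, summary = summarize_mc(draws), config = config),
            class = "wetrisk_mc")
}

mc_output_cols <- function(draws) {
  grep("^(hq_|cr_)|^(thi|tcr)$", names(draws), value = TRUE)
}

summarize_mc <- function(draws) {
  probs <- c(1, 5, 25, 50, 75, 95, 99) / 100
  draws |>
    pivot_longer(all_of(mc_output_cols(draws)),
                 names_to = "output", values_to = "value") |>
    group_by(.data$group, .data$population, .data$output) |>
    summarise(
      mean = mean(.data$value), sd = sd(.data$value),
      !!!setNames(
        map(probs, function(p) rlang::expr(quantile(.data$value, !!p, names = FALSE))),
        paste0("p", probs * 100)),
      .groups = "drop"
    )
}

#' @export
print.wetrisk_mc <- function(x, ...) {
  cfg <- x$config
  cat("<wetrisk Monte Carlo run>\n")
  cat("  iterations:", cfg$n_iterations, " seed:", cfg$seed,
      " concentrations:", cfg$concentration_mode,
      if (cfg$fix_ef) " (EF fixed)", "\n")
  print(filter(x$summary, .data$output %in% c("thi", "tcr")))
  invisible(x)
}

#' @describeIn run_mc Summary statistics (mean, sd, percentiles) of every
#'   simulated output as a tibble.
#' @param x A `wetrisk_mc`.
#' @param ... Unused.
#' @export
tidy.wetrisk_mc <- function(x, ...) x$summary

#' @describeIn run_mc One-row tibble echoing the run configuration.
#' @export
glance.wetrisk_mc <- function(x, ...) {
  cfg <- x$config
  tibble(
    n_iterations = cfg$n_iterations, seed = cfg$seed,
    concentration_mode = cfg$concentration_mode, fix_ef = cfg$fix_ef,
    groups = paste(cfg$groups, collapse = ","),
    populations = paste(cfg$populations, collapse = ",")
  )
}

#' Exceedance probability and cumulative frequency
#'
#' `exceedance_probability()` is the fraction of draws strictly greater
#' than `threshold`; `cumulative_frequency()` is its complement, the
#' fraction of draws less than or equal to `value` (the height of the
#' empirical CDF). Both return fractions in `[0, 1]`.
#'
#' @param draws Numeric vector of simulated output values.
#' @param threshold,value The risk threshold / evaluation point.
#' @return A fraction in `[0, 1]`.
#' @examples
#' exceedance_probability(c(0.5, 1.5, 2.5, 3.5), 1)  # 0.75
#' @export
exceedance_probability <- function(draws, threshold) {
  if (length(draws) < 1) stop_invalid("'draws' must be non-empty")
  mean(draws > threshold)
}

#' @rdname exceedance_probability
#' @export
cumulative_frequency <- function(draws, value) {
  if (length(draws) < 1) stop_invalid("'draws' must be non-empty")
  mean(draws <= value)
}

#' @export
autoplot.wetrisk_mc <- function(object, output = "thi",
                                type = c("histogram", "cdf"), ...) {
  type <- match.arg(type)
  if (!output %in% mc_output_cols(object$draws)) {
    stop_invalid("unknown output '%s'", output)
  }
  d <- object$draws
  d$value <- d[[output]]
  base <- ggplot(d, aes(x = .data$value,
                        colour = interaction(.data$group, .data$population, sep = " / "))) +
    labs(x = toupper(output), colour = NULL,
         title = sprintf("Monte Carlo distribution of %s", toupper(output))) +
    theme_minimal()
  if (type == "histogram") {
    base + geom_freqpoly(bins = 60)
  } else {
    base + stat_ecdf() + labs(y = "cumulative frequency")
  }
}
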