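#' Distribution specifications for uncertain quantities
#'
#' Every uncertain input of the assessment (ingestion rate, exposure
#' frequency, body weight, metal concentrations) is described by a small
#' distribution specification that can be sampled, collapsed to a point
#' value, or queried for its analytic mean. Five families are supported:
#'
#' * `point`: a degenerate value (`value`);
#' * `normal`: `mean`, `sd`;
#' * `triangular`: `min`, `mode`, `max`;
#' * `lognormal`: `mean`, `sd` *on the natural (arithmetic) scale* — the
#'   log-scale parameters are derived by moment inversion;
#' * `empirical`: a vector of `values` resampled with replacement.
#'
#' An optional `lower` truncation bound guarantees that every sampled value
#' is at least `lower` (used for detection-limit floors and to keep body
#' weight and ingestion rate positive).
#'
#' @param family One of `"point"`, `"normal"`, `"triangular"`,
#'   `"lognormal"`, `"empirical"`.
#' @param ... Family-specific parameters, see above.
#' @param lower Optional lower truncation bound.
#' @return An object of class `wetrisk_dist`.
#' @examples
#' ef <- dist_spec("triangular", min = 180, mode = 350, max = 360)
#' dist_mean(ef)   # (180 + 350 + 360) / 3
#' dist_point(ef)  # the mode, 350
#' @export
dist_spec <- function(family = c("point", "normal", "triangular", "lognormal", "empirical"),
                      ..., lower = NULL) {
  family <- match.arg(family)
  p <- list(...)
  need <- function(nms) {
    missing <- setdiff(nms, names(p))
    if (length(missing) > 0) {
      stop_invalid("distribution '%s' requires parameter(s): %s",
                   family, paste(missing, collapse = ", "))
    }
    for (nm in nms) {
      if (!is.numeric(p[[nm]]) || anyNA(p[[nm]])) {
        stop_invalid("distribution '%s': parameter '%s' must be numeric", family, nm)
      }
    }
  }
  switch(family,
    point = {
      need("value")
    },
    normal = {
      need(c("mean", "sd"))
      if (p$sd < 0) stop_invalid("normal distribution: 'sd' must be >= 0")
    },
    triangular = {
      need(c("min", "mode", "max"))
      if (!(p$min <= p$mode && p$mode <= p$max)) {
        stop_invalid("triangular distribution requires min <= mode <= max")
      }
      if (p$min >= p$max) stop_invalid("triangular distribution requires min < max")
    },
    lognormal = {
      need(c("mean", "sd"))
      if (p$mean <= 0) stop_invalid("lognormal distribution: 'mean' must be > 0")
      if (p$sd < 0) stop_invalid("lognormal distribution: 'sd' must be >= 0")
    },
    empirical = {
      need("values")
      if (length(p$values) < 1) stop_invalid("empirical distribution needs >= 1 value")
    }
  )
  if (!is.null(lower) && (!is.numeric(lower) || length(lower) != 1)) {
    stop_invalid("'lower' must be a single number")
  }
  structure(c(list(family = family), p, list(lower = lower)),
            class = "wetrisk_dist")
}

#' @export
print.wetrisk_dist <- function(x, ...) {
  pars <- x[setdiff(names(x), c("family", "lower"))]
  cat("<dist ", x$family, "(",
      paste(names(pars), unlist(pars, use.names = FALSE), sep = "=", collapse = ", "),
      ")", if (!is.null(x$lower)) paste0(", lower=", x$lower), ">\n", sep = "")
  invisible(x)
}

## Log-scale parameters of the lognormal with given arithmetic mean and sd.
lnorm_params <- function(mean, sd) {
  sigma2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Fit a lognormal distribution by its first two moments
#'
#' Inverts the lognormal moment equations so that the returned
#' distribution's arithmetic mean and standard deviation equal the inputs:
#' `sigma^2 = log(1 + (sd/mean)^2)`, `mu = log(mean) - sigma^2/2`.
#' A zero `sd` collapses to a point mass at `mean`.
#'
#' @param mean Arithmetic mean (must be > 0).
#' @param sd Arithmetic standard deviation (>= 0).
#' @param lower Optional lower truncation bound for sampling.
#' @return A `wetrisk_dist` of family `"lognormal"` (or `"point"` when
#'   `sd = 0`).
#' @examples
#' fit_lognormal_moments(0.16, 0.21)
#' @export
fit_lognormal_moments <- function(mean, sd, lower = NULL) {
  if (!is.numeric(mean) || mean <= 0) stop_invalid("'mean' must be > 0")
  if (!is.numeric(sd) || sd < 0) stop_invalid("'sd' must be >= 0")
  if (sd == 0) return(dist_spec("point", value = mean, lower = lower))
  dist_spec("lognormal", mean = mean, sd = sd, lower = lower)
}

## Inverse-CDF sampler for the triangular distribution.
rtriangular <- function(n, min, mode, max, u = runif(n)) {
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

ptriangular <- function(q, min, mode, max) {
  ifelse(q <= min, 0,
  ifelse(q >= max, 1,
  ifelse(q < mode,
         (q - min)^2 / ((max - min) * (mode - min)),
         1 - (max - q)^2 / ((max - min) * (max - mode)))))
}

#' Sample from a distribution specification
#'
#' Truncation (when the spec has a `lower` bound) is applied by inverse-CDF
#' restriction for the normal, lognormal and triangular families, so no
#' rejection loop is needed and draws remain a deterministic function of the
#' RNG stream.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return A numeric vector of length `n`; every value `>= spec$lower` when
#'   a bound is set.
#' @export
dist_sample <- function(spec, n) {
  stopifnot(inherits(spec, "wetrisk_dist"))
  lo <- spec$lower
  x <- switch(spec$family,
    point = rep(spec$value, n),
    normal = {
      if (spec$sd == 0) rep(spec$mean, n)
      else if (is.null(lo)) rnorm(n, spec$mean, spec$sd)
      else qnorm(runif(n, pnorm(lo, spec$mean, spec$sd), 1), spec$mean, spec$sd)
    },
    triangular = {
      if (is.null(lo)) rtriangular(n, spec$min, spec$mode, spec$max)
      else rtriangular(n, spec$min, spec$mode, spec$max,
                       u = runif(n, ptriangular(lo, spec$min, spec$mode, spec$max), 1))
    },
    lognormal = {
      lp <- lnorm_params(spec$mean, spec$sd)
      if (is.null(lo) || lo <= 0) rlnorm(n, lp$meanlog, lp$sdlog)
      else qlnorm(runif(n, plnorm(lo, lp$meanlog, lp$sdlog), 1), lp$meanlog, lp$sdlog)
    },
    empirical = sample(spec$values, n, replace = TRUE)
  )
  if (!is.null(lo)) x <- pmax(x, lo)
  x
}

#' Collapse a distribution specification to its point value
#'
#' The point collapse used by the deterministic evaluation mode: the mean
#' for normal and lognormal specs, the mode for triangular specs, the value
#' itself for point specs, and the arithmetic mean for empirical specs.
#'
#' @param spec A [dist_spec()].
#' @return A single number.
#' @export
dist_point <- function(spec) {
  stopifnot(inherits(spec, "wetrisk_dist"))
  switch(spec$family,
    point = spec$value,
    normal = spec$mean,
    triangular = spec$mode,
    lognormal = spec$mean,
    empirical = mean(spec$values)
  )
}

#' Analytic mean of a distribution specification
#'
#' Unlike [dist_point()], the triangular family returns its true mean
#' `(min + mode + max) / 3`. Truncation bounds are ignored (the bounds used
#' in this package cut off negligible mass; see the methods vignette).
#'
#' @param spec A [dist_spec()].
#' @return A single number.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "wetrisk_dist"))
  switch(spec$family,
    triangular = (spec$min + spec$mode + spec$max) / 3,
    dist_point(spec)
  )
}
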