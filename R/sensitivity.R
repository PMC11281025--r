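#' Spearman rank correlation between two draw vectors
#'
#' Rank correlation with average ranks for ties. A zero-variance input
#' yields an undefined correlation, reported as 0 with a warning so that
#' degenerate (fixed) inputs drop out of the sensitivity ranking instead
#' of poisoning it.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return A correlation in `[-1, 1]`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("'x' and 'y' must have equal length")
  if (length(x) < 3) stop_invalid("need at least 3 draws")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero-variance input: rank correlation undefined, reported as 0")
    return(0)
  }
  cor(x, y, method = "spearman")
}

#' Contribution-to-variance of each input to an output
#'
#' The sensitivity statistic popularized by spreadsheet risk simulators:
#' each input's signed, normalized squared rank correlation with the
#' output, `contribution_k = sign(rho_k) * 100 * rho_k^2 / sum_j rho_j^2`,
#' where `rho` are Spearman correlations over the Monte Carlo draws. The
#' absolute contributions sum to 100%; the sign carries the direction of
#' association (body weight, which divides the dose, comes out negative).
#' Because ranks are invariant under strictly monotone transforms, so are
#' the contributions.
#'
#' @param inputs A data frame (or named list of equal-length vectors) of
#'   input draws.
#' @param output Numeric vector of output draws.
#' @return A tibble `input`, `rank_correlation`, `contribution_pct`,
#'   ordered by absolute contribution.
#' @examples
#' set.seed(1)
#' x <- data.frame(a = rnorm(1000), b = rnorm(1000))
#' contributions(x, x$a + x$b)  # roughly +50% / +50%
#' @export
contributions <- function(inputs, output) {
  inputs <- as_tibble(inputs)
  if (ncol(inputs) < 1) stop_invalid("need at least one input")
  rho <- map_dbl(inputs, function(x) {
    if (sd(x) == 0) 0 else cor(x, output, method = "spearman")
  })
  if (all(rho == 0)) {
    stop_invalid("output insensitive to all inputs: all rank correlations are zero")
  }
  out <- tibble(
    input = names(rho),
    rank_correlation = unname(rho),
    contribution_pct = unname(sign(rho) * 100 * rho^2 / sum(rho^2))
  )
  arrange(out, dplyr::desc(abs(.data$contribution_pct)))
}

#' Sensitivity analysis of a Monte Carlo run
#'
#' Ranks the drivers of the total hazard index and the total cancer risk
#' by contribution-to-variance (see [contributions()]). The inputs are the
#' sampled exposure parameters (`ir`, `ef`, `bw`) and the per-metal
#' concentration draws of the metals that actually enter the output: all
#' assessable metals for the hazard index, the carcinogenic-assessable
#' metals for the cancer risk. Inputs with zero variance (e.g. fixed
#' concentrations) are reported with zero contribution.
#'
#' @param mc A `wetrisk_mc` from [run_mc()].
#' @param outputs Which aggregate outputs to analyse (`"thi"`, `"tcr"`).
#' @param registry The registry used for the run (identifies the
#'   carcinogenic metals).
#' @return A `wetrisk_sensitivity` tibble: `group`, `population`,
#'   `output`, `input`, `rank_correlation`, `contribution_pct`, with the
#'   method recorded in the `"method"` attribute.
#' @export
mc_sensitivity <- function(mc, outputs = c("thi", "tcr"),
                           registry = default_registry()) {
  stopifnot(inherits(mc, "wetrisk_mc"))
  outputs <- match.arg(outputs, several.ok = TRUE)
  metals_for <- list(
    thi = noncarcinogenic_metals(registry),
    tcr = carcinogenic_metals(registry)
  )
  res <- list()
  combos <- distinct(mc$draws, .data$group, .data$population)
  for (i in seq_len(nrow(combos))) {
    d <- filter(mc$draws, .data$group == combos$group[i],
                .data$population == combos$population[i])
    for (out in outputs) {
      cols <- c("ir", "ef", "bw", paste0("conc_", metals_for[[out]]))
      inp <- select(d, all_of(cols)) |>
        rename_with(~ sub("^conc_", "", .x))
      res[[paste(i, out)]] <- contributions(inp, d[[out]]) |>
        mutate(group = combos$group[i], population = combos$population[i],
               output = out, .before = 1)
    }
  }
  structure(list_rbind(res),
            method = "contribution to variance (signed normalized squared Spearman correlation)",
            class = c("wetrisk_sensitivity", "tbl_df", "tbl", "data.frame"))
}

#' @export
autoplot.wetrisk_sensitivity <- function(object, output = "tcr", ...) {
  d <- filter(as_tibble(object), .data$output == !!output) |>
    mutate(input = stats::reorder(.data$input, abs(.data$contribution_pct)))
  ggplot(d, aes(x = .data$contribution_pct, y = .data$input,
                fill = .data$contribution_pct > 0)) +
    geom_col(show.legend = FALSE) +
    facet_grid(group ~ population) +
    labs(x = "contribution to variance (%)", y = NULL,
         title = sprintf("Sensitivity of %s", toupper(output))) +
    theme_minimal()
}
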