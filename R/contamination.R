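#' Single-factor pollution index
#'
#' The per-metal contamination measure `P_i = C_i / S_i`: the measured
#' concentration divided by the regulatory evaluation threshold (here the
#' surface-water Class II limit).
#'
#' @param concentration Concentration(s) in ug/L, `>= 0`.
#' @param threshold Evaluation threshold(s) in ug/L, `> 0`.
#' @return Dimensionless index, same length as the inputs.
#' @examples
#' single_pollution_index(0.88, 0.05)  # 17.6
#' @export
single_pollution_index <- function(concentration, threshold) {
  if (!is.numeric(concentration) || any(is.na(concentration)) || any(concentration < 0)) {
    stop_invalid("'concentration' must be nonnegative")
  }
  if (!is.numeric(threshold) || any(is.na(threshold)) || any(threshold <= 0)) {
    stop_invalid("'threshold' must be strictly positive")
  }
  concentration / threshold
}

#' Nemerow composite pollution index
#'
#' Combines the single-factor indices of all metals into one index that
#' emphasizes the worst pollutant:
#' `NPI = sqrt((P_max^2 + P_ave^2) / 2)`, with `P_max` the maximum and
#' `P_ave` the arithmetic mean of the per-metal indices. Algebraically
#' `P_ave <= NPI <= P_max`.
#'
#' @param p Numeric vector of single-factor indices, all `>= 0`, length
#'   `>= 1`.
#' @return A single dimensionless index.
#' @examples
#' nemerow_index(c(3.21, 0.05, 0.04, 0.09, 0.12, 0.02))  # 2.3076
#' @export
nemerow_index <- function(p) {
  if (length(p) < 1) stop_invalid("'p' must contain at least one index")
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0)) {
    stop_invalid("'p' must be nonnegative with no NA")
  }
  sqrt((max(p)^2 + mean(p)^2) / 2)
}

#' Assess contamination of a sample set
#'
#' Computes per-sample and per-group single-factor indices and Nemerow
#' composite indices, with contamination classes attached from the
#' registry's classification scheme. Group-level indices are computed from
#' the group-mean concentrations (equivalently, the mean of the per-sample
#' `P_i`, by linearity); set `group_method = "mean_of_sample_npi"` to
#' instead average the per-sample composite indices.
#'
#' @param samples A sample tibble (columns `sample_id`, `group`, one per
#'   metal).
#' @param registry A `wetrisk_registry`.
#' @param group_method How the group-level composite index is formed:
#'   `"mean_concentration"` (default) evaluates the composite on the
#'   group-average single-factor indices; `"mean_of_sample_npi"` averages
#'   the per-sample composite indices.
#' @return A `wetrisk_contamination` object: list of tibbles
#'   `sample_indices` (`sample_id`, `group`, `metal`, `concentration`,
#'   `p_i`, `class`), `sample_npi` (`sample_id`, `group`, `p_max`, `p_ave`,
#'   `npi`, `class`), `group_indices` and `group_npi` (same shapes keyed by
#'   `group`). Indices are kept at full precision; round only for display.
#' @examples
#' reg <- default_registry()
#' s <- generate_samples(reg, seed = 1)
#' res <- assess_contamination(s, reg)
#' res$group_npi
#' @export
assess_contamination <- function(samples, registry = default_registry(),
                                 group_method = c("mean_concentration",
                                                  "mean_of_sample_npi")) {
  group_method <- match.arg(group_method)
  scheme <- registry$schemes$contamination
  long <- samples_long(samples, registry) |>
    left_join(select(registry$metals, "metal", "class2_threshold"), by = "metal") |>
    mutate(p_i = single_pollution_index(.data$concentration, .data$class2_threshold))

  sample_indices <- long |>
    mutate(class = classify(.data$p_i, scheme)) |>
    select("sample_id", "group", "metal", "concentration", "p_i", "class")

  sample_npi <- sample_indices |>
    group_by(.data$sample_id, .data$group) |>
    summarise(p_max = max(.data$p_i), p_ave = mean(.data$p_i),
              npi = nemerow_index(.data$p_i), .groups = "drop") |>
    mutate(class = classify(.data$npi, scheme))

  group_indices <- sample_indices |>
    group_by(.data$group, .data$metal) |>
    summarise(concentration = mean(.data$concentration),
              p_i = mean(.data$p_i), .groups = "drop") |>
    mutate(class = classify(.data$p_i, scheme))

  group_npi <- if (group_method == "mean_concentration") {
    group_indices |>
      group_by(.data$group) |>
      summarise(p_max = max(.data$p_i), p_ave = mean(.data$p_i),
                npi = nemerow_index(.data$p_i), .groups = "drop")
  } else {
    sample_npi |>
      group_by(.data$group) |>
      summarise(p_max = mean(.data$p_max), p_ave = mean(.data$p_ave),
                npi = mean(.data$npi), .groups = "drop")
  }
  group_npi <- mutate(group_npi, class = classify(.data$npi, scheme))

  structure(
    list(sample_indices = sample_indices, sample_npi = sample_npi,
         group_indices = group_indices, group_npi = group_npi,
         group_method = group_method),
    class = "wetrisk_contamination"
  )
}

#' @export
print.wetrisk_contamination <- function(x, ...) {
  cat("<wetrisk contamination assessment>\n")
  cat("  samples:", nrow(x$sample_npi), " groups:",
      paste(x$group_npi$group, collapse = ", "), "\n\n")
  cat("Group composite (Nemerow) indices:\n")
  print(mutate(x$group_npi, across(where(is.numeric), ~ round(.x, 2))))
  invisible(x)
}

#' Tidy a contamination assessment
#'
#' @param x A `wetrisk_contamination`.
#' @param level `"group"` (default) or `"sample"`.
#' @param what `"indices"` for per-metal single-factor indices (default) or
#'   `"npi"` for composite indices.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wetrisk_contamination <- function(x, level = c("group", "sample"),
                                       what = c("indices", "npi"), ...) {
  level <- match.arg(level)
  what <- match.arg(what)
  x[[paste(level, if (what == "indices") "indices" else "npi", sep = "_")]]
}

#' @export
autoplot.wetrisk_contamination <- function(object, ...) {
  ggplot(object$group_indices,
         aes(x = factor(.data$metal, levels = unique(.data$metal)),
             y = .data$p_i, fill = .data$group)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = NULL, y = "single-factor pollution index",
         fill = NULL,
         title = "Group-average single-factor pollution indices") +
    theme_minimal()
}
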