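#' Pipeline commands with run manifests
#'
#' `run_simulate()`, `run_assess()` and `run_mc_report()` are the
#' file-to-file entry points used by the command-line front end
#' (`inst/cli/wetrisk.R`): each wraps the corresponding in-memory functions,
#' writes its outputs into `out_dir`, and records a `manifest.json` with
#' the timestamp, package version, configuration hash, seed(s), input file
#' digests and output file list, so that a run can be audited and
#' reproduced. Reruns with identical inputs and seed produce identical
#' output tables.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (required where randomness is involved).
#' @param registry A `wetrisk_registry`.
#' @param groups Sampling groups.
#' @param moment_match Passed to [generate_samples()].
#' @return The manifest, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(out_dir, seed, registry = default_registry(),
                         groups = names(registry$groups), moment_match = TRUE) {
  if (missing(seed) || is.null(seed)) stop_invalid("'seed' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- generate_samples(registry, groups = groups, seed = seed,
                              moment_match = moment_match)
  out_csv <- file.path(out_dir, "samples.csv")
  write_water_samples(samples, out_csv)
  manifest <- write_manifest(
    out_dir, command = "simulate",
    config = list(groups = groups, moment_match = moment_match), seed = seed,
    inputs = character(), outputs = "samples.csv")
  invisible(manifest)
}

#' @rdname pipeline
#' @param input Path to a sample CSV (the schema of
#'   [read_water_samples()]).
#' @param populations Populations to assess.
#' @export
run_assess <- function(input, out_dir, registry = default_registry(),
                       populations = names(registry$exposure)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- read_water_samples(input, registry)
  cont <- assess_contamination(samples, registry)
  risk <- assess_risk(samples, registry, populations = populations)

  readr::write_csv(
    bind_rows(
      mutate(cont$sample_indices, scope = .data$sample_id),
      mutate(cont$group_indices, scope = paste0("group:", .data$group))
    ) |> select("scope", "group", "metal", "p_i", "class"),
    file.path(out_dir, "pollution_indices.csv"), progress = FALSE)
  readr::write_csv(
    bind_rows(
      mutate(cont$sample_npi, scope = .data$sample_id),
      mutate(cont$group_npi, scope = paste0("group:", .data$group),
             sample_id = NA_character_)
    ) |> select("scope", "group", "p_max", "p_ave", "npi", "class"),
    file.path(out_dir, "nemerow_indices.csv"), progress = FALSE)
  readr::write_csv(risk$by_metal, file.path(out_dir, "risk_by_metal.csv"),
                   progress = FALSE)
  readr::write_csv(risk$totals, file.path(out_dir, "risk_totals.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(totals = risk$totals, skipped_metals = risk$skipped),
    file.path(out_dir, "risk_totals.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)

  manifest <- write_manifest(
    out_dir, command = "assess",
    config = list(populations = populations), seed = NULL,
    inputs = input,
    outputs = c("pollution_indices.csv", "nemerow_indices.csv",
                "risk_by_metal.csv", "risk_totals.csv", "risk_totals.json"))
  invisible(manifest)
}

#' @rdname pipeline
#' @param n_iterations,concentration_mode,fix_ef Passed to [run_mc()].
#' @export
run_mc_report <- function(out_dir, seed, registry = default_registry(),
                          input = NULL,
                          groups = names(registry$groups),
                          populations = names(registry$exposure),
                          n_iterations = 10000,
                          concentration_mode = "distribution",
                          fix_ef = FALSE) {
  if (missing(seed) || is.null(seed)) stop_invalid("'seed' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- if (!is.null(input)) read_water_samples(input, registry)
  mc <- run_mc(registry, groups = groups, populations = populations,
               n_iterations = n_iterations, seed = seed,
               concentration_mode = concentration_mode, samples = samples,
               fix_ef = fix_ef)
  sens <- mc_sensitivity(mc, registry = registry)

  readr::write_csv(mc$draws, file.path(out_dir, "mc_draws.csv"), progress = FALSE)
  jsonlite::write_json(
    list(config = mc$config, summary = mc$summary),
    file.path(out_dir, "mc_summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  readr::write_csv(as_tibble(sens), file.path(out_dir, "sensitivity.csv"),
                   progress = FALSE)

  manifest <- write_manifest(
    out_dir, command = "mc",
    config = list(groups = groups, populations = populations,
                  n_iterations = n_iterations,
                  concentration_mode = concentration_mode, fix_ef = fix_ef),
    seed = seed,
    inputs = if (is.null(input)) character() else input,
    outputs = c("mc_draws.csv", "mc_summary.json", "sensitivity.csv"))
  invisible(manifest)
}

write_manifest <- function(out_dir, command, config, seed, inputs, outputs) {
  manifest <- list(
    command = command,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(packageVersion("wetrisk")),
    config = config,
    config_hash = rlang::hash(config),
    seed = seed,
    inputs = lapply(inputs, function(p) {
      list(path = p, digest = rlang::hash(readBin(p, "raw", file.size(p))))
    }),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}
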