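#' Read and write per-sample water chemistry tables
#'
#' The on-disk sample format is a UTF-8 CSV with header
#' `sample_id,group,Hg,As,Cu,Zn,Pb,Cd,pH,EC`, concentrations in ug/L and
#' `.` as the decimal separator. `pH` and `EC` are optional metadata.
#' Columns not in the schema are dropped with a warning; metal columns
#' must all be present and numeric.
#'
#' @param path CSV file path.
#' @param registry A `wetrisk_registry` (defines the expected metals).
#' @return A tibble in the package's sample schema.
#' @export
read_water_samples <- function(path, registry = default_registry()) {
  if (!file.exists(path)) {
    abort(sprintf("sample file not found: %s", path), class = "wetrisk_io_error")
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(d) == 0) stop_invalid("sample file '%s' contains no rows", path)
  metals <- registry$metals$metal
  keep <- c("sample_id", "group", metals, "pH", "EC")
  extra <- setdiff(names(d), keep)
  if (length(extra) > 0) {
    warn(sprintf("ignoring unrecognized column(s): %s", paste(extra, collapse = ", ")))
    d <- select(d, -all_of(extra))
  }
  missing <- setdiff(metals, names(d))
  if (length(missing) > 0) {
    stop_invalid("sample file is missing metal column(s): %s",
                 paste(missing, collapse = ", "))
  }
  for (sym in metals) {
    if (!is.numeric(d[[sym]])) stop_invalid("column '%s' must be numeric", sym)
  }
  d
}

#' @rdname read_water_samples
#' @param samples A sample tibble.
#' @export
write_water_samples <- function(samples, path) {
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}
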