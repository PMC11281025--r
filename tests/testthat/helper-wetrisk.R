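## Shared fixtures, built once per test run.

test_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- default_registry()
    reg
  }
})

## Group-mean concentrations as a (group, metal, concentration) tibble.
group_mean_conc <- function(registry = test_registry()) {
  dplyr::mutate(group_profiles(registry), concentration = mean)
}

## A tiny wide sample table where every metal is constant except those
## supplied, handy for hand-arithmetic oracles.
toy_samples <- function(..., group = "toy") {
  over <- list(...)
  n <- if (length(over) > 0) length(over[[1]]) else 4
  base <- list(Hg = 1, As = 1, Cu = 1, Zn = 1, Pb = 1, Cd = 1)
  cols <- utils::modifyList(base, over)
  tibble::tibble(
    sample_id = sprintf("T%02d", seq_len(n)),
    group = group,
    !!!lapply(cols, function(v) rep_len(v, n))
  )
}

## One large Monte Carlo run shared by the sensitivity and acceptance
## tests. The body-weight spread in the study design is tiny (SD 0.15 kg),
## so its rank correlation with the outputs is of order 1e-3 for adults; a
## large draw count is needed for its sign to be signal rather than noise.
shared_big_mc <- local({
  mc <- NULL
  function() {
    if (is.null(mc)) {
      mc <<- run_mc(test_registry(), groups = "rural",
                    populations = c("children", "adults"),
                    n_iterations = 2e5, seed = 42)
    }
    mc
  }
})
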