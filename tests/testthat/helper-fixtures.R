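# Shared fixtures.  Calibration takes ~1 s per gene, so base-case parameter
# sets and calibrated schedules are cached per gene across test files.
.test_cache <- new.env(parent = emptyenv())

base_params <- function(gene) {
  key <- paste0("params_", gene)
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- load_parameters(gene = gene)
  .test_cache[[key]]
}

base_onset <- function(gene) {
  key <- paste0("onset_", gene)
  if (is.null(.test_cache[[key]])) {
    cal <- calibrate_gene(base_params(gene))
    .test_cache[[key]] <- list(ec = cal$ec, oc = cal$oc)
  }
  .test_cache[[key]]
}

base_cea <- function(gene) {
  key <- paste0("cea_", gene)
  if (is.null(.test_cache[[key]])) {
    p <- base_params(gene)
    res <- evaluate_strategies(p, onset = base_onset(gene))
    .test_cache[[key]] <- build_frontier(res, wtp = param_get(p, "wtp"))
  }
  .test_cache[[key]]
}

# deterministic cohort world without background mortality: useful for
# closed-form accounting checks
zero_mortality_life_table <- function() {
  validate_life_table(data.frame(age = 25:110, qx = 0))
}

constant_life_table <- function(q) {
  validate_life_table(data.frame(age = 25:110, qx = q))
}

zero_onset_pair <- function() {
  zero <- seed_from_cumulative(data.frame(age = c(30, 75), ci = c(0, 0)))
  list(ec = zero, oc = zero)
}

# parameter set with a deterministic, event-free accounting world:
# no deaths, no complications, optional zero cancer risk
accounting_params <- function(gene = "MSH2", life_table = zero_mortality_life_table()) {
  p <- load_parameters(gene = gene, life_table = life_table)
  p <- param_set(p, "surgical_mortality", 0)
  p <- param_set(p, "complication_prob", 0)
  p
}
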