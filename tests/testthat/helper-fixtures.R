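# Shared fixtures: default parameter objects and small deterministic runs
# reused across test files. Everything is generated in code at test time.

g_def <- gating_params()
d_def <- drug_params()

# noiseless single-"cell" records for a protocol at a concentration
noiseless_records <- function(kind, conc, ..., init = "auto") {
  run_protocol(build_protocol(kind, ...), g_def, d_def, conc = conc,
               init = init, cell_id = sprintf("%s_%g", kind, conc))$records
}

# a reduced state-dependence protocol for fast tests (same topology,
# fewer pulses)
small_sd_protocol <- function(pulses = 20) {
  build_protocol("state_dependence", pulses_per_interval = pulses)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) < tol),
              label = sprintf("%s within %g of %s",
                              paste(signif(actual, 6), collapse = ","), tol,
                              paste(signif(expected, 6), collapse = ",")))
}
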