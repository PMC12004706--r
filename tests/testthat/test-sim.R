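# Protocol runner and dataset generator.

test_that("the drug-free IV relationship peaks at -25 mV", {
  iv <- noiseless_records("activation", 0)
  expect_equal(iv$step_mV[which.max(abs(iv$peak_pA))], -25)
  # inward currents are negative below the reversal potential
  expect_true(all(iv$peak_pA <= 0))
})

test_that("zero conductance gives zero peaks everywhere", {
  out <- run_protocol(build_protocol("ssi"), g_def, d_def, conc = 0,
                      cell = cell_params(g_max = 1e-12))
  expect_equal(max(abs(out$records$peak_pA)), 0, tolerance = 1e-9)
})

test_that("a protocol without test segments is rejected", {
  p <- build_protocol("activation")
  p$sweeps <- lapply(p$sweeps, function(s) {
    s$segments$label[s$segments$label == "test"] <- "holding"
    s
  })
  expect_error(run_protocol(p, g_def, d_def, 0), "no test segments")
})

test_that("drug application produces no tonic block on the first pulse", {
  # compound applied at time zero of the first -110 mV interval: with the
  # slow association rate, the first 20 ms pulse is essentially unblocked
  p <- small_sd_protocol(5)
  veh <- run_protocol(p, g_def, d_def, 0)$records
  drg <- run_protocol(p, g_def, d_def, 30)$records
  first <- function(r) r$peak_pA[r$interval_index == 1 & r$pulse_number == 1]
  expect_lt(abs(1 - first(drg) / first(veh)), 0.05)
})

test_that("block is use-dependent at depolarised holding potentials", {
  p <- build_protocol("state_dependence")
  drg <- run_protocol(p, g_def, d_def, 30)$records
  veh <- run_protocol(p, g_def, d_def, 0)$records
  at <- function(r, j, n) {
    abs(r$peak_pA[r$interval_index == j & r$pulse_number == n])
  }
  # -80 mV interval: strong accumulation over the train
  expect_lt(at(drg, 4, 180), 0.5 * at(drg, 4, 1))
  # vehicle: flat at hyperpolarised holdings; at depolarised holdings only
  # the slow-inactivation pool settles over the train (a few percent),
  # which the vehicle normalisation removes downstream
  expect_equal(at(veh, 1, 180) / at(veh, 1, 1), 1, tolerance = 0.02)
  for (j in 2:4) expect_equal(at(veh, j, 180) / at(veh, j, 1), 1,
                              tolerance = 0.12)
})

test_that("recovery from inactivation is slowed only after long prepulses", {
  rows <- list()
  for (pp in c(20, 5000)) for (cc in c(0, 30)) {
    rows[[length(rows) + 1]] <-
      run_protocol(build_protocol("recovery", prepulse_duration_ms = pp),
                   g_def, d_def, cc, cell_id = sprintf("c%d_%d", pp, cc)
      )$records
  }
  out <- analyze_recovery(dplyr::bind_rows(rows))
  s <- out$summary
  r20 <- s$t_half_ratio_vs_vehicle[s$conc_uM == 30 & s$prepulse_ms == 20]
  r5000 <- s$t_half_ratio_vs_vehicle[s$conc_uM == 30 & s$prepulse_ms == 5000]
  expect_lt(abs(r20 - 1), 0.05)   # fast inactivation recovery untouched
  expect_gt(r5000, 1.5)           # deep inactivation recovery slowed
})

test_that("generated datasets are reproducible and correctly shaped", {
  design <- list(protocols = "activation",
                 concentrations = c(1, 3, 10, 30, 100, 300),
                 cells_per_conc = 8, include_vehicle = FALSE)
  a <- generate_dataset(design, g_def, d_def, cell_params(), seed = 42)
  b <- generate_dataset(design, g_def, d_def, cell_params(), seed = 42)
  expect_identical(a$records, b$records)
  expect_equal(nrow(a$records), 6 * 8 * 30)
  d <- generate_dataset(design, g_def, d_def, cell_params(), seed = 43)
  expect_false(identical(a$records$peak_pA, d$records$peak_pA))
})

test_that("vehicle cells carry concentration exactly zero", {
  design <- list(protocols = "ssi", concentrations = 30,
                 cells_per_conc = 2, include_vehicle = TRUE)
  ds <- generate_dataset(design, g_def, d_def, cell_params(), seed = 7)
  expect_identical(sort(unique(ds$records$conc_uM)), c(0, 30))
  percell <- tapply(ds$records$conc_uM, ds$records$cell_id,
                    function(x) length(unique(x)))
  expect_true(all(percell == 1))   # one concentration per cell
})

test_that("adding cells does not perturb existing cells' draws", {
  design <- list(protocols = "activation", concentrations = 30,
                 cells_per_conc = 2, include_vehicle = FALSE)
  small <- generate_dataset(design, g_def, d_def, cell_params(), seed = 5)
  design$cells_per_conc <- 4
  big <- generate_dataset(design, g_def, d_def, cell_params(), seed = 5)
  shared <- unique(small$records$cell_id)
  expect_identical(small$records,
                   dplyr::filter(big$records, cell_id %in% shared))
})

test_that("empty designs are rejected", {
  expect_error(generate_dataset(list(protocols = character(),
                                     concentrations = 1)), "empty design")
  expect_error(generate_dataset(list(protocols = "ssi",
                                     concentrations = numeric())),
               "empty design")
  expect_error(generate_dataset(list(protocols = "ssi",
                                     concentrations = -5)), ">= 0")
})

test_that("peak-record tables survive a CSV round trip with validation", {
  design <- list(protocols = "kinetics", concentrations = 30,
                 cells_per_conc = 1, include_vehicle = TRUE)
  ds <- generate_dataset(design, g_def, d_def, cell_params(), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_records(ds$records, path)
  back <- read_peak_records(path)
  expect_equal(back$peak_pA, ds$records$peak_pA)
  # schema violations are caught
  bad <- ds$records[, -which(names(ds$records) == "peak_pA")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path2)
  expect_error(read_peak_records(path2), "missing column")
  mixed <- ds$records
  mixed$conc_uM[1] <- 99
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(mixed, path3)
  expect_error(read_peak_records(path3), "single concentration")
})
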