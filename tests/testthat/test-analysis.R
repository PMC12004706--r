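# Analysis stages: QC, vehicle normalisation, stage analyses, the
# concentration-response builder and the four-state fit.

toy_records <- function(rm, rs, peak) {
  tibble::tibble(cell_id = sprintf("c%d", seq_along(rm)),
                 protocol = "activation", holding_mV = -120,
                 step_mV = -20, prepulse_ms = NA, recovery_ms = NA,
                 pulse_number = NA, interval_index = NA, elapsed_s = 0,
                 conc_uM = 0, peak_pA = -peak, rm_MOhm = rm, rs_MOhm = rs,
                 cap_pF = 15)
}

test_that("QC excludes cells by strict thresholds, cell-wise", {
  rec <- toy_records(rm = c(600, 400, 600, 600, 700),
                     rs = c(5, 5, 12, 5, 2),
                     peak = c(800, 800, 800, 400, 900))
  out <- apply_qc(rec)
  expect_setequal(unique(out$records$cell_id), c("c1", "c5"))
  expect_setequal(out$exclusions$criterion,
                  c("membrane_resistance", "series_resistance",
                    "peak_magnitude"))
  # values exactly on a threshold are excluded (strict inequalities)
  border <- toy_records(rm = c(500, 600), rs = c(10, 5), peak = c(500, 900))
  out2 <- apply_qc(border)
  expect_identical(unique(out2$records$cell_id), "c2")
  expect_equal(nrow(out2$exclusions), 3)  # c1 fails all three
  expect_error(apply_qc(toy_records(100, 20, 10)), "no cells survive")
})

test_that("vehicle normalisation removes shared rundown", {
  t <- 0:10
  same <- vehicle_normalize(data.frame(time_s = t, value = 0.9),
                            data.frame(time_s = t, value = 0.9))
  expect_equal(same$inhibition, rep(0, 11))
  half <- vehicle_normalize(data.frame(time_s = t, value = 0.45),
                            data.frame(time_s = t, value = 0.9))
  expect_equal(half$inhibition, rep(0.5, 11))
  expect_error(
    vehicle_normalize(data.frame(time_s = t, value = 1),
                      data.frame(time_s = t, value = 0)), "zero")
  clamped <- vehicle_normalize(data.frame(time_s = 0, value = 2),
                               data.frame(time_s = 0, value = 1))
  expect_equal(clamped$inhibition, -0.2)
  expect_true(clamped$out_of_range)
})

test_that("activation analysis reports conductance loss without a gating shift", {
  rows <- list()
  for (cc in c(0, 30)) {
    rows[[length(rows) + 1]] <-
      run_protocol(build_protocol("activation"), g_def, d_def, cc,
                   cell_id = paste0("a", cc))$records
  }
  act <- analyze_activation(dplyr::bind_rows(rows))
  expect_equal(act$e_na_source, "nernst_fallback")  # IV stops below E_Na
  ratio <- act$gmax$ratio_vs_vehicle[act$gmax$conc_uM == 30]
  expect_gt(ratio, 0.4); expect_lt(ratio, 0.6)
  dv <- act$delta_v_half$delta_v_half[act$delta_v_half$conc_uM == 30]
  expect_lt(abs(dv), 2)
  # current density is peak over capacitance
  dens <- act$current_density
  r25 <- dens[dens$conc_uM == 0 & dens$step_mV == -25, ]
  raw <- rows[[1]]
  expect_equal(r25$density_pA_pF,
               raw$peak_pA[raw$step_mV == -25] / raw$cap_pF[1])
  expect_error(analyze_activation(rows[[2]]), "vehicle")
})

test_that("SSI analysis recovers the availability curve and drug shifts", {
  rows <- list()
  for (cc in c(0, 4, 30)) {
    rows[[length(rows) + 1]] <-
      run_protocol(build_protocol("ssi"), g_def, d_def, cc,
                   cell_id = paste0("s", cc))$records
  }
  ssi <- analyze_ssi(dplyr::bind_rows(rows), 500)
  f0 <- ssi$fits[["0"]]
  expect_lt(abs(f0$v_half - (-80)), 4)   # vehicle round trip
  expect_lt(abs(f0$k - 8), 1)
  dv <- ssi$delta_v_half
  expect_true(all(dv$delta_v_half[dv$conc_uM > 0] < 0))
  expect_gt(abs(dv$delta_v_half[dv$conc_uM == 30]),
            abs(dv$delta_v_half[dv$conc_uM == 4]))
  expect_error(analyze_ssi(dplyr::bind_rows(rows), 123), "no SSI records")
})

test_that("two vehicle subsets give matching SSI midpoints", {
  design <- list(protocols = "ssi", concentrations = 0,
                 cells_per_conc = 8, include_vehicle = TRUE)
  ds <- generate_dataset(design, g_def, d_def, cell_params(), seed = 11)
  cells <- unique(ds$records$cell_id)
  a <- analyze_ssi(dplyr::filter(ds$records, cell_id %in% cells[1:4]), 500)
  b <- analyze_ssi(dplyr::filter(ds$records, cell_id %in% cells[5:8]), 500)
  expect_lt(abs(a$fits[["0"]]$v_half - b$fits[["0"]]$v_half), 1.5)
})

test_that("block-kinetics analysis matches the relaxation eigenvalue", {
  kin <- dplyr::bind_rows(
    run_protocol(build_protocol("kinetics", holding_potential = -90),
                 g_def, d_def, 0, cell_id = "v")$records,
    run_protocol(build_protocol("kinetics", holding_potential = -90),
                 g_def, d_def, 10, cell_id = "d10")$records,
    run_protocol(build_protocol("kinetics", holding_potential = -90),
                 g_def, d_def, 30, cell_id = "d30")$records)
  bk <- analyze_block_kinetics(kin)
  # oracle: slowest non-zero eigenvalue of the generator at the holding
  # potential (binding relaxation; gating modes are orders faster)
  tau_eig <- function(conc) {
    ev <- sort(Re(eigen(rate_matrix(g_def, d_def, -90, conc))$values))
    -1 / ev[length(ev) - 1] / 1000
  }
  t30 <- bk$tau_s[bk$conc_uM == 30]
  expect_lt(abs(t30 / tau_eig(30) - 1), 0.15)
  # equilibration accelerates with concentration
  expect_lt(t30, bk$tau_s[bk$conc_uM == 10])
  expect_error(analyze_block_kinetics(
    dplyr::filter(kin, conc_uM > 0)), "vehicle")
})

test_that("negligible resting block yields a no-fit flag at -110 mV", {
  d_weak <- drug_params(k_r = 1e5, k_i = 3.6)
  kin <- dplyr::bind_rows(
    run_protocol(build_protocol("kinetics", holding_potential = -110),
                 g_def, d_weak, 0, cell_id = "v")$records,
    run_protocol(build_protocol("kinetics", holding_potential = -110),
                 g_def, d_weak, 4, cell_id = "d")$records)
  bk <- analyze_block_kinetics(kin)
  expect_true(bk$no_fit)
  expect_lt(bk$final_inhibition, 0.05)
})

test_that("open-state inactivation tau matches the gating eigenvalue", {
  ds <- generate_dataset(
    list(protocols = "activation", concentrations = c(0, 30),
         cells_per_conc = 1, include_vehicle = FALSE),
    g_def, d_def, cell_params(), seed = 1, keep_traces = TRUE)
  ot <- analyze_open_state_tau(ds$traces)
  expect_equal(ot$step_mV, -25)
  # closed-form relaxation of the free C/O/IF subsystem at -25 mV
  # (slow-inactivation exchange is orders of magnitude slower and ignored)
  Q <- rate_matrix(g_def, d_def, -25, 0)
  Q3 <- Q[1:3, 1:3]; diag(Q3) <- 0; diag(Q3) <- -colSums(Q3)
  ev <- sort(Re(eigen(Q3)$values))
  tau_oracle <- -1 / ev[2]
  tau_v <- ot$summary$tau_mean_ms[ot$summary$conc_uM == 0]
  expect_lt(abs(tau_v / tau_oracle - 1), 0.05)
  expect_gt(tau_v, 0.5); expect_lt(tau_v, 1)  # calibration band, ms
  # no open-state binding: drug taus indistinguishable from vehicle
  tau_d <- ot$summary$tau_mean_ms[ot$summary$conc_uM == 30]
  expect_lt(abs(tau_d / tau_v - 1), 0.01)
})

test_that("a monotonically rising trace is rejected", {
  tr <- tibble::tibble(time_ms = seq(0, 20, 0.04),
                       current_pA = -seq(0, 20, 0.04))
  attr(tr, "step_mV") <- -25
  expect_error(analyze_open_state_tau(list(tr), at_step = -25), "decay")
})

test_that("concentration-response pooling averages cells as stated", {
  # two drug cells with inhibition 0.4 and 0.6 pool to 0.5 with n = 2
  mk <- function(id, conc, p1_i1, p2_all) {
    tibble::tibble(cell_id = id, protocol = "state_dependence",
                   holding_mV = -90, step_mV = 0, prepulse_ms = NA,
                   recovery_ms = NA, pulse_number = c(1, 2),
                   interval_index = 1, elapsed_s = c(0, 1), conc_uM = conc,
                   peak_pA = -c(p1_i1, p2_all), rm_MOhm = 600, rs_MOhm = 5,
                   cap_pF = 15)
  }
  rec <- dplyr::bind_rows(
    mk("veh", 0, 1000, 1000),
    mk("d1", 10, 1000, 600),    # inhibition 0.4 at the last pulse
    mk("d2", 10, 1000, 400))    # inhibition 0.6
  cr <- build_concentration_response(rec, equilibrium_pulses = 1)
  last <- dplyr::filter(cr$table, pulse == "last")
  expect_equal(last$inhibition, 0.5)
  expect_equal(last$n, 2)
  first <- dplyr::filter(cr$table, pulse == "first")
  expect_equal(first$inhibition, 0)
  expect_error(build_concentration_response(
    dplyr::filter(rec, conc_uM > 0)), "vehicle")
  expect_error(build_concentration_response(
    dplyr::filter(rec, pulse_number == 1)), "missing first or last")
})

test_that("first-pulse curves carry the no-inhibition flag", {
  p <- small_sd_protocol(12)
  rows <- lapply(c(0, 3, 30, 300), function(cc) {
    run_protocol(p, g_def, d_def, cc, cell_id = paste0("c", cc))$records
  })
  cr <- build_concentration_response(dplyr::bind_rows(rows))
  # the first interval's first pulse precedes any drug equilibration
  expect_true(is_no_inhibition(cr$fits[["-110"]]$first))
  # by the last pulse the -80 mV interval is strongly inhibited
  expect_false(is_no_inhibition(cr$fits[["-80"]]$last))
})

test_that("the four-state fit inverts its own closed form", {
  h <- function(v) 1 / (1 + exp((v + 80) / 8))
  v <- c(-110, -100, -90, -80)
  ic <- 1 / (h(v) / 108 + (1 - h(v)) / 3.6)
  f <- fit_four_state(setNames(ic, v), h)
  expect_rel_equal(f$k_r, 108, 1e-9)
  expect_rel_equal(f$k_i, 3.6, 1e-9)
  expect_rel_equal(f$fold_preference, 30, 1e-9)
  expect_lt(max(abs(f$residuals)), 1e-12)
  # identical IC50s collapse to K_R = K_I = IC50
  f2 <- fit_four_state(setNames(rep(20, 4), v), h)
  expect_rel_equal(f2$k_r, 20, 1e-9)
  expect_rel_equal(f2$k_i, 20, 1e-9)
  # weighting options agree on noiseless data
  f3 <- fit_four_state(setNames(ic, v), h, weights = "absolute")
  expect_rel_equal(f3$k_r, 108, 1e-9)
})

test_that("four-state degeneracies are flagged or rejected", {
  h <- function(v) rep(0.9, length(v))
  expect_error(fit_four_state(setNames(c(10, 20), c(-100, -80)), h),
               "identical")
  # IC50s *increasing* with inactivation force a boundary solution
  hb <- function(v) 1 / (1 + exp((v + 80) / 8))
  v <- c(-110, -80)
  f <- fit_four_state(setNames(c(5, 100), v), hb)
  expect_true(f$boundary)
  expect_true(f$k_r > 0, f$k_i > 0)
  # censored mode enters flagged voltages at the bound
  tab <- tibble::tibble(holding_mV = c(-110, -90, -80),
                        ic50_uM = c(NA, 12.6, 6.7),
                        no_inhibition = c(TRUE, FALSE, FALSE))
  fc <- fit_four_state(tab, hb, censored = TRUE, censor_value = 300)
  expect_length(fc$voltages, 3)
  fd <- fit_four_state(tab, hb)
  expect_length(fd$voltages, 2)
})

test_that("equilibrium inhibition prediction matches the printed check", {
  expect_equal(predict_equilibrium_inhibition(96.5, 0), 0)
  expect_equal(predict_equilibrium_inhibition(1, 1e9), 1, tolerance = 1e-8)
  expect_equal(predict_equilibrium_inhibition(96.5, 30), 0.237,
               tolerance = 1e-3)
  expect_error(predict_equilibrium_inhibition(-1, 10))
})
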