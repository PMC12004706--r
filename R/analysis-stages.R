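# Stage analyses over peak-record tables: activation/conductance, SSI,
# recovery from inactivation, block kinetics, open-state inactivation tau.

#' Activation (IV / conductance) analysis
#'
#' Converts activation-protocol peak currents to conductances
#' (`G = I / (V - E_Na)`), fits the normalised G-V with a Boltzmann per
#' concentration, and reports maximal conductance and current density,
#' with drug/vehicle maximal-conductance ratios and activation midpoint
#' shifts.
#'
#' @param records Peak-record tibble containing activation-protocol rows
#'   (vehicle arm required for ratios).
#' @param e_na Reversal potential (mV), or `NULL` to estimate it from the
#'   vehicle IV zero crossing, falling back to the Nernst potential of the
#'   standard solutions when the IV does not reach reversal.
#' @return A list: `e_na`, `e_na_source`, `gv` (mean conductance and
#'   normalised conductance per concentration and voltage), `fits`
#'   (activation `boltzmann_fit` per concentration), `gmax` (per-cell
#'   maxima summarised per concentration, with `ratio_vs_vehicle`),
#'   `delta_v_half`, and `current_density` (pA/pF).
#' @export
analyze_activation <- function(records, e_na = NULL) {
  act <- dplyr::filter(records, .data$protocol == "activation")
  if (!nrow(act)) stop("no activation-protocol records")
  has_vehicle <- any(act$conc_uM == 0)
  if (!has_vehicle) stop("missing vehicle arm: drug/vehicle ratios need conc 0")

  e_na_source <- "user"
  if (is.null(e_na)) {
    veh_iv <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(act, .data$conc_uM == 0), .data$step_mV),
      peak_pA = mean(.data$peak_pA), .groups = "drop")
    e_na <- tryCatch({
      e_na_source <- "iv_zero_crossing"
      estimate_reversal(veh_iv)
    }, error = function(e) {
      e_na_source <<- "nernst_fallback"
      nernst_potential()
    })
  }

  g <- dplyr::group_modify(
    dplyr::group_by(act, .data$conc_uM, .data$cell_id),
    function(df, key) {
      gg <- conductance_from_iv(df[, c("step_mV", "peak_pA")], e_na)
      gg$cap_pF <- df$cap_pF
      gg$gmax <- max(gg$g_nS, na.rm = TRUE)
      gg$g_norm <- gg$g_nS / gg$gmax
      gg
    })
  g <- dplyr::ungroup(g)

  gv <- dplyr::summarise(
    dplyr::group_by(g, .data$conc_uM, .data$step_mV),
    g_mean = mean(.data$g_nS), g_norm_mean = mean(.data$g_norm),
    n = dplyr::n(), .groups = "drop")

  fits <- list()
  for (cc in sort(unique(gv$conc_uM))) {
    sub <- dplyr::filter(gv, .data$conc_uM == cc, !is.na(.data$g_norm_mean))
    fits[[as.character(cc)]] <-
      fit_boltzmann(sub$step_mV, sub$g_norm_mean, "activation")
  }

  gmax_cells <- dplyr::summarise(
    dplyr::group_by(g, .data$conc_uM, .data$cell_id),
    gmax = .data$gmax[1], .groups = "drop")
  gmax <- dplyr::group_modify(dplyr::group_by(gmax_cells, .data$conc_uM),
                              function(df, key) mean_sem(df$gmax))
  gmax <- dplyr::ungroup(gmax)
  gmax_veh <- gmax$mean[gmax$conc_uM == 0]
  gmax$ratio_vs_vehicle <- gmax$mean / gmax_veh

  v0 <- fits[["0"]]$v_half
  delta_v_half <- tibble::tibble(
    conc_uM = as.numeric(names(fits)),
    v_half = vapply(fits, function(f) f$v_half, numeric(1)),
    delta_v_half = vapply(fits, function(f) f$v_half - v0, numeric(1)))

  dens <- dplyr::summarise(
    dplyr::group_by(act, .data$conc_uM, .data$step_mV),
    density_pA_pF = mean(.data$peak_pA / .data$cap_pF),
    n = dplyr::n(), .groups = "drop")

  list(e_na = e_na, e_na_source = e_na_source, gv = gv, fits = fits,
       gmax = gmax, delta_v_half = delta_v_half, current_density = dens)
}

#' Steady-state inactivation analysis
#'
#' Normalises test-pulse currents to the per-cell maximum, averages the
#' availability curve per concentration, fits each with an inactivation
#' Boltzmann, and reports the midpoint shift relative to vehicle.
#'
#' @param records Peak-record tibble with `ssi` or `slow_ssi` rows.
#' @param prepulse_duration Prepulse duration to analyse, ms (500 for the
#'   standard SSI; 1000/3000/5000/10000 for slow inactivation).
#' @return A list: `curve` (per concentration and prepulse voltage),
#'   `fits` (inactivation `boltzmann_fit` per concentration),
#'   `delta_v_half` tibble.
#' @export
analyze_ssi <- function(records, prepulse_duration = 500) {
  ssi <- dplyr::filter(records,
                       .data$protocol %in% c("ssi", "slow_ssi"),
                       .data$prepulse_ms == prepulse_duration)
  if (!nrow(ssi)) {
    stop("no SSI records at prepulse duration ", prepulse_duration, " ms")
  }
  if (length(unique(ssi$step_mV)) < 4) {
    stop("need at least 4 prepulse voltages")
  }
  # signed ratio to the largest-magnitude sweep: the near-zero tail of the
  # availability curve then carries symmetric noise instead of |noise|
  norm <- dplyr::mutate(
    dplyr::group_by(ssi, .data$conc_uM, .data$cell_id),
    avail = .data$peak_pA / .data$peak_pA[which.max(abs(.data$peak_pA))])
  curve <- dplyr::summarise(
    dplyr::group_by(dplyr::ungroup(norm), .data$conc_uM, .data$step_mV),
    avail_mean = mean(.data$avail), avail_sem = sd(.data$avail) /
      sqrt(dplyr::n()), n = dplyr::n(), .groups = "drop")
  # slow-inactivation availability saturates above zero (only part of the
  # population slow-inactivates), so long prepulses get a free floor
  floor_mode <- if (prepulse_duration > 500) "free" else "zero"
  fits <- list()
  for (cc in sort(unique(curve$conc_uM))) {
    sub <- dplyr::filter(curve, .data$conc_uM == cc)
    fits[[as.character(cc)]] <-
      fit_boltzmann(sub$step_mV, sub$avail_mean, "inactivation",
                    floor = floor_mode)
  }
  v0 <- if (!is.null(fits[["0"]])) fits[["0"]]$v_half else NA_real_
  delta <- tibble::tibble(
    conc_uM = as.numeric(names(fits)),
    v_half = vapply(fits, function(f) f$v_half, numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    delta_v_half = vapply(fits, function(f) f$v_half - v0, numeric(1)))
  list(curve = curve, fits = fits, delta_v_half = delta,
       prepulse_duration = prepulse_duration)
}

#' Recovery-from-inactivation analysis
#'
#' Availability (test-pulse current normalised to the per-cell maximum
#' over the recovery ladder) versus recovery interval, averaged per
#' concentration and conditioning-prepulse duration and fitted with the
#' bi-exponential recovery function; reports the time to half recovery
#' per condition and its ratio to vehicle.
#'
#' @param records Peak-record tibble with recovery-protocol rows.
#' @return A list: `curve`, `fits` (named `<prepulse_ms>@<conc>`), and
#'   `summary` (one row per condition: `t_half_s`, `t_half_ratio_vs_vehicle`).
#' @export
analyze_recovery <- function(records) {
  rec <- dplyr::filter(records, .data$protocol == "recovery")
  if (!nrow(rec)) stop("no recovery-protocol records")
  dup <- dplyr::summarise(
    dplyr::group_by(rec, .data$cell_id, .data$prepulse_ms),
    bad = anyDuplicated(.data$recovery_ms) > 0, .groups = "drop")
  if (any(dup$bad)) stop("unordered or duplicated recovery intervals")
  norm <- dplyr::mutate(
    dplyr::group_by(rec, .data$conc_uM, .data$prepulse_ms, .data$cell_id),
    avail = .data$peak_pA / .data$peak_pA[which.max(abs(.data$peak_pA))])
  curve <- dplyr::summarise(
    dplyr::group_by(dplyr::ungroup(norm), .data$conc_uM, .data$prepulse_ms,
                    .data$recovery_ms),
    avail_mean = mean(.data$avail), n = dplyr::n(), .groups = "drop")
  curve <- dplyr::arrange(curve, .data$conc_uM, .data$prepulse_ms,
                          .data$recovery_ms)
  conds <- dplyr::distinct(curve, .data$conc_uM, .data$prepulse_ms)
  fits <- list(); rows <- list()
  for (i in seq_len(nrow(conds))) {
    cc <- conds$conc_uM[i]; pp <- conds$prepulse_ms[i]
    sub <- dplyr::filter(curve, .data$conc_uM == cc, .data$prepulse_ms == pp)
    t_s <- sub$recovery_ms / 1000
    fit <- fit_biexp(t_s, sub$avail_mean)
    key <- sprintf("%g@%g", pp, cc)
    fits[[key]] <- fit
    rows[[key]] <- tibble::tibble(conc_uM = cc, prepulse_ms = pp,
                                  t_half_s = biexp_half_time(fit),
                                  percent_fast = fit$percent_fast,
                                  k_fast = fit$k_fast, k_slow = fit$k_slow,
                                  degenerate = fit$degenerate)
  }
  summary <- dplyr::bind_rows(rows)
  veh <- dplyr::select(dplyr::filter(summary, .data$conc_uM == 0),
                       "prepulse_ms", t_half_vehicle = "t_half_s")
  summary <- dplyr::left_join(summary, veh, by = "prepulse_ms")
  summary$t_half_ratio_vs_vehicle <- summary$t_half_s / summary$t_half_vehicle
  list(curve = curve, fits = fits, summary = summary)
}

# time at which a bi-exponential fit crosses halfway between Y0 and plateau
biexp_half_time <- function(fit) {
  target <- (fit$y0 + fit$plateau) / 2
  f <- function(t) {
    fit$plateau + fit$span_fast * exp(-fit$k_fast * t) +
      fit$span_slow * exp(-fit$k_slow * t) - target
  }
  lo <- 1e-6; hi <- 1e4
  if (f(lo) * f(hi) > 0) return(NA_real_)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Drug-block equilibration kinetics
#'
#' Builds the vehicle-normalised inhibition time course per concentration
#' and holding potential from kinetics-protocol records and fits it with a
#' single exponential; the reported `tau` (1/K) is the observed
#' equilibration time constant. Conditions whose final inhibition (mean of
#' the last three points) is below 5% are flagged `no_fit` instead of
#' being fitted.
#'
#' @param records Peak-record tibble with kinetics-protocol rows (drug
#'   arms); must span at least 3 minutes of pulsing.
#' @param vehicle Optional separate vehicle table; by default the
#'   `conc_uM == 0` rows of `records` are used (error if absent).
#' @return A tibble with one row per (concentration, holding potential):
#'   `tau_s`, `k_per_s`, `final_inhibition`, `no_fit`, and a `fit`
#'   list-column.
#' @export
analyze_block_kinetics <- function(records, vehicle = NULL) {
  kin <- dplyr::filter(records, .data$protocol == "kinetics")
  if (is.null(vehicle)) vehicle <- dplyr::filter(kin, .data$conc_uM == 0)
  else vehicle <- dplyr::filter(vehicle, .data$protocol == "kinetics",
                                .data$conc_uM == 0)
  if (!nrow(vehicle)) stop("vehicle table missing for kinetics analysis")
  drug <- dplyr::filter(kin, .data$conc_uM > 0)
  if (!nrow(drug)) stop("no drug-arm kinetics records")
  if (diff(range(kin$elapsed_s)) < 170) {
    stop("kinetics records must span at least 3 minutes")
  }

  mean_series <- function(df) {
    norm <- dplyr::mutate(
      dplyr::group_by(df, .data$cell_id),
      value = abs(.data$peak_pA) / abs(.data$peak_pA[1]))
    dplyr::summarise(dplyr::group_by(dplyr::ungroup(norm), .data$elapsed_s),
                     value = mean(.data$value), .groups = "drop")
  }

  conds <- dplyr::distinct(drug, .data$conc_uM, .data$holding_mV)
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    cc <- conds$conc_uM[i]; hp <- conds$holding_mV[i]
    d <- mean_series(dplyr::filter(drug, .data$conc_uM == cc,
                                   .data$holding_mV == hp))
    v <- mean_series(dplyr::filter(vehicle, .data$holding_mV == hp))
    if (!nrow(v)) stop("vehicle arm missing at holding potential ", hp)
    inh <- vehicle_normalize(
      data.frame(time_s = d$elapsed_s, value = d$value),
      data.frame(time_s = v$elapsed_s, value = v$value))
    final <- mean(tail(inh$inhibition, 3))
    if (final < 0.05) {
      rows[[i]] <- tibble::tibble(conc_uM = cc, holding_mV = hp,
                                  tau_s = NA_real_, k_per_s = NA_real_,
                                  final_inhibition = final, no_fit = TRUE,
                                  fit = list(NULL))
    } else {
      fit <- fit_monoexp(inh$time_s, inh$inhibition)
      rows[[i]] <- tibble::tibble(conc_uM = cc, holding_mV = hp,
                                  tau_s = fit$tau, k_per_s = fit$k,
                                  final_inhibition = final, no_fit = FALSE,
                                  fit = list(fit))
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$holding_mV, .data$conc_uM)
}

#' Open-state inactivation time constant from current traces
#'
#' Fits a mono-exponential to the decaying phase (from the peak to the end
#' of the test step) of the current trace at the IV-peak voltage and
#' summarises the time constant per concentration (mean and SD across
#' cells/traces).
#'
#' @param traces The `traces` element of a [generate_dataset()] call with
#'   `keep_traces = TRUE` (a named list `"activation@<conc>"` of trace
#'   lists), or a plain list of traces carrying `step_mV` attributes.
#' @param at_step Voltage of the step to analyse (mV); default picks the
#'   step with the largest vehicle peak current.
#' @param blank_ms Initial blanking window, ms.
#' @return A list with `per_trace` (tibble: `conc_uM`, `step_mV`,
#'   `tau_ms`) and `summary` (per-concentration mean, SD, n).
#' @export
analyze_open_state_tau <- function(traces, at_step = NULL, blank_ms = 0.5) {
  if (!length(traces)) stop("no traces supplied")
  named_sets <- !is.null(names(traces)) && all(grepl("@", names(traces)))
  flat <- list()
  if (named_sets) {
    for (nm in names(traces)) {
      cc <- as.numeric(sub(".*@", "", nm))
      for (tr in traces[[nm]]) {
        attr(tr, "conc_uM") <- cc
        flat[[length(flat) + 1]] <- tr
      }
    }
  } else {
    flat <- traces
  }
  step <- vapply(flat, function(tr) attr(tr, "step_mV"), numeric(1))
  conc <- vapply(flat, function(tr) attr(tr, "conc_uM") %||% 0, numeric(1))
  if (is.null(at_step)) {
    ref <- which(conc == min(conc))
    pk <- vapply(flat[ref], function(tr) max(abs(tr$current_pA)), numeric(1))
    at_step <- step[ref][which.max(pk)]
  }
  sel <- which(step == at_step)
  if (!length(sel)) stop("no trace at step voltage ", at_step, " mV")
  rows <- lapply(sel, function(j) {
    tr <- flat[[j]]
    use <- tr$time_ms >= blank_ms
    tm <- tr$time_ms[use]; cur <- tr$current_pA[use]
    ip <- which.max(abs(cur))
    if (ip >= length(cur) - 3) {
      stop("trace has no decay phase after its extremum")
    }
    # fit the late decay: near the extremum the residual activation mode
    # still cancels part of the inactivation relaxation, so the window
    # starts once the current has fallen to half its peak
    pk <- abs(cur[ip])
    i0 <- ip + which(abs(cur[(ip + 1):length(cur)]) <= 0.5 * pk)[1]
    if (is.na(i0) || i0 >= length(cur) - 4) i0 <- ip
    dec_t <- tm[i0:length(tm)] - tm[i0]
    dec_y <- abs(cur[i0:length(cur)])
    keep <- dec_y > 0.01 * pk
    fit <- fit_monoexp(dec_t[keep], dec_y[keep])
    tibble::tibble(conc_uM = attr(tr, "conc_uM") %||% 0,
                   step_mV = at_step, tau_ms = fit$tau)
  })
  per_trace <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(per_trace, .data$conc_uM),
    tau_mean_ms = mean(.data$tau_ms), tau_sd_ms = sd(.data$tau_ms),
    n = dplyr::n(), .groups = "drop")
  list(per_trace = per_trace, summary = summary, step_mV = at_step)
}
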