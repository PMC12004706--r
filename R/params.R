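#' Gating parameters of the Nav channel model
#'
#' Parameters of the free (drug-unbound) gating scheme
#' `C <-> O -> IF <-> IS` plus the direct `C <-> IF` equilibrium that
#' carries the steady-state inactivation (SSI) Boltzmann. Voltage-dependent
#' rates are exponential in voltage; each forward/backward pair shares a
#' midpoint and slope so that its equilibrium is exactly Boltzmann-shaped:
#' for closed-state inactivation the equilibrium availability is
#' `1 / (1 + exp((V - ssi_v_half) / ssi_slope))`.
#'
#' Rate pairs whose uncapped values would exceed `rate_cap` are scaled down
#' jointly, preserving their ratio, so equilibria (and hence detailed
#' balance) are unaffected by the cap.
#'
#' @param act_v_half Activation midpoint (mV).
#' @param act_slope Activation slope factor (mV, > 0).
#' @param ssi_v_half Steady-state inactivation midpoint (mV).
#' @param ssi_slope Steady-state inactivation slope factor (mV, > 0).
#' @param r_act Base rate of the activation/deactivation pair (1/ms).
#' @param k_oi Open to fast-inactivated rate (1/ms).
#' @param r_ssi Base rate of the closed/fast-inactivated pair (1/ms).
#' @param k_fs Fast- to slow-inactivated rate (1/ms, voltage-independent).
#' @param k_sf Slow- to fast-inactivated rate (1/ms, voltage-independent).
#' @param rate_cap Ceiling applied to voltage-dependent rates (1/ms).
#'
#' @return An object of class `gating_params`.
#' @seealso [drug_params()], [cell_params()], [steady_state_availability()]
#' @export
#' @examples
#' g <- gating_params()
#' steady_state_availability(g, -100)
gating_params <- function(act_v_half = -32, act_slope = 7,
                          ssi_v_half = -80, ssi_slope = 8,
                          r_act = 1.6, k_oi = 1.6, r_ssi = 0.06,
                          k_fs = 1e-4, k_sf = 5e-4, rate_cap = 3) {
  stopifnot(act_slope > 0, ssi_slope > 0, r_act >= 0, k_oi >= 0,
            r_ssi >= 0, k_fs >= 0, k_sf >= 0, rate_cap > 0)
  structure(list(act_v_half = act_v_half, act_slope = act_slope,
                 ssi_v_half = ssi_v_half, ssi_slope = ssi_slope,
                 r_act = r_act, k_oi = k_oi, r_ssi = r_ssi,
                 k_fs = k_fs, k_sf = k_sf, rate_cap = rate_cap),
            class = "gating_params")
}

#' Drug binding parameters (modulated-receptor model)
#'
#' The drug binds the resting (closed) state with dissociation constant
#' `k_r` and the fast- and slow-inactivated states with `k_i`; there is no
#' binding edge to the open state. A single association rate `k_on` is
#' shared by all binding edges, so the unbinding rates are `k_on * k_r`
#' from the bound-closed state and `k_on * k_i` from the bound-inactivated
#' states.
#'
#' @param k_r Resting-state dissociation constant (micromolar, > 0).
#' @param k_i Inactivated-state dissociation constant (micromolar, > 0).
#' @param k_on Association rate constant (1 / (micromolar * second), > 0).
#'
#' @return An object of class `drug_params`.
#' @export
#' @examples
#' d <- drug_params()
#' d$k_r / d$k_i   # fold preference for inactivated states
drug_params <- function(k_r = 108, k_i = 3.6, k_on = 0.002) {
  stopifnot(k_r > 0, k_i > 0, k_on > 0)
  structure(list(k_r = k_r, k_i = k_i, k_on = k_on,
                 k_off_r = k_on * k_r, k_off_i = k_on * k_i),
            class = "drug_params")
}

#' Cell-level recording parameters
#'
#' Template describing one recorded cell: maximal conductance, membrane
#' capacitance, sodium reversal potential, and the observation model
#' (multiplicative peak noise and slow rundown). `g_max_cv` and `cap_cv`
#' are the between-cell coefficients of variation used by
#' [generate_dataset()] when many cells are drawn from this template.
#'
#' @param g_max Maximal conductance (nS, > 0).
#' @param capacitance Membrane capacitance (pF, > 0).
#' @param e_na Sodium reversal potential (mV); the default is the Nernst
#'   potential for 145 mM external / 10 mM internal sodium at 22 C.
#' @param peak_noise_sigma Multiplicative Gaussian noise SD on peaks
#'   (fraction, >= 0).
#' @param rundown_rate Rundown rate (fraction per minute, >= 0).
#' @param g_max_cv,cap_cv Between-cell coefficients of variation.
#' @param seed Integer seed for cell-level draws.
#'
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(g_max = 50, capacitance = 15, e_na = 68,
                        peak_noise_sigma = 0.05, rundown_rate = 0.01,
                        g_max_cv = 0.25, cap_cv = 0.15, seed = 1L) {
  stopifnot(g_max > 0, capacitance > 0, is.finite(e_na),
            peak_noise_sigma >= 0, rundown_rate >= 0,
            g_max_cv >= 0, cap_cv >= 0)
  structure(list(g_max = g_max, capacitance = capacitance, e_na = e_na,
                 peak_noise_sigma = peak_noise_sigma,
                 rundown_rate = rundown_rate,
                 g_max_cv = g_max_cv, cap_cv = cap_cv,
                 seed = as.integer(seed)),
            class = "cell_params")
}

#' @export
print.gating_params <- function(x, ...) {
  cat("Nav gating parameters\n")
  cat(sprintf("  activation:   V1/2 = %g mV, slope = %g mV, base rate = %g /ms\n",
              x$act_v_half, x$act_slope, x$r_act))
  cat(sprintf("  inactivation: V1/2 = %g mV, slope = %g mV, base rate = %g /ms\n",
              x$ssi_v_half, x$ssi_slope, x$r_ssi))
  cat(sprintf("  open -> IF: %g /ms;  IF <-> IS: %g / %g /ms;  rate cap %g /ms\n",
              x$k_oi, x$k_fs, x$k_sf, x$rate_cap))
  invisible(x)
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("Drug parameters: K_R = %g uM, K_I = %g uM (%.1f-fold), k_on = %g /(uM*s)\n",
              x$k_r, x$k_i, x$k_r / x$k_i, x$k_on))
  invisible(x)
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(
    "Cell template: g_max = %g nS (CV %g), C_m = %g pF, E_Na = %g mV\n",
    x$g_max, x$g_max_cv, x$capacitance, x$e_na))
  cat(sprintf("  peak noise sigma = %g, rundown = %g/min, seed = %d\n",
              x$peak_noise_sigma, x$rundown_rate, x$seed))
  invisible(x)
}
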