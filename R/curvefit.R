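# Fitting primitives: Hill-Langmuir, Boltzmann, mono-/bi-exponential.
#
# All fitters share one engine: bounded Levenberg-Marquardt least squares
# (minpack.lm) started from a fixed grid of initial values. The best
# residual wins; exact ties are broken by the lexicographically smallest
# parameter vector, so a fit is a deterministic function of its inputs.

ls_engine <- function(resid_fn, starts, lower, upper) {
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                     maxiter = 400)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(s, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-14 ||
        (abs(ssr - best$ssr) <= 1e-14 &&
         isTRUE(lex_less(fit$par, best$par)))) {
      best <- list(par = fit$par, ssr = ssr, fvec = fit$fvec)
    }
  }
  if (is.null(best)) stop("least-squares fit failed from every start")
  best$se <- param_se(resid_fn, best$par, best$ssr)
  best
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-15) return(TRUE)
    if (a[i] > b[i] + 1e-15) return(FALSE)
  }
  FALSE
}

# standard errors from the Jacobian at the optimum
param_se <- function(resid_fn, par, ssr) {
  n <- length(resid_fn(par)); p <- length(par)
  if (n <= p) return(rep(NA_real_, p))
  J <- matrix(0, n, p)
  for (j in seq_len(p)) {
    h <- max(1e-7, abs(par[j]) * 1e-7)
    J[, j] <- (resid_fn(par + h * (seq_len(p) == j)) -
               resid_fn(par - h * (seq_len(p) == j))) / (2 * h)
  }
  s2 <- ssr / (n - p)
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov)) rep(NA_real_, p) else sqrt(pmax(diag(cov), 0))
}

#' Hill-Langmuir concentration-response fit
#'
#' Fits normalised inhibition `Y = C^h / (IC50^h + C^h)` by bounded least
#' squares (IC50 in `(1e-3, 1e5)` micromolar, Hill coefficient `h` in
#' `[0.3, 3]`). If every response is indistinguishable from zero (maximum
#' below 0.05) no fit is attempted and a no-inhibition flag is returned
#' instead, mirroring the treatment of conditions without discernible
#' block.
#'
#' @param conc Concentrations, micromolar (zeros are ignored for fitting).
#' @param response Normalised inhibition fractions in `[-0.2, 1.2]`.
#' @param fix_slope Optional fixed Hill coefficient (e.g. 1, the classical
#'   choice when the top of the curve is poorly constrained).
#' @return An object of class `hill_fit`: `ic50`, `hill`, `slope_fixed`,
#'   standard errors, residual sum of squares, and `no_inhibition`.
#' @export
#' @examples
#' cc <- c(1, 3, 10, 30, 100)
#' fit_hill(cc, cc / (cc + 6.7))   # recovers IC50 = 6.7, h = 1
fit_hill <- function(conc, response, fix_slope = NULL) {
  stopifnot(length(conc) == length(response))
  ok <- is.finite(conc) & is.finite(response) & conc > 0
  conc <- conc[ok]; response <- response[ok]
  if (any(response < -0.2 | response > 1.2)) {
    stop("responses must lie in [-0.2, 1.2]")
  }
  if (max(response) < 0.05) {
    return(hill_no_inhibition(length(conc), !is.null(fix_slope)))
  }
  ndist <- length(unique(conc))
  need <- if (is.null(fix_slope)) 3 else 2
  if (ndist < need) {
    stop("need at least ", need, " distinct positive concentrations, got ",
         ndist)
  }
  lg <- log10(range(conc))
  ic_starts <- 10^seq(lg[1] - 1, lg[2] + 1, length.out = 7)
  if (is.null(fix_slope)) {
    resid <- function(p) response - conc^p[2] / (p[1]^p[2] + conc^p[2])
    starts <- unlist(lapply(ic_starts, function(ic) {
      lapply(c(0.5, 1, 2), function(h) c(ic, h))
    }), recursive = FALSE)
    best <- ls_engine(resid, starts, lower = c(1e-3, 0.3),
                      upper = c(1e5, 3))
    ic50 <- best$par[1]; hill <- best$par[2]
    se <- best$se
  } else {
    h <- fix_slope
    resid <- function(p) response - conc^h / (p[1]^h + conc^h)
    best <- ls_engine(resid, as.list(ic_starts), lower = 1e-3, upper = 1e5)
    ic50 <- best$par[1]; hill <- h
    se <- c(best$se, NA_real_)
  }
  structure(list(ic50 = ic50, hill = hill,
                 slope_fixed = !is.null(fix_slope),
                 se_ic50 = se[1], se_hill = se[2],
                 ssr = best$ssr, n = length(conc), no_inhibition = FALSE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$no_inhibition) {
    cat("<hill_fit> no inhibition (all responses < 5%)\n")
  } else {
    cat(sprintf("<hill_fit> IC50 = %.3g uM (SE %.2g), h = %.3g%s, n = %d\n",
                x$ic50, x$se_ic50, x$hill,
                if (x$slope_fixed) " [fixed]" else "", x$n))
  }
  invisible(x)
}

hill_no_inhibition <- function(n, slope_fixed = FALSE) {
  structure(list(ic50 = NA_real_, hill = NA_real_, slope_fixed = slope_fixed,
                 se_ic50 = NA_real_, se_hill = NA_real_, ssr = NA_real_,
                 n = n, no_inhibition = TRUE),
            class = "hill_fit")
}

#' Test for the no-inhibition flag on a fit
#' @param fit A `hill_fit` or `exp_fit` object.
#' @export
is_no_inhibition <- function(fit) isTRUE(fit$no_inhibition)

#' Boltzmann fit of a voltage dependence
#'
#' Fits `y = A / (1 + exp(s (v - V1/2) / k))` with `s = +1` for
#' inactivation (availability decreasing with depolarisation) and
#' `s = -1` for activation. The reported slope `k` is always positive;
#' the direction carries the sign convention.
#'
#' @param v Membrane potentials, mV (>= 4 points spanning the transition).
#' @param y Normalised amplitudes.
#' @param direction `"inactivation"` or `"activation"`.
#' @param floor `"zero"` (classical two-state Boltzmann, default) or
#'   `"free"`: fit a non-zero lower asymptote, needed when a fraction of
#'   channels never enters the probed inactivated state (e.g. slow
#'   inactivation availability curves that saturate above zero).
#' @return An object of class `boltzmann_fit`: `v_half`, `k`, `amplitude`,
#'   `floor`, `direction`, standard errors, `ssr`.
#' @export
#' @examples
#' v <- seq(-120, -40, 5)
#' fit_boltzmann(v, 1 / (1 + exp((v + 80) / 8)), "inactivation")
fit_boltzmann <- function(v, y, direction = c("inactivation", "activation"),
                          floor = c("zero", "free")) {
  direction <- match.arg(direction)
  floor <- match.arg(floor)
  stopifnot(length(v) == length(y))
  ok <- is.finite(v) & is.finite(y)
  v <- v[ok]; y <- y[ok]
  if (length(v) < 4 + (floor == "free")) {
    stop("need at least ", 4 + (floor == "free"),
         " points for this Boltzmann fit")
  }
  sgn <- if (direction == "inactivation") 1 else -1
  amp0 <- max(abs(y))
  free_floor <- floor == "free"
  resid <- function(p) {
    f0 <- if (free_floor) p[4] else 0
    y - (f0 + (p[1] - f0) / (1 + exp(sgn * (v - p[2]) / p[3])))
  }
  starts <- list()
  for (vh in quantile(v, c(0.25, 0.5, 0.75), names = FALSE)) {
    for (k in c(4, 8, 15)) {
      s <- c(amp0, vh, k)
      if (free_floor) s <- c(s, min(y))
      starts[[length(starts) + 1]] <- s
    }
  }
  lower <- c(0.1 * amp0, min(v) - 30, 0.5)
  upper <- c(3 * amp0, max(v) + 30, 30)
  if (free_floor) {
    lower <- c(lower, -0.5 * amp0); upper <- c(upper, amp0)
  }
  best <- ls_engine(resid, starts, lower = lower, upper = upper)
  # the constant model is nested in the Boltzmann, so demand a meaningful
  # improvement over it rather than a bare inequality
  ssr_const <- sum((y - mean(y))^2)
  if (best$ssr > 0.95 * ssr_const) {
    stop("input is not sigmoidal: Boltzmann fit is no better than a constant")
  }
  structure(list(amplitude = best$par[1], v_half = best$par[2],
                 k = best$par[3],
                 floor = if (free_floor) best$par[4] else 0,
                 direction = direction,
                 se_amplitude = best$se[1], se_v_half = best$se[2],
                 se_k = best$se[3],
                 se_floor = if (free_floor) best$se[4] else NA_real_,
                 ssr = best$ssr, n = length(v)),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit: %s> V1/2 = %.2f mV (SE %.2g), k = %.2f mV, A = %.3g\n",
    x$direction, x$v_half, x$se_v_half, x$k, x$amplitude))
  invisible(x)
}

#' Predict from a Boltzmann fit
#' @param object A `boltzmann_fit`.
#' @param v Voltages, mV.
#' @param ... Unused.
#' @export
predict.boltzmann_fit <- function(object, v, ...) {
  sgn <- if (object$direction == "inactivation") 1 else -1
  f0 <- object$floor %||% 0
  f0 + (object$amplitude - f0) /
    (1 + exp(sgn * (v - object$v_half) / object$k))
}

#' Mono-exponential time-course fit
#'
#' Fits `Y = (Y0 - Plateau) exp(-K t) + Plateau`; `tau = 1/K` is the
#' observed time constant (for drug-block time courses, the equilibration
#' time constant).
#'
#' @param t Times (s), strictly increasing, >= 4 points.
#' @param y Values.
#' @return An object of class `exp_fit`: `y0`, `plateau`, `k` (1/s),
#'   `tau` (s), standard errors, `ssr`.
#' @export
fit_monoexp <- function(t, y) {
  stopifnot(length(t) == length(y))
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 4) stop("need at least 4 points")
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  if (sd(y) == 0) stop("constant series: rate constant is unidentifiable")
  span <- diff(range(t[t > min(t)]))
  ks <- 10^seq(log10(0.1 / max(diff(range(t)), 1e-9)),
               log10(50 / max(min(diff(t)), 1e-9)), length.out = 8)
  resid <- function(p) y - ((p[1] - p[2]) * exp(-p[3] * t) + p[2])
  starts <- lapply(ks, function(k) c(y[1], y[length(y)], k))
  best <- ls_engine(resid, starts,
                    lower = c(-Inf, -Inf, 1e-9), upper = c(Inf, Inf, 1e9))
  if (abs(best$par[1] - best$par[2]) < 1e-12 * max(1, abs(best$par[1]))) {
    stop("no resolvable decay: Y0 and plateau coincide")
  }
  structure(list(y0 = best$par[1], plateau = best$par[2], k = best$par[3],
                 tau = 1 / best$par[3],
                 se_y0 = best$se[1], se_plateau = best$se[2],
                 se_k = best$se[3], ssr = best$ssr, n = length(t),
                 no_inhibition = FALSE),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> Y0 = %.3g, plateau = %.3g, K = %.3g /s (tau = %.3g s)\n",
              x$y0, x$plateau, x$k, x$tau))
  invisible(x)
}

#' Bi-exponential time-course fit
#'
#' Fits `Y = Plateau + SpanFast exp(-KFast t) + SpanSlow exp(-KSlow t)`
#' with `SpanFast = (Y0 - Plateau) PercentFast / 100` and
#' `SpanSlow = (Y0 - Plateau)(100 - PercentFast) / 100`, so the value at
#' `t = 0` is exactly `Y0`. `k_fast >= k_slow` is enforced by relabelling.
#' If the two rates collapse (ratio < 2) or one span vanishes, the fit is
#' returned with `percent_fast` at the boundary and `degenerate = TRUE`.
#'
#' @param t Times (s), >= 6 points spanning at least one decade.
#' @param y Values.
#' @return An object of class `biexp_fit`: `y0`, `plateau`,
#'   `percent_fast`, `k_fast`, `k_slow`, derived `span_fast`/`span_slow`,
#'   standard errors, `ssr`, `degenerate`.
#' @export
fit_biexp <- function(t, y) {
  stopifnot(length(t) == length(y))
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 6) stop("need at least 6 points")
  tp <- t[t > 0]
  if (length(tp) < 2 || max(tp) / min(tp) < 10) {
    stop("time points must span at least one decade")
  }
  model <- function(p, t) {
    sf <- (p[1] - p[2]) * p[3] / 100
    ss <- (p[1] - p[2]) * (100 - p[3]) / 100
    p[2] + sf * exp(-p[4] * t) + ss * exp(-p[5] * t)
  }
  resid <- function(p) y - model(p, t)
  kmid <- 1 / stats::median(tp)
  starts <- list()
  for (ka in kmid * c(0.3, 1, 3)) {
    for (ratio in c(10, 100)) {
      for (pf in c(30, 70)) {
        starts[[length(starts) + 1]] <-
          c(y[1], y[length(y)], pf, ka * sqrt(ratio), ka / sqrt(ratio))
      }
    }
  }
  best <- ls_engine(resid, starts,
                    lower = c(-Inf, -Inf, 0, 1e-9, 1e-9),
                    upper = c(Inf, Inf, 100, 1e9, 1e9))
  p <- best$par
  if (p[4] < p[5]) {  # relabel so k_fast >= k_slow
    p <- c(p[1], p[2], 100 - p[3], p[5], p[4])
    best$se <- best$se[c(1, 2, 3, 5, 4)]
  }
  degenerate <- p[4] / p[5] < 2 || p[3] <= 1 || p[3] >= 99
  if (degenerate) p[3] <- if (p[3] > 50) 100 else 0
  span <- p[1] - p[2]
  structure(list(y0 = p[1], plateau = p[2], percent_fast = p[3],
                 k_fast = p[4], k_slow = p[5],
                 span_fast = span * p[3] / 100,
                 span_slow = span * (100 - p[3]) / 100,
                 se = setNames(best$se, c("y0", "plateau", "percent_fast",
                                          "k_fast", "k_slow")),
                 ssr = best$ssr, n = length(t), degenerate = degenerate),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "<biexp_fit> Y0 = %.3g, plateau = %.3g, %%fast = %.1f, Kfast = %.3g /s, Kslow = %.3g /s%s\n",
    x$y0, x$plateau, x$percent_fast, x$k_fast, x$k_slow,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Reversal potential from an IV relationship
#'
#' Zero-crossing voltage by linear interpolation between the two IV points
#' bracketing the sign change of the peak current.
#'
#' @param iv A data frame with columns `step_mV` and `peak_pA` (an IV
#'   table from the activation protocol).
#' @return Reversal potential, mV.
#' @seealso [nernst_potential()] for the fallback when the IV does not
#'   reach reversal.
#' @export
estimate_reversal <- function(iv) {
  stopifnot(all(c("step_mV", "peak_pA") %in% names(iv)))
  iv <- iv[order(iv$step_mV), ]
  v <- iv$step_mV; i <- iv$peak_pA
  z <- which(i == 0)
  if (length(z)) return(v[z[1]])
  cross <- which(i[-length(i)] * i[-1] < 0)
  if (!length(cross)) {
    stop("IV has no zero crossing; use nernst_potential() as a fallback")
  }
  k <- cross[1]
  v[k] - i[k] * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
}

#' Nernst equilibrium potential for sodium
#'
#' @param na_out,na_in External and internal sodium concentrations (mM);
#'   defaults are the standard recording solutions (145 / 10 mM).
#' @param temp_c Temperature, Celsius.
#' @return Potential, mV.
#' @export
#' @examples
#' nernst_potential()   # ~ +68 mV at 22 C
nernst_potential <- function(na_out = 145, na_in = 10, temp_c = 22) {
  stopifnot(na_out > 0, na_in > 0)
  1000 * 8.314462618 * (temp_c + 273.15) / 96485.33212 * log(na_out / na_in)
}

#' Conductance transform of an IV relationship
#'
#' `G = I / (V - E_Na)` per record; records within 2 mV of the reversal
#' potential are excluded (flagged), where the transform is singular.
#' Units: pA / mV = nS.
#'
#' @param iv A data frame with columns `step_mV` and `peak_pA`.
#' @param e_na Reversal potential, mV (finite).
#' @return The input with added columns `g_nS` (NA where excluded) and
#'   `excluded`.
#' @export
conductance_from_iv <- function(iv, e_na) {
  stopifnot(is.finite(e_na), all(c("step_mV", "peak_pA") %in% names(iv)))
  excl <- abs(iv$step_mV - e_na) < 2
  g <- ifelse(excl, NA_real_, iv$peak_pA / (iv$step_mV - e_na))
  dplyr::mutate(tibble::as_tibble(iv), g_nS = g, excluded = excl)
}
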