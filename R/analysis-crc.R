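# Concentration-response construction from use-dependence pulse trains and
# the four-state (modulated-receptor) fit resolving K_R and K_I.

#' Concentration-response curves from state-dependence pulse trains
#'
#' For every holding-potential interval, pools the inhibition at the first
#' and at the last pulse across cells (each cell carries a single drug
#' concentration) and attaches a Hill fit per curve. Peaks are normalised
#' per cell to the first pulse of the first interval, then divided by the
#' mean vehicle time course at the matching pulse to remove rundown and
#' accumulated gating effects shared by both arms; inhibition is
#' `1 - normalised ratio`.
#'
#' Slope handling follows common practice: the Hill coefficient is free by
#' default, but if its relative standard error exceeds
#' `fix_slope_rse` (50%) the curve is refitted with the slope fixed to 1.
#' Curves whose largest pooled inhibition is below 5% get a no-inhibition
#' flag instead of a fit.
#'
#' @param records Peak-record tibble with state-dependence rows including
#'   a vehicle arm (`conc_uM == 0`).
#' @param fix_slope_rse Relative-standard-error threshold above which the
#'   Hill slope is fixed to 1.
#' @param equilibrium_pulses Number of final pulses averaged per cell for
#'   the "last" (equilibrium) response. By the end of a 180-pulse train
#'   the block time course is flat, so a short terminal average estimates
#'   the same equilibrium with less measurement noise; the default 3
#'   matches the convention of taking the mean of the last three points of
#'   an equilibrated time course. Set to 1 to use pulse 180 alone.
#' @return An object of class `conc_response`: `table` (pooled inhibition
#'   per holding potential, pulse selector and concentration) and `fits`
#'   (`fits[[holding]][[c("first", "last")]]`).
#' @export
build_concentration_response <- function(records, fix_slope_rse = 0.5,
                                         equilibrium_pulses = 3) {
  sd_rec <- dplyr::filter(records, .data$protocol == "state_dependence")
  if (!nrow(sd_rec)) stop("no state-dependence records")
  if (!any(sd_rec$conc_uM == 0)) {
    stop("vehicle arm (conc 0) required for normalisation")
  }
  last_pulse <- max(sd_rec$pulse_number)
  if (last_pulse == 1) {
    stop("missing first or last pulse: records contain a single pulse ",
         "per interval")
  }
  have <- dplyr::summarise(
    dplyr::group_by(sd_rec, .data$cell_id, .data$interval_index),
    ok = any(.data$pulse_number == 1) && any(.data$pulse_number == last_pulse),
    .groups = "drop")
  if (!all(have$ok)) {
    bad <- have[!have$ok, ]
    stop("missing first or last pulse for cell ", bad$cell_id[1],
         ", interval ", bad$interval_index[1])
  }

  npool <- max(1, min(equilibrium_pulses, last_pulse - 1))
  sel <- dplyr::filter(sd_rec, .data$pulse_number == 1 |
                         .data$pulse_number > last_pulse - npool)
  sel$pulse <- ifelse(sel$pulse_number == 1, "first", "last")
  ref <- dplyr::summarise(
    dplyr::group_by(sd_rec, .data$cell_id),
    ref = .data$peak_pA[.data$interval_index == 1 & .data$pulse_number == 1][1],
    .groups = "drop")
  sel <- dplyr::left_join(sel, ref, by = "cell_id")

  # per cell, interval and selector: mean normalised response
  cellm <- dplyr::summarise(
    dplyr::group_by(sel, .data$conc_uM, .data$cell_id, .data$holding_mV,
                    .data$interval_index, .data$pulse),
    norm = mean(.data$peak_pA / .data$ref), .groups = "drop")

  veh <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(cellm, .data$conc_uM == 0),
                    .data$interval_index, .data$pulse),
    veh_norm = mean(.data$norm), .groups = "drop")
  drg <- dplyr::left_join(dplyr::filter(cellm, .data$conc_uM > 0), veh,
                          by = c("interval_index", "pulse"))
  drg$inhibition <- pmin(pmax(1 - drg$norm / drg$veh_norm, -0.2), 1.2)

  table <- dplyr::summarise(
    dplyr::group_by(drg, .data$holding_mV, .data$pulse, .data$conc_uM),
    inhibition = mean(.data$inhibition), sd = sd(.data$inhibition),
    n = dplyr::n(), .groups = "drop")

  fits <- list()
  for (hp in sort(unique(table$holding_mV))) {
    fits[[as.character(hp)]] <- list()
    for (pl in c("first", "last")) {
      sub <- dplyr::filter(table, .data$holding_mV == hp, .data$pulse == pl)
      if (!nrow(sub)) {
        fits[[as.character(hp)]][pl] <- list(NULL)
        next
      }
      ncc <- length(unique(sub$conc_uM[sub$conc_uM > 0]))
      fit <- if (max(sub$inhibition) < 0.05) {
        hill_no_inhibition(nrow(sub))
      } else if (ncc >= 3) {
        f <- fit_hill(sub$conc_uM, sub$inhibition)
        # slope-fixing rule: fall back to h = 1 when the free slope is
        # poorly determined
        if (!is_no_inhibition(f) &&
            (!is.finite(f$se_hill) || f$se_hill / f$hill > fix_slope_rse)) {
          f <- fit_hill(sub$conc_uM, sub$inhibition, fix_slope = 1)
        }
        f
      } else if (ncc == 2) {
        fit_hill(sub$conc_uM, sub$inhibition, fix_slope = 1)
      } else {
        NULL   # a single concentration cannot constrain an IC50
      }
      fits[[as.character(hp)]][[pl]] <- fit
    }
  }
  structure(list(table = table, fits = fits, last_pulse = last_pulse),
            class = "conc_response")
}

#' @export
print.conc_response <- function(x, ...) {
  cat("<conc_response> apparent IC50s (last pulse):\n")
  for (hp in names(x$fits)) {
    f <- x$fits[[hp]]$last
    if (is.null(f) || is_no_inhibition(f)) {
      cat(sprintf("  %s mV: no inhibition\n", hp))
    } else {
      cat(sprintf("  %s mV: IC50 = %.3g uM (h = %.2f%s)\n", hp, f$ic50,
                  f$hill, if (f$slope_fixed) ", fixed" else ""))
    }
  }
  invisible(x)
}

#' Apparent IC50s per holding potential from a concentration-response set
#'
#' @param cr A `conc_response` object.
#' @param pulse `"last"` (default) or `"first"`.
#' @return A tibble with `holding_mV`, `ic50_uM`, `hill`, `no_inhibition`.
#' @export
apparent_ic50s <- function(cr, pulse = "last") {
  stopifnot(inherits(cr, "conc_response"))
  rows <- lapply(names(cr$fits), function(hp) {
    f <- cr$fits[[hp]][[pulse]]
    none <- is.null(f) || is_no_inhibition(f)
    tibble::tibble(holding_mV = as.numeric(hp),
                   ic50_uM = if (none) NA_real_ else f$ic50,
                   hill = if (none) NA_real_ else f$hill,
                   no_inhibition = none)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$holding_mV)
}

#' Four-state binding-model fit of apparent IC50 versus availability
#'
#' In the modulated-receptor framework the inverse apparent IC50 at a
#' holding potential is a mixture of the resting- and inactivated-state
#' affinities weighted by availability `h(V)`:
#' `1 / IC50(V) = h(V) / K_R + (1 - h(V)) / K_I`.
#' Given apparent IC50s at two or more voltages and an availability curve
#' (typically the vehicle SSI Boltzmann), the model is linear in
#' `(1/K_R, 1/K_I)` and is solved in closed form by least squares, with
#' non-negativity enforced by boundary refits.
#'
#' Because fitted IC50s are log-normally distributed (multiplicative
#' errors) and span more than a decade across holding potentials, the
#' default weighting minimises the *relative* misfit of the inverse IC50s
#' (`weights = "relative"`, i.e. weight `IC50^2` on the `1/IC50` scale);
#' `weights = "absolute"` gives the unweighted fit, and a numeric vector
#' gives full control.
#'
#' Voltages with a no-inhibition flag are excluded by default; with
#' `censored = TRUE` they are instead treated as `IC50 >= max tested
#' concentration` (entered at that bound).
#'
#' @param ic50_by_voltage Named numeric vector (names = holding potentials
#'   in mV) or a tibble with `holding_mV` and `ic50_uM` (optionally
#'   `no_inhibition`).
#' @param availability_fit A `boltzmann_fit` of the vehicle steady-state
#'   inactivation curve (its normalised value supplies `h(V)`), or a
#'   function of voltage returning availability.
#' @param censored If `TRUE`, no-inhibition voltages enter at
#'   `censor_value` instead of being dropped.
#' @param censor_value IC50 bound used for censored voltages, micromolar.
#' @param weights `"relative"` (default), `"absolute"`, or a numeric
#'   vector of weights on the `1/IC50` scale (one per retained voltage).
#' @return An object of class `state_dependence_fit`: `k_r`, `k_i`,
#'   `fold_preference`, `voltages`, `availability`, `residuals`,
#'   `boundary` flag.
#' @export
#' @examples
#' h <- function(v) 1 / (1 + exp((v + 80) / 8))
#' v <- c(-110, -100, -90, -80)
#' ic <- 1 / (h(v) / 108 + (1 - h(v)) / 3.6)
#' fit_four_state(setNames(ic, v), h)   # recovers K_R = 108, K_I = 3.6
fit_four_state <- function(ic50_by_voltage, availability_fit,
                           censored = FALSE, censor_value = NULL,
                           weights = c("relative", "absolute")) {
  if (is.data.frame(ic50_by_voltage)) {
    v <- ic50_by_voltage$holding_mV
    ic <- ic50_by_voltage$ic50_uM
    flag <- ic50_by_voltage$no_inhibition %||% rep(FALSE, length(ic))
  } else {
    v <- as.numeric(names(ic50_by_voltage))
    ic <- as.numeric(ic50_by_voltage)
    flag <- !is.finite(ic)
  }
  if (censored) {
    if (is.null(censor_value)) stop("censored mode needs a censor_value")
    ic[flag] <- censor_value
    flag[] <- FALSE
  }
  keep <- !flag & is.finite(ic)
  v <- v[keep]; ic <- ic[keep]
  if (length(v) < 2) stop("need apparent IC50s at >= 2 voltages")
  h <- if (is.function(availability_fit)) {
    availability_fit(v)
  } else if (inherits(availability_fit, "boltzmann_fit")) {
    predict(availability_fit, v) / availability_fit$amplitude
  } else stop("availability_fit must be a boltzmann_fit or a function")
  if (diff(range(h)) < 1e-9) {
    stop("availability is identical at all voltages; K_R and K_I are not ",
         "separately identifiable")
  }
  y <- 1 / ic
  X <- cbind(rest = h, inact = 1 - h)
  w <- if (is.numeric(weights)) {
    if (length(weights) != length(y)) {
      stop("numeric weights must have one entry per retained voltage")
    }
    weights
  } else if (match.arg(weights) == "relative") ic^2 else rep(1, length(y))
  sw <- sqrt(w)
  b <- as.numeric(qr.solve(X * sw, y * sw))
  boundary <- FALSE
  if (any(b <= 0)) {
    boundary <- TRUE
    b1 <- c(sum(w * X[, 1] * y) / sum(w * X[, 1]^2), 0)  # inactivated arm off
    b2 <- c(0, sum(w * X[, 2] * y) / sum(w * X[, 2]^2))  # resting arm off
    ss1 <- sum(w * (y - X %*% b1)^2); ss2 <- sum(w * (y - X %*% b2)^2)
    b <- if (ss1 <= ss2) pmax(b1, 0) else pmax(b2, 0)
  }
  k_r <- if (b[1] > 0) 1 / b[1] else Inf
  k_i <- if (b[2] > 0) 1 / b[2] else Inf
  structure(list(k_r = k_r, k_i = k_i, fold_preference = k_r / k_i,
                 voltages = v, availability = h,
                 ic50_uM = ic, residuals = as.numeric(y - X %*% b),
                 boundary = boundary, censored = censored),
            class = "state_dependence_fit")
}

#' @export
print.state_dependence_fit <- function(x, ...) {
  cat(sprintf(
    "<state_dependence_fit> K_R = %.3g uM, K_I = %.3g uM, fold = %.3g%s\n",
    x$k_r, x$k_i, x$fold_preference,
    if (x$boundary) " [boundary]" else ""))
  cat("  voltages:", paste(x$voltages, collapse = ", "), "mV\n")
  invisible(x)
}

#' Equilibrium inhibition predicted from an apparent IC50
#'
#' The Hill-Langmuir prediction with unit slope:
#' `inhibition = conc / (conc + ic50)`.
#'
#' @param ic50 Apparent IC50, micromolar (> 0).
#' @param conc Concentration, micromolar (>= 0).
#' @export
#' @examples
#' predict_equilibrium_inhibition(96.5, 30)   # ~0.237
predict_equilibrium_inhibition <- function(ic50, conc) {
  stopifnot(ic50 > 0, all(conc >= 0))
  conc / (conc + ic50)
}
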