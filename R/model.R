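#' State labels of the channel + drug Markov model
#'
#' Seven states: closed (`C`), open (`O`), fast-inactivated (`IF`),
#' slow-inactivated (`IS`), and the drug-bound counterparts of the
#' non-conducting states (`CB`, `IFB`, `ISB`). There is no drug-bound open
#' state: the model encodes a compound that interacts with resting and
#' inactivated conformations only.
#'
#' @export
nav_states <- c("C", "O", "IF", "IS", "CB", "IFB", "ISB")

#' Equilibrium channel availability at a voltage
#'
#' The closed/fast-inactivated equilibrium of the gating model is exactly
#' Boltzmann: `1 / (1 + exp((v - ssi_v_half) / ssi_slope))`, decreasing
#' with depolarisation.
#'
#' @param gating A [gating_params()] object.
#' @param v Membrane potential(s), mV.
#' @return Availability fraction(s) in (0, 1).
#' @export
#' @examples
#' steady_state_availability(gating_params(), -100)  # ~0.924
steady_state_availability <- function(gating, v) {
  stopifnot(inherits(gating, "gating_params"))
  1 / (1 + exp((v - gating$ssi_v_half) / gating$ssi_slope))
}

#' Apparent IC50 predicted by the four-state binding model
#'
#' With availability `h` (fraction of channels in the resting state) and
#' state dissociation constants `K_R` and `K_I`, the equilibrium apparent
#' IC50 is `1 / (h / K_R + (1 - h) / K_I)`; it interpolates between `K_I`
#' (all channels inactivated) and `K_R` (all at rest).
#'
#' @param drug A [drug_params()] object.
#' @param availability Resting fraction(s) in `[0, 1]`.
#' @return Apparent IC50(s), micromolar.
#' @export
#' @examples
#' equilibrium_apparent_ic50(drug_params(), 0.924)  # ~33.7 uM
equilibrium_apparent_ic50 <- function(drug, availability) {
  stopifnot(inherits(drug, "drug_params"))
  if (any(availability < 0 | availability > 1)) {
    stop("availability must lie in [0, 1]")
  }
  1 / (availability / drug$k_r + (1 - availability) / drug$k_i)
}

# Voltage-dependent rate pair with Boltzmann equilibrium: forward/backward
# rates share the midpoint and slope; if either uncapped rate exceeds the
# cap, both are scaled down jointly so the equilibrium is preserved.
rate_pair <- function(v, v_half, slope, base, cap) {
  f <- base * exp((v - v_half) / (2 * slope))
  b <- base * exp(-(v - v_half) / (2 * slope))
  s <- pmin(1, cap / pmax(f, b))
  c(forward = f * s, backward = b * s)
}

#' Generator matrix of the seven-state channel + drug model
#'
#' Columns are source states in the order of [nav_states]; entry `[j, i]`
#' is the transition rate (1/ms) from state `i` to state `j`, and each
#' column sums to zero. Drug binding edges (`C -> CB`, `IF -> IFB`,
#' `IS -> ISB`) carry rate `k_on * conc`; unbinding is `k_on * K_R` from
#' `CB` and `k_on * K_I` from `IFB`/`ISB`. Gating among bound states
#' mirrors the free states, with the closed/inactivated equilibrium
#' shifted by `K_R / K_I` so that every binding cycle satisfies
#' microscopic reversibility.
#'
#' @param gating A [gating_params()] object.
#' @param drug A [drug_params()] object.
#' @param v Membrane potential, mV.
#' @param conc Drug concentration, micromolar (>= 0).
#' @return A 7 x 7 generator matrix with `dimnames` [nav_states].
#' @export
rate_matrix <- function(gating, drug, v, conc) {
  stopifnot(inherits(gating, "gating_params"), inherits(drug, "drug_params"))
  if (conc < 0) stop("drug concentration must be >= 0")
  act <- rate_pair(v, gating$act_v_half, gating$act_slope, gating$r_act,
                   gating$rate_cap)
  inact <- rate_pair(v, gating$ssi_v_half, gating$ssi_slope, gating$r_ssi,
                     gating$rate_cap)
  shift <- sqrt(drug$k_r / drug$k_i)
  kon_ms <- drug$k_on / 1000 * conc       # k_on is per uM per second
  koff_r <- drug$k_on / 1000 * drug$k_r
  koff_i <- drug$k_on / 1000 * drug$k_i
  Q <- matrix(0, 7, 7, dimnames = list(nav_states, nav_states))
  add <- function(from, to, rate) Q[to, from] <<- Q[to, from] + rate
  add("C", "O", act[["forward"]]); add("O", "C", act[["backward"]])
  add("O", "IF", gating$k_oi)
  add("C", "IF", inact[["forward"]]); add("IF", "C", inact[["backward"]])
  add("IF", "IS", gating$k_fs); add("IS", "IF", gating$k_sf)
  add("C", "CB", kon_ms); add("CB", "C", koff_r)
  add("IF", "IFB", kon_ms); add("IFB", "IF", koff_i)
  add("IS", "ISB", kon_ms); add("ISB", "IS", koff_i)
  add("CB", "IFB", inact[["forward"]] * shift)
  add("IFB", "CB", inact[["backward"]] / shift)
  add("IFB", "ISB", gating$k_fs); add("ISB", "IFB", gating$k_sf)
  diag(Q) <- -colSums(Q)
  Q
}

#' Create a state occupancy vector
#'
#' @param occupancies Named or positional occupancies over [nav_states];
#'   must be non-negative and sum to 1 (tolerance 1e-10).
#' @return A named numeric vector of class `state_vector`.
#' @export
state_vector <- function(occupancies) {
  x <- rep(0, 7); names(x) <- nav_states
  if (!is.null(names(occupancies))) {
    bad <- setdiff(names(occupancies), nav_states)
    if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "))
    x[names(occupancies)] <- occupancies
  } else {
    stopifnot(length(occupancies) == 7)
    x[] <- occupancies
  }
  if (any(x < 0)) stop("occupancies must be non-negative")
  if (abs(sum(x) - 1) > 1e-10) stop("occupancies must sum to 1")
  structure(x, class = "state_vector")
}

#' Propagate a state vector under a constant generator
#'
#' Exact linear evolution `p(t) = expm(Q t) p(0)` for a constant-voltage
#' segment; no time stepping is involved. Tiny negative occupancies from
#' floating-point round-off (> -1e-12) are clamped to zero.
#'
#' @param state A [state_vector()] (or plain numeric of length 7).
#' @param matrix A generator matrix from [rate_matrix()].
#' @param duration Duration, ms (>= 0).
#' @return The propagated `state_vector`.
#' @export
propagate <- function(state, matrix, duration) {
  stopifnot(length(state) == 7, duration >= 0)
  if (any(!is.finite(matrix))) stop("generator matrix has non-finite entries")
  if (duration == 0) return(state_vector(as.numeric(state)))
  p <- as.numeric(Matrix::expm(matrix * duration) %*% as.numeric(state))
  if (any(p < -1e-9)) stop("propagation produced negative occupancies")
  state_vector(pmax(p, 0) / sum(pmax(p, 0)) * sum(p))
}

#' Equilibrium state distribution at a voltage and concentration
#'
#' Solves `Q p = 0`, `sum(p) = 1`. With `conc = 0` the bound occupancies
#' are exactly zero (the drug-free stationary distribution is selected).
#'
#' @inheritParams rate_matrix
#' @return A `state_vector`.
#' @export
equilibrium_state <- function(gating, drug, v, conc) {
  Q <- rate_matrix(gating, drug, v, conc)
  if (conc == 0) {
    # bound block is disconnected from the free block; restrict to free states
    Qf <- Q[1:4, 1:4]
    pf <- unname(qr.solve(rbind(Qf, rep(1, 4)), c(rep(0, 4), 1)))
    return(state_vector(c(pmax(pf, 0) / sum(pmax(pf, 0)), rep(0, 3))))
  }
  p <- unname(qr.solve(rbind(Q, rep(1, 7)), c(rep(0, 7), 1)))
  state_vector(pmax(p, 0) / sum(pmax(p, 0)))
}
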