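# Protocol runner: exact piecewise-constant propagation of the 7-state model.
#
# Within one run the drug concentration is fixed, so the generator depends
# only on the segment voltage; eigendecompositions are cached per voltage
# and reused across the (possibly thousands of) segments of a protocol.

eig_cache_new <- function() new.env(parent = emptyenv())

eig_for <- function(cache, gating, drug, v, conc) {
  key <- sprintf("v%.6g", v)
  e <- cache[[key]]
  if (is.null(e)) {
    Q <- rate_matrix(gating, drug, v, conc)
    ed <- eigen(Q)
    vinv <- tryCatch(solve(ed$vectors), error = function(e) NULL)
    e <- list(Q = Q, vec = ed$vectors, vinv = vinv, vals = ed$values,
              grids = new.env(parent = emptyenv()))
    cache[[key]] <- e
  }
  e
}

# state after `dur` ms at constant voltage
step_state <- function(e, state, dur) {
  if (is.null(e$vinv)) {
    return(as.numeric(Matrix::expm(e$Q * dur) %*% state))
  }
  c0 <- e$vinv %*% state
  p <- Re(e$vec %*% (c0 * exp(e$vals * dur)))[, 1]
  pmax(p, 0)
}

# evaluation grid for peak detection: dense where the transient lives,
# sparse over the remainder of the segment
peak_grid <- function(dur, blank) {
  g <- seq(blank, min(dur, 12), by = 0.05)
  if (dur > 12) g <- c(g, seq(14, min(dur, 40), by = 2))
  if (dur > 40) g <- c(g, seq(50, dur, by = 25))
  unique(c(g, dur))
}

# open-state occupancy on a time grid, plus end-of-segment state
segment_po <- function(e, state, tgrid, dur) {
  if (is.null(e$vinv)) {
    po <- vapply(tgrid, function(t) {
      as.numeric(Matrix::expm(e$Q * t) %*% state)[2]
    }, numeric(1))
    return(list(po = po, end = as.numeric(Matrix::expm(e$Q * dur) %*% state)))
  }
  c0 <- (e$vinv %*% state)[, 1]
  gk <- sprintf("g%.6g_%.6g", dur, length(tgrid))
  E <- e$grids[[gk]]
  if (is.null(E) || ncol(E) != length(tgrid)) {
    E <- exp(outer(e$vals, tgrid))
    e$grids[[gk]] <- E
  }
  po <- Re(colSums((c0 * e$vec[2, ]) * E))
  end <- pmax(Re(e$vec %*% (c0 * exp(e$vals * dur)))[, 1], 0)
  list(po = po, end = end)
}

#' Run a voltage-clamp protocol through the channel model
#'
#' Propagates the seven-state occupancy vector exactly (matrix
#' exponential per constant-voltage segment) through every sweep of a
#' protocol and records the peak current of each test segment. The current
#' is `g_max * P_O(t) * (V - e_na)` (pA, inward negative); the peak is the
#' extremum within the test segment after a capacitive blanking window.
#'
#' @param protocol A `nav_protocol` from [build_protocol()].
#' @param gating A [gating_params()] object.
#' @param drug A [drug_params()] object.
#' @param conc Drug concentration, micromolar.
#' @param cell A [cell_params()] object (conductance, capacitance,
#'   reversal potential; noise parameters are *not* applied here --
#'   [run_protocol()] is deterministic, [generate_dataset()] adds the
#'   observation model).
#' @param init Initial condition: `"equilibrated"` starts from the full
#'   equilibrium at the first holding level including drug (a recording
#'   begun after long compound exposure); `"naive"` starts from the
#'   drug-free gating equilibrium at the first holding level, i.e. the
#'   compound is applied at time zero (appropriate for use-dependence and
#'   block-kinetics protocols that time-resolve equilibration). `"auto"`
#'   (default) selects `"naive"` for `state_dependence` and `kinetics`
#'   protocols and `"equilibrated"` otherwise.
#' @param keep_traces If `TRUE`, the open-probability time course of every
#'   test segment is retained as a current trace sampled at the protocol's
#'   `sample_interval` (needed for open-state inactivation tau analysis).
#' @param blank_ms Capacitive blanking window at the start of each test
#'   segment, ms.
#' @param cell_id Identifier stored in the records.
#'
#' @return A list with `records` (a peak-record tibble, one row per test
#'   segment; see [generate_dataset()] for the schema), `traces` (`NULL`,
#'   or a list of tibbles `time_ms`/`current_pA` with sweep metadata as
#'   attributes) and `final_state` (the occupancy vector at protocol end).
#' @export
#' @examples
#' p <- build_protocol("activation")
#' out <- run_protocol(p, gating_params(), drug_params(), conc = 0)
#' out$records$step_mV[which.max(abs(out$records$peak_pA))]  # IV peak at -25
run_protocol <- function(protocol, gating = gating_params(),
                         drug = drug_params(), conc = 0,
                         cell = cell_params(),
                         init = c("auto", "equilibrated", "naive"),
                         keep_traces = FALSE, blank_ms = 0.5,
                         cell_id = "cell_1") {
  stopifnot(inherits(protocol, "nav_protocol"))
  init <- match.arg(init)
  if (init == "auto") {
    init <- if (protocol$kind %in% c("state_dependence", "kinetics")) {
      "naive"
    } else "equilibrated"
  }
  n_test <- sum(vapply(protocol$sweeps, function(s) {
    sum(s$segments$label == "test")
  }, numeric(1)))
  if (n_test == 0) stop("protocol contains no test segments")

  v0 <- protocol$sweeps[[1]]$meta$holding_potential
  if (is.null(v0) || is.na(v0)) v0 <- protocol$sweeps[[1]]$segments$level_mV[1]
  state <- as.numeric(
    equilibrium_state(gating, drug, v0, if (init == "naive") 0 else conc))

  cache <- eig_cache_new()
  nsw <- length(protocol$sweeps)
  peak <- numeric(nsw); elapsed <- numeric(nsw)
  traces <- if (keep_traces) vector("list", nsw) else NULL

  for (i in seq_len(nsw)) {
    sw <- protocol$sweeps[[i]]
    t_in_sweep <- 0
    for (k in seq_len(nrow(sw$segments))) {
      lev <- sw$segments$level_mV[k]
      dur <- sw$segments$duration_ms[k]
      e <- eig_for(cache, gating, drug, lev, conc)
      if (sw$segments$label[k] == "test") {
        tg <- if (keep_traces) {
          seq(0, dur, by = protocol$sample_interval)
        } else peak_grid(dur, blank_ms)
        res <- segment_po(e, state, tg, dur)
        drive <- lev - cell$e_na
        cur <- cell$g_max * res$po * drive
        sel <- tg >= blank_ms
        pk <- cur[sel][which.max(abs(cur[sel]))]
        peak[i] <- if (length(pk)) pk else 0
        elapsed[i] <- sw$start_time + t_in_sweep / 1000
        if (keep_traces) {
          tr <- tibble::tibble(time_ms = tg, current_pA = cur)
          attr(tr, "sweep_index") <- i
          attr(tr, "step_mV") <- lev
          attr(tr, "meta") <- sw$meta
          traces[[i]] <- tr
        }
        state <- res$end
      } else {
        state <- step_state(e, state, dur)
      }
      t_in_sweep <- t_in_sweep + dur
    }
  }

  meta_num <- function(field) {
    vapply(protocol$sweeps, function(s) {
      v <- s$meta[[field]]
      if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  records <- tibble::tibble(
    cell_id = cell_id,
    protocol = protocol$kind,
    holding_mV = meta_num("holding_potential"),
    step_mV = meta_num("step_voltage"),
    prepulse_ms = meta_num("prepulse_duration"),
    recovery_ms = meta_num("recovery_interval"),
    pulse_number = meta_num("pulse_number"),
    interval_index = meta_num("interval_index"),
    elapsed_s = elapsed,
    conc_uM = conc,
    peak_pA = peak,
    rm_MOhm = NA_real_,
    rs_MOhm = NA_real_,
    cap_pF = cell$capacitance)

  names(state) <- nav_states
  list(records = records,
       traces = if (keep_traces) traces[!vapply(traces, is.null, logical(1))],
       final_state = state)
}
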