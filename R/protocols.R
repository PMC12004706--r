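#' Voltage-clamp protocols as data objects
#'
#' `build_protocol()` constructs one of the six voltage-clamp protocols used
#' to characterise state-dependent Nav channel block. A protocol is an
#' ordered list of sweeps; each sweep is a contiguous sequence of
#' piecewise-constant voltage segments, exactly one of which is labelled
#' `test` (the segment in which the peak current is measured).
#'
#' Supported kinds and their defaults:
#'
#' * `activation`: 500 ms test steps from -120 to +25 mV in 5 mV
#'   increments from a -120 mV holding potential; 150 ms inter-sweep
#'   holding (a fast IV, as run on plate-based instruments).
#' * `ssi`: 500 ms prepulses from -120 to +25 mV in 5 mV increments,
#'   each followed by a 10 ms test pulse to -20 mV.
#' * `slow_ssi`: as `ssi` but with a long prepulse (`prepulse_duration_ms`
#'   of 1, 3, 5 or 10 s), a 100 ms recovery step at -120 mV that clears
#'   fast inactivation, then the 10 ms test pulse; 10 mV prepulse grid.
#' * `state_dependence`: four holding-potential intervals (-110, -100,
#'   -90, -80 mV), each an uninterrupted train of 180 x 20 ms
#'   depolarisations to 0 mV at 1 Hz, with a 10 s recovery step to
#'   -120 mV between intervals. Each interval opens with a short
#'   (`equilibration_ms`, default 200 ms) hold at the new potential --
#'   long enough for channel gating to settle, far too short for
#'   appreciable drug equilibration -- before the first pulse fires.
#' * `recovery`: conditioning prepulse to -20 mV (20, 500 or 5000 ms),
#'   recovery at -120 mV for each interval of a log-spaced ladder, then a
#'   10 ms test pulse to -20 mV.
#' * `kinetics`: one 20 ms pulse to -20 mV every 5 s for 3 min from a
#'   fixed holding potential, used to time-resolve drug equilibration.
#'
#' @param kind Protocol kind; one of `"activation"`, `"ssi"`,
#'   `"slow_ssi"`, `"state_dependence"`, `"recovery"`, `"kinetics"`.
#' @param ... Named overrides of the kind's documented parameters (see
#'   Details); unknown names are an error.
#' @param sample_interval Sampling interval in ms (default 0.04, i.e.
#'   25 kHz).
#'
#' @return An object of class `nav_protocol` with elements `kind`,
#'   `params` (fully resolved parameter list) and `sweeps`.
#' @seealso [enumerate_sweeps()], [protocol_sweep_table()],
#'   [run_protocol()]
#' @export
#' @examples
#' p <- build_protocol("activation")
#' length(p$sweeps)                      # 30 voltage steps
#' head(protocol_sweep_table(p))
build_protocol <- function(kind, ..., sample_interval = 0.04) {
  kinds <- c("activation", "ssi", "slow_ssi", "state_dependence",
             "recovery", "kinetics")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds) {
    stop("unknown protocol kind: ", deparse(substitute(kind)),
         "; must be one of ", paste(kinds, collapse = ", "))
  }
  defaults <- protocol_defaults(kind)
  overrides <- list(...)
  if (length(overrides) && is.null(names(overrides))) {
    stop("protocol overrides must be named")
  }
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop("unknown protocol parameter(s) for kind '", kind, "': ",
         paste(bad, collapse = ", "))
  }
  params <- modifyList(defaults, overrides)
  sweeps <- switch(kind,
    activation       = sweeps_activation(params),
    ssi              = sweeps_ssi(params),
    slow_ssi         = sweeps_slow_ssi(params),
    state_dependence = sweeps_state_dependence(params),
    recovery         = sweeps_recovery(params),
    kinetics         = sweeps_kinetics(params))
  if (!length(sweeps)) stop("protocol '", kind, "' resolved to an empty sweep list")
  for (sw in sweeps) {
    if (any(sw$segments$duration_ms <= 0)) {
      stop("protocol '", kind, "' contains a non-positive segment duration")
    }
    if (any(sw$segments$level_mV < -150 | sw$segments$level_mV > 80)) {
      stop("protocol '", kind, "' contains a voltage outside [-150, 80] mV")
    }
    if (sum(sw$segments$label == "test") != 1) {
      stop("each sweep must contain exactly one test segment")
    }
  }
  sweeps <- assign_start_times(sweeps)
  structure(list(kind = kind, params = params, sweeps = sweeps,
                 sample_interval = sample_interval),
            class = "nav_protocol")
}

protocol_defaults <- function(kind) {
  switch(kind,
    activation = list(
      holding_potential = -120, test_from = -120, test_to = 25,
      test_increment = 5, test_duration_ms = 500, inter_sweep_ms = 150),
    ssi = list(
      holding_potential = -120, prepulse_from = -120, prepulse_to = 25,
      prepulse_increment = 5, prepulse_duration_ms = 500,
      test_voltage = -20, test_duration_ms = 10, inter_sweep_ms = 4490),
    slow_ssi = list(
      holding_potential = -120, prepulse_from = -120, prepulse_to = 20,
      prepulse_increment = 10, prepulse_duration_ms = 1000,
      recovery_voltage = -120, recovery_duration_ms = 100,
      test_voltage = -20, test_duration_ms = 10, inter_sweep_ms = 5000),
    state_dependence = list(
      holding_potentials = c(-110, -100, -90, -80),
      pulses_per_interval = 180, pulse_voltage = 0, pulse_duration_ms = 20,
      pulse_period_ms = 1000, recovery_voltage = -120,
      recovery_duration_ms = 10000, equilibration_ms = 200),
    recovery = list(
      holding_potential = -120, prepulse_voltage = -20,
      prepulse_duration_ms = 20,
      recovery_intervals_ms = c(1, 2, 5, 10, 20, 50, 100, 200, 500,
                                1000, 3000, 10000),
      test_voltage = -20, test_duration_ms = 10, inter_sweep_ms = 5000),
    kinetics = list(
      holding_potential = -90, pulse_voltage = -20, pulse_duration_ms = 20,
      pulse_period_ms = 5000, total_duration_s = 180))
}

segment <- function(level, duration, label) {
  data.frame(level_mV = as.numeric(level), duration_ms = as.numeric(duration),
             label = label, stringsAsFactors = FALSE)
}

new_sweep <- function(segments, meta) {
  list(segments = segments, start_time = NA_real_, meta = meta)
}

voltage_grid <- function(from, to, by, what) {
  if (by == 0) stop("degenerate ", what, " increment (0 mV)")
  n <- (to - from) / by
  if (n < 0 || abs(n - round(n)) > 1e-9) {
    stop(what, " range is not an exact multiple of the increment")
  }
  from + by * (0:round(n))
}

sweeps_activation <- function(p) {
  vs <- voltage_grid(p$test_from, p$test_to, p$test_increment, "test voltage")
  lapply(vs, function(v) {
    new_sweep(rbind(segment(p$holding_potential, p$inter_sweep_ms, "holding"),
                    segment(v, p$test_duration_ms, "test")),
              list(holding_potential = p$holding_potential, step_voltage = v,
                   prepulse_duration = NA_real_, recovery_interval = NA_real_,
                   pulse_number = NA_integer_, interval_index = NA_integer_))
  })
}

sweeps_ssi <- function(p) {
  vs <- voltage_grid(p$prepulse_from, p$prepulse_to, p$prepulse_increment,
                     "prepulse voltage")
  lapply(vs, function(v) {
    new_sweep(rbind(segment(p$holding_potential, p$inter_sweep_ms, "holding"),
                    segment(v, p$prepulse_duration_ms, "prepulse"),
                    segment(p$test_voltage, p$test_duration_ms, "test")),
              list(holding_potential = p$holding_potential, step_voltage = v,
                   prepulse_duration = p$prepulse_duration_ms,
                   recovery_interval = NA_real_,
                   pulse_number = NA_integer_, interval_index = NA_integer_))
  })
}

sweeps_slow_ssi <- function(p) {
  vs <- voltage_grid(p$prepulse_from, p$prepulse_to, p$prepulse_increment,
                     "prepulse voltage")
  lapply(vs, function(v) {
    new_sweep(rbind(segment(p$holding_potential, p$inter_sweep_ms, "holding"),
                    segment(v, p$prepulse_duration_ms, "prepulse"),
                    segment(p$recovery_voltage, p$recovery_duration_ms,
                            "recovery"),
                    segment(p$test_voltage, p$test_duration_ms, "test")),
              list(holding_potential = p$holding_potential, step_voltage = v,
                   prepulse_duration = p$prepulse_duration_ms,
                   recovery_interval = NA_real_,
                   pulse_number = NA_integer_, interval_index = NA_integer_))
  })
}

sweeps_state_dependence <- function(p) {
  if (p$pulses_per_interval < 1) stop("pulses_per_interval must be >= 1")
  interpulse <- p$pulse_period_ms - p$pulse_duration_ms
  if (interpulse <= 0) stop("pulse period must exceed pulse duration")
  sweeps <- list()
  for (j in seq_along(p$holding_potentials)) {
    hp <- p$holding_potentials[j]
    for (n in seq_len(p$pulses_per_interval)) {
      segs <- NULL
      if (n == 1) {
        if (j > 1) {
          segs <- rbind(segs, segment(p$recovery_voltage,
                                      p$recovery_duration_ms, "recovery"))
        }
        if (p$equilibration_ms > 0) {
          segs <- rbind(segs, segment(hp, p$equilibration_ms, "holding"))
        }
      } else {
        segs <- rbind(segs, segment(hp, interpulse, "interpulse"))
      }
      segs <- rbind(segs, segment(p$pulse_voltage, p$pulse_duration_ms, "test"))
      sweeps[[length(sweeps) + 1L]] <- new_sweep(
        segs,
        list(holding_potential = hp, step_voltage = p$pulse_voltage,
             prepulse_duration = NA_real_, recovery_interval = NA_real_,
             pulse_number = n, interval_index = j))
    }
  }
  sweeps
}

sweeps_recovery <- function(p) {
  ivals <- sort(p$recovery_intervals_ms)
  lapply(ivals, function(dt) {
    new_sweep(rbind(segment(p$holding_potential, p$inter_sweep_ms, "holding"),
                    segment(p$prepulse_voltage, p$prepulse_duration_ms,
                            "prepulse"),
                    segment(p$holding_potential, dt, "recovery"),
                    segment(p$test_voltage, p$test_duration_ms, "test")),
              list(holding_potential = p$holding_potential,
                   step_voltage = p$test_voltage,
                   prepulse_duration = p$prepulse_duration_ms,
                   recovery_interval = dt,
                   pulse_number = NA_integer_, interval_index = NA_integer_))
  })
}

sweeps_kinetics <- function(p) {
  n <- floor(p$total_duration_s * 1000 / p$pulse_period_ms) + 1L
  hold <- p$pulse_period_ms - p$pulse_duration_ms
  lapply(seq_len(n), function(i) {
    new_sweep(rbind(segment(p$holding_potential, hold,
                            if (i == 1) "holding" else "interpulse"),
                    segment(p$pulse_voltage, p$pulse_duration_ms, "test")),
              list(holding_potential = p$holding_potential,
                   step_voltage = p$pulse_voltage,
                   prepulse_duration = NA_real_, recovery_interval = NA_real_,
                   pulse_number = i, interval_index = 1L))
  })
}

assign_start_times <- function(sweeps) {
  t0 <- 0
  for (i in seq_along(sweeps)) {
    sweeps[[i]]$start_time <- t0
    t0 <- t0 + sum(sweeps[[i]]$segments$duration_ms) / 1000
  }
  sweeps
}

#' Enumerate the sweeps of a protocol with their absolute start times
#'
#' A pure function of the protocol object: start times are the cumulative
#' segment durations (sweeps are contiguous, with inter-sweep holding
#' represented explicitly as a leading segment).
#'
#' @param protocol A `nav_protocol` from [build_protocol()].
#' @return A tibble with `sweep_index`, `start_s`, `test_onset_s` (absolute
#'   time at which the test segment begins) and a `sweep` list-column.
#' @export
enumerate_sweeps <- function(protocol) {
  stopifnot(inherits(protocol, "nav_protocol"))
  start <- vapply(protocol$sweeps, function(s) s$start_time, numeric(1))
  onset <- vapply(protocol$sweeps, function(s) {
    pre <- cumsum(c(0, s$segments$duration_ms))
    s$start_time + pre[which(s$segments$label == "test")] / 1000
  }, numeric(1))
  tibble::tibble(sweep_index = seq_along(protocol$sweeps),
                 start_s = start, test_onset_s = onset,
                 sweep = protocol$sweeps)
}

#' Resolved sweep table of a protocol
#'
#' @param protocol A `nav_protocol`.
#' @return A tibble with one row per segment: `sweep_index`, `start_s`,
#'   `segment_label`, `level_mV`, `duration_ms`.
#' @export
protocol_sweep_table <- function(protocol) {
  stopifnot(inherits(protocol, "nav_protocol"))
  rows <- lapply(seq_along(protocol$sweeps), function(i) {
    sw <- protocol$sweeps[[i]]
    tibble::tibble(sweep_index = i, start_s = sw$start_time,
                   segment_label = sw$segments$label,
                   level_mV = sw$segments$level_mV,
                   duration_ms = sw$segments$duration_ms)
  })
  dplyr::bind_rows(rows)
}

#' Serialise a protocol to JSON (and back)
#'
#' The JSON stores the kind, the resolved parameter map and the resolved
#' sweep table; deserialisation rebuilds the protocol from kind and
#' parameters, so a write-then-read round trip is exact.
#'
#' @param protocol A `nav_protocol`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
protocol_to_json <- function(protocol, path = NULL) {
  stopifnot(inherits(protocol, "nav_protocol"))
  x <- list(kind = protocol$kind, params = protocol$params,
            sample_interval = protocol$sample_interval,
            sweep_table = protocol_sweep_table(protocol))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname protocol_to_json
#' @param json A JSON string or file path produced by [protocol_to_json()].
#' @export
protocol_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  params <- x$params
  do.call(build_protocol,
          c(list(kind = x$kind), params,
            list(sample_interval = x$sample_interval)))
}

#' @export
print.nav_protocol <- function(x, ...) {
  n_test <- length(x$sweeps)
  dur <- x$sweeps[[n_test]]$start_time +
    sum(x$sweeps[[n_test]]$segments$duration_ms) / 1000
  cat(sprintf("<nav_protocol: %s>  %d sweeps, %.1f s total, %g ms sampling\n",
              x$kind, n_test, dur, x$sample_interval))
  utils::str(x$params, give.attr = FALSE, no.list = TRUE, comp.str = "  ")
  invisible(x)
}
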