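#' Generate a synthetic automated patch-clamp dataset
#'
#' Emulates a plate-based voltage-clamp experiment: every synthetic cell is
#' exposed to a single drug concentration, runs one or more protocols, and
#' reports one peak current per test segment. The deterministic model
#' response ([run_protocol()]) is shared by all cells at a concentration;
#' cells then differ by (i) a log-normal maximal-conductance scale and a
#' Gaussian capacitance draw, (ii) multiplicative Gaussian noise on each
#' peak, (iii) a slow multiplicative rundown shared in law by vehicle and
#' drug cells, and (iv) seal-quality attributes (membrane and series
#' resistance) drawn from log-normal distributions typical of automated
#' patch platforms.
#'
#' Randomness is reproducible and local: each cell derives its own seed
#' from the master `seed`, the concentration index and the replicate
#' index, so adding concentrations or cells does not perturb the draws of
#' existing cells.
#'
#' @param design A list with elements `protocols` (character vector of
#'   protocol kinds, or a list of `nav_protocol` objects),
#'   `concentrations` (micromolar; 0 = vehicle), `cells_per_conc`
#'   (replicates per concentration) and optionally `include_vehicle`
#'   (default `TRUE`; prepends concentration 0 if absent).
#' @param gating,drug,cell Model parameter objects; `cell` is the template
#'   from which per-cell properties are drawn.
#' @param seed Master integer seed.
#' @param keep_traces If `TRUE`, deterministic current traces of the test
#'   segments are retained per concentration and protocol (not per cell).
#'
#' @return A list with `records` (tibble; columns `cell_id`, `protocol`,
#'   `holding_mV`, `step_mV`, `prepulse_ms`, `recovery_ms`,
#'   `pulse_number`, `interval_index`, `elapsed_s`, `conc_uM`, `peak_pA`,
#'   `rm_MOhm`, `rs_MOhm`, `cap_pF`) and `traces` (named list
#'   `<protocol>@<conc>` or `NULL`).
#' @export
#' @examples
#' ds <- generate_dataset(
#'   design = list(protocols = "activation", concentrations = c(0, 30),
#'                 cells_per_conc = 2, include_vehicle = FALSE),
#'   seed = 1)
#' dplyr::count(ds$records, cell_id, conc_uM)
generate_dataset <- function(design, gating = gating_params(),
                             drug = drug_params(), cell = cell_params(),
                             seed = 1L, keep_traces = FALSE) {
  if (is.null(design$protocols) || length(design$protocols) == 0) {
    stop("empty design: no protocols given")
  }
  if (is.null(design$concentrations) || length(design$concentrations) == 0) {
    stop("empty design: no concentrations given")
  }
  if (any(design$concentrations < 0)) stop("concentrations must be >= 0")
  cells_per_conc <- design$cells_per_conc %||% 1L
  if (cells_per_conc < 1) stop("cells_per_conc must be >= 1")
  include_vehicle <- design$include_vehicle %||% TRUE

  concs <- design$concentrations
  if (include_vehicle && !any(concs == 0)) concs <- c(0, concs)
  concs <- sort(unique(concs))

  protos <- design$protocols
  if (is.character(protos)) protos <- lapply(protos, build_protocol)
  stopifnot(all(vapply(protos, inherits, logical(1), "nav_protocol")))

  # deterministic model response per (protocol, concentration)
  base <- list()
  traces <- if (keep_traces) list() else NULL
  for (pr in protos) {
    for (cc in concs) {
      key <- sprintf("%s@%g", pr$kind, cc)
      out <- run_protocol(pr, gating, drug, conc = cc, cell = cell,
                          keep_traces = keep_traces)
      base[[key]] <- out$records
      if (keep_traces) traces[[key]] <- out$traces
    }
  }

  rows <- list()
  for (ci in seq_along(concs)) {
    cc <- concs[ci]
    for (ri in seq_len(cells_per_conc)) {
      cell_seed <- (as.integer(seed) + 1000003L * ci + 7919L * ri) %%
        2147483647L
      id <- sprintf("c%02d_r%02d", ci, ri)
      draws <- withr::with_seed(cell_seed, {
        list(g_scale = rlnorm(1, -cell$g_max_cv^2 / 2, cell$g_max_cv),
             cap = max(3, rnorm(1, cell$capacitance,
                                cell$cap_cv * cell$capacitance)),
             rm = rlnorm(1, log(900), 0.45),
             rs = rlnorm(1, log(4.5), 0.4),
             rundown = max(0, rnorm(1, cell$rundown_rate,
                                    0.2 * cell$rundown_rate)))
      })
      for (pr in protos) {
        rec <- base[[sprintf("%s@%g", pr$kind, cc)]]
        n <- nrow(rec)
        noise <- withr::with_seed((cell_seed + 97L) %% 2147483647L,
                                  rnorm(n, 0, cell$peak_noise_sigma))
        rec$cell_id <- id
        rec$peak_pA <- rec$peak_pA * draws$g_scale *
          exp(-draws$rundown * rec$elapsed_s / 60) * (1 + noise)
        rec$rm_MOhm <- draws$rm
        rec$rs_MOhm <- draws$rs
        rec$cap_pF <- draws$cap
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  records <- dplyr::bind_rows(rows)
  list(records = records, traces = traces)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write peak-record tables
#'
#' Plain-CSV serialisation of the peak-record schema produced by
#' [generate_dataset()]; externally produced tables with the same columns
#' (e.g. adapted instrument exports) can be read back for analysis.
#'
#' @param records A peak-record tibble.
#' @param path File path.
#' @export
write_peak_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_peak_records
#' @export
read_peak_records <- function(path) {
  cols <- readr::cols(
    cell_id = readr::col_character(),
    protocol = readr::col_character(),
    .default = readr::col_double())
  rec <- readr::read_csv(path, col_types = cols, comment = "#")
  needed <- c("cell_id", "protocol", "holding_mV", "step_mV", "prepulse_ms",
              "recovery_ms", "pulse_number", "interval_index", "elapsed_s",
              "conc_uM", "peak_pA", "rm_MOhm", "rs_MOhm", "cap_pF")
  missing <- setdiff(needed, names(rec))
  if (length(missing)) {
    stop("peak-record file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- dplyr::summarise(dplyr::group_by(rec, .data$cell_id),
                          n = dplyr::n_distinct(.data$conc_uM))
  if (any(bad$n > 1)) {
    stop("each cell must carry a single concentration; offending cell(s): ",
         paste(bad$cell_id[bad$n > 1], collapse = ", "))
  }
  rec
}
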