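#' Quality-control thresholds for automated patch-clamp recordings
#'
#' Cells are retained only if membrane resistance exceeds `min_rm`, series
#' resistance is below `max_rs`, and the largest peak sodium current
#' magnitude exceeds `min_peak`. Comparisons are strict, so a cell sitting
#' exactly on a threshold is excluded.
#'
#' @param min_rm Minimum membrane (seal) resistance, MOhm.
#' @param max_rs Maximum series resistance, MOhm.
#' @param min_peak Minimum peak current magnitude, pA.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_rm = 500, max_rs = 10, min_peak = 500) {
  stopifnot(min_rm > 0, max_rs > 0, min_peak > 0)
  structure(list(min_rm = min_rm, max_rs = max_rs, min_peak = min_peak),
            class = "qc_thresholds")
}

#' Apply cell-level quality control to a peak-record table
#'
#' A cell failing any criterion is removed entirely (all its records, all
#' protocols). The exclusion log lists every failed criterion with the
#' offending value.
#'
#' @param records A peak-record tibble (see [generate_dataset()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `records` (filtered) and `exclusions` (tibble with
#'   `cell_id`, `criterion`, `value`).
#' @export
apply_qc <- function(records, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  need <- c("cell_id", "rm_MOhm", "rs_MOhm", "peak_pA")
  if (!all(need %in% names(records))) {
    stop("records lack QC attributes: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  }
  cells <- dplyr::summarise(
    dplyr::group_by(records, .data$cell_id),
    rm = .data$rm_MOhm[1], rs = .data$rs_MOhm[1],
    peak = max(abs(.data$peak_pA)), .groups = "drop")
  excl <- list()
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    if (!is.na(cl$rm) && cl$rm <= thresholds$min_rm) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        cell_id = cl$cell_id, criterion = "membrane_resistance",
        value = cl$rm)
    }
    if (!is.na(cl$rs) && cl$rs >= thresholds$max_rs) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        cell_id = cl$cell_id, criterion = "series_resistance", value = cl$rs)
    }
    if (cl$peak <= thresholds$min_peak) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        cell_id = cl$cell_id, criterion = "peak_magnitude", value = cl$peak)
    }
  }
  exclusions <- if (length(excl)) dplyr::bind_rows(excl) else {
    tibble::tibble(cell_id = character(), criterion = character(),
                   value = numeric())
  }
  keep <- setdiff(cells$cell_id, unique(exclusions$cell_id))
  if (!length(keep)) {
    worst <- names(sort(table(exclusions$criterion), decreasing = TRUE))[1]
    stop("no cells survive QC; most frequently failed criterion: ", worst)
  }
  list(records = dplyr::filter(records, .data$cell_id %in% keep),
       exclusions = exclusions)
}

#' Vehicle-normalise a drug time course
#'
#' Removes compound-independent decay (rundown) from a drug response by
#' dividing by the vehicle response, then expresses the result as an
#' inhibition fraction: `inhibition(t) = 1 - drug(t) / vehicle(t)`. Both
#' series must already be normalised to their own baselines. The vehicle
#' series is linearly interpolated onto the drug time grid. Values outside
#' `[-0.2, 1.2]` are clamped and flagged.
#'
#' @param drug_series,vehicle_series Data frames with columns `time_s`
#'   and `value`.
#' @return A tibble with `time_s`, `inhibition`, `out_of_range`.
#' @export
#' @examples
#' t <- 0:10
#' vehicle_normalize(data.frame(time_s = t, value = 0.45),
#'                   data.frame(time_s = t, value = 0.9))  # 0.5 throughout
vehicle_normalize <- function(drug_series, vehicle_series) {
  stopifnot(all(c("time_s", "value") %in% names(drug_series)),
            all(c("time_s", "value") %in% names(vehicle_series)))
  veh <- if (nrow(vehicle_series) == 1) {
    rep(vehicle_series$value, nrow(drug_series))
  } else {
    approx(vehicle_series$time_s, vehicle_series$value,
           xout = drug_series$time_s, rule = 2)$y
  }
  if (any(veh == 0)) stop("vehicle series reaches zero; cannot normalise")
  raw <- 1 - drug_series$value / veh
  tibble::tibble(time_s = drug_series$time_s,
                 inhibition = pmin(pmax(raw, -0.2), 1.2),
                 out_of_range = raw < -0.2 | raw > 1.2)
}

mean_sem <- function(x) {
  x <- x[is.finite(x)]
  tibble::tibble(mean = mean(x), sem = sd(x) / sqrt(length(x)),
                 sd = sd(x), n = length(x))
}
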