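# JSON-configured end-to-end runs: generate -> QC -> stage analyses ->
# four-state fit -> report.

#' Default run configuration
#'
#' The fully resolved default configuration: the state-dependence
#' experiment (six concentrations, eight cells per arm plus vehicle,
#' 5% multiplicative peak noise, 1%/min rundown) together with the
#' vehicle SSI protocol that supplies the availability curve for the
#' four-state fit.
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  structure(list(
    seed = 1234L,
    generator = list(
      gating = unclass(gating_params()),
      drug = unclass(drug_params())[c("k_r", "k_i", "k_on")],
      cell = unclass(cell_params()),
      design = list(
        protocols = c("ssi", "state_dependence"),
        concentrations = c(1, 3, 10, 30, 100, 300),
        cells_per_conc = 8L,
        include_vehicle = TRUE),
      keep_traces = FALSE),
    protocol_overrides = list(),
    qc = unclass(qc_thresholds()),
    analysis = list(
      availability_source = "ssi",
      censored_voltages = FALSE,
      censor_value = NULL,
      fix_slope_rse = 0.5)),
    class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, fills defaults, and rejects unknown keys;
#' validation failures name the offending field path.
#'
#' @param path Path to a JSON file (or a JSON string).
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- merge_config(unclass(default_config()), raw, "")
  validate_config(structure(cfg, class = "run_config"))
}

merge_config <- function(defaults, user, prefix) {
  if (!is.list(user)) return(user)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) && !identical(prefix, "$protocol_overrides")) {
    stop("unknown configuration key(s): ",
         paste0(sub("^\\$", "", paste0(prefix, "$", bad)), collapse = ", "))
  }
  out <- defaults
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      out[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                paste0(prefix, "$", nm))
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  out
}

validate_config <- function(cfg) {
  fail <- function(field, msg) stop("invalid config at ", field, ": ", msg)
  if (is.null(cfg$seed)) cfg$seed <- 1234L
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    fail("seed", "must be a single integer")
  }
  d <- cfg$generator$design
  if (any(d$concentrations < 0)) {
    fail("generator$design$concentrations", "must be >= 0")
  }
  kinds <- c("activation", "ssi", "slow_ssi", "state_dependence",
             "recovery", "kinetics")
  bad <- setdiff(d$protocols, kinds)
  if (length(bad)) {
    fail("generator$design$protocols", paste("unknown kind:", bad[1]))
  }
  if (d$cells_per_conc < 1) {
    fail("generator$design$cells_per_conc", "must be >= 1")
  }
  if (!cfg$analysis$availability_source %in% c("ssi", "default_boltzmann")) {
    fail("analysis$availability_source",
         "must be 'ssi' or 'default_boltzmann'")
  }
  dr <- cfg$generator$drug
  if (dr$k_r <= 0 || dr$k_i <= 0 || dr$k_on <= 0) {
    fail("generator$drug", "dissociation constants and k_on must be > 0")
  }
  cfg
}

config_objects <- function(cfg) {
  g <- cfg$generator$gating
  list(gating = do.call(gating_params, g[setdiff(names(g), character())]),
       drug = do.call(drug_params, cfg$generator$drug[c("k_r", "k_i", "k_on")]),
       cell = do.call(cell_params, cfg$generator$cell[
         c("g_max", "capacitance", "e_na", "peak_noise_sigma",
           "rundown_rate", "g_max_cv", "cap_cv", "seed")]),
       qc = do.call(qc_thresholds, cfg$qc))
}

#' Run the full analysis pipeline
#'
#' Executes generate -> QC -> vehicle-referenced stage analyses ->
#' four-state fit for the given configuration. Fully deterministic for a
#' fixed seed. Any stage failure is re-raised with the stage name.
#'
#' @param config A `run_config` from [load_config()] or
#'   [default_config()].
#' @return An object of class `run_report`; headline elements include
#'   `k_r_uM`, `k_i_uM`, `fold_preference` and `ic50_by_voltage`, with
#'   per-stage results under `stages`.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  config <- validate_config(config)
  obj <- config_objects(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  protos <- stage("protocols", {
    lapply(config$generator$design$protocols, function(kind) {
      ov <- config$protocol_overrides[[kind]]
      if (is.null(ov)) build_protocol(kind)
      else do.call(build_protocol, c(list(kind), ov))
    })
  })

  design <- config$generator$design
  design$protocols <- protos
  ds <- stage("generate", {
    generate_dataset(design, obj$gating, obj$drug, obj$cell,
                     seed = config$seed,
                     keep_traces = isTRUE(config$generator$keep_traces))
  })

  analyze_records(ds$records, config, traces = ds$traces, seed = config$seed)
}

#' Analyse a peak-record table under a run configuration
#'
#' The analysis half of [run_pipeline()]: quality control, the stage
#' analyses for every protocol kind present in the table, and (when
#' state-dependence records are present) the concentration-response and
#' four-state fits. Accepts externally produced peak-record tables (see
#' [read_peak_records()]) as well as [generate_dataset()] output.
#'
#' @param records A peak-record tibble.
#' @param config A `run_config` (QC thresholds and analysis options are
#'   honoured; the generator block is ignored except as provenance).
#' @param traces Optional trace store for open-state tau analysis.
#' @param seed Seed recorded in the report.
#' @return A `run_report`.
#' @export
analyze_records <- function(records, config = default_config(),
                            traces = NULL, seed = config$seed) {
  stopifnot(inherits(config, "run_config"))
  obj <- config_objects(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  ds <- list(records = records, traces = traces)

  qc <- stage("qc", apply_qc(ds$records, obj$qc))
  rec <- qc$records
  kinds <- unique(rec$protocol)
  stages <- list(qc_exclusions = qc$exclusions)

  if ("ssi" %in% kinds) {
    stages$ssi <- stage("ssi", analyze_ssi(rec, 500))
  }
  if ("slow_ssi" %in% kinds) {
    durs <- unique(rec$prepulse_ms[rec$protocol == "slow_ssi"])
    stages$slow_ssi <- stage("slow_ssi", {
      lapply(setNames(durs, paste0("ms", durs)), function(d) {
        analyze_ssi(rec, d)
      })
    })
  }
  if ("activation" %in% kinds) {
    stages$activation <- stage("activation", analyze_activation(rec))
    if (!is.null(ds$traces)) {
      act_traces <- ds$traces[grepl("^activation@", names(ds$traces))]
      if (length(act_traces)) {
        stages$open_state_tau <-
          stage("open_state_tau", analyze_open_state_tau(act_traces))
      }
    }
  }
  if ("recovery" %in% kinds) {
    stages$recovery <- stage("recovery", analyze_recovery(rec))
  }
  if ("kinetics" %in% kinds) {
    stages$kinetics <- stage("kinetics", analyze_block_kinetics(rec))
  }

  headline <- list(k_r_uM = NA_real_, k_i_uM = NA_real_,
                   fold_preference = NA_real_, ic50_by_voltage = list())
  if ("state_dependence" %in% kinds) {
    stages$concentration_response <- stage("concentration_response", {
      build_concentration_response(rec, config$analysis$fix_slope_rse)
    })
    ics <- apparent_ic50s(stages$concentration_response, "last")
    avail <- stage("availability", {
      if (config$analysis$availability_source == "ssi") {
        if (is.null(stages$ssi)) {
          stop("availability_source 'ssi' needs the ssi protocol in the design")
        }
        stages$ssi$fits[["0"]]
      } else {
        g <- obj$gating
        function(v) steady_state_availability(g, v)
      }
    })
    stages$four_state <- stage("four_state", {
      fit_four_state(ics, avail,
                     censored = isTRUE(config$analysis$censored_voltages),
                     censor_value = config$analysis$censor_value %||%
                       max(rec$conc_uM))
    })
    headline$k_r_uM <- stages$four_state$k_r
    headline$k_i_uM <- stages$four_state$k_i
    headline$fold_preference <- stages$four_state$fold_preference
    headline$ic50_by_voltage <-
      setNames(as.list(ics$ic50_uM), ics$holding_mV)
    headline$ic50_fold_range <- {
      fin <- ics$ic50_uM[is.finite(ics$ic50_uM)]
      if (length(fin) >= 2) max(fin) / min(fin) else NA_real_
    }
  }
  if (!is.null(stages$ssi)) {
    headline$ssi_delta_v_half <- stages$ssi$delta_v_half
  }
  if (!is.null(stages$activation)) {
    headline$gmax_ratio <- stages$activation$gmax[
      , c("conc_uM", "ratio_vs_vehicle")]
    headline$activation_delta_v_half <- stages$activation$delta_v_half
  }
  if (!is.null(stages$kinetics)) {
    headline$tau_observed <- stages$kinetics[
      , c("conc_uM", "holding_mV", "tau_s", "no_fit")]
  }

  structure(list(
    headline = headline,
    stages = stages,
    records = rec,
    seed = seed,
    config = config,
    config_hash = rlang::hash(unclass(config)),
    version = as.character(utils::packageVersion("navstate"))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>  seed", x$seed, " config", substr(x$config_hash, 1, 8),
      "\n")
  h <- x$headline
  if (is.finite(h$k_i_uM)) {
    cat(sprintf("  K_R = %.3g uM, K_I = %.3g uM, fold preference = %.3g\n",
                h$k_r_uM, h$k_i_uM, h$fold_preference))
    ic <- unlist(h$ic50_by_voltage)
    cat("  apparent IC50 (uM):",
        paste(sprintf("%s mV: %.3g", names(ic), ic), collapse = ",  "), "\n")
  }
  cat("  stages:", paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}

#' Write a run report and its stage tables to disk
#'
#' Produces `report.json` (headline parameters, seed, config echo and
#' hash) plus tidy CSV tables for the main stage outputs; every file
#' carries the config hash and seed (CSVs as a leading comment line).
#'
#' @param report A `run_report`.
#' @param path Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (file.access(path, 2) != 0) stop("output path is not writable: ", path)
  stamp <- sprintf("# navstate config_hash=%s seed=%d", report$config_hash,
                   as.integer(report$seed))
  write_stamped <- function(df, file) {
    fp <- file.path(path, file)
    writeLines(stamp, fp)
    suppressWarnings(readr::write_csv(df, fp, append = TRUE,
                                      col_names = TRUE))
    fp
  }
  files <- character()
  js <- list(
    k_r_uM = report$headline$k_r_uM,
    k_i_uM = report$headline$k_i_uM,
    fold_preference = report$headline$fold_preference,
    ic50_by_voltage = report$headline$ic50_by_voltage,
    seed = report$seed,
    config_hash = report$config_hash,
    version = report$version,
    config = unclass(report$config))
  jp <- file.path(path, "report.json")
  jsonlite::write_json(js, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(files, jp)
  files <- c(files, write_stamped(report$records, "peak_records.csv"))
  st <- report$stages
  if (!is.null(st$concentration_response)) {
    files <- c(files, write_stamped(st$concentration_response$table,
                                    "concentration_response.csv"))
    files <- c(files, write_stamped(
      apparent_ic50s(st$concentration_response), "ic50_by_voltage.csv"))
  }
  if (!is.null(st$ssi)) {
    files <- c(files, write_stamped(st$ssi$delta_v_half, "ssi_v_half.csv"))
  }
  if (!is.null(st$kinetics)) {
    files <- c(files, write_stamped(
      dplyr::select(st$kinetics, -"fit"), "tau_observed.csv"))
  }
  if (!is.null(st$qc_exclusions)) {
    files <- c(files, write_stamped(st$qc_exclusions, "qc_exclusions.csv"))
  }
  invisible(files)
}
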