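# Trace/report serialization (CSV + JSON sidecars) and YAML run
# configurations.  All artifacts are plain text and embed the package
# version so runs are diffable and attributable.

artifact_version <- function() {
  as.character(utils::packageVersion("cardioec"))
}

#' Write a simulation trace to CSV
#'
#' Column names carry the units (`time_ms`, `vm_mV`, `ca_i_uM`,
#' `tension_kPa`, ...).  A JSON sidecar (`<path>.json`) records the fully
#' resolved run metadata: case, impact factors, protocol, solver settings
#' and package version.
#'
#' @param trace A `myocyte_trace` (or plain data frame).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  check_trace_df(trace, character())
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(
    artifact = "myocyte_trace",
    version = artifact_version(),
    case = attr(trace, "case"),
    factors = as.list(unclass(attr(trace, "factors"))),
    protocol = unclass(attr(trace, "protocol")),
    lambda = attr(trace, "lambda"),
    solver = attr(trace, "solver")
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trace CSV
#'
#' Validates the required columns and a strictly increasing time grid;
#' malformed files are rejected with the offending row identified.
#'
#' @param path CSV path (columns `time_ms` plus any signal columns).
#' @param required Signal columns that must be present.
#' @return A tibble.
#' @export
read_trace <- function(path, required = "ca_i_uM") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = TRUE)
  miss <- setdiff(c("time_ms", required), names(df))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$time_ms) || anyNA(df$time_ms)) {
    stop(path, ": non-numeric time_ms values", call. = FALSE)
  }
  bad <- which(diff(df$time_ms) <= 0)
  if (length(bad)) {
    stop(path, ": time_ms not strictly increasing at data row ", bad[1] + 1,
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a biomarker report to JSON
#'
#' @param report A [biomarker_report()] (or any one-or-more-row tibble).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(artifact = "biomarker_report", version = artifact_version(),
         report = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

config_defaults <- function() {
  list(
    model = list(case = "A", severity = NULL, factors = NULL,
                 gpb = list(), nhs = list(), lambda = 1),
    protocol = list(amplitude = -9.5, duration = 5, cycle_length = 1000,
                    n_prepace = 100, n_record = 1),
    solver = list(rtol = 1e-7, atol = 1e-10, record_dt = 0.1),
    mechanics = list(ho = list(), sphere = list()),
    outputs = list(trace = NULL, report = NULL)
  )
}

check_known_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

#' Load and resolve a YAML run configuration
#'
#' Reads a YAML file with optional sections `model`, `protocol`, `solver`,
#' `mechanics`, `outputs`, validates every key against the known schema
#' (unknown keys are rejected), and merges with package defaults.  The
#' resolved configuration is what a run actually uses and can be written
#' back verbatim with [write_config()].
#'
#' @param path YAML file path.
#' @return A fully resolved configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (is.null(raw)) raw <- list()
  resolve_config(raw)
}

#' @rdname load_config
#' @param config A (possibly partial) configuration list.
#' @export
resolve_config <- function(config = list()) {
  def <- config_defaults()
  check_known_keys(config, names(def), "top level")
  for (sec in names(def)) {
    if (!is.null(config[[sec]])) {
      check_known_keys(config[[sec]], names(def[[sec]]),
                       paste0("section '", sec, "'"))
      keys <- names(def[[sec]])
      def[[sec]] <- utils::modifyList(def[[sec]], config[[sec]])
      # modifyList drops NULL-valued entries; keep the full schema so a
      # resolved config round-trips through YAML unchanged
      missing <- setdiff(keys, names(def[[sec]]))
      for (nm in missing) def[[sec]][nm] <- list(NULL)
      def[[sec]] <- def[[sec]][keys]
    }
  }
  check_known_keys(def$model$gpb, names(gpb_parameters()), "model$gpb")
  check_known_keys(def$model$nhs, names(nhs_parameters()), "model$nhs")
  check_known_keys(def$mechanics$ho, names(unclass(ho_parameters())),
                   "mechanics$ho")
  check_known_keys(def$mechanics$sphere,
                   c("r_inner", "r_outer", "edp", "esp"),
                   "mechanics$sphere")
  structure(def, class = "run_config")
}

#' Write a resolved configuration to YAML
#' @param config A `run_config` from [load_config()] / [resolve_config()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Execute a resolved run configuration
#'
#' Runs the myocyte simulation described by the configuration, extracts the
#' biomarker report, and writes the trace CSV / report JSON when output
#' paths are configured (each with the resolved metadata embedded).
#'
#' @param config A `run_config`.
#' @return A list with elements `trace` and `report`.
#' @export
run_config <- function(config = resolve_config()) {
  stopifnot(inherits(config, "run_config"))
  m <- config$model
  case <- if (!is.null(m$factors)) {
    as_impact_factors(unlist(m$factors))
  } else if (!is.null(m$severity)) {
    m$severity
  } else {
    m$case
  }
  params <- do.call(gpb_parameters, m$gpb)
  nhs <- do.call(nhs_parameters, m$nhs)
  prot <- do.call(stimulus_protocol, config$protocol)
  tr <- simulate_myocyte(case, prot, params = params, nhs = nhs,
                         lambda = m$lambda,
                         rtol = config$solver$rtol,
                         atol = config$solver$atol,
                         record_dt = config$solver$record_dt)
  rep <- biomarker_report(tr)
  if (!is.null(config$outputs$trace)) write_trace(tr, config$outputs$trace)
  if (!is.null(config$outputs$report)) {
    write_report(rep, config$outputs$report)
  }
  list(trace = tr, report = rep)
}
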