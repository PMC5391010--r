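# broom-style tidiers for the package's result objects.

#' Tidy a simulated trace into long format
#'
#' @param x A `myocyte_trace`.
#' @param ... Ignored.
#' @return A tibble with columns `time_ms`, `signal`, `value`.
#' @export
tidy.myocyte_trace <- function(x, ...) {
  x |>
    dplyr::select(dplyr::any_of(c("time_ms", "vm_mV", "ca_i_uM",
                                  "tension_kPa"))) |>
    tidyr::pivot_longer(-"time_ms", names_to = "signal",
                        values_to = "value")
}

#' One-row summary of a simulated trace
#'
#' @param x A `myocyte_trace`.
#' @param ... Ignored.
#' @return A one-row tibble: case, beat duration, sample count, and the
#'   headline biomarkers (APD90, CaT peak, peak tension).
#' @export
glance.myocyte_trace <- function(x, ...) {
  tibble::tibble(
    case = attr(x, "case") %||% NA_character_,
    n_samples = nrow(x),
    duration_ms = max(x$time_ms) - min(x$time_ms),
    apd90_ms = tryCatch(apd(x), error = function(e) NA_real_),
    cat_peak_uM = max(x$ca_i_uM),
    tension_peak_kPa = max(x$tension_kPa)
  )
}

#' Tidy a biomarker report into name/value pairs
#'
#' @param x A `biomarker_report`.
#' @param ... Ignored.
#' @return A tibble with columns `case`, `biomarker`, `value`.
#' @export
tidy.biomarker_report <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"case",
                      names_to = "biomarker", values_to = "value")
}

#' One-row summary of a surrogate sweep
#'
#' @param x An `lv_sweep`.
#' @param ... Ignored.
#' @return A one-row tibble: grid size, parameter ranges, best ejection
#'   fraction and whether any grid point ejects.
#' @export
glance.lv_sweep <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x),
    edp_range = paste(range(x$edp), collapse = "-"),
    esp_range = paste(range(x$esp), collapse = "-"),
    T_scale_range = paste(range(x$T_scale), collapse = "-"),
    best_ef_percent = max(x$ef_percent),
    any_ejection = any(x$sv_mL > 0)
  )
}
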