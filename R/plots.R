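# ggplot2 displays for traces, biomarker tables and surrogate sweeps.

trace_long <- function(trace, signals = c("vm", "ca_i", "tension")) {
  cols <- vapply(signals, signal_column, character(1))
  labels <- c(vm_mV = "Vm (mV)", ca_i_uM = "[Ca]i (uM)",
              tension_kPa = "Active tension (kPa)")
  trace |>
    dplyr::select(dplyr::all_of(c("time_ms", unname(cols)))) |>
    tidyr::pivot_longer(-"time_ms", names_to = "signal",
                        values_to = "value") |>
    dplyr::mutate(signal = factor(labels[.data$signal],
                                  levels = labels[cols]))
}

#' Plot a simulated beat
#'
#' Stacked panels of membrane potential, Ca transient and active tension
#' against time.
#'
#' @param object A `myocyte_trace`.
#' @param signals Which signals to show (`"vm"`, `"ca_i"`, `"tension"`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.myocyte_trace <- function(object,
                                   signals = c("vm", "ca_i", "tension"),
                                   ...) {
  dat <- trace_long(object, signals)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_ms, .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$signal), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = paste0("Paced beat",
                                 if (!is.null(attr(object, "case"))) {
                                   paste0(" (case ", attr(object, "case"), ")")
                                 })) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.placement = "outside")
}

#' Overlay beats from several disease cases
#'
#' @param traces Named list of `myocyte_trace` objects (names used as case
#'   labels; unnamed lists use their `case` attribute).
#' @param signals Signals to facet.
#' @return A ggplot object.
#' @export
plot_case_traces <- function(traces, signals = c("vm", "ca_i", "tension")) {
  if (is.null(names(traces))) {
    names(traces) <- vapply(traces, function(x) {
      as.character(attr(x, "case") %||% "?")
    }, character(1))
  }
  dat <- purrr::imap_dfr(traces, function(tr, nm) {
    dplyr::mutate(trace_long(tr, signals), case = nm)
  })
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_ms, .data$value,
                                    colour = .data$case)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$signal),
                        scales = "free_y", switch = "y") +
    ggplot2::labs(x = "time (ms)", y = NULL, colour = "case") +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.placement = "outside")
}

#' Plot pump-function trends of the sphere surrogate
#'
#' End-systolic volume against end-systolic pressure, one line per
#' contractility scaling (the reduced-order analogue of the afterload /
#' contractility sweeps).
#'
#' @param object An `lv_sweep`.
#' @param y Column to plot (`"esv_mL"`, `"sv_mL"` or `"ef_percent"`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.lv_sweep <- function(object, y = "esv_mL", ...) {
  stopifnot(y %in% c("esv_mL", "sv_mL", "ef_percent", "edv_mL"))
  xvar <- if (dplyr::n_distinct(object$esp) > 1) "esp" else "edp"
  ggplot2::ggplot(object,
                  ggplot2::aes(.data[[xvar]], .data[[y]],
                               colour = factor(.data$T_scale),
                               group = factor(.data$T_scale))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = paste(xvar, "(mmHg)"), y = y,
                  colour = "T_scale") +
    ggplot2::theme_minimal()
}
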