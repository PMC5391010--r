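# Synthetic analytic waveforms with closed-form biomarker values.  These
# exercise the biomarker extractors against known ground truth and serve as
# text fixtures for I/O round-trips; each generator attaches its own truth
# as an attribute.

#' Synthetic triangular action potential
#'
#' A piecewise-linear AP: rise from `v_rest` to `v_peak` over `t_rise`,
#' linear fall back over `t_fall`, then rest until `t_end`.  Its biomarkers
#' follow from the geometry: APD at fraction q is
#' `t_rise + q * t_fall - t_up`, where `t_up` is the detected upstroke time
#' (the first interior sample of the constant-slope rise, i.e. one sample
#' step), and the upstroke velocity is the rise slope.
#'
#' @param t_rise,t_fall Rise / fall durations (ms).
#' @param v_rest,v_peak Resting / peak potentials (mV).
#' @param t_end Trace length (ms).
#' @param dt Sampling interval (ms).
#' @return A tibble (`time_ms`, `vm_mV`) with attribute `truth`, a list
#'   with `apd90`, `apd` (function of fraction), `apd_tolerance` (the
#'   upstroke-placement ambiguity of a constant-slope rise, `t_rise + dt`),
#'   `upstroke_velocity`, `amplitude`, `resting_potential`.
#' @export
synth_triangle_ap <- function(t_rise = 1, t_fall = 300, v_rest = -80,
                              v_peak = 40, t_end = 500, dt = 0.1) {
  stopifnot(t_rise > 0, t_fall > 0, t_end > t_rise + t_fall)
  tt <- seq(0, t_end, by = dt)
  vm <- ifelse(tt <= t_rise,
               v_rest + (v_peak - v_rest) * tt / t_rise,
        ifelse(tt <= t_rise + t_fall,
               v_peak - (v_peak - v_rest) * (tt - t_rise) / t_fall,
               v_rest))
  # the constant-slope rise makes "time of maximal dV/dt" ambiguous within
  # the rise; quote the geometric value (upstroke at onset) with tolerance
  apd_fun <- function(q) t_rise + q * t_fall
  out <- tibble::tibble(time_ms = tt, vm_mV = vm)
  attr(out, "truth") <- list(
    apd90 = apd_fun(0.9), apd = apd_fun, apd_tolerance = t_rise + dt,
    upstroke_velocity = (v_peak - v_rest) / t_rise,
    amplitude = v_peak - v_rest, resting_potential = v_rest)
  out
}

#' Synthetic Gaussian transient
#'
#' `baseline + amplitude * exp(-(t - t0)^2 / (2 sigma^2))`, the canonical
#' smooth single-peak transient.  All five transient features have closed
#' forms, attached as the `truth` attribute (peak, time to peak, amplitude
#' above the value at t = 0, maximal rate of rise `A e^{-1/2} / sigma`,
#' and RT50 from the half-amplitude decay crossing).
#'
#' @param baseline,amplitude Baseline and peak height above baseline.
#' @param t0 Peak time (ms).
#' @param sigma Gaussian width (ms).
#' @param t_end Trace length (ms).
#' @param dt Sampling interval (ms).
#' @param signal `"ca_i"` (column `ca_i_uM`) or `"tension"`
#'   (`tension_kPa`).
#' @return A tibble with attribute `truth`.
#' @export
synth_gaussian_transient <- function(baseline = 0.1, amplitude = 0.9,
                                     t0 = 60, sigma = 25, t_end = 400,
                                     dt = 0.1, signal = c("ca_i", "tension")) {
  signal <- match.arg(signal)
  stopifnot(sigma > 0, amplitude > 0, t0 > 0, t_end > t0)
  tt <- seq(0, t_end, by = dt)
  x <- baseline + amplitude * exp(-(tt - t0)^2 / (2 * sigma^2))
  diastolic <- baseline + amplitude * exp(-t0^2 / (2 * sigma^2))
  amp <- baseline + amplitude - diastolic
  # decay crossing of diastolic + amp/2
  ratio <- (diastolic + amp / 2 - baseline) / amplitude
  rt50 <- sigma * sqrt(-2 * log(ratio))
  out <- tibble::tibble(time_ms = tt)
  out[[signal_column(signal)]] <- x
  attr(out, "truth") <- list(
    peak = baseline + amplitude,
    time_to_peak_s = t0 / 1000,
    amplitude = amp,
    rate_of_development = amplitude * exp(-0.5) / sigma * 1000,
    rt50_s = rt50 / 1000)
  out
}

#' Generate the text fixture set
#'
#' Writes the synthetic analytic waveforms (triangular AP, Gaussian Ca and
#' tension transients) as CSV files with a JSON manifest carrying their
#' closed-form biomarker values, plus a short coarse reference trace of the
#' healthy coupled model for regression pinning.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the (deterministically jittered) waveform
#'   parameters.
#' @param reference_trace Also generate the short simulated reference
#'   trace (a few seconds of compute).
#' @return Character vector of the files written.
#' @export
generate_fixtures <- function(dir = tempfile("fixtures"), seed = 1,
                              reference_trace = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  tri <- synth_triangle_ap(t_rise = 1, t_fall = round(250 + 100 * stats::runif(1)),
                           v_rest = -80, v_peak = 40)
  gca <- synth_gaussian_transient(baseline = 0.1, amplitude = 0.9,
                                  t0 = 40 + round(40 * stats::runif(1)),
                                  sigma = 25, signal = "ca_i")
  gtn <- synth_gaussian_transient(baseline = 0, amplitude = 10,
                                  t0 = 120, sigma = 60, t_end = 800,
                                  signal = "tension")
  files <- c(
    triangle_ap = file.path(dir, "triangle_ap.csv"),
    gaussian_cat = file.path(dir, "gaussian_cat.csv"),
    gaussian_tension = file.path(dir, "gaussian_tension.csv")
  )
  utils::write.csv(as.data.frame(tri), files[["triangle_ap"]],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(gca), files[["gaussian_cat"]],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(gtn), files[["gaussian_tension"]],
                   row.names = FALSE)
  manifest <- list(
    version = artifact_version(), seed = seed,
    triangle_ap = attr(tri, "truth")[c("apd90", "apd_tolerance",
                                       "upstroke_velocity",
                                       "amplitude", "resting_potential")],
    gaussian_cat = attr(gca, "truth"),
    gaussian_tension = attr(gtn, "truth")
  )
  manifest_path <- file.path(dir, "fixtures.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out <- c(files, manifest = manifest_path)
  if (reference_trace) {
    tr <- simulate_myocyte("A", stimulus_protocol(n_prepace = 1),
                           rtol = 1e-6, atol = 1e-9, record_dt = 1)
    ref_path <- file.path(dir, "reference_trace_caseA.csv")
    write_trace(tr, ref_path)
    out <- c(out, reference_trace = ref_path)
  }
  out
}
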