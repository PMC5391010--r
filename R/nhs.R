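# NHS myofilament model: troponin Ca binding with tension-dependent
# unbinding, tropomyosin site-availability kinetics, length-dependent
# activation, and three fading-memory crossbridge variables driven by the
# stretch rate.  Native units: seconds, micromolar, kPa.

# core evaluation shared by the coupled RHS and the standalone driver;
# `nhs` may be a parameter list or any named vector holding the constants
nhs_eval <- function(ca_trpn, z, q1, q2, q3, ca_i_uM, lambda, dlambda_dt,
                     nhs) {
  N <- function(nm) {
    if (is.list(nhs)) nhs[[nm]]
    else if (nm %in% names(nhs)) unname(nhs[[nm]])
    else NULL
  }
  lam <- min(max(lambda, N("lambda_min") %||% 0.8),
             N("lambda_max") %||% 1.15)
  Ca50 <- N("Ca_50ref") * (1 + N("beta_1") * (lam - 1))
  CaTRPN50 <- Ca50 * N("Ca_TRPN_max") /
    (Ca50 + (N("k_ref_off") / N("k_on")) *
       (1 - (1 + N("beta_0") * (lam - 1)) * 0.5 / N("gamma_trpn")))
  zpn <- N("z_p")^N("n_rel"); kzn <- N("K_z")^N("n_rel")
  K2 <- N("alpha_r2") * zpn / (zpn + kzn) *
    (1 - N("n_rel") * kzn / (zpn + kzn))
  K1 <- N("alpha_r2") * N("z_p")^(N("n_rel") - 1) * N("n_rel") * kzn /
    (zpn + kzn)^2
  act_max <- N("alpha_0") * (N("Ca_TRPN_max") / CaTRPN50)^N("n_hill")
  z_max <- (act_max - K2) / (N("alpha_r1") + K1 + act_max)
  d_z <- N("alpha_0") * (ca_trpn / CaTRPN50)^N("n_hill") * (1 - z) -
    N("alpha_r1") * z -
    N("alpha_r2") * z^N("n_rel") / (z^N("n_rel") + kzn)
  T0 <- N("T_ref") * (1 + N("beta_0") * (lam - 1)) * z / z_max
  Q <- q1 + q2 + q3
  tension <- if (Q < 0) {
    T0 * (N("a_xb") * Q + 1) / (1 - Q)
  } else {
    T0 * (1 + (N("a_xb") + 2) * Q) / (1 + Q)
  }
  d_q1 <- N("A_1") * dlambda_dt - N("alpha_1") * q1
  d_q2 <- N("A_2") * dlambda_dt - N("alpha_2") * q2
  d_q3 <- N("A_3") * dlambda_dt - N("alpha_3") * q3
  k_off <- N("k_ref_off") * (1 - tension / (N("gamma_trpn") * N("T_ref")))
  d_ca_trpn <- N("k_on") * ca_i_uM * (N("Ca_TRPN_max") - ca_trpn) -
    k_off * ca_trpn
  list(d_ca_trpn = d_ca_trpn, d_z = d_z, d_q1 = d_q1, d_q2 = d_q2,
       d_q3 = d_q3, tension = tension, T0 = T0, z_max = z_max,
       CaTRPN50 = CaTRPN50)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resting myofilament state
#'
#' All myofilament states at zero: no troponin-bound Ca, no available actin
#' sites, no crossbridge memory.  Active tension is exactly 0 kPa here.
#'
#' @return Named numeric vector `(ca_trpn, z_tm, q1, q2, q3)`.
#' @export
nhs_initial_state <- function() {
  c(ca_trpn = 0, z_tm = 0, q1 = 0, q2 = 0, q3 = 0)
}

#' Time derivatives of the myofilament state
#'
#' Right-hand side of the NHS model in its native units (per second), for a
#' given intracellular Ca concentration and mechanical input.
#'
#' @param t Time (s); the system is autonomous.
#' @param nhs_state Named vector `(ca_trpn, z_tm, q1, q2, q3)` (uM for
#'   `ca_trpn`, others dimensionless).
#' @param ca_i Intracellular free Ca (uM), non-negative.
#' @param lambda Fibre stretch (dimensionless, > 0).
#' @param dlambda_dt Stretch rate (1/s).
#' @param params Parameter list from [nhs_parameters()].
#' @return Named vector of derivatives (per s).
#' @export
nhs_derivatives <- function(t = 0, nhs_state, ca_i, lambda = 1,
                            dlambda_dt = 0, params = nhs_parameters()) {
  if (!is.finite(ca_i) || ca_i < 0) {
    stop("`ca_i` must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(lambda) || lambda <= 0) {
    stop("stretch `lambda` must be positive", call. = FALSE)
  }
  ev <- nhs_eval(nhs_state[["ca_trpn"]], nhs_state[["z_tm"]],
                 nhs_state[["q1"]], nhs_state[["q2"]], nhs_state[["q3"]],
                 ca_i, lambda, dlambda_dt, params)
  c(ca_trpn = ev$d_ca_trpn, z_tm = ev$d_z, q1 = ev$d_q1, q2 = ev$d_q2,
    q3 = ev$d_q3)
}

#' Active tension of the myofilament state
#'
#' Tension (kPa) generated by the NHS state: the length-dependent isometric
#' tension scaled by the crossbridge fading-memory correction.  Zero at the
#' resting initial state.
#'
#' @inheritParams nhs_derivatives
#' @return Active tension in kPa.
#' @export
#' @examples
#' active_tension(nhs_initial_state())  # 0 kPa at rest
active_tension <- function(nhs_state, lambda = 1, params = nhs_parameters()) {
  if (!is.finite(lambda) || lambda <= 0) {
    stop("stretch `lambda` must be positive", call. = FALSE)
  }
  ev <- nhs_eval(nhs_state[["ca_trpn"]], nhs_state[["z_tm"]],
                 nhs_state[["q1"]], nhs_state[["q2"]], nhs_state[["q3"]],
                 ca_i_uM = 0, lambda = lambda, dlambda_dt = 0, nhs = params)
  ev$tension
}

#' Drive the myofilament model with a prescribed Ca transient
#'
#' Integrates the NHS model against a tabulated intracellular Ca transient
#' (linearly interpolated between samples, constant beyond the last sample)
#' under constant stretch — the isometric protocol when `lambda = 1`.
#'
#' @param ca_trace A data frame with columns `time_ms` and `ca_i_uM` on a
#'   strictly increasing time grid, or a simulation trace from
#'   [simulate_myocyte()] (columns `time_ms`, `ca_i_uM`).
#' @param lambda Constant fibre stretch (default 1, resting length).
#' @param params Parameter list from [nhs_parameters()].
#' @param init Initial myofilament state, see [nhs_initial_state()].
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `time_ms`, `ca_i_uM`, `tension_kPa` and the
#'   myofilament states, on the input time grid.
#' @export
run_isometric <- function(ca_trace, lambda = 1, params = nhs_parameters(),
                          init = nhs_initial_state(),
                          rtol = 1e-8, atol = 1e-10) {
  if (!is.data.frame(ca_trace) || nrow(ca_trace) == 0) {
    stop("`ca_trace` must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("time_ms", "ca_i_uM") %in% names(ca_trace))) {
    stop("`ca_trace` needs columns `time_ms` and `ca_i_uM`", call. = FALSE)
  }
  tt <- ca_trace$time_ms
  if (any(diff(tt) <= 0)) {
    stop("`time_ms` must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(lambda) || lambda <= 0) {
    stop("stretch `lambda` must be positive", call. = FALSE)
  }
  ca_fun <- stats::approxfun(tt, pmax(ca_trace$ca_i_uM, 0), rule = 2)
  rhs <- function(t, y, parms) {
    ev <- nhs_eval(y[["ca_trpn"]], y[["z_tm"]], y[["q1"]], y[["q2"]],
                   y[["q3"]], ca_fun(t), lambda, 0, params)
    # native rates are per second; time grid is ms
    list(1e-3 * c(ev$d_ca_trpn, ev$d_z, ev$d_q1, ev$d_q2, ev$d_q3))
  }
  sol <- deSolve::ode(y = init, times = tt, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time_ms"
  out$ca_i_uM <- ca_fun(out$time_ms)
  out$tension_kPa <- vapply(seq_len(nrow(out)), function(i) {
    active_tension(c(ca_trpn = out$ca_trpn[i], z_tm = out$z_tm[i],
                     q1 = out$q1[i], q2 = out$q2[i], q3 = out$q3[i]),
                   lambda = lambda, params = params)
  }, numeric(1))
  dplyr::relocate(out, "time_ms", "ca_i_uM", "tension_kPa")
}
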