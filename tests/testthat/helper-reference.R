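# Published reference values used across the suite, and a per-session cache
# of the (deterministic) case simulations so each disease case is simulated
# once per test run.

# printed impact-factor table rows (healthy A to end-stage failing D)
published_table1 <- function() {
  tibble::tribble(
    ~case, ~f_hl, ~f_NaL, ~f_Ki, ~f_NaK, ~f_Nabk, ~f_Cabk, ~f_ncx, ~f_to,
    ~f_SRleak, ~f_SRca, ~f_EC50SR,
    "A", 1,     1,     1,     1,     1,     1,     1,     1,    1,     1,     1,
    "B", 1.333, 1.333, 0.893, 0.833, 0.667, 1.177, 1.25,  0.8,  2.333, 0.833, 0.963,
    "C", 1.666, 1.666, 0.787, 0.667, 0.333, 1.353, 1.5,   0.6,  3.667, 0.667, 0.927,
    "D", 2,     2,     0.68,  0.5,   0,     1.530, 1.75,  0.4,  5,     0.5,   0.89
  )
}

# printed per-case biomarker table (AP, Ca transient, active tension)
published_table2 <- function() {
  tibble::tribble(
    ~biomarker,                        ~A,      ~B,      ~C,      ~D,
    "apd90_ms",                        270.19,  301.91,  341.77,  399.89,
    "resting_potential_mV",            -80.55,  -80.00,  -79.17,  -77.86,
    "ap_amplitude_mV",                 123.36,  123.87,  123.86,  122.42,
    "ap_upstroke_velocity_V_per_s",    370.70,  354.71,  330.71,  291.18,
    "erp_ms",                          261.06,  291.23,  330.00,  385.89,
    "cat_peak_uM",                     0.9752,  0.6712,  0.4714,  0.3690,
    "cat_time_to_peak_s",              0.039,   0.054,   0.076,   0.106,
    "cat_upstroke_velocity_uM_per_s",  139.54,  45.97,   14.19,   5.10,
    "cat_amplitude_uM",                0.87,    0.56,    0.36,    0.25,
    "tension_peak_kPa",                9.87,    5.72,    3.85,    3.31,
    "tension_rate_kPa_per_s",          211.96,  99.20,   43.62,   22.98,
    "tension_rt50_s",                  0.182,   0.294,   0.412,   0.497
  )
}

.case_cache <- new.env(parent = emptyenv())

# recorded beat of a disease case under the default protocol, densely
# sampled for biomarker extraction; cached per session
case_trace <- function(case, record_dt = 0.02) {
  key <- paste0(case, "@", record_dt)
  if (is.null(.case_cache[[key]])) {
    .case_cache[[key]] <- simulate_myocyte(
      case, stimulus_protocol(), record_dt = record_dt)
  }
  .case_cache[[key]]
}

# central-difference gradient of a scalar function of a 3x3 matrix
num_grad_matrix <- function(fun, F, h = 1e-6) {
  G <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    G[i, j] <- (fun(Fp) - fun(Fm)) / (2 * h)
  }
  G
}

# random isochoric deformation gradient near the identity
random_isochoric_F <- function(scale = 0.15) {
  F <- diag(3) + matrix(stats::rnorm(9, sd = scale), 3)
  if (det(F) <= 0) F <- diag(3) + 0.5 * (F - diag(3))
  F / det(F)^(1 / 3)
}

# evaluate the compiled right-hand side once at a state
compiled_derivatives <- function(state, pv) {
  out <- deSolve::DLLfunc(func = "cardioec_derivs", dllname = "cardioec",
                          initfunc = "cardioec_initmod", times = 0,
                          y = state, parms = pv, nout = 1,
                          outnames = "tension_kPa")
  list(dy = out$dy, tension = unname(out$var))
}

# random valid perturbation of the resting state; Vm stays inside the
# physiologically reachable window (the source model's L-type `f` gate has
# a fitted steady state slightly above 1 below about -120 mV)
perturbed_state <- function(sd = 0.2) {
  reg <- state_registry()
  y <- initial_state()
  fac <- exp(stats::rnorm(length(y), sd = sd))
  y2 <- y * fac
  y2[["vm"]] <- min(max(y[["vm"]] + stats::rnorm(1, sd = 25), -90), 30)
  # keep gates and buffers inside their bounds
  hi <- reg$upper
  ok <- !is.na(hi)
  y2[ok] <- pmin(y2[ok], hi[ok] * 0.999)
  names(y2) <- names(y)
  y2
}
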