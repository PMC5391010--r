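#' Canonical state registry of the coupled myocyte model
#'
#' The coupled cell model carries 46 state variables: 41 electrophysiology
#' states (the 38 free ordinary differential equations of the ionic model, a
#' clamped bulk potassium concentration, and the two late-sodium gates added
#' to it) followed by 5 myofilament states.  All code — the R reference
#' right-hand side, the compiled right-hand side, I/O and the tests — resolves
#' state positions through this registry; positional literals are never used
#' elsewhere.
#'
#' Units follow the internal convention: time in ms, membrane potential in mV,
#' ionic concentrations in mM (note `ca_trpn` is in uM, the myofilament
#' model's native unit), gates and occupancy fractions dimensionless.
#'
#' @return A tibble with columns `name`, `index`, `unit`, `kind` (one of
#'   `"gate"`, `"buffer"`, `"concentration"`, `"potential"`, `"myofilament"`),
#'   `lower`, `upper` (validity bounds; `NA` means unbounded) and
#'   `description`.
#' @export
#' @examples
#' state_registry()
state_registry <- function() {
  g <- function(name, desc) {
    tibble::tibble(name = name, unit = "1", kind = "gate",
                   lower = 0, upper = 1, description = desc)
  }
  b <- function(name, bmax, desc) {
    tibble::tibble(name = name, unit = "mM", kind = "buffer",
                   lower = 0, upper = bmax, description = desc)
  }
  conc <- function(name, desc) {
    tibble::tibble(name = name, unit = "mM", kind = "concentration",
                   lower = 0, upper = NA_real_, description = desc)
  }
  p <- gpb_parameters()
  out <- dplyr::bind_rows(
    g("m_na", "fast Na+ activation gate"),
    g("h_na", "fast Na+ fast inactivation gate"),
    g("j_na", "fast Na+ slow inactivation gate"),
    g("d_ca", "L-type Ca2+ activation gate"),
    g("f_ca", "L-type Ca2+ voltage-dependent inactivation gate"),
    g("fcab_junc", "L-type Ca2+ Ca-dependent inactivation, junctional"),
    g("fcab_sl", "L-type Ca2+ Ca-dependent inactivation, subsarcolemmal"),
    g("x_tos", "transient outward K+ slow activation"),
    g("y_tos", "transient outward K+ slow inactivation"),
    g("x_tof", "transient outward K+ fast activation"),
    g("y_tof", "transient outward K+ fast inactivation"),
    g("x_kr", "rapid delayed rectifier K+ activation"),
    g("x_ks", "slow delayed rectifier K+ activation"),
    g("ryr_r", "RyR release channel, resting fraction"),
    g("ryr_o", "RyR release channel, open fraction"),
    g("ryr_i", "RyR release channel, inactivated fraction"),
    b("nab_junc", p$Bmax_Naj, "Na+ bound to junctional buffer"),
    b("nab_sl", p$Bmax_Nasl, "Na+ bound to subsarcolemmal buffer"),
    b("tnc_low", p$Bmax_TnClow, "Ca2+ bound to troponin-C low-affinity sites"),
    b("tnc_high_ca", p$Bmax_TnChigh, "Ca2+ bound to troponin-C high-affinity sites"),
    b("tnc_high_mg", p$Bmax_TnChigh, "Mg2+ bound to troponin-C high-affinity sites"),
    b("cam", p$Bmax_CaM, "Ca2+ bound to calmodulin"),
    b("myo_ca", p$Bmax_myosin, "Ca2+ bound to myosin"),
    b("myo_mg", p$Bmax_myosin, "Mg2+ bound to myosin"),
    b("srb", p$Bmax_SR, "Ca2+ bound to SR-membrane buffer"),
    b("sll_junc", p$Bmax_SLlowj, "Ca2+ on low-affinity sarcolemmal sites, junctional"),
    b("sll_sl", p$Bmax_SLlowsl, "Ca2+ on low-affinity sarcolemmal sites, subsarcolemmal"),
    b("slh_junc", p$Bmax_SLhighj, "Ca2+ on high-affinity sarcolemmal sites, junctional"),
    b("slh_sl", p$Bmax_SLhighsl, "Ca2+ on high-affinity sarcolemmal sites, subsarcolemmal"),
    b("csqn", p$Bmax_Csqn, "Ca2+ bound to calsequestrin (SR)"),
    conc("ca_sr", "free Ca2+ in the sarcoplasmic reticulum"),
    conc("na_junc", "free Na+ in the junctional cleft"),
    conc("na_sl", "free Na+ in the subsarcolemmal space"),
    conc("na_i", "free Na+ in the bulk cytosol"),
    conc("k_i", "bulk K+ (clamped; derivative fixed at zero)"),
    conc("ca_junc", "free Ca2+ in the junctional cleft"),
    conc("ca_sl", "free Ca2+ in the subsarcolemmal space"),
    conc("ca_i", "free Ca2+ in the bulk cytosol"),
    tibble::tibble(name = "vm", unit = "mV", kind = "potential",
                   lower = -150, upper = 100,
                   description = "membrane potential"),
    g("m_late", "late Na+ activation gate"),
    g("h_late", "late Na+ inactivation gate"),
    tibble::tibble(name = "ca_trpn", unit = "uM", kind = "myofilament",
                   lower = 0, upper = 70,
                   description = "Ca2+ bound to myofilament troponin (NHS pool)"),
    tibble::tibble(name = "z_tm", unit = "1", kind = "myofilament",
                   lower = 0, upper = 1,
                   description = "fraction of actin sites made available by tropomyosin"),
    tibble::tibble(
      name = c("q1", "q2", "q3"), unit = "1", kind = "myofilament",
      lower = NA_real_, upper = NA_real_,
      description = "crossbridge fading-memory variable (stretch-rate driven)")
  )
  out$index <- seq_len(nrow(out))
  dplyr::relocate(out, "index")
}

#' Number of electrophysiology states (membrane model only)
#' @keywords internal
n_ep_states <- function() 41L

#' Index of a named state variable
#' @param name Character vector of registry names.
#' @return Integer indices into the state vector.
#' @keywords internal
state_index <- function(name) {
  reg <- state_registry()
  i <- match(name, reg$name)
  if (anyNA(i)) stop("unknown state name(s): ",
                     paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Default initial state of the coupled model
#'
#' The electrophysiology states start from the published resting state of the
#' ionic model (approximately the 1 Hz paced steady state of the original
#' formulation); the two late-sodium gates are initialised at their
#' steady-state values for the resting potential, and the myofilament states
#' start at zero so that active tension is exactly 0 kPa at time zero.
#'
#' @param params Parameter list from [gpb_parameters()].
#' @return Named numeric vector of length `nrow(state_registry())`.
#' @export
initial_state <- function(params = gpb_parameters()) {
  y <- c(
    m_na  = 1.405627e-3, h_na = 9.867005e-1, j_na = 9.915620e-1,
    d_ca  = 7.175662e-6, f_ca = 1.000681,
    fcab_junc = 2.421991e-2, fcab_sl = 1.452605e-2,
    x_tos = 4.051574e-3, y_tos = 9.945511e-1,
    x_tof = 4.051574e-3, y_tof = 9.945511e-1,
    x_kr  = 8.641386e-3, x_ks = 5.412034e-3,
    ryr_r = 8.884332e-1, ryr_o = 8.156628e-7, ryr_i = 1.024274e-7,
    nab_junc = 3.539892, nab_sl = 7.720854e-1,
    tnc_low = 8.773191e-3, tnc_high_ca = 1.078283e-1, tnc_high_mg = 1.524002e-2,
    cam = 2.911916e-4, myo_ca = 1.298754e-3, myo_mg = 1.381982e-1,
    srb = 2.143165e-3,
    sll_junc = 9.566355e-3, sll_sl = 1.110363e-1,
    slh_junc = 7.347888e-3, slh_sl = 7.297378e-2,
    csqn = 1.242988,
    ca_sr = 5.545201e-1,
    na_junc = 9.06, na_sl = 9.06, na_i = 9.06,
    k_i = 120,
    ca_junc = 1.737475e-4, ca_sl = 1.031812e-4, ca_i = 8.597401e-5,
    vm = -8.09763e+1,
    m_late = NA_real_, h_late = NA_real_,
    ca_trpn = 0, z_tm = 0, q1 = 0, q2 = 0, q3 = 0
  )
  lr <- late_na_gate_rates(y[["vm"]], params)
  y[["m_late"]] <- lr$alpha_mL / (lr$alpha_mL + lr$beta_mL)
  y[["h_late"]] <- lr$hL_inf
  # the published f gate value sits a hair above 1; clamp to the gate bound
  y[["f_ca"]] <- min(y[["f_ca"]], 1)
  stopifnot(identical(names(y), state_registry()$name))
  y
}

#' Validate a model state against the registry bounds
#'
#' Checks that every gating variable and buffer occupancy lies within its
#' bounds and that all ionic concentrations are strictly positive.
#'
#' @param state Named numeric state vector (see [state_registry()]).
#' @param tol Slack allowed beyond the nominal bounds (integration round-off).
#' @return Invisibly, `state`; signals an error naming the offending
#'   component otherwise.
#' @export
validate_state <- function(state, tol = 1e-6) {
  reg <- state_registry()
  if (length(state) != nrow(reg)) {
    stop("state vector has length ", length(state), ", expected ",
         nrow(reg), call. = FALSE)
  }
  if (!is.null(names(state)) && !identical(names(state), reg$name)) {
    stop("state names do not match the registry ordering", call. = FALSE)
  }
  if (any(!is.finite(state))) {
    stop("non-finite state component: ",
         paste(reg$name[!is.finite(state)], collapse = ", "), call. = FALSE)
  }
  lo_bad <- !is.na(reg$lower) & state < reg$lower - tol
  hi_bad <- !is.na(reg$upper) & state > reg$upper + tol
  conc_bad <- reg$kind == "concentration" & state <= 0
  bad <- lo_bad | hi_bad | conc_bad
  if (any(bad)) {
    stop("state component(s) out of bounds: ",
         paste(sprintf("%s=%g", reg$name[bad], state[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(state)
}
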