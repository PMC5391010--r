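#' Parameters of the modified ionic membrane model
#'
#' Returns the full constant set of the human ventricular ionic model:
#' physical constants, cell geometry and derived compartment volumes,
#' membrane partition fractions, external ion concentrations, maximal
#' conductances and transporter rates, SR flux parameters, and all buffer
#' capacities and rate constants.  Two constants differ from the original
#' published formulation: the junctional-to-subsarcolemmal and
#' subsarcolemmal-to-cytosol Ca diffusion constants are raised to
#' `1.2362e-12` and `7.4485e-12` L/ms so that the healthy cytosolic Ca
#' transient peaks near 1 uM, as required by the downstream myofilament
#' model.  The late Na current adds `g_NaL` (mS/uF) and `tau_hL` (ms).
#'
#' Units: time ms, voltage mV, membrane currents uA/uF, concentrations mM,
#' fluxes mM/ms, volumes L.
#'
#' @param ... Named overrides of individual constants, e.g.
#'   `gpb_parameters(g_NaL = 0)`.  Unknown names are rejected.
#' @return Named list of constants.
#' @export
#' @examples
#' p <- gpb_parameters()
#' p$J_ca_juncsl
gpb_parameters <- function(...) {
  # physical constants
  R_gas <- 8314       # J/(kmol K)
  Frdy  <- 96485      # C/mol
  Temp  <- 310        # K
  # cell geometry (um); volumes in L
  cellLength <- 100
  cellRadius <- 10.25
  Vcell <- pi * cellRadius^2 * cellLength * 1e-15
  p <- list(
    R_gas = R_gas, Frdy = Frdy, Temp = Temp, FoRT = Frdy / (R_gas * Temp),
    Cmem = 1.381e-10,          # F, membrane capacitance
    Vcell = Vcell,
    Vmyo  = 0.65 * Vcell, Vsr = 0.035 * Vcell,
    Vsl   = 0.02 * Vcell, Vjunc = 0.0539 * 0.01 * Vcell,
    # inter-compartment diffusion constants (L/ms); the two Ca constants are
    # the adjusted values of the modified model (original: 8.2413e-13 and
    # 3.7243e-12)
    J_ca_juncsl = 1.2362e-12, J_ca_slmyo = 7.4485e-12,
    J_na_juncsl = 1 / (1.6382e12 / 3 * 100),
    J_na_slmyo  = 1 / (1.8308e10 / 3 * 100),
    # membrane partition fractions
    Fjunc = 0.11, Fsl = 0.89, Fjunc_CaL = 0.9, Fsl_CaL = 0.1,
    # fixed ion concentrations (mM)
    Cli = 15, Clo = 150, Ko = 5.4, Nao = 140, Cao = 1.8, Mgi = 1,
    # fast / background / late Na and Na/K pump
    GNa = 23, GNaB = 0.597e-3, IbarNaK = 1.8, KmNaip = 11, KmKo = 1.5,
    g_NaL = 0.0065, tau_hL = 233,
    # K currents
    pNaK = 0.01833, gkp = 0.002, gkr_coef = 0.035, gks = 0.0035,
    GtoSlow = 0.13 * 0.12, GtoFast = 0.13 * 0.88, gki_coef = 0.35,
    # Cl currents
    GClCa = 0.5 * 0.109625, GClB = 9e-3, KdClCa = 100e-3,
    # L-type Ca channel permeabilities (cm/s) and open-probability scale
    pNa = 0.5 * 1.5e-8, pCa = 0.5 * 5.4e-4, pK = 0.5 * 2.7e-7,
    ICaL_scale = 0.45,
    # Na/Ca exchanger
    IbarNCX = 4.5, KmCai = 3.59e-3, KmCao = 1.3, KmNai = 12.29,
    KmNao = 87.5, ksat = 0.32, nu = 0.27, Kdact = 0.150e-3,
    # sarcolemmal Ca pump and background Ca
    IbarSLCaP = 0.0673, KmPCa = 0.5e-3, GCaB = 5.513e-4,
    # SR fluxes: SERCA, RyR release, leak
    Vmax_SRCaP = 5.3114e-3, Kmf = 0.246e-3, Kmr = 1.7, hillSRCaP = 1.787,
    ks_rel = 25, koCa = 10, kom = 0.06, kiCa = 0.5, kim = 0.005,
    ec50SR = 0.45, MaxSR = 15, MinSR = 1, leak_coef = 5.348e-6,
    # Na buffers
    Bmax_Naj = 7.561, Bmax_Nasl = 1.65, koff_na = 1e-3, kon_na = 0.1e-3,
    # cytosolic Ca buffers
    Bmax_TnClow = 70e-3, koff_tncl = 19.6e-3, kon_tncl = 32.7,
    Bmax_TnChigh = 140e-3, koff_tnchca = 0.032e-3, kon_tnchca = 2.37,
    koff_tnchmg = 3.33e-3, kon_tnchmg = 3e-3,
    Bmax_CaM = 24e-3, koff_cam = 238e-3, kon_cam = 34,
    Bmax_myosin = 140e-3, koff_myoca = 0.46e-3, kon_myoca = 13.8,
    koff_myomg = 0.057e-3, kon_myomg = 0.0157,
    Bmax_SR = 19 * 0.9e-3, koff_sr = 60e-3, kon_sr = 100,
    # sarcolemmal Ca buffers (capacities scale with compartment volume)
    koff_sll = 1300e-3, kon_sll = 100, koff_slh = 30e-3, kon_slh = 100,
    # calsequestrin
    koff_csqn = 65, kon_csqn = 100
  )
  p$Bmax_SLlowsl  <- 37.4e-3 * p$Vmyo / p$Vsl
  p$Bmax_SLlowj   <- 4.6e-3 * p$Vmyo / p$Vjunc * 0.1
  p$Bmax_SLhighsl <- 13.4e-3 * p$Vmyo / p$Vsl
  p$Bmax_SLhighj  <- 1.65e-3 * p$Vmyo / p$Vjunc * 0.1
  p$Bmax_Csqn     <- 140e-3 * p$Vmyo / p$Vsr
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_gpb_parameters(p)
  p
}

#' @keywords internal
validate_gpb_parameters <- function(p) {
  nonneg <- c("GNa", "GNaB", "IbarNaK", "g_NaL", "tau_hL", "gkp", "gks",
              "GtoSlow", "GtoFast", "GClCa", "GClB", "pNa", "pCa", "pK",
              "IbarNCX", "IbarSLCaP", "GCaB", "Vmax_SRCaP", "ks_rel",
              "leak_coef", "Vmyo", "Vsr", "Vsl", "Vjunc",
              "J_ca_juncsl", "J_ca_slmyo", "J_na_juncsl", "J_na_slmyo",
              "Bmax_Naj", "Bmax_Nasl", "Bmax_TnClow", "Bmax_TnChigh",
              "Bmax_CaM", "Bmax_myosin", "Bmax_SR", "Bmax_SLlowsl",
              "Bmax_SLlowj", "Bmax_SLhighsl", "Bmax_SLhighj", "Bmax_Csqn")
  bad <- vapply(p[nonneg], function(x) !is.finite(x) || x < 0, logical(1))
  if (any(bad)) {
    stop("parameter(s) must be finite and non-negative: ",
         paste(nonneg[bad], collapse = ", "), call. = FALSE)
  }
  if (abs(p$Fjunc + p$Fsl - 1) > 1e-12 ||
      abs(p$Fjunc_CaL + p$Fsl_CaL - 1) > 1e-12) {
    stop("membrane partition fractions must sum to 1", call. = FALSE)
  }
  invisible(p)
}

#' Parameters of the NHS myofilament model
#'
#' Constants of the Niederer-Hunter-Smith contraction model in its native
#' units (seconds, micromolar, kPa): troponin Ca binding, tropomyosin
#' kinetics, length dependence and the crossbridge fading-memory terms.
#'
#' @param ... Named overrides, as in [gpb_parameters()].
#' @return Named list of constants.
#' @export
nhs_parameters <- function(...) {
  p <- list(
    k_on = 100,          # 1/(uM s), Ca binding to troponin
    k_ref_off = 200,     # 1/s, reference unbinding rate
    gamma_trpn = 2,      # tension dependence of unbinding
    Ca_TRPN_max = 70,    # uM, troponin site capacity
    alpha_0 = 8,         # 1/s, tropomyosin activation rate scale
    alpha_r1 = 2,        # 1/s, linear relaxation rate
    alpha_r2 = 1.75,     # 1/s, nonlinear relaxation rate scale
    n_rel = 3,           # relaxation Hill exponent
    K_z = 0.15,          # relaxation half-point
    n_hill = 3,          # activation Hill exponent
    Ca_50ref = 1.05,     # uM, reference Ca sensitivity
    z_p = 0.85,          # linearisation point for z_max
    beta_0 = 4.9,        # length dependence of tension
    beta_1 = -4,         # length dependence of Ca sensitivity
    T_ref = 56.2,        # kPa, reference tension at resting length
    a_xb = 0.35,         # crossbridge curvature parameter
    A_1 = -29, A_2 = 138, A_3 = 129,          # fading-memory amplitudes
    alpha_1 = 30, alpha_2 = 130, alpha_3 = 625,  # 1/s, memory rates
    lambda_min = 0.8, lambda_max = 1.15       # stretch validity window
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  p
}

# ---------------------------------------------------------------------------
# Flat parameter vector passed to the compiled right-hand side.  The C code
# indexes this vector positionally (same order as here); the R reference
# implementation consumes the same vector by name.  Any misalignment is
# caught by the R-vs-C agreement test.
# ---------------------------------------------------------------------------

#' @keywords internal
ode_parameter_vector <- function(params = gpb_parameters(),
                                 factors = impact_factors(),
                                 nhs = nhs_parameters(),
                                 stim_amplitude = 0,
                                 lambda = 1, dlambda_dt = 0) {
  f <- as_impact_factors(factors)
  c(
    # physical / geometry
    Frdy = params$Frdy, FoRT = params$FoRT, Cmem = params$Cmem,
    Vmyo = params$Vmyo, Vsr = params$Vsr, Vsl = params$Vsl,
    Vjunc = params$Vjunc,
    J_ca_juncsl = params$J_ca_juncsl, J_ca_slmyo = params$J_ca_slmyo,
    J_na_juncsl = params$J_na_juncsl, J_na_slmyo = params$J_na_slmyo,
    Fjunc = params$Fjunc, Fsl = params$Fsl,
    Fjunc_CaL = params$Fjunc_CaL, Fsl_CaL = params$Fsl_CaL,
    Cli = params$Cli, Clo = params$Clo, Ko = params$Ko,
    Nao = params$Nao, Cao = params$Cao, Mgi = params$Mgi,
    # Na currents / pump
    GNa = params$GNa, GNaB = params$GNaB, IbarNaK = params$IbarNaK,
    KmNaip = params$KmNaip, KmKo = params$KmKo,
    g_NaL = params$g_NaL, tau_hL = params$tau_hL,
    # K currents
    pNaK = params$pNaK, gkp = params$gkp, gkr_coef = params$gkr_coef,
    gks = params$gks, GtoSlow = params$GtoSlow, GtoFast = params$GtoFast,
    gki_coef = params$gki_coef,
    # Cl currents
    GClCa = params$GClCa, GClB = params$GClB, KdClCa = params$KdClCa,
    # L-type Ca
    pNa = params$pNa, pCa = params$pCa, pK = params$pK,
    ICaL_scale = params$ICaL_scale,
    # NCX
    IbarNCX = params$IbarNCX, KmCai = params$KmCai, KmCao = params$KmCao,
    KmNai = params$KmNai, KmNao = params$KmNao, ksat = params$ksat,
    nu = params$nu, Kdact = params$Kdact,
    # sarcolemmal Ca pump / background Ca
    IbarSLCaP = params$IbarSLCaP, KmPCa = params$KmPCa, GCaB = params$GCaB,
    # SR fluxes
    Vmax_SRCaP = params$Vmax_SRCaP, Kmf = params$Kmf, Kmr = params$Kmr,
    hillSRCaP = params$hillSRCaP, ks_rel = params$ks_rel,
    koCa = params$koCa, kom = params$kom, kiCa = params$kiCa,
    kim = params$kim, ec50SR = params$ec50SR, MaxSR = params$MaxSR,
    MinSR = params$MinSR, leak_coef = params$leak_coef,
    # buffers
    Bmax_Naj = params$Bmax_Naj, Bmax_Nasl = params$Bmax_Nasl,
    koff_na = params$koff_na, kon_na = params$kon_na,
    Bmax_TnClow = params$Bmax_TnClow, koff_tncl = params$koff_tncl,
    kon_tncl = params$kon_tncl, Bmax_TnChigh = params$Bmax_TnChigh,
    koff_tnchca = params$koff_tnchca, kon_tnchca = params$kon_tnchca,
    koff_tnchmg = params$koff_tnchmg, kon_tnchmg = params$kon_tnchmg,
    Bmax_CaM = params$Bmax_CaM, koff_cam = params$koff_cam,
    kon_cam = params$kon_cam, Bmax_myosin = params$Bmax_myosin,
    koff_myoca = params$koff_myoca, kon_myoca = params$kon_myoca,
    koff_myomg = params$koff_myomg, kon_myomg = params$kon_myomg,
    Bmax_SR = params$Bmax_SR, koff_sr = params$koff_sr,
    kon_sr = params$kon_sr,
    Bmax_SLlowsl = params$Bmax_SLlowsl, Bmax_SLlowj = params$Bmax_SLlowj,
    koff_sll = params$koff_sll, kon_sll = params$kon_sll,
    Bmax_SLhighsl = params$Bmax_SLhighsl, Bmax_SLhighj = params$Bmax_SLhighj,
    koff_slh = params$koff_slh, kon_slh = params$kon_slh,
    Bmax_Csqn = params$Bmax_Csqn, koff_csqn = params$koff_csqn,
    kon_csqn = params$kon_csqn,
    # impact factors (healthy-to-failing remodelling multipliers)
    f_hl = f[["f_hl"]], f_NaL = f[["f_NaL"]], f_Ki = f[["f_Ki"]],
    f_NaK = f[["f_NaK"]], f_Nabk = f[["f_Nabk"]], f_Cabk = f[["f_Cabk"]],
    f_ncx = f[["f_ncx"]], f_to = f[["f_to"]], f_SRleak = f[["f_SRleak"]],
    f_SRca = f[["f_SRca"]], f_EC50SR = f[["f_EC50SR"]],
    # stimulus (amplitude in uA/uF; nonzero only during the pulse segment)
    stim_amplitude = stim_amplitude,
    # NHS myofilament block (native units s, uM, kPa)
    k_on = nhs$k_on, k_ref_off = nhs$k_ref_off, gamma_trpn = nhs$gamma_trpn,
    Ca_TRPN_max = nhs$Ca_TRPN_max, alpha_0 = nhs$alpha_0,
    alpha_r1 = nhs$alpha_r1, alpha_r2 = nhs$alpha_r2, n_rel = nhs$n_rel,
    K_z = nhs$K_z, n_hill = nhs$n_hill, Ca_50ref = nhs$Ca_50ref,
    z_p = nhs$z_p, beta_0 = nhs$beta_0, beta_1 = nhs$beta_1,
    T_ref = nhs$T_ref, a_xb = nhs$a_xb,
    A_1 = nhs$A_1, A_2 = nhs$A_2, A_3 = nhs$A_3,
    alpha_1 = nhs$alpha_1, alpha_2 = nhs$alpha_2, alpha_3 = nhs$alpha_3,
    lambda = lambda, dlambda_dt = dlambda_dt
  )
}
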