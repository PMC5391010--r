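# Reference (pure R) implementation of the modified ionic membrane model and
# the coupled myofilament block.  The compiled right-hand side in src/ is the
# production path for integration; this implementation is the readable source
# of truth and the two are required by the test suite to agree to round-off
# at arbitrary valid states.

# limit-protected x*(ci*e^x - co)/(e^x - 1), the voltage-dependent part of a
# Goldman-Hodgkin-Katz flux; |x| below the guard uses the series limit so the
# removable singularity at Vm = 0 never produces NaN
ghk_factor <- function(x, ci, co, guard = 1e-5) {
  if (abs(x) < guard) (ci - co) + x * (ci + co) / 2
  else x * (ci * exp(x) - co) / expm1(x)
}

#' Opening and closing rates of the late sodium gates
#'
#' Voltage-dependent kinetics of the late Na current: activation rates
#' `alpha_mL`, `beta_mL` (1/ms), steady-state inactivation `hL_inf`, and the
#' effective inactivation time constant `tau_hL_eff = f_hl * tau_hL`.
#' The activation opening rate has a removable singularity at
#' Vm = -47.13 mV, which is evaluated by its analytic limit.
#'
#' @param Vm Membrane potential (mV), finite scalar.
#' @param params Parameter list from [gpb_parameters()] (uses `tau_hL`).
#' @param f_hl Impact factor scaling the inactivation time constant.
#' @return A list with `alpha_mL`, `beta_mL`, `hL_inf`, `tau_hL_eff`.
#' @export
#' @examples
#' late_na_gate_rates(-47.13)$alpha_mL  # analytic limit 0.32/0.1
late_na_gate_rates <- function(Vm, params = gpb_parameters(), f_hl = 1) {
  if (!is.numeric(Vm) || length(Vm) != 1 || !is.finite(Vm)) {
    stop("`Vm` must be a finite scalar", call. = FALSE)
  }
  u <- Vm + 47.13
  alpha_mL <- if (abs(0.1 * u) < 1e-4) {
    0.32 / 0.1 * (1 + 0.05 * u)       # series limit at the singular voltage
  } else {
    0.32 * u / (1 - exp(-0.1 * u))
  }
  beta_mL <- 0.08 * exp(-Vm / 11)
  # steady-state inactivation; standard sigmoid form (the 1/(1 - e^x)
  # variant sometimes printed is negative for Vm > -91 mV and cannot be a
  # gate; see MODEL_NOTES.md)
  hL_inf <- 1 / (1 + exp((Vm + 91) / 6.1))
  list(alpha_mL = alpha_mL, beta_mL = beta_mL, hL_inf = hL_inf,
       tau_hL_eff = f_hl * params$tau_hL)
}

#' Late sodium current
#'
#' Hodgkin-Huxley late Na current, split between the junctional and
#' subsarcolemmal membrane fractions:
#' `I_NaL_junc = Fjunc * (f_NaL * g_NaL) * mL^3 * hL * (Vm - E_junc)` and
#' analogously for the subsarcolemmal part, with `I_NaL` their sum.
#'
#' @param Vm Membrane potential (mV).
#' @param mL,hL Activation / inactivation gate values in `[0, 1]`.
#' @param params Parameter list from [gpb_parameters()].
#' @param nernst_junc,nernst_sl Na Nernst potentials of the two compartments
#'   (mV).
#' @param f_NaL Impact factor scaling the maximal conductance.
#' @return A list with `I_NaL_junc`, `I_NaL_sl`, `I_NaL` (uA/uF).
#' @export
late_na_current <- function(Vm, mL, hL, params = gpb_parameters(),
                            nernst_junc, nernst_sl, f_NaL = 1) {
  if (!is.finite(Vm)) stop("`Vm` must be finite", call. = FALSE)
  if (mL < 0 || mL > 1 || hL < 0 || hL > 1) {
    stop("gates `mL` and `hL` must lie in [0, 1]", call. = FALSE)
  }
  g <- f_NaL * params$g_NaL * mL^3 * hL
  I_junc <- params$Fjunc * g * (Vm - nernst_junc)
  I_sl <- params$Fsl * g * (Vm - nernst_sl)
  list(I_NaL_junc = I_junc, I_NaL_sl = I_sl, I_NaL = I_junc + I_sl)
}

# Full model evaluation at one state: all currents/fluxes and all state
# derivatives.  `pv` is the flat named parameter vector from
# ode_parameter_vector(); `stim` is the applied current (uA/uF) added to the
# membrane equation with dVm/dt = -(I_tot + stim).
model_eval_r <- function(t, y, pv, stim = 0) {
  P <- function(nm) pv[[nm]]
  Y <- function(nm) y[[nm]]
  FoRT <- P("FoRT"); Frdy <- P("Frdy")
  Vm <- Y("vm")

  # Nernst potentials
  ena_junc <- (1 / FoRT) * log(P("Nao") / Y("na_junc"))
  ena_sl   <- (1 / FoRT) * log(P("Nao") / Y("na_sl"))
  ek       <- (1 / FoRT) * log(P("Ko") / Y("k_i"))
  eca_junc <- (1 / (2 * FoRT)) * log(P("Cao") / Y("ca_junc"))
  eca_sl   <- (1 / (2 * FoRT)) * log(P("Cao") / Y("ca_sl"))
  ecl      <- (1 / FoRT) * log(P("Cli") / P("Clo"))

  # --- fast Na current -----------------------------------------------------
  mss <- 1 / (1 + exp(-(56.86 + Vm) / 9.03))^2
  taum <- 0.1292 * exp(-((Vm + 45.79) / 15.54)^2) +
    0.06487 * exp(-((Vm - 4.823) / 51.12)^2)
  if (Vm >= -40) {
    ah <- 0
    bh <- 0.77 / (0.13 * (1 + exp(-(Vm + 10.66) / 11.1)))
    aj <- 0
    bj <- 0.6 * exp(0.057 * Vm) / (1 + exp(-0.1 * (Vm + 32)))
  } else {
    ah <- 0.057 * exp(-(Vm + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * Vm) + 3.1e5 * exp(0.3485 * Vm)
    aj <- (-2.5428e4 * exp(0.2444 * Vm) - 6.948e-6 * exp(-0.04391 * Vm)) *
      (Vm + 37.78) / (1 + exp(0.311 * (Vm + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * Vm) / (1 + exp(-0.1378 * (Vm + 40.14)))
  }
  tauh <- 1 / (ah + bh); hss <- 1 / (1 + exp((Vm + 71.55) / 7.43))^2
  tauj <- 1 / (aj + bj); jss <- hss
  d_m <- (mss - Y("m_na")) / taum
  d_h <- (hss - Y("h_na")) / tauh
  d_j <- (jss - Y("j_na")) / tauj
  gNa_open <- P("GNa") * Y("m_na")^3 * Y("h_na") * Y("j_na")
  I_Na_junc <- P("Fjunc") * gNa_open * (Vm - ena_junc)
  I_Na_sl <- P("Fsl") * gNa_open * (Vm - ena_sl)

  # --- late Na current -----------------------------------------------------
  u <- Vm + 47.13
  alpha_mL <- if (abs(0.1 * u) < 1e-4) 0.32 / 0.1 * (1 + 0.05 * u)
              else 0.32 * u / (1 - exp(-0.1 * u))
  beta_mL <- 0.08 * exp(-Vm / 11)
  hL_inf <- 1 / (1 + exp((Vm + 91) / 6.1))
  d_mL <- alpha_mL * (1 - Y("m_late")) - beta_mL * Y("m_late")
  d_hL <- (hL_inf - Y("h_late")) / (P("f_hl") * P("tau_hL"))
  gNaL_open <- P("f_NaL") * P("g_NaL") * Y("m_late")^3 * Y("h_late")
  I_NaL_junc <- P("Fjunc") * gNaL_open * (Vm - ena_junc)
  I_NaL_sl <- P("Fsl") * gNaL_open * (Vm - ena_sl)

  # --- background Na and Na/K pump -----------------------------------------
  I_nabk_junc <- P("f_Nabk") * P("Fjunc") * P("GNaB") * (Vm - ena_junc)
  I_nabk_sl <- P("f_Nabk") * P("Fsl") * P("GNaB") * (Vm - ena_sl)
  sigma <- (exp(P("Nao") / 67.3) - 1) / 7
  fnak <- 1 / (1 + 0.1245 * exp(-0.1 * Vm * FoRT) +
                 0.0365 * sigma * exp(-Vm * FoRT))
  nak_scale <- P("f_NaK") * P("IbarNaK") * fnak * P("Ko") /
    (P("Ko") + P("KmKo"))
  I_nak_junc <- P("Fjunc") * nak_scale / (1 + (P("KmNaip") / Y("na_junc"))^4)
  I_nak_sl <- P("Fsl") * nak_scale / (1 + (P("KmNaip") / Y("na_sl"))^4)

  # --- K currents ----------------------------------------------------------
  gkr <- P("gkr_coef") * sqrt(P("Ko") / 5.4)
  xrss <- 1 / (1 + exp(-(Vm + 10) / 5))
  tauxr <- 550 / (1 + exp((-22 - Vm) / 9)) * 6 / (1 + exp((Vm + 11) / 9)) +
    230 / (1 + exp((Vm + 40) / 20))
  d_xkr <- (xrss - Y("x_kr")) / tauxr
  rkr <- 1 / (1 + exp((Vm + 74) / 24))
  I_kr <- gkr * Y("x_kr") * rkr * (Vm - ek)

  eks <- (1 / FoRT) * log((P("Ko") + P("pNaK") * P("Nao")) /
                            (Y("k_i") + P("pNaK") * Y("na_i")))
  xsss <- 1 / (1 + exp(-(Vm + 3.8) / 14.25))
  tauxs <- 990.1 / (1 + exp(-(Vm + 2.436) / 14.12))
  d_xks <- (xsss - Y("x_ks")) / tauxs
  I_ks <- P("gks") * Y("x_ks")^2 * (Vm - eks)   # junc+sl fractions sum to 1

  kp_kp <- 1 / (1 + exp(7.488 - Vm / 5.98))
  I_kp <- P("gkp") * kp_kp * (Vm - ek)

  xtoss <- 1 / (1 + exp(-(Vm - 19.0) / 13))
  ytoss <- 1 / (1 + exp((Vm + 19.5) / 5))
  tauxtos <- 9 / (1 + exp((Vm + 3.0) / 15)) + 0.5
  tauytos <- 800 / (1 + exp((Vm + 60.0) / 10)) + 30
  d_xtos <- (xtoss - Y("x_tos")) / tauxtos
  d_ytos <- (ytoss - Y("y_tos")) / tauytos
  I_tos <- P("f_to") * P("GtoSlow") * Y("x_tos") * Y("y_tos") * (Vm - ek)
  tauxtof <- 8.5 * exp(-((Vm + 45) / 50)^2) + 0.5
  tauytof <- 85 * exp(-(Vm + 40)^2 / 220) + 7
  d_xtof <- (xtoss - Y("x_tof")) / tauxtof
  d_ytof <- (ytoss - Y("y_tof")) / tauytof
  I_tof <- P("f_to") * P("GtoFast") * Y("x_tof") * Y("y_tof") * (Vm - ek)
  I_to <- I_tos + I_tof

  aki <- 1.02 / (1 + exp(0.2385 * (Vm - ek - 59.215)))
  bki <- (0.49124 * exp(0.08032 * (Vm + 5.476 - ek)) +
            exp(0.06175 * (Vm - ek - 594.31))) /
    (1 + exp(-0.5143 * (Vm - ek + 4.753)))
  kiss <- aki / (aki + bki)
  I_ki <- P("f_Ki") * P("gki_coef") * sqrt(P("Ko") / 5.4) * kiss * (Vm - ek)

  # --- Cl currents ---------------------------------------------------------
  I_ClCa_junc <- P("Fjunc") * P("GClCa") / (1 + P("KdClCa") / Y("ca_junc")) *
    (Vm - ecl)
  I_ClCa_sl <- P("Fsl") * P("GClCa") / (1 + P("KdClCa") / Y("ca_sl")) *
    (Vm - ecl)
  I_ClCa <- I_ClCa_junc + I_ClCa_sl
  I_Clbk <- P("GClB") * (Vm - ecl)

  # --- L-type Ca current ---------------------------------------------------
  dss <- 1 / (1 + exp(-(Vm + 5) / 6))
  ud <- Vm + 5
  taud <- if (abs(ud) < 1e-4) dss / 0.21 * (1 - ud / 12)
          else dss * (1 - exp(-ud / 6)) / (0.035 * ud)
  fss <- 1 / (1 + exp((Vm + 35) / 9)) + 0.6 / (1 + exp((50 - Vm) / 20))
  tauf <- 1 / (0.0197 * exp(-(0.0337 * (Vm + 14.5))^2) + 0.02)
  d_d <- (dss - Y("d_ca")) / taud
  d_f <- (fss - Y("f_ca")) / tauf
  d_fcabj <- 1.7 * Y("ca_junc") * (1 - Y("fcab_junc")) -
    11.9e-3 * Y("fcab_junc")
  d_fcabsl <- 1.7 * Y("ca_sl") * (1 - Y("fcab_sl")) - 11.9e-3 * Y("fcab_sl")
  ibarca_j <- P("pCa") * 2 * Frdy *
    ghk_factor(2 * Vm * FoRT, 0.341 * Y("ca_junc"), 0.341 * P("Cao"))
  ibarca_sl <- P("pCa") * 2 * Frdy *
    ghk_factor(2 * Vm * FoRT, 0.341 * Y("ca_sl"), 0.341 * P("Cao"))
  ibark <- P("pK") * Frdy *
    ghk_factor(Vm * FoRT, 0.75 * Y("k_i"), 0.75 * P("Ko"))
  ibarna_j <- P("pNa") * Frdy *
    ghk_factor(Vm * FoRT, 0.75 * Y("na_junc"), 0.75 * P("Nao"))
  ibarna_sl <- P("pNa") * Frdy *
    ghk_factor(Vm * FoRT, 0.75 * Y("na_sl"), 0.75 * P("Nao"))
  po <- Y("d_ca") * Y("f_ca") * P("ICaL_scale")
  I_Ca_junc <- P("Fjunc_CaL") * ibarca_j * po * (1 - Y("fcab_junc"))
  I_Ca_sl <- P("Fsl_CaL") * ibarca_sl * po * (1 - Y("fcab_sl"))
  I_CaK <- ibark * po * (P("Fjunc_CaL") * (1 - Y("fcab_junc")) +
                           P("Fsl_CaL") * (1 - Y("fcab_sl")))
  I_CaNa_junc <- P("Fjunc_CaL") * ibarna_j * po * (1 - Y("fcab_junc"))
  I_CaNa_sl <- P("Fsl_CaL") * ibarna_sl * po * (1 - Y("fcab_sl"))

  # --- Na/Ca exchanger -----------------------------------------------------
  Ka_junc <- 1 / (1 + (P("Kdact") / Y("ca_junc"))^2)
  Ka_sl <- 1 / (1 + (P("Kdact") / Y("ca_sl"))^2)
  s1_junc <- exp(P("nu") * Vm * FoRT) * Y("na_junc")^3 * P("Cao")
  s1_sl <- exp(P("nu") * Vm * FoRT) * Y("na_sl")^3 * P("Cao")
  s2_junc <- exp((P("nu") - 1) * Vm * FoRT) * P("Nao")^3 * Y("ca_junc")
  s2_sl <- exp((P("nu") - 1) * Vm * FoRT) * P("Nao")^3 * Y("ca_sl")
  s3_junc <- P("KmCai") * P("Nao")^3 * (1 + (Y("na_junc") / P("KmNai"))^3) +
    P("KmNao")^3 * Y("ca_junc") * (1 + Y("ca_junc") / P("KmCai")) +
    P("KmCao") * Y("na_junc")^3 + Y("na_junc")^3 * P("Cao") +
    P("Nao")^3 * Y("ca_junc")
  s3_sl <- P("KmCai") * P("Nao")^3 * (1 + (Y("na_sl") / P("KmNai"))^3) +
    P("KmNao")^3 * Y("ca_sl") * (1 + Y("ca_sl") / P("KmCai")) +
    P("KmCao") * Y("na_sl")^3 + Y("na_sl")^3 * P("Cao") +
    P("Nao")^3 * Y("ca_sl")
  ksat_term <- 1 + P("ksat") * exp((P("nu") - 1) * Vm * FoRT)
  I_ncx_junc <- P("f_ncx") * P("Fjunc") * P("IbarNCX") * Ka_junc *
    (s1_junc - s2_junc) / s3_junc / ksat_term
  I_ncx_sl <- P("f_ncx") * P("Fsl") * P("IbarNCX") * Ka_sl *
    (s1_sl - s2_sl) / s3_sl / ksat_term

  # --- sarcolemmal Ca pump and background Ca -------------------------------
  I_pca_junc <- P("Fjunc") * P("IbarSLCaP") * Y("ca_junc")^1.6 /
    (P("KmPCa")^1.6 + Y("ca_junc")^1.6)
  I_pca_sl <- P("Fsl") * P("IbarSLCaP") * Y("ca_sl")^1.6 /
    (P("KmPCa")^1.6 + Y("ca_sl")^1.6)
  I_cabk_junc <- P("f_Cabk") * P("Fjunc") * P("GCaB") * (Vm - eca_junc)
  I_cabk_sl <- P("f_Cabk") * P("Fsl") * P("GCaB") * (Vm - eca_sl)

  # --- SR fluxes -----------------------------------------------------------
  ec50 <- P("f_EC50SR") * P("ec50SR")
  kCaSR <- P("MaxSR") - (P("MaxSR") - P("MinSR")) /
    (1 + (ec50 / Y("ca_sr"))^2.5)
  koSRCa <- P("koCa") / kCaSR
  kiSRCa <- P("kiCa") * kCaSR
  RI <- 1 - Y("ryr_r") - Y("ryr_o") - Y("ryr_i")
  d_ryr_r <- (P("kim") * RI - kiSRCa * Y("ca_junc") * Y("ryr_r")) -
    (koSRCa * Y("ca_junc")^2 * Y("ryr_r") - P("kom") * Y("ryr_o"))
  d_ryr_o <- (koSRCa * Y("ca_junc")^2 * Y("ryr_r") - P("kom") * Y("ryr_o")) -
    (kiSRCa * Y("ca_junc") * Y("ryr_o") - P("kim") * Y("ryr_i"))
  d_ryr_i <- (kiSRCa * Y("ca_junc") * Y("ryr_o") - P("kim") * Y("ryr_i")) -
    (P("kom") * Y("ryr_i") - koSRCa * Y("ca_junc")^2 * RI)
  J_SRCarel <- P("ks_rel") * Y("ryr_o") * (Y("ca_sr") - Y("ca_junc"))
  J_serca <- P("f_SRca") * P("Vmax_SRCaP") *
    ((Y("ca_i") / P("Kmf"))^P("hillSRCaP") -
       (Y("ca_sr") / P("Kmr"))^P("hillSRCaP")) /
    (1 + (Y("ca_i") / P("Kmf"))^P("hillSRCaP") +
       (Y("ca_sr") / P("Kmr"))^P("hillSRCaP"))
  J_SRleak <- P("f_SRleak") * P("leak_coef") * (Y("ca_sr") - Y("ca_junc"))

  # --- buffering -----------------------------------------------------------
  d_nabj <- P("kon_na") * Y("na_junc") * (P("Bmax_Naj") - Y("nab_junc")) -
    P("koff_na") * Y("nab_junc")
  d_nabsl <- P("kon_na") * Y("na_sl") * (P("Bmax_Nasl") - Y("nab_sl")) -
    P("koff_na") * Y("nab_sl")
  d_tncl <- P("kon_tncl") * Y("ca_i") * (P("Bmax_TnClow") - Y("tnc_low")) -
    P("koff_tncl") * Y("tnc_low")
  tnch_free <- P("Bmax_TnChigh") - Y("tnc_high_ca") - Y("tnc_high_mg")
  d_tnchca <- P("kon_tnchca") * Y("ca_i") * tnch_free -
    P("koff_tnchca") * Y("tnc_high_ca")
  d_tnchmg <- P("kon_tnchmg") * P("Mgi") * tnch_free -
    P("koff_tnchmg") * Y("tnc_high_mg")
  d_cam <- P("kon_cam") * Y("ca_i") * (P("Bmax_CaM") - Y("cam")) -
    P("koff_cam") * Y("cam")
  myo_free <- P("Bmax_myosin") - Y("myo_ca") - Y("myo_mg")
  d_myoca <- P("kon_myoca") * Y("ca_i") * myo_free -
    P("koff_myoca") * Y("myo_ca")
  d_myomg <- P("kon_myomg") * P("Mgi") * myo_free -
    P("koff_myomg") * Y("myo_mg")
  d_srb <- P("kon_sr") * Y("ca_i") * (P("Bmax_SR") - Y("srb")) -
    P("koff_sr") * Y("srb")
  J_CaB_cytosol <- d_tncl + d_tnchca + d_tnchmg + d_cam + d_myoca +
    d_myomg + d_srb
  d_sllj <- P("kon_sll") * Y("ca_junc") * (P("Bmax_SLlowj") - Y("sll_junc")) -
    P("koff_sll") * Y("sll_junc")
  d_sllsl <- P("kon_sll") * Y("ca_sl") * (P("Bmax_SLlowsl") - Y("sll_sl")) -
    P("koff_sll") * Y("sll_sl")
  d_slhj <- P("kon_slh") * Y("ca_junc") * (P("Bmax_SLhighj") - Y("slh_junc")) -
    P("koff_slh") * Y("slh_junc")
  d_slhsl <- P("kon_slh") * Y("ca_sl") * (P("Bmax_SLhighsl") - Y("slh_sl")) -
    P("koff_slh") * Y("slh_sl")
  J_CaB_junction <- d_sllj + d_slhj
  J_CaB_sl <- d_sllsl + d_slhsl
  d_csqn <- P("kon_csqn") * Y("ca_sr") * (P("Bmax_Csqn") - Y("csqn")) -
    P("koff_csqn") * Y("csqn")

  # --- ion balances --------------------------------------------------------
  d_casr <- J_serca - (J_SRleak * P("Vmyo") / P("Vsr") + J_SRCarel) - d_csqn
  I_Na_tot_junc <- I_Na_junc + I_nabk_junc + 3 * I_ncx_junc +
    3 * I_nak_junc + I_CaNa_junc + I_NaL_junc
  I_Na_tot_sl <- I_Na_sl + I_nabk_sl + 3 * I_ncx_sl + 3 * I_nak_sl +
    I_CaNa_sl + I_NaL_sl
  CmF <- P("Cmem") / Frdy
  d_naj <- -I_Na_tot_junc * CmF / P("Vjunc") +
    P("J_na_juncsl") / P("Vjunc") * (Y("na_sl") - Y("na_junc")) - d_nabj
  d_nasl <- -I_Na_tot_sl * CmF / P("Vsl") +
    P("J_na_juncsl") / P("Vsl") * (Y("na_junc") - Y("na_sl")) +
    P("J_na_slmyo") / P("Vsl") * (Y("na_i") - Y("na_sl")) - d_nabsl
  d_nai <- P("J_na_slmyo") / P("Vmyo") * (Y("na_sl") - Y("na_i"))
  I_nak <- I_nak_junc + I_nak_sl
  I_K_tot <- I_to + I_kr + I_ks + I_ki - 2 * I_nak + I_CaK + I_kp
  d_ki <- 0   # bulk K clamped, as in the source model
  I_Ca_tot_junc <- I_Ca_junc + I_cabk_junc + I_pca_junc - 2 * I_ncx_junc
  I_Ca_tot_sl <- I_Ca_sl + I_cabk_sl + I_pca_sl - 2 * I_ncx_sl
  d_caj <- -I_Ca_tot_junc * CmF / (2 * P("Vjunc")) +
    P("J_ca_juncsl") / P("Vjunc") * (Y("ca_sl") - Y("ca_junc")) -
    J_CaB_junction + J_SRCarel * P("Vsr") / P("Vjunc") +
    J_SRleak * P("Vmyo") / P("Vjunc")
  d_casl <- -I_Ca_tot_sl * CmF / (2 * P("Vsl")) +
    P("J_ca_juncsl") / P("Vsl") * (Y("ca_junc") - Y("ca_sl")) +
    P("J_ca_slmyo") / P("Vsl") * (Y("ca_i") - Y("ca_sl")) - J_CaB_sl
  d_cai <- -J_serca * P("Vsr") / P("Vmyo") - J_CaB_cytosol +
    P("J_ca_slmyo") / P("Vmyo") * (Y("ca_sl") - Y("ca_i"))

  # --- membrane potential --------------------------------------------------
  I_Na_tot <- I_Na_tot_junc + I_Na_tot_sl
  I_Cl_tot <- I_ClCa + I_Clbk
  I_Ca_tot <- I_Ca_tot_junc + I_Ca_tot_sl
  I_tot <- I_Na_tot + I_Cl_tot + I_Ca_tot + I_K_tot
  d_vm <- -(I_tot + stim)

  # --- NHS myofilament block (native units s/uM; converted to per-ms) ------
  nhs <- nhs_eval(
    ca_trpn = Y("ca_trpn"), z = Y("z_tm"),
    q1 = Y("q1"), q2 = Y("q2"), q3 = Y("q3"),
    ca_i_uM = Y("ca_i") * 1e3,
    lambda = P("lambda"), dlambda_dt = P("dlambda_dt"),
    nhs = pv)

  dy <- c(
    m_na = d_m, h_na = d_h, j_na = d_j, d_ca = d_d, f_ca = d_f,
    fcab_junc = d_fcabj, fcab_sl = d_fcabsl,
    x_tos = d_xtos, y_tos = d_ytos, x_tof = d_xtof, y_tof = d_ytof,
    x_kr = d_xkr, x_ks = d_xks,
    ryr_r = d_ryr_r, ryr_o = d_ryr_o, ryr_i = d_ryr_i,
    nab_junc = d_nabj, nab_sl = d_nabsl,
    tnc_low = d_tncl, tnc_high_ca = d_tnchca, tnc_high_mg = d_tnchmg,
    cam = d_cam, myo_ca = d_myoca, myo_mg = d_myomg, srb = d_srb,
    sll_junc = d_sllj, sll_sl = d_sllsl, slh_junc = d_slhj,
    slh_sl = d_slhsl, csqn = d_csqn, ca_sr = d_casr,
    na_junc = d_naj, na_sl = d_nasl, na_i = d_nai, k_i = d_ki,
    ca_junc = d_caj, ca_sl = d_casl, ca_i = d_cai, vm = d_vm,
    m_late = d_mL, h_late = d_hL,
    ca_trpn = nhs$d_ca_trpn * 1e-3, z_tm = nhs$d_z * 1e-3,
    q1 = nhs$d_q1 * 1e-3, q2 = nhs$d_q2 * 1e-3, q3 = nhs$d_q3 * 1e-3
  )

  currents <- c(
    I_Na_junc = I_Na_junc, I_Na_sl = I_Na_sl, I_Na = I_Na_junc + I_Na_sl,
    I_NaL_junc = I_NaL_junc, I_NaL_sl = I_NaL_sl,
    I_NaL = I_NaL_junc + I_NaL_sl,
    I_nabk = I_nabk_junc + I_nabk_sl, I_nak = I_nak,
    I_kr = I_kr, I_ks = I_ks, I_kp = I_kp, I_to = I_to, I_ki = I_ki,
    I_ClCa = I_ClCa, I_Clbk = I_Clbk,
    I_Ca_junc = I_Ca_junc, I_Ca_sl = I_Ca_sl, I_Ca = I_Ca_junc + I_Ca_sl,
    I_CaK = I_CaK, I_CaNa = I_CaNa_junc + I_CaNa_sl,
    I_ncx_junc = I_ncx_junc, I_ncx_sl = I_ncx_sl,
    I_ncx = I_ncx_junc + I_ncx_sl,
    I_pca = I_pca_junc + I_pca_sl, I_cabk = I_cabk_junc + I_cabk_sl,
    J_SRCarel = J_SRCarel, J_serca = J_serca, J_SRleak = J_SRleak,
    I_tot = I_tot
  )
  list(dy = dy, currents = currents, tension = nhs$tension)
}

#' All ionic currents and SR fluxes at a given state
#'
#' Evaluates every membrane current (uA/uF) and SR Ca flux (mM/ms) of the
#' modified ionic model at one state, with remodelling factors applied.
#'
#' @param state Named state vector (see [state_registry()]); validated first.
#' @param params Parameter list from [gpb_parameters()].
#' @param factors Impact factors (vector, case letter or severity fraction).
#' @return A one-row tibble, one column per current/flux.
#' @export
#' @examples
#' gpb_currents(initial_state())
gpb_currents <- function(state, params = gpb_parameters(), factors = "A") {
  validate_state(state)
  pv <- ode_parameter_vector(params, as_impact_factors(factors))
  ev <- model_eval_r(0, state, pv)
  tibble::as_tibble(as.list(ev$currents))
}

#' Time derivatives of the full model state
#'
#' The coupled right-hand side: 41 electrophysiology states plus the 5
#' myofilament states, evaluated with the given remodelling factors,
#' applied stimulus current and (constant) fibre stretch.
#'
#' @inheritParams gpb_currents
#' @param t Time (ms); the system is autonomous, `t` is accepted for solver
#'   compatibility.
#' @param stim Applied membrane current (uA/uF); negative values are inward
#'   (depolarising) with the sign convention `dVm/dt = -(I_tot + stim)`.
#' @param lambda,dlambda_dt Fibre stretch and stretch rate seen by the
#'   myofilament block (defaults: isometric at resting length).
#' @return Named numeric vector of d(state)/dt (per ms).
#' @export
gpb_derivatives <- function(t = 0, state, params = gpb_parameters(),
                            factors = "A", stim = 0,
                            lambda = 1, dlambda_dt = 0) {
  validate_state(state)
  if (!is.finite(stim)) stop("`stim` must be finite", call. = FALSE)
  pv <- ode_parameter_vector(params, as_impact_factors(factors),
                             lambda = lambda, dlambda_dt = dlambda_dt)
  model_eval_r(t, state, pv, stim = stim)$dy
}

#' Total calcium content of the cell (volume-weighted)
#'
#' Sums free and buffered Ca over the junctional, subsarcolemmal, cytosolic
#' and SR compartments, weighted by compartment volume.  With all
#' sarcolemmal Ca pathways zeroed this quantity is a conserved invariant of
#' the dynamics.  Note the cytosolic balance of the source model debits the
#' free-Ca pool for occupancy changes of *all* seven cytosolic buffer
#' states — including the two Mg-occupied high-affinity states — so the
#' conserved quantity includes `tnc_high_mg` and `myo_mg`.  The myofilament
#' troponin pool is diagnostic only and does not drain the
#' electrophysiology Ca balance.
#'
#' @inheritParams gpb_currents
#' @return Total Ca content in mmol.
#' @export
total_calcium <- function(state, params = gpb_parameters()) {
  Y <- function(nm) state[[nm]]
  params$Vjunc * (Y("ca_junc") + Y("sll_junc") + Y("slh_junc")) +
    params$Vsl * (Y("ca_sl") + Y("sll_sl") + Y("slh_sl")) +
    params$Vmyo * (Y("ca_i") + Y("tnc_low") + Y("tnc_high_ca") +
                     Y("tnc_high_mg") + Y("cam") + Y("myo_ca") +
                     Y("myo_mg") + Y("srb")) +
    params$Vsr * (Y("ca_sr") + Y("csqn"))
}
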