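/* Compiled right-hand side of the coupled myocyte model for deSolve.
 *
 * State ordering follows state_registry() (R/registry.R); parameter
 * ordering follows ode_parameter_vector() (R/parameters.R).  The pure-R
 * reference implementation in R/gpb-model.R computes the same quantities;
 * the test suite requires the two to agree to round-off at random states,
 * which also catches any ordering mismatch between this enum and the R
 * vector builder.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

enum {
  i_Frdy, i_FoRT, i_Cmem, i_Vmyo, i_Vsr, i_Vsl, i_Vjunc,
  i_J_ca_juncsl, i_J_ca_slmyo, i_J_na_juncsl, i_J_na_slmyo,
  i_Fjunc, i_Fsl, i_Fjunc_CaL, i_Fsl_CaL,
  i_Cli, i_Clo, i_Ko, i_Nao, i_Cao, i_Mgi,
  i_GNa, i_GNaB, i_IbarNaK, i_KmNaip, i_KmKo, i_g_NaL, i_tau_hL,
  i_pNaK, i_gkp, i_gkr_coef, i_gks, i_GtoSlow, i_GtoFast, i_gki_coef,
  i_GClCa, i_GClB, i_KdClCa,
  i_pNa, i_pCa, i_pK, i_ICaL_scale,
  i_IbarNCX, i_KmCai, i_KmCao, i_KmNai, i_KmNao, i_ksat, i_nu, i_Kdact,
  i_IbarSLCaP, i_KmPCa, i_GCaB,
  i_Vmax_SRCaP, i_Kmf, i_Kmr, i_hillSRCaP, i_ks_rel, i_koCa, i_kom,
  i_kiCa, i_kim, i_ec50SR, i_MaxSR, i_MinSR, i_leak_coef,
  i_Bmax_Naj, i_Bmax_Nasl, i_koff_na, i_kon_na,
  i_Bmax_TnClow, i_koff_tncl, i_kon_tncl,
  i_Bmax_TnChigh, i_koff_tnchca, i_kon_tnchca, i_koff_tnchmg, i_kon_tnchmg,
  i_Bmax_CaM, i_koff_cam, i_kon_cam,
  i_Bmax_myosin, i_koff_myoca, i_kon_myoca, i_koff_myomg, i_kon_myomg,
  i_Bmax_SR, i_koff_sr, i_kon_sr,
  i_Bmax_SLlowsl, i_Bmax_SLlowj, i_koff_sll, i_kon_sll,
  i_Bmax_SLhighsl, i_Bmax_SLhighj, i_koff_slh, i_kon_slh,
  i_Bmax_Csqn, i_koff_csqn, i_kon_csqn,
  i_f_hl, i_f_NaL, i_f_Ki, i_f_NaK, i_f_Nabk, i_f_Cabk, i_f_ncx, i_f_to,
  i_f_SRleak, i_f_SRca, i_f_EC50SR,
  i_stim_amplitude,
  i_k_on, i_k_ref_off, i_gamma_trpn, i_Ca_TRPN_max, i_alpha_0, i_alpha_r1,
  i_alpha_r2, i_n_rel, i_K_z, i_n_hill, i_Ca_50ref, i_z_p, i_beta_0,
  i_beta_1, i_T_ref, i_a_xb, i_A_1, i_A_2, i_A_3, i_alpha_1, i_alpha_2,
  i_alpha_3, i_lambda, i_dlambda_dt,
  NPAR
};

/* state indices, 0-based, matching state_registry() */
enum {
  s_m_na, s_h_na, s_j_na, s_d_ca, s_f_ca, s_fcab_junc, s_fcab_sl,
  s_x_tos, s_y_tos, s_x_tof, s_y_tof, s_x_kr, s_x_ks,
  s_ryr_r, s_ryr_o, s_ryr_i,
  s_nab_junc, s_nab_sl, s_tnc_low, s_tnc_high_ca, s_tnc_high_mg,
  s_cam, s_myo_ca, s_myo_mg, s_srb,
  s_sll_junc, s_sll_sl, s_slh_junc, s_slh_sl, s_csqn,
  s_ca_sr, s_na_junc, s_na_sl, s_na_i, s_k_i,
  s_ca_junc, s_ca_sl, s_ca_i, s_vm, s_m_late, s_h_late,
  s_ca_trpn, s_z_tm, s_q1, s_q2, s_q3,
  NSTATE
};

static double p[NPAR];

void cardioec_initmod(void (*odeparms)(int *, double *)) {
  int n = NPAR;
  odeparms(&n, p);
}

/* limit-protected x*(ci*e^x - co)/(e^x - 1) */
static double ghk_factor(double x, double ci, double co) {
  if (fabs(x) < 1e-5) return (ci - co) + x * (ci + co) / 2.0;
  return x * (ci * exp(x) - co) / expm1(x);
}

void cardioec_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip) {
  const double FoRT = p[i_FoRT], Frdy = p[i_Frdy];
  const double Vm = y[s_vm];

  /* Nernst potentials */
  const double ena_junc = (1.0 / FoRT) * log(p[i_Nao] / y[s_na_junc]);
  const double ena_sl   = (1.0 / FoRT) * log(p[i_Nao] / y[s_na_sl]);
  const double ek       = (1.0 / FoRT) * log(p[i_Ko] / y[s_k_i]);
  const double eca_junc = (1.0 / (2.0 * FoRT)) * log(p[i_Cao] / y[s_ca_junc]);
  const double eca_sl   = (1.0 / (2.0 * FoRT)) * log(p[i_Cao] / y[s_ca_sl]);
  const double ecl      = (1.0 / FoRT) * log(p[i_Cli] / p[i_Clo]);

  /* fast Na current */
  double sm = 1.0 + exp(-(56.86 + Vm) / 9.03);
  double mss = 1.0 / (sm * sm);
  double taum = 0.1292 * exp(-pow((Vm + 45.79) / 15.54, 2)) +
    0.06487 * exp(-pow((Vm - 4.823) / 51.12, 2));
  double ah, bh, aj, bj;
  if (Vm >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + exp(-(Vm + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.6 * exp(0.057 * Vm) / (1.0 + exp(-0.1 * (Vm + 32.0)));
  } else {
    ah = 0.057 * exp(-(Vm + 80.0) / 6.8);
    bh = 2.7 * exp(0.079 * Vm) + 3.1e5 * exp(0.3485 * Vm);
    aj = (-2.5428e4 * exp(0.2444 * Vm) - 6.948e-6 * exp(-0.04391 * Vm)) *
      (Vm + 37.78) / (1.0 + exp(0.311 * (Vm + 79.23)));
    bj = 0.02424 * exp(-0.01052 * Vm) / (1.0 + exp(-0.1378 * (Vm + 40.14)));
  }
  double sh = 1.0 + exp((Vm + 71.55) / 7.43);
  double hss = 1.0 / (sh * sh), jss = hss;
  ydot[s_m_na] = (mss - y[s_m_na]) / taum;
  ydot[s_h_na] = (hss - y[s_h_na]) * (ah + bh);
  ydot[s_j_na] = (jss - y[s_j_na]) * (aj + bj);
  double gNa_open = p[i_GNa] * y[s_m_na] * y[s_m_na] * y[s_m_na] *
    y[s_h_na] * y[s_j_na];
  double I_Na_junc = p[i_Fjunc] * gNa_open * (Vm - ena_junc);
  double I_Na_sl = p[i_Fsl] * gNa_open * (Vm - ena_sl);

  /* late Na current */
  double u = Vm + 47.13;
  double alpha_mL = (fabs(0.1 * u) < 1e-4)
    ? 0.32 / 0.1 * (1.0 + 0.05 * u)
    : 0.32 * u / (1.0 - exp(-0.1 * u));
  double beta_mL = 0.08 * exp(-Vm / 11.0);
  double hL_inf = 1.0 / (1.0 + exp((Vm + 91.0) / 6.1));
  ydot[s_m_late] = alpha_mL * (1.0 - y[s_m_late]) - beta_mL * y[s_m_late];
  ydot[s_h_late] = (hL_inf - y[s_h_late]) / (p[i_f_hl] * p[i_tau_hL]);
  double gNaL_open = p[i_f_NaL] * p[i_g_NaL] *
    y[s_m_late] * y[s_m_late] * y[s_m_late] * y[s_h_late];
  double I_NaL_junc = p[i_Fjunc] * gNaL_open * (Vm - ena_junc);
  double I_NaL_sl = p[i_Fsl] * gNaL_open * (Vm - ena_sl);

  /* background Na and Na/K pump */
  double I_nabk_junc = p[i_f_Nabk] * p[i_Fjunc] * p[i_GNaB] * (Vm - ena_junc);
  double I_nabk_sl = p[i_f_Nabk] * p[i_Fsl] * p[i_GNaB] * (Vm - ena_sl);
  double sigma = (exp(p[i_Nao] / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * exp(-0.1 * Vm * FoRT) +
                       0.0365 * sigma * exp(-Vm * FoRT));
  double nak_scale = p[i_f_NaK] * p[i_IbarNaK] * fnak * p[i_Ko] /
    (p[i_Ko] + p[i_KmKo]);
  double rj = p[i_KmNaip] / y[s_na_junc];
  double rs = p[i_KmNaip] / y[s_na_sl];
  double I_nak_junc = p[i_Fjunc] * nak_scale / (1.0 + rj * rj * rj * rj);
  double I_nak_sl = p[i_Fsl] * nak_scale / (1.0 + rs * rs * rs * rs);

  /* K currents */
  double gkr = p[i_gkr_coef] * sqrt(p[i_Ko] / 5.4);
  double xrss = 1.0 / (1.0 + exp(-(Vm + 10.0) / 5.0));
  double tauxr = 550.0 / (1.0 + exp((-22.0 - Vm) / 9.0)) * 6.0 /
    (1.0 + exp((Vm + 11.0) / 9.0)) + 230.0 / (1.0 + exp((Vm + 40.0) / 20.0));
  ydot[s_x_kr] = (xrss - y[s_x_kr]) / tauxr;
  double rkr = 1.0 / (1.0 + exp((Vm + 74.0) / 24.0));
  double I_kr = gkr * y[s_x_kr] * rkr * (Vm - ek);

  double eks = (1.0 / FoRT) * log((p[i_Ko] + p[i_pNaK] * p[i_Nao]) /
                                  (y[s_k_i] + p[i_pNaK] * y[s_na_i]));
  double xsss = 1.0 / (1.0 + exp(-(Vm + 3.8) / 14.25));
  double tauxs = 990.1 / (1.0 + exp(-(Vm + 2.436) / 14.12));
  ydot[s_x_ks] = (xsss - y[s_x_ks]) / tauxs;
  double I_ks = p[i_gks] * y[s_x_ks] * y[s_x_ks] * (Vm - eks);

  double kp_kp = 1.0 / (1.0 + exp(7.488 - Vm / 5.98));
  double I_kp = p[i_gkp] * kp_kp * (Vm - ek);

  double xtoss = 1.0 / (1.0 + exp(-(Vm - 19.0) / 13.0));
  double ytoss = 1.0 / (1.0 + exp((Vm + 19.5) / 5.0));
  double tauxtos = 9.0 / (1.0 + exp((Vm + 3.0) / 15.0)) + 0.5;
  double tauytos = 800.0 / (1.0 + exp((Vm + 60.0) / 10.0)) + 30.0;
  ydot[s_x_tos] = (xtoss - y[s_x_tos]) / tauxtos;
  ydot[s_y_tos] = (ytoss - y[s_y_tos]) / tauytos;
  double I_tos = p[i_f_to] * p[i_GtoSlow] * y[s_x_tos] * y[s_y_tos] *
    (Vm - ek);
  double tauxtof = 8.5 * exp(-pow((Vm + 45.0) / 50.0, 2)) + 0.5;
  double tauytof = 85.0 * exp(-(Vm + 40.0) * (Vm + 40.0) / 220.0) + 7.0;
  ydot[s_x_tof] = (xtoss - y[s_x_tof]) / tauxtof;
  ydot[s_y_tof] = (ytoss - y[s_y_tof]) / tauytof;
  double I_tof = p[i_f_to] * p[i_GtoFast] * y[s_x_tof] * y[s_y_tof] *
    (Vm - ek);
  double I_to = I_tos + I_tof;

  double aki = 1.02 / (1.0 + exp(0.2385 * (Vm - ek - 59.215)));
  double bki = (0.49124 * exp(0.08032 * (Vm + 5.476 - ek)) +
                exp(0.06175 * (Vm - ek - 594.31))) /
    (1.0 + exp(-0.5143 * (Vm - ek + 4.753)));
  double kiss = aki / (aki + bki);
  double I_ki = p[i_f_Ki] * p[i_gki_coef] * sqrt(p[i_Ko] / 5.4) * kiss *
    (Vm - ek);

  /* Cl currents */
  double I_ClCa = p[i_Fjunc] * p[i_GClCa] /
      (1.0 + p[i_KdClCa] / y[s_ca_junc]) * (Vm - ecl) +
    p[i_Fsl] * p[i_GClCa] / (1.0 + p[i_KdClCa] / y[s_ca_sl]) * (Vm - ecl);
  double I_Clbk = p[i_GClB] * (Vm - ecl);

  /* L-type Ca current */
  double dss = 1.0 / (1.0 + exp(-(Vm + 5.0) / 6.0));
  double ud = Vm + 5.0;
  double taud = (fabs(ud) < 1e-4)
    ? dss / 0.21 * (1.0 - ud / 12.0)
    : dss * (1.0 - exp(-ud / 6.0)) / (0.035 * ud);
  double fss = 1.0 / (1.0 + exp((Vm + 35.0) / 9.0)) +
    0.6 / (1.0 + exp((50.0 - Vm) / 20.0));
  double tauf = 1.0 / (0.0197 *
    exp(-pow(0.0337 * (Vm + 14.5), 2)) + 0.02);
  ydot[s_d_ca] = (dss - y[s_d_ca]) / taud;
  ydot[s_f_ca] = (fss - y[s_f_ca]) / tauf;
  ydot[s_fcab_junc] = 1.7 * y[s_ca_junc] * (1.0 - y[s_fcab_junc]) -
    11.9e-3 * y[s_fcab_junc];
  ydot[s_fcab_sl] = 1.7 * y[s_ca_sl] * (1.0 - y[s_fcab_sl]) -
    11.9e-3 * y[s_fcab_sl];
  double ibarca_j = p[i_pCa] * 2.0 * Frdy *
    ghk_factor(2.0 * Vm * FoRT, 0.341 * y[s_ca_junc], 0.341 * p[i_Cao]);
  double ibarca_sl = p[i_pCa] * 2.0 * Frdy *
    ghk_factor(2.0 * Vm * FoRT, 0.341 * y[s_ca_sl], 0.341 * p[i_Cao]);
  double ibark = p[i_pK] * Frdy *
    ghk_factor(Vm * FoRT, 0.75 * y[s_k_i], 0.75 * p[i_Ko]);
  double ibarna_j = p[i_pNa] * Frdy *
    ghk_factor(Vm * FoRT, 0.75 * y[s_na_junc], 0.75 * p[i_Nao]);
  double ibarna_sl = p[i_pNa] * Frdy *
    ghk_factor(Vm * FoRT, 0.75 * y[s_na_sl], 0.75 * p[i_Nao]);
  double po = y[s_d_ca] * y[s_f_ca] * p[i_ICaL_scale];
  double I_Ca_junc = p[i_Fjunc_CaL] * ibarca_j * po *
    (1.0 - y[s_fcab_junc]);
  double I_Ca_sl = p[i_Fsl_CaL] * ibarca_sl * po * (1.0 - y[s_fcab_sl]);
  double I_CaK = ibark * po * (p[i_Fjunc_CaL] * (1.0 - y[s_fcab_junc]) +
                               p[i_Fsl_CaL] * (1.0 - y[s_fcab_sl]));
  double I_CaNa_junc = p[i_Fjunc_CaL] * ibarna_j * po *
    (1.0 - y[s_fcab_junc]);
  double I_CaNa_sl = p[i_Fsl_CaL] * ibarna_sl * po * (1.0 - y[s_fcab_sl]);

  /* Na/Ca exchanger */
  double kda_j = p[i_Kdact] / y[s_ca_junc];
  double kda_s = p[i_Kdact] / y[s_ca_sl];
  double Ka_junc = 1.0 / (1.0 + kda_j * kda_j);
  double Ka_sl = 1.0 / (1.0 + kda_s * kda_s);
  double naj3 = pow(y[s_na_junc], 3), nasl3 = pow(y[s_na_sl], 3);
  double Nao3 = pow(p[i_Nao], 3);
  double expnu = exp(p[i_nu] * Vm * FoRT);
  double expnu1 = exp((p[i_nu] - 1.0) * Vm * FoRT);
  double s1_junc = expnu * naj3 * p[i_Cao];
  double s1_sl = expnu * nasl3 * p[i_Cao];
  double s2_junc = expnu1 * Nao3 * y[s_ca_junc];
  double s2_sl = expnu1 * Nao3 * y[s_ca_sl];
  double s3_junc = p[i_KmCai] * Nao3 *
      (1.0 + pow(y[s_na_junc] / p[i_KmNai], 3)) +
    pow(p[i_KmNao], 3) * y[s_ca_junc] * (1.0 + y[s_ca_junc] / p[i_KmCai]) +
    p[i_KmCao] * naj3 + naj3 * p[i_Cao] + Nao3 * y[s_ca_junc];
  double s3_sl = p[i_KmCai] * Nao3 *
      (1.0 + pow(y[s_na_sl] / p[i_KmNai], 3)) +
    pow(p[i_KmNao], 3) * y[s_ca_sl] * (1.0 + y[s_ca_sl] / p[i_KmCai]) +
    p[i_KmCao] * nasl3 + nasl3 * p[i_Cao] + Nao3 * y[s_ca_sl];
  double ksat_term = 1.0 + p[i_ksat] * expnu1;
  double I_ncx_junc = p[i_f_ncx] * p[i_Fjunc] * p[i_IbarNCX] * Ka_junc *
    (s1_junc - s2_junc) / s3_junc / ksat_term;
  double I_ncx_sl = p[i_f_ncx] * p[i_Fsl] * p[i_IbarNCX] * Ka_sl *
    (s1_sl - s2_sl) / s3_sl / ksat_term;

  /* sarcolemmal Ca pump and background Ca */
  double caj16 = pow(y[s_ca_junc], 1.6), casl16 = pow(y[s_ca_sl], 1.6);
  double km16 = pow(p[i_KmPCa], 1.6);
  double I_pca_junc = p[i_Fjunc] * p[i_IbarSLCaP] * caj16 / (km16 + caj16);
  double I_pca_sl = p[i_Fsl] * p[i_IbarSLCaP] * casl16 / (km16 + casl16);
  double I_cabk_junc = p[i_f_Cabk] * p[i_Fjunc] * p[i_GCaB] *
    (Vm - eca_junc);
  double I_cabk_sl = p[i_f_Cabk] * p[i_Fsl] * p[i_GCaB] * (Vm - eca_sl);

  /* SR fluxes */
  double ec50 = p[i_f_EC50SR] * p[i_ec50SR];
  double kCaSR = p[i_MaxSR] - (p[i_MaxSR] - p[i_MinSR]) /
    (1.0 + pow(ec50 / y[s_ca_sr], 2.5));
  double koSRCa = p[i_koCa] / kCaSR;
  double kiSRCa = p[i_kiCa] * kCaSR;
  double RI = 1.0 - y[s_ryr_r] - y[s_ryr_o] - y[s_ryr_i];
  double caj2 = y[s_ca_junc] * y[s_ca_junc];
  ydot[s_ryr_r] = (p[i_kim] * RI - kiSRCa * y[s_ca_junc] * y[s_ryr_r]) -
    (koSRCa * caj2 * y[s_ryr_r] - p[i_kom] * y[s_ryr_o]);
  ydot[s_ryr_o] = (koSRCa * caj2 * y[s_ryr_r] - p[i_kom] * y[s_ryr_o]) -
    (kiSRCa * y[s_ca_junc] * y[s_ryr_o] - p[i_kim] * y[s_ryr_i]);
  ydot[s_ryr_i] = (kiSRCa * y[s_ca_junc] * y[s_ryr_o] -
                   p[i_kim] * y[s_ryr_i]) -
    (p[i_kom] * y[s_ryr_i] - koSRCa * caj2 * RI);
  double J_SRCarel = p[i_ks_rel] * y[s_ryr_o] * (y[s_ca_sr] - y[s_ca_junc]);
  double rf = pow(y[s_ca_i] / p[i_Kmf], p[i_hillSRCaP]);
  double rr = pow(y[s_ca_sr] / p[i_Kmr], p[i_hillSRCaP]);
  double J_serca = p[i_f_SRca] * p[i_Vmax_SRCaP] * (rf - rr) /
    (1.0 + rf + rr);
  double J_SRleak = p[i_f_SRleak] * p[i_leak_coef] *
    (y[s_ca_sr] - y[s_ca_junc]);

  /* buffering */
  ydot[s_nab_junc] = p[i_kon_na] * y[s_na_junc] *
    (p[i_Bmax_Naj] - y[s_nab_junc]) - p[i_koff_na] * y[s_nab_junc];
  ydot[s_nab_sl] = p[i_kon_na] * y[s_na_sl] *
    (p[i_Bmax_Nasl] - y[s_nab_sl]) - p[i_koff_na] * y[s_nab_sl];
  ydot[s_tnc_low] = p[i_kon_tncl] * y[s_ca_i] *
    (p[i_Bmax_TnClow] - y[s_tnc_low]) - p[i_koff_tncl] * y[s_tnc_low];
  double tnch_free = p[i_Bmax_TnChigh] - y[s_tnc_high_ca] - y[s_tnc_high_mg];
  ydot[s_tnc_high_ca] = p[i_kon_tnchca] * y[s_ca_i] * tnch_free -
    p[i_koff_tnchca] * y[s_tnc_high_ca];
  ydot[s_tnc_high_mg] = p[i_kon_tnchmg] * p[i_Mgi] * tnch_free -
    p[i_koff_tnchmg] * y[s_tnc_high_mg];
  ydot[s_cam] = p[i_kon_cam] * y[s_ca_i] * (p[i_Bmax_CaM] - y[s_cam]) -
    p[i_koff_cam] * y[s_cam];
  double myo_free = p[i_Bmax_myosin] - y[s_myo_ca] - y[s_myo_mg];
  ydot[s_myo_ca] = p[i_kon_myoca] * y[s_ca_i] * myo_free -
    p[i_koff_myoca] * y[s_myo_ca];
  ydot[s_myo_mg] = p[i_kon_myomg] * p[i_Mgi] * myo_free -
    p[i_koff_myomg] * y[s_myo_mg];
  ydot[s_srb] = p[i_kon_sr] * y[s_ca_i] * (p[i_Bmax_SR] - y[s_srb]) -
    p[i_koff_sr] * y[s_srb];
  double J_CaB_cytosol = ydot[s_tnc_low] + ydot[s_tnc_high_ca] +
    ydot[s_tnc_high_mg] + ydot[s_cam] + ydot[s_myo_ca] + ydot[s_myo_mg] +
    ydot[s_srb];
  ydot[s_sll_junc] = p[i_kon_sll] * y[s_ca_junc] *
    (p[i_Bmax_SLlowj] - y[s_sll_junc]) - p[i_koff_sll] * y[s_sll_junc];
  ydot[s_sll_sl] = p[i_kon_sll] * y[s_ca_sl] *
    (p[i_Bmax_SLlowsl] - y[s_sll_sl]) - p[i_koff_sll] * y[s_sll_sl];
  ydot[s_slh_junc] = p[i_kon_slh] * y[s_ca_junc] *
    (p[i_Bmax_SLhighj] - y[s_slh_junc]) - p[i_koff_slh] * y[s_slh_junc];
  ydot[s_slh_sl] = p[i_kon_slh] * y[s_ca_sl] *
    (p[i_Bmax_SLhighsl] - y[s_slh_sl]) - p[i_koff_slh] * y[s_slh_sl];
  double J_CaB_junction = ydot[s_sll_junc] + ydot[s_slh_junc];
  double J_CaB_sl = ydot[s_sll_sl] + ydot[s_slh_sl];
  ydot[s_csqn] = p[i_kon_csqn] * y[s_ca_sr] *
    (p[i_Bmax_Csqn] - y[s_csqn]) - p[i_koff_csqn] * y[s_csqn];

  /* ion balances */
  ydot[s_ca_sr] = J_serca -
    (J_SRleak * p[i_Vmyo] / p[i_Vsr] + J_SRCarel) - ydot[s_csqn];
  double I_Na_tot_junc = I_Na_junc + I_nabk_junc + 3.0 * I_ncx_junc +
    3.0 * I_nak_junc + I_CaNa_junc + I_NaL_junc;
  double I_Na_tot_sl = I_Na_sl + I_nabk_sl + 3.0 * I_ncx_sl +
    3.0 * I_nak_sl + I_CaNa_sl + I_NaL_sl;
  double CmF = p[i_Cmem] / Frdy;
  ydot[s_na_junc] = -I_Na_tot_junc * CmF / p[i_Vjunc] +
    p[i_J_na_juncsl] / p[i_Vjunc] * (y[s_na_sl] - y[s_na_junc]) -
    ydot[s_nab_junc];
  ydot[s_na_sl] = -I_Na_tot_sl * CmF / p[i_Vsl] +
    p[i_J_na_juncsl] / p[i_Vsl] * (y[s_na_junc] - y[s_na_sl]) +
    p[i_J_na_slmyo] / p[i_Vsl] * (y[s_na_i] - y[s_na_sl]) - ydot[s_nab_sl];
  ydot[s_na_i] = p[i_J_na_slmyo] / p[i_Vmyo] * (y[s_na_sl] - y[s_na_i]);
  double I_nak = I_nak_junc + I_nak_sl;
  double I_K_tot = I_to + I_kr + I_ks + I_ki - 2.0 * I_nak + I_CaK + I_kp;
  ydot[s_k_i] = 0.0;   /* bulk K clamped */
  double I_Ca_tot_junc = I_Ca_junc + I_cabk_junc + I_pca_junc -
    2.0 * I_ncx_junc;
  double I_Ca_tot_sl = I_Ca_sl + I_cabk_sl + I_pca_sl - 2.0 * I_ncx_sl;
  ydot[s_ca_junc] = -I_Ca_tot_junc * CmF / (2.0 * p[i_Vjunc]) +
    p[i_J_ca_juncsl] / p[i_Vjunc] * (y[s_ca_sl] - y[s_ca_junc]) -
    J_CaB_junction + J_SRCarel * p[i_Vsr] / p[i_Vjunc] +
    J_SRleak * p[i_Vmyo] / p[i_Vjunc];
  ydot[s_ca_sl] = -I_Ca_tot_sl * CmF / (2.0 * p[i_Vsl]) +
    p[i_J_ca_juncsl] / p[i_Vsl] * (y[s_ca_junc] - y[s_ca_sl]) +
    p[i_J_ca_slmyo] / p[i_Vsl] * (y[s_ca_i] - y[s_ca_sl]) - J_CaB_sl;
  ydot[s_ca_i] = -J_serca * p[i_Vsr] / p[i_Vmyo] - J_CaB_cytosol +
    p[i_J_ca_slmyo] / p[i_Vmyo] * (y[s_ca_sl] - y[s_ca_i]);

  double I_Na_tot = I_Na_tot_junc + I_Na_tot_sl;
  double I_Cl_tot = I_ClCa + I_Clbk;
  double I_Ca_tot = I_Ca_tot_junc + I_Ca_tot_sl;
  double I_tot = I_Na_tot + I_Cl_tot + I_Ca_tot + I_K_tot;
  ydot[s_vm] = -(I_tot + p[i_stim_amplitude]);

  /* NHS myofilament block; native rates are per second -> scale by 1e-3 */
  double lam = p[i_lambda];
  if (lam < 0.8) lam = 0.8;
  if (lam > 1.15) lam = 1.15;
  double Ca50 = p[i_Ca_50ref] * (1.0 + p[i_beta_1] * (lam - 1.0));
  double CaTRPN50 = Ca50 * p[i_Ca_TRPN_max] /
    (Ca50 + (p[i_k_ref_off] / p[i_k_on]) *
     (1.0 - (1.0 + p[i_beta_0] * (lam - 1.0)) * 0.5 / p[i_gamma_trpn]));
  double zpn = pow(p[i_z_p], p[i_n_rel]);
  double kzn = pow(p[i_K_z], p[i_n_rel]);
  double K2 = p[i_alpha_r2] * zpn / (zpn + kzn) *
    (1.0 - p[i_n_rel] * kzn / (zpn + kzn));
  double K1 = p[i_alpha_r2] * pow(p[i_z_p], p[i_n_rel] - 1.0) *
    p[i_n_rel] * kzn / ((zpn + kzn) * (zpn + kzn));
  double act_max = p[i_alpha_0] *
    pow(p[i_Ca_TRPN_max] / CaTRPN50, p[i_n_hill]);
  double z_max = (act_max - K2) / (p[i_alpha_r1] + K1 + act_max);
  double z = y[s_z_tm];
  double zn = pow(z, p[i_n_rel]);
  double d_z = p[i_alpha_0] *
    pow(y[s_ca_trpn] / CaTRPN50, p[i_n_hill]) * (1.0 - z) -
    p[i_alpha_r1] * z - p[i_alpha_r2] * zn / (zn + kzn);
  double T0 = p[i_T_ref] * (1.0 + p[i_beta_0] * (lam - 1.0)) * z / z_max;
  double Q = y[s_q1] + y[s_q2] + y[s_q3];
  double tension = (Q < 0.0)
    ? T0 * (p[i_a_xb] * Q + 1.0) / (1.0 - Q)
    : T0 * (1.0 + (p[i_a_xb] + 2.0) * Q) / (1.0 + Q);
  double k_off = p[i_k_ref_off] *
    (1.0 - tension / (p[i_gamma_trpn] * p[i_T_ref]));
  double ca_uM = y[s_ca_i] * 1e3;
  double d_ca_trpn = p[i_k_on] * ca_uM *
    (p[i_Ca_TRPN_max] - y[s_ca_trpn]) - k_off * y[s_ca_trpn];
  ydot[s_ca_trpn] = 1e-3 * d_ca_trpn;
  ydot[s_z_tm] = 1e-3 * d_z;
  ydot[s_q1] = 1e-3 * (p[i_A_1] * p[i_dlambda_dt] - p[i_alpha_1] * y[s_q1]);
  ydot[s_q2] = 1e-3 * (p[i_A_2] * p[i_dlambda_dt] - p[i_alpha_2] * y[s_q2]);
  ydot[s_q3] = 1e-3 * (p[i_A_3] * p[i_dlambda_dt] - p[i_alpha_3] * y[s_q3]);

  if (ip[0] >= 1) yout[0] = tension;
}
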