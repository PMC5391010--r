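test_that("late Na current follows its Hodgkin-Huxley definition", {
  p <- gpb_parameters()
  # zero driving force and closed activation gate give zero current
  z <- late_na_current(70, 0.5, 0.5, p, nernst_junc = 70, nernst_sl = 70)
  expect_identical(unlist(z), c(I_NaL_junc = 0, I_NaL_sl = 0, I_NaL = 0))
  z2 <- late_na_current(-20, 0, 0.5, p, nernst_junc = 70, nernst_sl = 65)
  expect_identical(z2$I_NaL, 0)
  # hand evaluation of the defining expressions (independent arithmetic)
  got <- late_na_current(-20, 0.5, 0.5, p, nernst_junc = 70,
                         nernst_sl = 65, f_NaL = 1)
  expect_equal(got$I_NaL_junc, 0.11 * 0.0065 * 0.5^3 * 0.5 * (-20 - 70))
  expect_equal(got$I_NaL_sl, 0.89 * 0.0065 * 0.5^3 * 0.5 * (-20 - 65))
  expect_equal(got$I_NaL, got$I_NaL_junc + got$I_NaL_sl)
  # the impact factor scales the conductance linearly
  got2 <- late_na_current(-20, 0.5, 0.5, p, 70, 65, f_NaL = 2)
  expect_equal(got2$I_NaL, 2 * got$I_NaL)
  expect_error(late_na_current(NaN, 0.5, 0.5, p, 70, 65), "finite")
  expect_error(late_na_current(-20, 1.5, 0.5, p, 70, 65), "\\[0, 1\\]")
})

test_that("late Na gate kinetics handle the removable singularity and scaling", {
  # analytic limit of 0.32 u / (1 - e^{-0.1 u}) at u = 0
  expect_equal(late_na_gate_rates(-47.13)$alpha_mL, 0.32 / 0.1,
               tolerance = 1e-9)
  # continuity across the guard window
  a <- vapply(c(-47.1305, -47.13, -47.1295), function(v) {
    late_na_gate_rates(v)$alpha_mL
  }, numeric(1))
  expect_lt(max(abs(diff(a))), 1e-4)
  # standard sigmoid inactivation: half-inactivated at -91 mV, in (0, 1)
  expect_equal(late_na_gate_rates(-91)$hL_inf, 0.5)
  vs <- seq(-120, 40, by = 5)
  h <- vapply(vs, function(v) late_na_gate_rates(v)$hL_inf, numeric(1))
  expect_true(all(h > 0 & h < 1))
  expect_true(all(diff(h) < 0))
  # f_hl scales the 233 ms inactivation time constant (466 ms when doubled)
  expect_equal(late_na_gate_rates(-20, f_hl = 2)$tau_hL_eff, 466)
  expect_error(late_na_gate_rates(Inf), "finite")
})

test_that("current set responds to factors as multiplicative scalings", {
  y <- initial_state()
  base <- gpb_currents(y, factors = "A")
  expect_true(all(is.finite(as.numeric(base))))
  # resting physiology: pump current positive, inward rectifier near zero
  # driving force, SERCA uptake balancing leak direction
  expect_gt(base$I_nak, 0)
  expect_gt(base$J_SRleak, 0)
  no_to <- gpb_currents(y, factors = as_impact_factors(
    stats::setNames(c(1, 1, 1, 1, 1, 1, 1, 0, 1, 1, 1),
                    names(impact_factors()))))
  expect_identical(no_to$I_to, 0)
  dbl <- impact_factors(f_SRleak = 2)
  expect_equal(gpb_currents(y, factors = dbl)$J_SRleak, 2 * base$J_SRleak)
  expect_error(gpb_currents(replace(y, "ca_i", -1)), "ca_i")
})

test_that("resting currents match an independent re-evaluation of the formulas", {
  # pointwise oracle: evaluate the defining expressions directly at the
  # resting state, outside the package implementation
  p <- gpb_parameters()
  y <- initial_state()
  FoRT <- p$Frdy / (p$R_gas * p$Temp)
  ena_j <- log(p$Nao / y[["na_junc"]]) / FoRT
  sigma <- (exp(p$Nao / 67.3) - 1) / 7
  fnak <- 1 / (1 + 0.1245 * exp(-0.1 * y[["vm"]] * FoRT) +
                 0.0365 * sigma * exp(-y[["vm"]] * FoRT))
  inak <- p$IbarNaK * fnak * p$Ko / (p$Ko + p$KmKo) *
    (p$Fjunc / (1 + (p$KmNaip / y[["na_junc"]])^4) +
       p$Fsl / (1 + (p$KmNaip / y[["na_sl"]])^4))
  cur <- gpb_currents(y)
  expect_equal(cur$I_nak, inak, tolerance = 1e-12)
  expect_equal(cur$I_nabk, p$GNaB * (p$Fjunc * (y[["vm"]] - ena_j) +
                                       p$Fsl * (y[["vm"]] -
                                                  log(p$Nao / y[["na_sl"]]) / FoRT)),
               tolerance = 1e-12)
  expect_equal(cur$J_SRleak, 5.348e-6 * (y[["ca_sr"]] - y[["ca_junc"]]),
               tolerance = 1e-12)
})

test_that("compiled and reference right-hand sides agree at random states", {
  set.seed(7)
  for (k in 1:12) {
    y <- perturbed_state()
    f <- factors_for_case(stats::runif(1))
    pv <- cardioec:::ode_parameter_vector(
      gpb_parameters(), f, stim_amplitude = stats::rnorm(1, sd = 3))
    evR <- cardioec:::model_eval_r(0, y, pv, stim = pv[["stim_amplitude"]])
    evC <- compiled_derivatives(y, pv)
    denom <- pmax(abs(evR$dy), 1e-10)
    expect_lt(max(abs(evC$dy - evR$dy) / denom), 1e-10)
    expect_equal(evC$tension, evR$tension, tolerance = 1e-12)
  }
})

test_that("gate derivatives relax towards their steady states", {
  set.seed(11)
  gates <- c("m_na", "h_na", "j_na", "d_ca", "f_ca", "x_tos", "y_tos",
             "x_tof", "y_tof", "x_kr", "x_ks", "m_late", "h_late")
  for (k in 1:5) {
    y <- perturbed_state()
    dy <- gpb_derivatives(state = y)
    # push every HH gate to 0 and to 1: derivative must be >= 0 resp. <= 0
    y0 <- y; y0[gates] <- 1e-9
    y1 <- y; y1[gates] <- 1 - 1e-9
    expect_true(all(gpb_derivatives(state = y0)[gates] >= 0))
    expect_true(all(gpb_derivatives(state = y1)[gates] <= 0))
    expect_true(all(is.finite(dy)))
  }
})

test_that("a long unstimulated integration reaches a quiescent steady state", {
  pv <- cardioec:::ode_parameter_vector(stim_amplitude = 0)
  out <- cardioec:::integrate_segment(initial_state(), c(0, 1e6), pv,
                                      rtol = 1e-8, atol = 1e-11,
                                      maxsteps = 1e6)
  y_end <- out[nrow(out), 1 + seq_len(nrow(state_registry()))]
  names(y_end) <- state_registry()$name
  dy <- gpb_derivatives(state = y_end)
  # exclude the slowest drift modes' absolute scale by normalising
  expect_lt(max(abs(dy) / pmax(abs(y_end), 1e-3)), 1e-7)
})

test_that("total Ca is conserved when sarcolemmal Ca pathways are closed", {
  p <- gpb_parameters(pCa = 0, GCaB = 0, IbarNCX = 0, IbarSLCaP = 0)
  pv <- cardioec:::ode_parameter_vector(p, impact_factors(),
                                        stim_amplitude = 0)
  y0 <- initial_state(p)
  # analytic: the instantaneous total-Ca derivative vanishes
  dy <- gpb_derivatives(state = y0, params = p)
  dtot <- p$Vjunc * sum(dy[c("ca_junc", "sll_junc", "slh_junc")]) +
    p$Vsl * sum(dy[c("ca_sl", "sll_sl", "slh_sl")]) +
    p$Vmyo * sum(dy[c("ca_i", "tnc_low", "tnc_high_ca", "tnc_high_mg",
                      "cam", "myo_ca", "myo_mg", "srb")]) +
    p$Vsr * sum(dy[c("ca_sr", "csqn")])
  expect_lt(abs(dtot), 1e-18)
  # and along a trajectory, to integration tolerance
  out <- cardioec:::integrate_segment(y0, seq(0, 5000, by = 500), pv,
                                      rtol = 1e-9, atol = 1e-12)
  totals <- apply(out[, 1 + seq_len(nrow(state_registry()))], 1, function(r) {
    names(r) <- state_registry()$name
    total_calcium(r, p)
  })
  expect_lt(max(abs(totals - totals[1])) / totals[1], 1e-8)
})

test_that("the late Na current reverses at the Na Nernst potential", {
  p <- gpb_parameters()
  y <- initial_state()
  FoRT <- p$Frdy / (p$R_gas * p$Temp)
  ena_j <- log(p$Nao / y[["na_junc"]]) / FoRT
  # same Na in both compartments at the initial state, so one reversal
  got <- late_na_current(ena_j, 0.4, 0.3, p, ena_j, ena_j)
  expect_equal(got$I_NaL, 0)
  above <- late_na_current(ena_j + 1, 0.4, 0.3, p, ena_j, ena_j)$I_NaL
  below <- late_na_current(ena_j - 1, 0.4, 0.3, p, ena_j, ena_j)$I_NaL
  expect_gt(above, 0)
  expect_lt(below, 0)
})

test_that("state validation names the offending component", {
  y <- initial_state()
  expect_silent(validate_state(y))
  expect_error(validate_state(replace(y, "m_na", 1.5)), "m_na")
  expect_error(validate_state(replace(y, "na_i", -2)), "na_i")
  expect_error(validate_state(y[-1]), "length")
  reg <- state_registry()
  expect_identical(nrow(reg), 46L)
  expect_identical(sum(reg$kind != "myofilament"), 41L)
})
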