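test_that("the reference configuration is energy- and stress-free", {
  expect_identical(strain_energy(diag(3)), 0)
  expect_identical(max(abs(passive_pk1(diag(3)))), 0)
  # pure rotations carry no strain energy and no stress (objectivity)
  th <- 0.7
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(strain_energy(Q), 0, tolerance = 1e-12)
  expect_equal(max(abs(passive_pk1(Q))), 0, tolerance = 1e-10)
})

test_that("fiber and sheet terms act only under stretch", {
  # uniaxial fiber compression, isochoric: I4f < 1 so the fiber term is out
  lam <- 0.9
  Fc <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  p_iso_off <- ho_parameters(a = 0, a_s = 0, a_fs = 0)
  expect_identical(strain_energy(Fc, p_iso_off), 0)
  expect_identical(max(abs(passive_pk1(Fc, p_iso_off))), 0)
  # under stretch it switches on
  Fs <- diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1)))
  expect_gt(strain_energy(Fs, p_iso_off), 0)
})

test_that("strain energy under fiber stretch matches a symbolic evaluation", {
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  p <- ho_parameters()
  # independent evaluation of the energy expression
  I1 <- lam^2 + 2 / lam
  I4f <- lam^2
  W_hand <- p$a / (2 * p$b) * (exp(p$b * (I1 - 3)) - 1) +
    p$a_f / (2 * p$b_f) * (exp(p$b_f * (I4f - 1)^2) - 1)
  expect_equal(strain_energy(F, p), W_hand, tolerance = 1e-12)
})

test_that("analytic stress equals the numeric energy gradient", {
  set.seed(3)
  p <- ho_parameters()
  for (k in 1:20) {
    F <- random_isochoric_F()
    d <- deformation_state(F)
    corr <- p$a * exp(p$b * (d$I1 - 3)) * t(solve(F))
    num <- num_grad_matrix(function(Fx) strain_energy(Fx, p), F) - corr
    ana <- passive_pk1(F, p)
    expect_lt(max(abs(ana - num)) / max(abs(ana)), 1e-5)
  }
})

test_that("simple shear engages the fiber-sheet coupling invariant", {
  gam <- 0.2
  F <- diag(3); F[1, 2] <- gam
  d <- deformation_state(F)
  expect_equal(d$I8fs, gam, tolerance = 1e-12)
  P <- passive_pk1(d)
  expect_gt(max(abs(P)), 0)
})

test_that("energy is invariant to superposed rotations", {
  set.seed(5)
  for (k in 1:10) {
    F <- random_isochoric_F()
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- stats::runif(1, 0, pi)
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
               c(-ax[2], ax[1], 0))
    Q <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    expect_equal(strain_energy(Q %*% F), strain_energy(F),
                 tolerance = 1e-10)
  }
})

test_that("active stress is rank-one along the fiber", {
  expect_identical(max(abs(active_cauchy_stress(0, c(1, 0, 0), 3))), 0)
  S <- active_cauchy_stress(10, c(1, 0, 0), T_scale = 3)
  expect_equal(S, diag(c(30, 0, 0)))
  expect_equal(sum(diag(S)), 30)
  fb <- c(1, 1, 1) / sqrt(3)
  S2 <- active_cauchy_stress(5, fb, 2)
  ev <- eigen(S2, symmetric = TRUE)
  expect_equal(sort(ev$values), c(0, 0, 10), tolerance = 1e-12)
  expect_equal(abs(sum(ev$vectors[, which.max(ev$values)] * fb)), 1,
               tolerance = 1e-12)
  expect_error(active_cauchy_stress(5, c(1, 1, 0)), "unit")
})

test_that("the closed-form sphere integrand matches the generic stress", {
  p <- ho_parameters()
  cfg <- sphere_lv_config()
  for (ri in c(1.6, 2.0, 2.6)) {
    for (R in c(2.1, 2.7, 3.2)) {
      r <- (ri^3 + R^3 - cfg$r_inner^3)^(1 / 3)
      lam <- r / R
      F <- diag(c(lam^-2, lam, lam))
      P <- passive_pk1(deformation_state(F, c(0, 1, 0), c(0, 0, 1)), p)
      sig <- P %*% t(F)
      dev_generic <- sig[2, 2] + sig[3, 3] - 2 * sig[1, 1]
      got <- cardioec:::sphere_cavity_pressure(ri,
        sphere_lv_config(r_inner = cfg$r_inner, r_outer = cfg$r_outer),
        p)
      # compare through a 1-point version of the integrand
      l2 <- lam^2; I1 <- lam^-4 + 2 * l2
      dev_closed <- p$a * exp(p$b * (I1 - 3)) * 2 * (l2 - lam^-4) +
        (if (l2 > 1) 2 * ((p$a_f * (l2 - 1) * exp(p$b_f * (l2 - 1)^2)) +
                            (p$a_s * (l2 - 1) * exp(p$b_s * (l2 - 1)^2))) * l2
         else 0)
      expect_equal(dev_closed, dev_generic, tolerance = 1e-10)
      expect_true(is.finite(got))
    }
  }
})

test_that("unloaded, inactive sphere keeps its reference geometry", {
  pv <- sphere_pv(sphere_lv_config(edp = 0, esp = 0), tension = 0)
  ref <- 4 / 3 * pi * sphere_lv_config()$r_inner^3
  expect_equal(pv$edv_mL, ref, tolerance = 1e-6)
  expect_equal(pv$sv_mL, 0, tolerance = 1e-6)
})

test_that("pump-function trends are directionally correct", {
  # afterload: ESV grows with ESP; contractility: ESV falls with T_scale
  sw <- lv_sweep(tension = 9.87, esp = c(100, 125, 150), T_scale = c(3, 6))
  by_ts <- split(sw, sw$T_scale)
  for (d in by_ts) expect_true(all(diff(d$esv_mL[order(d$esp)]) > 0))
  by_esp <- split(sw, sw$esp)
  for (d in by_esp) expect_true(all(diff(d$esv_mL[order(d$T_scale)]) < 0))
  # preload: EDV grows with EDP (Frank-Starling direction)
  sw2 <- lv_sweep(tension = 9.87, edp = c(4, 8, 12, 16), esp = 120,
                  T_scale = 3)
  expect_true(all(diff(sw2$edv_mL) > 0))
  # doubling contractility at fixed afterload strictly reduces ESV
  a <- sphere_pv(sphere_lv_config(), ho_parameters(T_scale = 3), 9.87)
  b <- sphere_pv(sphere_lv_config(), ho_parameters(T_scale = 6), 9.87)
  expect_lt(b$esv_mL, a$esv_mL)
})

test_that("material and geometry validation reject bad inputs", {
  expect_error(ho_parameters(a = -1), "non-negative")
  expect_error(sphere_lv_config(r_inner = 3, r_outer = 2), "r_inner")
  expect_error(sphere_lv_config(edp = -1), ">= 0")
  expect_error(deformation_state(diag(c(1, 1, -1))), "det F")
  expect_error(deformation_state(diag(3), f0 = c(2, 0, 0)), "unit")
})
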