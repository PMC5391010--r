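# Passive myocardium: Holzapfel-Ogden orthotropic strain energy with fiber,
# sheet and fiber-sheet coupling terms; active stress as a rank-one Cauchy
# tensor along the current fiber direction; and a thick-walled incompressible
# sphere as a reduced left-ventricle surrogate for qualitative pump-function
# trends.

#' Holzapfel-Ogden material parameters
#'
#' The eight non-negative constants of the orthotropic strain-energy
#' function (`a`-type in kPa, `b`-type dimensionless) plus the active
#' tension scaling `T_scale` that maps myofilament tension to tissue-level
#' contractility.  Defaults are the values used for the left-ventricle
#' simulations.
#'
#' @param a,b Isotropic matrix response (kPa, -).
#' @param a_f,b_f Fiber response (kPa, -).
#' @param a_s,b_s Sheet response (kPa, -).
#' @param a_fs,b_fs Fiber-sheet coupling (kPa, -).
#' @param T_scale Active tension multiplier (dimensionless).
#' @return Named list of class `ho_parameters`.
#' @export
ho_parameters <- function(a = 0.24, b = 5.08, a_f = 1.46, b_f = 4.15,
                          a_s = 0.87, b_s = 1.6, a_fs = 0.3, b_fs = 1.3,
                          T_scale = 3.0) {
  p <- list(a = a, b = b, a_f = a_f, b_f = b_f, a_s = a_s, b_s = b_s,
            a_fs = a_fs, b_fs = b_fs, T_scale = T_scale)
  bad <- vapply(p, function(x) !is.finite(x) || x < 0, logical(1))
  if (any(bad)) {
    stop("material parameters must be finite and non-negative: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  }
  structure(p, class = "ho_parameters")
}

#' Deformation state from a deformation gradient
#'
#' Builds the kinematic quantities used by the constitutive law: the right
#' Cauchy-Green tensor `C = F'F`, `J = det F`, the invariants `I1`,
#' `I4f = f0' C f0`, `I4s`, `I8fs = f0' C s0`, and the current (unit) fiber
#' direction.
#'
#' @param F 3x3 deformation gradient with `det F > 0`.
#' @param f0,s0 Reference fiber and sheet directions (unit vectors).
#' @return A list of class `deformation_state`.
#' @export
deformation_state <- function(F, f0 = c(1, 0, 0), s0 = c(0, 1, 0)) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)), all(is.finite(F)))
  J <- det(F)
  if (J <= 0) stop("deformation gradient must have det F > 0", call. = FALSE)
  if (abs(sum(f0^2) - 1) > 1e-8 || abs(sum(s0^2) - 1) > 1e-8) {
    stop("f0 and s0 must be unit vectors", call. = FALSE)
  }
  C <- t(F) %*% F
  f <- drop(F %*% f0)
  s <- drop(F %*% s0)
  structure(list(
    F = F, C = C, J = J, f0 = f0, s0 = s0, f = f, s = s,
    fbar = f / sqrt(sum(f^2)),
    I1 = sum(diag(C)),
    I4f = drop(t(f0) %*% C %*% f0),
    I4s = drop(t(s0) %*% C %*% s0),
    I8fs = drop(t(f0) %*% C %*% s0)
  ), class = "deformation_state")
}

#' Passive strain energy of the myocardium
#'
#' The orthotropic strain-energy density (kPa), normalised to zero at the
#' reference state: an exponential isotropic term in `I1`, exponential
#' fiber and sheet terms in `I4f`, `I4s` that are active only under
#' stretch (`I4i' = max(I4i, 1)`, so fibers bear no load in compression),
#' and an exponential fiber-sheet coupling term in `I8fs`.
#'
#' @param defo A [deformation_state()] (or a 3x3 matrix, coerced with
#'   default directions).
#' @param params [ho_parameters()].
#' @return Strain energy density in kPa.
#' @export
strain_energy <- function(defo, params = ho_parameters()) {
  if (is.matrix(defo)) defo <- deformation_state(defo)
  p <- params
  i4f <- max(defo$I4f, 1)
  i4s <- max(defo$I4s, 1)
  p$a / (2 * p$b) * (exp(p$b * (defo$I1 - 3)) - 1) +
    p$a_f / (2 * p$b_f) * (exp(p$b_f * (i4f - 1)^2) - 1) +
    p$a_s / (2 * p$b_s) * (exp(p$b_s * (i4s - 1)^2) - 1) +
    p$a_fs / (2 * p$b_fs) * (exp(p$b_fs * defo$I8fs^2) - 1)
}

#' Passive first Piola-Kirchhoff stress
#'
#' Analytic stress of the passive law,
#' `P = dW/dF - a exp(b (I1 - 3)) F^-T`; the correction term makes the
#' reference state exactly stress free.  Fiber and sheet terms contribute
#' only when stretched.
#'
#' @inheritParams strain_energy
#' @return 3x3 first Piola-Kirchhoff stress tensor (kPa).
#' @export
passive_pk1 <- function(defo, params = ho_parameters()) {
  if (is.matrix(defo)) defo <- deformation_state(defo)
  p <- params
  F <- defo$F
  expb <- exp(p$b * (defo$I1 - 3))
  P <- p$a * expb * F
  if (defo$I4f > 1) {
    P <- P + 2 * p$a_f * (defo$I4f - 1) *
      exp(p$b_f * (defo$I4f - 1)^2) * (F %*% (defo$f0 %o% defo$f0))
  }
  if (defo$I4s > 1) {
    P <- P + 2 * p$a_s * (defo$I4s - 1) *
      exp(p$b_s * (defo$I4s - 1)^2) * (F %*% (defo$s0 %o% defo$s0))
  }
  P <- P + p$a_fs * defo$I8fs * exp(p$b_fs * defo$I8fs^2) *
    (F %*% (defo$f0 %o% defo$s0 + defo$s0 %o% defo$f0))
  P - p$a * expb * t(solve(F))
}

#' Active Cauchy stress along the fiber direction
#'
#' The rank-one active stress `sigma_a = T_scale * T * fbar (x) fbar`,
#' with `fbar` the unit current fiber direction.
#'
#' @param tension Active tension `T` (kPa), from the myofilament model.
#' @param fbar Unit current fiber direction.
#' @param T_scale Scaling of myofilament tension to tissue contractility.
#' @return 3x3 Cauchy stress tensor (kPa).
#' @export
active_cauchy_stress <- function(tension, fbar, T_scale = 1) {
  if (abs(sum(fbar^2) - 1) > 1e-8) {
    stop("`fbar` must be a unit vector", call. = FALSE)
  }
  T_scale * tension * (fbar %o% fbar)
}

#' Configuration of the spherical left-ventricle surrogate
#'
#' Reference geometry and loading of the incompressible thick-walled-sphere
#' surrogate.  Default radii give a reference cavity of ~34 mL and a wall
#' volume of ~145 mL, in the range of a human left ventricle; default
#' pressures are the end-diastolic 8 mmHg and end-systolic 150 mmHg used
#' for the organ-level simulations.
#'
#' @param r_inner,r_outer Reference endocardial / epicardial radii (cm).
#' @param edp End-diastolic cavity pressure (mmHg).
#' @param esp End-systolic cavity pressure (mmHg).
#' @return Named list of class `sphere_lv_config`.
#' @export
sphere_lv_config <- function(r_inner = 2.0, r_outer = 3.3,
                             edp = 8, esp = 150) {
  if (!(r_inner > 0 && r_outer > r_inner)) {
    stop("need 0 < r_inner < r_outer", call. = FALSE)
  }
  if (edp < 0 || esp < 0) stop("pressures must be >= 0", call. = FALSE)
  structure(list(r_inner = r_inner, r_outer = r_outer, edp = edp,
                 esp = esp),
            class = "sphere_lv_config")
}

mmHg_to_kPa <- function(x) x * 0.133322

# cavity pressure (kPa) holding an incompressible sphere at deformed inner
# radius ri, given wall material and a spatially uniform active tension Ta
# (kPa) split equally between the two tangential directions.
#
# Kinematics are diagonal (F = diag(lam^-2, lam, lam), fiber along theta,
# sheet along phi, I8fs = 0), so the wall-stress combination
# (sig_tt + sig_pp - 2 sig_rr) has the closed form used below; the generic
# passive_pk1() reproduces it (checked in the test suite).  The pressure-like
# correction term of the stress is isotropic and drops out of the
# combination.
sphere_cavity_pressure <- function(ri, config, params, Ta = 0) {
  Ri <- config$r_inner; Ro <- config$r_outer
  p <- params
  integrand <- function(R) {
    r <- (ri^3 + R^3 - Ri^3)^(1 / 3)
    lam <- r / R
    l2 <- lam^2
    I1 <- lam^-4 + 2 * l2
    dev <- p$a * exp(p$b * (I1 - 3)) * 2 * (l2 - lam^-4)
    stretch <- l2 > 1
    fib <- 2 * (p$a_f * (l2 - 1) * exp(p$b_f * (l2 - 1)^2) +
                  p$a_s * (l2 - 1) * exp(p$b_s * (l2 - 1)^2)) * l2
    dev <- dev + ifelse(stretch, fib, 0) + Ta
    # change of variables r -> R:  dr = (R^2 / r^2) dR
    dev / r * (R^2 / r^2)
  }
  stats::integrate(integrand, Ri, Ro, rel.tol = 1e-8)$value
}

#' Pump-function summary of the sphere surrogate
#'
#' Quasi-static pressure-volume points of the surrogate: the end-diastolic
#' volume from passive inflation at the end-diastolic pressure, the
#' end-systolic volume from equilibrium at the end-systolic pressure with
#' the peak active tension (times `T_scale`) distributed tangentially in
#' the wall, and the derived stroke volume and ejection fraction.
#' Equilibrium is found by bracketed root finding on the deformed inner
#' radius over `[0.3, 3] x` the reference radius.
#'
#' @param config [sphere_lv_config()].
#' @param params [ho_parameters()]; `params$T_scale` scales the active
#'   tension.
#' @param tension Peak active tension (kPa): a scalar, or a trace with a
#'   `tension_kPa` column whose maximum is used.
#' @return A one-row tibble with `edv_mL`, `esv_mL`, `sv_mL`, `ef_percent`
#'   (ejection fraction; negative when the loaded sphere cannot eject).
#' @export
#' @examples
#' sphere_pv(sphere_lv_config(), ho_parameters(), tension = 9.9)
sphere_pv <- function(config = sphere_lv_config(), params = ho_parameters(),
                      tension = 0) {
  if (is.data.frame(tension)) {
    if (!"tension_kPa" %in% names(tension)) {
      stop("tension trace needs a `tension_kPa` column", call. = FALSE)
    }
    tension <- max(tension$tension_kPa)
  }
  stopifnot(is.finite(tension), tension >= 0)
  # the cavity-pressure curve of an activated sphere can fold (several
  # equilibria); scan the bracket, refine every sign change, and return the
  # most contracted equilibrium — a deterministic, documented selection
  solve_ri <- function(pressure_kPa, Ta, n_scan = 120) {
    g <- function(ri) {
      sphere_cavity_pressure(ri, config, params, Ta) - pressure_kPa
    }
    lo <- 0.3 * config$r_inner; hi <- 3 * config$r_inner
    grid <- seq(lo, hi, length.out = n_scan)
    gv <- vapply(grid, g, numeric(1))
    sgn <- which(gv[-1] * gv[-n_scan] <= 0)
    if (!length(sgn)) {
      stop("no equilibrium in the bracket [", signif(lo, 3), ", ",
           signif(hi, 3), "] cm; residual range [", signif(min(gv), 3),
           ", ", signif(max(gv), 3), "] kPa", call. = FALSE)
    }
    i <- sgn[1]
    stats::uniroot(g, grid[c(i, i + 1)], tol = 1e-9)$root
  }
  ri_ed <- solve_ri(mmHg_to_kPa(config$edp), 0)
  ri_es <- solve_ri(mmHg_to_kPa(config$esp), params$T_scale * tension)
  edv <- 4 / 3 * pi * ri_ed^3
  esv <- 4 / 3 * pi * ri_es^3
  tibble::tibble(edv_mL = edv, esv_mL = esv, sv_mL = edv - esv,
                 ef_percent = 100 * (edv - esv) / edv)
}

#' Sweep the surrogate over loading and contractility grids
#'
#' Evaluates [sphere_pv()] on the Cartesian grid of end-diastolic
#' pressures, end-systolic pressures and `T_scale` values, producing a tidy
#' table of pump-function trends (the reduced-order analogue of varying
#' afterload, preload and contractility).
#'
#' @param config Base [sphere_lv_config()].
#' @param params Base [ho_parameters()].
#' @param tension Peak active tension (kPa) of the underlying myocyte.
#' @param edp,esp,T_scale Numeric vectors of grid values (defaults: the
#'   base configuration values).
#' @return A tibble of class `lv_sweep`, one row per grid point with the
#'   inputs and `edv_mL`, `esv_mL`, `sv_mL`, `ef_percent`.
#' @export
lv_sweep <- function(config = sphere_lv_config(), params = ho_parameters(),
                     tension = 0, edp = config$edp, esp = config$esp,
                     T_scale = params$T_scale) {
  grid <- tidyr::expand_grid(edp = edp, esp = esp, T_scale = T_scale)
  out <- purrr::pmap_dfr(grid, function(edp, esp, T_scale) {
    cfg <- sphere_lv_config(config$r_inner, config$r_outer, edp, esp)
    prm <- params; prm$T_scale <- T_scale
    dplyr::bind_cols(tibble::tibble(edp = edp, esp = esp,
                                    T_scale = T_scale),
                     sphere_pv(cfg, prm, tension))
  })
  class(out) <- c("lv_sweep", class(out))
  out
}
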