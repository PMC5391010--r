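test_that("triangular AP biomarkers match their closed forms", {
  for (t_fall in c(200, 300, 400)) {
    tri <- synth_triangle_ap(t_rise = 1, t_fall = t_fall)
    truth <- attr(tri, "truth")
    expect_equal(apd(tri, 0.9), truth$apd90, tolerance = truth$apd_tolerance)
    expect_equal(apd(tri, 0.5), truth$apd(0.5),
                 tolerance = truth$apd_tolerance)
    expect_equal(upstroke_velocity(tri, "vm"), truth$upstroke_velocity,
                 tolerance = 1e-9)
  }
})

test_that("a linear voltage ramp has its slope as upstroke velocity", {
  ramp <- tibble::tibble(time_ms = seq(0, 1, by = 0.1),
                         vm_mV = seq(0, 100, by = 10))
  expect_equal(upstroke_velocity(ramp, "vm"), 100)
  expect_error(upstroke_velocity(ramp[1:2, ], "vm"), "3 samples")
})

test_that("constant and monotone traces are rejected with clear errors", {
  flat <- tibble::tibble(time_ms = 0:100, vm_mV = -80)
  expect_error(apd(flat), "no AP")
  mono <- tibble::tibble(time_ms = 0:100, ca_i_uM = seq(0, 1, length.out = 101))
  expect_error(transient_features(mono, "ca_i"), "peak")
  expect_error(apd(tibble::tibble(time_ms = c(0, 1, 1), vm_mV = 1:3)),
               "strictly increasing")
})

test_that("Gaussian transient features match their closed forms", {
  for (sigma in c(15, 25, 60)) {
    g <- synth_gaussian_transient(baseline = 0.1, amplitude = 0.9,
                                  t0 = 80, sigma = sigma, t_end = 600,
                                  dt = 0.05)
    truth <- attr(g, "truth")
    got <- transient_features(g, "ca_i")
    expect_equal(got$peak, truth$peak, tolerance = 1e-6)
    expect_equal(got$time_to_peak_s, truth$time_to_peak_s, tolerance = 1e-3)
    expect_equal(got$amplitude, truth$amplitude, tolerance = 1e-6)
    expect_equal(got$rate_of_development, truth$rate_of_development,
                 tolerance = 1e-4)
    expect_equal(got$rt50_s, truth$rt50_s, tolerance = 1e-4)
  }
})

test_that("the refractory interval at 90% repolarization equals APD90", {
  tr <- case_trace("A")
  expect_equal(erp(tr, repolarization_fraction = 0.9), apd(tr, 0.9))
  # at the documented default level it is shorter than APD90
  expect_lt(erp(tr), apd(tr, 0.9))
  expect_equal(erp_repolarization_fraction(), 0.85)
})

test_that("feature extraction is stable under time-grid refinement", {
  g1 <- synth_gaussian_transient(t0 = 80, sigma = 25, dt = 0.2,
                                 signal = "tension", baseline = 0,
                                 amplitude = 10)
  g2 <- synth_gaussian_transient(t0 = 80, sigma = 25, dt = 0.1,
                                 signal = "tension", baseline = 0,
                                 amplitude = 10)
  f1 <- transient_features(g1, "tension")
  f2 <- transient_features(g2, "tension")
  for (col in c("peak", "amplitude", "rate_of_development", "rt50_s")) {
    expect_lt(abs(f1[[col]] - f2[[col]]) / abs(f2[[col]]), 1e-3)
  }
  # and for the simulated beat, 2x refinement moves biomarkers < 0.1%
  b1 <- biomarker_report(case_trace("A", record_dt = 0.04))
  b2 <- biomarker_report(case_trace("A", record_dt = 0.02))
  for (col in c("apd90_ms", "cat_peak_uM", "tension_peak_kPa", "erp_ms",
                "cat_amplitude_uM", "tension_rt50_s")) {
    expect_lt(abs(b1[[col]] - b2[[col]]) / abs(b2[[col]]), 1e-3)
  }
})

test_that("the biomarker report carries all twelve features", {
  rep <- biomarker_report(case_trace("A"))
  expect_s3_class(rep, "biomarker_report")
  expect_identical(nrow(rep), 1L)
  expect_identical(ncol(rep), 13L)  # case label + 12 features
  expect_true(all(is.finite(as.numeric(rep[-1]))))
  expect_gt(rep$apd90_ms, 100)
  expect_lt(rep$resting_potential_mV, -70)
  expect_gt(rep$tension_peak_kPa, 0)
  long <- generics::tidy(rep)
  expect_identical(nrow(long), 12L)
})
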