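test_that("tension is exactly zero at the resting myofilament state", {
  expect_identical(active_tension(nhs_initial_state()), 0)
  # and with no Ca ever supplied, it stays zero
  flat <- tibble::tibble(time_ms = seq(0, 500, by = 1), ca_i_uM = 0)
  out <- run_isometric(flat)
  expect_true(all(out$tension_kPa == 0))
})

test_that("troponin occupancy cannot grow without Ca", {
  d0 <- nhs_derivatives(nhs_state = nhs_initial_state(), ca_i = 0)
  expect_lte(d0[["ca_trpn"]], 0)
  st <- c(ca_trpn = 10, z_tm = 0.2, q1 = 0, q2 = 0, q3 = 0)
  expect_lt(nhs_derivatives(nhs_state = st, ca_i = 0)[["ca_trpn"]], 0)
  # binding rate increases with Ca
  d1 <- nhs_derivatives(nhs_state = st, ca_i = 0.5)[["ca_trpn"]]
  d2 <- nhs_derivatives(nhs_state = st, ca_i = 1.5)[["ca_trpn"]]
  expect_gt(d2, d1)
  expect_error(nhs_derivatives(nhs_state = st, ca_i = -1), ">= 0")
  expect_error(nhs_derivatives(nhs_state = st, ca_i = 1, lambda = 0),
               "positive")
})

test_that("troponin binding matches the scalar-ODE oracle under saturating Ca", {
  # freeze tropomyosin kinetics (alpha_0 = 0 keeps z = 0, hence tension 0,
  # hence constant unbinding rate): the binding equation alone is linear
  # with the closed form K (1 - e^{-r t})
  p <- nhs_parameters(alpha_0 = 0)
  ca <- 50  # uM, saturating
  r <- p$k_on * ca + p$k_ref_off
  K <- p$k_on * ca * p$Ca_TRPN_max / r
  ca_tr <- tibble::tibble(time_ms = seq(0, 200, by = 0.5), ca_i_uM = ca)
  out <- run_isometric(ca_tr, params = p)
  expected <- K * (1 - exp(-r * out$time_ms / 1000))
  expect_equal(out$ca_trpn, expected, tolerance = 1e-5)
  # approach to the asymptote is monotone from below (solver wiggle at the
  # plateau stays far below the oracle tolerance)
  expect_true(all(diff(out$ca_trpn) >= -1e-6 * max(out$ca_trpn)))
  expect_lt(max(out$ca_trpn), p$Ca_TRPN_max)
})

test_that("a step rise in Ca produces a monotone tension rise to a peak", {
  ca_tr <- tibble::tibble(
    time_ms = seq(0, 800, by = 1),
    ca_i_uM = ifelse(time_ms < 10, 0.1, 1.0))
  out <- run_isometric(ca_tr)
  i_pk <- which.max(out$tension_kPa)
  expect_gt(i_pk, 5)
  rising <- out$tension_kPa[out$time_ms >= 10 & out$time_ms <= out$time_ms[i_pk]]
  expect_true(all(diff(rising) >= -1e-10))
  expect_gt(max(out$tension_kPa), 0)
})

test_that("isometric runs never exercise the stretch-rate memory terms", {
  tr <- case_trace("A")
  # co-integrated myofilament state: Q variables must remain exactly zero
  tr_states <- simulate_myocyte("A", stimulus_protocol(n_prepace = 1),
                                keep_states = TRUE, record_dt = 1)
  expect_true(all(tr_states$q1 == 0))
  expect_true(all(tr_states$q2 == 0))
  expect_true(all(tr_states$q3 == 0))
  expect_true(all(tr$tension_kPa >= 0))
})

test_that("peak tension is monotone in a uniform Ca-transient scaling", {
  ca_tr <- dplyr::select(tibble::as_tibble(case_trace("A", record_dt = 0.5)),
                         "time_ms", "ca_i_uM")
  peaks <- vapply(c(0.25, 0.5, 0.75, 1), function(k) {
    scaled <- dplyr::mutate(ca_tr, ca_i_uM = k * .data$ca_i_uM)
    max(run_isometric(scaled)$tension_kPa)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("trace-driven and co-integrated coupling agree", {
  tr <- simulate_myocyte("A", stimulus_protocol(n_prepace = 5),
                         record_dt = 0.1, keep_states = TRUE)
  ca_only <- dplyr::select(tibble::as_tibble(tr), "time_ms", "ca_i_uM")
  # start the standalone run from the same (pre-paced) myofilament state
  init <- c(ca_trpn = tr$ca_trpn[1], z_tm = tr$z_tm[1], q1 = tr$q1[1],
            q2 = tr$q2[1], q3 = tr$q3[1])
  standalone <- run_isometric(ca_only, init = init)
  expect_equal(max(standalone$tension_kPa), max(tr$tension_kPa),
               tolerance = 2e-3)
})

test_that("degenerate isometric inputs are rejected", {
  expect_error(run_isometric(tibble::tibble()), "non-empty")
  expect_error(run_isometric(tibble::tibble(time_ms = c(0, 0, 1),
                                            ca_i_uM = 1)),
               "strictly increasing")
  expect_error(run_isometric(tibble::tibble(time_ms = 0:10, ca_i_uM = 1),
                             lambda = -1), "positive")
})
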