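test_that("protocol construction enforces its invariants", {
  p <- stimulus_protocol()
  expect_equal(p$cycle_length, 1000)
  expect_equal(p$amplitude, -9.5)
  expect_error(stimulus_protocol(duration = 1200), "shorter than")
  expect_error(stimulus_protocol(amplitude = 0), "nonzero")
  expect_error(stimulus_protocol(n_record = 0), "n_record")
})

test_that("a sub-threshold stimulus leaves the membrane quiescent", {
  # settle to the unstimulated rest first, then apply a far-sub-threshold
  # pulse: the membrane must not leave the resting neighbourhood
  pv <- cardioec:::ode_parameter_vector(stim_amplitude = 0)
  out <- cardioec:::integrate_segment(initial_state(), c(0, 2e4), pv,
                                      rtol = 1e-8, atol = 1e-11,
                                      maxsteps = 2e5)
  rest <- out[nrow(out), 1 + seq_len(nrow(state_registry()))]
  names(rest) <- state_registry()$name
  tr <- simulate_myocyte("A", stimulus_protocol(amplitude = -1e-3,
                                                n_prepace = 0),
                         init = rest, record_dt = 1)
  expect_lt(max(abs(tr$vm_mV - tr$vm_mV[1])), 1)
})

test_that("identical configurations reproduce bitwise-identical output", {
  prot <- stimulus_protocol(n_prepace = 2)
  t1 <- simulate_myocyte("B", prot, record_dt = 0.5)
  t2 <- simulate_myocyte("B", prot, record_dt = 0.5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trace(t1, f1); write_trace(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the recorded beat is densely and monotonically sampled", {
  tr <- case_trace("A")
  expect_true(all(diff(tr$time_ms) > 0))
  expect_lte(max(diff(tr$time_ms)), 0.5)   # upstroke resolution requirement
  expect_equal(tr$time_ms[1], 0)
  expect_equal(max(tr$time_ms), 1000)
  expect_named(tr[1:4], c("time_ms", "vm_mV", "ca_i_uM", "tension_kPa"))
})

test_that("trajectories respect gate bounds and positivity over ten beats", {
  tr <- simulate_myocyte("A", stimulus_protocol(n_prepace = 0, n_record = 10),
                         keep_states = TRUE, record_dt = 1)
  reg <- state_registry()
  for (k in seq_len(nrow(reg))) {
    x <- tr[[reg$name[k]]]
    if (!is.na(reg$lower[k])) expect_gte(min(x), reg$lower[k] - 1e-6)
    if (!is.na(reg$upper[k])) expect_lte(max(x), reg$upper[k] + 1e-6)
    if (reg$kind[k] == "concentration") expect_gt(min(x), 0)
  }
})

test_that("tolerance refinement does not change the beat (solver oracle)", {
  prot <- stimulus_protocol(n_prepace = 1)
  lo <- simulate_myocyte("A", prot, rtol = 1e-6, atol = 1e-9,
                         record_dt = 0.5)
  hi <- simulate_myocyte("A", prot, rtol = 1e-9, atol = 1e-12,
                         record_dt = 0.5)
  expect_lt(max(abs(lo$vm_mV - hi$vm_mV)), 0.1)
})

test_that("paced_to_steady_state honours its tolerance contract", {
  prot <- stimulus_protocol(n_prepace = 3)
  st <- paced_to_steady_state("A", prot, tolerance = Inf)
  expect_identical(attr(st, "beats_run"), 3L)
  expect_false(attr(st, "converged"))
  # restarting from the returned state reproduces the next beat
  tr1 <- simulate_myocyte("A", stimulus_protocol(n_prepace = 0), init = st,
                          record_dt = 1)
  tr2 <- simulate_myocyte("A", stimulus_protocol(n_prepace = 0), init = st,
                          record_dt = 1)
  expect_identical(tr1$vm_mV, tr2$vm_mV)
  # loose tolerance met immediately reports convergence
  st2 <- paced_to_steady_state("A", stimulus_protocol(n_prepace = 5),
                               tolerance = 10)
  expect_true(attr(st2, "converged"))
  expect_warning(
    paced_to_steady_state("A", stimulus_protocol(n_prepace = 2),
                          tolerance = 1e-12),
    "did not fall")
})

test_that("pacing converges: beat-to-beat Vm differences shrink", {
  # successive recorded beats approach the paced limit cycle
  tr <- simulate_myocyte("A", stimulus_protocol(n_prepace = 0, n_record = 8),
                         record_dt = 1)
  beats <- split(tr$vm_mV, findInterval(tr$time_ms - 1e-9, 1000 * (1:8)))
  n <- min(lengths(beats))
  d <- vapply(seq_len(length(beats) - 1), function(b) {
    max(abs(beats[[b + 1]][1:n] - beats[[b]][1:n]))
  }, numeric(1))
  expect_lt(d[length(d)], d[1])
})

test_that("solver failures carry a time and state snapshot", {
  bad <- initial_state()
  bad[["ca_sr"]] <- 1e-12   # degenerate SR content forces tiny steps
  suppressWarnings(expect_error(
    cardioec:::integrate_segment(bad, c(0, 1e9),
                                 cardioec:::ode_parameter_vector(),
                                 rtol = 1e-12, atol = 1e-16, maxsteps = 10),
    "istate|steps"))
})
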