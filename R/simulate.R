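#' Pacing protocol for myocyte simulations
#'
#' A square-pulse pacing protocol: an inward current pulse of given
#' amplitude and duration applied at the start of every cycle.  The default
#' is the conventional 1 Hz protocol used for all shipped results: a
#' -9.5 uA/uF, 5 ms pulse at a 1000 ms basic cycle length, 100 pre-pacing
#' beats to approach the paced limit cycle, and one recorded beat.
#'
#' @param amplitude Pulse amplitude (uA/uF); negative = inward
#'   (depolarising).
#' @param duration Pulse duration (ms), shorter than the cycle length.
#' @param cycle_length Basic cycle length (ms).
#' @param n_prepace Number of unrecorded conditioning beats.
#' @param n_record Number of recorded beats.
#' @return A list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude = -9.5, duration = 5,
                              cycle_length = 1000, n_prepace = 100,
                              n_record = 1) {
  stopifnot(is.finite(amplitude), is.finite(duration), is.finite(cycle_length))
  if (abs(amplitude) <= 0 || duration <= 0 || cycle_length <= 0) {
    stop("amplitude, duration and cycle length must be nonzero and positive",
         call. = FALSE)
  }
  if (duration >= cycle_length) {
    stop("pulse duration must be shorter than the cycle length",
         call. = FALSE)
  }
  if (n_prepace < 0 || n_record < 1) {
    stop("need n_prepace >= 0 and n_record >= 1", call. = FALSE)
  }
  structure(list(amplitude = amplitude, duration = duration,
                 cycle_length = cycle_length,
                 n_prepace = as.integer(n_prepace),
                 n_record = as.integer(n_record)),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> %g uA/uF x %g ms pulse, BCL %g ms, %d prepace + %d recorded beat(s)\n",
    x$amplitude, x$duration, x$cycle_length, x$n_prepace, x$n_record))
  invisible(x)
}

# integrate one time segment with the compiled RHS (or the R reference when
# use_compiled = FALSE); returns the deSolve output matrix
integrate_segment <- function(y, times, pv, rtol, atol, use_compiled = TRUE,
                              maxsteps = 50000) {
  if (use_compiled) {
    out <- deSolve::ode(y = y, times = times, func = "cardioec_derivs",
                        parms = pv, dllname = "cardioec",
                        initfunc = "cardioec_initmod",
                        nout = 1, outnames = "tension_kPa",
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = maxsteps)
  } else {
    rhs <- function(t, y, parms) {
      ev <- model_eval_r(t, y, parms, stim = parms[["stim_amplitude"]])
      list(ev$dy, tension_kPa = ev$tension)
    }
    out <- deSolve::ode(y = y, times = times, func = rhs, parms = pv,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = maxsteps)
  }
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    last <- out[nrow(out), ]
    stop("solver failed (istate ", istate, ") at t = ", last[1],
         " ms; state snapshot: ",
         paste(sprintf("%s=%.4g", names(y), last[1 + seq_along(y)]),
               collapse = ", "), call. = FALSE)
  }
  out
}

# advance the state through one paced beat; returns the end-of-beat state
advance_beat <- function(y, pv_on, pv_off, protocol, rtol, atol,
                         use_compiled = TRUE) {
  seg1 <- integrate_segment(y, c(0, protocol$duration), pv_on, rtol, atol,
                            use_compiled)
  y1 <- seg1[nrow(seg1), 1 + seq_along(y)]
  names(y1) <- names(y)
  seg2 <- integrate_segment(y1, c(protocol$duration, protocol$cycle_length),
                            pv_off, rtol, atol, use_compiled)
  y2 <- seg2[nrow(seg2), 1 + seq_along(y)]
  names(y2) <- names(y)
  y2
}

#' Simulate a paced myocyte
#'
#' Integrates the coupled electrophysiology + myofilament model under a
#' square-pulse pacing protocol and returns the recorded beat(s) as a tidy
#' trace.  The disease state is selected by a case letter (`"A"`-`"D"`), a
#' severity fraction in `[0, 1]`, or an explicit impact-factor vector.
#' The recorded beat starts at stimulus onset (`time_ms = 0`); the sample at
#' `time_ms = 0` is the pre-stimulus (end-diastolic) state.
#'
#' @param case Disease case: letter, severity fraction or
#'   [impact_factors()] vector.
#' @param protocol A [stimulus_protocol()].
#' @param params Membrane-model parameters ([gpb_parameters()]).
#' @param nhs Myofilament parameters ([nhs_parameters()]).
#' @param init Initial state (default [initial_state()]).
#' @param lambda Constant fibre stretch for the myofilament block
#'   (default 1: isometric at resting length).
#' @param rtol,atol Solver tolerances (lsoda).
#' @param record_dt Output sampling interval of the recorded beat (ms).
#' @param keep_states Also return all 46 state variables as columns.
#' @param use_compiled Use the compiled right-hand side (default); the pure-R
#'   reference is available for cross-checking at small problem sizes.
#' @return A tibble of class `myocyte_trace` with columns `time_ms`,
#'   `vm_mV`, `ca_i_uM`, `tension_kPa` (and the states if requested).
#'   Attributes: `case`, `factors`, `protocol`, `solver`, `diastolic_state`.
#' @export
#' @examples
#' \donttest{
#' tr <- simulate_myocyte("A", stimulus_protocol(n_prepace = 2))
#' head(tr)
#' }
simulate_myocyte <- function(case = "A", protocol = stimulus_protocol(),
                             params = gpb_parameters(),
                             nhs = nhs_parameters(),
                             init = initial_state(params),
                             lambda = 1, rtol = 1e-7, atol = 1e-10,
                             record_dt = 0.1, keep_states = FALSE,
                             use_compiled = TRUE) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  factors <- as_impact_factors(case)
  validate_state(init)
  pv_on <- ode_parameter_vector(params, factors, nhs,
                                stim_amplitude = protocol$amplitude,
                                lambda = lambda)
  pv_off <- ode_parameter_vector(params, factors, nhs,
                                 stim_amplitude = 0, lambda = lambda)
  y <- init
  for (b in seq_len(protocol$n_prepace)) {
    y <- advance_beat(y, pv_on, pv_off, protocol, rtol, atol, use_compiled)
  }
  diastolic <- y
  rows <- vector("list", protocol$n_record)
  for (b in seq_len(protocol$n_record)) {
    t_on <- seq(0, protocol$duration, by = min(record_dt, protocol$duration))
    if (t_on[length(t_on)] < protocol$duration) {
      t_on <- c(t_on, protocol$duration)
    }
    seg1 <- integrate_segment(y, t_on, pv_on, rtol, atol, use_compiled)
    y1 <- seg1[nrow(seg1), 1 + seq_along(y)]; names(y1) <- names(y)
    t_off <- seq(protocol$duration, protocol$cycle_length, by = record_dt)
    if (t_off[length(t_off)] < protocol$cycle_length) {
      t_off <- c(t_off, protocol$cycle_length)
    }
    seg2 <- integrate_segment(y1, t_off, pv_off, rtol, atol, use_compiled)
    seg <- rbind(seg1[-nrow(seg1), , drop = FALSE], seg2)
    seg[, 1] <- seg[, 1] + (b - 1) * protocol$cycle_length
    rows[[b]] <- if (b < protocol$n_record) {
      seg[-nrow(seg), , drop = FALSE]   # drop duplicated beat boundary
    } else {
      seg
    }
    y <- seg2[nrow(seg2), 1 + seq_along(y)]
    names(y) <- state_registry()$name
  }
  m <- do.call(rbind, rows)
  df <- tibble::as_tibble(as.data.frame(m))
  names(df)[1] <- "time_ms"
  out <- tibble::tibble(
    time_ms = df$time_ms,
    vm_mV = df$vm,
    ca_i_uM = df$ca_i * 1e3,
    tension_kPa = df$tension_kPa
  )
  if (keep_states) {
    out <- dplyr::bind_cols(out, df[state_registry()$name])
  }
  structure(out,
            class = c("myocyte_trace", class(out)),
            case = if (is.character(case)) toupper(case) else "custom",
            factors = factors,
            protocol = protocol,
            lambda = lambda,
            solver = list(method = "lsoda", rtol = rtol, atol = atol,
                          record_dt = record_dt,
                          compiled = use_compiled),
            diastolic_state = diastolic,
            final_state = y)
}

#' Pace a myocyte towards its periodic steady state
#'
#' Applies the pacing protocol beat by beat and returns the end-diastolic
#' state once the beat-to-beat maximum relative state change falls below
#' `tolerance`, or after `protocol$n_prepace` beats (with a warning if the
#' tolerance was not reached; `tolerance = Inf` simply runs the configured
#' beats).
#'
#' @inheritParams simulate_myocyte
#' @param tolerance Convergence threshold on the beat-to-beat maximum
#'   relative state change (componentwise, relative to scale
#'   `max(|state|, 1e-6)`).
#' @return Named end-diastolic state vector, with attributes `beats_run` and
#'   `converged`.
#' @export
paced_to_steady_state <- function(case = "A", protocol = stimulus_protocol(),
                                  tolerance = Inf,
                                  params = gpb_parameters(),
                                  nhs = nhs_parameters(),
                                  init = initial_state(params),
                                  lambda = 1, rtol = 1e-7, atol = 1e-10,
                                  use_compiled = TRUE) {
  stopifnot(inherits(protocol, "stimulus_protocol"), protocol$n_prepace >= 1)
  factors <- as_impact_factors(case)
  pv_on <- ode_parameter_vector(params, factors, nhs,
                                stim_amplitude = protocol$amplitude,
                                lambda = lambda)
  pv_off <- ode_parameter_vector(params, factors, nhs,
                                 stim_amplitude = 0, lambda = lambda)
  y <- init
  converged <- FALSE
  b_done <- 0L
  for (b in seq_len(protocol$n_prepace)) {
    y_new <- advance_beat(y, pv_on, pv_off, protocol, rtol, atol,
                          use_compiled)
    delta <- max(abs(y_new - y) / pmax(abs(y), 1e-6))
    b_done <- b
    y <- y_new
    if (is.finite(tolerance) && delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (is.finite(tolerance) && !converged) {
    warning("beat-to-beat change did not fall below tolerance within ",
            protocol$n_prepace, " beats")
  }
  structure(y, beats_run = b_done, converged = converged)
}
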