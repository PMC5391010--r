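#' Ion-channel remodelling (impact) factors
#'
#' An impact-factor vector holds the 11 dimensionless multipliers that place
#' a myocyte on the healthy-to-failing continuum.  Each factor scales the
#' physiological quantity it is named after: `f_hl` the late-Na inactivation
#' time constant, `f_NaL` the late Na current, `f_Ki` the inward rectifier K
#' current, `f_NaK` the Na/K pump, `f_Nabk`/`f_Cabk` the background Na/Ca
#' currents, `f_ncx` the Na-Ca exchanger, `f_to` the transient outward K
#' current, `f_SRleak` the SR leak flux, `f_SRca` the SERCA uptake flux, and
#' `f_EC50SR` the SR-Ca half-activation of RyR release.  The unit vector is
#' the healthy state.
#'
#' @param f_hl,f_NaL,f_Ki,f_NaK,f_Nabk,f_Cabk,f_ncx,f_to,f_SRleak,f_SRca,f_EC50SR
#'   Non-negative multipliers (default 1 = healthy).
#' @return A named numeric vector of class `impact_factors`.
#' @seealso [factors_for_case()] for the published disease cases.
#' @export
#' @examples
#' impact_factors(f_NaL = 2, f_hl = 2)
impact_factors <- function(f_hl = 1, f_NaL = 1, f_Ki = 1, f_NaK = 1,
                           f_Nabk = 1, f_Cabk = 1, f_ncx = 1, f_to = 1,
                           f_SRleak = 1, f_SRca = 1, f_EC50SR = 1) {
  x <- c(f_hl = f_hl, f_NaL = f_NaL, f_Ki = f_Ki, f_NaK = f_NaK,
         f_Nabk = f_Nabk, f_Cabk = f_Cabk, f_ncx = f_ncx, f_to = f_to,
         f_SRleak = f_SRleak, f_SRca = f_SRca, f_EC50SR = f_EC50SR)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("impact factors must be finite and >= 0", call. = FALSE)
  }
  structure(x, class = c("impact_factors", "numeric"))
}

#' @export
print.impact_factors <- function(x, ...) {
  cat("<impact_factors>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Coerce to an impact-factor vector
#' @param x An `impact_factors` object, a named numeric vector with the 11
#'   factor names, a case label (`"A"`-`"D"`), or a severity fraction.
#' @return An `impact_factors` vector.
#' @export
as_impact_factors <- function(x) {
  if (inherits(x, "impact_factors")) return(x)
  if (is.character(x) && length(x) == 1) return(factors_for_case(x))
  if (is.numeric(x) && length(x) == 1 && is.null(names(x))) {
    return(factors_for_case(x))
  }
  if (is.numeric(x) && length(x) == 11) {
    nm <- names(impact_factors())
    if (is.null(names(x))) names(x) <- nm
    if (!setequal(names(x), nm)) {
      stop("impact-factor names must be ", paste(nm, collapse = ", "),
           call. = FALSE)
    }
    return(do.call(impact_factors, as.list(x[nm])))
  }
  stop("cannot interpret `x` as impact factors", call. = FALSE)
}

# endpoint rows of the disease continuum (healthy A, end-stage failing D)
case_a_factors <- function() impact_factors()
case_d_factors <- function() {
  impact_factors(f_hl = 2, f_NaL = 2, f_Ki = 0.68, f_NaK = 0.5, f_Nabk = 0,
                 f_Cabk = 1.530, f_ncx = 1.75, f_to = 0.4, f_SRleak = 5,
                 f_SRca = 0.5, f_EC50SR = 0.89)
}

#' Impact factors for a disease case or severity fraction
#'
#' The four published cases lie on a straight line in impact-factor space:
#' Case A (healthy, all ones), Case D (end-stage failure), and Cases B and C
#' obtained by moving one-third and two-thirds of the way from A to D.
#' A continuous severity fraction `s` interpolates componentwise,
#' `A + s * (D - A)`, at full precision (the published intermediate rows are
#' this interpolation rounded for display).
#'
#' @param label `"A"`, `"B"`, `"C"`, `"D"` (case-insensitive) or a numeric
#'   severity fraction with 0 = healthy and 1 = end-stage failing.  Values
#'   outside `[0, 1]` extrapolate along the same line, with a warning.
#' @return An `impact_factors` vector.
#' @export
#' @examples
#' factors_for_case("B")
#' factors_for_case(0.5)
factors_for_case <- function(label) {
  if (is.character(label)) {
    lab <- toupper(label)
    if (length(lab) != 1 || !lab %in% c("A", "B", "C", "D")) {
      stop("case label must be one of A, B, C, D", call. = FALSE)
    }
    s <- c(A = 0, B = 1 / 3, C = 2 / 3, D = 1)[[lab]]
  } else if (is.numeric(label) && length(label) == 1 && is.finite(label)) {
    s <- as.numeric(label)
    if (s < 0 || s > 1) {
      warning("severity fraction ", s,
              " lies outside [0, 1]; extrapolating the A-D line")
    }
  } else {
    stop("case label must be a single letter A-D or a severity fraction",
         call. = FALSE)
  }
  a <- unclass(case_a_factors())
  d <- unclass(case_d_factors())
  structure(a + s * (d - a), class = c("impact_factors", "numeric"))
}

#' The published impact-factor table
#'
#' All four disease cases as a tidy table, computed by [factors_for_case()]
#' (Cases B and C are exact interpolants; print with 3-4 significant digits
#' to recover the published rounded values).
#'
#' @return A tibble with columns `case`, `severity`, and the 11 factors.
#' @export
#' @examples
#' impact_factor_table()
impact_factor_table <- function() {
  cases <- c("A", "B", "C", "D")
  rows <- purrr::map(cases, function(cc) {
    f <- factors_for_case(cc)
    tibble::as_tibble(as.list(unclass(f)))
  })
  dplyr::bind_cols(
    tibble::tibble(case = cases, severity = c(0, 1 / 3, 2 / 3, 1)),
    dplyr::bind_rows(rows)
  )
}
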