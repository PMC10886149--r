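#' Kinetic parameters of the glucose-release model
#'
#' Container for the constants of the enzymatic hydrolysis model.  The
#' defaults are the fitted values for glucoamylase acting on DE<=5
#' maltodextrin at 30 degC and pH 7.0 (the conditions of microbial
#' cultivations, far from the enzyme's pH/temperature optimum).
#'
#' @param kS catalytic constant of the susceptible dextrin fraction,
#'   g (U h)^-1.  Must be > 0.
#' @param kR catalytic constant of the resistant fraction, g (U h)^-1.
#'   Must be >= 0; typically ~60-fold smaller than `kS`.
#' @param K shared Michaelis constant, g/L.  At working dextrin
#'   concentrations (tens of g/L) the kinetics are effectively zero order in
#'   substrate, so K is hardly identifiable and fixed at a low value.
#' @param WS0 initial susceptible proportion of the dextrin, g/g in `[0, 1]`.
#' @param nu anhydroglucose-to-glucose conversion factor (hydration mass
#'   gain on hydrolysis), dimensionless, >= 1.  1 g of polymerized glucose
#'   yields 1.111 g of free glucose.
#' @param r_evap evaporation rate, L/h (default 30 uL/h, typical for an
#'   aerated 10 mL mini-bioreactor).
#' @param k_single catalytic constant for the single-substrate variants,
#'   g (U h)^-1.
#' @param KiP product-inhibition constant, g/L (used by `*_pi` variants).
#' @param KiS substrate-inhibition constant, g/L (used by `*_si` variants).
#'
#' @return an object of class `release_parameters` (a named list).
#' @seealso [release_state()], [model_variants()]
#' @export
#' @examples
#' release_parameters()
#' release_parameters(kS = 0.076)  # value recalibrated under cultivation aeration
release_parameters <- function(kS = 0.134, kR = 0.00212, K = 0.001,
                               WS0 = 0.464, nu = 1.111, r_evap = 3.0e-5,
                               k_single = 0.134, KiP = Inf, KiS = Inf) {
  p <- list(kS = kS, kR = kR, K = K, WS0 = WS0, nu = nu, r_evap = r_evap,
            k_single = k_single, KiP = KiP, KiS = KiS)
  validate_release_parameters(p)
  structure(p, class = "release_parameters")
}

validate_release_parameters <- function(p) {
  stopifnot(
    p$kS > 0, p$kR >= 0, p$K > 0,
    p$WS0 >= 0, p$WS0 <= 1,
    p$nu >= 1, p$r_evap >= 0,
    p$k_single > 0, p$KiP > 0, p$KiS > 0
  )
  invisible(p)
}

#' @export
print.release_parameters <- function(x, ...) {
  cat("Glucose-release model parameters\n")
  cat(sprintf("  kS  = %g g/(U h)   kR = %g g/(U h)   K = %g g/L\n",
              x$kS, x$kR, x$K))
  cat(sprintf("  WS0 = %g g/g       nu = %g           r_evap = %g L/h\n",
              x$WS0, x$nu, x$r_evap))
  cat(sprintf("  k_single = %g g/(U h)   KiP = %g g/L   KiS = %g g/L\n",
              x$k_single, x$KiP, x$KiS))
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named entries replaced, re-validated.
#'
#' @param params a [release_parameters()] object.
#' @param ... named scalar replacements, e.g. `kS = 0.1`.
#' @return a `release_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  repl <- list(...)
  stopifnot(all(names(repl) %in% names(params)))
  params[names(repl)] <- repl
  validate_release_parameters(params)
  structure(params, class = "release_parameters")
}
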