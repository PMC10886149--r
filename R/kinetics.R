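#' Hydrolysis rates of the two dextrin fractions
#'
#' Michaelis-Menten release rates of the susceptible (`rS`) and resistant
#' (`rR`) dextrin pools.  Both pools compete for the same enzyme and share a
#' single Michaelis constant K, so the denominator contains the total
#' substrate:
#' \deqn{r_S = k_S E \, SS / (SS + SR + K), \quad
#'       r_R = k_R E \, SR / (SS + SR + K).}
#'
#' @param state a [release_state()].
#' @param params a [release_parameters()].
#' @return named numeric vector `c(rS = , rR = )`, g/(L h), both >= 0.
#' @export
#' @examples
#' s <- release_state(S = 40, WS = 0.464, E = 10, V = 0.011)
#' release_rates(s, release_parameters())
release_rates <- function(state, params) {
  validate_release_state(state)
  validate_release_parameters(params)
  SS <- susceptible_substrate(state)
  SR <- resistant_substrate(state)
  denom <- SS + SR + params$K
  c(rS = params$kS * state$E * SS / denom,
    rR = params$kR * state$E * SR / denom)
}

#' Total pre-conversion release rate of a kinetic variant
#'
#' Evaluates the summed hydrolysis rate (before the anhydroglucose
#' conversion factor) for any of the seven kinetic variants.  Product
#' inhibition replaces K by `K * (1 + P/KiP)` (competitive form); substrate
#' inhibition adds `S^2/KiS` to the denominator.
#'
#' @inheritParams release_rates
#' @param variant a tag from [model_variants()].
#' @return scalar rate, g/(L h).
#' @export
variant_rate <- function(state, params, variant = "two_substrate") {
  validate_release_state(state)
  validate_release_parameters(params)
  variant <- match.arg(variant, model_variants())
  if (variant_has_pi(variant) && !is.finite(params$KiP))
    stop("variant '", variant, "' requires a finite KiP")
  if (variant_has_si(variant) && !is.finite(params$KiS))
    stop("variant '", variant, "' requires a finite KiS")

  S <- state$S
  Keff <- if (variant_has_pi(variant)) params$K * (1 + state$P / params$KiP) else params$K
  denom <- S + Keff + if (variant_has_si(variant)) S^2 / params$KiS else 0

  if (variant_is_two_substrate(variant)) {
    SS <- susceptible_substrate(state)
    SR <- resistant_substrate(state)
    params$kS * state$E * SS / denom + params$kR * state$E * SR / denom
  } else {
    params$k_single * state$E * S / denom
  }
}

# zero-substrate threshold below which dWS/dt is defined as 0
.ws_eps <- 1e-12

#' Right-hand side of the release ODE system
#'
#' Time derivatives of (P, S, WS, E, V).  For the two-substrate variants the
#' susceptible-proportion dynamics follow from the quotient rule applied to
#' WS = SS/S; for single-substrate variants WS is constant.  Evaporation
#' removes water only, so all concentrations carry the dilution term
#' `-(dV/dt)/V * C`.
#'
#' This reference implementation in R defines the model; the simulator uses
#' an equivalent compiled version for speed (see [simulate_release()]).
#'
#' @inheritParams variant_rate
#' @return named numeric vector of derivatives
#'   `c(dP = , dS = , dWS = , dE = , dV = )`.
#' @export
#' @examples
#' s <- release_state(S = 40, WS = 0.464, E = 10, V = 0.011)
#' release_rhs(s, release_parameters())
release_rhs <- function(state, params, variant = "two_substrate") {
  variant <- match.arg(variant, model_variants())
  validate_release_state(state)
  validate_release_parameters(params)

  dV <- -params$r_evap
  dil <- dV / state$V

  if (variant_is_two_substrate(variant)) {
    Keff <- if (variant_has_pi(variant)) params$K * (1 + state$P / params$KiP) else params$K
    denom <- state$S + Keff +
      if (variant_has_si(variant)) state$S^2 / params$KiS else 0
    SS <- susceptible_substrate(state)
    SR <- resistant_substrate(state)
    rS <- params$kS * state$E * SS / denom
    rR <- params$kR * state$E * SR / denom
    R <- rS + rR
    dWS <- if (state$S > .ws_eps) (-rS + state$WS * R) / state$S else 0
  } else {
    R <- variant_rate(state, params, variant)
    dWS <- 0
  }

  c(dP = params$nu * R - dil * state$P,
    dS = -R - dil * state$S,
    dWS = dWS,
    dE = -dil * state$E,
    dV = dV)
}

#' Maximum glucose obtainable from a dextrin concentration
#'
#' Complete hydrolysis of D g/L dextrin yields `nu * D` g/L free glucose:
#' each anhydroglucose unit gains one water molecule on cleavage
#' (conversion factor 1.111 for glucans).
#'
#' @param D dextrin concentration, g/L (>= 0); vectorized.
#' @param params a [release_parameters()]; only `nu` is used.
#' @return glucose-equivalent yield, g/L.
#' @export
#' @examples
#' max_release(c(15, 37.5))  # ~16.6 and ~41.7 g/L
max_release <- function(D, params = release_parameters()) {
  if (any(D < 0)) stop("dextrin concentration must be >= 0")
  params$nu * D
}
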