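#' Kinetic model variants
#'
#' The hydrolysis of dextrin by glucoamylase can be described by a family of
#' Michaelis-Menten (MM) type models: a single lumped substrate pool or two
#' pools (a susceptible fraction hydrolysed quickly and a resistant fraction
#' hydrolysed slowly), optionally extended with product inhibition by free
#' glucose and/or substrate inhibition at high dextrin concentrations.
#'
#' Variant tags, in canonical order:
#' \describe{
#'   \item{`simple_mm`}{single substrate, plain MM kinetics (`k_single`).}
#'   \item{`simple_mm_pi`}{single substrate with competitive product
#'     inhibition: the Michaelis constant K is replaced by
#'     `K * (1 + P / KiP)`.}
#'   \item{`simple_mm_si`}{single substrate with substrate inhibition:
#'     `S^2 / KiS` is added to the rate denominator.}
#'   \item{`simple_mm_pi_si`}{both inhibition terms.}
#'   \item{`two_substrate`}{two fractions with catalytic constants `kS`
#'     (susceptible) and `kR` (resistant) sharing one K.}
#'   \item{`two_substrate_pi`}{two fractions with product inhibition.}
#'   \item{`two_substrate_pi_si`}{two fractions with product and substrate
#'     inhibition.}
#' }
#'
#' @return `model_variants()` returns the character vector of the seven
#'   variant tags in canonical order.
#' @seealso [variant_rate()], [release_rhs()]
#' @export
#' @examples
#' model_variants()
model_variants <- function() {
  c("simple_mm", "simple_mm_pi", "simple_mm_si", "simple_mm_pi_si",
    "two_substrate", "two_substrate_pi", "two_substrate_pi_si")
}

#' @rdname model_variants
#' @param variant a variant tag, one of `model_variants()`.
#' @return `variant_code()` returns the integer code (1-7) used by the
#'   compiled right-hand side; `variant_label()` a human-readable label used
#'   in comparison tables.
#' @export
variant_code <- function(variant) {
  code <- match(match.arg(variant, model_variants()), model_variants())
  code
}

#' @rdname model_variants
#' @export
variant_label <- function(variant) {
  labels <- c(
    simple_mm           = "Simple MM",
    simple_mm_pi        = "Simple MM with product inhibition",
    simple_mm_si        = "Simple MM with substrate inhibition",
    simple_mm_pi_si     = "Simple MM with product and substrate inhibition",
    two_substrate       = "MM considering two substrates",
    two_substrate_pi    = "MM considering two substrates with product inhibition",
    two_substrate_pi_si = "MM considering two substrates with product and substrate inhibition"
  )
  unname(labels[match.arg(variant, model_variants())])
}

variant_is_two_substrate <- function(variant) {
  variant_code(variant) >= 5L
}

variant_has_pi <- function(variant) {
  variant_code(variant) %in% c(2L, 4L, 6L, 7L)
}

variant_has_si <- function(variant) {
  variant_code(variant) %in% c(3L, 4L, 7L)
}

#' Free parameters of a kinetic variant
#'
#' Names of the parameters that are estimated when fitting the given variant
#' (the Michaelis constant K is fixed by default; see [fit_global()]).
#'
#' @inheritParams variant_code
#' @return character vector of parameter names.
#' @export
variant_free_parameters <- function(variant) {
  variant <- match.arg(variant, model_variants())
  free <- if (variant_is_two_substrate(variant)) c("kS", "kR", "WS0") else "k_single"
  if (variant_has_pi(variant)) free <- c(free, "KiP")
  if (variant_has_si(variant)) free <- c(free, "KiS")
  free
}
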