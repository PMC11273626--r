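#' Oral absorption parameters from intestinal permeability
#'
#' Passive intestinal absorption is parameterised by an effective
#' permeability `Peff`, the small-intestinal radius `R` and the
#' small-intestinal transit time `Tsi`:
#' absorption rate constant `ka = 2 * Peff / R` and fraction absorbed
#' `Fa = 1 - exp(-ka * Tsi)`.  Species defaults: `R` = 0.18 cm (rat) and
#' 1 cm (human); `Tsi` = 1.47 h (rat) and 3.32 h (human).  With the
#' calibrated human permeability these give ka = 0.21 (rat) and 0.14
#' (human) 1/h and Fa = 0.26 (rat) and 0.36 (human); the shipped compound
#' parameter sets pin these rounded values, so the PBK model does not
#' depend on the permeability correlation.
#'
#' @name absorption
NULL

#' Human effective permeability from a Caco-2 apparent permeability
#'
#' Log-linear in-vitro-to-in-vivo correlation
#' `log10(Peff) = a * log10(Papp) + b`.  The correlation coefficients are
#' configuration: the default intercept is calibrated such that the
#' downstream human `ka` (radius 1 cm) reproduces 0.14 1/h, i.e.
#' `Peff_human` about 1.9e-5 cm/s, because the published value and units
#' of the apparent-permeability input are ambiguous.
#'
#' @param log_papp log10 apparent permeability of the Caco-2 assay.
#' @param a,b correlation slope and intercept on the log10 scale.
#' @return effective permeability in cm/s.
#' @export
papp_to_peff_human <- function(log_papp, a = 1,
                               b = log10(1.9444e-05) - 1 * (-0.233)) {
  stopifnot(is.finite(log_papp))
  10^(a * log_papp + b)
}

#' Interspecies scaling of effective permeability
#'
#' `Peff_rat = Peff_human / factor`; the default factor 3.6 is the
#' conventional human-to-rat permeability ratio.
#'
#' @param peff_human effective permeability (any consistent unit).
#' @param factor positive dimensionless divisor.
#' @return rat effective permeability in the same unit.
#' @export
peff_interspecies <- function(peff_human, factor = 3.6) {
  if (factor <= 0) stop("interspecies factor must be > 0")
  peff_human / factor
}

#' Absorption rate constant from effective permeability
#'
#' `ka = 2 * Peff / R` for a cylindrical small intestine of radius `R`.
#'
#' @param peff effective permeability in cm/h.
#' @param R small-intestinal radius in cm (> 0).
#' @return ka in 1/h.
#' @export
compute_ka <- function(peff, R) {
  if (R <= 0) stop("intestinal radius must be > 0")
  2 * peff / R
}

#' Fraction of the oral dose absorbed
#'
#' `Fa = 1 - exp(-ka * Tsi)`: first-order uptake over one small-intestinal
#' transit.
#'
#' @param ka absorption rate constant in 1/h (>= 0).
#' @param Tsi small-intestinal transit time in h (>= 0).
#' @return fraction in `[0, 1)`.
#' @export
compute_fa <- function(ka, Tsi) {
  if (ka < 0 || Tsi < 0) stop("ka and Tsi must be >= 0")
  1 - exp(-ka * Tsi)
}

#' Derive the full oral absorption parameter set for both species
#'
#' Chains [papp_to_peff_human()], [peff_interspecies()], [compute_ka()] and
#' [compute_fa()] with the species geometry defaults.
#'
#' @param log_papp log10 Caco-2 apparent permeability (default -0.233, the
#'   QSAR-predicted value whose absolute units are absorbed into the
#'   calibrated correlation intercept of [papp_to_peff_human()]).
#' @param interspecies_factor human-to-rat permeability divisor.
#' @return list with per-species `peff` (cm/h), `ka` (1/h), `fa`, and the
#'   geometry used.
#' @export
absorption_params <- function(log_papp = -0.233, interspecies_factor = 3.6) {
  peff_h_cms <- papp_to_peff_human(log_papp)
  peff_h <- peff_h_cms * 3600              # cm/s -> cm/h
  peff_r <- peff_interspecies(peff_h, interspecies_factor)
  geom <- list(rat = list(R = 0.18, Tsi = 1.47),
               human = list(R = 1, Tsi = 3.32))
  ka_r <- compute_ka(peff_r, geom$rat$R)
  ka_h <- compute_ka(peff_h, geom$human$R)
  list(
    rat = list(peff = peff_r, R = geom$rat$R, Tsi = geom$rat$Tsi,
               ka = ka_r, fa = compute_fa(ka_r, geom$rat$Tsi)),
    human = list(peff = peff_h, R = geom$human$R, Tsi = geom$human$Tsi,
                 ka = ka_h, fa = compute_fa(ka_h, geom$human$Tsi)),
    interspecies_factor = interspecies_factor)
}
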