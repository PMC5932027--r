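#' Physical constants used throughout the package
#'
#' Returns the table of physical constants (CODATA 2018) in the CGS-Gaussian
#' units used internally by the magnetometry and EPR layers, together with a
#' few derived conversion factors.  All magnetometry arithmetic is CGS
#' (emu, gauss, erg) because the Langevin model and the saturation
#' magnetizations quoted for magnetite/maghemite and ferrihydrite are
#' conventionally CGS; SI values are accepted at the boundaries.
#'
#' @return A named list:
#' \describe{
#'   \item{mu_B}{Bohr magneton, erg/G.}
#'   \item{k_B}{Boltzmann constant, erg/K.}
#'   \item{h}{Planck constant, erg s.}
#'   \item{ghz_per_mt}{Zeeman factor \eqn{\mu_B/h} expressed in GHz per mT
#'     per unit g: the energy (GHz) of one Bohr magneton in a 1 mT field.}
#'   \item{x_coef}{\eqn{\mu_B/k_B} in 1/(G K): the Langevin argument is
#'     \code{x = mu_p * H * x_coef / T} with \code{mu_p} in Bohr magnetons,
#'     \code{H} in gauss and \code{T} in kelvin (dimensionless by
#'     construction).}
#'   \item{kelvin_per_ghz}{\eqn{h/k_B} scaled to K per GHz, for Boltzmann
#'     populations of spin levels whose energies are kept in GHz.}
#'   \item{fe_molar_mass}{Molar mass of iron, g/mol.}
#'   \item{ferritin_capacity}{Maximum number of iron atoms a ferritin core
#'     accommodates (4500).}
#'   \item{fe3_ion_moment}{Ionic magnetic moment of high-spin Fe(III),
#'     Bohr magnetons (5.92).}
#' }
#' @export
#' @examples
#' iron_constants()$fe_molar_mass
iron_constants <- function() {
  mu_B <- 9.2740100783e-21   # erg/G
  k_B  <- 1.380649e-16       # erg/K
  h    <- 6.62607015e-27     # erg s
  list(
    mu_B = mu_B,
    k_B = k_B,
    h = h,
    ghz_per_mt = mu_B / h * 1e-9 * 10,   # Hz/G -> GHz/mT (1 mT = 10 G)
    x_coef = mu_B / k_B,
    kelvin_per_ghz = h / k_B * 1e9,
    fe_molar_mass = 55.845,
    ferritin_capacity = 4500,
    fe3_ion_moment = 5.92
  )
}

#' Convert a tissue iron mass concentration to molarity
#'
#' Converts micrograms of iron per gram of (wet) tissue to micromolar,
#' assuming a tissue density (default 1.0 g/mL, the value implied by the
#' usual wet-tissue conversions).
#'
#' @param conc_ug_g Iron concentration, ug per g of tissue (non-negative).
#' @param density Tissue density in g/mL.
#' @return Concentration in uM.
#' @export
#' @examples
#' mass_to_molar(14.95)  # ~267.7 uM
mass_to_molar <- function(conc_ug_g, density = 1.0) {
  if (any(conc_ug_g < 0)) stop("concentration must be non-negative")
  if (density <= 0) stop("density must be positive")
  # ug/g * g/mL = ug/mL; / (g/mol) = umol/mL -> *1000 = umol/L
  conc_ug_g * density / iron_constants()$fe_molar_mass * 1000
}
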