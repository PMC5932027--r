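## Raw-signal synthesis for ground-truth panels: every downstream fitting
## stage gets a parameter-recovery surface that is exact at zero noise.

#' Add Rician noise to a magnitude signal
#'
#' Magnitude-detector noise model: \code{sqrt((s + n1)^2 + n2^2)} with
#' independent Gaussian \code{n1, n2} of standard deviation \code{sd}.
#' At \code{sd = 0} the signal is returned unchanged.
#'
#' @param s Noiseless magnitude signal (vector or array).
#' @param sd Gaussian channel noise standard deviation (>= 0).
#' @return Noisy magnitude, same shape as \code{s}.
#' @export
rician_noise <- function(s, sd) {
  if (sd < 0) stop("noise sd must be non-negative")
  if (sd == 0) return(s)
  n <- length(s)
  out <- sqrt((s + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
  if (!is.null(dim(s))) dim(out) <- dim(s)
  out
}

#' Synthesize a multi-echo magnitude stack for one subject
#'
#' Every voxel decays as \code{A exp(-TE * R2*)} with the subject's true
#' rate; Rician noise of standard deviation \code{noise_frac * A} is then
#' applied (an SNR of 20 corresponds to \code{noise_frac = 0.05}).
#'
#' @param r2star True decay rate, ms^-1.
#' @param te_ms Echo times, ms, strictly increasing (acquisition default
#'   12.5, 23.3, 33.9, 44.6 ms).
#' @param noise_frac Rician channel noise as a fraction of \code{A}.
#' @param shape Spatial voxel grid dimensions.
#' @param A Prefactor (first-echo-extrapolated magnitude).
#' @return A [multi_echo_stack()].
#' @export
synthesize_echo_stack <- function(r2star, te_ms = c(12.5, 23.3, 33.9, 44.6),
                                  noise_frac = 0, shape = c(12, 12),
                                  A = 1000) {
  if (noise_frac < 0) stop("noise fraction must be non-negative")
  if (is.unsorted(te_ms, strictly = TRUE))
    stop("echo times must be strictly increasing")
  decay <- A * exp(-te_ms * r2star)
  data <- array(rep(decay, each = prod(shape)), c(shape, length(te_ms)))
  multi_echo_stack(rician_noise(data, noise_frac * A), te_ms)
}

#' Synthesize an IRM curve for one subject
#'
#' Evaluates the Langevin remanence model at the requested fields using
#' the temperature-appropriate mineral: at 100 K the magnetite/maghemite
#' channel (\code{Ms = 84 emu/g}, mass fraction from the panel's
#' concentration in ng/g, moment \code{magnetite_moment}); at 5 K the
#' ferrihydrite channel (\code{Ms = 0.62 emu/g}, fraction from ug/g,
#' moment \code{ferritin_moment}).  Gaussian noise (lock-in/flux
#' detection) is added in emu/g.
#'
#' @param panel One-row data.frame (a [generate_cohort()] row).
#' @param temperature_K 100 or 5.
#' @param fields_G Field grid, gauss; default 30 log-spaced steps over
#'   the low-field range 10 G - 2.5 T.
#' @param noise_sd Gaussian noise standard deviation, emu/g.
#' @param dry_mass_g Dry sample mass, g.
#' @param b_offset Residual-field background constant, emu/g.
#' @param noise_floor_emu Instrument noise floor, emu.
#' @return An [irm_curve()].
#' @export
synthesize_irm <- function(panel, temperature_K,
                           fields_G = exp(seq(log(10), log(25000),
                                              length.out = 30)),
                           noise_sd = 0, dry_mass_g = 0.05,
                           b_offset = 1e-6, noise_floor_emu = 1e-8) {
  if (noise_sd < 0) stop("noise sd must be non-negative")
  pars <- irm_true_parameters(panel, temperature_K)
  m <- irm_model(fields_G, pars$Ms, pars$f, pars$mu_p, b_offset,
                 temperature_K)
  if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
  irm_curve(fields_G, m, temperature_K, dry_mass_g, noise_floor_emu)
}

#' @rdname synthesize_irm
#' @export
irm_true_parameters <- function(panel, temperature_K) {
  if (temperature_K == 100) {
    list(Ms = 84, f = panel$magnetite * 1e-9, mu_p = panel$magnetite_moment)
  } else if (temperature_K == 5) {
    list(Ms = 0.62, f = panel$ferrihydrite * 1e-6,
         mu_p = panel$ferritin_moment)
  } else {
    stop("temperature must be 100 K (magnetite) or 5 K (ferrihydrite)")
  }
}

#' Synthesize an EPR spectrum for one subject
#'
#' Scales a fixed-parameter simulated template so that the expected double
#' integral equals \code{calibration * Fe(III) * mass} (the same
#' proportionality the reference sample obeys, so quantification
#' round-trips exactly at zero noise), then adds Gaussian amplitude noise.
#'
#' @param panel One-row data.frame with column \code{fe3} (ug/g wet).
#' @param template Unit-amplitude template from
#'   [simulate_epr_spectrum()].
#' @param noise_sd Gaussian noise standard deviation, in amplitude units.
#' @param sample_mass_g Wet tissue mass, g.
#' @param calibration Double integral per (ug/g x g) of Fe(III); the same
#'   constant must be used for the reference record.
#' @return An [epr_spectrum()] with \code{sample_mass_g} set.
#' @export
synthesize_epr_spectrum <- function(panel, template, noise_sd = 0,
                                    sample_mass_g = 0.015, calibration = 1) {
  if (noise_sd < 0) stop("noise sd must be non-negative")
  ti <- double_integral(template)
  scale <- calibration * panel$fe3 * sample_mass_g / ti
  amp <- scale * template$amplitude
  if (noise_sd > 0) amp <- amp + stats::rnorm(length(amp), 0, noise_sd)
  epr_spectrum(template$field_mT, amp, template$frequency_GHz,
               temperature_K = template$temperature_K,
               sample_mass_g = sample_mass_g)
}

#' Reference record matched to the synthetic calibration
#'
#' Builds the [epr_reference()] whose double integral obeys the same
#' calibration constant used by [synthesize_epr_spectrum()].
#'
#' @param calibration Double integral per (ug/g x g) of Fe(III).
#' @param concentration_ug_g,mass_g Reference concentration and mass.
#' @param temperature_K Reference measurement temperature, K.
#' @return An [epr_reference()].
#' @export
synthetic_epr_reference <- function(calibration = 1,
                                    concentration_ug_g = 2.79,
                                    mass_g = 0.015, temperature_K = 12) {
  epr_reference(concentration_ug_g, mass_g,
                calibration * concentration_ug_g * mass_g,
                temperature_K = temperature_K)
}
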