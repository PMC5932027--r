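## Two-column text formats with JSON sidecars for spectroscopy and
## magnetometry curves.  The sidecar lives next to the data file with
## extension .json.

.sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Write / read an EPR spectrum as CSV plus JSON sidecar
#'
#' The CSV holds two columns (\code{field_mT}, \code{amplitude}); the
#' sidecar carries frequency (GHz), temperature (K), modulation (G
#' peak-to-peak) and sample mass (g).  Native Bruker formats are out of
#' scope; convert to two-column text first.
#'
#' @param spectrum An [epr_spectrum()].
#' @param path CSV path.
#' @return \code{write_epr_csv} returns \code{path} invisibly;
#'   \code{read_epr_csv} an [epr_spectrum()].
#' @export
write_epr_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(field_mT = spectrum$field_mT,
                              amplitude = spectrum$amplitude),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(frequency_GHz = spectrum$frequency_GHz,
         temperature_K = spectrum$temperature_K,
         modulation_Gpp = spectrum$modulation_Gpp,
         sample_mass_g = spectrum$sample_mass_g),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epr_csv
#' @export
read_epr_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  epr_spectrum(d[[1]], d[[2]], meta$frequency_GHz,
               temperature_K = meta$temperature_K,
               modulation_Gpp = meta$modulation_Gpp,
               sample_mass_g = if (is.null(meta$sample_mass_g)) NA_real_
                               else meta$sample_mass_g)
}

#' Write / read an IRM curve as CSV plus JSON sidecar
#'
#' Two columns (\code{field_G}, \code{moment_emu_g}); the sidecar carries
#' temperature (K), dry mass (g) and the instrument noise floor (emu).
#'
#' @param curve An [irm_curve()].
#' @param path CSV path.
#' @return \code{write_irm_csv} returns \code{path} invisibly;
#'   \code{read_irm_csv} an [irm_curve()].
#' @export
write_irm_csv <- function(curve, path) {
  utils::write.csv(data.frame(field_G = curve$field_G,
                              moment_emu_g = curve$moment_emu_g),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(temperature_K = curve$temperature_K,
         dry_mass_g = curve$dry_mass_g,
         noise_floor_emu = curve$noise_floor_emu),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_irm_csv
#' @export
read_irm_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  irm_curve(d[[1]], d[[2]], meta$temperature_K, meta$dry_mass_g,
            meta$noise_floor_emu)
}
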