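#' Simulation configuration
#'
#' Holds the acquisition constants shared by all synthetic-data generators:
#' the RNG seed, pixel sizes for confocal line profiles (µm) and EM sections
#' (nm), the serial-section thickness, and the global noise model. A fixed
#' config yields byte-identical outputs from every generator.
#'
#' Confocal pixel size defaults to 0.05 µm/px (a typical 60x/1.4 NA
#' acquisition; the original acquisitions do not state one, so it is an
#' explicit configuration choice). EM pixel size defaults to 4 nm/px and the
#' section thickness to the 60 nm of the serial-sectioning protocol.
#'
#' @param seed Integer RNG seed.
#' @param pixel_size_um Confocal pixel size, µm/px (> 0).
#' @param pixel_size_nm EM pixel size, nm/px (> 0).
#' @param section_thickness_nm Axial spacing of serial sections, nm (> 0).
#' @param noise_sd Additive Gaussian noise SD, intensity units (>= 0).
#' @param background_level Baseline intensity added to all synthetic images
#'   and profiles.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 42)
#' @export
sim_config <- function(seed = 1L, pixel_size_um = 0.05, pixel_size_nm = 4,
                       section_thickness_nm = 60, noise_sd = 8,
                       background_level = 20) {
  stopifnot(
    is.numeric(seed), length(seed) == 1, is.finite(seed),
    pixel_size_um > 0, pixel_size_nm > 0, section_thickness_nm > 0,
    noise_sd >= 0, background_level >= 0
  )
  structure(
    list(
      seed = as.integer(seed),
      pixel_size_um = pixel_size_um,
      pixel_size_nm = pixel_size_nm,
      section_thickness_nm = section_thickness_nm,
      noise_sd = noise_sd,
      background_level = background_level
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> seed %d | %.3g um/px confocal | %.3g nm/px EM | ",
           "%g nm sections | noise sd %.3g | background %.3g\n"),
    x$seed, x$pixel_size_um, x$pixel_size_nm, x$section_thickness_nm,
    x$noise_sd, x$background_level
  ))
  invisible(x)
}
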