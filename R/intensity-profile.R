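#' Construct an intensity line profile
#'
#' An `intensity_profile` is a tibble with one row per sample along a line
#' drawn on a microscopy image (for example a 12 µm line from the nuclear
#' envelope to the periphery of an epidermal cell, or a 45 µm line along a
#' motor axon). It carries the physical pixel size, the background level used
#' for gap detection, and a free-text label as attributes, so it can flow
#' through dplyr pipelines while staying self-describing.
#'
#' @param intensity Numeric vector of intensities, finite and non-negative
#'   (nominally on a 0--255 scale for 8-bit sources).
#' @param pixel_size_um Distance between consecutive samples, in µm. Must be
#'   strictly positive.
#' @param background Scalar background intensity (mean of an off-structure
#'   region), used by [detect_gaps()]. Default 0.
#' @param label Free-text label (channel, genotype, region).
#' @param position_um Optional explicit positions in µm; must be uniformly
#'   spaced. Defaults to `(seq_along(intensity) - 1) * pixel_size_um`, i.e.
#'   the first sample sits at 0.
#'
#' @return A tibble of class `intensity_profile` with columns `position_um`
#'   and `intensity`, and attributes `pixel_size_um`, `background`, `label`.
#' @examples
#' p <- intensity_profile(c(10, 20, 30), pixel_size_um = 0.1)
#' mean_intensity(p)
#' @export
intensity_profile <- function(intensity, pixel_size_um, background = 0,
                              label = "", position_um = NULL) {
  intensity <- as.numeric(intensity)
  if (length(intensity) < 2) {
    stop("an intensity profile needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  if (is.null(position_um)) {
    position_um <- (seq_along(intensity) - 1) * pixel_size_um
  } else {
    position_um <- as.numeric(position_um)
    if (length(position_um) != length(intensity)) {
      stop("`position_um` and `intensity` lengths differ", call. = FALSE)
    }
    d <- diff(position_um)
    if (any(d <= 0) || diff(range(d)) > 1e-9) {
      stop("positions must be strictly increasing with uniform spacing",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(position_um = position_um, intensity = intensity)
  attr(out, "pixel_size_um") <- pixel_size_um
  attr(out, "background") <- background
  attr(out, "label") <- label
  class(out) <- c("intensity_profile", class(out))
  out
}

#' @export
print.intensity_profile <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "<intensity_profile> %d px, %.3g um/px, length %.4g um%s\n",
    n, attr(x, "pixel_size_um"), n * attr(x, "pixel_size_um"),
    if (nzchar(attr(x, "label"))) paste0(", '", attr(x, "label"), "'") else ""
  ))
  NextMethod()
}

pixel_size <- function(profile) attr(profile, "pixel_size_um")

as_profile_intensity <- function(profile) {
  if (inherits(profile, "intensity_profile") || is.data.frame(profile)) {
    as.numeric(profile$intensity)
  } else {
    as.numeric(profile)
  }
}

#' Flag saturated profiles
#'
#' Images containing saturated pixels are unanalyzable for intensity
#' statistics and are flagged (not dropped) so the analyst can exclude them.
#'
#' @param profile An [intensity_profile()].
#' @param scale_max Saturation value of the acquisition scale (default 255).
#' @return Logical: `TRUE` if any sample equals `scale_max`.
#' @export
is_saturated <- function(profile, scale_max = 255) {
  any(as_profile_intensity(profile) >= scale_max)
}
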