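# Gaussian smoothing with reflective padding; sum-preserving by rescale.
smooth_gaussian <- function(x, sigma_px) {
  if (!is.finite(sigma_px)) {
    # infinite smoothing limit: everything collapses to the mean
    return(rep(mean(x), length(x)))
  }
  if (sigma_px <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_px))
  kx <- (-half):half
  kern <- exp(-kx^2 / (2 * sigma_px^2))
  kern <- kern / sum(kern)
  n <- length(x)
  pad_l <- x[pmin(n, pmax(1, half:1 + 1))]      # reflect at start
  pad_r <- x[pmax(1, pmin(n, n - (1:half)))]     # reflect at end
  xp <- c(pad_l, x, pad_r)
  sm <- stats::convolve(xp, rev(kern), type = "filter")
  if (sum(sm) > 0) sm <- sm * (sum(x) / sum(sm))
  sm
}

#' Simulate an epidermal-cell ER line profile
#'
#' Generates the intensity along a line drawn from the nuclear envelope to
#' the cell periphery of a larval epidermal cell with ER-lumen (KDEL-type)
#' labeling. In `"reticular"` mode the line crosses discrete ER tubules,
#' modeled as randomly placed Gaussian peaks on a baseline; in `"diffuse"`
#' mode (ER network disorganized, as on loss of curvature-stabilizing
#' proteins) the same integrated intensity is redistributed by heavy
#' smoothing, so overall label level is preserved while local fluctuation is
#' suppressed.
#'
#' @param mode `"reticular"` or `"diffuse"`.
#' @param length_um Line length in µm (>= 12; the standard measurement line
#'   is 12 µm).
#' @param config A [sim_config()].
#' @param peak_density_per_um Mean number of tubule crossings per µm
#'   (default 1).
#' @param peak_amplitude Peak height above baseline, intensity units
#'   (default 80).
#' @param peak_sigma_um Width (Gaussian SD) of a tubule crossing, µm
#'   (default 0.15).
#' @param smooth_um Smoothing SD applied in diffuse mode, µm (default 3;
#'   `Inf` gives a perfectly flat profile before noise).
#' @return An [intensity_profile()]; attribute `truth` holds the ground-truth
#'   peak positions (µm) and the noiseless profile.
#' @export
gen_epidermal_profile <- function(mode = c("reticular", "diffuse"),
                                  length_um = 12, config = sim_config(),
                                  peak_density_per_um = 1,
                                  peak_amplitude = 80,
                                  peak_sigma_um = 0.15,
                                  smooth_um = 3) {
  mode <- match.arg(mode)
  psz <- config$pixel_size_um
  if (!is.finite(length_um) || length_um < 12) {
    stop("`length_um` must be >= 12 um", call. = FALSE)
  }
  n <- max(2L, as.integer(round(length_um / psz)))
  pos <- (seq_len(n) - 1) * psz
  with_seed(config$seed, {
    n_peaks <- stats::rpois(1, peak_density_per_um * length_um)
    centers <- sort(stats::runif(n_peaks, 0, length_um))
    signal <- rep(config$background_level, n)
    for (ctr in centers) {
      signal <- signal + peak_amplitude * exp(-(pos - ctr)^2 /
                                                (2 * peak_sigma_um^2))
    }
    if (mode == "diffuse") {
      signal <- smooth_gaussian(signal, smooth_um / psz)
    }
    noisy <- pmax(0, signal + stats::rnorm(n, 0, config$noise_sd))
    out <- intensity_profile(noisy, pixel_size_um = psz,
                             background = config$background_level,
                             label = paste0("epidermal_", mode))
    attr(out, "truth") <- list(peak_centers_um = centers, noiseless = signal)
    out
  })
}

#' Simulate an axonal ER line profile with gaps
#'
#' Generates the intensity of an ER label along a stretch of motor axon
#' (typically 45 µm across the mid-larval segments), with optional gaps --
#' intervals where the ER label is absent and only background remains.
#'
#' @param length_um Profile length, µm (> 0).
#' @param gap_spec List of `c(start_um, end_um)` gap intervals, within
#'   `[0, length_um]` and pairwise non-overlapping. A pixel at position `p`
#'   is inside a gap when `start <= p < end`.
#' @param amplitude Label intensity above background outside gaps.
#' @param config A [sim_config()].
#' @return An [intensity_profile()] with background set from the config;
#'   attribute `truth` holds the logical gap mask and the noiseless profile.
#' @examples
#' cfg <- sim_config(seed = 7, noise_sd = 0)
#' p <- gen_axon_profile(45, list(c(18, 27)), amplitude = 120, config = cfg)
#' gap_percent(p) # 20
#' @export
gen_axon_profile <- function(length_um = 45, gap_spec = list(),
                             amplitude = 120, config = sim_config()) {
  psz <- config$pixel_size_um
  if (!is.finite(length_um) || length_um <= 0) {
    stop("`length_um` must be positive", call. = FALSE)
  }
  if (length(gap_spec)) {
    iv <- do.call(rbind, lapply(gap_spec, function(g) {
      if (length(g) != 2 || g[1] >= g[2]) {
        stop("each gap must be c(start_um, end_um) with start < end",
             call. = FALSE)
      }
      g
    }))
    if (any(iv < 0) || any(iv > length_um)) {
      stop("gap intervals must lie within [0, length_um]", call. = FALSE)
    }
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      stop("gap intervals overlap", call. = FALSE)
    }
  } else {
    iv <- matrix(numeric(0), ncol = 2)
  }
  n <- max(2L, as.integer(round(length_um / psz)))
  pos <- (seq_len(n) - 1) * psz
  in_gap <- rep(FALSE, n)
  for (i in seq_len(nrow(iv))) {
    in_gap <- in_gap | (pos >= iv[i, 1] & pos < iv[i, 2])
  }
  signal <- config$background_level + ifelse(in_gap, 0, amplitude)
  with_seed(config$seed, {
    noisy <- pmax(0, signal + stats::rnorm(n, 0, config$noise_sd))
    out <- intensity_profile(noisy, pixel_size_um = psz,
                             background = config$background_level,
                             label = "axon")
    attr(out, "truth") <- list(gap_mask = in_gap, noiseless = signal,
                               gap_intervals = iv)
    out
  })
}
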