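#' Rolling local normalized variance of an intensity profile
#'
#' Computes the local normalized variance (NV) that quantifies how strongly a
#' fluorescence profile fluctuates around its local level: for every full
#' rolling window (trailing, step 1 px) the sample variance of the
#' intensities is divided by their mean. Reticular ER label (the line crosses
#' discrete tubules) fluctuates strongly and scores high; diffuse label
#' scores low. One summary value per profile is reported as the arithmetic
#' mean of the per-window NVs.
#'
#' Windows whose mean intensity is at or below `eps` are excluded from the
#' summary (NV is undefined there) and counted in `n_excluded`.
#'
#' @param profile An [intensity_profile()], a data frame with an `intensity`
#'   column, or a bare numeric vector.
#' @param window_px Window width in pixels (default 10, minimum 2).
#' @param eps Mean-intensity floor below which a window is excluded.
#' @return A tibble of class `fluctuation_result` with one row per window:
#'   `window` (index of the first pixel), `nv`, `window_mean`, `retained`;
#'   attributes `summary_nv`, `mean_intensity`, `window_px`, `n_excluded`,
#'   `summary_stat = "mean"` (the per-profile reduction used).
#' @examples
#' p <- intensity_profile(rep(c(0, 100), 50), pixel_size_um = 0.05)
#' res <- rolling_local_nv(p, window_px = 10)
#' attr(res, "summary_nv")
#' @export
rolling_local_nv <- function(profile, window_px = 10L, eps = 1e-9) {
  x <- as_profile_intensity(profile)
  n <- length(x)
  window_px <- as.integer(window_px)
  if (is.na(window_px) || window_px < 2) {
    stop("`window_px` must be an integer >= 2", call. = FALSE)
  }
  if (n < window_px) {
    stop(sprintf("profile (%d px) shorter than window (%d px)", n, window_px),
         call. = FALSE)
  }
  # rolling mean and unbiased variance from cumulative sums
  w <- window_px
  c1 <- c(0, cumsum(x))
  c2 <- c(0, cumsum(x^2))
  s1 <- c1[(w + 1):(n + 1)] - c1[1:(n - w + 1)]
  s2 <- c2[(w + 1):(n + 1)] - c2[1:(n - w + 1)]
  m <- s1 / w
  v <- pmax(0, (s2 - s1^2 / w) / (w - 1)) # clamp tiny negative fp residue
  retained <- m > eps
  nv <- ifelse(retained, v / m, NA_real_)
  out <- tibble::tibble(
    window = seq_len(n - w + 1),
    nv = nv,
    window_mean = m,
    retained = retained
  )
  attr(out, "summary_nv") <- if (any(retained)) mean(nv[retained]) else NA_real_
  attr(out, "mean_intensity") <- mean(x)
  attr(out, "window_px") <- w
  attr(out, "n_excluded") <- sum(!retained)
  attr(out, "summary_stat") <- "mean"
  class(out) <- c("fluctuation_result", class(out))
  out
}

#' Summary local NV of a profile
#'
#' Convenience wrapper returning just the per-profile summary value of
#' [rolling_local_nv()].
#'
#' @inheritParams rolling_local_nv
#' @return A single number (mean of per-window NVs over retained windows).
#' @export
summary_nv <- function(profile, window_px = 10L, eps = 1e-9) {
  attr(rolling_local_nv(profile, window_px, eps), "summary_nv")
}

#' Mean intensity of a profile
#'
#' Raw arithmetic mean of the sampled intensities, with no background
#' subtraction (matching how overall label levels are reported).
#'
#' @inheritParams rolling_local_nv
#' @return Mean intensity (same units as the input).
#' @export
mean_intensity <- function(profile) {
  x <- as_profile_intensity(profile)
  if (length(x) == 0) stop("empty profile", call. = FALSE)
  mean(x)
}

#' Coefficient of variation of a profile
#'
#' Sample standard deviation (denominator n - 1) divided by the mean, on the
#' raw intensities. Used as a per-axon measure of irregularity of ER label
#' along the axon.
#'
#' @inheritParams rolling_local_nv
#' @return Dimensionless CoV.
#' @export
coefficient_of_variation <- function(profile) {
  x <- as_profile_intensity(profile)
  if (length(x) < 2) stop("need at least 2 samples for a CoV", call. = FALSE)
  m <- mean(x)
  if (m <= 0) {
    stop("CoV undefined: profile mean is not positive", call. = FALSE)
  }
  stats::sd(x) / m
}

#' ER / plasma-membrane CoV ratio
#'
#' Ratio of the coefficient of variation of an ER-label profile to that of a
#' plasma-membrane-label profile from the same axon and extent. A smooth
#' plasma membrane with an irregular ER gives a ratio above 1; the ratio is
#' invariant to per-channel gain.
#'
#' @param er_profile,pm_profile Profiles (see [rolling_local_nv()] for
#'   accepted forms) of the ER and plasma-membrane channels.
#' @return Dimensionless ratio CoV(ER) / CoV(PM).
#' @export
cov_ratio <- function(er_profile, pm_profile) {
  cv_pm <- coefficient_of_variation(pm_profile)
  if (cv_pm == 0) {
    stop("CoV ratio undefined: plasma-membrane CoV is zero", call. = FALSE)
  }
  coefficient_of_variation(er_profile) / cv_pm
}

#' Detect gaps in an axonal intensity profile
#'
#' Subtracts the profile's background level (negatives clamped to zero) and
#' calls every maximal run of pixels with subtracted intensity strictly below
#' `threshold` a gap, provided the run is at least `min_gap_um` long. The
#' headline statistic is the percentage of the analyzed length that falls in
#' called gaps.
#'
#' `gap_percent` is computed from the retained runs, so it always equals the
#' summed interval lengths divided by the profile length; with the default
#' `min_gap_um = 0` this is identical to the fraction of sub-threshold
#' pixels.
#'
#' @param profile An [intensity_profile()] with its `background` attribute
#'   set (or pass `background`).
#' @param threshold Intensity threshold on the background-subtracted scale;
#'   default 20 on a 0--255 scale. Must lie in (0, `scale_max`).
#' @param min_gap_um Minimum gap length to report, in µm (default 0).
#' @param background Optional override of the profile's background attribute.
#' @param scale_max Top of the intensity scale (default 255).
#' @return A tibble of class `gap_report` with one row per gap:
#'   `start_um`, `end_um`, `length_um`, `start_px`, `end_px`; attributes
#'   `gap_percent`, `threshold`, `background`, `n_px`, `profile_length_um`,
#'   `saturated` (QC flag: any raw pixel at `scale_max`).
#' @examples
#' cfg <- sim_config(seed = 1, noise_sd = 0)
#' p <- gen_axon_profile(45, list(c(18, 27)), amplitude = 120, config = cfg)
#' attr(detect_gaps(p), "gap_percent") # 20
#' @export
detect_gaps <- function(profile, threshold = 20, min_gap_um = 0,
                        background = NULL, scale_max = 255) {
  x <- as_profile_intensity(profile)
  psz <- pixel_size(profile)
  if (is.null(psz)) stop("profile has no pixel size", call. = FALSE)
  if (is.null(background)) background <- attr(profile, "background")
  if (is.null(background) || !is.finite(background)) {
    stop("background level is not set", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold <= 0 || threshold >= scale_max) {
    stop("`threshold` must be a single number in (0, scale_max)",
         call. = FALSE)
  }
  n <- length(x)
  sub <- pmax(0, x - background)
  is_gap <- sub < threshold # strict: "less than"
  r <- rle(is_gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * psz >= min_gap_um)
  gaps <- tibble::tibble(
    start_px = starts[keep],
    end_px = ends[keep]
  )
  gaps$start_um <- (gaps$start_px - 1) * psz
  gaps$end_um <- gaps$end_px * psz
  gaps$length_um <- gaps$end_um - gaps$start_um
  gaps <- gaps[, c("start_um", "end_um", "length_um", "start_px", "end_px")]
  attr(gaps, "gap_percent") <- 100 * sum(gaps$end_px - gaps$start_px + 1) / n
  attr(gaps, "threshold") <- threshold
  attr(gaps, "background") <- background
  attr(gaps, "n_px") <- n
  attr(gaps, "profile_length_um") <- n * psz
  attr(gaps, "saturated") <- any(x >= scale_max)
  class(gaps) <- c("gap_report", class(gaps))
  gaps
}

#' Gap percentage of a profile
#'
#' Convenience wrapper returning just the `gap_percent` of [detect_gaps()].
#'
#' @inheritParams detect_gaps
#' @return Percentage (0--100) of the profile length called as gap.
#' @export
gap_percent <- function(profile, threshold = 20, min_gap_um = 0,
                        background = NULL, scale_max = 255) {
  attr(detect_gaps(profile, threshold, min_gap_um, background, scale_max),
       "gap_percent")
}

#' Profile statistics for a set of profiles
#'
#' Applies the per-profile statistics (mean intensity, CoV, summary local NV,
#' gap percentage) to a list of profiles and returns one tidy row per
#' profile.
#'
#' @param profiles A list of [intensity_profile()] objects.
#' @param window_px Window for the local NV (default 10).
#' @param threshold Gap threshold (default 20); gap detection is skipped
#'   (NA) for profiles without a background attribute.
#' @return A tibble with columns `label`, `n_px`, `mean_intensity`, `cov`,
#'   `summary_nv`, `gap_percent`, `saturated`.
#' @export
profile_stats <- function(profiles, window_px = 10L, threshold = 20) {
  purrr::map_dfr(profiles, function(p) {
    gp <- tryCatch(gap_percent(p, threshold = threshold),
                   error = function(e) NA_real_)
    tibble::tibble(
      label = attr(p, "label") %||% "",
      n_px = nrow(p),
      mean_intensity = mean_intensity(p),
      cov = coefficient_of_variation(p),
      summary_nv = summary_nv(p, window_px = window_px),
      gap_percent = gp,
      saturated = is_saturated(p)
    )
  })
}
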