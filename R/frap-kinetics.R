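#' Normalize a FRAP series
#'
#' Applies the two-step normalization used for axonal FRAP: (1) per frame,
#' subtract the background trace from the bleach-ROI trace and divide by the
#' background-subtracted whole-axon mean of the same frame (correcting for
#' acquisition-wide intensity changes such as observational bleaching); then
#' (2) rescale so the mean pre-bleach ratio maps to 1 and the ratio at the
#' first post-bleach frame maps to 0 exactly. Negative normalized values
#' (noise below the bleach floor) are retained, not clamped.
#'
#' @param series A [frap_series()].
#' @return A tibble with columns `time_s`, `t_post_s` (time relative to the
#'   bleach frame; `NA` for pre-bleach frames... see Details), `normalized`,
#'   and `phase` (`"pre"` / `"post"`). `t_post_s` is 0 at the bleach frame.
#'   Attributes `r_pre`, `r_bleach` record the anchors.
#' @details The bleach frame itself is included in the post-bleach set as
#'   the exact (0, 0) anchor of the recovery model.
#' @export
normalize_frap <- function(series) {
  stopifnot(inherits(series, "frap_series"))
  bi <- attr(series, "bleach_index")
  n_pre <- attr(series, "n_pre")
  denom <- series$axon_mean - series$background
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop(sprintf(
      "normalization failed: axon_mean - background <= 0 at frame %d",
      bad[1]
    ), call. = FALSE)
  }
  r <- (series$bleach_roi - series$background) / denom
  r_pre <- mean(r[seq_len(n_pre)])
  r_bleach <- r[bi]
  if (abs(r_pre - r_bleach) < 1e-12) {
    stop("normalization failed: pre-bleach and bleach levels coincide",
         call. = FALSE)
  }
  normalized <- (r - r_bleach) / (r_pre - r_bleach)
  out <- tibble::tibble(
    time_s = series$time_s,
    t_post_s = series$time_s - series$time_s[bi],
    normalized = normalized,
    phase = ifelse(seq_along(r) >= bi, "post", "pre")
  )
  attr(out, "r_pre") <- r_pre
  attr(out, "r_bleach") <- r_bleach
  attr(out, "bleach_index") <- bi
  class(out) <- c("frap_normalized", class(out))
  out
}

#' Fit single-exponential FRAP recovery
#'
#' Fits the recovery model `I(t) = A * (1 - exp(-k t))` to the post-bleach
#' portion of a normalized FRAP trace by unweighted nonlinear least squares,
#' where `A` is the plateau (mobile) fraction and `k` the rate constant.
#' The half-recovery time is `t_half = ln(2) / k`. Fitting is multi-start
#' (k0 of 0.005, 0.02 and 0.1 per second), keeping the best-residual
#' solution; `A` is constrained to (0, 1.5] (values above 1.1 are flagged as
#' suspect) and `k` to be positive.
#'
#' @param x Either the result of [normalize_frap()] (post-bleach rows are
#'   extracted automatically) or a numeric vector of post-bleach times
#'   (s, 0 at the bleach frame), in which case `normalized` supplies the
#'   trace.
#' @param normalized Normalized intensities matching `x` when `x` is a time
#'   vector.
#' @return An object of class `frap_fit`: list with `A`, `k`, `t_half_s`,
#'   `rms`, `n`, `converged`, `flagged_A` and the data used. Use [tidy()] /
#'   [glance()] or [autoplot()] on it.
#' @examples
#' s <- gen_frap_series(A = 0.8, k = 0.02, config = sim_config(noise_sd = 0))
#' fit <- fit_recovery(normalize_frap(s))
#' fit$k # 0.02
#' @export
fit_recovery <- function(x, normalized = NULL) {
  if (inherits(x, "frap_normalized") ||
      (is.data.frame(x) && all(c("t_post_s", "normalized") %in% names(x)))) {
    post <- x[x$t_post_s >= 0, ]
    t <- post$t_post_s
    y <- post$normalized
  } else {
    t <- as.numeric(x)
    y <- as.numeric(normalized)
  }
  if (length(t) < 5) stop("need at least 5 post-bleach points", call. = FALSE)
  if (length(t) != length(y)) stop("time/intensity length mismatch", call. = FALSE)
  if (stats::var(y) < 1e-8) {
    stop("recovery not identifiable: trace is flat (no recovery)",
         call. = FALSE)
  }
  dat <- data.frame(t = t, y = y)
  best <- NULL
  for (k0 in c(0.005, 0.02, 0.1)) {
    A0 <- min(1.4, max(0.1, stats::quantile(y, 0.95, names = FALSE)))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * (1 - exp(-k * t)), data = dat,
        start = list(A = A0, k = k0),
        lower = c(A = 1e-6, k = 1e-8), upper = c(A = 1.5, k = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("recovery not identifiable: no start converged", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  k <- unname(cf["k"])
  if (k <= 1e-8) {
    stop("recovery not identifiable: rate constant collapsed to zero",
         call. = FALSE)
  }
  structure(
    list(
      A = unname(cf["A"]),
      k = k,
      t_half_s = log(2) / k,
      rms = sqrt(best$rss / length(t)),
      n = length(t),
      converged = TRUE,
      flagged_A = unname(cf["A"]) > 1.1,
      data = tibble::tibble(t_post_s = t, normalized = y,
                            fitted = stats::fitted(best$fit))
    ),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> A = %.4g%s | k = %.4g /s | t_half = %.4g s | rms %.3g | n = %d\n",
    x$A, if (x$flagged_A) " [>1.1, flagged]" else "", x$k, x$t_half_s,
    x$rms, x$n
  ))
  invisible(x)
}

#' @rdname fit_recovery
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "k", "t_half_s"),
    estimate = c(x$A, x$k, x$t_half_s)
  )
}

#' @rdname fit_recovery
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(
    A = x$A, k = x$k, t_half_s = x$t_half_s, rms = x$rms, n = x$n,
    converged = x$converged, flagged_A = x$flagged_A
  )
}

#' Build a kymograph from a time-lapse movie
#'
#' Samples intensity along a polyline drawn along the axon, for every frame,
#' at 1-px arc-length steps (bilinear interpolation); rows are positions
#' along the path, columns are frames, so movement of labeled structures
#' appears as sloped lines whose slope is the velocity.
#'
#' @param movie 3-D array `[row, col, frame]` with at least 2 frames.
#' @param path Polyline as an n x 2 matrix of 0-based `(row, col)` pixel
#'   coordinates (vertices at pixel centers).
#' @param width_px Perpendicular averaging width in pixels (odd; default 1).
#' @param pixel_size_um Pixel size, µm (default 1: positions in px).
#' @param frame_interval_s Frame interval, s (default 1).
#' @return A matrix of class `kymograph` (positions x frames) with
#'   attributes `pixel_size_um`, `frame_interval_s`, `path`.
#' @export
build_kymograph <- function(movie, path, width_px = 1L, pixel_size_um = 1,
                            frame_interval_s = 1) {
  stopifnot(is.array(movie), length(dim(movie)) == 3, dim(movie)[3] >= 2)
  width_px <- as.integer(width_px)
  if (width_px < 1 || width_px %% 2 == 0) {
    stop("`width_px` must be a positive odd integer", call. = FALSE)
  }
  pts <- polyline_samples(path, step_px = 1)
  n_frames <- dim(movie)[3]
  offsets <- seq_len(width_px) - (width_px + 1) / 2
  mat <- matrix(NA_real_, nrow(pts), n_frames)
  for (f in seq_len(n_frames)) {
    frame <- movie[, , f]
    acc <- 0
    for (o in offsets) {
      acc <- acc + bilinear_sample(frame,
                                   pts[, "row"] + o * pts[, "nrow"],
                                   pts[, "col"] + o * pts[, "ncol"])
    }
    mat[, f] <- acc / width_px
  }
  attr(mat, "pixel_size_um") <- pixel_size_um
  attr(mat, "frame_interval_s") <- frame_interval_s
  attr(mat, "path") <- path
  class(mat) <- c("kymograph", class(mat))
  mat
}

#' Velocity from two points on a kymograph track
#'
#' Slope arithmetic for a hand-identified track on a kymograph: the signed
#' velocity between two (time, distance) points. Positive velocities are
#' anterograde (increasing distance coordinate), negative retrograde.
#'
#' @param p1,p2 Numeric `c(t_s, d_um)` points with `p2` later than `p1`.
#' @return Signed velocity in µm/s.
#' @examples
#' velocity_from_track(c(0, 0), c(10, 3)) # 0.3 um/s anterograde
#' @export
velocity_from_track <- function(p1, p2) {
  stopifnot(length(p1) == 2, length(p2) == 2)
  if (p2[1] <= p1[1]) {
    stop("`p2` must be later than `p1` (t2 > t1)", call. = FALSE)
  }
  (p2[2] - p1[2]) / (p2[1] - p1[1])
}
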