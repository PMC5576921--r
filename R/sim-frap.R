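#' Construct a FRAP series
#'
#' A `frap_series` is a tibble with one row per acquired frame and columns
#' `time_s`, `bleach_roi` (mean intensity of the bleached region),
#' `axon_mean` (mean intensity along the whole axon) and `background` (mean
#' of a non-expressing region), with the bleach bookkeeping as attributes.
#'
#' @param time_s Strictly increasing sample times (s).
#' @param bleach_roi,axon_mean,background Per-frame traces, same length as
#'   `time_s`.
#' @param bleach_index Index (1-based) of the first post-bleach frame.
#' @param n_pre Number of pre-bleach frames (defaults to
#'   `bleach_index - 1`).
#' @return A tibble of class `frap_series`.
#' @export
frap_series <- function(time_s, bleach_roi, axon_mean, background,
                        bleach_index, n_pre = bleach_index - 1L) {
  stopifnot(
    length(time_s) >= 2, all(diff(time_s) > 0),
    length(bleach_roi) == length(time_s),
    length(axon_mean) == length(time_s),
    length(background) == length(time_s)
  )
  bleach_index <- as.integer(bleach_index)
  n_pre <- as.integer(n_pre)
  if (bleach_index < 2 || bleach_index > length(time_s)) {
    stop("`bleach_index` must point at a frame after at least one pre-bleach frame",
         call. = FALSE)
  }
  if (n_pre < 1 || n_pre >= bleach_index) {
    stop("`n_pre` must be >= 1 and < bleach_index", call. = FALSE)
  }
  out <- tibble::tibble(
    time_s = as.numeric(time_s),
    bleach_roi = as.numeric(bleach_roi),
    axon_mean = as.numeric(axon_mean),
    background = as.numeric(background)
  )
  attr(out, "bleach_index") <- bleach_index
  attr(out, "n_pre") <- n_pre
  class(out) <- c("frap_series", class(out))
  out
}

#' Simulate a FRAP recording with known recovery kinetics
#'
#' Builds a three-trace FRAP recording (bleach ROI, whole-axon mean,
#' background) whose normalized recovery follows the single-exponential
#' model `A * (1 - exp(-k t))` exactly in the noiseless limit: pre-bleach
#' frames sit at the unbleached level, the first post-bleach frame (t = 0)
#' at the bleach floor, and recovery approaches the mobile fraction `A`.
#' The standard acquisition is one frame every 5 s for 200 s post-bleach.
#'
#' @param A Mobile (plateau) fraction, in (0, 1].
#' @param k Recovery rate constant, 1/s (> 0).
#' @param frame_interval_s Frame interval (default 5 s).
#' @param n_pre Number of pre-bleach frames (default 4).
#' @param duration_s Post-bleach duration (default 200 s).
#' @param config A [sim_config()]; `noise_sd` is applied to every trace in
#'   intensity units (the unbleached ROI signal spans `scale` units, so
#'   `noise_sd = 5` with the default `scale = 100` is 5% noise on the
#'   normalized scale).
#' @param scale Unbleached ROI intensity above background (default 100).
#' @return A [frap_series()]; attribute `truth` carries `A`, `k` and the
#'   noiseless normalized recovery.
#' @examples
#' s <- gen_frap_series(A = 0.8, k = 0.02, config = sim_config(noise_sd = 0))
#' fit <- fit_recovery(normalize_frap(s))
#' glance(fit)
#' @export
gen_frap_series <- function(A, k, frame_interval_s = 5, n_pre = 4L,
                            duration_s = 200, config = sim_config(),
                            scale = 100) {
  if (!is.numeric(A) || A <= 0 || A > 1) stop("`A` must be in (0, 1]", call. = FALSE)
  if (!is.numeric(k) || k <= 0) stop("`k` must be positive", call. = FALSE)
  n_pre <- as.integer(n_pre)
  stopifnot(n_pre >= 1, frame_interval_s > 0, duration_s > 0)
  t_post <- seq(0, duration_s, by = frame_interval_s)
  time_s <- c(seq(-n_pre, -1) * frame_interval_s, t_post)
  model <- c(rep(1, n_pre), A * (1 - exp(-k * t_post)))
  bg <- config$background_level
  with_seed(config$seed, {
    nz <- function(n) stats::rnorm(n, 0, config$noise_sd)
    n <- length(time_s)
    bleach_roi <- bg + scale * model + nz(n)
    axon_mean <- bg + scale + nz(n) / 4 # whole-axon mean: larger area, less noise
    background <- bg + nz(n) / 4
    out <- frap_series(time_s - time_s[1], bleach_roi, axon_mean, background,
                       bleach_index = n_pre + 1L, n_pre = n_pre)
    attr(out, "truth") <- list(A = A, k = k, model_normalized = model,
                               t_post_s = t_post)
    out
  })
}

#' Simulate FRAP by 1-D diffusion with optional ER discontinuities
#'
#' Explicit finite-difference simulation of one-dimensional diffusion of a
#' fluorescent ER-lumen/membrane protein along an axon, used to reproduce
#' the phenomenology of photobleaching experiments: with a continuous ER
#' network, fluorescence recovers into the bleached interval from both ends;
#' a physical discontinuity (gap) in the network is a barrier to diffusion,
#' so a bleached interval flanked by gaps on both sides never recovers.
#'
#' The concentration `u(x, t)` starts at 1 everywhere, is set to 0 on the
#' bleach interval at t = 0, and evolves under a conservative explicit
#' scheme. Each gap position becomes a zero-flux internal wall. Domain ends
#' are held at u = 1 (`boundary = "reservoir"`, the connected ER of the rest
#' of the neuron) or closed (`boundary = "closed"`, zero flux, which
#' conserves total signal and is used for conservation checks).
#'
#' The explicit scheme is stable only for `D * dt / dx^2 <= 0.5`; violating
#' parameters are refused, never silently adjusted.
#'
#' @param axon_length_um Domain length (µm).
#' @param bleach_interval_um `c(start, end)` of the bleached interval (µm),
#'   inside the domain; the standard bleach ROI is 12 µm long.
#' @param D Diffusion coefficient (µm^2/s). Default 2, a representative
#'   value for a fast-diffusing ER-associated fluorescent protein.
#' @param gap_positions Numeric vector of gap (wall) positions (µm).
#' @param dt Time step (s). @param dx Grid spacing (µm).
#' @param duration_s Simulated post-bleach duration (s).
#' @param frame_interval_s Sampling interval of the output trace (s).
#' @param boundary `"reservoir"` or `"closed"`.
#' @return A tibble of class `frap_trace` with columns `time_s` and
#'   `recovery` (mean u over the bleach interval). Attributes: `u` (grid
#'   snapshots at the sampled frames, one column per frame), `x_um` (cell
#'   centers), `mass` (total integral of u per sampled frame), and the
#'   simulation parameters.
#' @export
simulate_frap_diffusion <- function(axon_length_um = 45,
                                    bleach_interval_um = c(16.5, 28.5),
                                    D = 2, gap_positions = numeric(),
                                    dt = 0.004, dx = 0.15,
                                    duration_s = 200, frame_interval_s = 5,
                                    boundary = c("reservoir", "closed")) {
  boundary <- match.arg(boundary)
  stopifnot(axon_length_um > 0, D > 0, dt > 0, dx > 0, duration_s > 0)
  if (D * dt / dx^2 > 0.5 + 1e-12) {
    stop(sprintf(
      "explicit scheme unstable: D*dt/dx^2 = %.3g > 0.5; reduce dt or increase dx",
      D * dt / dx^2
    ), call. = FALSE)
  }
  if (length(bleach_interval_um) != 2 ||
      bleach_interval_um[1] >= bleach_interval_um[2] ||
      bleach_interval_um[1] < 0 || bleach_interval_um[2] > axon_length_um) {
    stop("`bleach_interval_um` must be c(start, end) inside the domain",
         call. = FALSE)
  }
  nx <- as.integer(round(axon_length_um / dx))
  xc <- (seq_len(nx) - 0.5) * dx # cell centers
  u <- rep(1, nx)
  bleached <- xc >= bleach_interval_um[1] & xc <= bleach_interval_um[2]
  if (!any(bleached)) stop("bleach interval contains no grid cells", call. = FALSE)
  u[bleached] <- 0
  # interface open/closed flags: interface i sits between cells i and i+1
  open_if <- rep(TRUE, nx - 1L)
  for (g in gap_positions) {
    if (g <= 0 || g >= axon_length_um) next
    i <- max(1L, min(nx - 1L, as.integer(round(g / dx))))
    open_if[i] <- FALSE
  }
  n_steps_per_frame <- max(1L, as.integer(round(frame_interval_s / dt)))
  n_frames <- as.integer(floor(duration_s / frame_interval_s)) + 1L
  alpha <- D * dt / dx^2
  usnap <- matrix(NA_real_, nx, n_frames)
  trace <- numeric(n_frames)
  mass <- numeric(n_frames)
  record <- function(j) {
    usnap[, j] <<- u
    trace[j] <<- mean(u[bleached])
    mass[j] <<- sum(u) * dx
  }
  record(1L)
  for (j in seq_len(n_frames - 1L)) {
    for (s in seq_len(n_steps_per_frame)) {
      flux <- ifelse(open_if, u[-1L] - u[-nx], 0) # ~ du across open interfaces
      du <- c(flux, 0) - c(0, flux)
      u <- u + alpha * du
      if (boundary == "reservoir") {
        u[1L] <- 1
        u[nx] <- 1
      }
    }
    record(j + 1L)
  }
  out <- tibble::tibble(
    time_s = (seq_len(n_frames) - 1L) * frame_interval_s,
    recovery = trace
  )
  attr(out, "u") <- usnap
  attr(out, "x_um") <- xc
  attr(out, "mass") <- mass
  attr(out, "params") <- list(
    axon_length_um = axon_length_um, bleach_interval_um = bleach_interval_um,
    D = D, gap_positions = gap_positions, dt = dt, dx = dx,
    duration_s = duration_s, frame_interval_s = frame_interval_s,
    boundary = boundary
  )
  class(out) <- c("frap_trace", class(out))
  out
}

#' Half-recovery time of a recovery trace
#'
#' First time at which a recovery trace reaches half of its final (last
#' sampled) level, found by linear interpolation between frames.
#'
#' @param trace A `frap_trace` (from [simulate_frap_diffusion()]) or any
#'   data frame with `time_s` and `recovery` columns.
#' @return Time in seconds, or `NA` if the trace never reaches half of its
#'   final level (e.g. no recovery at all).
#' @export
half_recovery_time <- function(trace) {
  t <- trace$time_s
  y <- trace$recovery
  target <- y[length(y)] / 2
  if (y[length(y)] <= 0) return(NA_real_)
  i <- which(y >= target)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1])
  t[i - 1] + (target - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}
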