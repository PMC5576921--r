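#' Construct a serial-section stack
#'
#' Light container for an ordered stack of aligned 2-D grayscale EM sections
#' with physical calibration: lateral pixel size in nm and the fixed section
#' thickness (60 nm in the standard serial-sectioning protocol).
#'
#' @param data 3-D numeric array `[row, col, section]`.
#' @param pixel_size_nm Lateral pixel size, nm/px.
#' @param thickness_nm Section thickness, nm (default 60).
#' @param er_bright Logical: `TRUE` if ER is brighter than background (the
#'   synthetic convention), `FALSE` for inverted-contrast (membrane-stained
#'   ROTO) material, which analysis functions flip internally.
#' @return A list of class `section_stack`.
#' @export
section_stack <- function(data, pixel_size_nm, thickness_nm = 60,
                          er_bright = TRUE) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            pixel_size_nm > 0, thickness_nm > 0)
  structure(
    list(data = data, pixel_size_nm = pixel_size_nm,
         thickness_nm = thickness_nm, er_bright = er_bright),
    class = "section_stack"
  )
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<section_stack> %d sections of %d x %d px | %.3g nm/px | %g nm thick | ER %s\n",
    d[3], d[1], d[2], x$pixel_size_nm, x$thickness_nm,
    if (x$er_bright) "bright" else "dark"
  ))
  invisible(x)
}

#' Simulate a serial-section EM stack of an axon's ER network with truth
#'
#' Renders an axon segment as a stack of transverse sections in which each
#' ER tubule appears as a bright disc (ER bright, background dark -- the
#' analysis accepts either polarity via an invert flag). Tubule centerlines
#' jitter by at most 1 px per section, each section gets an independent
#' log-normal brightness factor (emulating section-to-section staining and
#' contrast variability), and Gaussian noise is added. Axon-level gaps --
#' section ranges with complete loss of ER -- render no foreground at all.
#' The ground truth (segments, gap table) is returned alongside the stack.
#'
#' @param truth_params A list with elements:
#'   `n_tubules` (count, default 2);
#'   `diameter_nm` (per-tubule outer diameters, recycled; default 40);
#'   `gaps` (list of `c(z_start, z_end)` 1-based inclusive section ranges
#'     with no ER, pairwise non-overlapping; default none);
#'   `sheets` (list of `c(z_start, z_end, length_nm)` sheet patches rendered
#'     as elongated profiles; default none).
#' @param n_sections Number of serial sections (>= 3; the standard segment
#'   is 75 sections = 4.5 µm).
#' @param config A [sim_config()] (`pixel_size_nm`, `section_thickness_nm`,
#'   `noise_sd`, `background_level`, `seed`).
#' @param image_px Section side length in pixels (default 64).
#' @param amplitude Foreground intensity above background (default 100).
#' @param brightness_sdlog SD of the per-section log-normal brightness
#'   factor (default 0.2; 0 disables the variability).
#' @return A list with elements `stack` (a [section_stack()]) and `truth`
#'   (class `er_network_truth`: tibbles `segments` and `gaps`, plus the
#'   per-tubule centerline paths).
#' @examples
#' cfg <- sim_config(seed = 3, noise_sd = 0)
#' sim <- gen_section_stack(list(n_tubules = 1, gaps = list(c(30, 34))),
#'                          n_sections = 75, config = cfg,
#'                          brightness_sdlog = 0)
#' @export
gen_section_stack <- function(truth_params = list(), n_sections = 75,
                              config = sim_config(), image_px = 64,
                              amplitude = 100, brightness_sdlog = 0.2) {
  p <- list(n_tubules = 2L, diameter_nm = 40, gaps = list(), sheets = list())
  p[names(truth_params)] <- truth_params
  n_sections <- as.integer(n_sections)
  if (n_sections < 3) stop("`n_sections` must be >= 3", call. = FALSE)
  psz <- config$pixel_size_nm
  diam <- rep(p$diameter_nm, length.out = p$n_tubules)
  radius_px <- diam / 2 / psz
  if (any(diam / psz < 2)) {
    stop("tubule diameter below 2 px at this pixel size is unresolvable",
         call. = FALSE)
  }
  # validate gaps
  if (length(p$gaps)) {
    gv <- do.call(rbind, lapply(p$gaps, function(g) {
      if (length(g) != 2 || g[1] > g[2]) {
        stop("each gap must be c(z_start, z_end) with z_start <= z_end",
             call. = FALSE)
      }
      as.integer(g)
    }))
    if (any(gv < 1) || any(gv > n_sections)) {
      stop("gap section ranges must lie within the stack", call. = FALSE)
    }
    gv <- gv[order(gv[, 1]), , drop = FALSE]
    if (nrow(gv) > 1 && any(gv[-1, 1] <= gv[-nrow(gv), 2])) {
      stop("gap section ranges overlap", call. = FALSE)
    }
  } else {
    gv <- matrix(integer(0), ncol = 2)
  }
  in_gap <- rep(FALSE, n_sections)
  for (i in seq_len(nrow(gv))) in_gap[gv[i, 1]:gv[i, 2]] <- TRUE

  H <- W <- as.integer(image_px)
  margin <- max(radius_px) + 6
  with_seed(config$seed, {
    # initial centers: rejection-sample with pairwise separation
    centers <- matrix(NA_real_, p$n_tubules, 2)
    for (i in seq_len(p$n_tubules)) {
      for (try in 1:200) {
        cand <- stats::runif(2, margin, c(H, W) - margin)
        ok <- TRUE
        if (i > 1) {
          dd <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - cand)^2))
          ok <- all(dd > radius_px[i] + radius_px[seq_len(i - 1)] + 8)
        }
        if (ok) break
      }
      if (!ok) stop("could not place tubules without overlap; reduce count or diameter",
                    call. = FALSE)
      centers[i, ] <- cand
    }
    # jittered centerlines: random walk, |step| <= 1 px per axis per section,
    # clamped to +/- 3 px of the initial center so tubules never collide
    paths <- lapply(seq_len(p$n_tubules), function(i) {
      steps_r <- stats::runif(n_sections - 1, -1, 1)
      steps_c <- stats::runif(n_sections - 1, -1, 1)
      r <- centers[i, 1] + pmin(3, pmax(-3, cumsum(c(0, steps_r))))
      c_ <- centers[i, 2] + pmin(3, pmax(-3, cumsum(c(0, steps_c))))
      cbind(row = r, col = c_)
    })
    bright <- if (brightness_sdlog > 0) {
      stats::rlnorm(n_sections, 0, brightness_sdlog)
    } else {
      rep(1, n_sections)
    }
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    arr <- array(config$background_level, dim = c(H, W, n_sections))
    for (z in seq_len(n_sections)) {
      if (in_gap[z]) {
        # complete loss of ER: background only
      } else {
        fg <- matrix(FALSE, H, W)
        for (i in seq_len(p$n_tubules)) {
          ctr <- paths[[i]][z, ]
          fg <- fg | ((rows - ctr[1])^2 + (cols - ctr[2])^2 <= radius_px[i]^2)
        }
        for (s in p$sheets) {
          if (z >= s[1] && z <= s[2]) {
            half_len_px <- s[3] / 2 / psz
            fg <- fg | (abs(rows - H / 2) <= 1.5 &
                          abs(cols - W / 2) <= half_len_px)
          }
        }
        arr[, , z] <- arr[, , z] + fg * amplitude * bright[z]
      }
      if (config$noise_sd > 0) {
        arr[, , z] <- pmax(0, arr[, , z] +
                             stats::rnorm(H * W, 0, config$noise_sd))
      }
    }
    segments <- tibble::tibble(
      tubule_id = seq_len(p$n_tubules),
      radius_nm = diam / 2,
      diameter_nm = diam,
      z0 = 1L, z1 = n_sections,
      center_row = centers[, 1], center_col = centers[, 2]
    )
    gaps <- tibble::tibble(
      z_start = as.integer(gv[, 1]), z_end = as.integer(gv[, 2])
    )
    gaps$n_sections <- gaps$z_end - gaps$z_start + 1L
    gaps$length_nm <- gaps$n_sections * config$section_thickness_nm
    truth <- structure(
      list(segments = segments, gaps = gaps, paths = paths,
           section_in_gap = in_gap, brightness = bright,
           amplitude = amplitude),
      class = "er_network_truth"
    )
    list(
      stack = section_stack(arr, pixel_size_nm = psz,
                            thickness_nm = config$section_thickness_nm,
                            er_bright = TRUE),
      truth = truth
    )
  })
}
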