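# --- low-level raster helpers ---------------------------------------------

# windowed box mean via integral images, count-normalized at the edges
box_mean <- function(img, w) {
  stopifnot(w >= 1)
  h <- (w - 1L) %/% 2L
  H <- nrow(img)
  W <- ncol(img)
  csum <- function(m) {
    m <- apply(m, 2, cumsum)
    t(apply(m, 1, cumsum))
  }
  S <- rbind(0, cbind(0, csum(img)))
  C <- rbind(0, cbind(0, csum(matrix(1, H, W))))
  r0 <- pmax(0L, seq_len(H) - h - 1L)
  r1 <- pmin(H, seq_len(H) + h)
  c0 <- pmax(0L, seq_len(W) - h - 1L)
  c1 <- pmin(W, seq_len(W) + h)
  block <- function(M) {
    M[r1 + 1L, c1 + 1L, drop = FALSE] - M[r0 + 1L, c1 + 1L, drop = FALSE] -
      M[r1 + 1L, c0 + 1L, drop = FALSE] + M[r0 + 1L, c0 + 1L, drop = FALSE]
  }
  block(S) / block(C)
}

# 1-px (8-neighborhood) dilation of a set of linear pixel indices
dilate_indices <- function(idx, dm) {
  H <- dm[1]
  W <- dm[2]
  r <- ((idx - 1L) %% H) + 1L
  c_ <- ((idx - 1L) %/% H) + 1L
  rr <- rep(r, 9L) + rep(c(-1L, 0L, 1L), each = 3L * length(idx))
  cc <- rep(c_, 9L) + rep(rep(c(-1L, 0L, 1L), each = length(idx)), 3L)
  ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  unique((cc[ok] - 1L) * H + rr[ok])
}

overlap_px <- function(idx_a_dilated, idx_b) {
  length(intersect(idx_a_dilated, idx_b))
}

# --- segmentation ----------------------------------------------------------

#' Segment candidate ER tubule profiles in one EM section
#'
#' Local-threshold detection of tubule cross-sections: a pixel is a
#' candidate when it exceeds the mean of its `window_px` neighborhood by an
#' offset expressed in robust units (the median absolute deviation of the
#' ROI intensities, falling back to the SD when the MAD degenerates to
#' zero), which makes detection invariant to affine intensity changes of
#' the section. Connected components of at least `min_px` pixels become
#' detections; a detection is *strong* when it contains a pixel passing the
#' strong offset, otherwise *faint*. Faint detections are only provisional:
#' track linking admits them only next to a strong detection in an adjacent
#' section (the faint-signal rescue for sections with weak staining).
#'
#' @param image 2-D numeric matrix (one section).
#' @param axon_roi Optional logical matrix restricting analysis to one axon.
#' @param strong_offset,faint_offset Detection offsets in robust (MAD)
#'   units; must satisfy `strong_offset > faint_offset >= 0`. Defaults 5
#'   and 2.5.
#' @param window_px Local-mean window side, px (default 31).
#' @param invert Set `TRUE` for ER-dark (membrane-stained) material; the
#'   section is flipped to the ER-bright convention before thresholding.
#' @param min_px Minimum component size (default 2).
#' @return Tibble with one row per detection: `detection_id`, `n_px`,
#'   `centroid_row`, `centroid_col`, `strong`, `pixels` (list column of
#'   linear pixel indices); attribute `dim` is the image dimension.
#' @export
segment_section <- function(image, axon_roi = NULL, strong_offset = 5,
                            faint_offset = 2.5, window_px = 31L,
                            invert = FALSE, min_px = 2L) {
  stopifnot(is.matrix(image))
  if (!(strong_offset > faint_offset && faint_offset >= 0)) {
    stop("offsets must satisfy strong_offset > faint_offset >= 0",
         call. = FALSE)
  }
  if (is.null(axon_roi)) {
    axon_roi <- matrix(TRUE, nrow(image), ncol(image))
  }
  if (!any(axon_roi)) stop("axon ROI is empty", call. = FALSE)
  if (invert) image <- max(image) - image
  vals <- image[axon_roi]
  s <- stats::mad(vals)
  # noiseless sections have MAD 0; fall back to a range-based scale, which
  # stays gain-invariant and small relative to real structure
  if (s < 1e-9) s <- diff(range(vals)) / 100
  empty <- tibble::tibble(
    detection_id = integer(), n_px = integer(),
    centroid_row = numeric(), centroid_col = numeric(),
    strong = logical(), pixels = list()
  )
  attr(empty, "image_dim") <- dim(image)
  if (!is.finite(s) || s < 1e-12) return(empty) # uniform image
  lm <- box_mean(image, window_px)
  resid <- image - lm
  faint_mask <- axon_roi & (resid > faint_offset * s)
  strong_mask <- axon_roi & (resid > strong_offset * s)
  if (!any(faint_mask)) return(empty)
  lab <- EBImage::bwlabel(faint_mask * 1)
  lab <- as.integer(lab)
  idx_by_comp <- split(which(lab > 0), lab[lab > 0])
  H <- nrow(image)
  rows_list <- list()
  id <- 0L
  for (px in idx_by_comp) {
    if (length(px) < min_px) next
    id <- id + 1L
    r <- ((px - 1L) %% H) + 1L
    c_ <- ((px - 1L) %/% H) + 1L
    rows_list[[id]] <- tibble::tibble(
      detection_id = id, n_px = length(px),
      centroid_row = mean(r), centroid_col = mean(c_),
      strong = any(strong_mask[px]), pixels = list(as.integer(px))
    )
  }
  out <- if (id > 0) dplyr::bind_rows(rows_list) else empty
  attr(out, "image_dim") <- dim(image)
  out
}

# --- track linking ---------------------------------------------------------

#' Link per-section detections into tubule tracks
#'
#' Builds continuous ER tubules from per-section detections using the
#' same-position rule: two detections in consecutive sections belong to the
#' same tubule when their masks overlap by at least 1 px after 1-px
#' dilation. Chains are grown greedily by maximal overlap with a
#' deterministic tie-break (lowest centroid row, then column). A tubule must
#' persist for three or more consecutive sections; shorter chains are
#' discarded. Faint detections are admitted only when they overlap a strong
#' detection in an adjacent section.
#'
#' @param detections Tibble of detections across sections: the columns of
#'   [segment_section()] plus a section index column `z`; attribute `dim`
#'   (or `image_dim` argument) gives the section shape.
#' @param n_sections Total number of sections in the stack.
#' @param min_span Minimum persistence in sections (default 3).
#' @param image_dim Section dimension, needed if `detections` lacks the
#'   `dim` attribute.
#' @param axon_id Identifier stored on the output (default 1).
#' @return Tibble of class `tubule_tracks`: one row per (track, section)
#'   with `track_id`, `z`, `n_px`, `centroid_row`, `centroid_col`, `strong`,
#'   `pixels`; attributes `spans` (per-track z-range tibble), `dim`,
#'   `n_sections`, `axon_id`.
#' @export
link_tubule_tracks <- function(detections, n_sections, min_span = 3L,
                               image_dim = NULL, axon_id = 1L) {
  dm <- attr(detections, "image_dim") %||% image_dim
  empty <- tibble::tibble(
    track_id = integer(), z = integer(), n_px = integer(),
    centroid_row = numeric(), centroid_col = numeric(),
    strong = logical(), pixels = list()
  )
  finish <- function(x, spans) {
    attr(x, "spans") <- spans
    attr(x, "image_dim") <- dm
    attr(x, "n_sections") <- as.integer(n_sections)
    attr(x, "axon_id") <- axon_id
    class(x) <- c("tubule_tracks", class(x))
    x
  }
  if (nrow(detections) == 0) {
    return(finish(empty, tibble::tibble(track_id = integer(),
                                        z_first = integer(),
                                        z_last = integer())))
  }
  if (is.null(dm)) stop("section dimensions unknown; pass `image_dim`",
                        call. = FALSE)
  det <- dplyr::arrange(detections, .data$z, .data$detection_id)
  # faint-signal rescue: a faint detection is admissible only if it overlaps
  # (after 1-px dilation) a strong detection in section z-1 or z+1
  strong_by_z <- split(det$pixels[det$strong], det$z[det$strong])
  admissible <- det$strong
  for (i in which(!det$strong)) {
    dil <- dilate_indices(det$pixels[[i]], dm)
    near <- unlist(
      c(strong_by_z[[as.character(det$z[i] - 1L)]],
        strong_by_z[[as.character(det$z[i] + 1L)]]),
      use.names = FALSE
    )
    admissible[i] <- length(near) > 0 && overlap_px(dil, near) >= 1
  }
  det <- det[admissible, ]
  if (nrow(det) == 0) {
    return(finish(empty, tibble::tibble(track_id = integer(),
                                        z_first = integer(),
                                        z_last = integer())))
  }
  # greedy chain building over consecutive sections
  chains <- list() # each: list(rows = list of row indices into det, last_z)
  for (z in sort(unique(det$z))) {
    dz <- which(det$z == z)
    active <- which(vapply(chains, function(ch) ch$last_z == z - 1L, logical(1)))
    if (length(active) && length(dz)) {
      ov <- matrix(0L, length(active), length(dz))
      for (a in seq_along(active)) {
        last_row <- chains[[active[a]]]$rows[[length(chains[[active[a]]]$rows)]]
        dil <- dilate_indices(det$pixels[[last_row]], dm)
        for (b in seq_along(dz)) {
          ov[a, b] <- overlap_px(dil, det$pixels[[dz[b]]])
        }
      }
      repeat {
        mx <- max(ov)
        if (mx < 1) break
        hits <- which(ov == mx, arr.ind = TRUE)
        if (nrow(hits) > 1) {
          # deterministic tie-break on the detection centroid (row, then col),
          # then on the chain's last centroid
          key <- order(det$centroid_row[dz[hits[, 2]]],
                       det$centroid_col[dz[hits[, 2]]],
                       vapply(hits[, 1], function(a) {
                         lr <- chains[[active[a]]]$rows
                         det$centroid_row[lr[[length(lr)]]]
                       }, numeric(1)))
          hits <- hits[key[1], , drop = FALSE]
        }
        a <- hits[1, 1]
        b <- hits[1, 2]
        ci <- active[a]
        chains[[ci]]$rows <- c(chains[[ci]]$rows, dz[b])
        chains[[ci]]$last_z <- z
        ov[a, ] <- -1L
        ov[, b] <- -1L
      }
      taken <- vapply(chains[active], function(ch) ch$last_z == z, logical(1))
      dz <- setdiff(dz, unlist(lapply(chains[active[taken]], function(ch) {
        ch$rows[[length(ch$rows)]]
      })))
    }
    for (b in dz) {
      chains[[length(chains) + 1L]] <- list(rows = list(b), last_z = z)
    }
  }
  spans <- vapply(chains, function(ch) {
    zz <- det$z[unlist(ch$rows)]
    c(min(zz), max(zz))
  }, numeric(2))
  keep <- which(spans[2, ] - spans[1, ] + 1 >= min_span)
  if (!length(keep)) {
    return(finish(empty, tibble::tibble(track_id = integer(),
                                        z_first = integer(),
                                        z_last = integer())))
  }
  out <- dplyr::bind_rows(lapply(seq_along(keep), function(i) {
    rows <- unlist(chains[[keep[i]]]$rows)
    d <- det[rows, c("z", "n_px", "centroid_row", "centroid_col",
                     "strong", "pixels")]
    d$track_id <- i
    d[, c("track_id", "z", "n_px", "centroid_row", "centroid_col",
          "strong", "pixels")]
  }))
  span_tbl <- tibble::tibble(
    track_id = seq_along(keep),
    z_first = as.integer(spans[1, keep]),
    z_last = as.integer(spans[2, keep])
  )
  finish(out, span_tbl)
}

# --- shape measurement -----------------------------------------------------

#' Minimum Feret diameter of a pixel mask
#'
#' Smallest caliper width of a detection over all orientations, the standard
#' proxy for tubule outer diameter in cross-section. Computed by rotating
#' calipers on the convex hull of the pixel-corner outline (pixel corners,
#' not centers, so a single pixel has width exactly one pixel).
#'
#' @param mask Either a logical matrix, or an integer vector of linear pixel
#'   indices (then `image_dim` is required).
#' @param pixel_size_nm Pixel size, nm (default 1: result in px).
#' @param image_dim Image dimensions when `mask` is an index vector.
#' @return Minimum Feret diameter in nm (or px when `pixel_size_nm = 1`).
#' @examples
#' m <- matrix(FALSE, 5, 12); m[2:4, 2:11] <- TRUE
#' min_feret_diameter(m, pixel_size_nm = 4) # 3 px * 4 nm = 12 nm
#' @export
min_feret_diameter <- function(mask, pixel_size_nm = 1, image_dim = NULL) {
  if (is.matrix(mask)) {
    idx <- which(mask)
    H <- nrow(mask)
  } else {
    if (is.null(image_dim)) stop("`image_dim` required for index masks",
                                 call. = FALSE)
    idx <- as.integer(mask)
    H <- image_dim[1]
  }
  if (!length(idx)) stop("empty mask", call. = FALSE)
  r <- ((idx - 1L) %% H) + 1L
  c_ <- ((idx - 1L) %/% H) + 1L
  # pixel-corner cloud
  x <- c(c_ - 0.5, c_ - 0.5, c_ + 0.5, c_ + 0.5)
  y <- c(r - 0.5, r + 0.5, r - 0.5, r + 0.5)
  hull <- grDevices::chull(x, y)
  hx <- x[hull]
  hy <- y[hull]
  n <- length(hull)
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    ex <- hx[j] - hx[i]
    ey <- hy[j] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) return(Inf)
    # distance of all hull points from the line through edge i
    max(abs((hx - hx[i]) * ey - (hy - hy[i]) * ex)) / len
  }, numeric(1))
  min(widths) * pixel_size_nm
}

# --- gap calling and metrics -----------------------------------------------

#' Occupancy vector of an axon's tracks
#'
#' @param tracks A `tubule_tracks` object.
#' @param n_sections Stack length; defaults to the tracks attribute.
#' @return Logical vector: `TRUE` where at least one track is detected.
#' @export
track_occupancy <- function(tracks, n_sections = attr(tracks, "n_sections")) {
  occ <- rep(FALSE, n_sections)
  if (nrow(tracks)) occ[tracks$z] <- TRUE
  occ
}

#' Call ER gaps from a per-section occupancy vector
#'
#' A gap is the complete loss of ER tubules from `min_gap_sections` (default
#' 3) or more consecutive sections of an axon. Absence runs touching the
#' first or last section are *censored* -- their true extent beyond the
#' imaged volume is unknowable -- and are reported with `censored = TRUE`
#' but excluded from gap counts and length metrics downstream.
#'
#' @param occupancy Logical vector, `TRUE` where the axon has any detected
#'   ER tubule in that section.
#' @param thickness_nm Section thickness, nm (default 60).
#' @param min_gap_sections Minimum run length to call (default 3).
#' @return Tibble of class `gap_calls`: `z_start`, `z_end` (1-based,
#'   inclusive), `n_sections`, `length_nm`, `censored`.
#' @examples
#' call_gaps(c(rep(TRUE, 10), rep(FALSE, 3), rep(TRUE, 7)))
#' @export
call_gaps <- function(occupancy, thickness_nm = 60, min_gap_sections = 3L) {
  occupancy <- as.logical(occupancy)
  n <- length(occupancy)
  r <- rle(!occupancy)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_run <- r$values & r$lengths >= min_gap_sections
  cens <- starts == 1L | ends == n
  keep <- is_run
  out <- tibble::tibble(
    z_start = as.integer(starts[keep]),
    z_end = as.integer(ends[keep]),
    n_sections = as.integer(r$lengths[keep]),
    censored = cens[keep]
  )
  out$length_nm <- out$n_sections * thickness_nm
  out <- out[, c("z_start", "z_end", "n_sections", "length_nm", "censored")]
  class(out) <- c("gap_calls", class(out))
  out
}

#' Per-axon ER network metrics
#'
#' Summarizes an axon's tracked ER over a serial-section segment: mean
#' tubules per cross-section, pooled minimum Feret diameters, and the gap
#' metrics (count per µm, percent of axon length in gaps, has-gap flag).
#' Censored gap calls do not contribute to any gap metric. An axon with no
#' tracked ER at all is flagged `no_er` and its gap metrics are `NA` -- the
#' absence of detectable ER is not the same as a 100% gap.
#'
#' @param tracks A `tubule_tracks` object.
#' @param gaps A `gap_calls` tibble for the same axon.
#' @param n_sections Number of sections analyzed (> 0).
#' @param thickness_nm Section thickness, nm (default 60).
#' @param pixel_size_nm Lateral pixel size for Feret diameters; when `NULL`
#'   diameters are omitted.
#' @return One-row tibble of class `axon_er_metrics`: `axon_id`, `n_tracks`,
#'   `mean_tubules_per_section`, `mean_feret_nm`, `n_gaps`, `gaps_per_um`,
#'   `percent_length_with_gaps`, `has_gap`, `no_er`; attributes
#'   `tubules_per_section` (per-z counts) and `feret_nm` (per detection).
#' @export
axon_er_metrics <- function(tracks, gaps, n_sections, thickness_nm = 60,
                            pixel_size_nm = NULL) {
  n_sections <- as.integer(n_sections)
  if (n_sections <= 0) stop("`n_sections` must be positive", call. = FALSE)
  per_z <- tabulate(tracks$z, nbins = n_sections)
  no_er <- nrow(tracks) == 0
  feret <- if (!is.null(pixel_size_nm) && nrow(tracks)) {
    vapply(tracks$pixels, min_feret_diameter, numeric(1),
           pixel_size_nm = pixel_size_nm, image_dim = attr(tracks, "image_dim"))
  } else {
    numeric(0)
  }
  real_gaps <- gaps[!gaps$censored, , drop = FALSE]
  len_um <- n_sections * thickness_nm / 1000
  out <- tibble::tibble(
    axon_id = attr(tracks, "axon_id") %||% 1L,
    n_tracks = length(unique(tracks$track_id)),
    mean_tubules_per_section = if (no_er) 0 else mean(per_z),
    mean_feret_nm = if (length(feret)) mean(feret) else NA_real_,
    n_gaps = if (no_er) NA_integer_ else nrow(real_gaps),
    gaps_per_um = if (no_er) NA_real_ else nrow(real_gaps) / len_um,
    percent_length_with_gaps =
      if (no_er) NA_real_ else 100 * sum(real_gaps$n_sections) / n_sections,
    has_gap = if (no_er) NA else nrow(real_gaps) >= 1,
    no_er = no_er
  )
  attr(out, "tubules_per_section") <- per_z
  attr(out, "feret_nm") <- feret
  class(out) <- c("axon_er_metrics", class(out))
  out
}

#' Length of a traced ER sheet or membrane profile
#'
#' Physical length of a hand-traced polyline (e.g. an ER sheet profile or a
#' glial membrane) as the sum of Euclidean segment lengths times the pixel
#' size.
#'
#' @param polyline n x 2 matrix of pixel coordinates, n >= 2.
#' @param pixel_size_nm Pixel size, nm.
#' @return Length in nm.
#' @examples
#' sheet_profile_length(rbind(c(0, 0), c(3, 4)), pixel_size_nm = 4) # 20
#' @export
sheet_profile_length <- function(polyline, pixel_size_nm = 1) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2 || ncol(polyline) != 2) {
    stop("polyline needs at least 2 (row, col) vertices", call. = FALSE)
  }
  sum(sqrt(rowSums(diff(polyline)^2))) * pixel_size_nm
}

#' Export tracked tubules as a 3-D label volume
#'
#' Renders each tubule track into an integer-labeled voxel volume (0 =
#' background), with the anisotropic voxel spacing recorded in attributes --
#' the raw material for downstream 3-D reconstruction or rendering.
#'
#' @param tracks A `tubule_tracks` object.
#' @param pixel_size_nm Lateral voxel size, nm.
#' @param thickness_nm Axial voxel size (section thickness), nm.
#' @return 3-D integer array of class `label_volume` with attribute
#'   `spacing_nm = c(pixel_size_nm, pixel_size_nm, thickness_nm)`.
#' @export
export_label_volume <- function(tracks, pixel_size_nm = 1,
                                thickness_nm = 60) {
  dm <- attr(tracks, "image_dim")
  nz <- attr(tracks, "n_sections")
  if (is.null(dm) || is.null(nz)) {
    stop("tracks lack stack geometry attributes", call. = FALSE)
  }
  vol <- array(0L, dim = c(dm[1], dm[2], nz))
  plane <- as.integer(dm[1]) * as.integer(dm[2])
  for (i in seq_len(nrow(tracks))) {
    vol[tracks$pixels[[i]] + (tracks$z[i] - 1L) * plane] <- tracks$track_id[i]
  }
  attr(vol, "spacing_nm") <- c(pixel_size_nm, pixel_size_nm, thickness_nm)
  class(vol) <- c("label_volume", class(vol))
  vol
}

# --- orchestrator ----------------------------------------------------------

#' Analyze a serial-section stack end to end
#'
#' Runs the full EM pipeline on one axon: per-section local-threshold
#' segmentation, persistence-based track linking with faint-signal rescue,
#' gap calling with boundary censoring, and per-axon metrics including
#' minimum Feret diameters.
#'
#' @param stack A [section_stack()]. ER-dark material (its `er_bright`
#'   flag `FALSE`) is inverted internally.
#' @param axon_roi Optional logical matrix restricting analysis to one axon.
#' @param strong_offset,faint_offset,window_px,min_px Passed to
#'   [segment_section()].
#' @param min_gap_sections Passed to [call_gaps()] (default 3).
#' @param min_span Passed to [link_tubule_tracks()] (default 3).
#' @return A list of class `er_stack_analysis` with elements `detections`,
#'   `tracks`, `occupancy`, `gaps`, `metrics`.
#' @examples
#' sim <- gen_section_stack(list(n_tubules = 1), n_sections = 20,
#'                          config = sim_config(seed = 1, noise_sd = 0),
#'                          brightness_sdlog = 0)
#' res <- analyze_section_stack(sim$stack)
#' res$metrics$mean_tubules_per_section
#' @export
analyze_section_stack <- function(stack, axon_roi = NULL, strong_offset = 5,
                                  faint_offset = 2.5, window_px = 31L,
                                  min_px = 2L, min_gap_sections = 3L,
                                  min_span = 3L) {
  stopifnot(inherits(stack, "section_stack"))
  nz <- dim(stack$data)[3]
  det <- dplyr::bind_rows(lapply(seq_len(nz), function(z) {
    d <- segment_section(stack$data[, , z], axon_roi = axon_roi,
                         strong_offset = strong_offset,
                         faint_offset = faint_offset,
                         window_px = window_px,
                         invert = !stack$er_bright, min_px = min_px)
    if (nrow(d)) d$z <- as.integer(z)
    d
  }))
  attr(det, "image_dim") <- dim(stack$data)[1:2]
  tracks <- link_tubule_tracks(det, n_sections = nz, min_span = min_span,
                               image_dim = dim(stack$data)[1:2])
  occ <- track_occupancy(tracks, nz)
  gaps <- call_gaps(occ, thickness_nm = stack$thickness_nm,
                    min_gap_sections = min_gap_sections)
  metrics <- axon_er_metrics(tracks, gaps, n_sections = nz,
                             thickness_nm = stack$thickness_nm,
                             pixel_size_nm = stack$pixel_size_nm)
  structure(
    list(detections = det, tracks = tracks, occupancy = occ, gaps = gaps,
         metrics = metrics),
    class = "er_stack_analysis"
  )
}
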