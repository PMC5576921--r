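# --- geometry helpers ------------------------------------------------------
# Pixel coordinates throughout are 0-based (row, col) with vertices at pixel
# centers; an image of H rows spans rows 0 .. H-1.

# uniform arc-length samples along a polyline; returns a matrix with the
# sample coordinates and the unit normal of the local segment
polyline_samples <- function(path, step_px = 1) {
  path <- as.matrix(path)
  if (nrow(path) < 2 || ncol(path) != 2) {
    stop("`path` must be an n x 2 matrix with n >= 2 vertices", call. = FALSE)
  }
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  if (all(seg_len == 0)) stop("polyline has zero length", call. = FALSE)
  total <- sum(seg_len)
  n <- max(2L, as.integer(ceiling(total / step_px)))
  s <- seq(0, by = step_px, length.out = n)
  s[s > total] <- total
  cum <- c(0, cumsum(seg_len))
  out <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, c("row", "col", "nrow", "ncol", "s")))
  for (i in seq_len(n)) {
    j <- findInterval(s[i], cum, rightmost.closed = TRUE)
    j <- min(j, nrow(seg))
    f <- if (seg_len[j] > 0) (s[i] - cum[j]) / seg_len[j] else 0
    p <- path[j, ] + f * seg[j, ]
    tang <- seg[j, ] / max(seg_len[j], 1e-12)
    out[i, ] <- c(p[1], p[2], -tang[2], tang[1], s[i])
  }
  out
}

# bilinear interpolation at 0-based (row, col) coordinates
bilinear_sample <- function(img, r, c_) {
  H <- nrow(img)
  W <- ncol(img)
  if (any(r < 0 | r > H - 1 | c_ < 0 | c_ > W - 1)) {
    stop("sample point outside image bounds", call. = FALSE)
  }
  r0 <- pmin(floor(r), H - 2)
  c0 <- pmin(floor(c_), W - 2)
  fr <- r - r0
  fc <- c_ - c0
  i00 <- cbind(r0 + 1, c0 + 1)
  img[i00] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 2, c0 + 1)] * fr * (1 - fc) +
    img[cbind(r0 + 1, c0 + 2)] * (1 - fr) * fc +
    img[cbind(r0 + 2, c0 + 2)] * fr * fc
}

#' Sample an intensity profile along a polyline
#'
#' Automates the manual "draw a line, record pixel intensity" measurement:
#' samples an image by bilinear interpolation at uniform arc-length steps
#' along a polyline and returns the result as an [intensity_profile()] with
#' positions in µm.
#'
#' @param image 2-D numeric matrix.
#' @param path Polyline, n x 2 matrix of 0-based `(row, col)` coordinates
#'   (vertices at pixel centers), inside the image.
#' @param step_px Arc-length step between samples, px (default 1).
#' @param pixel_size_um Physical pixel size, µm.
#' @param background,label Passed to [intensity_profile()].
#' @return An [intensity_profile()] with `ceiling(arc_length / step_px)`
#'   samples (minimum 2).
#' @export
sample_polyline <- function(image, path, step_px = 1, pixel_size_um = 1,
                            background = 0, label = "") {
  pts <- polyline_samples(path, step_px)
  vals <- bilinear_sample(image, pts[, "row"], pts[, "col"])
  intensity_profile(pmax(0, vals), pixel_size_um = step_px * pixel_size_um,
                    background = background, label = label,
                    position_um = pts[, "s"] * pixel_size_um)
}

# --- TIFF stacks -----------------------------------------------------------

#' Load a multi-page TIFF stack
#'
#' Reads an ordered multi-page grayscale TIFF (serial EM sections or
#' time-lapse frames) into a 3-D array, on the package's 0--255 intensity
#' convention. Physical calibration not present in the file must be supplied
#' by the caller and is then filled in with a warning, never silently.
#'
#' @param path TIFF file path.
#' @param kind `"serial"` (returns a [section_stack()]) or `"movie"`
#'   (returns the bare array with `frame_interval_s` attribute).
#' @param pixel_size_nm,thickness_nm Calibration for `kind = "serial"`.
#' @param pixel_size_um,frame_interval_s Calibration for `kind = "movie"`.
#' @return A [section_stack()] or a 3-D array `[row, col, frame]`.
#' @export
load_stack <- function(path, kind = c("serial", "movie"),
                       pixel_size_nm = NULL, thickness_nm = 60,
                       pixel_size_um = NULL, frame_interval_s = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("ragged TIFF: pages have differing shapes", call. = FALSE)
  }
  arr <- array(unlist(pages), dim = c(dims[1, 1], dims[2, 1], length(pages)))
  arr <- arr * 255 # readTIFF scales to [0, 1]
  if (kind == "serial") {
    if (is.null(pixel_size_nm)) {
      warning("no pixel size in file or call; using 4 nm/px default")
      pixel_size_nm <- 4
    } else {
      warning("pixel size taken from caller-supplied value, not file metadata")
    }
    section_stack(arr, pixel_size_nm = pixel_size_nm,
                  thickness_nm = thickness_nm)
  } else {
    if (is.null(frame_interval_s)) {
      warning("no frame interval in file or call; using 5 s default")
      frame_interval_s <- 5
    }
    attr(arr, "pixel_size_um") <- pixel_size_um %||% 1
    attr(arr, "frame_interval_s") <- frame_interval_s
    arr
  }
}

#' Write a stack or image to a multi-page TIFF
#'
#' Writes a 2-D matrix, 3-D array or [section_stack()] as (multi-page)
#' grayscale TIFF, mapping the package's 0--255 intensity convention onto the
#' file's unit scale. Values outside 0--255 are clipped.
#'
#' @param x Matrix, array `[row, col, page]`, or [section_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "section_stack")) x <- x$data
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
  pages <- lapply(seq_len(dim(x)[3]), function(z) {
    pmax(pmin(x[, , z] / 255, 1), 0)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

# --- ROI / config YAML -----------------------------------------------------

#' Read a ROI specification from YAML
#'
#' ROIs are named regions: rectangles (`c(row0, col0, row1, col1)`) and
#' polylines (list of `c(row, col)` vertices), 0-based pixel coordinates.
#' Typical labels: `bleach`, `axon`, `background`, `axon_roi`.
#'
#' @param path YAML file.
#' @param image_dim Optional `c(rows, cols)`; when given, coordinates are
#'   validated against the image bounds.
#' @return Named list with elements `rect` (4-vector) or `polyline`
#'   (n x 2 matrix) per ROI.
#' @export
read_roi_yaml <- function(path, image_dim = NULL) {
  raw <- yaml::read_yaml(path)
  rois <- lapply(raw, function(r) {
    if (!is.null(r$rect)) {
      list(rect = as.numeric(unlist(r$rect)))
    } else if (!is.null(r$polyline)) {
      m <- do.call(rbind, lapply(r$polyline, as.numeric))
      if (nrow(m) < 2) stop("polyline ROI needs >= 2 vertices", call. = FALSE)
      list(polyline = m)
    } else {
      stop("ROI entries must have a `rect` or `polyline` field", call. = FALSE)
    }
  })
  if (!is.null(image_dim)) {
    for (nm in names(rois)) {
      coords <- rois[[nm]]$rect %||% rois[[nm]]$polyline
      cm <- matrix(coords, ncol = 2, byrow = is.null(dim(coords)))
      if (any(cm < 0) || any(cm[, 1] > image_dim[1] - 1) ||
          any(cm[, 2] > image_dim[2] - 1)) {
        stop("ROI '", nm, "' exceeds image bounds", call. = FALSE)
      }
    }
  }
  rois
}

#' Write profiles or traces as tidy CSV
#'
#' Writes a two-column CSV (`position_um`/`time_s`, `intensity`) with a
#' header comment carrying units and the configuration hash for provenance.
#'
#' @param x An [intensity_profile()] or data frame.
#' @param path Output CSV path.
#' @param config Optional configuration object to hash into the header.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: um / intensity(0-255); config_hash: %s",
                     if (is.null(config)) "none" else config_hash(config)),
             con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a profile CSV written by [write_profile_csv()]
#'
#' @param path CSV path.
#' @param pixel_size_um Pixel size override; inferred from the position
#'   column spacing when omitted.
#' @param background,label Passed to [intensity_profile()].
#' @return An [intensity_profile()].
#' @export
read_profile_csv <- function(path, pixel_size_um = NULL, background = 0,
                             label = "") {
  df <- utils::read.csv(path, comment.char = "#")
  pos <- df[[1]]
  if (is.null(pixel_size_um)) pixel_size_um <- stats::median(diff(pos))
  intensity_profile(df[[2]], pixel_size_um = pixel_size_um,
                    background = background, label = label,
                    position_um = pos)
}
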