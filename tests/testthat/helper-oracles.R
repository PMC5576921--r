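# Independent reference implementations used as oracles. These are written
# as plain loops / brute force, deliberately sharing no code with the
# package internals they check.

# run-length gap oracle: scan a boolean occupancy vector element by element
# and emit every absence run of >= min_len sections, flagging runs that
# touch either end of the stack as censored.
oracle_call_gaps <- function(occ, min_len = 3L) {
  n <- length(occ)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (!occ[i]) {
      j <- i
      while (j < n && !occ[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) {
        out[[length(out) + 1L]] <-
          data.frame(z_start = i, z_end = j, n_sections = j - i + 1L,
                     censored = (i == 1L || j == n))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(z_start = integer(), z_end = integer(),
               n_sections = integer(), censored = logical())
  }
}

# 1-D sub-threshold interval oracle for profile gap detection
oracle_profile_gaps <- function(below, psz, min_um = 0) {
  n <- length(below)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1L]) j <- j + 1L
      if ((j - i + 1L) * psz >= min_um) {
        runs[[length(runs) + 1L]] <- c(start_px = i, end_px = j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(runs)) do.call(rbind, runs) else
    matrix(integer(), ncol = 2, dimnames = list(NULL, c("start_px", "end_px")))
}

# brute-force minimum Feret: minimum projected width of the pixel-corner
# cloud over rotations in steps of `step_deg` degrees
oracle_min_feret <- function(mask, step_deg = 0.5) {
  idx <- which(mask)
  H <- nrow(mask)
  r <- ((idx - 1L) %% H) + 1L
  c_ <- ((idx - 1L) %/% H) + 1L
  x <- c(c_ - 0.5, c_ - 0.5, c_ + 0.5, c_ + 0.5)
  y <- c(r - 0.5, r + 0.5, r - 0.5, r + 0.5)
  thetas <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(thetas, function(th) {
    proj <- x * cos(th) + y * sin(th)
    max(proj) - min(proj)
  }, numeric(1))
  min(widths)
}

# per-window normalized variance by direct loop
oracle_rolling_nv <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n - w + 1L), function(i) {
    win <- x[i:(i + w - 1L)]
    stats::var(win) / mean(win)
  }, numeric(1))
}

# exhaustive two-sided Mann-Whitney permutation p-value (no ties assumed)
oracle_mw_perm_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  u_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, function(ix) {
    sum(rank(pooled)[ix]) - nx * (nx + 1) / 2
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# random pixel blob (connected, possibly non-convex): grown from a seed
# pixel by repeated neighbor accretion
random_blob <- function(dim = c(24, 24), n_px = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, dim[1], dim[2])
  r <- sample(5:(dim[1] - 5), 1)
  c_ <- sample(5:(dim[2] - 5), 1)
  m[r, c_] <- TRUE
  for (i in seq_len(n_px - 1)) {
    edge <- which(m)
    k <- edge[sample.int(length(edge), 1)]
    rr <- ((k - 1) %% dim[1]) + 1 + sample(c(-1, 0, 1), 1)
    cc <- ((k - 1) %/% dim[1]) + 1 + sample(c(-1, 0, 1), 1)
    rr <- min(max(rr, 2), dim[1] - 1)
    cc <- min(max(cc, 2), dim[2] - 1)
    m[rr, cc] <- TRUE
  }
  m
}
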