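# Independent brute-force oracles, deliberately written with plain loops so
# they share no code path with the package implementation.

# Pixel-counting oracle for a disc mask: pixels whose center lies within
# radius_mm of the center (1-based pixel coordinates, spacing in mm).
oracle_disc_mask <- function(ny, nx, center, radius_mm, spacing) {
  m <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    d <- sqrt(((i - center[1]) * spacing[1])^2 +
              ((j - center[2]) * spacing[2])^2)
    if (d <= radius_mm) m[i, j] <- TRUE
  }
  m
}

# Exhaustive-enumeration oracle for the effective orifice area at one frame.
oracle_eoa <- function(vframe, mask, pixel_area) {
  vals <- c()
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j]) vals <- c(vals, vframe[i, j])
  vbar <- sum(vals) / length(vals)
  n_above <- 0
  for (v in vals) if (v > vbar) n_above <- n_above + 1
  n_above * pixel_area
}

# Bitmask enumeration oracle for the exact two-sided Mann-Whitney p, using
# the pairwise-comparison definition of U rather than ranks.
oracle_mw_exact <- function(x, y) {
  u_pairs <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b)
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  pooled <- c(x, y)
  n <- length(pooled); n1 <- length(x)
  u_obs <- u_pairs(x, y)
  us <- c()
  for (code in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (sum(sel) == n1)
      us <- c(us, u_pairs(pooled[sel], pooled[!sel]))
  }
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Quick noiseless phantom shared by several tests (small but >= 8 px radius).
noiseless_spec <- function(...) {
  args <- list(grid_shape = c(64L, 64L), n_frames = 40L, noise_sd = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}
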