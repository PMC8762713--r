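# Small phantoms and oracles shared across test files.

# A compact layered phantom: 24 x 48 lateral, 0.52 mm deep, one or two
# vessels. Fast to render; used wherever the full standard phantom would be
# overkill.
small_phantom_spec <- function(seed = 1L, speckle_L = Inf, mu = 0,
                               shadows = list(), vessels = NULL) {
  if (is.null(vessels))
    vessels <- list(list(centerline = rbind(c(0, 0.75, 0.28), c(1.2, 0.75, 0.28)),
                         radius = 0.08))
  phantom_spec(dim = c(24L, 48L, 104L),
               spacing = c(0.05, 0.03125, 0.005),
               top = 0.05, bm = 0.15, csi = 0.40,
               vessels = vessels, speckle_L = speckle_L,
               shadows = shadows, mu = mu, seed = seed)
}

# Brute-force masked Niblack oracle: direct loops, no integral images.
niblack_oracle <- function(img, window, k, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  rr <- (window[1] - 1) %/% 2; rc <- (window[2] - 1) %/% 2
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - rr):min(nr, i + rr)
    cj <- max(1, j - rc):min(nc, j + rc)
    vals <- img[ri, cj][valid[ri, cj]]
    if (!length(vals) || !valid[i, j]) next
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    out[i, j] <- img[i, j] < m + k * s
  }
  out
}

# Brute-force Otsu oracle: scan every midpoint between distinct values.
otsu_oracle <- function(x) {
  ux <- sort(unique(x))
  cand <- (head(ux, -1) + tail(ux, -1)) / 2
  bc <- vapply(cand, function(t) {
    lo <- x[x < t]; hi <- x[x >= t]
    (length(lo) / length(x)) * (length(hi) / length(x)) *
      (mean(lo) - mean(hi))^2
  }, numeric(1))
  cand[which.max(bc)]
}

# Brute-force pair-counting AUC oracle.
pair_auc_oracle <- function(d, h) {
  s <- 0
  for (x in d) for (y in h) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(d) * length(h))
}

# Logical array selecting a range of slow-axis indices.
slice_b <- function(nb, na, nz, bs) {
  out <- array(FALSE, c(nb, na, nz))
  out[bs, , ] <- TRUE
  out
}

# Random vessel mask inside a random slab, for invariant checks.
random_mask <- function(dim = c(8L, 10L, 20L), p = 0.3) {
  bm <- matrix(sample(2:6, prod(dim[1:2]), TRUE), dim[1], dim[2])
  csi <- bm + matrix(sample(3:10, prod(dim[1:2]), TRUE), dim[1], dim[2])
  csi <- pmin(csi, dim[3] + 1L)
  surf <- surface_pair(bm, csi, nz = dim[3])
  sl <- slab_mask(dim, surf)
  lab <- sl & array(stats::runif(prod(dim)) < p, dim)
  vessel_mask(lab, surf, c(0.03, 0.03, 0.005))
}
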