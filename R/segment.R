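# Composite choroidal vessel segmentation: Niblack local thresholding in
# B-scan and C-scan views plus global Otsu, fused by majority vote.
# Vessels are the hyporeflective (low-intensity) phase: vessel iff I < T.

#' Segmentation parameters
#'
#' Niblack thresholds are `T = m + k * s` over a sliding window, with `m`
#' and `s` the (population) mean and standard deviation of the in-slab
#' voxels inside the window; a voxel is vessel iff its intensity is
#' strictly below `T` (ties go to stroma). `k` is negative for dark
#' vessels; its magnitude sets how many local noise standard deviations
#' below the local mean a voxel must fall, so it trades sensitivity against
#' false positives in vessel-free stroma.
#'
#' @param window_bscan_mm Niblack window `(lateral, depth)` in mm for the
#'   B-scan view. Windows should exceed the calibre of the largest vessel
#'   of interest, or windows inside large lumens see a lumen-dominated
#'   local mean and miss the interior.
#' @param window_cscan_mm Niblack window `(slow, fast)` in mm for the C-scan
#'   view.
#' @param k Signed Niblack parameter (default -1.0, calibrated on the
#'   standard phantom). Values near 0 flag roughly half of any homogeneous
#'   noisy region (`pnorm(k)` of it), which percolates into uncleanable
#'   components in 3-D; `|k|` of about one noise SD rejects vessel-free
#'   stroma while keeping lumens several noise SDs below the local mean.
#' @param global_method Global thresholding method; only `"otsu"`.
#' @param combine_rule One of `"majority"`, `"union"`, `"intersection"`.
#' @param min_component Connected components (26-connectivity) smaller than
#'   this many voxels are removed after fusion.
#' @return A list of class `threshold_params`.
#' @export
threshold_params <- function(window_bscan_mm = c(1.2, 0.5),
                             window_cscan_mm = c(0.8, 0.8),
                             k = -1.0, global_method = "otsu",
                             combine_rule = c("majority", "union", "intersection"),
                             min_component = 200L) {
  combine_rule <- match.arg(combine_rule)
  stopifnot(all(window_bscan_mm > 0), all(window_cscan_mm > 0),
            min_component >= 0)
  if (!identical(global_method, "otsu"))
    stop("unknown global thresholding method: ", global_method, call. = FALSE)
  structure(list(window_bscan_mm = window_bscan_mm,
                 window_cscan_mm = window_cscan_mm, k = k,
                 global_method = global_method, combine_rule = combine_rule,
                 min_component = as.integer(min_component)),
            class = "threshold_params")
}

# Box sums over a wr x wc window (truncated at borders) via integral images.
# Outer-indexed corner lookups give the full (nr, nc) result at once.
box_sums <- function(M, wr, wc) {
  nr <- nrow(M); nc <- ncol(M)
  rr <- (wr - 1L) %/% 2L; rc <- (wc - 1L) %/% 2L
  S <- matrix(apply(M, 2, cumsum), nr, nc)
  S <- t(matrix(apply(S, 1, cumsum), nc, nr))
  Sp <- matrix(0, nr + 1L, nc + 1L)
  Sp[-1L, -1L] <- S
  r1 <- pmax(seq_len(nr) - rr, 1L); r2 <- pmin(seq_len(nr) + rr, nr)
  c1 <- pmax(seq_len(nc) - rc, 1L); c2 <- pmin(seq_len(nc) + rc, nc)
  Sp[r2 + 1L, c2 + 1L] - Sp[r1, c2 + 1L] - Sp[r2 + 1L, c1] + Sp[r1, c1]
}

#' Niblack threshold surface of a 2-D image
#'
#' The local threshold `T = m + k * s` over a sliding `window` (odd
#' extents, truncated at borders), with `m` and `s` the mean and population
#' standard deviation of the `valid` pixels in the window. Pixels whose
#' window holds no valid neighbour get `NA`.
#'
#' @param img Numeric matrix.
#' @param window Odd window extents `(rows, cols)` in pixels.
#' @param k Signed Niblack parameter.
#' @param valid Logical matrix of pixels entering the statistics
#'   (default: all).
#' @return Matrix of thresholds.
#' @examples
#' niblack_threshold(matrix(1:9, 3, 3), window = c(3, 3), k = -0.2)[2, 2]
#' # 5 - 0.2 * sqrt(20/3) = 4.4836
#' @export
niblack_threshold <- function(img, window = c(3L, 3L), k = -0.2,
                              valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(img), ncol(img))
  if (any(window %% 2L == 0L)) stop("window extents must be odd", call. = FALSE)
  v <- valid * 1
  n <- box_sums(v, window[1], window[2])
  s1 <- box_sums(img * v, window[1], window[2])
  s2 <- box_sums(img * img * v, window[1], window[2])
  m <- s1 / pmax(n, 1)
  va <- pmax(s2 / pmax(n, 1) - m^2, 0)
  Tm <- m + k * sqrt(va)
  Tm[n == 0] <- NA_real_
  Tm
}

# Masked Niblack on one 2-D slice: statistics use only `valid` pixels.
# The strict inequality carries a relative guard so integral-image rounding
# (a few ULPs on the window mean) cannot flag pixels of a constant region.
niblack_slice <- function(img, valid, wr, wc, k) {
  Tm <- niblack_threshold(img, c(wr, wc), k, valid)
  tol <- 1e-9 * (abs(Tm) + 1)
  valid & !is.na(Tm) & (img < Tm - tol)
}

#' Niblack local thresholding in the B-scan view
#'
#' Applies the Niblack rule per B-scan with a 2-D `(lateral, depth)`
#' window. Window statistics use only in-slab voxels, so retinal and
#' scleral intensities never leak into the local mean; the mask is zero
#' outside the slab.
#'
#' @param vol An [oct_volume()] (typically enhanced).
#' @param surfaces A [surface_pair()] delimiting the choroid slab.
#' @param params A [threshold_params()].
#' @return A [vessel_mask()].
#' @export
niblack_mask_bscan <- function(vol, surfaces, params = threshold_params()) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$intensities)
  sl <- slab_mask(d, surfaces)
  wa <- odd_window(params$window_bscan_mm[1], vol$spacing[2])
  wz <- odd_window(params$window_bscan_mm[2], vol$spacing[3])
  if (wa > d[2] || wz > d[3])
    stop("Niblack window exceeds the B-scan plane", call. = FALSE)
  out <- array(FALSE, d)
  for (b in seq_len(d[1])) {
    out[b, , ] <- niblack_slice(vol$intensities[b, , ], sl[b, , ],
                                wa, wz, params$k)
  }
  vessel_mask(out, surfaces, vol$spacing)
}

#' Niblack local thresholding in the C-scan view
#'
#' Flattens the volume to Bruch's membrane (unless already flattened),
#' applies the Niblack rule on each en-face slice with a 2-D lateral
#' window, and maps the mask back to original depth coordinates. Because
#' vessels at the same depth below BM have similar calibre, this view
#' improves connectivity across vessel sizes.
#'
#' @param x An [oct_volume()] or a `flattened_volume`.
#' @param surfaces A [surface_pair()] (ignored for flattened input).
#' @param params A [threshold_params()].
#' @return A [vessel_mask()] in original (unflattened) coordinates.
#' @export
niblack_mask_cscan <- function(x, surfaces = NULL, params = threshold_params()) {
  flat <- if (inherits(x, "flattened_volume")) x else flatten(x, surfaces)
  d <- dim(flat$intensities)
  wb <- odd_window(params$window_cscan_mm[1], flat$spacing[1])
  wa <- odd_window(params$window_cscan_mm[2], flat$spacing[2])
  if (wb > d[1] || wa > d[2])
    stop("Niblack window exceeds the C-scan plane", call. = FALSE)
  thick <- flat$surfaces$csi - flat$surfaces$bm
  ref <- flat$reference_depth
  outf <- array(FALSE, d)
  for (off in 0:(max(thick) - 1L)) {
    valid <- off < thick
    if (!any(valid)) break
    z <- ref + off
    outf[, , z] <- niblack_slice(flat$intensities[, , z], valid,
                                 wb, wa, params$k)
  }
  out <- unflatten(flat, outf) > 0
  vessel_mask(array(out, d), flat$surfaces, flat$spacing)
}

#' Otsu threshold of a numeric sample
#'
#' Exact Otsu on the empirical distribution: the split of the sorted values
#' maximizing the between-class variance `w0 * w1 * (mu0 - mu1)^2`,
#' evaluated at every boundary between distinct values; the returned
#' threshold is the midpoint of the optimal pair (ties to the lower
#' threshold). No histogram binning is involved.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  ux <- unique(x)
  if (length(ux) < 2L)
    stop("Otsu threshold undefined: sample has a single distinct value",
         call. = FALSE)
  cs <- cumsum(x)
  # candidate splits at the last occurrence of each distinct value
  idx <- cumsum(tabulate(match(x, ux)))[-length(ux)]
  w0 <- idx / n
  mu0 <- cs[idx] / idx
  mu1 <- (cs[n] - cs[idx]) / (n - idx)
  bc <- w0 * (1 - w0) * (mu0 - mu1)^2
  i <- which.max(bc)                      # which.max takes the lower tie
  (ux[i] + ux[i + 1L]) / 2
}

#' Global thresholding of the choroid slab
#'
#' One Otsu threshold over all in-slab intensities; vessel iff `I < T`.
#' Best suited to large dilated vessels that defeat local windows.
#'
#' @param vol An [oct_volume()].
#' @param surfaces A [surface_pair()].
#' @param method Only `"otsu"`.
#' @return A [vessel_mask()] with the chosen threshold attached as
#'   attribute `"threshold"`.
#' @export
global_mask <- function(vol, surfaces, method = "otsu") {
  stopifnot(inherits(vol, "oct_volume"), identical(method, "otsu"))
  sl <- slab_mask(dim(vol$intensities), surfaces)
  if (!any(sl)) stop("empty slab", call. = FALSE)
  Tg <- otsu_threshold(vol$intensities[sl])
  m <- vessel_mask(sl & (vol$intensities < Tg), surfaces, vol$spacing)
  attr(m, "threshold") <- Tg
  m
}

#' Fuse the three view segmentations
#'
#' Voxelwise vote over congruent masks (default: majority, vessel iff at
#' least 2 of 3 agree), followed by removal of 26-connected components
#' smaller than `min_component` voxels. The pre-cleanup result always lies
#' between the intersection and the union of the inputs.
#'
#' @param masks List of [vessel_mask()] objects over the same slab.
#' @param rule `"majority"`, `"union"` or `"intersection"`.
#' @param min_component Minimum surviving component size in voxels.
#' @return A [vessel_mask()].
#' @export
combine_masks <- function(masks, rule = c("majority", "union", "intersection"),
                          min_component = 27L) {
  rule <- match.arg(rule)
  stopifnot(length(masks) >= 1)
  d <- dim(masks[[1]]$labels)
  for (m in masks)
    if (!identical(dim(m$labels), d))
      stop("masks are not congruent", call. = FALSE)
  votes <- Reduce(`+`, lapply(masks, function(m) m$labels * 1L))
  need <- switch(rule,
                 majority = ceiling((length(masks) + 1) / 2),
                 union = 1L,
                 intersection = length(masks))
  lab <- votes >= need
  lab <- remove_small_components(lab, min_component)
  vessel_mask(lab, masks[[1]]$slab, masks[[1]]$spacing)
}

#' Remove small 26-connected components from a binary 3-D mask
#'
#' @param mask Logical 3-D array.
#' @param min_component Components with fewer voxels are dropped.
#' @return Logical 3-D array.
#' @export
remove_small_components <- function(mask, min_component) {
  if (min_component <= 1L || !any(mask)) return(mask)
  lab <- label_components26_cpp(as.vector(mask), dim(mask))
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes >= min_component
  out <- array(FALSE, dim(mask))
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Stroma mask: the slab complement of the vessel mask
#'
#' Vessel and stroma voxel counts partition the slab exactly.
#'
#' @param vessel A [vessel_mask()].
#' @return A [vessel_mask()] whose labels mark stroma voxels.
#' @export
stroma_mask <- function(vessel) {
  stopifnot(inherits(vessel, "vessel_mask"))
  sl <- slab_mask(dim(vessel$labels), vessel$slab)
  vessel_mask(sl & !vessel$labels, vessel$slab, vessel$spacing)
}

#' Dice similarity of two masks
#'
#' `2 |A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param pred,truth [vessel_mask()] objects or logical arrays of equal
#'   shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  a <- if (inherits(pred, "vessel_mask")) pred$labels else pred
  b <- if (inherits(truth, "vessel_mask")) truth$labels else truth
  if (!identical(dim(a), dim(b))) stop("mask shapes differ", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Composite vessel segmentation
#'
#' Convenience wrapper running the three views on an enhanced volume and
#' fusing them with the configured rule.
#'
#' @param vol An enhanced [oct_volume()].
#' @param surfaces A [surface_pair()].
#' @param params A [threshold_params()].
#' @return A list with the fused `vessel` mask, the per-view masks
#'   (`bscan`, `cscan`, `global`) and the global threshold.
#' @export
segment_choroid <- function(vol, surfaces, params = threshold_params()) {
  flat <- flatten(vol, surfaces)
  mb <- niblack_mask_bscan(vol, surfaces, params)
  mc <- niblack_mask_cscan(flat, params = params)
  mg <- global_mask(vol, surfaces, params$global_method)
  fused <- combine_masks(list(mb, mc, mg), rule = params$combine_rule,
                         min_component = params$min_component)
  list(vessel = fused, bscan = mb, cscan = mc, global = mg,
       global_threshold = attr(mg, "threshold"))
}
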