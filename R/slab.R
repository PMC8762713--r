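# Choroid slab handling: phantom surface detection, BM flattening, C-scans.

#' Detect layer surfaces on a phantom-like volume
#'
#' A simple gradient finder for synthetic volumes with high-contrast layer
#' boundaries (real-data layer segmentation is an input to this package,
#' not a feature). Per A-line, the retinal surface is the strongest
#' positive axial gradient; BM is the first strong positive gradient at
#' least `margin_mm` deeper (the retina is darker than the choroidal
#' stroma); the CSI is the deepest strong negative gradient below BM
#' (vessel boundaries lie above it). The volume is median-denoised and
#' axially smoothed first, and the resulting depth maps are median-filtered
#' laterally.
#'
#' @param vol An [oct_volume()].
#' @param margin_mm Minimum retina thickness separating the retinal surface
#'   from the BM search range.
#' @param axial_sigma Gaussian smoothing (voxels) applied along depth before
#'   differentiation.
#' @param lateral_sigma Gaussian smoothing (voxels) applied along both
#'   lateral axes; layer boundaries vary slowly laterally, so this prior
#'   suppresses speckle without biasing the edge depth.
#' @param lateral_median Odd lateral median window (voxels) applied to the
#'   detected depth maps.
#' @param min_contrast Minimum axial gradient magnitude; a flat A-line with
#'   no gradient above this raises a detection error naming the A-line.
#' @return A [surface_pair()].
#' @export
detect_surfaces_phantom <- function(vol, margin_mm = 0.1, axial_sigma = 2,
                                    lateral_sigma = 1.5, lateral_median = 5L,
                                    min_contrast = 0.01) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$intensities)
  arr <- median_filter3_cpp(vol$intensities, d, c(3L, 3L, 3L))
  if (lateral_sigma > 0) {
    arr <- convolve_axis(arr, gauss_kernel(lateral_sigma), 1L)
    arr <- convolve_axis(arr, gauss_kernel(lateral_sigma), 2L)
  }
  arr <- convolve_axis(arr, gauss_kernel(axial_sigma), 3L)
  nz <- d[3]
  # forward difference: g[, , z] = I[, , z + 1] - I[, , z]
  g <- arr[, , 2:nz, drop = FALSE] - arr[, , 1:(nz - 1), drop = FALSE]
  margin <- max(1L, as.integer(round(margin_mm / vol$spacing[3])))
  bm <- matrix(NA_integer_, d[1], d[2])
  csi <- matrix(NA_integer_, d[1], d[2])
  # argmax inside the first (or last) contiguous run of strong gradients;
  # the run keeps vessel-wall edges deeper in the slab from hijacking BM/CSI
  run_peak <- function(seg, thr, first = TRUE) {
    hit <- seg >= thr
    if (!any(hit)) return(NA_integer_)
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    k <- if (first) runs[1] else runs[length(runs)]
    idx <- starts[k]:ends[k]
    idx[which.max(seg[idx])]
  }
  for (b in seq_len(d[1])) {
    gb <- g[b, , ]                       # na x (nz - 1)
    zs <- max.col(gb, ties.method = "first")
    gmax <- gb[cbind(seq_len(d[2]), zs)]
    for (a in seq_len(d[2])) {
      if (gmax[a] < min_contrast)
        stop(sprintf("no layer gradient found at B-scan %d, A-line %d", b, a),
             call. = FALSE)
      lo <- zs[a] + margin
      if (lo > nz - 1)
        stop(sprintf("no choroid found below the retina at B-scan %d, A-line %d",
                     b, a), call. = FALSE)
      seg <- gb[a, lo:(nz - 1)]
      p <- run_peak(seg, min_contrast, first = TRUE)
      if (is.na(p))
        stop(sprintf("no BM gradient at B-scan %d, A-line %d", b, a),
             call. = FALSE)
      bm[b, a] <- lo + p - 1L + 1L       # edge z -> first slab voxel z + 1
      seg2 <- gb[a, bm[b, a]:(nz - 1)]
      p2 <- run_peak(-seg2, min_contrast, first = FALSE)
      if (is.na(p2))
        stop(sprintf("no CSI gradient at B-scan %d, A-line %d", b, a),
             call. = FALSE)
      csi[b, a] <- bm[b, a] + p2 - 1L + 1L
    }
  }
  w <- as.integer(lateral_median)
  if (w > 1) {
    bm <- matrix(median_filter3_cpp(array(as.numeric(bm), c(d[1:2], 1L)),
                                    c(d[1:2], 1L), c(w, w, 1L)), d[1])
    csi <- matrix(median_filter3_cpp(array(as.numeric(csi), c(d[1:2], 1L)),
                                     c(d[1:2], 1L), c(w, w, 1L)), d[1])
    bm <- round(bm); csi <- round(csi)
  }
  csi <- pmax(csi, bm + 1)
  surface_pair(bm, pmin(csi, nz + 1L), nz = nz)
}

#' Flatten a volume with respect to Bruch's membrane
#'
#' Shifts each A-line axially by an integer so that BM sits at a constant
#' reference depth; voxels shifted out of range are padded with zeros. The
#' shift map is stored, making the operation invertible on its support, and
#' integer shifts keep voxel counts conservative.
#'
#' @param vol An [oct_volume()].
#' @param surfaces A [surface_pair()].
#' @param reference_depth Depth index BM is moved to; defaults to
#'   `max(bm)` so that no A-line shifts upward. The whole slab must stay
#'   inside the depth range.
#' @return An object of class `flattened_volume` with fields `intensities`,
#'   `spacing`, `reference_depth`, `shift` (per-A-line applied shift),
#'   `surfaces_flat` and `surfaces` (the originals).
#' @export
flatten <- function(vol, surfaces, reference_depth = NULL) {
  stopifnot(inherits(vol, "oct_volume"), inherits(surfaces, "surface_pair"))
  d <- dim(vol$intensities)
  if (is.null(reference_depth)) reference_depth <- max(surfaces$bm)
  reference_depth <- as.integer(reference_depth)
  if (reference_depth < 1L || reference_depth > d[3])
    stop("reference_depth out of range", call. = FALSE)
  if (reference_depth + max(surfaces$csi - surfaces$bm) > d[3] + 1L)
    stop("slab does not fit below reference_depth; lower it", call. = FALSE)
  shift <- reference_depth - surfaces$bm
  out <- shift_volume(vol$intensities, shift)
  surf_flat <- surface_pair(
    matrix(reference_depth, d[1], d[2]),
    matrix(reference_depth + (surfaces$csi - surfaces$bm), d[1], d[2]),
    nz = d[3]
  )
  structure(list(intensities = out, spacing = vol$spacing,
                 reference_depth = reference_depth, shift = shift,
                 surfaces_flat = surf_flat, surfaces = surfaces),
            class = "flattened_volume")
}

# Apply per-A-line integer axial shifts (positive = deeper), zero padding.
shift_volume <- function(arr, shift) {
  d <- dim(arr)
  out <- array(0, d)
  nbna <- prod(d[1:2])
  for (sv in sort(unique(as.vector(shift)))) {
    lat <- which(shift == sv)
    zsrc <- max(1L, 1L - sv):min(d[3], d[3] - sv)
    for (z in zsrc)
      out[lat + (z + sv - 1L) * nbna] <- arr[lat + (z - 1L) * nbna]
  }
  out
}

#' Undo flattening
#'
#' @param flat A `flattened_volume` (or a 3-D array plus the `shift` map).
#' @param arr Optional array in flattened coordinates to unshift instead of
#'   the stored intensities (e.g. a mask computed in the C-scan view).
#' @return An [oct_volume()] (or a plain array when `arr` is given).
#' @export
unflatten <- function(flat, arr = NULL) {
  stopifnot(inherits(flat, "flattened_volume"))
  if (is.null(arr)) {
    oct_volume(shift_volume(flat$intensities, -flat$shift), flat$spacing)
  } else {
    shift_volume(arr, -flat$shift)
  }
}

#' @export
print.flattened_volume <- function(x, ...) {
  cat(sprintf("<flattened_volume> BM at depth %d; shifts in [%d, %d]\n",
              x$reference_depth, min(x$shift), max(x$shift)))
  invisible(x)
}

#' Extract the choroid-slab voxel mask
#'
#' @param x An [oct_volume()] or `flattened_volume`.
#' @param surfaces A [surface_pair()] (ignored for flattened input, which
#'   carries its own).
#' @return Logical 3-D array marking `bm <= z < csi` voxels.
#' @export
extract_slab <- function(x, surfaces = NULL) {
  if (inherits(x, "flattened_volume"))
    return(slab_mask(dim(x$intensities), x$surfaces_flat))
  stopifnot(inherits(x, "oct_volume"), inherits(surfaces, "surface_pair"))
  slab_mask(dim(x$intensities), surfaces)
}

#' En-face C-scan slice at a fixed offset below Bruch's membrane
#'
#' @param flat A `flattened_volume`.
#' @param offset Integer voxels below BM, `0 <= offset < max slab depth`.
#' @return A `(nb, na)` matrix; A-lines whose slab ends above the offset
#'   are `NA`.
#' @export
cscan <- function(flat, offset) {
  stopifnot(inherits(flat, "flattened_volume"))
  thick <- flat$surfaces$csi - flat$surfaces$bm
  offset <- as.integer(offset)
  if (offset < 0L || offset >= max(thick))
    stop("offset out of the slab depth range", call. = FALSE)
  sl <- flat$intensities[, , flat$reference_depth + offset]
  sl[offset >= thick] <- NA_real_
  sl
}
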