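# Domain types and I/O: OCT volumes, layer surfaces, vessel masks, en-face maps.

#' Construct an OCT volume
#'
#' An `oct_volume` carries a 3-D grid of non-negative, arbitrary-unit
#' reflectivities indexed `(b, a, z)` (slow axis, fast axis, depth) together
#' with the physical voxel spacing in mm.
#'
#' @param intensities 3-D numeric array, all values >= 0.
#' @param spacing Numeric length-3 vector `(db, da, dz)` in mm per voxel,
#'   all > 0.
#' @return An object of class `oct_volume` with elements `intensities` and
#'   `spacing`.
#' @examples
#' vol <- oct_volume(array(runif(4 * 5 * 6), c(4, 5, 6)), c(0.03, 0.03, 0.005))
#' voxel_volume(vol)
#' @export
oct_volume <- function(intensities, spacing) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (db, da, dz) in mm", call. = FALSE)
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative", call. = FALSE)
  structure(list(intensities = intensities, spacing = spacing),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<oct_volume> %d x %d x %d voxels (b, a, z)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.4g x %.4g x %.4g mm; extent: %.3g x %.3g x %.3g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              d[1] * x$spacing[1], d[2] * x$spacing[2], d[3] * x$spacing[3]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' The product of the three spacing components, in mm^3. Volumes of labelled
#' regions are obtained by multiplying voxel counts by this quantity.
#'
#' @param vol An [oct_volume()], or a numeric length-3 spacing vector.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(vol) {
  sp <- if (inherits(vol, "oct_volume")) vol$spacing else as.numeric(vol)
  if (length(sp) != 3L || any(sp <= 0)) stop("need three positive spacings", call. = FALSE)
  prod(sp)
}

#' Construct a pair of layer surfaces delimiting the choroid slab
#'
#' Depth-index grids of Bruch's membrane (BM) and the choroidal-scleral
#' interface (CSI), one value per A-line. Indices are 1-based voxel indices;
#' the slab is half-open, `bm <= z < csi`, so a column contributes
#' `csi - bm` voxels.
#'
#' @param bm,csi Integer matrices of shape `(nb, na)` with `1 <= bm < csi`.
#' @param nz Optional depth extent used to validate `csi <= nz + 1`.
#' @return An object of class `surface_pair` with elements `bm` and `csi`.
#' @export
surface_pair <- function(bm, csi, nz = NULL) {
  bm <- as.matrix(bm); csi <- as.matrix(csi)
  if (!identical(dim(bm), dim(csi)))
    stop("`bm` and `csi` grids must have identical shape", call. = FALSE)
  if (any(bm != round(bm)) || any(csi != round(csi)))
    stop("surface depths must be integer voxel indices", call. = FALSE)
  storage.mode(bm) <- "integer"; storage.mode(csi) <- "integer"
  if (any(bm < 1L)) stop("bm depth indices must be >= 1", call. = FALSE)
  if (any(bm >= csi))
    stop("surfaces cross: bm must be strictly above csi at every A-line", call. = FALSE)
  if (!is.null(nz) && any(csi > nz + 1L))
    stop("csi exceeds the depth extent of the volume", call. = FALSE)
  structure(list(bm = bm, csi = csi), class = "surface_pair")
}

#' @export
print.surface_pair <- function(x, ...) {
  cat(sprintf("<surface_pair> %d x %d A-lines; bm in [%d, %d], csi in [%d, %d]\n",
              nrow(x$bm), ncol(x$bm), min(x$bm), max(x$bm), min(x$csi), max(x$csi)))
  invisible(x)
}

#' Logical mask of choroid-slab voxels
#'
#' Marks every voxel between BM (inclusive) and CSI (exclusive). The total
#' count equals `sum(csi - bm)`.
#'
#' @param dim Integer length-3 volume dimensions `(nb, na, nz)`.
#' @param surfaces A [surface_pair()] congruent with the lateral shape.
#' @return Logical 3-D array.
#' @export
slab_mask <- function(dim, surfaces) {
  stopifnot(inherits(surfaces, "surface_pair"))
  if (!identical(as.integer(dim[1:2]), as.integer(dim(surfaces$bm))))
    stop("surface grids do not match the volume's lateral shape", call. = FALSE)
  nz <- dim[3]
  z <- rep(seq_len(nz), each = prod(dim[1:2]))
  out <- z >= as.vector(surfaces$bm) & z < as.vector(surfaces$csi)
  array(out, dim)
}

#' Construct a vessel mask bound to its choroid slab
#'
#' Binary per-voxel vessel labels. Labels must vanish outside the slab; this
#' is checked, not assumed.
#'
#' @param labels Logical or 0/1 3-D array.
#' @param surfaces The [surface_pair()] the mask was computed within.
#' @param spacing Voxel spacing in mm (kept for volume computations).
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(labels, surfaces, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array", call. = FALSE)
  if (is.numeric(labels)) {
    if (any(labels != 0 & labels != 1)) stop("labels must be 0/1", call. = FALSE)
    labels <- array(labels == 1, dim(labels))
  }
  sl <- slab_mask(dim(labels), surfaces)
  if (any(labels & !sl))
    stop("vessel labels found outside the [bm, csi) slab", call. = FALSE)
  structure(list(labels = labels, slab = surfaces, spacing = as.numeric(spacing)),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  n <- sum(x$labels)
  ns <- sum(x$slab$csi - x$slab$bm)
  cat(sprintf("<vessel_mask> %d vessel voxels / %d slab voxels (%.1f%%)\n",
              n, ns, 100 * n / max(ns, 1)))
  invisible(x)
}

#' Construct an en-face map
#'
#' A 2-D lateral map obtained by aggregating a volumetric quantity along
#' depth at each A-line.
#'
#' @param values Non-negative numeric matrix `(nb, na)`.
#' @param units One of `"mm3"`, `"mm"`, `"dimensionless"`.
#' @param spacing Lateral spacing `(db, da)` in mm.
#' @return An object of class `en_face_map`.
#' @export
en_face_map <- function(values, units = c("mm3", "mm", "dimensionless"),
                        spacing) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("map values must be >= 0", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("`spacing` must be (db, da) in mm", call. = FALSE)
  structure(list(values = values, units = units, spacing = spacing),
            class = "en_face_map")
}

#' @export
print.en_face_map <- function(x, ...) {
  cat(sprintf("<en_face_map> %d x %d A-lines [%s]; sum = %.5g, max = %.4g\n",
              nrow(x$values), ncol(x$values), x$units,
              sum(x$values), max(x$values)))
  invisible(x)
}

format_of_path <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return("tiff")
  stop("unsupported volume format (use .nii, .nii.gz, .tif or .tiff): ", path,
       call. = FALSE)
}

#' Read an OCT volume from NIfTI or multi-page TIFF
#'
#' TIFF pages are B-scans: page `b` holds the `(a, z)` plane. NIfTI arrays
#' are stored directly in `(b, a, z)` order. Integer-valued payloads are
#' rescaled to `[0, 1]` by the global maximum so thresholding stages see a
#' stable intensity scale; floating-point payloads are taken as-is.
#'
#' @param path File path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param extent Lateral physical extent `(slow, fast)` in mm used to derive
#'   spacing as extent / axis length. For NIfTI, defaults to the header
#'   spacing when present; otherwise `c(9, 12)`.
#' @param dz Axial pixel pitch in mm; default 0.0026 when the header has
#'   none.
#' @return An [oct_volume()].
#' @export
read_volume <- function(path, extent = NULL, dz = NULL) {
  fmt <- format_of_path(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- unclass(as.array(img))
    attributes(arr) <- list(dim = dim(arr))
    if (length(dim(arr)) != 3L)
      stop("NIfTI payload is not 3-D: ", paste(dim(arr), collapse = "x"),
           call. = FALSE)
    pd <- RNifti::pixdim(img)
    sp <- c(
      if (!is.null(extent)) extent[1] / dim(arr)[1] else if (length(pd) >= 1 && pd[1] > 0) pd[1] else 9 / dim(arr)[1],
      if (!is.null(extent)) extent[2] / dim(arr)[2] else if (length(pd) >= 2 && pd[2] > 0) pd[2] else 12 / dim(arr)[2],
      if (!is.null(dz)) dz else if (length(pd) >= 3 && pd[3] > 0) pd[3] else 0.0026
    )
    int_like <- grepl("int", RNifti::niftiHeader(img)$datatype_string %||% "") ||
      is.integer(arr)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!length(pages)) stop("empty TIFF: ", path, call. = FALSE)
    d2 <- dim(pages[[1]])
    if (length(d2) != 2L) stop("TIFF pages must be single-channel 2-D images",
                               call. = FALSE)
    arr <- array(0, c(length(pages), d2))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    if (is.null(extent)) extent <- c(9, 12)
    if (is.null(dz)) dz <- 0.0026
    sp <- c(extent[1] / dim(arr)[1], extent[2] / dim(arr)[2], dz)
    # integer payloads arrive scaled by the dtype maximum; renormalise by
    # the observed maximum instead (float payloads pass through untouched)
    bps <- attr(pages[[1]], "bits.per.sample") %||% 8L
    int_like <- !identical(attr(pages[[1]], "sample.format"), "float") &&
      bps < 32L
  }
  if (!is.null(extent)) {
    if (length(extent) != 2L || any(extent <= 0))
      stop("`extent` must be two positive lengths in mm", call. = FALSE)
  }
  if (int_like) {
    mx <- max(arr)
    if (mx > 0) arr <- arr / mx
  }
  oct_volume(arr, sp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an OCT volume to NIfTI or multi-page TIFF
#'
#' NIfTI carries the voxel spacing in its header. TIFF is written as one
#' 32-bit float page per B-scan and requires intensities in `[0, 1]`
#' (values are clipped with a warning otherwise); spacing must then be
#' re-supplied on read.
#'
#' @param vol An [oct_volume()].
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  fmt <- format_of_path(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(vol$intensities)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else {
    arr <- vol$intensities
    if (min(arr) < 0 || max(arr) > 1) {
      warning("TIFF export clips intensities to [0, 1]")
      arr <- pmin(pmax(arr, 0), 1)
    }
    pages <- lapply(seq_len(dim(arr)[1]), function(b) arr[b, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read and write surface pairs as CSV
#'
#' Long-format CSV with columns `surface` (`"bm"` or `"csi"`), `b`, `a`, and
#' `depth` (1-based voxel index).
#'
#' @param path CSV file path.
#' @return `read_surfaces()` returns a [surface_pair()];
#'   `write_surfaces()` returns `path` invisibly.
#' @export
read_surfaces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("surface", "b", "a", "depth")
  if (!all(need %in% names(df)))
    stop("surface CSV must have columns surface, b, a, depth", call. = FALSE)
  grids <- lapply(c("bm", "csi"), function(s) {
    sub <- df[df$surface == s, ]
    if (!nrow(sub)) stop("surface CSV lacks rows for '", s, "'", call. = FALSE)
    nb <- max(sub$b); na <- max(sub$a)
    if (nrow(sub) != nb * na) stop("incomplete '", s, "' grid", call. = FALSE)
    m <- matrix(NA_real_, nb, na)
    m[cbind(sub$b, sub$a)] <- sub$depth
    m
  })
  surface_pair(grids[[1]], grids[[2]])
}

#' @rdname read_surfaces
#' @param surfaces A [surface_pair()] to serialize.
#' @export
write_surfaces <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "surface_pair"))
  nb <- nrow(surfaces$bm); na <- ncol(surfaces$bm)
  idx <- expand.grid(b = seq_len(nb), a = seq_len(na))
  df <- rbind(
    data.frame(surface = "bm", idx, depth = as.vector(surfaces$bm)),
    data.frame(surface = "csi", idx, depth = as.vector(surfaces$csi))
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write en-face maps as CSV
#'
#' Long-format CSV with columns `b`, `a`, `value` plus metadata columns
#' `units`, `db`, `da` repeated on every row.
#'
#' @param path CSV file path.
#' @return `read_map()` returns an [en_face_map()]; `write_map()` returns
#'   `path` invisibly.
#' @export
read_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  nb <- max(df$b); na <- max(df$a)
  m <- matrix(NA_real_, nb, na)
  m[cbind(df$b, df$a)] <- df$value
  en_face_map(m, units = df$units[1], spacing = c(df$db[1], df$da[1]))
}

#' @rdname read_map
#' @param map An [en_face_map()] to serialize.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "en_face_map"))
  idx <- expand.grid(b = seq_len(nrow(map$values)), a = seq_len(ncol(map$values)))
  df <- data.frame(idx, value = as.vector(map$values), units = map$units,
                   db = map$spacing[1], da = map$spacing[2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a vessel mask as a 0/1 volume
#'
#' @param mask A [vessel_mask()].
#' @param path Destination (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "vessel_mask"))
  vol <- oct_volume(array(as.numeric(mask$labels), dim(mask$labels)),
                    mask$spacing)
  write_volume(vol, path)
}
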