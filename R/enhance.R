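# Volume enhancement: denoise -> shadow reduction -> attenuation
# compensation -> local contrast enhancement, in that fixed order.

odd_window <- function(mm, d) max(1L, 2L * as.integer(floor(mm / (2 * d))) + 1L)

#' Speckle denoising
#'
#' Classical despeckling filters behind one strategy interface. `"median"`
#' runs a 3-D running median (the default; robust to the heavy-tailed
#' multiplicative speckle), `"gaussian"` a separable Gaussian, `"nlm"` a
#' per-B-scan non-local means.
#'
#' @param vol An [oct_volume()].
#' @param method One of `"median"`, `"gaussian"`, `"nlm"`.
#' @param size Odd window extents (voxels) for the median filter; scalar or
#'   length 3.
#' @param sigma Gaussian standard deviations (voxels); scalar or length 3.
#' @param search_radius,patch_radius,h Non-local means controls; `h` is the
#'   similarity bandwidth as a fraction of the slice intensity SD.
#' @return A denoised [oct_volume()] of identical shape and spacing.
#' @export
denoise <- function(vol, method = c("median", "gaussian", "nlm"),
                    size = 3L, sigma = 1, search_radius = 5L,
                    patch_radius = 1L, h = 0.8) {
  stopifnot(inherits(vol, "oct_volume"))
  method <- match.arg(method)
  arr <- vol$intensities
  if (method == "median") {
    w <- rep_len(as.integer(size), 3L)
    if (any(w %% 2L == 0L)) stop("median window extents must be odd", call. = FALSE)
    out <- median_filter3_cpp(arr, dim(arr), w)
  } else if (method == "gaussian") {
    sg <- rep_len(as.numeric(sigma), 3L)
    out <- arr
    for (ax in 1:3) {
      if (sg[ax] <= 0) next
      out <- convolve_axis(out, gauss_kernel(sg[ax]), ax)
    }
  } else {
    out <- arr
    sdev <- stats::sd(arr)
    if (sdev > 0) {
      for (b in seq_len(dim(arr)[1]))
        out[b, , ] <- nlm2_cpp(arr[b, , ], as.integer(search_radius),
                               as.integer(patch_radius), h * sdev)
    }
  }
  out[out < 0] <- 0
  oct_volume(out, vol$spacing)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable 1-D convolution along one array axis with border renormalisation
# (the truncated kernel is rescaled to unit mass at the edges).
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- matrix(aperm(arr, perm), d[axis])
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  # banded convolution matrix, rows renormalised where the kernel is clipped
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + kernel[j]
  }
  K <- K / rowSums(K)
  y <- K %*% x
  aperm(array(y, d[perm]), order(perm))
}

#' Per-A-line energy profile
#'
#' Sums each A-line's intensity over the full depth (`raw`) and smooths the
#' resulting lateral map with a 2-D running median (`smoothed`). Shadows
#' cast by retinal vessels appear as narrow dips in `raw` that the median
#' removes when the window exceeds the shadow width.
#'
#' @param vol An [oct_volume()].
#' @param window_mm Lateral smoothing extent in mm, converted per axis to
#'   odd voxel windows.
#' @return An object of class `energy_profile` with `raw`, `smoothed`
#'   matrices and the window used.
#' @export
energy_profile <- function(vol, window_mm = 0.5) {
  stopifnot(inherits(vol, "oct_volume"), window_mm > 0)
  raw <- rowSums(vol$intensities, dims = 2L)
  w <- c(odd_window(window_mm, vol$spacing[1]),
         odd_window(window_mm, vol$spacing[2]))
  sm <- median_filter3_cpp(array(raw, c(dim(raw), 1L)),
                           c(dim(raw), 1L), c(w, 1L))
  structure(list(raw = raw, smoothed = matrix(sm, nrow(raw)),
                 window_mm = window_mm, window_vox = w),
            class = "energy_profile")
}

#' Retinal-vessel shadow reduction
#'
#' Normalizes each A-line by its energy relative to the median-smoothed
#' lateral energy profile: `I'(b,a,z) = I(b,a,z) * smoothed(b,a) /
#' max(raw(b,a), eps)`. A pure per-column rescaling, so intensity ratios
#' within an A-line — its contrast — are preserved exactly; after
#' correction the A-line energy equals the smoothed profile wherever
#' `raw > eps`.
#'
#' @param vol An [oct_volume()].
#' @param window_mm Profile smoothing window in mm (should exceed the
#'   retinal-vessel shadow width, typically 0.05-0.15 mm; default 0.5).
#' @param eps Energy floor guarding empty A-lines.
#' @return A corrected [oct_volume()].
#' @export
shadow_reduce <- function(vol, window_mm = 0.5, eps = 1e-8) {
  stopifnot(inherits(vol, "oct_volume"))
  ep <- energy_profile(vol, window_mm)
  scale <- ep$smoothed / pmax(ep$raw, eps)
  out <- vol$intensities * as.vector(scale)  # (b,a) recycles along z
  oct_volume(out, vol$spacing)
}

#' Depth attenuation compensation
#'
#' Rescales each depth sample by the remaining depth-integrated signal
#' below it: `I_c(b,a,z) = I^n / (2 * max(sum_{z' >= z} I^n, eps))`.
#' Restores contrast in the deep choroid where the beam has been
#' attenuated; for an exponentially decaying A-line the compensated profile
#' is flat up to the finite-tail truncation. Output lies in `[0, 0.5]`, and
#' the deepest positive sample maps to exactly 0.5 when it is the whole
#' remaining tail.
#'
#' @param vol An [oct_volume()].
#' @param n Contrast exponent applied before compensation (> 0).
#' @param eps Tail-energy floor; all-zero tails yield zero output.
#' @return A compensated [oct_volume()].
#' @export
attenuation_compensate <- function(vol, n = 1, eps = 1e-8) {
  stopifnot(inherits(vol, "oct_volume"), n > 0)
  arr <- vol$intensities
  d <- dim(arr)
  P <- matrix(aperm(arr^n, c(3, 1, 2)), d[3])
  U <- upper.tri(diag(d[3]), diag = TRUE) * 1  # tail-sum operator
  tails <- U %*% P
  out <- P / (2 * pmax(tails, eps))
  out[tails < eps] <- 0
  oct_volume(aperm(array(out, c(d[3], d[1], d[2])), c(2, 3, 1)), vol$spacing)
}

#' Local contrast enhancement (per-B-scan CLAHE)
#'
#' Contrast-limited adaptive histogram equalization applied slice-wise to
#' each B-scan, with tile sizes given in mm. Constant slices pass through
#' unchanged.
#'
#' @param vol An [oct_volume()].
#' @param tile_mm Tile extents `(lateral, depth)` in mm; at least 2 tiles
#'   per axis are enforced.
#' @param clip CLAHE clip limit (multiples of the uniform bin height);
#'   `Inf` gives plain tile-wise equalization.
#' @param bins Histogram bins.
#' @param log_compress Apply the standard OCT log display compression
#'   `log(1 + x / floor)` before equalization, so a large dynamic range
#'   (e.g. after attenuation compensation) is not squeezed into a few
#'   histogram bins. The floor is `1e-4` of the volume maximum.
#' @return An enhanced [oct_volume()] with intensities in `[0, 1]`.
#' @export
local_contrast_enhance <- function(vol, tile_mm = c(1, 0.25), clip = 4,
                                   bins = 512L, log_compress = TRUE) {
  stopifnot(inherits(vol, "oct_volume"))
  if (any(tile_mm <= 0)) stop("tile sizes must be > 0", call. = FALSE)
  arr <- vol$intensities
  if (diff(range(arr)) == 0) return(vol)   # constant volumes pass through
  mx <- max(arr)
  if (log_compress && mx > 0) {
    arr <- log1p(arr / (1e-4 * mx))
    mx <- max(arr)
  }
  # CLAHE operates on [0, 1]
  if (mx > 1) arr <- arr / mx
  d <- dim(arr)
  nx <- max(2L, as.integer(round(d[2] * vol$spacing[2] / tile_mm[1])))
  ny <- max(2L, as.integer(round(d[3] * vol$spacing[3] / tile_mm[2])))
  lim <- if (is.infinite(clip)) bins else clip
  out <- arr
  for (b in seq_len(d[1])) {
    sl <- arr[b, , ]
    if (diff(range(sl)) == 0) next
    r <- EBImage::clahe(sl, nx = nx, ny = ny, bins = bins, limit = lim)
    out[b, , ] <- as.numeric(r)
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  oct_volume(out, vol$spacing)
}

#' Enhancement pipeline configuration
#'
#' Stage order is fixed (denoise, shadow, attenuation, contrast); each stage
#' can be toggled. Unknown fields and any reordering of `order` are
#' rejected.
#'
#' @param denoise,shadow,attenuation,contrast Logical stage switches.
#' @param denoise_method,denoise_size Passed to [denoise()].
#' @param shadow_window_mm Passed to [shadow_reduce()].
#' @param attenuation_n Passed to [attenuation_compensate()].
#' @param tile_mm,clip Passed to [local_contrast_enhance()].
#' @param eps Numerical floor shared by shadow and attenuation stages.
#' @return A list of class `enhance_config`.
#' @export
enhance_config <- function(denoise = TRUE, shadow = TRUE, attenuation = TRUE,
                           contrast = TRUE, denoise_method = "median",
                           denoise_size = c(3L, 3L, 7L), shadow_window_mm = 0.5,
                           attenuation_n = 1, tile_mm = c(1, 0.25), clip = 4,
                           eps = 1e-8) {
  structure(list(order = c("denoise", "shadow", "attenuation", "contrast"),
                 denoise = denoise, shadow = shadow,
                 attenuation = attenuation, contrast = contrast,
                 denoise_method = denoise_method, denoise_size = denoise_size,
                 shadow_window_mm = shadow_window_mm,
                 attenuation_n = attenuation_n, tile_mm = tile_mm,
                 clip = clip, eps = eps),
            class = "enhance_config")
}

validate_enhance_config <- function(config) {
  ref <- enhance_config()
  extra <- setdiff(names(config), names(ref))
  if (length(extra))
    stop("unknown enhancement config fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  config <- modifyList(unclass(ref), unclass(config))
  if (!identical(config$order, ref$order))
    stop("the stage order is fixed: denoise, shadow, attenuation, contrast",
         call. = FALSE)
  config
}

#' Run the full enhancement pipeline
#'
#' Applies the enabled stages in the fixed order denoise -> shadow
#' reduction -> attenuation compensation -> local contrast enhancement.
#' With every stage disabled this is the identity. All stages are
#' deterministic.
#'
#' @param vol An [oct_volume()].
#' @param config An [enhance_config()] (or plain named list of overrides).
#' @param verbose Emit one message per stage with its timing.
#' @return The enhanced [oct_volume()].
#' @export
enhance_pipeline <- function(vol, config = enhance_config(), verbose = FALSE) {
  stopifnot(inherits(vol, "oct_volume"))
  cf <- validate_enhance_config(config)
  stage <- function(name, on, fun) {
    if (!on) return(invisible(NULL))
    t0 <- proc.time()[3]
    vol <<- fun(vol)
    if (verbose)
      message(sprintf("stage %-12s %.2fs", name, proc.time()[3] - t0))
  }
  stage("denoise", cf$denoise, function(v)
    denoise(v, method = cf$denoise_method, size = cf$denoise_size))
  stage("shadow", cf$shadow, function(v)
    shadow_reduce(v, window_mm = cf$shadow_window_mm, eps = cf$eps))
  stage("attenuation", cf$attenuation, function(v)
    attenuation_compensate(v, n = cf$attenuation_n, eps = cf$eps))
  stage("contrast", cf$contrast, function(v)
    local_contrast_enhance(v, tile_mm = cf$tile_mm, clip = cf$clip))
  vol
}
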