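# Synthetic layered OCT phantoms with per-voxel vessel ground truth.
#
# The phantom emulates the degradations the enhancement pipeline removes:
# multiplicative L-look Gamma speckle, columnar retinal-vessel shadows cast
# below Bruch's membrane, and exponential depth attenuation from the retinal
# surface. Tissue is a layered vitreous/retina/choroid/sclera model with
# hyporeflective tubular vessels embedded in the choroid slab.

#' Specification for a synthetic OCT phantom
#'
#' All geometry is in mm; voxel centers sit at `(i - 0.5) * spacing`. Layer
#' depths may be scalars (flat layers) or `(nb, na)` matrices (smooth
#' fields). Vessels are tubes around centerline polylines; a voxel belongs
#' to a vessel iff its center lies within the radius of the centerline.
#'
#' @param dim Grid size `(nb, na, nz)`.
#' @param spacing Voxel spacing `(db, da, dz)` in mm.
#' @param top,bm,csi Depths (mm) of the retinal surface, Bruch's membrane
#'   and the choroidal-scleral interface; scalar or `(nb, na)` matrix.
#' @param vessels List of vessels, each a list with `centerline` (n x 3
#'   matrix of (b, a, z) mm coordinates), `radius` (mm) and optionally
#'   `lumen` intensity.
#' @param intensities Named list of tissue reflectivities:
#'   `vitreous`, `retina`, `stroma`, `sclera`, `lumen` (vessels are
#'   hyporeflective: `lumen < stroma`).
#' @param speckle_L Number of looks of the multiplicative Gamma speckle
#'   (`Inf` disables speckle; smaller L = noisier, contrast `1/sqrt(L)`).
#' @param shadows List of shadow columns, each a list with `center` (fast
#'   axis position, mm), `width` (mm) and `transmission` in (0, 1]; the
#'   factor multiplies every voxel below BM in the lateral footprint.
#' @param mu Attenuation coefficient in 1/mm, applied as
#'   `exp(-mu * depth-below-retinal-surface)`.
#' @param seed Integer seed making the speckle field reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96L, 192L, 208L),
                         spacing = c(0.03125, 0.03125, 0.005),
                         top = 0.10, bm = 0.30, csi = 0.80,
                         vessels = list(),
                         intensities = list(vitreous = 0.02, retina = 0.45,
                                            stroma = 0.60, sclera = 0.45,
                                            lumen = 0.20),
                         speckle_L = Inf, shadows = list(), mu = 0,
                         seed = 1L) {
  stopifnot(length(dim) == 3L, all(dim >= 2), length(spacing) == 3L,
            all(spacing > 0))
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0", call. = FALSE)
  if (!(speckle_L > 0)) stop("speckle_L must be > 0", call. = FALSE)
  for (v in vessels) {
    if (is.null(v$radius) || v$radius <= 0) stop("vessel radius must be > 0", call. = FALSE)
    lum <- v$lumen %||% intensities$lumen
    if (lum >= intensities$stroma)
      stop("vessel lumen must be darker than stroma", call. = FALSE)
  }
  for (s in shadows) {
    if (s$transmission <= 0 || s$transmission > 1)
      stop("shadow transmission must be in (0, 1]", call. = FALSE)
    if (s$width <= 0) stop("shadow width must be > 0", call. = FALSE)
  }
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 top = top, bm = bm, csi = csi, vessels = vessels,
                 intensities = intensities, speckle_L = speckle_L,
                 shadows = shadows, mu = mu, seed = as.integer(seed)),
            class = "phantom_spec")
}

as_field <- function(x, nb, na) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == nb, ncol(x) == na)
    x
  } else matrix(x, nb, na)
}

# First voxel index whose center depth is >= the boundary depth in mm.
depth_to_index <- function(depth_mm, dz) as.integer(ceiling(depth_mm / dz + 0.5))

#' The standard validation phantom
#'
#' A 3 x 6 mm lateral patch with a 0.5 mm-thick choroid containing six
#' straight cylindrical vessels of radii 0.05-0.2 mm running the full fast
#' axis, 4-look speckle, two retinal-vessel shadow columns and attenuation
#' 0.5/mm. This is the fixture used throughout validation; vessels occupy
#' about 21% of the slab.
#'
#' @param seed Integer seed for the speckle field.
#' @param speckle_L,shadows_on,mu Overrides for ablation experiments.
#' @return A `phantom_spec`.
#' @export
standard_phantom_spec <- function(seed = 1L, speckle_L = 4,
                                  shadows_on = TRUE, mu = 0.5) {
  # vessels run along the slow axis with a slight fast-axis drift, so each
  # B-scan crosses them as compact elliptical lumens (as in real choroids)
  radii <- c(0.05, 0.08, 0.10, 0.125, 0.16, 0.20)
  apos <- c(0.50, 1.40, 2.30, 3.20, 4.20, 5.20)
  drift <- c(0.25, -0.20, 0.30, -0.25, 0.20, 0.25)
  zpos <- c(0.45, 0.62, 0.50, 0.66, 0.56, 0.55)
  vessels <- lapply(seq_along(radii), function(i)
    list(centerline = rbind(c(0, apos[i], zpos[i]),
                            c(3, apos[i] + drift[i], zpos[i])),
         radius = radii[i]))
  shadows <- if (shadows_on)
    list(list(center = 1.85, width = 0.12, transmission = 0.5),
         list(center = 4.70, width = 0.10, transmission = 0.4))
  else list()
  phantom_spec(vessels = vessels, speckle_L = speckle_L, shadows = shadows,
               mu = mu, seed = seed)
}

#' Render a phantom volume with ground truth
#'
#' Renders the clean layered tissue model, then applies (i) multiplicative
#' Gamma(L, 1/L) speckle i.i.d. per voxel, (ii) shadow columns multiplying
#' all voxels below BM in their footprint by the transmission factor, and
#' (iii) depth attenuation `exp(-mu * max(0, z - top))` measured from the
#' retinal surface. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_truth`: list with `volume`
#'   ([oct_volume()]), `vessel_truth` ([vessel_mask()]), `surfaces`
#'   ([surface_pair()]), `clean` (the noiseless [oct_volume()]) and
#'   `analytic` (tibble of per-vessel analytic volumes, pi r^2 L for
#'   straight tubes).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nb <- spec$dim[1]; na <- spec$dim[2]; nz <- spec$dim[3]
  db <- spec$spacing[1]; da <- spec$spacing[2]; dz <- spec$spacing[3]
  bc <- (seq_len(nb) - 0.5) * db
  ac <- (seq_len(na) - 0.5) * da
  zc <- (seq_len(nz) - 0.5) * dz

  topf <- as_field(spec$top, nb, na)
  bmf  <- as_field(spec$bm, nb, na)
  csif <- as_field(spec$csi, nb, na)
  if (any(topf >= bmf) || any(bmf >= csif))
    stop("layer depths must satisfy top < bm < csi", call. = FALSE)
  ti <- spec$intensities

  # layered tissue, built by depth comparison against the (recycled) fields
  zarr <- array(rep(zc, each = nb * na), spec$dim)
  arr <- array(ti$vitreous, spec$dim)
  arr[zarr >= c(topf)] <- ti$retina
  arr[zarr >= c(bmf)]  <- ti$stroma
  arr[zarr >= c(csif)] <- ti$sclera

  # vessels: voxel centers within radius of a centerline, clipped to the slab
  sl <- zarr >= c(bmf) & zarr < c(csif)
  truth <- array(FALSE, spec$dim)
  analytic <- numeric(length(spec$vessels))
  for (vi in seq_along(spec$vessels)) {
    v <- spec$vessels[[vi]]
    cl <- v$centerline
    if (any(cl[, 1] < 0 | cl[, 1] > nb * db | cl[, 3] < 0 | cl[, 3] > nz * dz))
      stop("vessel ", vi, " centerline leaves the grid", call. = FALSE)
    r <- v$radius
    lum <- v$lumen %||% ti$lumen
    seg_len <- 0
    vmask <- array(FALSE, spec$dim)
    for (si in seq_len(nrow(cl) - 1L)) {
      p0 <- cl[si, ]; p1 <- cl[si + 1L, ]
      seg <- p1 - p0
      L2 <- sum(seg^2)
      seg_len <- seg_len + sqrt(L2)
      ib <- which(bc >= min(p0[1], p1[1]) - r & bc <= max(p0[1], p1[1]) + r)
      ia <- which(ac >= min(p0[2], p1[2]) - r & ac <= max(p0[2], p1[2]) + r)
      iz <- which(zc >= min(p0[3], p1[3]) - r & zc <= max(p0[3], p1[3]) + r)
      if (!length(ib) || !length(ia) || !length(iz)) next
      g <- expand.grid(b = bc[ib], a = ac[ia], z = zc[iz])
      w <- if (L2 > 0)
        pmin(pmax(((g$b - p0[1]) * seg[1] + (g$a - p0[2]) * seg[2] +
                     (g$z - p0[3]) * seg[3]) / L2, 0), 1)
      else 0
      d2 <- (g$b - (p0[1] + w * seg[1]))^2 +
            (g$a - (p0[2] + w * seg[2]))^2 +
            (g$z - (p0[3] + w * seg[3]))^2
      inside <- array(d2 <= r^2, c(length(ib), length(ia), length(iz)))
      vmask[ib, ia, iz] <- vmask[ib, ia, iz] | inside
    }
    analytic[vi] <- pi * r^2 * seg_len
    arr[vmask & sl] <- lum
    truth <- truth | vmask
  }
  truth <- truth & sl
  clean <- arr

  # degradations: speckle, shadows, attenuation (all multiplicative)
  if (is.finite(spec$speckle_L)) {
    L <- spec$speckle_L
    arr <- withr::with_seed(spec$seed,
      arr * array(rgamma(length(arr), shape = L, rate = L), spec$dim))
  }
  if (length(spec$shadows)) {
    below_bm <- zarr >= c(bmf)
    for (s in spec$shadows) {
      cols <- abs(ac - s$center) < s$width / 2
      if (!any(cols)) next
      fac <- array(1, spec$dim)
      fac[, cols, ][below_bm[, cols, ]] <- s$transmission
      arr <- arr * fac
    }
  }
  if (spec$mu > 0) {
    depth_below <- pmax(zarr - array(rep(c(topf), nz), spec$dim), 0)
    arr <- arr * exp(-spec$mu * depth_below)
  }

  surf <- surface_pair(
    matrix(depth_to_index(bmf, dz), nb, na),
    matrix(depth_to_index(csif, dz), nb, na),
    nz = nz
  )
  structure(list(
    volume = oct_volume(arr, spec$spacing),
    clean = oct_volume(clean, spec$spacing),
    vessel_truth = vessel_mask(truth, surf, spec$spacing),
    surfaces = surf,
    analytic = tibble::tibble(
      vessel = seq_along(spec$vessels),
      radius_mm = vapply(spec$vessels, `[[`, numeric(1), "radius"),
      volume_mm3 = analytic
    ),
    spec = spec
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>\n")
  print(x$volume)
  print(x$vessel_truth)
  cat(sprintf("  analytic vessel volume: %.4f mm^3 over %d vessels\n",
              sum(x$analytic$volume_mm3), nrow(x$analytic)))
  invisible(x)
}

#' Speckle contrast (coefficient of variation) in a region
#'
#' The ratio sd/mean of the intensities in a region; the canonical
#' homogeneity metric for multiplicative speckle. For L-look Gamma speckle
#' on constant tissue the expected value is `1/sqrt(L)`. Scale-invariant.
#'
#' @param vol An [oct_volume()] or numeric array.
#' @param region Logical array congruent with the volume, or `NULL` for the
#'   whole grid.
#' @return Dimensionless scalar; 0 for a constant region.
#' @export
speckle_contrast <- function(vol, region = NULL) {
  arr <- if (inherits(vol, "oct_volume")) vol$intensities else vol
  vals <- if (is.null(region)) as.vector(arr) else arr[region]
  if (!length(vals)) stop("empty region", call. = FALSE)
  m <- mean(vals)
  if (m == 0) return(0)
  stats::sd(vals) / m
}
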