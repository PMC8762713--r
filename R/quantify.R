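# Quantitative en-face maps, ETDRS regional aggregation, vessel index.
# All volumes follow the pixel-counting rule: count x voxel volume.

#' En-face vessel volume map
#'
#' `V(b, a) = (number of vessel voxels in the A-line) * voxel volume`, in
#' mm^3 per A-line footprint. The map total equals the mask voxel count
#' times the voxel volume exactly (integer arithmetic before the final
#' product).
#'
#' @param mask A [vessel_mask()].
#' @param spacing Voxel spacing; defaults to the mask's.
#' @return An [en_face_map()] in mm^3.
#' @export
vessel_volume_map <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (is.null(spacing)) spacing <- mask$spacing
  counts <- rowSums(mask$labels, dims = 2L)
  en_face_map(counts * voxel_volume(spacing), units = "mm3",
              spacing = spacing[1:2])
}

#' En-face choroid volume (or thickness) map
#'
#' `C(b, a) = (csi - bm) * voxel volume` in mm^3, or `(csi - bm) * dz` in
#' mm when `thickness = TRUE`.
#'
#' @param surfaces A [surface_pair()].
#' @param spacing Voxel spacing `(db, da, dz)` in mm.
#' @param thickness Return thickness in mm instead of volume in mm^3.
#' @return An [en_face_map()].
#' @export
choroid_volume_map <- function(surfaces, spacing, thickness = FALSE) {
  stopifnot(inherits(surfaces, "surface_pair"))
  counts <- surfaces$csi - surfaces$bm
  if (thickness)
    en_face_map(counts * spacing[3], units = "mm", spacing = spacing[1:2])
  else
    en_face_map(counts * voxel_volume(spacing), units = "mm3",
                spacing = spacing[1:2])
}

#' ETDRS grid specification
#'
#' Concentric rings of 1, 3 and 6 mm diameter centred on the macula with
#' superior/inferior/nasal/temporal quadrants whose boundaries run at 45
#' degrees to the horizontal (fast) axis. Orientation convention: the fast
#' axis is horizontal, the slow axis vertical with `b` increasing
#' inferiorly; for a right eye (OD) the nasal side is the +a direction and
#' for a left eye (OS) the -a direction.
#'
#' @param center Grid centre `(b, a)` in mm, or `NULL` for the lateral scan
#'   centre.
#' @param diameters Strictly increasing ring diameters in mm.
#' @param laterality `"OD"` or `"OS"`.
#' @return A list of class `etdrs_grid`.
#' @export
etdrs_grid <- function(center = NULL, diameters = c(1, 3, 6),
                       laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  if (length(diameters) != 3L || any(diff(diameters) <= 0))
    stop("`diameters` must be three strictly increasing values", call. = FALSE)
  structure(list(center = center, diameters = diameters,
                 laterality = laterality),
            class = "etdrs_grid")
}

etdrs_region_names <- function() {
  c("central",
    paste0("inner_", c("superior", "inferior", "nasal", "temporal")),
    paste0("outer_", c("superior", "inferior", "nasal", "temporal")))
}

# Assign each A-line footprint centre to an ETDRS region (or NA outside the
# outer ring). Membership is by footprint centre; no partial-area weighting.
etdrs_membership <- function(map, grid) {
  nb <- nrow(map$values); na <- ncol(map$values)
  db <- map$spacing[1]; da <- map$spacing[2]
  center <- grid$center %||% c(nb * db / 2, na * da / 2)
  if (center[1] < 0 || center[1] > nb * db ||
      center[2] < 0 || center[2] > na * da)
    stop("grid centre lies outside the scan extent", call. = FALSE)
  bc <- (seq_len(nb) - 0.5) * db - center[1]
  ac <- (seq_len(na) - 0.5) * da - center[2]
  dy <- matrix(-bc, nb, na)                 # superior = up = decreasing b
  dx <- matrix(ac, nb, na, byrow = TRUE)
  if (grid$laterality == "OS") dx <- -dx    # nasal flips with laterality
  r <- sqrt(dx^2 + dy^2)
  rad <- grid$diameters / 2
  ring <- ifelse(r < rad[1], 1L, ifelse(r < rad[2], 2L, ifelse(r < rad[3], 3L, NA)))
  quad <- ifelse(abs(dy) > abs(dx),
                 ifelse(dy > 0, "superior", "inferior"),
                 ifelse(dx > 0, "nasal", "temporal"))
  out <- matrix(NA_character_, nb, na)
  out[!is.na(ring) & ring == 1L] <- "central"
  sel <- !is.na(ring) & ring == 2L
  out[sel] <- paste0("inner_", quad[sel])
  sel <- !is.na(ring) & ring == 3L
  out[sel] <- paste0("outer_", quad[sel])
  out
}

#' Aggregate an en-face map over the ETDRS regions
#'
#' Sums the map over the central subfield (1 mm diameter), the four inner
#' (1-3 mm) and four outer (3-6 mm) quadrants, and reports the full 6-mm
#' circle as their total. Regions are disjoint by construction, so the
#' nine subregion sums add up to the circle sum exactly.
#'
#' @param map An [en_face_map()].
#' @param grid An [etdrs_grid()].
#' @return A tibble with columns `region`, `value`, `n_alines`.
#' @export
etdrs_aggregate <- function(map, grid = etdrs_grid()) {
  stopifnot(inherits(map, "en_face_map"))
  mem <- etdrs_membership(map, grid)
  regions <- etdrs_region_names()
  vals <- vapply(regions, function(rg)
    sum(map$values[!is.na(mem) & mem == rg]), numeric(1))
  ns <- vapply(regions, function(rg)
    sum(!is.na(mem) & mem == rg), numeric(1))
  tibble::tibble(
    region = c(regions, "circle_6mm"),
    value = unname(c(vals, sum(vals))),
    n_alines = as.integer(unname(c(ns, sum(ns))))
  )
}

#' Choroidal vessel index
#'
#' `VI = 100 * Vv / Vc` percent, the ratio of vessel volume to total
#' choroidal volume. Undefined (NA) when `Vc = 0`. Scale-invariant:
#' rescaling all spacings leaves it unchanged.
#'
#' @param Vv,Vc Vessel and choroidal volumes in mm^3.
#' @return Percentage in `[0, 100]`, or `NA` where `Vc = 0`.
#' @export
vessel_index <- function(Vv, Vc) {
  out <- ifelse(Vc > 0, 100 * Vv / Vc, NA_real_)
  if (any(!is.na(out) & (out < 0 | out > 100 + 1e-9)))
    stop("vessel volume exceeds choroidal volume", call. = FALSE)
  out
}

#' Regional choroidal metrics over the ETDRS grid
#'
#' For each ETDRS region: choroidal volume `Vc_mm3`, vessel volume
#' `Vv_mm3`, and vessel index `VI_percent = 100 * Vv / Vc` computed on the
#' aggregated volumes (ratio of sums, not mean of per-A-line ratios).
#'
#' @param vmap Vessel volume [en_face_map()] (mm^3).
#' @param cmap Choroid volume [en_face_map()] (mm^3).
#' @param grid An [etdrs_grid()].
#' @return A tibble with columns `region`, `Vc_mm3`, `Vv_mm3`,
#'   `VI_percent`.
#' @export
region_metrics <- function(vmap, cmap, grid = etdrs_grid()) {
  if (!identical(dim(vmap$values), dim(cmap$values)))
    stop("vessel and choroid maps are not congruent", call. = FALSE)
  av <- etdrs_aggregate(vmap, grid)
  ac <- etdrs_aggregate(cmap, grid)
  tibble::tibble(
    region = av$region,
    Vc_mm3 = ac$value,
    Vv_mm3 = av$value,
    VI_percent = vessel_index(av$value, ac$value)
  )
}

#' Render an en-face map to PNG
#'
#' Warm colormaps highlight the vasculature; cool colormaps suit the
#' inspection of volume change. Fixed scale limits shared across calls give
#' identical colorbars for comparable maps.
#'
#' @param map An [en_face_map()].
#' @param path Output PNG path.
#' @param colormap `"warm"` or `"cool"`.
#' @param limits Colour scale limits (same units as the map); defaults to
#'   `c(0, max)`.
#' @param width_px,height_px Image size in pixels.
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, colormap = c("warm", "cool"),
                       limits = NULL, width_px = 800, height_px = 600) {
  stopifnot(inherits(map, "en_face_map"))
  colormap <- match.arg(colormap)
  if (is.null(limits)) limits <- c(0, max(map$values))
  if (length(limits) != 2L || limits[2] <= limits[1])
    stop("invalid colour limits", call. = FALSE)
  p <- autoplot.en_face_map(map, colormap = colormap, limits = limits)
  grDevices::png(path, width = width_px, height = height_px)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Plot an en-face map
#'
#' @param object An [en_face_map()].
#' @param colormap `"warm"` or `"cool"`.
#' @param limits Optional fixed colour limits.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.en_face_map <- function(object, colormap = c("warm", "cool"),
                                 limits = NULL, ...) {
  colormap <- match.arg(colormap)
  pal <- if (colormap == "warm")
    grDevices::hcl.colors(64, "Inferno")
  else
    rev(grDevices::hcl.colors(64, "Blues 3"))
  nb <- nrow(object$values); na <- ncol(object$values)
  df <- data.frame(
    a = rep((seq_len(na) - 0.5) * object$spacing[2], each = nb),
    b = rep((seq_len(nb) - 0.5) * object$spacing[1], times = na),
    value = as.vector(object$values)
  )
  lab <- switch(object$units, mm3 = "mm³", mm = "mm", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colors = pal, limits = limits,
                                  name = lab) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "fast axis (mm)", y = "slow axis (mm)") +
    ggplot2::theme_minimal()
}
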