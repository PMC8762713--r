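const_vol <- function(value = 0.4, dim = c(6, 10, 12), spacing = c(0.1, 0.1, 0.05))
  oct_volume(array(value, dim), spacing)

test_that("denoising leaves constant volumes unchanged and rejects impulses", {
  v <- const_vol()
  for (m in c("median", "gaussian", "nlm"))
    expect_equal(denoise(v, method = m)$intensities, v$intensities,
                 tolerance = 1e-12)
  imp <- array(0, c(7, 7, 7)); imp[4, 4, 4] <- 1
  out <- denoise(oct_volume(imp, c(1, 1, 1)), "median", size = 3)
  expect_equal(max(out$intensities), 0)
  expect_error(denoise(v, method = "median", size = 4), "odd")
})

test_that("default denoising reduces speckle contrast by at least 40%", {
  ph <- make_phantom(small_phantom_spec(seed = 3L, speckle_L = 4))
  stroma <- extract_slab(ph$volume, ph$surfaces) & !ph$vessel_truth$labels
  core <- stroma & denoise(oct_volume(1 - 1 * ph$vessel_truth$labels,
                                      ph$volume$spacing), "median")$intensities == 1
  before <- speckle_contrast(ph$volume, core)
  after <- speckle_contrast(denoise(ph$volume, "median", size = c(3, 3, 7)), core)
  expect_lt(after, 0.6 * before)
  expect_lt(speckle_contrast(denoise(ph$volume, "median", size = 3), core), before)
})

test_that("energy profile: uniform volumes and shadow dips behave as built", {
  v <- const_vol()
  ep <- energy_profile(v, 0.5)
  expect_equal(ep$raw, matrix(0.4 * 12, 6, 10))
  expect_equal(ep$smoothed, ep$raw)
  # a transmission-0.5 full-depth shadow halves raw; wide smoothing removes it
  arr <- v$intensities; arr[, 5, ] <- arr[, 5, ] * 0.5
  vs <- oct_volume(arr, v$spacing)
  eps <- energy_profile(vs, 0.5)   # window 5 voxels >> 1-column shadow
  expect_equal(eps$raw[, 5], rep(0.4 * 12 * 0.5, 6))
  expect_equal(eps$smoothed[, 5], rep(0.4 * 12, 6))
  # window smaller than the shadow keeps the dip
  arr2 <- v$intensities; arr2[, 3:7, ] <- arr2[, 3:7, ] * 0.5
  epn <- energy_profile(oct_volume(arr2, v$spacing), 0.1)
  expect_equal(epn$smoothed[, 5], epn$raw[, 5])
  # smoothed bounded by the raw local min/max
  expect_true(all(eps$smoothed >= min(eps$raw) & eps$smoothed <= max(eps$raw)))
})

test_that("shadow reduction restores energy and preserves within-A-line ratios", {
  v <- const_vol()
  expect_equal(shadow_reduce(v)$intensities, v$intensities, tolerance = 1e-12)
  ph <- make_phantom(small_phantom_spec(
    speckle_L = Inf,
    shadows = list(list(center = 0.75, width = 0.125, transmission = 0.5))))
  out <- shadow_reduce(ph$volume, window_mm = 0.5)
  ac <- (seq_len(dim(out$intensities)[2]) - 0.5) * out$spacing[2]
  in_sh <- which(abs(ac - 0.75) < 0.0625)
  ref <- which(abs(ac - 0.75) >= 0.15 & abs(ac - 0.75) < 0.25)
  e <- rowSums(out$intensities, dims = 2)
  expect_lt(max(abs(e[, in_sh] / mean(e[, ref]) - 1)), 0.05)
  # pure per-column scaling: within-column ratios exact
  r0 <- ph$volume$intensities[3, in_sh[1], ] / ph$volume$intensities[3, in_sh[1], 50]
  r1 <- out$intensities[3, in_sh[1], ] / out$intensities[3, in_sh[1], 50]
  expect_equal(r1, r0, tolerance = 1e-12)
  # near-idempotence: a second pass changes energies only through
  # re-smoothing of the (already nearly flat) profile
  twice <- shadow_reduce(out, window_mm = 0.5)
  expect_equal(twice$intensities, out$intensities, tolerance = 0.01)
})

test_that("attenuation compensation matches its closed forms", {
  # constant A-line [c, c, c, c] -> [1/8, 1/6, 1/4, 1/2], independent of c
  for (cc in c(0.2, 5)) {
    v <- oct_volume(array(cc, c(1, 1, 4)), c(1, 1, 1))
    expect_equal(as.vector(attenuation_compensate(v)$intensities),
                 c(1 / 8, 1 / 6, 1 / 4, 1 / 2))
  }
  # exponentially attenuated line is flattened (consecutive ratios closer to 1)
  z <- 0:39
  att <- exp(-0.2 * z) * 0.7
  v <- oct_volume(array(att, c(1, 1, 40)), c(1, 1, 0.01))
  out <- as.vector(attenuation_compensate(v)$intensities)
  rin <- att[2:30] / att[1:29]
  rout <- out[2:30] / out[1:29]
  expect_true(all(abs(rout - 1) < abs(rin - 1)))
  # bounds and the all-zero guard
  expect_true(all(out >= 0 & out <= 0.5))
  expect_equal(out[40], 0.5)   # last positive voxel is its own tail
  z0 <- attenuation_compensate(oct_volume(array(0, c(2, 2, 5)), c(1, 1, 1)))
  expect_true(all(z0$intensities == 0))
})

test_that("attenuation compensation cancels any per-A-line rescaling", {
  # this identity makes shadow_reduce (a pure per-column scaling) a no-op
  # for everything downstream of attenuation compensation
  ph <- make_phantom(small_phantom_spec(
    seed = 4L, speckle_L = 4,
    shadows = list(list(center = 0.75, width = 0.125, transmission = 0.5))))
  direct <- attenuation_compensate(ph$volume)
  via_shadow <- attenuation_compensate(shadow_reduce(ph$volume))
  expect_equal(via_shadow$intensities, direct$intensities, tolerance = 1e-12)
})

test_that("local contrast enhancement: fixed points and contrast growth", {
  v <- const_vol()
  expect_equal(local_contrast_enhance(v)$intensities, v$intensities,
               tolerance = 1e-12)
  # two-level image: separation is not decreased, output in [0, 1]
  arr <- array(0.3, c(4, 40, 40)); arr[, , 21:40] <- 0.6
  v2 <- oct_volume(arr, c(0.1, 0.025, 0.025))
  out <- local_contrast_enhance(v2, tile_mm = c(0.5, 0.5), log_compress = FALSE)
  lo <- mean(out$intensities[, , 1:20]); hi <- mean(out$intensities[, , 21:40])
  expect_gte(hi - lo, 0.6 - 0.3)   # absolute separation not decreased
  expect_true(all(out$intensities >= 0 & out$intensities <= 1))
  expect_error(local_contrast_enhance(v, tile_mm = c(0, 1)), "> 0")
})

test_that("the enhancement pipeline composes, toggles, and validates config", {
  ph <- make_phantom(small_phantom_spec(seed = 5L, speckle_L = 4, mu = 0.5))
  off <- enhance_config(denoise = FALSE, shadow = FALSE, attenuation = FALSE,
                        contrast = FALSE)
  expect_equal(enhance_pipeline(ph$volume, off)$intensities,
               ph$volume$intensities)
  cfg <- enhance_config()
  bad <- cfg; bad$order <- rev(bad$order)
  expect_error(enhance_pipeline(ph$volume, bad), "order is fixed")
  bad2 <- cfg; bad2$despeckle <- TRUE
  expect_error(enhance_pipeline(ph$volume, bad2), "unknown")
  # determinism: equal inputs give equal outputs
  e1 <- enhance_pipeline(ph$volume)
  e2 <- enhance_pipeline(ph$volume)
  expect_identical(e1$intensities, e2$intensities)
})

test_that("enhancement improves vessel/stroma separability in the deep slab", {
  ph <- make_phantom(small_phantom_spec(seed = 6L, speckle_L = 4, mu = 0.5))
  deep <- slab_mask(dim(ph$volume$intensities),
                    surface_pair(ph$surfaces$bm + 25L, ph$surfaces$csi,
                                 nz = dim(ph$volume$intensities)[3]))
  fisher <- function(v) {
    lu <- v$intensities[deep & ph$vessel_truth$labels]
    st <- v$intensities[deep & !ph$vessel_truth$labels]
    (mean(st) - mean(lu))^2 / (stats::var(st) + stats::var(lu))
  }
  expect_gt(fisher(enhance_pipeline(ph$volume)), fisher(ph$volume))
})
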