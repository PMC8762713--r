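test_that("vessel volume maps conserve mask counts exactly", {
  withr::local_seed(21)
  for (rep in 1:5) {
    m <- random_mask()
    vmap <- vessel_volume_map(m)
    expect_equal(sum(vmap$values), sum(m$labels) * voxel_volume(m$spacing))
  }
  # column with 10 vessel voxels at the DRI-like voxel volume
  s <- surface_pair(matrix(3L, 2, 2), matrix(20L, 2, 2), nz = 24)
  lab <- array(FALSE, c(2, 2, 24)); lab[1, 1, 5:14] <- TRUE
  sp <- c(9 / 256, 12 / 512, 0.0026)
  vmap <- vessel_volume_map(vessel_mask(lab, s, sp))
  expect_equal(vmap$values[1, 1], 10 * prod(sp))
  expect_equal(vmap$values[2, 2], 0)
  empty <- vessel_mask(array(FALSE, c(2, 2, 24)), s, sp)
  expect_true(all(vessel_volume_map(empty)$values == 0))
})

test_that("choroid maps follow (csi - bm) arithmetic and bound vessel maps", {
  s <- surface_pair(matrix(100L, 4, 6), matrix(200L, 4, 6))
  sp <- c(0.05, 0.05, 0.005)
  cmap <- choroid_volume_map(s, sp)
  expect_true(all(cmap$values == 100 * prod(sp)))
  tmap <- choroid_volume_map(s, sp, thickness = TRUE)
  expect_true(all(tmap$values == 100 * 0.005))
  expect_equal(tmap$units, "mm")
  one <- surface_pair(matrix(5L, 2, 2), matrix(6L, 2, 2))
  expect_true(all(choroid_volume_map(one, sp)$values == prod(sp)))
  # any in-slab mask is pointwise bounded by the choroid map
  withr::local_seed(22)
  m <- random_mask()
  vmap <- vessel_volume_map(m)
  cm <- choroid_volume_map(m$slab, m$spacing)
  expect_true(all(vmap$values <= cm$values + 1e-12))
})

test_that("ETDRS membership geometry matches the ring radii", {
  sp <- c(0.05, 0.05)
  m <- en_face_map(matrix(1, 160, 160), "mm3", sp)  # 8 x 8 mm
  g <- etdrs_grid()                                  # centred at (4, 4)
  mem <- chorovol:::etdrs_membership(m, g)
  at <- function(bmm, amm) mem[ceiling(bmm / sp[1]), ceiling(amm / sp[2])]
  expect_equal(at(4.025, 4.425), "central")          # radius 0.4 mm
  expect_true(is.na(at(4.025, 7.125)))               # radius 3.1 mm
  expect_equal(at(3.025, 4.025), "inner_superior")   # 1 mm up
  expect_equal(at(4.975, 4.025), "inner_inferior")
  expect_equal(at(4.025, 6.025), "outer_nasal")      # OD: nasal = +a
  g2 <- etdrs_grid(laterality = "OS")
  mem2 <- chorovol:::etdrs_membership(m, g2)
  expect_equal(mem2[ceiling(4.025 / 0.05), ceiling(6.025 / 0.05)],
               "outer_temporal")
  expect_error(etdrs_aggregate(m, etdrs_grid(center = c(20, 4))), "outside")
})

test_that("uniform maps give area-ratio sums and an exact region partition", {
  m <- en_face_map(matrix(2, 240, 240), "mm3", c(0.03, 0.03))
  agg <- etdrs_aggregate(m)
  expect_equal(nrow(agg), 10)
  inner <- sum(agg$value[grepl("inner", agg$region)])
  central <- agg$value[agg$region == "central"]
  expect_equal(inner / central, 8, tolerance = 0.02)  # (3^2 - 1) : 1
  expect_equal(sum(agg$value[agg$region != "circle_6mm"]),
               agg$value[agg$region == "circle_6mm"])
  # partition exactness on random maps
  withr::local_seed(23)
  r <- en_face_map(matrix(runif(90 * 120), 90, 120), "mm3", c(0.05, 0.05))
  ar <- etdrs_aggregate(r)
  expect_equal(sum(ar$value[ar$region != "circle_6mm"]),
               ar$value[ar$region == "circle_6mm"], tolerance = 1e-12)
})

test_that("vessel index is the percent ratio with its edge cases", {
  expect_equal(vessel_index(3.17, 6.47), 48.99, tolerance = 1e-3)
  expect_equal(vessel_index(0, 5), 0)
  expect_equal(vessel_index(5, 5), 100)
  expect_true(is.na(vessel_index(0, 0)))
  expect_error(vessel_index(6, 5), "exceeds")
  # scale invariance through region_metrics
  withr::local_seed(24)
  m <- random_mask()
  v1 <- vessel_volume_map(m)
  c1 <- choroid_volume_map(m$slab, m$spacing)
  m2 <- vessel_mask(m$labels, m$slab, m$spacing * 2)
  v2 <- vessel_volume_map(m2)
  c2 <- choroid_volume_map(m$slab, m$spacing * 2)
  # the grid scales with the scan so region membership is unchanged
  r1 <- region_metrics(v1, c1, etdrs_grid(diameters = c(0.05, 0.15, 0.3)))
  r2 <- region_metrics(v2, c2, etdrs_grid(diameters = 2 * c(0.05, 0.15, 0.3)))
  expect_equal(r1$VI_percent, r2$VI_percent, tolerance = 1e-9)
})

test_that("map rendering writes PNGs with a shared scale", {
  m <- en_face_map(matrix(runif(30 * 40), 30, 40), "mm3", c(0.1, 0.1))
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_map(m, p1, "warm", limits = c(0, 2))
  render_map(m, p2, "cool", limits = c(0, 2))
  expect_true(file.exists(p1) && file.size(p1) > 0)
  expect_true(file.exists(p2) && file.size(p2) > 0)
  expect_error(render_map(m, p1, limits = c(2, 1)), "invalid")
  expect_s3_class(autoplot(m), "ggplot")
})
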