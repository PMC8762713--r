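test_that("the 3x3 Niblack worked example gives T = 4.4835 at the centre", {
  img <- matrix(1:9, 3, 3)
  Tm <- niblack_threshold(img, window = c(3, 3), k = -0.2)
  expect_equal(Tm[2, 2], 5 - 0.2 * sqrt(20 / 3))
  expect_equal(Tm[2, 2], 4.4835, tolerance = 1e-4)
  expect_false(niblack_oracle(img, c(3, 3), -0.2)[2, 2])  # 5 > 4.4835
})

test_that("Niblack masks match the brute-force windowed oracle", {
  withr::local_seed(11)
  for (rep in 1:5) {
    img <- matrix(runif(16 * 16), 16, 16)
    valid <- matrix(runif(16 * 16) > 0.2, 16, 16)
    for (w in list(c(3, 3), c(5, 3))) for (k in c(-0.4, 0, 0.3)) {
      Tm <- niblack_threshold(img, w, k, valid)
      got <- valid & !is.na(Tm) & img < Tm
      expect_identical(got, niblack_oracle(img, w, k, valid))
    }
  }
})

test_that("Niblack with k = 0 flags nothing on constant images", {
  vol <- oct_volume(array(0.5, c(2, 16, 16)), c(0.1, 0.1, 0.1))
  s <- surface_pair(matrix(3L, 2, 16), matrix(14L, 2, 16), nz = 16)
  p <- threshold_params(window_bscan_mm = c(0.5, 0.5), k = 0)
  expect_equal(sum(niblack_mask_bscan(vol, s, p)$labels), 0)  # strict <
})

test_that("a dark phantom cylinder is flagged almost entirely when noiseless", {
  ph <- make_phantom(small_phantom_spec(speckle_L = Inf))
  p <- threshold_params(window_bscan_mm = c(0.6, 0.25), k = -0.5,
                        min_component = 0)
  m <- niblack_mask_bscan(ph$volume, ph$surfaces, p)
  tr <- ph$vessel_truth$labels
  expect_gte(sum(m$labels & tr) / sum(tr), 0.90)
})

test_that("Otsu separates a bimodal sample and matches exhaustive search", {
  x <- c(rep(0.1, 6), rep(0.9, 4))
  Tg <- otsu_threshold(x)
  expect_gt(Tg, 0.1); expect_lt(Tg, 0.9)
  expect_equal(sum(x < Tg), 6)
  withr::local_seed(12)
  for (rep in 1:10) {
    y <- c(rnorm(40, 0.3, 0.05), rnorm(30, 0.7, 0.08))
    expect_equal(otsu_threshold(y), otsu_oracle(y))
  }
  expect_error(otsu_threshold(rep(1, 5)), "single distinct")
})

test_that("global thresholding recovers the phantom vessel fraction", {
  ph <- make_phantom(small_phantom_spec(speckle_L = Inf))
  g <- global_mask(ph$volume, ph$surfaces)
  tr <- ph$vessel_truth$labels
  sl <- extract_slab(ph$volume, ph$surfaces)
  expect_lt(abs(sum(g$labels) - sum(tr)) / sum(sl), 0.05)
  con <- oct_volume(array(1, dim(sl)), ph$volume$spacing)
  expect_error(global_mask(con, ph$surfaces), "single distinct")
})

test_that("mask fusion follows its rule semantics and removes small blobs", {
  s <- surface_pair(matrix(2L, 6, 6), matrix(10L, 6, 6), nz = 12)
  sl <- slab_mask(c(6, 6, 12), s)
  base <- array(FALSE, c(6, 6, 12))
  A <- base; A[3, 3, 4:6] <- TRUE
  B <- base; B[3, 3, 4:6] <- TRUE
  C <- base
  mk <- function(x) vessel_mask(x, s, c(1, 1, 1))
  # unanimity
  same <- combine_masks(list(mk(A), mk(A), mk(A)), "majority", 0)
  expect_equal(same$labels, A)
  # 2-of-3 majority vs intersection
  expect_true(all(combine_masks(list(mk(A), mk(B), mk(C)), "majority", 0)$labels == A))
  expect_equal(sum(combine_masks(list(mk(A), mk(B), mk(C)), "intersection", 0)$labels), 0)
  expect_true(all(combine_masks(list(mk(A), mk(C), mk(C)), "union", 0)$labels == A))
  # small component removal: isolated 2-voxel blob below min_component = 5
  D <- base; D[2, 2, 3:4] <- TRUE; D[5, 5, 5:9] <- TRUE
  cleaned <- combine_masks(list(mk(D), mk(D), mk(D)), "majority", 5)
  expect_equal(sum(cleaned$labels[2, 2, ]), 0)
  expect_equal(sum(cleaned$labels[5, 5, ]), 5)
  expect_error(combine_masks(list(mk(A), vessel_mask(array(FALSE, c(6, 6, 13)),
    surface_pair(matrix(2L, 6, 6), matrix(10L, 6, 6), nz = 13), c(1, 1, 1)))),
    "congruent")
})

test_that("majority fusion is monotone in its inputs", {
  withr::local_seed(13)
  s <- surface_pair(matrix(2L, 5, 5), matrix(9L, 5, 5), nz = 10)
  sl <- slab_mask(c(5, 5, 10), s)
  for (rep in 1:10) {
    ms <- lapply(1:3, function(i)
      vessel_mask(sl & array(runif(250) < 0.4, c(5, 5, 10)), s, c(1, 1, 1)))
    grown <- ms[[1]]$labels | (sl & array(runif(250) < 0.2, c(5, 5, 10)))
    ms2 <- ms; ms2[[1]] <- vessel_mask(grown, s, c(1, 1, 1))
    f1 <- combine_masks(ms, "majority", 0)$labels
    f2 <- combine_masks(ms2, "majority", 0)$labels
    expect_true(all(f2[f1]))
  }
})

test_that("vessel and stroma partition the slab exactly", {
  withr::local_seed(14)
  for (rep in 1:5) {
    m <- random_mask()
    st <- stroma_mask(m)
    sl <- slab_mask(dim(m$labels), m$slab)
    expect_equal(sum(m$labels) + sum(st$labels), sum(sl))
    expect_equal(sum(m$labels & st$labels), 0)
    expect_true(all((m$labels | st$labels) == sl))
  }
})

test_that("dice follows its formula and edge cases", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  expect_equal(dice(a, b), 1)          # both empty
  a[1:25] <- TRUE
  expect_equal(dice(a, a), 1)
  b2 <- array(FALSE, c(4, 4, 4)); b2[26:50] <- TRUE
  expect_equal(dice(a, b2), 0)
  x <- array(FALSE, c(10, 10, 10)); y <- x
  x[1:100] <- TRUE; y[21:120] <- TRUE  # |A| = |B| = 100, overlap 80
  expect_equal(dice(x, y), 0.8)
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), "differ")
})

test_that("C-scan segmentation keeps an axis-aligned vessel connected", {
  # vessel at constant offset below a staircase BM stays one component
  nb <- 20L; na <- 40L; nz <- 80L
  bm0 <- matrix(rep(12L + 2L * (0:9), each = 4)[1:na], nb, na, byrow = TRUE)
  surf <- surface_pair(bm0, bm0 + 40L, nz = nz)
  arr <- array(0.6, c(nb, na, nz))
  zidx <- array(rep(seq_len(nz), each = nb * na), c(nb, na, nz))
  off <- sweep(zidx, c(1, 2), bm0, "-")
  lum <- off >= 14 & off < 20 & slice_b(nb, na, nz, 9:12)
  arr[lum] <- 0.2
  vol <- oct_volume(arr, c(0.05, 0.03, 0.01))
  p <- threshold_params(window_cscan_mm = c(0.6, 0.6), k = -0.5,
                        min_component = 0)
  m <- niblack_mask_cscan(vol, surf, p)
  lab <- chorovol:::label_components26_cpp(as.vector(m$labels), dim(m$labels))
  expect_equal(max(lab), 1)
  expect_gte(sum(m$labels & lum) / sum(lum), 0.9)
})
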