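two_level_tube <- function() {
  arr <- array(0, c(30, 12, 12))
  for (i in 5:25) for (j in 1:12) for (k in 1:12)
    if ((j - 6.2)^2 + (k - 6.3)^2 <= 6) arr[i, j, k] <- 100
  cow_volume(arr, c(1, 1, 1))
}

test_that("adaptive k-means isolates the bright phase of a bimodal image", {
  v <- two_level_tube()
  mask <- adaptive_kmeans(v, segmentation_params("strict", n_clusters_init = 3))
  expect_identical(mask & TRUE, v$data == 100)
})

test_that("cluster centres closer than the minimum distance are merged", {
  arr <- array(0, c(10, 10, 10))
  arr[1:200] <- 0.97   # rescales to ~247; within 10 of 255
  arr[201:400] <- 1.0
  v <- cow_volume(arr, c(1, 1, 1))
  mask <- adaptive_kmeans(v, segmentation_params("strict",
                                                 n_clusters_init = 3))
  centers <- attr(mask, "centers")
  expect_length(centers, 2L)          # 0.97 and 1.0 merged into one centre
  expect_identical(mask & TRUE, v$data > 0.5)  # both bright levels kept
})

test_that("adaptive k-means is deterministic and rejects flat images", {
  v <- two_level_tube()
  p <- segmentation_params("strict")
  expect_identical(adaptive_kmeans(v, p), adaptive_kmeans(v, p))
  expect_error(adaptive_kmeans(cow_volume(array(1, c(5, 5, 5)), c(1, 1, 1)),
                               p), "distinct")
})

test_that("Chan-Vese fixes the true mask of a noise-free two-level image", {
  v <- two_level_tube()
  truth <- v$data == 100
  out <- chan_vese(v, truth, segmentation_params("strict"))
  expect_identical(out & TRUE, truth)
})

test_that("Chan-Vese energy is non-increasing and below the initial energy", {
  v <- two_level_tube()
  v$data <- v$data + withr::with_seed(5L, array(rnorm(length(v$data), 0, 20),
                                                dim(v$data)))
  init <- adaptive_kmeans(v, segmentation_params("relaxed", keep_top = 1))
  out <- chan_vese(v, init, segmentation_params("relaxed", keep_top = 1))
  en <- attr(out, "energy")
  expect_true(all(diff(en) <= 1e-9))
  expect_lte(en[length(en)], en[1])
})

test_that("Chan-Vese recovers a noisy tube with Dice >= 0.85", {
  v <- two_level_tube()
  truth <- v$data == 100
  v$data <- pmax(v$data + withr::with_seed(6L,
    array(rnorm(length(v$data), 0, 20), dim(v$data))), 0)
  p <- segmentation_params("strict", n_clusters_init = 3)
  mask <- chan_vese(v, adaptive_kmeans(v, p), p)
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gte(dice, 0.85)
})

test_that("Chan-Vese rejects empty or full initializations", {
  v <- two_level_tube()
  expect_error(chan_vese(v, array(FALSE, dim(v$data))), "empty")
  expect_error(chan_vese(v, array(TRUE, dim(v$data))), "whole volume")
})

test_that("the strict mask is always contained in the relaxed mask", {
  ph <- make_phantom(fast_config(seed = 2))
  seg <- two_phase_segment(ph$volume)
  expect_true(all(seg$mask_relaxed[seg$mask_strict]))
})

test_that("relaxed over-segmentation covers the eroded true vessel mask", {
  erode6 <- function(m) {
    d <- dim(m)
    out <- m
    pad <- function(a, ax, by) {
      idx <- lapply(d, seq_len)
      src <- idx
      src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1), d[ax])
      a[src[[1]], src[[2]], src[[3]]]
    }
    for (ax in 1:3) for (by in c(-1, 1)) out <- out & pad(m, ax, by)
    out
  }
  ph <- make_phantom(fast_config(noise_sigma = 0))
  seg <- two_phase_segment(ph$volume)
  truth <- ph$clean$data >= 0.07  # half the dimmest segmentable baseline
  core <- erode6(truth)
  expect_true(all(seg$mask_relaxed[core]))
})

test_that("equal strict and relaxed parameters give identical masks", {
  ph <- make_phantom(fast_config(seed = 3))
  s <- segmentation_params("strict")
  r <- segmentation_params("relaxed", keep_top = s$keep_top, cv_mu = s$cv_mu,
                           cv_lambda1 = s$cv_lambda1,
                           cv_lambda2 = s$cv_lambda2)
  seg <- two_phase_segment(ph$volume, s, r)
  expect_identical(seg$mask_strict & TRUE, seg$mask_relaxed & TRUE)
})

test_that("the thin ACo is relaxed-only under default parameters", {
  ph <- make_phantom(phantom_config(seed = 4))  # full 0.5 mm grid
  seg <- two_phase_segment(ph$volume)
  ijk <- round(world_to_voxel(ph$volume, c(58, 40, 26.1)))
  expect_false(seg$mask_strict[ijk])
  expect_true(seg$mask_relaxed[ijk])
})

test_that("segmentation is invariant to affine intensity rescaling", {
  ph <- make_phantom(fast_config(seed = 5))
  ref <- rasterize(build_cow_spec(fast_config(noise_sigma = 0))$specs,
                   fast_config(noise_sigma = 0))
  seg1 <- two_phase_segment(histogram_match(ph$volume, ref))
  shifted <- cow_volume(3.7 * ph$volume$data + 11, ph$volume$spacing,
                        ph$volume$origin)
  seg2 <- two_phase_segment(histogram_match(shifted, ref))
  expect_identical(seg1$mask_strict & TRUE, seg2$mask_strict & TRUE)
  expect_identical(seg1$mask_relaxed, seg2$mask_relaxed)
})
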