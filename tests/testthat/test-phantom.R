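test_that("vessel_spec enforces its invariants", {
  expect_error(vessel_spec("BA", rbind(c(0, 0, 0)), 1, 1), "2 points")
  expect_error(vessel_spec("BA", rbind(c(0, 0, 0), c(0, 0, 0)), 1, 1),
               "distinct")
  expect_error(vessel_spec("BA", rbind(c(0, 0, 0), c(1, 0, 0)), 0, 1),
               "positive")
})

test_that("build_cow_spec realizes the requested variant topology", {
  complete <- build_cow_spec(phantom_config(variant = "complete"))
  nms <- vapply(complete$specs, function(s) s$name, "")
  expect_length(complete$specs, 16L)
  expect_true(all(c("A1-L", "A1-R", "ACo", "BA") %in% nms))
  expect_named(complete$ground_truth$node_positions,
               c("basilar", "m1a1_left", "m1a1_right"))

  apl <- build_cow_spec(phantom_config(variant = "a1_aplasia_right"))
  expect_false("A1-R" %in% vapply(apl$specs, function(s) s$name, ""))
  expect_named(apl$ground_truth$node_positions, c("basilar", "m1a1_left"))

  hypo <- build_cow_spec(phantom_config(variant = "a1_hypoplasia_left",
                                        hypoplasia_factor = 0.4))
  a1 <- function(b, side) b$specs[[which(vapply(b$specs, function(s)
    s$name, "") == side)]]
  expect_equal(a1(hypo, "A1-L")$radius_profile,
               0.4 * a1(complete, "A1-L")$radius_profile)
  expect_equal(a1(hypo, "A1-R")$radius_profile,
               a1(complete, "A1-R")$radius_profile)
})

test_that("unknown variant and invalid config fields are rejected", {
  expect_error(phantom_config(variant = "p1_aplasia"), "unknown variant")
  expect_error(phantom_config(hypoplasia_factor = 1.2), "hypoplasia_factor")
  expect_error(phantom_config(noise_sigma = -1), "noise_sigma")
})

test_that("rasterized cylinder volume matches the analytic voxel count", {
  cfg <- phantom_config(shape = c(60L, 20L, 20L), spacing = c(1, 1, 1),
                        noise_sigma = 0)
  tube <- vessel_spec("BA", rbind(c(10, 10.2, 10.3), c(50, 10.2, 10.3)),
                      2.0, 0.2, 0)
  v <- rasterize(list(tube), cfg)
  fg <- sum(v$data >= 0.1)  # half the nominal intensity
  # brute-force oracle: voxel centres inside the analytic cylinder
  ctr <- expand.grid(x = (1:60) - 0.5, y = (1:20) - 0.5, z = (1:20) - 0.5)
  oracle <- sum(ctr$x >= 10 & ctr$x <= 50 &
                  (ctr$y - 10.2)^2 + (ctr$z - 10.3)^2 <= 4)
  expect_lt(abs(fg - oracle) / oracle, 0.15)
  expect_lt(abs(fg - pi * 2^2 * 40) / (pi * 4 * 40), 0.15)
})

test_that("rasterize handles empty spec lists and repeated calls", {
  cfg <- phantom_config(shape = c(20L, 20L, 10L), spacing = c(1, 1, 1))
  expect_true(all(rasterize(list(), cfg)$data == 0))
  tube <- list(vessel_spec("BA", rbind(c(5, 10, 5), c(15, 10, 5)), 1.5, 1))
  expect_identical(rasterize(tube, cfg)$data, rasterize(tube, cfg)$data)
})

test_that("a vessel leaving the grid is rejected by name", {
  cfg <- phantom_config(shape = c(20L, 20L, 10L), spacing = c(1, 1, 1))
  bad <- list(vessel_spec("M1-L", rbind(c(5, 10, 5), c(30, 10, 5)), 1.5, 1))
  expect_error(rasterize(bad, cfg), "M1-L")
})

test_that("add_noise matches its stated distribution and edge cases", {
  cfg <- phantom_config(shape = c(100L, 100L, 100L), spacing = c(1, 1, 1),
                        noise_sigma = 0)
  v <- cow_volume(array(0, c(100, 100, 100)), c(1, 1, 1))
  expect_identical(add_noise(v, 0, seed = 1), v)
  # Monte-Carlo: background SD of 10^6 draws within 5% of sigma * baseline
  n1 <- add_noise(v, 0.1, seed = 7, baseline = 1)
  raw <- withr::with_seed(7L, rnorm(1e6, 0, 0.1))
  expect_lt(abs(sd(raw) - 0.1) / 0.1, 0.05)
  expect_true(all(n1$data >= 0))  # clipped at zero
  # pre-clip values equal the volume plus the same Gaussian draw
  expect_equal(as.numeric(n1$data), pmax(raw, 0), tolerance = 1e-12)
  n2 <- add_noise(v, 0.1, seed = 8, baseline = 1)
  expect_false(identical(n1$data, n2$data))
})

test_that("complete-variant phantoms are mirror-symmetric about the midline", {
  ph <- make_phantom(fast_config(noise_sigma = 0))
  flipped <- ph$clean$data[, dim(ph$clean$data)[2]:1, ]
  expect_identical(ph$clean$data, flipped)
})

test_that("ground-truth nodes lie inside the noise-free foreground", {
  for (variant in c("complete", "a1_aplasia_left")) {
    ph <- make_phantom(fast_config(variant, noise_sigma = 0))
    for (w in ph$ground_truth$node_positions) {
      ijk <- round(world_to_voxel(ph$clean, w))
      expect_gt(ph$clean$data[ijk], 0.05)
    }
  }
})

test_that("straight-centerline specs have true tortuosity exactly 1", {
  cfg <- fast_config(noise_sigma = 0)
  built <- build_cow_spec(cfg)
  # the phantom's own segments are curved; a straight spec is the oracle
  straight <- vessel_spec("BA", rbind(c(5, 10, 5), c(35, 22, 17)), 1, 1)
  dense <- cowpipe:::densify_spec(straight, 0.1)
  expect_true(cowpipe:::is_collinear(straight$centerline))
  expect_equal(tortuosity(dense$points), 1)
  # curved A1 has tortuosity > 1 in the ground truth
  expect_gt(built$ground_truth$segments[["A1-L"]]$tortuosity, 1)
})

test_that("ground truth JSON round-trips", {
  gt <- build_cow_spec(phantom_config())$ground_truth
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, f)
  back <- read_ground_truth(f)
  expect_equal(back$node_positions$basilar, gt$node_positions$basilar)
  expect_equal(back$median_sagittal_y, gt$median_sagittal_y)
})
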