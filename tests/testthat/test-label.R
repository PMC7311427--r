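test_that("score_B substitutes directly and is linear in the midline term", {
  # node on the midline with branch centre of mass at x = 10 -> B = -10
  g <- toy_graph(rbind(c(10, 40, 20)),
                 list(toy_path(c(10, 40, 20), c(0, 1, 0), 1)))
  nd <- toy_bignode(g, 1)
  expect_equal(score_B(nd, g, plane_y = 40), -10)
  expect_equal(score_B(nd, g, plane_y = 40, negate_midline_term = FALSE), -10)

  # two nodes identical except d_y 0 vs 8 mm differ in B by exactly 8
  g2 <- toy_graph(rbind(c(10, 40, 20), c(10, 48, 20)),
                  list(toy_path(c(10, 40, 20), c(0, 0, 1), 1),
                       toy_path(c(10, 48, 20), c(0, 0, 1), 1)))
  b1 <- score_B(toy_bignode(g2, 1), g2, 40)
  b2 <- score_B(toy_bignode(g2, 2), g2, 40)
  expect_equal(abs(b1 - b2), 8)

  branchless <- toy_bignode(g, 1)
  branchless$n_branches <- 0L
  expect_error(score_B(branchless, g, 40), "branchless")
})

test_that("branch_y_extent caps at 15 mm and handles degenerate branches", {
  g <- toy_graph(rbind(c(30, 30, 20), c(30, 60, 20), c(30, 45, 20)),
                 list(toy_path(c(30, 30, 20), c(0, 1, 0), 23),  # 22 mm in y
                      toy_path(c(30, 60, 20), c(0, 1, 0), 5),   # 4 mm in y
                      toy_path(c(30, 45, 20), c(0, 0, 0) + c(1, 0, 0), 1)))
  expect_equal(branch_y_extent(toy_bignode(g, 1), g), 15)
  expect_equal(branch_y_extent(toy_bignode(g, 2), g), 4)
  expect_equal(branch_y_extent(toy_bignode(g, 3), g), 0)
})

test_that("g, M and S substitute directly", {
  # coincident midline pair
  expect_equal(score_g(c(0, 40, 0), c(0, 40, 0), 40, beta = 1), 0)
  # beta = 1, d = 20, d_y = (5, 9) -> g = 11
  xi <- c(0, 45, 0)
  xj <- c(sqrt(20^2 - 4^2), 49, 0)
  expect_equal(score_g(xi, xj, 40, beta = 1), 11)
  # M: e = (15, 5), g = 3, alpha = 1 -> 7
  expect_equal(score_M(xi, xj, ei = 15, ej = 5, plane_y = 40, alpha = 1,
                       beta = 1, g = 3), 7)
  expect_equal(score_M(xi, xj, ei = 5, ej = 5, plane_y = 40, alpha = 1,
                       beta = 1, g = 0), 0)
  # S: y = (10, 5), g = 2 -> 2 - 5/25 = 1.8
  expect_equal(score_S(c(0, 50, 0), c(0, 45, 0), 40, beta = 1, g = 2), 1.8)
  # mirrored pair with g = 0 -> 0
  expect_equal(score_S(c(0, 28, 0), c(0, 52, 0), 40, beta = 1, g = 0), 0)
  # midline node -> -Inf sentinel
  expect_identical(score_S(c(0, 40, 0), c(0, 45, 0), 40, beta = 1), -Inf)
})

test_that("g, M and S are symmetric over random node pairs", {
  withr::with_seed(99L, {
    for (r in 1:100) {
      xi <- runif(3, 0, 80)
      xj <- runif(3, 0, 80)
      beta <- runif(1, 0.1, 2)
      alpha <- runif(1, -3, 3)
      ei <- runif(1, 0, 15)
      ej <- runif(1, 0, 15)
      expect_equal(score_g(xi, xj, 40, beta), score_g(xj, xi, 40, beta))
      expect_equal(score_M(xi, xj, ei, ej, 40, alpha, beta),
                   score_M(xj, xi, ej, ei, 40, alpha, beta))
      expect_equal(score_S(xi, xj, 40, beta), score_S(xj, xi, 40, beta))
    }
  })
})

test_that("scores are invariant to z translation and midline mirroring", {
  withr::with_seed(42L, {
    for (r in 1:20) {
      xi <- runif(3, 5, 75)
      xj <- runif(3, 5, 75)
      beta <- 0.3
      shift <- c(0, 0, runif(1, -5, 5))
      expect_equal(score_g(xi + shift, xj + shift, 40, beta),
                   score_g(xi, xj, 40, beta), tolerance = 1e-9)
      mirror <- function(p) c(p[1], 80 - p[2], p[3])
      expect_equal(score_g(mirror(xi), mirror(xj), 40, beta),
                   score_g(xi, xj, 40, beta), tolerance = 1e-9)
      expect_equal(score_S(mirror(xi), mirror(xj), 40, beta),
                   score_S(xi, xj, 40, beta), tolerance = 1e-9)
    }
  })
})

test_that("candidate_nodes uses a closed ball and sorts by distance", {
  g <- toy_graph(rbind(c(10, 40, 20), c(40, 40, 20), c(25, 40, 20)),
                 list(toy_path(c(10, 40, 20), c(1, 0, 0), 2),
                      toy_path(c(40, 40, 20), c(1, 0, 0), 2),
                      toy_path(c(25, 40, 20), c(1, 0, 0), 2)))
  bn <- merge_big_nodes(g, 5)
  landmark <- c(10, 40, 20)
  cands <- candidate_nodes(bn, landmark, radius_mm = 30)
  expect_length(cands, 3L)  # the node at exactly 30 mm is included
  expect_equal(attr(cands, "distance"), c(0, 15, 30))
  expect_length(candidate_nodes(bn, c(200, 40, 20), radius_mm = 30), 0L)
  expect_length(candidate_nodes(bn, landmark, radius_mm = 30, k = 2), 2L)
})

test_that("label_basilar picks the argmax-B candidate", {
  ph <- make_phantom(phantom_config(seed = 2))
  res <- graph_from_volume(ph$volume)
  atlas <- default_atlas()
  bas <- label_basilar(res$bignodes, res$graph, atlas)
  err <- sqrt(sum((bas$node$center -
                     ph$ground_truth$node_positions$basilar)^2))
  expect_lt(err, 5)
  expect_identical(bas$status, "labeled")
  expect_identical(which.max(bas$scores), 1L)
  # empty candidate pool -> indeterminate
  none <- label_basilar(structure(list(), class = "cow_bignodes"),
                        res$graph, atlas)
  expect_identical(none$status, "indeterminate")
  expect_null(none$node)
})

test_that("classify_a1 applies the failure rule and the S threshold", {
  unlabeled <- list(status = "left_only", S = NA_real_)
  expect_identical(classify_a1(unlabeled)$status, "variant")
  low <- list(status = "both", S = -50)
  expect_identical(classify_a1(low, s_threshold = -8)$status, "variant")
  sentinel <- list(status = "both", S = -Inf)
  expect_identical(classify_a1(sentinel, s_threshold = -8)$status, "variant")
  ok <- list(status = "both", S = -6)
  expect_identical(classify_a1(ok, s_threshold = -8)$status, "normal")
})

test_that("atlas landmark invariants and JSON round-trip hold", {
  expect_error(atlas_landmarks(c(25, 40, 22), c(48, 41, 24), c(48, 54, 24),
                               40), "invariant")
  atlas <- default_atlas()
  f <- withr::local_tempfile(fileext = ".json")
  write_atlas(atlas, f)
  back <- read_atlas(f)
  expect_equal(back$basilar, atlas$basilar)
  expect_equal(back$median_sagittal_y, atlas$median_sagittal_y)
})
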