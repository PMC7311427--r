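test_that("a straight solid tube skeletonizes to a single simple path", {
  for (along in c("x", "z")) {
    v <- tube_volume(2, along)
    sk <- skeletonize3d(v$data >= 0.5, spacing = v$spacing)
    g <- skeleton_to_graph(sk)
    expect_identical(sum(g$nodes$kind == "branch"), 0L)
    expect_identical(sum(g$nodes$kind == "end"), 2L)
    expect_length(g$edges, 1L)
  }
})

test_that("a solid ball keeps one nonempty component", {
  ball <- array(FALSE, c(15L, 15L, 15L))
  for (i in 1:15) for (j in 1:15) for (k in 1:15)
    ball[i, j, k] <- (i - 8.2)^2 + (j - 8.3)^2 + (k - 8.1)^2 <= 25
  sk <- skeletonize3d(ball)
  expect_gte(sum(sk$mask), 1)
  expect_identical(count_components26(sk$mask), 1L)
})

test_that("a Y-shaped tube union yields one branch point and three ends", {
  v <- y_volume()
  sk <- skeletonize3d(v$data >= 0.5, spacing = v$spacing)
  g <- skeleton_to_graph(sk)
  expect_identical(sum(g$nodes$kind == "branch"), 1L)
  expect_identical(sum(g$nodes$kind == "end"), 3L)
  expect_length(g$edges, 3L)
})

test_that("the preserve contract is enforced and honoured", {
  v <- tube_volume(2, "x")
  mask <- v$data >= 0.5
  sk1 <- skeletonize3d(mask, spacing = v$spacing, phase = "strict")
  # preserve outside the mask is rejected
  bad <- array(FALSE, dim(mask))
  bad[1, 1, 1] <- TRUE
  expect_error(skeletonize3d(mask, preserve = bad), "not contained")
  # every preserved voxel survives thinning of a dilated mask
  grown <- mask
  grown[2:49, , ] <- mask[2:49, , ] | mask[1:48, , ]
  sk2 <- skeletonize3d(grown, preserve = sk1, spacing = v$spacing,
                       phase = "merged")
  expect_true(all(sk2$mask[sk1$mask]))
})

test_that("skeleton_to_graph handles paths, stars and empty skeletons", {
  as_skel <- function(mask) structure(list(mask = mask, phase = "merged",
                                           spacing = c(1, 1, 1),
                                           origin = c(0, 0, 0)),
                                      class = "cow_skeleton")
  path <- array(FALSE, c(30, 5, 5))
  path[4:23, 3, 3] <- TRUE  # 20-voxel path
  g <- skeleton_to_graph(as_skel(path))
  expect_identical(nrow(g$nodes), 2L)
  expect_length(g$edges, 1L)
  expect_equal(g$edges[[1]]$length_mm, 19)

  ystar <- array(FALSE, c(21, 21, 5))
  ystar[10:16, 11, 3] <- TRUE          # one arm +x
  for (s in 1:6) {
    ystar[10 - s, 11 - s, 3] <- TRUE   # arm -x-y
    ystar[10 - s, 11 + s, 3] <- TRUE   # arm -x+y
  }
  gy <- skeleton_to_graph(as_skel(ystar))
  expect_identical(sum(gy$nodes$kind == "branch"), 1L)
  expect_identical(sum(gy$nodes$kind == "end"), 3L)
  expect_length(gy$edges, 3L)

  empty <- skeleton_to_graph(as_skel(array(FALSE, c(4, 4, 4))))
  expect_identical(nrow(empty$nodes), 0L)
  expect_length(empty$edges, 0L)
})

test_that("a closed loop is anchored into one node with a self-edge", {
  sk <- skeletonize3d(torus_mask())
  g <- prune(skeleton_to_graph(sk), 3)
  expect_identical(nrow(g$nodes), 1L)
  expect_length(g$edges, 1L)
  expect_identical(g$edges[[1]]$from, g$edges[[1]]$to)
  expect_identical(count_components26(torus_mask()),
                   count_components26(sk$mask))
})

test_that("prune removes short terminal spurs and is idempotent", {
  spur <- array(FALSE, c(40, 21, 5))
  spur[5:35, 11, 3] <- TRUE          # long path
  for (s in 1:5) spur[20 + s, 11 + s, 3] <- TRUE  # 5-voxel spur
  sk <- structure(list(mask = spur, phase = "merged", spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)), class = "cow_skeleton")
  g <- skeleton_to_graph(sk)
  expect_identical(sum(g$nodes$kind == "branch"), 1L)
  pruned <- prune(g, 10)
  expect_identical(nrow(pruned$nodes), 2L)
  expect_true(all(pruned$nodes$kind == "end"))
  expect_length(pruned$edges, 1L)
  # no-op and fixpoint contracts
  expect_identical(prune(g, 0), g)
  again <- prune(pruned, 10)
  expect_equal(again$nodes, pruned$nodes)
  expect_length(again$edges, length(pruned$edges))
})

test_that("big-node merging follows the 5 mm single-linkage rule", {
  # two branch nodes 3 mm apart merge; 12 mm apart stay separate
  near <- toy_graph(rbind(c(30, 40, 20), c(33, 40, 20)),
                    list(toy_path(c(30, 40, 20), c(0, 1, 0), 5),
                         toy_path(c(33, 40, 20), c(0, -1, 0), 5)))
  bn <- merge_big_nodes(near, 5)
  expect_length(bn, 1L)
  expect_identical(bn[[1]]$node_ids, 1:2)

  far <- toy_graph(rbind(c(30, 40, 20), c(42, 40, 20)),
                   list(toy_path(c(30, 40, 20), c(0, 1, 0), 5),
                        toy_path(c(42, 40, 20), c(0, -1, 0), 5)))
  expect_length(merge_big_nodes(far, 5), 2L)
})

test_that("the phantom basilar tip merges into one big node with 5 branches", {
  ph <- make_phantom(phantom_config(seed = 1))  # 0.5 mm study grid
  res <- graph_from_volume(ph$volume)
  bas <- candidate_nodes(res$bignodes,
                         ph$ground_truth$node_positions$basilar,
                         radius_mm = 5)
  expect_length(bas, 1L)
  expect_identical(bas[[1]]$n_branches, 5L)
})

test_that("skeletonization preserves component counts on phantoms", {
  for (s in 1:3) {
    ph <- make_phantom(fast_config(seed = 10 + s))
    seg <- two_phase_segment(ph$volume)
    sk <- skeletonize3d(seg$mask_relaxed, spacing = ph$volume$spacing,
                        spur_min_voxels = 0)
    expect_identical(count_components26(seg$mask_relaxed),
                     count_components26(sk$mask))
  }
})

test_that("arc length is invariant under big-node merging", {
  ph <- make_phantom(fast_config(seed = 14))
  res <- graph_from_volume(ph$volume)
  total_before <- sum(vapply(res$graph$edges, function(e) e$length_mm, 0))
  invisible(merge_big_nodes(res$graph, 5))
  total_after <- sum(vapply(res$graph$edges, function(e) e$length_mm, 0))
  expect_identical(total_before, total_after)
})
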