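#' Atlas landmarks for the Circle of Willis branching points
#'
#' Expected world positions (mm, atlas space) of the basilar tip and the
#' left/right M1/A1 bifurcations, plus the y position of the median
#' sagittal plane. With the left-to-right y convention the left landmark
#' must lie below the midline and the right above it.
#'
#' @param basilar,m1a1_left,m1a1_right numeric length-3 world coordinates.
#' @param median_sagittal_y world y of the midline plane.
#' @param candidate_radius_mm search radius around each landmark (default
#'   30 mm).
#' @return a list of class `atlas_landmarks`.
#' @export
atlas_landmarks <- function(basilar, m1a1_left, m1a1_right,
                            median_sagittal_y, candidate_radius_mm = 30) {
  stopifnot(length(basilar) == 3, length(m1a1_left) == 3,
            length(m1a1_right) == 3)
  if (!(m1a1_left[2] < median_sagittal_y && median_sagittal_y < m1a1_right[2]))
    stop("atlas invariant violated: need m1a1_left y < midline < m1a1_right y")
  structure(list(basilar = as.numeric(basilar),
                 m1a1_left = as.numeric(m1a1_left),
                 m1a1_right = as.numeric(m1a1_right),
                 median_sagittal_y = median_sagittal_y,
                 candidate_radius_mm = candidate_radius_mm),
            class = "atlas_landmarks")
}

#' Default atlas: the complete-variant phantom ground truth
#'
#' The phantom's complete-variant branching points double as the
#' pre-labeled atlas (an artifact convention: for clinical use an atlas
#' built from a registered healthy reference would be supplied instead).
#' @export
default_atlas <- function() {
  gt <- build_cow_spec(phantom_config(variant = "complete"))$ground_truth
  atlas_landmarks(gt$node_positions$basilar, gt$node_positions$m1a1_left,
                  gt$node_positions$m1a1_right, gt$median_sagittal_y)
}

#' Write / read atlas landmarks as JSON
#' @param atlas an [atlas_landmarks].
#' @param path JSON path.
#' @export
write_atlas <- function(atlas, path) {
  jsonlite::write_json(unclass(atlas), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  a <- jsonlite::read_json(path, simplifyVector = TRUE)
  atlas_landmarks(a$basilar, a$m1a1_left, a$m1a1_right, a$median_sagittal_y,
                  a$candidate_radius_mm %||% 30)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Candidate big nodes near an atlas landmark
#'
#' All big nodes whose centre lies within `radius_mm` of the landmark
#' (closed ball: a node at exactly the radius is included), sorted by
#' distance; optionally capped at the `k` nearest. An empty list is a
#' legitimate result and drives the indeterminate/variant logic downstream.
#'
#' @param bignodes a `cow_bignodes` list.
#' @param landmark numeric length-3 world mm coordinate.
#' @param radius_mm search radius (default 30 mm).
#' @param k keep at most this many nearest candidates (default all).
#' @return a `cow_bignodes` list (possibly empty) with attribute
#'   `"distance"` giving the centre-to-landmark distances.
#' @export
candidate_nodes <- function(bignodes, landmark, radius_mm = 30, k = Inf) {
  if (length(bignodes) == 0L)
    return(structure(list(), class = "cow_bignodes", distance = numeric(0)))
  d <- vapply(bignodes, function(b) sqrt(sum((b$center - landmark)^2)), 0)
  keep <- which(d <= radius_mm)
  keep <- keep[order(d[keep])]
  if (is.finite(k)) keep <- head(keep, k)
  structure(unclass(bignodes)[keep], class = "cow_bignodes",
            distance = d[keep])
}

#' Basilar candidate score B
#'
#' B scores a candidate big node n for being the end-basilar branching
#' point from its midline offset and the anterior-posterior position of its
#' branches: `B(n) = d_y(n, m) - h(n)_x`, where `d_y` is the absolute y
#' distance from the node centre to the median sagittal plane and `h(n)_x`
#' is the x projection (posterior-to-anterior) of the centre of mass of all
#' branch voxels, both in mm. With `negate_midline_term = TRUE` (the
#' default, frozen against the phantom ground truth) the midline term
#' enters negated so that midline proximity is rewarded; the literal form
#' is kept available behind the flag.
#'
#' @param bignode a big node with at least one branch.
#' @param graph the `cow_graph` the big node belongs to.
#' @param plane_y world y of the median sagittal plane.
#' @param negate_midline_term see above.
#' @return scalar B (mm).
#' @export
score_B <- function(bignode, graph, plane_y, negate_midline_term = TRUE) {
  if (bignode$n_branches == 0L)
    stop("score_B is undefined for a branchless node")
  d_y <- abs(bignode$center[2] - plane_y)
  h_x <- mean(bignode_branch_points(graph, bignode)[, 1])
  (if (negate_midline_term) -d_y else d_y) - h_x
}

#' Label the end-basilar branching point
#'
#' Scores the candidate big nodes within the atlas search radius with
#' [score_B] and returns the candidate with the highest B; ties are broken
#' by distance to the atlas landmark.
#'
#' @param bignodes a `cow_bignodes` list.
#' @param graph the underlying `cow_graph`.
#' @param atlas an [atlas_landmarks].
#' @param k number of nearest candidates retained (default 3).
#' @param negate_midline_term passed to [score_B].
#' @return list with `node` (the winning big node, or `NULL` when no
#'   candidate exists: basilar indeterminate), `scores` (B per candidate)
#'   and `candidates`.
#' @export
label_basilar <- function(bignodes, graph, atlas, k = 3,
                          negate_midline_term = TRUE) {
  cands <- candidate_nodes(bignodes, atlas$basilar,
                           atlas$candidate_radius_mm, k = k)
  if (length(cands) == 0L)
    return(list(node = NULL, scores = numeric(0), candidates = cands,
                status = "indeterminate"))
  b <- vapply(cands, function(nd) score_B(nd, graph, atlas$median_sagittal_y,
                                          negate_midline_term), 0)
  best <- which(b == max(b))
  if (length(best) > 1L)  # tie: candidates are sorted by landmark distance
    best <- best[1L]
  else best <- which.max(b)
  list(node = cands[[best]], scores = b, candidates = cands,
       status = "labeled")
}

#' Maximum y extent of a node's branches, capped
#'
#' `e_i = min(cap_mm, max |y - y_node|)` over the voxels of the big node's
#' branches, in mm. A branch is followed through pure continuation nodes
#' (nodes with exactly two incident edges, which are path splits left by
#' skeletonization, not anatomy) so that the extent reflects the full
#' vessel sweep; it stops at genuine bifurcations. The cap (15 mm) keeps
#' very long lateral sweeps, like the M1 wingspan, from dominating the
#' pair score.
#'
#' @param bignode a big node.
#' @param graph its `cow_graph`.
#' @param cap_mm extent cap in mm (default 15).
#' @return scalar e (mm); 0 for a node whose branches carry no y offset.
#' @export
branch_y_extent <- function(bignode, graph, cap_mm = 15) {
  if (bignode$n_branches == 0L)
    stop("branch_y_extent is undefined for a branchless node")
  yc <- bignode$center[2]
  ne <- length(graph$edges)
  incident <- integer(nrow(graph$nodes))
  for (e in graph$edges) {
    incident[e$from] <- incident[e$from] + 1L
    if (e$to != e$from) incident[e$to] <- incident[e$to] + 1L
    else incident[e$from] <- incident[e$from] + 1L
  }
  edge_y_extent <- function(e) {
    yw <- graph$origin[2] + (e$path[, 2] - 0.5) * graph$spacing[2]
    max(abs(yw - yc))
  }
  visited <- rep(FALSE, ne)
  best <- 0
  queue <- lapply(bignode$branch_edges, function(i)
    list(edge = i, entry = if (graph$edges[[i]]$from %in% bignode$node_ids)
      graph$edges[[i]]$from else graph$edges[[i]]$to))
  while (length(queue) && best < cap_mm) {
    item <- queue[[1]]
    queue <- queue[-1]
    i <- item$edge
    if (visited[i]) next
    visited[i] <- TRUE
    e <- graph$edges[[i]]
    best <- max(best, edge_y_extent(e))
    far <- if (e$from == item$entry) e$to else e$from
    if (far != item$entry && incident[far] == 2L) {
      nxt <- which(!visited & vapply(graph$edges, function(e2)
        e2$from == far || e2$to == far, TRUE))
      for (j in nxt) queue[[length(queue) + 1L]] <- list(edge = j, entry = far)
    }
  }
  min(cap_mm, best)
}

#' Pair score g: compactness versus midline offset
#'
#' `g(i, j) = beta * d(i, j) - max(d_y(i, m), d_y(j, m))` with d the 3-D
#' Euclidean distance between the node centres and d_y the absolute y
#' distance to the median sagittal plane (the max runs over both nodes).
#' Symmetric in (i, j).
#'
#' @param xi,xj numeric length-3 node centres (world mm).
#' @param plane_y world y of the median sagittal plane.
#' @param beta scaling parameter.
#' @return scalar g (mm).
#' @export
score_g <- function(xi, xj, plane_y, beta) {
  beta * sqrt(sum((xi - xj)^2)) -
    max(abs(xi[2] - plane_y), abs(xj[2] - plane_y))
}

#' Pair score M for M1/A1 identification
#'
#' `M(i, j) = alpha * |e_i - e_j| - g(i, j)`, combining the branch-extent
#' contrast of the two candidates with their pair geometry. The node pair
#' with the highest M is labeled as the M1/A1 branching points.
#'
#' @param xi,xj node centres (world mm).
#' @param ei,ej branch y extents from [branch_y_extent].
#' @param plane_y midline y.
#' @param alpha,beta scaling parameters (frozen from the phantom pilot;
#'   see [label_params]).
#' @param g optionally a precomputed g(i, j) to reuse.
#' @return scalar M.
#' @export
score_M <- function(xi, xj, ei, ej, plane_y, alpha, beta, g = NULL) {
  if (is.null(g)) g <- score_g(xi, xj, plane_y, beta)
  alpha * abs(ei - ej) - g
}

#' Symmetry score S for the selected M1/A1 pair
#'
#' `S(i, j) = g(i, j) - |y_i - y_j| / min(y_i, y_j)^2` where `y_i` is the
#' absolute y offset of node i from the median sagittal plane. The penalty
#' term explodes for pairs hugging the midline, which is exactly the
#' failure signature of an aplastic A1: with no lateral bifurcation to
#' find, the pair search falls back on near-midline nodes and S collapses.
#' A node exactly on the midline yields `-Inf` (flagged sentinel).
#'
#' @inheritParams score_g
#' @param beta passed to [score_g].
#' @param g optionally a precomputed g(i, j).
#' @return scalar S; `-Inf` if either node sits on the midline.
#' @export
score_S <- function(xi, xj, plane_y, beta, g = NULL) {
  if (is.null(g)) g <- score_g(xi, xj, plane_y, beta)
  yi <- abs(xi[2] - plane_y)
  yj <- abs(xj[2] - plane_y)
  if (min(yi, yj) == 0) return(-Inf)
  g - abs(yi - yj) / min(yi, yj)^2
}

#' Labeling parameters
#'
#' `alpha` and `beta` weight the M and g pair scores; no canonical values
#' exist, so the defaults were chosen on a phantom pilot grid (maximizing
#' labeling accuracy over complete and aplastic variants) and frozen.
#' `s_threshold` is the default decision cut on S for A1 variant
#' classification, frozen at the Youden-optimal point of the phantom ROC.
#'
#' @param alpha weight of the extent-contrast term in M.
#' @param beta weight of the pair-distance term in g.
#' @param candidate_radius_mm atlas search radius (mm).
#' @param n_candidates candidates kept per landmark.
#' @param cap_mm branch extent cap (mm).
#' @param s_threshold decision threshold on S.
#' @param negate_midline_term sign convention of the B midline term.
#' @export
label_params <- function(alpha = -2, beta = 0.3, candidate_radius_mm = 30,
                         n_candidates = 3, cap_mm = 15, s_threshold = -8,
                         negate_midline_term = TRUE) {
  list(alpha = alpha, beta = beta, candidate_radius_mm = candidate_radius_mm,
       n_candidates = n_candidates, cap_mm = cap_mm,
       s_threshold = s_threshold,
       negate_midline_term = negate_midline_term)
}

#' Label the left and right M1/A1 branching points
#'
#' Collects the nearest candidate big nodes around each of the atlas
#' m1a1 landmarks, assigns candidates to a side by the sign of
#' `y - plane_y`, evaluates M over all left-right candidate pairs and
#' selects the argmax (ties broken by combined distance to the landmarks).
#' A side with no candidates stays unlabeled, which feeds the variant
#' logic. The symmetry score S is evaluated on the winning pair.
#'
#' @param graph a `cow_graph`.
#' @param bignodes its `cow_bignodes`.
#' @param atlas an [atlas_landmarks].
#' @param params a [label_params].
#' @param exclude big nodes already assigned to another anatomical label
#'   (the basilar tip in the full pipeline: the posterior circulation is
#'   labeled first and its node is removed from the carotid candidate
#'   pool).
#' @return list with `left`, `right` (big nodes or `NULL`), `S`, `pairs`
#'   (a data frame of all evaluated pairs with g and M), `e` values, and
#'   `status` (`"both"`, `"left_only"`, `"right_only"`, `"none"`).
#' @export
label_m1a1 <- function(graph, bignodes, atlas, params = label_params(),
                       exclude = NULL) {
  m <- atlas$median_sagittal_y
  if (!is.null(exclude)) {
    if (!is.null(exclude$center)) exclude <- list(exclude)
    ex_centers <- lapply(exclude, function(b) b$center)
    keep <- vapply(bignodes, function(b)
      !any(vapply(ex_centers, function(ctr)
        sqrt(sum((b$center - ctr)^2)) < 1e-9, TRUE)), TRUE)
    bignodes <- structure(unclass(bignodes)[keep], class = "cow_bignodes")
  }
  side_cands <- function(landmark, want_left) {
    cands <- candidate_nodes(bignodes, landmark, params$candidate_radius_mm,
                             k = params$n_candidates)
    sel <- vapply(cands, function(b)
      if (want_left) b$center[2] < m else b$center[2] > m, TRUE)
    unclass(cands)[sel]
  }
  cl <- side_cands(atlas$m1a1_left, TRUE)
  cr <- side_cands(atlas$m1a1_right, FALSE)
  status <- if (length(cl) && length(cr)) "both"
  else if (length(cl)) "left_only"
  else if (length(cr)) "right_only"
  else "none"
  res <- list(left = NULL, right = NULL, S = NA_real_,
              pairs = data.frame(), e = list(), status = status)
  if (status != "both") {
    if (length(cl)) res$left <- best_single(cl, atlas$m1a1_left)
    if (length(cr)) res$right <- best_single(cr, atlas$m1a1_right)
    return(res)
  }
  e_l <- vapply(cl, branch_y_extent, 0, graph = graph, cap_mm = params$cap_mm)
  e_r <- vapply(cr, branch_y_extent, 0, graph = graph, cap_mm = params$cap_mm)
  grid <- expand.grid(i = seq_along(cl), j = seq_along(cr))
  gv <- mv <- dv <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    i <- grid$i[r]; j <- grid$j[r]
    xi <- cl[[i]]$center; xj <- cr[[j]]$center
    gv[r] <- score_g(xi, xj, m, params$beta)
    mv[r] <- score_M(xi, xj, e_l[i], e_r[j], m, params$alpha, params$beta,
                     g = gv[r])
    dv[r] <- sqrt(sum((xi - atlas$m1a1_left)^2)) +
      sqrt(sum((xj - atlas$m1a1_right)^2))
  }
  best <- which(mv == max(mv))
  if (length(best) > 1L) best <- best[which.min(dv[best])]
  bi <- grid$i[best]; bj <- grid$j[best]
  res$left <- cl[[bi]]
  res$right <- cr[[bj]]
  res$S <- score_S(cl[[bi]]$center, cr[[bj]]$center, m, params$beta,
                   g = gv[best])
  res$pairs <- cbind(grid, g = gv, M = mv)
  res$e <- list(left = e_l, right = e_r)
  res
}

best_single <- function(cands, landmark) {
  d <- vapply(cands, function(b) sqrt(sum((b$center - landmark)^2)), 0)
  cands[[which.min(d)]]
}

#' Classify A1 anatomy from the M1/A1 labeling result
#'
#' Variant anatomy is flagged when the pipeline failed to label one (or
#' both) sides, or when the symmetry score S of the selected pair falls
#' below `s_threshold` (including the midline `-Inf` sentinel); otherwise
#' the anatomy is called normal. An indeterminate basilar label does not
#' affect the A1 call.
#'
#' @param m1a1 result of [label_m1a1].
#' @param s_threshold decision threshold on S (default from
#'   [label_params]).
#' @return list with `status` (`"normal"` or `"variant"`), `reason`, `S`
#'   and `s_threshold_used`.
#' @export
classify_a1 <- function(m1a1, s_threshold = label_params()$s_threshold) {
  if (m1a1$status != "both")
    return(list(status = "variant", reason = paste0("unlabeled side (",
                                                    m1a1$status, ")"),
                S = m1a1$S, s_threshold_used = s_threshold))
  if (!is.finite(m1a1$S) || m1a1$S < s_threshold)
    return(list(status = "variant", reason = "S below threshold",
                S = m1a1$S, s_threshold_used = s_threshold))
  list(status = "normal", reason = "symmetric M1/A1 pair identified",
       S = m1a1$S, s_threshold_used = s_threshold)
}
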