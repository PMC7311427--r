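# shared fixtures and independent oracles, all built in code

# number of 26-connected components of a logical array (union-find over the
# voxel adjacency; independent of the skeletonization code path)
count_components26 <- function(mask) {
  d <- dim(mask)
  lin <- which(mask)
  n <- length(lin)
  if (n == 0L) return(0L)
  coords <- arrayInd(lin, d)
  idmap <- array(0L, d)
  idmap[lin] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  off <- off[off[, 1] + 3 * off[, 2] + 9 * off[, 3] > 0, ]
  for (r in seq_len(nrow(off))) {
    sh <- coords + matrix(off[r, ], n, 3, byrow = TRUE)
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    nb <- integer(n)
    nb[ok] <- idmap[sh[ok, , drop = FALSE]]
    for (i in which(nb > 0L)) {
      ri <- find(i)
      rj <- find(nb[i])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# noise-free straight tube volume (generic, off-grid-centre coordinates)
tube_volume <- function(radius = 2, along = "x") {
  if (along == "x") {
    cfg <- phantom_config(shape = c(50L, 16L, 16L), spacing = c(1, 1, 1),
                          noise_sigma = 0)
    sp <- vessel_spec("BA", rbind(c(5, 8.3, 8.2), c(45, 8.3, 8.2)),
                      radius, 1, 0)
  } else {
    cfg <- phantom_config(shape = c(16L, 16L, 50L), spacing = c(1, 1, 1),
                          noise_sigma = 0)
    sp <- vessel_spec("BA", rbind(c(8.3, 8.2, 5), c(8.3, 8.2, 45)),
                      radius, 1, 0)
  }
  rasterize(list(sp), cfg)
}

# noise-free Y-shaped union of three tubes
y_volume <- function() {
  cfg <- phantom_config(shape = c(40L, 40L, 20L), spacing = c(1, 1, 1),
                        noise_sigma = 0)
  specs <- list(
    vessel_spec("BA", rbind(c(20.3, 20.2, 4), c(20.3, 20.2, 12)), 1.5, 1, 0),
    vessel_spec("P1-L", rbind(c(20.3, 20.2, 12), c(12.3, 12.2, 16)),
                1.5, 1, 0),
    vessel_spec("P1-R", rbind(c(20.3, 20.2, 12), c(28.3, 12.2, 16)),
                1.5, 1, 0))
  rasterize(specs, cfg)
}

# solid torus mask (loop-handling oracle)
torus_mask <- function() {
  d <- c(30L, 30L, 12L)
  arr <- array(FALSE, d)
  for (i in 1:30) for (j in 1:30) for (k in 1:12) {
    rr <- sqrt((i - 15.5)^2 + (j - 15.5)^2)
    arr[i, j, k] <- sqrt((rr - 8)^2 + (k - 6.5)^2) <= 2
  }
  arr
}

# fast phantom at 1 mm isotropic (same world geometry, 8x fewer voxels)
fast_config <- function(variant = "complete", seed = 1L, noise_sigma = 0.1) {
  phantom_config(variant = variant, shape = c(80L, 80L, 40L),
                 spacing = c(1, 1, 1), noise_sigma = noise_sigma, seed = seed)
}

# run segmentation -> skeleton -> graph -> big nodes for a phantom volume
graph_from_volume <- function(v) {
  seg <- two_phase_segment(v)
  s1 <- skeletonize3d(seg$mask_strict, spacing = v$spacing,
                      origin = v$origin, phase = "strict")
  s2 <- skeletonize3d(seg$mask_relaxed, preserve = s1, spacing = v$spacing,
                      origin = v$origin, phase = "merged")
  g <- prune(skeleton_to_graph(s2), 10)
  list(seg = seg, skel_strict = s1, skel_merged = s2, graph = g,
       bignodes = merge_big_nodes(g, 5))
}

# hand-built minimal graph for the score arithmetic tests: branch nodes at
# given world coordinates (1 mm spacing, origin 0), each carrying one edge
# whose voxel path is supplied (voxel index = world + 0.5 on this grid)
toy_graph <- function(node_coords, edge_paths) {
  node_coords <- rbind(node_coords)
  # fixture nodes stand in for genuine junctions (degree >= 3)
  nodes <- data.frame(id = seq_len(nrow(node_coords)), kind = "branch",
                      x = node_coords[, 1], y = node_coords[, 2],
                      z = node_coords[, 3], degree = 3L)
  members <- list()
  edges <- list()
  for (i in seq_len(nrow(node_coords))) {
    vox <- node_coords[i, ] + 0.5
    members[[i]] <- matrix(vox, 1, 3)
    path <- edge_paths[[i]]
    edges[[i]] <- list(from = i, to = i, path = path,
                       length_mm = if (nrow(path) > 1)
                         sum(sqrt(rowSums(diff(path)^2))) else 0)
  }
  structure(list(nodes = nodes, members = members, edges = edges,
                 spacing = c(1, 1, 1), origin = c(0, 0, 0),
                 dims = c(100L, 100L, 60L)), class = "cow_graph")
}

# straight voxel path from a world point along a unit direction (1 mm grid)
toy_path <- function(start_world, direction, n) {
  steps <- outer(0:(n - 1), direction)
  sweep(steps, 2, start_world + 0.5, "+")
}

toy_bignode <- function(graph, i) {
  list(id = i, node_ids = i,
       center = as.numeric(graph$nodes[i, c("x", "y", "z")]),
       branch_edges = i, n_branches = 1L)
}
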