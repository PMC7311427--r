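nb26 <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off[rowSums(abs(off)) > 0, , drop = FALSE]
}

# adjacency among the TRUE voxels of a 3-D logical array (26-connectivity);
# returns coords (n x 3), adj (list of neighbor ids), deg
skel_adjacency <- function(mask) {
  d <- dim(mask)
  lin <- which(mask)
  n <- length(lin)
  if (n == 0L)
    return(list(coords = matrix(0L, 0, 3), adj = list(), deg = integer(0),
                lin = lin, dims = d))
  coords <- arrayInd(lin, d)
  idmap <- array(0L, d)
  idmap[lin] <- seq_len(n)
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  off <- nb26()
  half <- off[off[, 1] + 3 * off[, 2] + 9 * off[, 3] > 0, , drop = FALSE]
  for (r in seq_len(nrow(half))) {
    sh <- coords + matrix(half[r, ], n, 3, byrow = TRUE)
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    if (!any(ok)) next
    nb <- integer(n)
    nb[ok] <- idmap[sh[ok, , drop = FALSE]]
    hit <- nb > 0L
    pairs_i <- c(pairs_i, which(hit))
    pairs_j <- c(pairs_j, nb[hit])
  }
  adj <- vector("list", n)
  if (length(pairs_i)) {
    all_i <- c(pairs_i, pairs_j)
    all_j <- c(pairs_j, pairs_i)
    ord <- order(all_i, all_j)
    adj_split <- split(all_j[ord], factor(all_i[ord], levels = seq_len(n)))
    adj <- unname(adj_split)
  }
  deg <- lengths(adj)
  list(coords = coords, adj = adj, deg = deg, lin = lin, dims = d)
}

# remove terminal chains shorter than min_voxels that end at a junction;
# chains touching `protect` (logical array) are kept; whole components are
# never deleted (component-count preservation)
remove_spurs <- function(mask, min_voxels, protect = NULL) {
  if (min_voxels <= 0) return(mask)
  info <- skel_adjacency(mask)
  if (length(info$lin) == 0) return(mask)
  prot <- if (is.null(protect)) rep(FALSE, length(info$lin)) else
    protect[info$lin]
  drop <- integer(0)
  for (ep in which(info$deg == 1L)) {
    chain <- integer(0)
    prev <- 0L
    cur <- ep
    reached_junction <- FALSE
    while (TRUE) {
      if (info$deg[cur] >= 3L) { reached_junction <- TRUE; break }
      chain <- c(chain, cur)
      if (length(chain) >= min_voxels) break
      nxt <- setdiff(info$adj[[cur]], prev)
      if (length(nxt) == 0L) break  # component is a bare path: keep
      prev <- cur
      cur <- nxt[1L]
    }
    if (reached_junction && length(chain) < min_voxels && !any(prot[chain]))
      drop <- c(drop, chain)
  }
  if (length(drop)) mask[info$lin[unique(drop)]] <- FALSE
  mask
}

#' One-voxel-thick skeleton of a binary mask
#'
#' Topology-preserving 3-D thinning (26-connectivity foreground,
#' 6-connectivity background): voxels are peeled from the six face
#' directions in sequence and removed only when deletion provably leaves
#' both foreground and background connectivity unchanged (simple-point
#' test), so the skeleton has exactly as many connected components as the
#' mask. Voxels of `preserve` are never deleted, which is how the Phase-1
#' skeleton survives inside the Phase-2 segmentation. Raw thinning emits
#' one- and two-voxel whiskers wherever the tube surface is rough; terminal
#' chains shorter than `spur_min_voxels` are suppressed before graph
#' conversion.
#'
#' @param mask nonempty logical array (or 0/1 [cow_volume]).
#' @param preserve an earlier [skeletonize3d] result (or logical array)
#'   whose voxels must all lie inside `mask`; optional.
#' @param spacing,origin grid geometry (taken from `mask` when it is a
#'   [cow_volume]).
#' @param spur_min_voxels suppress terminal spurs shorter than this many
#'   voxels (0 disables).
#' @param phase provenance tag: `"strict"`, `"relaxed"` or `"merged"`.
#' @return a `cow_skeleton`: list with the skeleton `mask`, `phase`,
#'   `spacing`, `origin`.
#' @export
skeletonize3d <- function(mask, preserve = NULL, spacing = c(1, 1, 1),
                          origin = c(0, 0, 0), spur_min_voxels = 3L,
                          phase = "strict") {
  if (inherits(mask, "cow_volume")) {
    spacing <- mask$spacing
    origin <- mask$origin
    mask <- mask$data > 0
  }
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("mask is empty: nothing to skeletonize")
  pres <- NULL
  if (!is.null(preserve)) {
    pres <- if (inherits(preserve, "cow_skeleton")) preserve$mask else preserve
    stopifnot(identical(dim(pres), dim(mask)))
    if (any(pres & !mask))
      stop("preserve skeleton is not contained in the mask")
  }
  thin <- .cpp_thin3d(as.logical(mask), as.integer(dim(mask)),
                      if (is.null(pres)) logical(0) else as.logical(pres))
  thin <- array(thin, dim(mask))
  thin <- remove_spurs(thin, spur_min_voxels, protect = pres)
  structure(list(mask = thin, phase = phase, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "cow_skeleton")
}

#' @export
print.cow_skeleton <- function(x, ...) {
  cat(sprintf("<cow_skeleton> %d voxels (%s phase)\n", sum(x$mask), x$phase))
  invisible(x)
}

#' Convert a skeleton to a vascular graph
#'
#' Skeleton voxels with a number of 26-neighbors other than two become
#' graph nodes (branch points, end points, isolated voxels); adjacent node
#' voxels are grouped into a single node (lexicographic voxel order breaks
#' grouping ties so runs are bit-reproducible); maximal degree-2 chains
#' between nodes become edges carrying their ordered voxel path and arc
#' length in mm. A closed loop with no node voxel is anchored at its
#' lexicographically smallest voxel, which becomes a node with a self-edge.
#'
#' @param skeleton a `cow_skeleton` from [skeletonize3d].
#' @return a `cow_graph`: `nodes` (data frame: id, kind, world mm
#'   coordinates, degree), `members` (voxel coordinates per node), `edges`
#'   (from, to, voxel path, length_mm), plus grid geometry. An empty
#'   skeleton yields an empty graph.
#' @export
skeleton_to_graph <- function(skeleton) {
  stopifnot(inherits(skeleton, "cow_skeleton"))
  sp <- skeleton$spacing
  org <- skeleton$origin
  info <- skel_adjacency(skeleton$mask)
  n <- length(info$lin)
  empty_nodes <- data.frame(id = integer(0), kind = character(0),
                            x = numeric(0), y = numeric(0), z = numeric(0),
                            degree = integer(0))
  g <- structure(list(nodes = empty_nodes, members = list(), edges = list(),
                      spacing = sp, origin = org, dims = info$dims),
                 class = "cow_graph")
  if (n == 0L) return(g)

  is_node <- info$deg != 2L
  node_ids <- which(is_node)
  # group adjacent node voxels (union-find)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (v in node_ids) {
    for (w in info$adj[[v]]) {
      if (w > v && is_node[w]) {
        rv <- find(v); rw <- find(w)
        if (rv != rw) parent[max(rv, rw)] <- min(rv, rw)
      }
    }
  }
  group_of <- integer(n)
  roots <- vapply(node_ids, find, 1L)
  uroots <- sort(unique(roots))
  group_of[node_ids] <- match(roots, uroots)
  ngroups <- length(uroots)
  members <- split(node_ids, group_of[node_ids])

  to_world <- function(vox) {
    vox <- rbind(vox)
    sweep(sweep(vox - 0.5, 2, sp, "*"), 2, org, "+")
  }

  kinds <- character(ngroups)
  centers <- matrix(0, ngroups, 3)
  memb_coords <- vector("list", ngroups)
  for (gid in seq_len(ngroups)) {
    mv <- members[[gid]]
    dmax <- max(info$deg[mv])
    kinds[gid] <- if (dmax >= 3L) "branch" else if (dmax == 1L) "end"
    else "isolated"
    memb_coords[[gid]] <- info$coords[mv, , drop = FALSE]
    centers[gid, ] <- colMeans(to_world(memb_coords[[gid]]))
  }

  visited <- rep(FALSE, n)
  edges <- list()
  add_edge <- function(from, to, path_ids) {
    pc <- info$coords[path_ids, , drop = FALSE]
    wl <- to_world(pc)
    len <- if (nrow(wl) > 1) sum(sqrt(rowSums(diff(wl)^2))) else 0
    edges[[length(edges) + 1L]] <<- list(from = from, to = to, path = pc,
                                         length_mm = len)
  }
  for (gid in seq_len(ngroups)) {
    for (v in members[[gid]]) {
      for (w in info$adj[[v]]) {
        if (is_node[w] || visited[w]) next
        path <- c(v, w)
        visited[w] <- TRUE
        prev <- v
        cur <- w
        while (!is_node[cur]) {
          nxt <- setdiff(info$adj[[cur]], prev)
          if (length(nxt) == 0L) break  # dangling chain end (cannot happen)
          prev <- cur
          cur <- nxt[1L]
          if (!is_node[cur]) visited[cur] <- TRUE
          path <- c(path, cur)
        }
        add_edge(gid, if (is_node[cur]) group_of[cur] else gid, path)
      }
    }
  }
  # pure cycles with no node voxel: anchor at the smallest remaining voxel
  remaining <- which(!is_node & !visited)
  while (length(remaining)) {
    anchor <- remaining[1L]
    ngroups <- ngroups + 1L
    kinds <- c(kinds, "anchor")
    memb_coords[[ngroups]] <- info$coords[anchor, , drop = FALSE]
    centers <- rbind(centers, to_world(info$coords[anchor, , drop = FALSE]))
    group_of[anchor] <- ngroups
    is_node[anchor] <- TRUE
    visited[anchor] <- TRUE
    path <- anchor
    prev <- anchor
    cur <- info$adj[[anchor]][1L]
    while (cur != anchor) {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nxt <- setdiff(info$adj[[cur]], prev)
      prev <- cur
      cur <- if (length(nxt)) nxt[1L] else anchor
    }
    path <- c(path, anchor)
    add_edge(ngroups, ngroups, path)
    remaining <- which(!is_node & !visited)
  }

  degree <- integer(ngroups)
  for (e in edges) {
    degree[e$from] <- degree[e$from] + 1L
    if (e$to != e$from) degree[e$to] <- degree[e$to] + 1L
    else degree[e$from] <- degree[e$from] + 1L
  }
  g$nodes <- data.frame(id = seq_len(ngroups), kind = kinds,
                        x = centers[, 1], y = centers[, 2], z = centers[, 3],
                        degree = degree)
  g$members <- memb_coords
  g$edges <- edges
  g
}

#' @export
print.cow_graph <- function(x, ...) {
  cat(sprintf("<cow_graph> %d nodes (%d branch, %d end), %d edges, %.1f mm total\n",
              nrow(x$nodes), sum(x$nodes$kind == "branch"),
              sum(x$nodes$kind == "end"), length(x$edges),
              sum(vapply(x$edges, function(e) e$length_mm, 0))))
  invisible(x)
}

# rebuild the skeleton voxel mask underlying a graph
graph_to_mask <- function(graph) {
  m <- array(FALSE, graph$dims)
  for (mc in graph$members) m[mc] <- TRUE
  for (e in graph$edges) m[e$path] <- TRUE
  m
}

#' Prune short terminal edges and skeleton artifacts from a vascular graph
#'
#' Removes terminal (leaf) segments shorter than `min_length_px` skeleton
#' voxels, re-merges the degree-2 nodes this creates, and repeats to a
#' fixed point; pruning is idempotent. Two further skeleton artifacts are
#' dissolved along the way: small cycles (self-edges or parallel edge
#' pairs whose cycle is at most `2 * min_length_px` voxels; these arise
#' where the preserved Phase-1 skeleton and the Phase-2 thinning disagree
#' by a voxel) keep only their shorter branch, and degenerate junction
#' clusters left with exactly two incident edges are reduced to a simple
#' connector path so the through-edge is re-merged. `min_length_px = 0`
#' returns the graph unchanged.
#'
#' @param graph a `cow_graph`.
#' @param min_length_px minimum terminal segment length in voxels.
#' @return a pruned `cow_graph`.
#' @export
prune <- function(graph, min_length_px = 10) {
  stopifnot(inherits(graph, "cow_graph"), min_length_px >= 0)
  if (min_length_px == 0 || nrow(graph$nodes) == 0) return(graph)
  mask <- graph_to_mask(graph)
  skel <- structure(list(mask = mask, phase = "merged",
                         spacing = graph$spacing, origin = graph$origin),
                    class = "cow_skeleton")
  g <- graph
  repeat {
    repeat {
      before <- sum(skel$mask)
      skel$mask <- remove_spurs(skel$mask, min_length_px)
      if (sum(skel$mask) == before) break
    }
    g <- skeleton_to_graph(skel)
    drop_vox <- prune_artifact_voxels(g, min_length_px)
    if (length(drop_vox) == 0L) break
    skel$mask[drop_vox] <- FALSE
  }
  g
}

# linear voxel indices to delete for small-cycle and degenerate-junction
# artifacts of a graph (empty when the graph is clean)
prune_artifact_voxels <- function(g, min_length_px) {
  d <- g$dims
  lin <- function(vox) vox[, 1] + d[1] * (vox[, 2] - 1L) +
    d[1] * d[2] * (vox[, 3] - 1L)
  member_lin <- lapply(g$members, lin)
  interior <- function(e) {
    pl <- lin(e$path)
    setdiff(pl, c(member_lin[[e$from]], member_lin[[e$to]]))
  }
  # short self-edges
  for (e in g$edges) {
    if (e$from == e$to && nrow(e$path) - 1 <= 2 * min_length_px) {
      iv <- interior(e)
      if (length(iv)) return(iv)
    }
  }
  # parallel edge pairs forming a small cycle: drop the longer branch
  if (length(g$edges) >= 2) {
    keys <- vapply(g$edges, function(e)
      paste(sort(c(e$from, e$to)), collapse = "-"), "")
    for (k in unique(keys[duplicated(keys)])) {
      idx <- which(keys == k)
      if (g$edges[[idx[1]]]$from == g$edges[[idx[1]]]$to) next
      sz <- vapply(g$edges[idx], function(e) nrow(e$path), 0L)
      if (sum(sz[order(sz)[1:2]]) <= 2 * min_length_px + 2) {
        iv <- interior(g$edges[[idx[order(sz, decreasing = TRUE)[1]]]])
        if (length(iv)) return(iv)
      }
    }
  }
  # degenerate junction clusters: branch-voxel groups with exactly two
  # incident edges collapse to the shortest member path linking the two
  # edge attachment voxels
  inc <- vector("list", nrow(g$nodes))
  for (i in seq_along(g$edges)) {
    e <- g$edges[[i]]
    inc[[e$from]] <- c(inc[[e$from]], i)
    if (e$to != e$from) inc[[e$to]] <- c(inc[[e$to]], i)
  }
  for (nid in which(g$nodes$kind == "branch")) {
    ids <- inc[[nid]]
    if (length(ids) != 2L || nrow(g$members[[nid]]) < 2L) next
    if (any(vapply(g$edges[ids], function(e) e$from == e$to, TRUE))) next
    ml <- member_lin[[nid]]
    att <- vapply(ids, function(i) {
      pl <- lin(g$edges[[i]]$path)
      pl[pl %in% ml][1]
    }, 0)
    keep <- connector_path(g$members[[nid]], ml, att[1], att[2])
    iv <- setdiff(ml, keep)
    if (length(iv)) return(iv)
  }
  integer(0)
}

# shortest 26-connected path between two voxels within a small member set
# (linear indices); returns the linear indices to keep
connector_path <- function(coords, mlin, a, b) {
  n <- length(mlin)
  ia <- match(a, mlin)
  ib <- match(b, mlin)
  if (is.na(ia) || is.na(ib)) return(mlin)
  adjm <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && max(abs(coords[i, ] - coords[j, ])) <= 1) adjm[i, j] <- TRUE
  }
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  queue <- ia
  seen[ia] <- TRUE
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    if (cur == ib) break
    for (j in which(adjm[cur, ] & !seen)) {
      seen[j] <- TRUE
      prev[j] <- cur
      queue <- c(queue, j)
    }
  }
  if (!seen[ib]) return(mlin)
  path <- ib
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  mlin[path]
}

#' Merge nearby branch points into big nodes
#'
#' Anatomical branching points (e.g. the basilar tip, where both P1s, the
#' superior cerebellar arteries and the basilar artery meet) fragment into
#' several skeleton branch voxels; all graph junctions (branch nodes with
#' at least three incident edges) within a region of at most `radius_mm`
#' are merged into one *big node* by single-linkage clustering, with
#' clusters whose diameter exceeds `2 * radius_mm` split post hoc. Each
#' big node carries the incident edges of all its members that leave the
#' cluster.
#'
#' @param graph a `cow_graph`.
#' @param radius_mm region radius in mm (default 5).
#' @return list of class `cow_bignodes`; each element has `node_ids`,
#'   `center` (mean member world coordinate), `branch_edges` (edge indices
#'   into `graph$edges`) and `n_branches`.
#' @export
merge_big_nodes <- function(graph, radius_mm = 5) {
  stopifnot(inherits(graph, "cow_graph"), radius_mm > 0)
  # anatomical branching points are junctions of the graph (>= 3 incident
  # edges); a branch-kind voxel cluster whose other edges were pruned away
  # is a path remnant, not a bifurcation
  bidx <- which(graph$nodes$kind == "branch" & graph$nodes$degree >= 3L)
  out <- list()
  if (length(bidx) == 0L)
    return(structure(out, class = "cow_bignodes"))
  coords <- as.matrix(graph$nodes[bidx, c("x", "y", "z")])
  cluster_ids <- cluster_linkage(coords, radius_mm)
  for (cl in sort(unique(cluster_ids))) {
    node_ids <- bidx[cluster_ids == cl]
    center <- colMeans(coords[cluster_ids == cl, , drop = FALSE])
    inside <- logical(nrow(graph$nodes))
    inside[node_ids] <- TRUE
    branch_edges <- which(vapply(graph$edges, function(e)
      xor(inside[e$from], inside[e$to]), TRUE))
    out[[length(out) + 1L]] <- list(id = length(out) + 1L,
                                    node_ids = node_ids,
                                    center = as.numeric(center),
                                    branch_edges = branch_edges,
                                    n_branches = length(branch_edges))
  }
  structure(out, class = "cow_bignodes")
}

# single-linkage clustering with linkage cut `h`, splitting any cluster
# whose diameter exceeds 2 h by re-cutting at a smaller height
cluster_linkage <- function(coords, h) {
  n <- nrow(coords)
  if (n == 1L) return(1L)
  cl <- cutree(hclust(dist(coords), method = "single"), h = h)
  repeat {
    changed <- FALSE
    for (c0 in unique(cl)) {
      sel <- cl == c0
      if (sum(sel) < 2L) next
      dm <- dist(coords[sel, , drop = FALSE])
      hh <- h
      while (max(dm) > 2 * h && hh > h / 16) {
        hh <- hh * 0.75
        sub <- cutree(hclust(dm, method = "single"), h = hh)
        if (length(unique(sub)) > 1L) {
          cl[sel] <- max(cl) + sub
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  as.integer(factor(cl))
}

# world coordinates of all voxels on a big node's branch edges
bignode_branch_points <- function(graph, bignode) {
  if (length(bignode$branch_edges) == 0L)
    return(matrix(numeric(0), 0, 3))
  vox <- do.call(rbind, lapply(graph$edges[bignode$branch_edges],
                               function(e) e$path))
  sweep(sweep(vox - 0.5, 2, graph$spacing, "*"), 2, graph$origin, "+")
}

#' @export
print.cow_bignodes <- function(x, ...) {
  cat(sprintf("<cow_bignodes> %d big nodes\n", length(x)))
  for (b in x)
    cat(sprintf("  #%d: %d member nodes, %d branches, center (%.1f, %.1f, %.1f)\n",
                b$id, length(b$node_ids), b$n_branches, b$center[1],
                b$center[2], b$center[3]))
  invisible(x)
}
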