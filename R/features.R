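#' F-score parameters and the fitted F* coefficients
#'
#' Weights of the bilateral A1 comparison score
#' `F = a|r_i - r_j| + b|p_i - p_j| + H(i, j) - c|T_i + T_j|`
#' and the reduced fitted form
#' `F* = 0.19367 |r_i - r_j| - 7.1199 |p_i - p_j|`,
#' whose two coefficients are fixed by default. No canonical a/b/c weights
#' exist; the defaults simply expose every term.
#'
#' @param a,b,c weights of the radius, intensity and tortuosity terms of F.
#' @param fstar_r_coef,fstar_p_coef coefficients of the fitted F* score.
#' @param fstar_threshold classification cut on F* (frozen from the phantom
#'   pilot; hypoplastic iff F* exceeds it).
#' @export
fscore_params <- function(a = 1, b = 1, c = 0.1,
                          fstar_r_coef = 0.19367, fstar_p_coef = 7.1199,
                          fstar_threshold = 0.08) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c),
            is.finite(fstar_r_coef), is.finite(fstar_p_coef))
  list(a = a, b = b, c = c, fstar_r_coef = fstar_r_coef,
       fstar_p_coef = fstar_p_coef, fstar_threshold = fstar_threshold)
}

#' Extract the A1 segment path from a labeled M1/A1 node
#'
#' From the M1/A1 big node, follows the incident edge that heads medially:
#' the edge minimizing the smallest midline offset |y - m| reached along
#' its voxel path (the A1 is the only branch that runs toward the anterior
#' communicating junction at the midline). The path starts at the node and
#' is truncated at the first node encountered moving medially or at the
#' median sagittal plane crossing, whichever comes first. If no incident
#' edge moves the path closer to the midline than the node itself, the
#' side is flagged aplastic-by-feature.
#'
#' @param graph a `cow_graph`.
#' @param m1a1_node the labeled big node for one side.
#' @param plane_y world y of the median sagittal plane.
#' @return list with `path` (ordered voxel coordinates), `world` (the same
#'   in world mm), `has_endpoint` (the walk terminated at a free skeleton
#'   end before reaching the midline or a node), and `status`
#'   (`"ok"` or `"aplastic"` when no medial edge exists).
#' @export
extract_a1_path <- function(graph, m1a1_node, plane_y) {
  if (m1a1_node$n_branches == 0L)
    return(list(path = NULL, world = NULL, has_endpoint = FALSE,
                status = "aplastic"))
  node_y <- abs(m1a1_node$center[2] - plane_y)
  world_of <- function(vox)
    sweep(sweep(vox - 0.5, 2, graph$spacing, "*"), 2, graph$origin, "+")
  inside <- logical(nrow(graph$nodes))
  inside[m1a1_node$node_ids] <- TRUE
  best <- NULL
  best_min <- Inf
  for (ei in m1a1_node$branch_edges) {
    e <- graph$edges[[ei]]
    pw <- world_of(e$path)
    if (!inside[e$from]) pw <- pw[rev(seq_len(nrow(pw))), , drop = FALSE]
    mn <- min(abs(pw[, 2] - plane_y))
    if (mn < best_min) {
      best_min <- mn
      best <- list(edge = ei, world = pw,
                   far = if (inside[e$from]) e$to else e$from)
    }
  }
  if (is.null(best) || best_min >= node_y)
    return(list(path = NULL, world = NULL, has_endpoint = FALSE,
                status = "aplastic"))
  pw <- best$world
  e <- graph$edges[[best$edge]]
  path <- if (!inside[e$from]) e$path[rev(seq_len(nrow(e$path))), ,
                                      drop = FALSE] else e$path
  side0 <- sign(pw[1, 2] - plane_y)
  crossed <- which(sign(pw[, 2] - plane_y) == -side0)
  cut <- if (length(crossed)) crossed[1L] - 1L else nrow(pw)
  truncated <- length(crossed) > 0L
  path <- path[seq_len(cut), , drop = FALSE]
  pw <- pw[seq_len(cut), , drop = FALSE]
  has_endpoint <- !truncated && graph$nodes$kind[best$far] == "end"
  list(path = path, world = pw, has_endpoint = has_endpoint, status = "ok")
}

#' Radius and intensity of a segment via the sphere-union artery model
#'
#' The artery volume is modeled as the union of all spheres centred on the
#' skeleton path that fit inside the segmentation mask; the sphere radius
#' at each path voxel is the Euclidean distance (spacing-aware, mm) from
#' the voxel centre to the nearest background voxel centre. `r` is the
#' mean sphere radius and `p` the mean signal intensity over the union
#' volume.
#'
#' @param path n x 3 voxel coordinates (must all lie inside `mask`).
#' @param mask logical array: the (relaxed) segmentation mask.
#' @param volume the intensity [cow_volume].
#' @return list with `r` (mm), `p` (intensity units), per-voxel `radii`,
#'   and the number of voxels in the sphere union.
#' @export
sphere_union_stats <- function(path, mask, volume) {
  stopifnot(is.matrix(path), nrow(path) >= 1)
  if (!all(mask[path]))
    stop("path voxel outside the segmentation mask")
  d <- dim(mask)
  sp <- volume$spacing
  edt <- array(.cpp_edt(as.logical(mask), as.integer(d), sp), d)
  radii <- edt[path]
  union <- array(FALSE, d)
  for (i in seq_len(nrow(path))) {
    r <- radii[i]
    ctr <- path[i, ]
    span <- ceiling(r / sp)
    rng <- lapply(1:3, function(a)
      max(1, ctr[a] - span[a]):min(d[a], ctr[a] + span[a]))
    box <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    dd <- sweep(box, 2, ctr)
    dd <- sweep(dd, 2, sp, "*")
    inside <- rowSums(dd^2) <= r^2
    union[box[inside, , drop = FALSE]] <- TRUE
  }
  list(r = mean(radii), p = mean(volume$data[union]), radii = radii,
       union_voxels = sum(union))
}

#' Tortuosity of a skeleton path
#'
#' Arc length of the path divided by the chord between its end points;
#' T >= 1, with equality exactly for a straight path. Paths with
#' coincident end points (loops) are rejected.
#'
#' @param world n x 3 matrix of ordered world mm coordinates (n >= 2).
#' @return scalar tortuosity (dimensionless).
#' @export
tortuosity <- function(world) {
  stopifnot(is.matrix(world), nrow(world) >= 2)
  chord <- sqrt(sum((world[nrow(world), ] - world[1, ])^2))
  if (chord == 0) stop("coincident path end points: tortuosity undefined")
  arc <- sum(sqrt(rowSums(diff(world)^2)))
  max(1, arc / chord)
}

#' Endpoint asymmetry indicator H
#'
#' 1 if and only if side i's A1 skeleton has a free end point and side j's
#' does not; 0 otherwise. Deliberately asymmetric: `H(i, j) != H(j, i)`
#' when exactly one side ends freely.
#'
#' @param i,j per-side feature lists with a logical `has_endpoint`.
#' @return 0 or 1.
#' @export
endpoint_asymmetry_H <- function(i, j) {
  as.numeric(isTRUE(i$has_endpoint) && !isTRUE(j$has_endpoint))
}

#' Bilateral A1 comparison score F
#'
#' `F_i = a|r_i - r_j| + b|p_i - p_j| + H(i, j) - c|T_i + T_j|` comparing
#' the left and right A1 segments; only the H term breaks the i/j symmetry.
#'
#' @param i,j per-side feature lists with `r`, `p`, `T`, `has_endpoint`.
#' @param params an [fscore_params].
#' @return scalar F.
#' @export
score_F <- function(i, j, params = fscore_params()) {
  params$a * abs(i$r - j$r) + params$b * abs(i$p - j$p) +
    endpoint_asymmetry_H(i, j) - params$c * abs(i$T + j$T)
}

#' Reduced fitted score F*
#'
#' `F* = 0.19367 |r_i - r_j| - 7.1199 |p_i - p_j|` with the fitted
#' coefficients fixed by default; r in mm, p on the histogram-matched
#' intensity scale.
#'
#' @inheritParams score_F
#' @return scalar F*.
#' @export
score_Fstar <- function(i, j, params = fscore_params()) {
  params$fstar_r_coef * abs(i$r - j$r) - params$fstar_p_coef * abs(i$p - j$p)
}

#' Classify hypoplasia from F*
#'
#' @param fstar scalar F* value.
#' @param threshold decision cut (default from [fscore_params]).
#' @return `"hypoplastic"` iff `fstar > threshold`, else `"normal"`.
#' @export
classify_hypoplasia <- function(fstar,
                                threshold = fscore_params()$fstar_threshold) {
  if (fstar > threshold) "hypoplastic" else "normal"
}

#' Fit the F* coefficients from a labeled cohort
#'
#' Ordinary least squares of the response on the four F terms |dr|, |dp|,
#' H and |T_i + T_j|; zero-variance predictors are dropped up front, terms
#' with coefficient p-value >= `p_cut` are disregarded and the model
#' refitted on the survivors.
#'
#' @param cohort data frame with columns `dr`, `dp`, `H`, `Tsum` and
#'   `label` (the response: 0/1 class or a continuous score).
#' @param p_cut significance cut for term dropping (default 0.05).
#' @return named numeric vector of surviving coefficients (intercept
#'   excluded), with the fitted `lm` attached as attribute `"fit"`.
#' @export
fit_fstar_coefficients <- function(cohort, p_cut = 0.05) {
  need <- c("dr", "dp", "H", "Tsum", "label")
  stopifnot(all(need %in% names(cohort)))
  classes <- unique(cohort$label)
  if (length(classes) < 2L)
    stop("single-class cohort: cannot fit a classifier")
  if (length(classes) == 2L && min(table(cohort$label)) < 2L)
    stop("need at least 2 subjects per class")
  terms <- c("dr", "dp", "H", "Tsum")
  keep <- terms[vapply(terms, function(t) length(unique(cohort[[t]])) > 1L,
                       TRUE)]
  if (length(keep) == 0L) stop("degenerate design matrix: no varying term")
  fit_terms <- function(tt) {
    f <- stats::as.formula(paste("label ~", paste(tt, collapse = " + ")))
    fit <- lm(f, data = cohort)
    if (any(is.na(coef(fit))))
      stop("degenerate design matrix: collinear terms")
    fit
  }
  fit <- fit_terms(keep)
  pv <- summary(fit)$coefficients[-1, 4]
  surv <- keep[pv < p_cut]
  if (length(surv) && length(surv) < length(keep)) fit <- fit_terms(surv)
  else surv <- keep
  out <- coef(fit)[surv]
  attr(out, "fit") <- fit
  out
}

#' Compute the per-side A1 features for a labeled subject
#'
#' Convenience wrapper running [extract_a1_path], [sphere_union_stats] and
#' [tortuosity] for one side.
#'
#' @param graph a `cow_graph`.
#' @param m1a1_node labeled big node (or `NULL` for an unlabeled side).
#' @param plane_y midline y.
#' @param mask_relaxed relaxed segmentation mask.
#' @param volume intensity [cow_volume].
#' @return list with `r`, `p`, `T`, `has_endpoint`, `status`, `path`.
#' @export
a1_features <- function(graph, m1a1_node, plane_y, mask_relaxed, volume) {
  if (is.null(m1a1_node))
    return(list(r = NA_real_, p = NA_real_, T = NA_real_,
                has_endpoint = FALSE, status = "unlabeled", path = NULL))
  ext <- extract_a1_path(graph, m1a1_node, plane_y)
  if (ext$status != "ok" || is.null(ext$path) || nrow(ext$path) < 2)
    return(list(r = NA_real_, p = NA_real_, T = NA_real_,
                has_endpoint = ext$has_endpoint, status = "aplastic",
                path = NULL))
  keep <- mask_relaxed[ext$path]
  path <- ext$path[keep, , drop = FALSE]
  world <- ext$world[keep, , drop = FALSE]
  if (nrow(path) < 2)
    return(list(r = NA_real_, p = NA_real_, T = NA_real_,
                has_endpoint = ext$has_endpoint, status = "aplastic",
                path = NULL))
  st <- sphere_union_stats(path, mask_relaxed, volume)
  list(r = st$r, p = st$p, T = tortuosity(world),
       has_endpoint = ext$has_endpoint, status = "ok", path = path)
}
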