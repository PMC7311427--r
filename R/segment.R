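#' Segmentation parameters for one phase
#'
#' The pipeline segments twice: a *strict* phase that isolates the bright
#' central vasculature and a *relaxed* phase that deliberately
#' over-segments to admit dimmer peripheral structure (thin communicating
#' arteries, partial-volume shells). Defaults for the two phases were
#' frozen from phantom pilot runs and differ only in the parameters below.
#'
#' @param phase `"strict"` or `"relaxed"`.
#' @param n_clusters_init initial K for the adaptive k-means intensity
#'   clustering.
#' @param min_center_distance minimum separation between retained cluster
#'   centres, measured on the internal 0-255 rescaled intensity axis;
#'   closer centres are merged (size-weighted).
#' @param keep_top how many of the brightest merged clusters form the
#'   initialization mask (1 for strict, more for relaxed).
#' @param cv_mu Chan-Vese boundary-length weight (per mm^2 of interface, on
#'   unit-normalized intensities).
#' @param cv_lambda1,cv_lambda2 inside/outside data-term weights.
#' @param cv_iterations iteration cap for the level-set descent.
#' @param cv_tol convergence tolerance: stop when the fraction of voxels
#'   changed per sweep falls below this.
#' @param smooth_sigma_mm SD (mm) of the Gaussian denoising filter applied
#'   before clustering inside [two_phase_segment] (the stand-in for the
#'   nonlinear noise filtering a clinical pipeline applies upstream);
#'   0 disables.
#' @return a list of class `segmentation_params`.
#' @export
segmentation_params <- function(phase = c("strict", "relaxed"),
                                n_clusters_init = 4L,
                                min_center_distance = 10,
                                keep_top = NULL,
                                cv_mu = NULL,
                                cv_lambda1 = NULL, cv_lambda2 = NULL,
                                cv_iterations = 200L, cv_tol = 1e-4,
                                smooth_sigma_mm = 0.4) {
  phase <- match.arg(phase)
  if (is.null(keep_top)) keep_top <- if (phase == "strict") 1L else 3L
  if (is.null(cv_mu)) cv_mu <- if (phase == "strict") 0.05 else 0.01
  if (is.null(cv_lambda1)) cv_lambda1 <- if (phase == "strict") 2 else 1
  if (is.null(cv_lambda2)) cv_lambda2 <- 1
  stopifnot(cv_iterations >= 1, is.finite(cv_mu), is.finite(cv_lambda1),
            is.finite(cv_lambda2), n_clusters_init >= 2)
  structure(list(phase = phase, n_clusters_init = as.integer(n_clusters_init),
                 min_center_distance = min_center_distance,
                 keep_top = as.integer(keep_top), cv_mu = cv_mu,
                 cv_lambda1 = cv_lambda1, cv_lambda2 = cv_lambda2,
                 cv_iterations = as.integer(cv_iterations), cv_tol = cv_tol,
                 smooth_sigma_mm = smooth_sigma_mm),
            class = "segmentation_params")
}

#' Adaptive k-means vessel initialization
#'
#' Clusters voxel intensities (rescaled to 0-255) with k-means seeded
#' deterministically at evenly spaced intensities, merges cluster centres
#' closer than `min_center_distance` on that axis (size-weighted), and
#' returns the union of the `keep_top` brightest clusters as the vessel
#' initialization mask. The procedure contains no random element, so
#' results are identical across seeds by construction.
#'
#' @param volume a [cow_volume] (at least 2 distinct intensities).
#' @param params a [segmentation_params].
#' @return logical array: the initialization mask. The merged cluster
#'   centres (0-255 axis) are attached as attribute `"centers"`.
#' @export
adaptive_kmeans <- function(volume, params = segmentation_params("strict")) {
  x <- as.numeric(volume$data)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("fewer than 2 distinct intensities: cannot cluster")
  xs <- (x - lo) / (hi - lo) * 255
  # deterministic subsample for the center fit; assignment uses all voxels
  n <- length(xs)
  fit_x <- if (n > 400000L) xs[seq(1L, n, length.out = 400000L)] else xs
  k <- params$n_clusters_init
  ux <- sort(unique(fit_x))
  centers <- if (length(ux) <= k) {
    # fewer distinct levels than clusters: the levels are the optimum
    ux
  } else {
    init <- seq(0, 255, length.out = k)
    km <- suppressWarnings(kmeans(fit_x, centers = matrix(init, ncol = 1),
                                  iter.max = 100L, algorithm = "Lloyd"))
    sort(as.numeric(km$centers[is.finite(km$centers)]))
  }
  sizes <- as.numeric(table(factor(findInterval(
    fit_x, midpoints(centers)) + 1L, levels = seq_along(centers))))
  # merge centres closer than the minimum separation, nearest pair first
  while (length(centers) > 1L) {
    gaps <- diff(centers)
    j <- which.min(gaps)
    if (gaps[j] >= params$min_center_distance) break
    w <- sizes[j] + sizes[j + 1L]
    centers[j] <- (centers[j] * sizes[j] + centers[j + 1L] * sizes[j + 1L]) / w
    sizes[j] <- w
    centers <- centers[-(j + 1L)]
    sizes <- sizes[-(j + 1L)]
  }
  ncl <- length(centers)
  keep <- max(1L, ncl - params$keep_top + 1L)
  assign_all <- findInterval(xs, midpoints(centers)) + 1L
  mask <- array(assign_all >= keep, dim(volume$data))
  attr(mask, "centers") <- centers
  mask
}

midpoints <- function(centers) {
  if (length(centers) < 2L) return(numeric(0))
  (centers[-1] + centers[-length(centers)]) / 2
}

#' Chan-Vese active contour refinement
#'
#' Minimizes the two-phase piecewise-constant Chan-Vese energy (region
#' means inside/outside plus a boundary-area penalty weighted by `cv_mu`)
#' starting from `init_mask`, by coordinate-wise descent on the binary
#' label field restricted to the boundary band. Intensities are
#' unit-normalized internally so the weights are transferable across
#' volumes. The energy is non-increasing across iterations; the returned
#' mask's energy never exceeds the initialization's.
#'
#' @param volume a [cow_volume].
#' @param init_mask logical array, nonempty and not full.
#' @param params a [segmentation_params].
#' @return logical array with attributes `"energy"` (per-iteration trace),
#'   `"iterations"`, and `"status"` (`"converged"`, `"maxiter"`, or
#'   `"diverged"`, in which case `init_mask` is returned with a warning).
#' @export
chan_vese <- function(volume, init_mask, params = segmentation_params("strict")) {
  stopifnot(identical(dim(init_mask), dim(volume$data)))
  if (!any(init_mask)) stop("init_mask is empty")
  if (all(init_mask)) stop("init_mask covers the whole volume")
  x <- as.numeric(volume$data)
  lo <- min(x); hi <- max(x)
  xn <- if (hi > lo) (x - lo) / (hi - lo) else x * 0
  res <- .cpp_chan_vese(xn, as.integer(dim(volume$data)),
                        as.logical(init_mask), params$cv_mu,
                        params$cv_lambda1, params$cv_lambda2,
                        volume$spacing, params$cv_iterations, params$cv_tol)
  if (identical(res$status, "diverged")) {
    warning("Chan-Vese diverged (mask empty or full); returning init_mask")
    out <- init_mask
    attr(out, "status") <- "diverged"
    attr(out, "energy") <- res$energy
    attr(out, "iterations") <- res$iterations
    return(out)
  }
  out <- array(res$mask, dim(volume$data))
  attr(out, "energy") <- res$energy
  attr(out, "iterations") <- res$iterations
  attr(out, "status") <- if (res$iterations < params$cv_iterations)
    "converged" else "maxiter"
  out
}

#' Two-phase segmentation: strict and relaxed vessel masks
#'
#' Runs the adaptive-k-means / Chan-Vese chain twice with the strict and
#' relaxed parameter sets and enforces the containment
#' `mask_strict` \eqn{\subseteq} `mask_relaxed` by taking the union of the
#' strict mask into the relaxed one (required downstream so the Phase-1
#' skeleton can be preserved inside the Phase-2 mask).
#'
#' @param volume a [cow_volume], normalized by the preprocess step.
#' @param strict,relaxed [segmentation_params] with matching `phase`.
#' @return list with logical arrays `mask_strict` and `mask_relaxed` plus
#'   `diagnostics` (energy traces and convergence statuses per phase).
#' @export
two_phase_segment <- function(volume,
                              strict = segmentation_params("strict"),
                              relaxed = segmentation_params("relaxed")) {
  stopifnot(strict$phase == "strict", relaxed$phase == "relaxed")
  run_phase <- function(p) {
    v <- if (p$smooth_sigma_mm > 0)
      gaussian_smooth(volume, p$smooth_sigma_mm) else volume
    init <- adaptive_kmeans(v, p)
    if (!any(init)) stop("k-means initialization produced an empty mask")
    chan_vese(v, init, p)
  }
  ms <- run_phase(strict)
  mr <- run_phase(relaxed)
  mask_relaxed <- mr | ms
  list(mask_strict = ms & TRUE, mask_relaxed = mask_relaxed,
       diagnostics = list(
         strict = list(energy = attr(ms, "energy"),
                       status = attr(ms, "status"),
                       iterations = attr(ms, "iterations")),
         relaxed = list(energy = attr(mr, "energy"),
                        status = attr(mr, "status"),
                        iterations = attr(mr, "iterations"))))
}

#' Separable Gaussian smoothing of a volume
#'
#' Physical-units Gaussian filter (SD in mm per axis, truncated at 3 SD),
#' applied as three 1-D convolutions with zero padding; used as a light
#' denoising step before intensity clustering.
#'
#' @param volume a [cow_volume].
#' @param sigma_mm Gaussian SD in mm (scalar).
#' @return a smoothed [cow_volume].
#' @export
gaussian_smooth <- function(volume, sigma_mm) {
  stopifnot(sigma_mm >= 0)
  if (sigma_mm == 0) return(volume)
  a <- volume$data
  d <- dim(a)
  for (ax in 1:3) {
    sv <- sigma_mm / volume$spacing[ax]
    r <- max(1L, ceiling(3 * sv))
    k <- exp(-((-r:r)^2) / (2 * sv^2))
    k <- k / sum(k)
    out <- array(0, d)
    for (o in -r:r) {
      w <- k[o + r + 1L]
      src <- seq_len(d[ax])
      dst <- src + o
      ok <- dst >= 1 & dst <= d[ax]
      idx_src <- src[ok]
      idx_dst <- dst[ok]
      if (ax == 1) out[idx_dst, , ] <- out[idx_dst, , ] + w * a[idx_src, , ]
      else if (ax == 2) out[, idx_dst, ] <- out[, idx_dst, ] + w * a[, idx_src, ]
      else out[, , idx_dst] <- out[, , idx_dst] + w * a[, , idx_src]
    }
    a <- out
  }
  cow_volume(a, volume$spacing, volume$origin,
             meta = c(volume$meta, list(smoothed_sigma_mm = sigma_mm)))
}
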