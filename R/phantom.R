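#' Phantom configuration
#'
#' Study conditions for the synthetic Circle of Willis (CoW) phantom: a
#' bright-tubular-vessel volume on a dark background with known ground
#' truth, emulating a time-of-flight MRA after brain extraction and
#' registration to 0.5 mm isotropic atlas space.
#'
#' @param variant one of `"complete"`, `"a1_aplasia_left"`,
#'   `"a1_aplasia_right"`, `"a1_hypoplasia_left"`, `"a1_hypoplasia_right"`.
#' @param hypoplasia_factor radius multiplier in (0, 1) applied to the
#'   affected A1 segment for hypoplastic variants.
#' @param shape integer length-3 voxel grid dimensions.
#' @param spacing numeric length-3 voxel size in mm.
#' @param noise_sigma additive Gaussian noise SD relative to the brightest
#'   vessel baseline (>= 0).
#' @param seed RNG seed for the noise draw.
#' @param supersample per-axis supersampling factor used for partial-volume
#'   rasterization.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(variant = "complete", hypoplasia_factor = 0.4,
                           shape = c(160L, 160L, 80L),
                           spacing = c(0.5, 0.5, 0.5),
                           noise_sigma = 0.1, seed = 1L, supersample = 3L) {
  variants <- c("complete", "a1_aplasia_left", "a1_aplasia_right",
                "a1_hypoplasia_left", "a1_hypoplasia_right")
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% variants)
    stop("unknown variant '", paste(variant, collapse = ","),
         "'; expected one of: ", paste(variants, collapse = ", "))
  if (!is.numeric(hypoplasia_factor) || hypoplasia_factor <= 0 ||
      hypoplasia_factor >= 1)
    stop("hypoplasia_factor must lie in (0, 1)")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(variant = variant, hypoplasia_factor = hypoplasia_factor,
                 shape = as.integer(shape), spacing = as.numeric(spacing),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 supersample = as.integer(supersample)),
            class = "phantom_config")
}

#' Vessel specification
#'
#' One tubular vessel: a centreline through world-coordinate control points
#' (piecewise natural cubic spline), a per-control-point radius profile, a
#' baseline signal, and a linear fractional intensity change per mm of arc
#' length that mimics flow-saturation signal loss along the vessel.
#'
#' @param name anatomical label (e.g. `"A1-L"`, `"BA"`).
#' @param centerline n x 3 matrix of world mm control points (n >= 2,
#'   consecutive points distinct).
#' @param radius_profile per-control-point tube radius in mm (positive).
#' @param intensity baseline signal in arbitrary units.
#' @param intensity_gradient fractional signal change per mm of arc length.
#' @return a list of class `vessel_spec`.
#' @export
vessel_spec <- function(name, centerline, radius_profile, intensity,
                        intensity_gradient = 0) {
  centerline <- rbind(centerline)
  if (nrow(centerline) < 2L) stop("centerline needs at least 2 points")
  steps <- diff(centerline)
  if (any(rowSums(steps^2) == 0))
    stop("consecutive centerline control points must be distinct")
  radius_profile <- rep_len(radius_profile, nrow(centerline))
  if (any(radius_profile <= 0)) stop("radius_profile must be positive")
  structure(list(name = name, centerline = unname(centerline),
                 radius_profile = as.numeric(radius_profile),
                 intensity = intensity,
                 intensity_gradient = intensity_gradient),
            class = "vessel_spec")
}

# Hand-authored left-side + midline geometry of the complete CoW (world mm;
# x posterior->anterior, y left->right, z inferior->superior; midline y = 40).
# Radii and relative intensities are typical of adult TOF MRA; the posterior
# communicating arteries are given a baseline far below the segmentation
# range, emulating their frequent invisibility from flow saturation.
cow_geometry <- function() {
  pts <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  list(
    list(name = "BA", mirror = FALSE,
         centerline = pts(20, 40, 4, 22, 40, 10, 24, 40, 16, 25, 40, 22),
         radius = 1.6, intensity = 0.20),
    list(name = "P1-L", mirror = TRUE,
         centerline = pts(25, 40, 22, 28, 36, 23, 31, 31, 24, 33, 28, 24),
         radius = 1.1, intensity = 0.17),
    list(name = "P2-L", mirror = TRUE,
         centerline = pts(33, 28, 24, 34, 25, 24.7, 30, 20, 26, 23, 17, 28,
                          16, 16, 30),
         radius = 1.0, intensity = 0.16),
    list(name = "SCA-L", mirror = TRUE,
         centerline = pts(25, 40, 20, 28, 35, 19, 30, 30, 18.5),
         radius = 0.8, intensity = 0.15),
    list(name = "ICA-L", mirror = TRUE,
         centerline = pts(50, 28, 4, 52, 28, 10, 50, 27, 16, 46, 26, 20,
                          48, 26, 24),
         radius = 2.0, intensity = 0.20),
    list(name = "M1-L", mirror = TRUE,
         centerline = pts(48, 26, 24, 46, 20, 24, 44, 14, 24, 43, 9, 24),
         radius = 1.7, intensity = 0.19),
    list(name = "A1-L", mirror = TRUE,
         centerline = pts(48, 26, 24, 52, 29, 25, 55, 33, 25.5, 58, 38, 26),
         radius = 1.6, intensity = 0.18),
    list(name = "ACo", mirror = FALSE, gradient = 0,
         centerline = pts(58, 38, 26, 58, 40, 26.2, 58, 42, 26),
         radius = 0.6, intensity = 0.11),
    list(name = "PCo-L", mirror = TRUE,
         centerline = pts(46, 26, 20, 40, 28, 21.5, 35, 30, 22.5, 31, 31, 24),
         radius = 0.5, intensity = 0.03)
  )
}

# world y of the phantom's median sagittal plane (fixed by the authored
# geometry, independent of the voxel grid)
cow_midline_y <- function() 40

mirror_name <- function(name) {
  if (grepl("-L$", name)) sub("-L$", "-R", name) else name
}

mirror_points <- function(p, m) {
  p[, 2] <- 2 * m - p[, 2]
  p
}

default_gradient <- function() -0.004

#' Build the vessel specifications and ground truth for a CoW variant
#'
#' Realizes the complete-CoW topology (two anterior trees joined by the
#' anterior communicating artery, posterior circulation from the basilar
#' artery) or an A1 variant of it. Aplastic variants omit the affected A1
#' spec entirely; hypoplastic variants scale its radius profile by
#' `config$hypoplasia_factor`. The complete variant is mirror-symmetric
#' about the median sagittal plane.
#'
#' @param config a [phantom_config].
#' @return list with `specs` (list of [vessel_spec]) and `ground_truth`
#'   (node positions in world mm, per-segment true radius / tortuosity /
#'   mean intensity, and `median_sagittal_y`).
#' @export
build_cow_spec <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  m <- cow_midline_y()
  geo <- cow_geometry()
  specs <- list()
  for (g in geo) {
    grad <- if (is.null(g$gradient)) default_gradient() else g$gradient
    specs[[g$name]] <- vessel_spec(g$name, g$centerline, g$radius,
                                   g$intensity, grad)
    if (isTRUE(g$mirror)) {
      rn <- mirror_name(g$name)
      specs[[rn]] <- vessel_spec(rn, mirror_points(g$centerline, m),
                                 g$radius, g$intensity, grad)
    }
  }

  drop <- switch(config$variant,
                 a1_aplasia_left = "A1-L",
                 a1_aplasia_right = "A1-R",
                 NULL)
  if (!is.null(drop)) specs[[drop]] <- NULL
  shrink <- switch(config$variant,
                   a1_hypoplasia_left = "A1-L",
                   a1_hypoplasia_right = "A1-R",
                   NULL)
  if (!is.null(shrink))
    specs[[shrink]]$radius_profile <-
      specs[[shrink]]$radius_profile * config$hypoplasia_factor

  nodes <- list(basilar = c(25, 40, 22))
  if ("A1-L" %in% names(specs)) nodes$m1a1_left <- c(48, 26, 24)
  if ("A1-R" %in% names(specs)) nodes$m1a1_right <- c(48, 54, 24)

  segments <- lapply(specs, function(s) {
    dense <- densify_spec(s, step = 0.1)
    arc <- sum(sqrt(rowSums(diff(dense$points)^2)))
    chord <- sqrt(sum((dense$points[nrow(dense$points), ] -
                         dense$points[1, ])^2))
    tort <- if (is_collinear(s$centerline)) 1 else arc / chord
    list(radius = mean(dense$radius), tortuosity = tort,
         intensity = mean(dense$value))
  })

  list(specs = unname(specs),
       ground_truth = list(node_positions = nodes, segments = segments,
                           median_sagittal_y = m))
}

is_collinear <- function(p, tol = 1e-9) {
  if (nrow(p) <= 2) return(TRUE)
  v <- p[nrow(p), ] - p[1, ]
  v <- v / sqrt(sum(v^2))
  dev <- sweep(p, 2, p[1, ]) - outer(c(sweep(p, 2, p[1, ]) %*% v), v)
  max(abs(dev)) < tol
}

# Resample a vessel spec densely along arc length: natural cubic spline per
# coordinate over the cumulative chord-length parameter, linear radius
# interpolation, intensity modulated by the linear gradient (clipped at 0).
densify_spec <- function(spec, step) {
  p <- spec$centerline
  t0 <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  tt <- seq(0, t0[length(t0)], by = step)
  if (tt[length(tt)] < t0[length(t0)]) tt <- c(tt, t0[length(t0)])
  if (nrow(p) == 2) {
    pts <- cbind(approx(t0, p[, 1], tt)$y, approx(t0, p[, 2], tt)$y,
                 approx(t0, p[, 3], tt)$y)
  } else {
    pts <- cbind(splinefun(t0, p[, 1], method = "natural")(tt),
                 splinefun(t0, p[, 2], method = "natural")(tt),
                 splinefun(t0, p[, 3], method = "natural")(tt))
  }
  rad <- approx(t0, spec$radius_profile, tt)$y
  val <- pmax(0, spec$intensity * (1 + spec$intensity_gradient * tt))
  list(points = pts, radius = rad, value = val)
}

#' Rasterize vessel specifications into a volume
#'
#' Voxels within any tube (distance to centreline below the local radius)
#' receive that vessel's gradient-modulated intensity; overlapping vessels
#' combine by maximum; background is 0. Partial volume is handled by
#' rasterizing at `config$supersample`-fold resolution per axis and
#' averaging down.
#'
#' @param specs list of [vessel_spec] (may be empty).
#' @param config a [phantom_config] providing grid shape and spacing.
#' @return a noise-free [cow_volume].
#' @export
rasterize <- function(specs, config) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$shape
  sp <- config$spacing
  origin <- c(0, 0, 0)
  upper <- origin + dims * sp
  step <- 0.25 * min(sp)
  tubes <- lapply(specs, function(s) densify_spec(s, step))
  for (i in seq_along(tubes)) {
    tb <- tubes[[i]]
    lo <- sweep(tb$points, 1, tb$radius, "-")
    hi <- sweep(tb$points, 1, tb$radius, "+")
    if (any(t(lo) < origin) || any(t(hi) > upper))
      stop("vessel '", specs[[i]]$name, "' exits the voxel grid")
  }
  data <- .cpp_raster_tubes(as.integer(dims), sp, origin,
                            config$supersample, tubes)
  cow_volume(array(data, dims), spacing = sp, origin = origin,
             meta = list(variant = config$variant))
}

#' Add Gaussian noise to a volume
#'
#' Zero-mean Gaussian noise with SD `noise_sigma * baseline` is added and
#' negative results are clipped at 0. `noise_sigma = 0` returns the input
#' unchanged. The noise model is Gaussian rather than Rician, which is
#' adequate for exercising thresholding behaviour.
#'
#' @param volume a [cow_volume].
#' @param noise_sigma noise SD relative to `baseline` (>= 0).
#' @param seed RNG seed (the draw does not disturb the caller's RNG state).
#' @param baseline reference signal level; defaults to the volume maximum
#'   (or 1 for an empty volume).
#' @return a [cow_volume].
#' @export
add_noise <- function(volume, noise_sigma, seed = 1L, baseline = NULL) {
  stopifnot(inherits(volume, "cow_volume"), noise_sigma >= 0)
  if (noise_sigma == 0) return(volume)
  if (is.null(baseline)) {
    baseline <- max(volume$data)
    if (baseline <= 0) baseline <- 1
  }
  noisy <- withr::with_seed(as.integer(seed), {
    volume$data + array(rnorm(length(volume$data), 0, noise_sigma * baseline),
                        dim(volume$data))
  })
  noisy[noisy < 0] <- 0
  cow_volume(noisy, volume$spacing, volume$origin,
             meta = c(volume$meta, list(noise_sigma = noise_sigma,
                                        noise_seed = as.integer(seed))))
}

#' Generate a complete phantom: specs, rasterization, noise, ground truth
#'
#' @param config a [phantom_config].
#' @return list with `volume` (noisy), `clean` (noise-free volume), `specs`,
#'   `ground_truth`, and `config`.
#' @export
make_phantom <- function(config = phantom_config()) {
  built <- build_cow_spec(config)
  clean <- rasterize(built$specs, config)
  baseline <- max(vapply(built$specs, function(s) s$intensity, 0))
  noisy <- add_noise(clean, config$noise_sigma, seed = config$seed,
                     baseline = baseline)
  list(volume = noisy, clean = clean, specs = built$specs,
       ground_truth = built$ground_truth, config = config)
}

#' Write phantom ground truth as JSON
#' @param ground_truth the `ground_truth` element of [build_cow_spec].
#' @param path output JSON path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read phantom ground truth JSON
#' @param path JSON path written by [write_ground_truth].
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$node_positions <- lapply(gt$node_positions, as.numeric)
  gt
}
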