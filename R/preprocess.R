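#' Linear histogram matching
#'
#' Maps input intensities through the affine transform that carries the
#' input's robust intensity range onto the reference's robust range. The
#' robust range is the 1st-99th percentile band; if that band is degenerate
#' (e.g. a sparse angiogram whose voxels are mostly background) the full
#' min-max range is used instead. The map is affine, hence monotone and
#' rank-preserving.
#'
#' @param volume input [cow_volume] (non-constant).
#' @param reference reference [cow_volume] (non-constant).
#' @param probs lower/upper percentile anchors of the robust range.
#' @return a [cow_volume] on the reference intensity scale; the anchors used
#'   are recorded in `meta$histogram_match`.
#' @export
histogram_match <- function(volume, reference, probs = c(0.01, 0.99)) {
  rng <- function(v) {
    q <- quantile(v$data, probs, names = FALSE)
    if (diff(q) <= 0) q <- range(v$data)
    if (diff(q) <= 0) stop("constant volume: histogram match undefined")
    q
  }
  qi <- rng(volume)
  qr <- rng(reference)
  scale <- diff(qr) / diff(qi)
  out <- (volume$data - qi[1]) * scale + qr[1]
  cow_volume(out, volume$spacing, volume$origin,
             meta = c(volume$meta,
                      list(histogram_match = list(probs = probs,
                                                  input_range = qi,
                                                  reference_range = qr))))
}

#' Resample a volume onto an isotropic atlas grid
#'
#' Trilinear resampling onto an isotropic grid at `target_spacing`
#' (default 0.5 mm). World coordinates of the content are preserved: the
#' output grid covers the same world extent and a landmark at world point w
#' stays at w. Trilinear interpolation is convex, so output intensities
#' never leave the input min/max range.
#'
#' @param volume input [cow_volume].
#' @param target_spacing isotropic voxel size in mm (positive scalar).
#' @return a [cow_volume] at `target_spacing`.
#' @export
resample_to_atlas <- function(volume, target_spacing = 0.5) {
  stopifnot(target_spacing > 0)
  sp <- volume$spacing
  dims <- dim(volume$data)
  if (all(abs(sp - target_spacing) < 1e-12)) return(volume)
  extent <- dims * sp
  new_dims <- pmax(1L, as.integer(round(extent / target_spacing)))
  # continuous source indices of the new voxel centres
  idx <- lapply(1:3, function(a) {
    w <- volume$origin[a] + (seq_len(new_dims[a]) - 0.5) * target_spacing
    (w - volume$origin[a]) / sp[a] + 0.5
  })
  data <- trilinear_sample(volume$data, idx[[1]], idx[[2]], idx[[3]])
  cow_volume(array(data, new_dims), spacing = rep(target_spacing, 3),
             origin = volume$origin,
             meta = c(volume$meta, list(resampled_from = sp)))
}

# vectorized trilinear interpolation of a 3-D array on the grid product of
# continuous (1-based) indices ix, iy, iz; clamped at the border
trilinear_sample <- function(arr, ix, iy, iz) {
  d <- dim(arr)
  clamp <- function(v, n) pmin(pmax(v, 1), n)
  ix <- clamp(ix, d[1]); iy <- clamp(iy, d[2]); iz <- clamp(iz, d[3])
  x0 <- pmin(floor(ix), d[1] - 1L); x0[d[1] == 1L] <- 1
  y0 <- pmin(floor(iy), d[2] - 1L); y0[d[2] == 1L] <- 1
  z0 <- pmin(floor(iz), d[3] - 1L); z0[d[3] == 1L] <- 1
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  if (d[1] == 1L) fx <- fx * 0
  if (d[2] == 1L) fy <- fy * 0
  if (d[3] == 1L) fz <- fz * 0
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  X0 <- rep(x0, times = ny * nz); FX <- rep(fx, times = ny * nz)
  Y0 <- rep(rep(y0, each = nx), times = nz)
  FY <- rep(rep(fy, each = nx), times = nz)
  Z0 <- rep(z0, each = nx * ny); FZ <- rep(fz, each = nx * ny)
  g <- function(xi, yi, zi) arr[cbind(xi, yi, zi)]
  x1 <- pmin(X0 + 1L, d[1]); y1 <- pmin(Y0 + 1L, d[2]); z1 <- pmin(Z0 + 1L, d[3])
  v000 <- g(X0, Y0, Z0); v100 <- g(x1, Y0, Z0)
  v010 <- g(X0, y1, Z0); v110 <- g(x1, y1, Z0)
  v001 <- g(X0, Y0, z1); v101 <- g(x1, Y0, z1)
  v011 <- g(X0, y1, z1); v111 <- g(x1, y1, z1)
  v00 <- v000 * (1 - FX) + v100 * FX
  v10 <- v010 * (1 - FX) + v110 * FX
  v01 <- v001 * (1 - FX) + v101 * FX
  v11 <- v011 * (1 - FX) + v111 * FX
  v0 <- v00 * (1 - FY) + v10 * FY
  v1 <- v01 * (1 - FY) + v11 * FY
  v0 * (1 - FZ) + v1 * FZ
}
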