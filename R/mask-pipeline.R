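# Replicate stacks -> binary mask, following the light-microscopy recipe:
# overlay n registered examples of a line, enhance contrast, Gaussian-blur
# (sigma = 1 voxel), then Otsu auto-threshold.

#' Mask pipeline parameters
#'
#' @param n_replicates Expected number of replicate stacks (3 in a typical
#'   screen; used for validation only).
#' @param overlay `"max"` (default) or `"sum"` voxelwise combination of
#'   replicates. Max is robust to replicate-count differences between lines.
#' @param saturation_fraction Total fraction of voxels clipped by contrast
#'   enhancement (half at each tail). Default 0.0035, the common interactive
#'   default for display contrast; must be in \[0, 0.5).
#' @param blur_sigma Gaussian sigma in voxel units (isotropic in index space),
#'   default 1.
#' @param histogram_bins Bins for the Otsu histogram, default 256.
#' @return A list of class `mask_pipeline_params`.
#' @export
mask_pipeline_params <- function(n_replicates = 3, overlay = c("max", "sum"),
                                 saturation_fraction = 0.0035, blur_sigma = 1,
                                 histogram_bins = 256L) {
  overlay <- match.arg(overlay)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  if (saturation_fraction < 0 || saturation_fraction >= 0.5) {
    stop("saturation_fraction must be in [0, 0.5)", call. = FALSE)
  }
  if (histogram_bins < 2) stop("histogram_bins must be >= 2", call. = FALSE)
  structure(list(n_replicates = as.integer(n_replicates), overlay = overlay,
                 saturation_fraction = saturation_fraction,
                 blur_sigma = blur_sigma,
                 histogram_bins = as.integer(histogram_bins)),
            class = "mask_pipeline_params")
}

#' Overlay replicate stacks
#'
#' Voxelwise maximum (default) or sum of registered replicate stacks of one
#' line, the first step of mask creation.
#'
#' @param stacks List of [lh_volume] on one grid.
#' @param mode `"max"` or `"sum"`.
#' @return An [lh_volume] on the same grid.
#' @export
overlay_replicates <- function(stacks, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  if (length(stacks) == 0L) stop("need at least one stack", call. = FALSE)
  stopifnot(all(vapply(stacks, inherits, logical(1), "lh_volume")))
  for (s in stacks[-1]) assert_same_grid(stacks[[1]], s)
  out <- stacks[[1]]
  acc <- out$data
  for (s in stacks[-1]) {
    acc <- if (mode == "max") pmax(acc, s$data) else acc + s$data
  }
  out$data <- acc
  out
}

#' Percentile-clip contrast enhancement
#'
#' Clips intensities at the lower and upper `saturation_fraction / 2`
#' quantiles, then rescales linearly to \[0, 1\]. With `saturation_fraction = 0`
#' this is a plain min-max rescale. A constant image cannot be rescaled; it
#' returns an all-zero image carrying a `constant_input` attribute and a
#' warning.
#'
#' @param v An [lh_volume].
#' @param saturation_fraction Total clipped fraction, in \[0, 0.5).
#' @return An [lh_volume] with intensities in \[0, 1\].
#' @export
enhance_contrast <- function(v, saturation_fraction = 0.0035) {
  stopifnot(inherits(v, "lh_volume"))
  if (saturation_fraction < 0 || saturation_fraction >= 0.5) {
    stop("saturation_fraction must be in [0, 0.5)", call. = FALSE)
  }
  x <- as.numeric(v$data)
  lo <- stats::quantile(x, saturation_fraction / 2, names = FALSE)
  hi <- stats::quantile(x, 1 - saturation_fraction / 2, names = FALSE)
  out <- v
  if (hi <= lo) {
    warning("constant image: contrast enhancement returns all zeros")
    out$data <- array(0, dim(v$data))
    attr(out, "constant_input") <- TRUE
    return(out)
  }
  y <- (pmin(pmax(x, lo), hi) - lo) / (hi - lo)
  out$data <- array(y, dim(v$data))
  attr(out, "clip_bounds") <- c(lower = lo, upper = hi)
  out
}

# Separable 1D Gaussian kernel, truncated at radius ceil(3*sigma), renormalised.
gaussian_kernel_1d <- function(sigma) {
  if (sigma == 0) return(1)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve along the first axis of a 3D array with edge replication, using
# stats::filter on the columns of the flattened (n1 x n2*n3) matrix.
convolve_axis1 <- function(arr, kernel) {
  r <- (length(kernel) - 1L) / 2L
  if (r == 0L) return(arr)
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1])
  padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                  m[rep(d[1], r), , drop = FALSE])
  f <- stats::filter(padded, kernel, method = "convolution", sides = 2)
  array(as.numeric(f[(r + 1L):(r + d[1]), , drop = FALSE]), dim = d)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with per-axis sigma in voxel units (edge
#' replication at boundaries). `sigma = 0` along an axis is the identity for
#' that axis. An anisotropic physical blur can be requested by passing
#' `sigma_um` instead, which is converted to voxel units by the volume's
#' spacing.
#'
#' @param v An [lh_volume].
#' @param sigma Scalar or length-3 sigma in voxels.
#' @param sigma_um Optional scalar or length-3 sigma in micrometres; overrides
#'   `sigma`.
#' @return The filtered [lh_volume].
#' @export
gaussian_smooth <- function(v, sigma = 1, sigma_um = NULL) {
  stopifnot(inherits(v, "lh_volume"))
  if (!is.null(sigma_um)) sigma <- rep(sigma_um, length.out = 3) / v$spacing
  sigma <- rep(as.numeric(sigma), length.out = 3)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  out <- v
  arr <- v$data
  arr <- convolve_axis1(arr, gaussian_kernel_1d(sigma[1]))
  arr <- aperm(convolve_axis1(aperm(arr, c(2, 1, 3)),
                              gaussian_kernel_1d(sigma[2])), c(2, 1, 3))
  arr <- aperm(convolve_axis1(aperm(arr, c(3, 2, 1)),
                              gaussian_kernel_1d(sigma[3])), c(3, 2, 1))
  out$data <- arr
  out
}

#' Otsu auto-threshold
#'
#' Picks the histogram threshold maximizing the between-class variance over
#' `bins` equal-width bins spanning the intensity range (equivalently,
#' minimizing the within-class variance). Ties are broken toward the lower
#' threshold. The mask keeps voxels strictly above the threshold.
#'
#' @param v An [lh_volume]; must not be constant.
#' @param bins Histogram bin count, default 256.
#' @param ... Metadata passed to [lh_mask()] (cell_type, compartment, ...).
#' @return A list with `threshold` (intensity units) and `mask` ([lh_mask]).
#' @export
otsu_threshold <- function(v, bins = 256L, ...) {
  stopifnot(inherits(v, "lh_volume"))
  x <- as.numeric(v$data)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop(paste0("constant image: Otsu threshold undefined; if an empty mask ",
                "is intended, construct it explicitly"), call. = FALSE)
  }
  bins <- as.integer(bins)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  # bin index per voxel; the top edge closes the last bin
  bi <- pmin(findInterval(x, edges, rightmost.closed = TRUE), bins)
  counts <- as.numeric(tabulate(bi, nbins = bins))
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * centers)
  n <- w[bins]; mu_t <- mu[bins]
  # between-class variance for a cut after bin k (k = 1..bins-1)
  k <- seq_len(bins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, bins - 1L)
  bcv[valid] <- (mu_t * w0[valid] / n - mu[k][valid])^2 * n /
    (w0[valid] * w1[valid] / n)
  best <- which.max(bcv)  # which.max takes the first maximum: lower threshold
  thr <- edges[best + 1L]
  mask <- lh_mask(v$data > thr, v$spacing, v$origin, v$space_id, ...)
  list(threshold = thr, mask = mask)
}

#' Build a binary mask from replicate stacks
#'
#' The full mask recipe: overlay the replicates, enhance contrast, Gaussian
#' blur, Otsu auto-threshold. Deterministic given inputs and parameters; the
#' chosen threshold and parameters are attached as a `provenance` attribute.
#'
#' @param stacks List of registered [lh_volume] replicates of one line.
#' @param params A [mask_pipeline_params()].
#' @param ... Metadata passed to [lh_mask()] (cell_type, compartment, ...).
#' @return An [lh_mask] with a `provenance` attribute (params and threshold).
#' @examples
#' st <- generate_replicate_stacks(arbor_params(seed = 1), n_replicates = 3)
#' m <- make_mask(st$stacks, cell_type = "AV1a1", compartment = "axon")
#' m
#' @export
make_mask <- function(stacks, params = mask_pipeline_params(), ...) {
  stopifnot(inherits(params, "mask_pipeline_params"))
  ov <- overlay_replicates(stacks, params$overlay)
  en <- enhance_contrast(ov, params$saturation_fraction)
  if (isTRUE(attr(en, "constant_input"))) {
    stop("replicate overlay is constant; cannot build a mask", call. = FALSE)
  }
  sm <- gaussian_smooth(en, params$blur_sigma)
  res <- otsu_threshold(sm, params$histogram_bins, ...)
  mask <- res$mask
  attr(mask, "provenance") <- list(
    params = unclass(params), threshold = res$threshold,
    n_stacks = length(stacks))
  mask
}
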