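# Multiscale Hessian vesselness (Frangi-type tubularity) and hysteresis
# segmentation.

# Sampled Gaussian (derivative) kernel in voxel units, normalized so that
# polynomial inputs give exact responses: order 0 sums to 1, order 1 has
# zero sum and unit first moment, order 2 has zero sum/first moment and
# second moment 2. This makes the filters exactly zero on constant volumes
# and invariant to additive HU offsets.
gaussian_kernel <- function(sigma_vox, order = 0) {
  r <- max(2L, ceiling(3.5 * sigma_vox))
  x <- seq(-r, r)
  g <- dnorm(x, sd = sigma_vox)
  if (order == 0) return(g / sum(g))
  if (order == 1) {
    k <- -(x / sigma_vox^2) * g
    k <- k - mean(k)
    return(k / sum(k * x))
  }
  if (order == 2) {
    k <- ((x^2 - sigma_vox^2) / sigma_vox^4) * g
    k <- k - mean(k)
    return(k * (2 / sum(k * x^2)))
  }
  stop("order must be 0, 1 or 2")
}

conv3 <- function(v, dm, kx = NULL, ky = NULL, kz = NULL) {
  if (!is.null(kx)) v <- cpp_conv3_axis(v, dm, kx, 0L)
  if (!is.null(ky)) v <- cpp_conv3_axis(v, dm, ky, 1L)
  if (!is.null(kz)) v <- cpp_conv3_axis(v, dm, kz, 2L)
  v
}

#' Scale-normalized Hessian eigenvalues of a volume
#'
#' Computes the Gaussian-derivative Hessian of the volume at physical scale
#' `sigma_um` (second derivatives multiplied by `sigma^2`, gamma = 1 scale
#' normalization) and returns the voxelwise eigenvalues sorted by absolute
#' value, `|l1| <= |l2| <= |l3|`. On the axis of a bright tube `l1 ~ 0` and
#' `l2, l3 < 0`; at the center of a bright blob all three are negative and
#' comparable. Boundary handling is reflective.
#'
#' @param volume a [ct_volume()].
#' @param sigma_um Gaussian scale (um). Scales below the voxel size are
#'   clamped to the voxel size with a warning.
#' @return List of three arrays `l1`, `l2`, `l3`.
#' @export
hessian_eigenvalues <- function(volume, sigma_um) {
  assert_volume(volume)
  if (sigma_um < volume$voxel_um) {
    warning("sigma (", sigma_um, " um) below voxel size; clamped to ",
            volume$voxel_um, " um")
    sigma_um <- volume$voxel_um
  }
  s <- sigma_um / volume$voxel_um
  k0 <- gaussian_kernel(s, 0); k1 <- gaussian_kernel(s, 1)
  k2 <- gaussian_kernel(s, 2)
  dm <- dim(volume$data)
  v <- as.numeric(volume$data)
  s2 <- s^2
  A <- conv3(v, dm, kz = k0)
  hxx <- conv3(A, dm, kx = k2, ky = k0) * s2
  hyy <- conv3(A, dm, kx = k0, ky = k2) * s2
  hxy <- conv3(A, dm, kx = k1, ky = k1) * s2
  B <- conv3(v, dm, ky = k0)
  hzz <- conv3(B, dm, kx = k0, kz = k2) * s2
  hxz <- conv3(B, dm, kx = k1, kz = k1) * s2
  Cv <- conv3(v, dm, kx = k0)
  hyz <- conv3(Cv, dm, ky = k1, kz = k1) * s2
  ev <- cpp_eig3_sorted(hxx, hyy, hzz, hxy, hxz, hyz)
  lapply(ev, array, dim = dm)
}

#' Vesselness filter parameters
#'
#' @param scales_um Gaussian scales (um), strictly increasing; the default
#'   is 6 scales geometric from 15 to 150 um, covering vessel diameters of
#'   roughly 40-300 um (the tubular optimum is near `sigma = radius /
#'   sqrt(2)`).
#' @param alpha plate-vs-line discriminator weight (default 0.5).
#' @param beta blob discriminator weight (default 0.5).
#' @param c structureness weight in HU; `"auto"` (default) uses half the
#'   maximum Hessian Frobenius norm per scale.
#' @param bright_on_dark polarity: `TRUE` enhances bright vessels.
#' @return A `vesselness_params` object.
#' @export
vesselness_params <- function(scales_um = 15 * (10^(1 / 5))^(0:5),
                              alpha = 0.5, beta = 0.5, c = "auto",
                              bright_on_dark = TRUE) {
  if (!length(scales_um)) stop("config error: empty scale list")
  if (any(scales_um <= 0) || is.unsorted(scales_um, strictly = TRUE))
    stop("scales must be strictly positive and increasing")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  structure(list(scales_um = scales_um, alpha = alpha, beta = beta, c = c,
                 bright_on_dark = isTRUE(bright_on_dark)),
            class = "vesselness_params")
}

#' Multiscale Frangi vesselness
#'
#' For each scale the tubularity response is computed from the sorted
#' Hessian eigenvalues: zero where the polarity condition fails (bright
#' vessels require `l2, l3 < 0`), otherwise
#' `V = (1 - exp(-RA^2 / 2 alpha^2)) * exp(-RB^2 / 2 beta^2) *
#' (1 - exp(-S^2 / 2 c^2))` with `RA = |l2|/|l3|`,
#' `RB = |l1|/sqrt(|l2 l3|)` and `S` the Frobenius norm. The output is the
#' voxelwise maximum over scales, bounded in \[0, 1\].
#'
#' @param volume a [ct_volume()].
#' @param params a [vesselness_params()].
#' @return A [ct_volume()] of vesselness values in \[0, 1\], with attribute
#'   `"scale_um"` (array of the argmax scale per voxel).
#' @export
frangi_vesselness <- function(volume, params = vesselness_params()) {
  assert_volume(volume)
  stopifnot(inherits(params, "vesselness_params"))
  dm <- dim(volume$data)
  best <- numeric(prod(dm))
  best_scale <- numeric(prod(dm))
  for (sg in params$scales_um) {
    ev <- suppressWarnings(hessian_eigenvalues(volume, sg))
    l1 <- as.numeric(ev$l1); l2 <- as.numeric(ev$l2); l3 <- as.numeric(ev$l3)
    cval <- params$c
    if (identical(cval, "auto")) {
      smax <- sqrt(max(l1^2 + l2^2 + l3^2))
      cval <- if (smax > 0) smax / 2 else 1
    }
    v <- cpp_frangi_combine(l1, l2, l3, params$alpha, params$beta, cval,
                            params$bright_on_dark)
    upd <- v > best
    best[upd] <- v[upd]
    best_scale[upd] <- sg
  }
  out <- ct_volume(array(best, dim = dm), volume$voxel_um, volume$origin_mm)
  attr(out, "scale_um") <- array(best_scale, dim = dm)
  out
}

#' Hysteresis vessel segmentation
#'
#' Voxels with vesselness at or above `high_threshold` seed the mask; voxels
#' at or above `low_threshold` are kept iff 26-connected to a seed. This
#' preserves thin, low-contrast vessel tails that a single threshold would
#' cut.
#'
#' @param vesselness a [ct_volume()] (typically from [frangi_vesselness()]).
#' @param low_threshold,high_threshold thresholds with
#'   `0 <= low <= high`.
#' @return A logical [ct_volume()] mask.
#' @export
segment_vessels <- function(vesselness, low_threshold = 0.05,
                            high_threshold = 0.5) {
  assert_volume(vesselness)
  if (high_threshold < low_threshold)
    stop("high_threshold must be >= low_threshold")
  if (low_threshold < 0) stop("thresholds must be non-negative")
  dm <- dim(vesselness$data)
  m <- cpp_hysteresis(as.numeric(vesselness$data), dm, low_threshold,
                      high_threshold)
  ct_volume(array(m, dim = dm), vesselness$voxel_um, vesselness$origin_mm)
}
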