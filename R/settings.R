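#' Registration settings
#'
#' Bundles the tunable parameters of the rigid and elastic registration
#' engines. The elastic stage parameterizes each displacement component
#' in a separable 3-D cosine (DCT-II) basis over the fixed image's
#' bounding box and minimizes a sum-of-squared-differences data term plus
#' a bending-energy penalty, coarse to fine over a resolution pyramid.
#' Mutual information is available for the inter-modality rigid stage
#' only; the elastic stage is intra-modality SSD by design.
#'
#' @param metric `"SSD"` or `"MI"` (MI: rigid stage only).
#' @param basis_orders integer length-3: cosine frequencies per axis
#'   (default `c(5, 4, 5)`; k = 0 is an unpenalized bulk shift).
#' @param regularization_weight bending-energy weight `lambda` (>= 0);
#'   the penalty is expressed analytically in coefficient space, with
#'   squared-curvature weights in mm^-4, against a data term normalized
#'   to unit image scale. Default 1e-4.
#' @param pyramid_mm voxel spacings (mm) of the resolution pyramid,
#'   coarse to fine. Default `c(0.8, 0.4)`.
#' @param smoothing_fwhm_mm Gaussian pre-smoothing FWHM per level;
#'   defaults to the level spacing.
#' @param max_iterations optimizer iterations per level (default 20).
#' @param convergence_tol relative objective decrease below which a level
#'   stops (default 1e-5).
#' @param intensity_scaling estimate a global multiplicative intensity
#'   factor between moving and fixed (closed form each iteration).
#' @param mask `"none"` or `"fixed"`: restrict the data term to voxels
#'   where the (smoothed) fixed image exceeds 1% of its robust maximum,
#'   dilated by one voxel. Default `"none"`.
#' @return object of class `registration_settings`.
#' @export
registration_settings <- function(metric = c("SSD", "MI"),
                                  basis_orders = c(5L, 4L, 5L),
                                  regularization_weight = 1e-4,
                                  pyramid_mm = c(0.8, 0.4),
                                  smoothing_fwhm_mm = NULL,
                                  max_iterations = 20L,
                                  convergence_tol = 1e-5,
                                  intensity_scaling = TRUE,
                                  mask = c("none", "fixed")) {
  metric <- match.arg(metric)
  mask <- match.arg(mask)
  if (is.null(smoothing_fwhm_mm)) smoothing_fwhm_mm <- pyramid_mm
  if (length(smoothing_fwhm_mm) == 1L)
    smoothing_fwhm_mm <- rep(smoothing_fwhm_mm, length(pyramid_mm))
  stopifnot(length(basis_orders) == 3L, all(basis_orders >= 1L),
            regularization_weight >= 0,
            length(smoothing_fwhm_mm) == length(pyramid_mm))
  structure(list(metric = metric, basis_orders = as.integer(basis_orders),
                 regularization_weight = regularization_weight,
                 pyramid_mm = pyramid_mm,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 intensity_scaling = isTRUE(intensity_scaling),
                 mask = mask),
            class = "registration_settings")
}

#' @export
print.registration_settings <- function(x, ...) {
  cat(sprintf("<registration_settings> metric %s, basis %s, lambda %.2g, pyramid %s mm\n",
              x$metric, paste(x$basis_orders, collapse = "x"),
              x$regularization_weight, paste(x$pyramid_mm, collapse = ", ")))
  invisible(x)
}

# separable Gaussian smoothing (dense per-axis kernel matrices, rows
# renormalized at the borders so constants are preserved)
gaussian_smooth_array <- function(values, sigma_vox) {
  v <- values
  d <- dim(v)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-3) next
    n <- d[ax]
    K <- outer(seq_len(n), seq_len(n), function(i, j) exp(-(i - j)^2 / (2 * s^2)))
    K[K < exp(-9 / 2)] <- 0          # truncate at 3 sigma
    K <- K / rowSums(K)
    m <- matrix(aperm(v, c(ax, setdiff(1:3, ax))), nrow = n)
    m <- K %*% m
    v <- aperm(array(m, c(n, d[setdiff(1:3, ax)])),
               order(c(ax, setdiff(1:3, ax))))
  }
  v
}

#' Gaussian smoothing of a volume
#'
#' @param vol a [brainvol()] (continuous modality).
#' @param fwhm_mm isotropic kernel full width at half maximum in mm.
#' @return smoothed [brainvol()].
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  if (is_discrete_modality(vol$modality))
    stop("validation error: cannot smooth a ", vol$modality, " volume")
  sigma <- (fwhm_mm / 2.35482) / vol$grid$spacing
  brainvol(gaussian_smooth_array(vol$values, sigma), vol$grid,
           modality = vol$modality, units = vol$units)
}

# grid covering the same world box at a different isotropic spacing
level_grid <- function(grid, spacing_mm) {
  edge <- grid$origin - grid$spacing / 2
  ext <- grid_extent(grid)
  shape <- pmax(1L, as.integer(round(ext / spacing_mm)))
  grid3d(shape, rep(spacing_mm, 3L), edge + spacing_mm / 2)
}

# smooth + resample a volume to a pyramid level
pyramid_level <- function(vol, spacing_mm, fwhm_mm) {
  sm <- if (fwhm_mm > 0) gaussian_smooth(vol, fwhm_mm) else vol
  tg <- level_grid(vol$grid, spacing_mm)
  resample(sm, tg, "trilinear")
}

robust_max <- function(x) {
  nz <- x[x != 0]
  if (length(nz) == 0L)
    stop("registration-failure error: image has no signal (all voxels zero)")
  as.numeric(stats::quantile(nz, 0.99, names = FALSE, na.rm = TRUE))
}

# central-difference spatial gradient arrays (per mm), list of 3
gradient_arrays <- function(values, spacing) {
  d <- dim(values)
  out <- vector("list", 3L)
  for (ax in 1:3) {
    hi <- shift_vals(values, ax, -1L)   # value at index+1
    lo <- shift_vals(values, ax, +1L)   # value at index-1
    g <- (hi - lo) / (2 * spacing[ax])
    out[[ax]] <- g
  }
  out
}

shift_vals <- function(v, axis, by) {
  d <- dim(v)
  out <- array(0, d)
  n <- d[axis]
  src <- if (by > 0) seq_len(n - by) else seq.int(1 - by, n)
  dst <- if (by > 0) seq.int(1 + by, n) else seq_len(n + by)
  if (axis == 1) out[dst, , ] <- v[src, , ]
  else if (axis == 2) out[, dst, ] <- v[, src, ]
  else out[, , dst] <- v[, , src]
  # replicate edge value so border gradients stay finite
  if (axis == 1) { if (by > 0) out[1, , ] <- v[1, , ] else out[n, , ] <- v[n, , ] }
  else if (axis == 2) { if (by > 0) out[, 1, ] <- v[, 1, ] else out[, n, ] <- v[, n, ] }
  else { if (by > 0) out[, , 1] <- v[, , 1] else out[, , n] <- v[, , n] }
  out
}
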