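# Sample a 3-D array at continuous 0-based voxel indices.
# idx: n x 3 matrix. Out-of-field samples take `fill`.
interp3 <- function(values, idx, method = c("trilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  d <- dim(values)
  n <- nrow(idx)
  if (method == "nearest") {
    i <- round(idx[, 1]); j <- round(idx[, 2]); k <- round(idx[, 3])
    ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
    out <- rep(fill, n)
    if (any(ok))
      out[ok] <- values[cbind(i[ok] + 1, j[ok] + 1, k[ok] + 1)]
    return(out)
  }
  i0 <- floor(idx[, 1]); j0 <- floor(idx[, 2]); k0 <- floor(idx[, 3])
  fi <- idx[, 1] - i0;   fj <- idx[, 2] - j0;   fk <- idx[, 3] - k0
  ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  out <- rep(as.numeric(fill), n)
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fi <- fi[ok]; fj <- fj[ok]; fk <- fk[ok]
  # clamp the upper corner for points exactly on the last voxel centre
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1); k1 <- pmin(k0 + 1, d[3] - 1)
  v000 <- values[cbind(i0 + 1, j0 + 1, k0 + 1)]
  v100 <- values[cbind(i1 + 1, j0 + 1, k0 + 1)]
  v010 <- values[cbind(i0 + 1, j1 + 1, k0 + 1)]
  v110 <- values[cbind(i1 + 1, j1 + 1, k0 + 1)]
  v001 <- values[cbind(i0 + 1, j0 + 1, k1 + 1)]
  v101 <- values[cbind(i1 + 1, j0 + 1, k1 + 1)]
  v011 <- values[cbind(i0 + 1, j1 + 1, k1 + 1)]
  v111 <- values[cbind(i1 + 1, j1 + 1, k1 + 1)]
  w00 <- v000 * (1 - fi) + v100 * fi
  w10 <- v010 * (1 - fi) + v110 * fi
  w01 <- v001 * (1 - fi) + v101 * fi
  w11 <- v011 * (1 - fi) + v111 * fi
  out[ok] <- (w00 * (1 - fj) + w10 * fj) * (1 - fk) +
             (w01 * (1 - fj) + w11 * fj) * fk
  out
}

# sample a volume at world coordinates (n x 3, mm)
sample_volume <- function(vol, xyz, method = "trilinear", fill = 0) {
  interp3(vol$values, world_to_voxel(vol$grid, xyz), method = method, fill = fill)
}

#' Resample a volume onto a target grid
#'
#' Sampling is performed in world coordinates (voxel-centre convention);
#' points falling outside the source field of view take the fill value 0.
#' Label, annotation and mask volumes must use nearest-neighbour
#' interpolation, which never invents labels.
#'
#' @param vol a [brainvol()].
#' @param target a [grid3d()] to sample onto.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return a [brainvol()] on `target`.
#' @export
resample <- function(vol, target, interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (is_discrete_modality(vol$modality) && interpolation != "nearest")
    stop("validation error: ", vol$modality,
         " volumes must be resampled with nearest-neighbour interpolation")
  if (grids_equal(vol$grid, target)) return(vol)
  xyz <- grid_coordinates(target)
  out <- interp3(vol$values, world_to_voxel(vol$grid, xyz),
                 method = interpolation, fill = 0)
  brainvol(array(out, dim = target$shape), target,
           modality = vol$modality, units = vol$units)
}

#' Embed a volume in a larger bounding box
#'
#' Zero-pads the volume so its grid covers `box`, keeping the original
#' voxel spacing and world frame: the volume is centred in the box and
#' any odd one-voxel remainder of padding goes to the high-index side.
#' The sum of voxel values is conserved exactly (padding only adds
#' zeros).
#'
#' @param vol a [brainvol()].
#' @param box a [bounding_box()]; must contain the volume extent on every
#'   axis.
#' @param spacing target voxel spacing in mm; must equal the volume's own
#'   spacing (embedding never resamples — combine with [resample()] if a
#'   spacing change is needed).
#' @return a [brainvol()] with grid shape `ceiling(box extent / spacing)`.
#' @export
embed_in_box <- function(vol, box, spacing = vol$grid$spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(abs(spacing - vol$grid$spacing) > 1e-9))
    stop("validation error: embed_in_box keeps the voxel spacing; resample first")
  ext <- grid_extent(vol$grid)
  if (any(box$extent < ext - 1e-9))
    stop("validation error: bounding box smaller than the volume extent")
  out_shape <- as.integer(ceiling(box$extent / spacing - 1e-9))
  pad <- out_shape - vol$grid$shape
  pad_lo <- pad %/% 2L
  out <- array(if (is_discrete_modality(vol$modality)) 0L else 0,
               dim = out_shape)
  idx <- Map(function(p, n) seq.int(p + 1L, p + n), pad_lo, vol$grid$shape)
  out[idx[[1]], idx[[2]], idx[[3]]] <- vol$values
  g <- grid3d(out_shape, spacing, vol$grid$origin - pad_lo * spacing)
  brainvol(out, g, modality = vol$modality, units = vol$units)
}

#' Crop a volume to a centred sub-extent
#'
#' Inverse of [embed_in_box()]: removes the padding that centring in a
#' larger box introduced.
#'
#' @param vol a [brainvol()].
#' @param shape integer length-3, voxels to keep per axis.
#' @return a [brainvol()] of the requested shape, same world frame.
#' @export
crop_to_shape <- function(vol, shape) {
  shape <- as.integer(shape)
  if (any(shape > vol$grid$shape)) stop("crop shape exceeds volume shape")
  lo <- (vol$grid$shape - shape) %/% 2L
  idx <- Map(function(p, n) seq.int(p + 1L, p + n), lo, shape)
  g <- grid3d(shape, vol$grid$spacing, vol$grid$origin + lo * vol$grid$spacing)
  brainvol(vol$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], g,
           modality = vol$modality, units = vol$units)
}
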