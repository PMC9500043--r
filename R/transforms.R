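#' Rigid transform
#'
#' A rigid-body mapping of world coordinates,
#' `phi(x) = R (x - c) + c + t`, with `R` built from Euler angles applied
#' about the canonical axes in the fixed order AP, then DV, then ML
#' (`R = R3(rz) R2(ry) R1(rx)`). Units: mm and radians.
#'
#' @param translation numeric length-3 (mm).
#' @param rotation numeric length-3 (radians).
#' @param center numeric length-3 (mm), rotation centre.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(translation) == 3L, length(rotation) == 3L, length(center) == 3L)
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%s) mm, r = (%s) deg, centre (%s) mm\n",
              paste(sprintf("%.3f", x$translation), collapse = ", "),
              paste(sprintf("%.3f", x$rotation * 180 / pi), collapse = ", "),
              paste(sprintf("%.2f", x$center), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(rotation) {
  cx <- cos(rotation[1]); sx <- sin(rotation[1])
  cy <- cos(rotation[2]); sy <- sin(rotation[2])
  cz <- cos(rotation[3]); sz <- sin(rotation[3])
  R1 <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  R2 <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  R3 <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R3 %*% R2 %*% R1
}

#' Apply a rigid transform to coordinates
#'
#' @param rt a [rigid_transform()].
#' @param xyz n x 3 matrix of world coordinates (mm), or length-3 vector.
#' @return n x 3 matrix of mapped coordinates.
#' @export
apply_rigid <- function(rt, xyz) {
  xyz <- rbind_coerce(xyz)
  R <- rotation_matrix(rt$rotation)
  xc <- sweep(xyz, 2, rt$center, "-")
  sweep(xc %*% t(R), 2, rt$center + rt$translation, "+")
}

#' Invert a rigid transform
#'
#' @param rt a [rigid_transform()].
#' @return the inverse as a [rigid_transform()] (same centre).
#' @export
rigid_inverse <- function(rt) {
  R <- rotation_matrix(rt$rotation)
  # phi^-1(y) = R' (y - c - t) + c; express as translation in the same form
  # using the rotation matrix directly
  inv <- rigid_transform(center = rt$center)
  inv$rotation_matrix <- t(R)
  inv$translation <- as.numeric(-t(R) %*% rt$translation)
  inv
}

# rotation matrix of a transform, honouring an explicit matrix override
# (used for inverses, whose Euler angles we never need)
rt_matrix <- function(rt) rt$rotation_matrix %||% rotation_matrix(rt$rotation)

apply_rigid_mat <- function(rt, xyz) {
  xyz <- rbind_coerce(xyz)
  R <- rt_matrix(rt)
  xc <- sweep(xyz, 2, rt$center, "-")
  sweep(xc %*% t(R), 2, rt$center + rt$translation, "+")
}

#' Dense deformation field
#'
#' A per-voxel displacement `d` (mm) on a template-space grid, following
#' the pull-back convention: a template-space point `x'` corresponds to
#' the subject-space point `x' + d(x')`. Optionally the field carries the
#' low-frequency cosine-basis coefficients it was synthesized from, plus
#' the world-space `domain` (box) over which the basis is defined, so
#' that the same coefficients evaluate consistently at any resolution.
#'
#' @param grid a [grid3d()].
#' @param displacement numeric array `c(shape, 3)` of per-voxel
#'   displacement vectors in mm, or NULL to synthesize from
#'   `coefficients`.
#' @param coefficients optional array `c(K1, K2, K3, 3)` of cosine-basis
#'   coefficients (mm).
#' @param domain optional list(edge, extent): world box of the basis;
#'   defaults to the grid's own box.
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(grid, displacement = NULL, coefficients = NULL,
                              domain = NULL) {
  if (is.null(domain))
    domain <- list(edge = grid$origin - grid$spacing / 2,
                   extent = grid_extent(grid))
  if (is.null(displacement)) {
    if (is.null(coefficients)) stop("need displacement or coefficients")
    displacement <- synthesize_field_array(coefficients, grid, domain)
  }
  if (!all(dim(displacement) == c(grid$shape, 3L)))
    stop("displacement array must have dim c(shape, 3)")
  if (any(!is.finite(displacement)))
    stop("validation error: deformation field must be finite everywhere")
  structure(list(grid = grid, displacement = displacement,
                 coefficients = coefficients, domain = domain),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$displacement, ncol = 3L)^2))
  cat(sprintf("<deformation_field> %s grid @ %s mm; |d| mean %.3f, max %.3f mm%s\n",
              paste(x$grid$shape, collapse = " x "),
              paste(format(x$grid$spacing), collapse = " x "),
              mean(mag), max(mag),
              if (!is.null(x$coefficients))
                sprintf("; basis %s", paste(dim(x$coefficients)[1:3], collapse = "x"))
              else ""))
  invisible(x)
}

#' Identity deformation field
#'
#' @param grid a [grid3d()].
#' @return a [deformation_field()] with zero displacement.
#' @export
identity_field <- function(grid) {
  deformation_field(grid, array(0, c(grid$shape, 3L)))
}

# cosine (DCT-II) design matrix over n points at normalized positions
# u_i = (i - 0.5)/n, frequencies k = 0..K-1: B[i, k+1] = cos(pi k u_i)
dct_basis <- function(u, K) {
  outer(u, seq_len(K) - 1, function(u, k) cos(pi * k * u))
}

grid_normalized_positions <- function(grid, domain) {
  lapply(1:3, function(a) {
    x <- grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a]
    (x - domain$edge[a]) / domain$extent[a]
  })
}

# synthesize dense displacement c(shape,3) from coefficients c(K1,K2,K3,3)
synthesize_field_array <- function(coef, grid, domain) {
  K <- dim(coef)[1:3]
  u <- grid_normalized_positions(grid, domain)
  B1 <- dct_basis(u[[1]], K[1]); B2 <- dct_basis(u[[2]], K[2]); B3 <- dct_basis(u[[3]], K[3])
  n <- grid$shape
  out <- array(0, c(n, 3L))
  for (a in 1:3) {
    A <- array(B1 %*% matrix(coef[, , , a], K[1], K[2] * K[3]), c(n[1], K[2], K[3]))
    A <- aperm(A, c(2, 1, 3))
    A <- array(B2 %*% matrix(A, K[2], n[1] * K[3]), c(n[2], n[1], K[3]))
    A <- aperm(A, c(3, 2, 1))                       # K3 x n1 x n2
    A <- array(B3 %*% matrix(A, K[3], n[1] * n[2]), c(n[3], n[1], n[2]))
    out[, , , a] <- aperm(A, c(2, 3, 1))
  }
  out
}

# displacement vectors interpolated at world points (n x 3). Points beyond
# the grid take the nearest-edge value (constant extrapolation): fields are
# low-frequency, and clamping keeps composition and inversion well behaved
# at the box border.
sample_field <- function(field, xyz) {
  idx <- world_to_voxel(field$grid, xyz)
  d <- field$grid$shape
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 0), d[a] - 1)
  cbind(interp3(field$displacement[, , , 1], idx, "trilinear", 0),
        interp3(field$displacement[, , , 2], idx, "trilinear", 0),
        interp3(field$displacement[, , , 3], idx, "trilinear", 0))
}

# mapped subject-space points for template-space points xyz
map_points <- function(xyz, rigid = NULL, field = NULL) {
  y <- rbind_coerce(xyz)
  if (!is.null(field)) y <- y + sample_field(field, y)
  if (!is.null(rigid)) y <- apply_rigid_mat(rigid, y)
  y
}

#' Warp a volume through a rigid transform and/or deformation field
#'
#' Pull-back resampling: the output value at template-space point `x'`
#' is `vol(rigid(x' + d(x')))` (field applied first, then the rigid
#' mapping; either may be omitted). Label/annotation/mask volumes
#' require nearest-neighbour interpolation.
#'
#' @param vol a [brainvol()] to sample from (subject space).
#' @param rigid optional [rigid_transform()].
#' @param field optional [deformation_field()]; its grid defines the
#'   output grid unless `target` is given.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param target optional output [grid3d()] (required if `field` is
#'   NULL).
#' @return a [brainvol()] on the output grid.
#' @export
apply_transform <- function(vol, rigid = NULL, field = NULL,
                            interpolation = c("trilinear", "nearest"),
                            target = NULL) {
  interpolation <- match.arg(interpolation)
  if (is.null(rigid) && is.null(field))
    stop("validation error: need at least one of rigid/field")
  if (is_discrete_modality(vol$modality) && interpolation != "nearest")
    stop("validation error: ", vol$modality, " volumes require nearest interpolation")
  out_grid <- target %||% (if (!is.null(field)) field$grid else vol$grid)
  xyz <- grid_coordinates(out_grid)
  y <- map_points(xyz, rigid = rigid, field = field)
  vals <- interp3(vol$values, world_to_voxel(vol$grid, y),
                  method = interpolation, fill = 0)
  brainvol(array(vals, out_grid$shape), out_grid,
           modality = vol$modality, units = vol$units)
}

#' Compose a deformation field with a second mapping
#'
#' Returns the field of the composed mapping `x' -> inner(outer(x'))`,
#' where `outer` is a deformation field (`outer(x') = x' + d(x')`) and
#' `inner` is a rigid transform or a second deformation field, evaluated
#' at the points `outer` maps to. Composition with the identity returns
#' the original field.
#'
#' @param outer a [deformation_field()].
#' @param inner a [rigid_transform()] or [deformation_field()].
#' @return a [deformation_field()] on `outer`'s grid.
#' @export
compose_fields <- function(outer, inner) {
  stopifnot(inherits(outer, "deformation_field"))
  xyz <- grid_coordinates(outer$grid)
  y <- xyz + matrix(outer$displacement, ncol = 3L)
  z <- if (inherits(inner, "rigid_transform")) apply_rigid_mat(inner, y)
       else if (inherits(inner, "deformation_field")) y + sample_field(inner, y)
       else stop("inner must be a rigid_transform or deformation_field")
  deformation_field(outer$grid, array(z - xyz, c(outer$grid$shape, 3L)))
}

#' Numerically invert a deformation field
#'
#' Fixed-point iteration for the field `e` with
#' `x + e(x) + d(x + e(x)) = x`, i.e. the inverse of `x -> x + d(x)`.
#' Converges for the smooth, moderate-amplitude fields this package
#' works with.
#'
#' @param field a [deformation_field()].
#' @param iterations fixed-point iterations (default 30).
#' @return a [deformation_field()] on the same grid.
#' @export
invert_field <- function(field, iterations = 30L) {
  xyz <- grid_coordinates(field$grid)
  e <- matrix(0, nrow(xyz), 3L)
  for (it in seq_len(iterations)) {
    e <- -sample_field(field, xyz + e)
  }
  deformation_field(field$grid, array(e, c(field$grid$shape, 3L)))
}

# convert a rigid transform to a dense field on a grid
rigid_to_field <- function(rt, grid) {
  xyz <- grid_coordinates(grid)
  deformation_field(grid, array(apply_rigid_mat(rt, xyz) - xyz, c(grid$shape, 3L)))
}
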