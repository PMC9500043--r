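#' Per-voxel displacement between two deformation fields
#'
#' Two normalization pipelines map the same template-space point `x'` to
#' (possibly different) subject-space points; their disagreement at `x'`
#' is the Euclidean distance between those points, which equals the norm
#' of the difference of the displacement vectors. Field b is resampled
#' onto field a's grid when the grids differ (their world boxes must be
#' compatible).
#'
#' @param field_a,field_b [deformation_field()]s of the same subject.
#' @return object of class `displacement_map`: `grid`, `values` (mm,
#'   >= 0), `n_subjects = 1`.
#' @export
pointwise_displacement <- function(field_a, field_b) {
  stopifnot(inherits(field_a, "deformation_field"),
            inherits(field_b, "deformation_field"))
  if (!grids_equal(field_a$grid, field_b$grid)) {
    ea <- grid_extent(field_a$grid); eb <- grid_extent(field_b$grid)
    if (any(abs(ea - eb) > pmax(field_a$grid$spacing, field_b$grid$spacing) * 2))
      stop("validation error: incompatible field extents")
    xyz <- grid_coordinates(field_a$grid)
    db <- sample_field(field_b, xyz)
  } else {
    db <- matrix(field_b$displacement, ncol = 3L)
  }
  da <- matrix(field_a$displacement, ncol = 3L)
  vals <- sqrt(rowSums((da - db)^2))
  structure(list(grid = field_a$grid,
                 values = array(vals, field_a$grid$shape),
                 n_subjects = 1L),
            class = "displacement_map")
}

#' @export
print.displacement_map <- function(x, ...) {
  cat(sprintf("<displacement_map> %s grid, n = %d; mean %.3f, max %.3f mm\n",
              paste(x$grid$shape, collapse = " x "), x$n_subjects,
              mean(x$values), max(x$values)))
  invisible(x)
}

#' Root-mean-squared displacement over subjects
#'
#' Per voxel, the square root of the mean over subjects of the squared
#' displacements: `sqrt( (1/N) sum_i ||delta_i||^2 )`.
#'
#' @param maps list of `displacement_map`s on a common grid.
#' @return aggregated `displacement_map` with `n_subjects` the total
#'   subject count.
#' @export
rms_over_subjects <- function(maps) {
  if (length(maps) == 0L) stop("validation error: empty map list")
  g <- maps[[1]]$grid
  for (m in maps) {
    stopifnot(inherits(m, "displacement_map"))
    if (!grids_equal(m$grid, g)) stop("validation error: maps on different grids")
  }
  n <- sum(vapply(maps, `[[`, integer(1), "n_subjects"))
  ssq <- Reduce(`+`, lapply(maps, function(m) m$values^2 * m$n_subjects))
  structure(list(grid = g, values = sqrt(ssq / n), n_subjects = n),
            class = "displacement_map")
}

#' Regional RMS displacement table
#'
#' Per VOI, the RMS displacement pooled over all voxels of the region
#' and all subjects: `sqrt( sum_{i,v} ||delta_{i,v}||^2 / (N V) )`. A
#' global row pooled over all labelled voxels is attached as an
#' attribute and printed alongside the table. Setting
#' `aggregate = "sum"` reproduces instead the plain per-region mean of
#' the per-voxel sum of displacement norms over subjects (a
#' non-normalized variant retained for comparison with legacy reports).
#'
#' @param maps list of per-subject `displacement_map`s (or one
#'   aggregated map).
#' @param atlas a `label_atlas` on the same template grid.
#' @param aggregate `"rms"` (default) or `"sum"`.
#' @return data.frame: region, abbreviation, side, displacement_mm; the
#'   pooled global value is in `attr(, "global_mm")`.
#' @export
regional_displacement <- function(maps, atlas, aggregate = c("rms", "sum")) {
  aggregate <- match.arg(aggregate)
  if (inherits(maps, "displacement_map")) maps <- list(maps)
  if (length(maps) == 0L) stop("validation error: empty map list")
  g <- maps[[1]]$grid
  if (!grids_equal(atlas$volume$grid, g))
    stop("validation error: atlas and maps on different grids")
  lab <- as.vector(atlas$volume$values)
  fl <- factor(lab, levels = atlas$regions$label)
  out <- atlas$regions[, c("name", "abbreviation", "side")]
  out$region <- region_display_names(atlas$regions)
  if (aggregate == "rms") {
    ssq <- 0; nn <- 0
    for (m in maps) { ssq <- ssq + as.vector(m$values)^2 * m$n_subjects; nn <- nn + m$n_subjects }
    sums <- tapply(ssq, fl, sum)
    cnts <- tapply(rep(1, length(lab)), fl, sum)
    out$displacement_mm <- as.numeric(sqrt(sums / (cnts * nn)))
    glob <- sqrt(sum(ssq[lab > 0]) / (sum(lab > 0) * nn))
  } else {
    tot <- 0
    for (m in maps) tot <- tot + as.vector(m$values) * m$n_subjects
    sums <- tapply(tot, fl, sum)
    cnts <- tapply(rep(1, length(lab)), fl, sum)
    out$displacement_mm <- as.numeric(sums / cnts)
    glob <- sum(tot[lab > 0]) / sum(lab > 0)
  }
  if (any(is.na(out$displacement_mm)))
    warning("region(s) empty on this grid: ",
            paste(out$abbreviation[is.na(out$displacement_mm)], collapse = ", "))
  out <- out[, c("region", "abbreviation", "side", "displacement_mm")]
  rownames(out) <- NULL
  attr(out, "global_mm") <- glob
  out
}
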