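#' VOI specification table
#'
#' A VOI spec maps a named brain region to the ontology structures whose
#' descendant sets define it, with laterality: `bilateral` regions are
#' split into left and right halves at the mid-sagittal plane, `central`
#' regions are kept whole. The default set shipped with the package
#' (`inst/extdata/voi_spec_ccf.csv`) contains 12 bilateral and 3 central
#' entries covering the main grey-matter divisions, so a complete build
#' yields 27 labelled regions.
#'
#' @param path CSV file with columns `name`, `abbreviation`, `laterality`
#'   (`bilateral`/`central`) and `acronyms` (semicolon-separated ontology
#'   acronyms), or a YAML file with the same fields per entry.
#' @return data.frame with one row per VOI.
#' @export
load_voi_specs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", tolower(path))) {
    y <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(y, function(e)
      data.frame(name = e$name, abbreviation = e$abbreviation,
                 laterality = e$laterality,
                 acronyms = paste(unlist(e$acronyms), collapse = ";"),
                 stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("name", "abbreviation", "laterality", "acronyms")
  if (!all(need %in% names(df)))
    stop("validation error: VOI spec must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$abbreviation))
    stop("validation error: duplicate VOI abbreviations")
  if (!all(df$laterality %in% c("bilateral", "central")))
    stop("validation error: laterality must be 'bilateral' or 'central'")
  df
}

#' @rdname load_voi_specs
#' @export
default_voi_specs <- function() {
  load_voi_specs(system.file("extdata", "voi_spec_ccf.csv", package = "ccfpet",
                             mustWork = TRUE))
}

# logical index restricting to one hemisphere along the ML axis (axis 3,
# increasing left -> right). Even dimension: split between the two central
# columns; odd dimension: the central column belongs to neither side.
hemisphere_index <- function(shape, side) {
  n <- shape[3]
  keep <- rep(TRUE, n)
  if (side == "whole") return(keep)
  half <- n %/% 2L
  if (side == "L") {
    keep[] <- FALSE; keep[seq_len(half)] <- TRUE
  } else if (side == "R") {
    keep[] <- FALSE; keep[seq.int(n - half + 1L, n)] <- TRUE
  } else stop("side must be 'L', 'R' or 'whole'")
  keep
}

#' Build a binary VOI mask from annotation ids
#'
#' @param annotation a [brainvol()] with modality `"annotation"`.
#' @param ids integer vector of annotation values belonging to the VOI.
#' @param side `"L"`, `"R"` or `"whole"`: hemisphere restriction at the
#'   mid-plane of the ML axis (`"whole"` applies none).
#' @return a [brainvol()] mask (0/1).
#' @export
build_voi_mask <- function(annotation, ids, side = "whole") {
  if (annotation$modality != "annotation")
    stop("validation error: build_voi_mask needs an annotation volume")
  if (length(ids) == 0L) stop("validation error: empty id set")
  m <- array(as.integer(annotation$values %in% as.integer(ids)),
             dim = annotation$grid$shape)
  keep <- hemisphere_index(annotation$grid$shape, side)
  if (!all(keep)) m[, , !keep] <- 0L
  if (sum(m) == 0L)
    message("note: VOI mask is empty (ids not present",
            if (side != "whole") paste0(" on side ", side) else "", ")")
  brainvol(m, annotation$grid, modality = "mask")
}

shift_mask <- function(m, axis, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) seq_len(n - by) else seq.int(1 - by, n)
  dst <- if (by > 0) seq.int(1 + by, n) else seq_len(n + by)
  if (axis == 1) out[dst, , ] <- m[src, , ]
  else if (axis == 2) out[, dst, ] <- m[, src, ]
  else out[, , dst] <- m[, , src]
  out
}

#' Morphological erosion of a binary mask
#'
#' Erodes with a face-neighbour (6-connected) cross by default, the
#' minimal structuring element for a "one voxel" erosion; a 26-connected
#' (3x3x3 cube) element is available. Voxels outside the volume count as
#' background, so the mask is also eroded at the field-of-view border.
#'
#' @param mask a [brainvol()] mask (binary).
#' @param iterations number of erosion passes (default 1).
#' @param connectivity 6 (cross) or 26 (cube).
#' @return eroded mask as a [brainvol()].
#' @export
erode_mask <- function(mask, iterations = 1L, connectivity = 6) {
  if (!is_discrete_modality(mask$modality))
    stop("validation error: erode_mask needs a mask/label volume")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  m <- mask$values > 0
  for (it in seq_len(iterations)) {
    if (connectivity == 6) {
      out <- m
      for (ax in 1:3) {
        out <- out & shift_mask(m, ax, 1L) & shift_mask(m, ax, -1L)
      }
      # border voxels have neighbours outside the volume -> background
      out[c(1, dim(m)[1]), , ] <- FALSE
      out[, c(1, dim(m)[2]), ] <- FALSE
      out[, , c(1, dim(m)[3])] <- FALSE
      m <- out
    } else {
      for (ax in 1:3) {   # 3x3x3 cube erosion is separable per axis
        m <- m & shift_mask(m, ax, 1L) & shift_mask(m, ax, -1L)
        if (ax == 1) m[c(1, dim(m)[1]), , ] <- FALSE
        if (ax == 2) m[, c(1, dim(m)[2]), ] <- FALSE
        if (ax == 3) m[, , c(1, dim(m)[3])] <- FALSE
      }
    }
  }
  brainvol(array(as.integer(m), dim(mask$values)), mask$grid, modality = "mask")
}

#' Build a labelled VOI atlas from an ontology and an annotation volume
#'
#' For each VOI spec (in table order) and each side implied by its
#' laterality, the full descendant structure set is collected from the
#' ontology, turned into a hemisphere-restricted binary mask, eroded, and
#' assigned the next free integer label. Regions whose post-erosion
#' volume falls below `min_volume_mm3` are rejected and reported. Voxels
#' already claimed by an earlier spec are never relabelled (overlaps are
#' reported with a warning); each voxel carries at most one label.
#'
#' @param annotation a [brainvol()] with modality `"annotation"`.
#' @param specs VOI spec data.frame (see [load_voi_specs()]).
#' @param tree root [ontology_node].
#' @param erosion_iters erosion passes per VOI (default 1).
#' @param connectivity erosion structuring element, 6 or 26.
#' @param min_volume_mm3 post-erosion volume threshold; regions smaller
#'   than this are excluded (default 1.5 mm^3, large compared to PET
#'   resolution).
#' @return object of class `label_atlas`: list with `volume` (label
#'   [brainvol()]), `regions` (data.frame: label, name, abbreviation,
#'   side, volume_mm3) and `dropped` (data.frame of rejected regions).
#' @export
build_label_atlas <- function(annotation, specs, tree, erosion_iters = 1L,
                              connectivity = 6, min_volume_mm3 = 1.5) {
  if (annotation$modality != "annotation")
    stop("validation error: build_label_atlas needs an annotation volume")
  voxvol <- prod(annotation$grid$spacing)
  labels <- array(0L, annotation$grid$shape)
  rows <- list(); dropped <- list()
  next_label <- 1L
  for (r in seq_len(nrow(specs))) {
    sp <- specs[r, ]
    ids <- collect_substructures(tree, acronyms_to_ids(tree, strsplit(sp$acronyms, ";")[[1]]))
    sides <- if (sp$laterality == "bilateral") c("L", "R") else "C"
    for (side in sides) {
      msk <- build_voi_mask(annotation, ids, side = if (side == "C") "whole" else side)
      if (erosion_iters > 0)
        msk <- erode_mask(msk, iterations = erosion_iters, connectivity = connectivity)
      vol_mm3 <- sum(msk$values) * voxvol
      if (vol_mm3 < min_volume_mm3) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(name = sp$name, abbreviation = sp$abbreviation, side = side,
                     volume_mm3 = vol_mm3, stringsAsFactors = FALSE)
        next
      }
      sel <- msk$values > 0L
      clash <- sel & labels > 0L
      if (any(clash)) {
        warning(sprintf("VOI %s (%s): %d voxels already labelled; keeping earlier label",
                        sp$abbreviation, side, sum(clash)))
        sel <- sel & labels == 0L
      }
      labels[sel] <- next_label
      rows[[length(rows) + 1L]] <-
        data.frame(label = next_label, name = sp$name,
                   abbreviation = sp$abbreviation, side = side,
                   volume_mm3 = sum(sel) * voxvol, stringsAsFactors = FALSE)
      next_label <- next_label + 1L
    }
  }
  regions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), name = character(0), abbreviation = character(0),
               side = character(0), volume_mm3 = numeric(0))
  # relabel consecutively in case rejections left gaps
  if (nrow(regions) && any(diff(c(0L, regions$label)) != 1L)) {
    remap <- integer(max(regions$label))
    remap[regions$label] <- seq_len(nrow(regions))
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
    regions$label <- seq_len(nrow(regions))
  }
  structure(list(volume = brainvol(labels, annotation$grid, modality = "label"),
                 regions = regions,
                 dropped = if (length(dropped)) do.call(rbind, dropped) else NULL),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %d regions on a %s grid (%s mm)\n",
              nrow(x$regions),
              paste(x$volume$grid$shape, collapse = " x "),
              paste(format(x$volume$grid$spacing), collapse = " x ")))
  if (!is.null(x$dropped))
    cat(sprintf("  %d region(s) rejected below the volume threshold\n", nrow(x$dropped)))
  invisible(x)
}

#' Region volumes of a label atlas
#'
#' @param atlas a `label_atlas`.
#' @return data.frame with `label`, `name`, `abbreviation`, `side` and
#'   `volume_mm3` (voxel count times voxel volume); background excluded.
#' @export
region_volumes <- function(atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  voxvol <- prod(atlas$volume$grid$spacing)
  counts <- tabulate(atlas$volume$values, nbins = max(atlas$regions$label, 1L))
  out <- atlas$regions
  out$volume_mm3 <- counts[out$label] * voxvol
  out
}

#' Whole-brain mask of a label atlas
#'
#' Union of all labelled regions — the package's working definition of
#' "cerebral" for global-mean scaling.
#'
#' @param atlas a `label_atlas`.
#' @return a [brainvol()] mask.
#' @export
atlas_brain_mask <- function(atlas) {
  brainvol(array(as.integer(atlas$volume$values > 0L), atlas$volume$grid$shape),
           atlas$volume$grid, modality = "mask")
}

# region label names like "Thalamus left" / "Cerebellum"
region_display_names <- function(regions) {
  suffix <- c(L = " left", R = " right", C = "")
  paste0(regions$name, suffix[regions$side])
}
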