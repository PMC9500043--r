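#' Annotated 3-D volume
#'
#' The package's container for imaging data: a 3-D numeric array plus its
#' [grid3d()] geometry, a modality tag and free-text units. Annotation,
#' label and mask volumes must hold non-negative integers; they are stored
#' as integer arrays and resampled with nearest-neighbour interpolation
#' only.
#'
#' @param values 3-D array matching `grid$shape`.
#' @param grid a [grid3d()].
#' @param modality one of `"CT"`, `"MR"`, `"PET"`, `"annotation"`,
#'   `"mask"`, `"label"`.
#' @param units free-text units (e.g. `"HU-like"`, `"kBq/mL"`, `"SUV"`).
#' @return object of class `brainvol`.
#' @export
brainvol <- function(values, grid, modality = "CT", units = "") {
  modality <- match.arg(modality, c("CT", "MR", "PET", "annotation", "mask", "label"))
  if (!inherits(grid, "grid3d")) stop("grid must be a grid3d")
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape))
    stop("array shape must equal grid shape exactly")
  if (is_discrete_modality(modality)) {
    if (any(!is.finite(values)))
      stop(modality, " volume must not contain non-finite values")
    if (any(values < 0) || any(values != round(values)))
      stop(modality, " volume values must be non-negative integers")
    storage.mode(values) <- "integer"
  } else {
    storage.mode(values) <- "double"
  }
  structure(list(values = values, grid = grid, modality = modality, units = units),
            class = "brainvol")
}

is_discrete_modality <- function(m) m %in% c("annotation", "mask", "label")

#' @export
print.brainvol <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<brainvol> %s%s, %d x %d x %d @ %s mm, range [%.4g, %.4g]\n",
              x$modality, if (nzchar(x$units)) paste0(" (", x$units, ")") else "",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              paste(format(x$grid$spacing), collapse = " x "), rng[1], rng[2]))
  invisible(x)
}

#' @export
#' @importFrom graphics image par title
#' @describeIn brainvol orthogonal mid-slice display (axial, coronal, sagittal).
plot.brainvol <- function(x, ...) {
  mid <- pmax(1L, x$grid$shape %/% 2L)
  op <- par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  sl <- list(x$values[mid[1], , ], x$values[, mid[2], ], x$values[, , mid[3]])
  nm <- c("coronal", "axial", "sagittal")
  for (i in 1:3) {
    image(sl[[i]], col = grDevices::gray.colors(128), axes = FALSE, useRaster = TRUE)
    title(sprintf("%s (%s)", nm[i], x$modality))
  }
  invisible(x)
}

# rotation taking RAS world axes to the canonical (AP, DV, ML) frame:
# AP = -A, DV = -S, ML = +R
ras_to_canonical <- function() {
  matrix(c(0, -1, 0,
           0,  0, -1,
           1,  0, 0), nrow = 3, byrow = TRUE)
}

# canonical-frame voxel->world affine of a grid (4x4)
grid_affine_canonical <- function(grid) {
  rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
}

# Decompose a canonical-frame affine into permutation + flips and reorder
# the array so index axis i advances canonical axis i with positive step.
# Errors if the affine is sheared/oblique beyond tol.
affine_to_grid_values <- function(values, affine, tol = 1e-4) {
  A <- affine[1:3, 1:3]
  spn <- sqrt(colSums(A^2))
  if (any(spn <= 0)) stop("geometry error: degenerate affine")
  D <- sweep(A, 2, spn, "/")
  perm <- integer(3); sgn <- numeric(3)
  for (j in 1:3) {
    ax <- which.max(abs(D[, j]))
    if (abs(abs(D[ax, j]) - 1) > tol || sum(abs(D[, j])) - abs(D[ax, j]) > tol)
      stop("geometry error: non-axis-aligned affine beyond tolerance")
    perm[j] <- ax
    sgn[j] <- sign(D[ax, j])
  }
  if (anyDuplicated(perm)) stop("geometry error: degenerate affine axes")
  dims <- dim(values)
  origin <- affine[1:3, 4]
  for (j in 1:3) {
    if (sgn[j] < 0) {
      idx <- rev(seq_len(dims[j]))
      values <- switch(j,
                       values[idx, , , drop = FALSE],
                       values[, idx, , drop = FALSE],
                       values[, , idx, drop = FALSE])
      # origin moves to what was the last voxel along this axis
      origin <- origin + A[, j] * (dims[j] - 1)
    }
  }
  jorder <- match(1:3, perm)   # index axis feeding each canonical axis
  values <- aperm(values, jorder)
  g <- grid3d(dim(values), spn[jorder], origin)
  list(values = values, grid = g)
}

#' Read a 3-D volume from NIfTI-1 or NRRD
#'
#' Reads the file, validates that its voxel-to-world transform is
#' axis-aligned (no shear/oblique axes), and canonicalizes the array to
#' the package's fixed (AP, DV, ML) axis order. Integer-typed arrays are
#' preserved losslessly for annotation/label/mask modalities.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.nrrd`).
#' @param modality modality tag to assign (see [brainvol()]); volumes read
#'   with modality `"annotation"`, `"label"` or `"mask"` are coerced to
#'   integer and validated.
#' @param format_hint optional, `"nifti"` or `"nrrd"`; by default inferred
#'   from the file extension.
#' @param units units string to attach.
#' @return a [brainvol()].
#' @export
read_volume <- function(path, modality = "CT", format_hint = NULL, units = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- format_hint
  if (is.null(fmt)) {
    low <- tolower(path)
    fmt <- if (grepl("\\.nrrd$|\\.nhdr$", low)) "nrrd" else "nifti"
  }
  if (fmt == "nrrd") {
    nr <- read_nrrd_raw(path)
    vol <- brainvol(nr$values, grid3d(dim(nr$values), nr$spacing, nr$origin),
                    modality = modality, units = units)
    return(vol)
  }
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("format error reading '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  aff <- RNifti::xform(img)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L) stop("format error: expected a 3-D volume")
  # rotate the RAS affine into the canonical frame before decomposition
  M <- ras_to_canonical()
  caff <- rbind(cbind(M %*% aff[1:3, 1:3], M %*% aff[1:3, 4]), c(0, 0, 0, 1))
  gz <- affine_to_grid_values(arr, caff)
  brainvol(gz$values, gz$grid, modality = modality, units = units)
}

#' Write a volume as NIfTI-1
#'
#' The canonical (AP, DV, ML) geometry is encoded as the equivalent RAS
#' world affine in both the qform and sform, so external viewers see the
#' correct anatomical orientation. `read_volume(write_volume(v))`
#' reproduces values, spacing and origin.
#'
#' @param vol a [brainvol()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "brainvol"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  if (is_discrete_modality(vol$modality) && any(!is.finite(vol$values)))
    stop("validation error: non-finite values in a ", vol$modality, " volume")
  M <- ras_to_canonical()
  caff <- grid_affine_canonical(vol$grid)
  raff <- rbind(cbind(t(M) %*% caff[1:3, 1:3], t(M) %*% caff[1:3, 4]), c(0, 0, 0, 1))
  dt <- if (is_discrete_modality(vol$modality)) "int32" else "double"
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$grid$spacing
  img <- RNifti::`sform<-`(img, structure(raff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(raff, code = 2L))
  ok <- tryCatch({RNifti::writeNifti(img, path, datatype = dt); TRUE},
                 error = function(e) stop("I/O error writing '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (!file.exists(path)) stop("I/O error: failed to write ", path)
  invisible(path)
}

# Minimal NRRD reader covering the Allen distribution style: attached
# binary data, raw or gzip encoding, 3-D, axis-aligned space directions.
# NRRD index axes are taken as already being in (AP, DV, ML) order, which
# matches the Allen mouse CCF volumes.
read_nrrd_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  # byte-wise line reads: readLines() buffers past the header and would
  # corrupt the binary payload offset
  read_line <- function() {
    bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L) return(NULL)
      if (b == as.raw(10L)) break
      bytes <- c(bytes, b)
    }
    sub("\r$", "", rawToChar(bytes))
  }
  magic <- read_line()
  if (is.null(magic) || !grepl("^NRRD000", magic))
    stop("format error: not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- read_line()
    if (is.null(ln)) stop("format error: NRRD header ended prematurely")
    if (ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexpr(":=?", ln), invert = TRUE)[[1]]
    if (length(kv) < 2L) next
    fields[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  need <- function(k) {
    if (is.null(fields[[k]])) stop("format error: NRRD header missing '", k, "'")
    fields[[k]]
  }
  dimn <- as.integer(need("dimension"))
  if (dimn != 3L) stop("format error: only 3-D NRRD supported")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- need("type")
  enc <- tolower(need("encoding"))
  endian <- tolower(fields[["endian"]] %||% "little")
  rtype <- switch(type,
                  "unsigned char" = , "uchar" = , "uint8" = , "uint8_t" = list("integer", 1, FALSE),
                  "short" = , "int16" = , "int16_t" = list("integer", 2, TRUE),
                  "unsigned short" = , "ushort" = , "uint16" = , "uint16_t" = list("integer", 2, FALSE),
                  "int" = , "int32" = , "int32_t" = list("integer", 4, TRUE),
                  "unsigned int" = , "uint32" = , "uint32_t" = list("integer", 4, FALSE),
                  "float" = list("double", 4, TRUE),
                  "double" = list("double", 8, TRUE),
                  stop("format error: unsupported NRRD type '", type, "'"))
  n <- prod(sizes)
  # connections (gzcon in particular) may return short reads; accumulate
  read_all <- function(src) {
    out <- vector(rtype[[1]], 0)
    while (length(out) < n) {
      chunk <- readBin(src, rtype[[1]], n = n - length(out), size = rtype[[2]],
                       signed = rtype[[3]] || rtype[[2]] > 2,
                       endian = if (endian == "big") "big" else "little")
      if (length(chunk) == 0L) break
      out <- c(out, chunk)
    }
    out
  }
  if (enc == "raw") {
    dat <- read_all(con)
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.size(path))
    # memDecompress handles both gzip- and zlib-framed streams
    dat <- readBin(memDecompress(comp, "gzip"), rtype[[1]], n = n,
                   size = rtype[[2]], signed = rtype[[3]] || rtype[[2]] > 2,
                   endian = if (endian == "big") "big" else "little")
  } else stop("format error: unsupported NRRD encoding '", enc, "'")
  if (length(dat) != n) stop("format error: NRRD data truncated")
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dirs <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(dirs^2))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  }
  list(values = array(dat, dim = sizes), spacing = spacing, origin = origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
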