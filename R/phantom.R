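# Seed table for the synthetic mouse-head anatomy. Coordinates are
# normalized ellipsoid coordinates (AP, DV, ML) in [-1, 1]; bilateral
# structures are mirrored about ML = 0. Each ontology group contributes
# two leaf structures with a small AP offset, so VOIs are genuine
# descendant unions. MR intensities and PET uptake are per group.
phantom_groups <- function() {
  g <- function(acr, id, name, lat, ap, dv, ml, mr, up)
    data.frame(acronym = acr, id = id, name = name, laterality = lat,
               ap = ap, dv = dv, ml = ml, mr = mr, uptake = up,
               stringsAsFactors = FALSE)
  rbind(
    g("OLF",  698, "Olfactory areas",         "bilateral", -0.85,  0.05, 0.25, 430, 1.00),
    g("ORB",  714, "Orbital areas",           "bilateral", -0.70, -0.30, 0.30, 460, 1.00),
    g("ACA",   31, "Anterior cingulate area", "bilateral", -0.45, -0.60, 0.12, 450, 1.05),
    g("MO",   500, "Somatomotor areas",       "bilateral", -0.45, -0.45, 0.45, 470, 1.00),
    g("SS",   453, "Somatosensory areas",     "bilateral", -0.10, -0.45, 0.60, 440, 1.00),
    g("AUD",  247, "Auditory areas",          "bilateral",  0.15, -0.25, 0.75, 455, 0.95),
    g("VIS",  669, "Visual areas",            "bilateral",  0.35, -0.55, 0.45, 445, 0.95),
    g("STRd", 485, "Striatum dorsal",         "bilateral", -0.35,  0.05, 0.40, 400, 1.10),
    g("STRv", 493, "Striatum ventral",        "bilateral", -0.35,  0.45, 0.30, 410, 1.05),
    g("HIP", 1080, "Hippocampal region",      "bilateral",  0.15, -0.05, 0.45, 420, 1.00),
    g("TH",   549, "Thalamus",                "bilateral",  0.05,  0.15, 0.18, 380, 1.10),
    g("HY",  1097, "Hypothalamus",            "bilateral",  0.00,  0.65, 0.15, 415, 0.95),
    g("MB",   313, "Midbrain",                "central",    0.35,  0.15, 0.00, 390, 1.05),
    g("CB",   512, "Cerebellum",              "central",    0.72, -0.20, 0.00, 425, 1.10),
    g("P",    771, "Pons",                    "central",    0.60,  0.50, 0.00, 405, 1.00),
    g("MY",   354, "Medulla",                 "central",    0.85,  0.30, 0.00, 405, 0.95)
  )
}

#' Synthetic CCF-like structure ontology
#'
#' Builds the hierarchical ontology of the synthetic phantom anatomy:
#' root, brain, 15 major-division groups (pons and medulla nested under a
#' hindbrain node as in the reference ontology) and two leaf structures
#' per group. Leaf ids are `group_id * 1000 + {1,2}` and are the values
#' stored in the phantom annotation volume. The tree is synthetic: it
#' mimics the Allen schema (it is not the Allen ontology).
#'
#' @return root [ontology_node].
#' @export
phantom_ontology <- function() {
  gr <- phantom_groups()
  leaf <- function(id, acr, nm) list(id = id, acronym = acr, name = nm, children = list())
  group_node <- function(row) {
    list(id = row$id, acronym = row$acronym, name = row$name,
         children = list(leaf(row$id * 1000 + 1, paste0(row$acronym, "1"),
                              paste(row$name, "part 1")),
                         leaf(row$id * 1000 + 2, paste0(row$acronym, "2"),
                              paste(row$name, "part 2"))))
  }
  hb_kids <- lapply(which(gr$acronym %in% c("P", "MY")), function(i) group_node(gr[i, ]))
  others <- lapply(which(!gr$acronym %in% c("P", "MY")), function(i) group_node(gr[i, ]))
  brain <- list(id = 8, acronym = "Brain", name = "Brain",
                children = c(others, list(list(id = 1065, acronym = "HB",
                                               name = "Hindbrain", children = hb_kids))))
  root <- list(id = 997, acronym = "root", name = "root", children = list(brain))
  build_ontology_node(root, NA_integer_)
}

#' Phantom specification
#'
#' Parameters of the synthetic mouse-head generator. Defaults emulate
#' the acquisition geometry of a small-animal PET-CT plus high-field MR
#' study: CT at 0.2 mm isotropic with a bright skull shell, MR at
#' 0.15 mm with soft-tissue contrast and dark bone, PET at 0.4 mm with a
#' sub-millimetre Gaussian point-spread function (default FWHM 0.8 mm)
#' and intensity-proportional Gaussian noise (a post-reconstruction
#' surrogate for count statistics). The brain is an ellipsoid inside the
#' native Allen-style box; internal regions are a mirror-symmetric
#' Voronoi partition seeded at anatomically arranged points.
#'
#' @param spacing working (anatomy) grid spacing in mm, default 0.2.
#' @param brain_semiaxes ellipsoid semi-axes (AP, DV, ML) in mm.
#' @param skull_thickness_mm skull shell thickness, default 0.4.
#' @param ct_spacing,mr_spacing,pet_spacing modality grid spacings (mm).
#' @param pet_psf_fwhm PET point-spread FWHM in mm, default 0.8.
#' @param ct_noise_sd,mr_noise_sd additive Gaussian noise SDs.
#' @param pet_noise_coef PET noise: `sd = coef * sqrt(intensity)`.
#' @param ct_intensities named vector (soft, brain, skull).
#' @param max_translation_mm,max_rotation_deg bounds of the random
#'   subject pose.
#' @param field_orders cosine orders of random subject deformations.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing = 0.2,
                         brain_semiaxes = c(5.6, 3.1, 4.4),
                         skull_thickness_mm = 0.4,
                         ct_spacing = 0.2, mr_spacing = 0.15, pet_spacing = 0.4,
                         pet_psf_fwhm = 0.8,
                         ct_noise_sd = 10, mr_noise_sd = 8,
                         pet_noise_coef = 0.05,
                         ct_intensities = c(soft = 60, brain = 40, skull = 800),
                         max_translation_mm = 0.5, max_rotation_deg = 3,
                         field_orders = c(3L, 3L, 3L)) {
  box <- extended_head_box()
  if (any(2 * brain_semiaxes > ara_native_box()$extent))
    stop("validation error: brain ellipsoid must fit the native reference box")
  structure(list(spacing = spacing, brain_semiaxes = brain_semiaxes,
                 skull_thickness_mm = skull_thickness_mm,
                 ct_spacing = ct_spacing, mr_spacing = mr_spacing,
                 pet_spacing = pet_spacing, pet_psf_fwhm = pet_psf_fwhm,
                 ct_noise_sd = ct_noise_sd, mr_noise_sd = mr_noise_sd,
                 pet_noise_coef = pet_noise_coef,
                 ct_intensities = ct_intensities,
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 field_orders = as.integer(field_orders),
                 box = box),
            class = "phantom_spec")
}

# grid covering the extended box, centred so that the voxel lattice is
# mirror-symmetric about the box centre (exact L/R symmetry)
centered_box_grid <- function(box, spacing) {
  shape <- pmax(1L, as.integer(round(box$extent / spacing)))
  origin <- (box$extent - (shape - 1) * spacing) / 2
  grid3d(shape, rep(spacing, 3L), origin)
}

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Build the reference phantom anatomy
#'
#' Deterministic (geometry only, no noise): brain ellipsoid partitioned
#' into mirror-symmetric Voronoi regions around the structure seeds,
#' wrapped in a skull shell and extra-cerebral soft tissue so that CT has
#' structure outside the brain. Returns the annotation volume (leaf
#' structure ids), a tissue-class volume (0 background, 1 soft tissue,
#' 2 skull, 3 brain), the ontology, and the VOI label atlas built from
#' the default spec set.
#'
#' @param spec a [phantom_spec()].
#' @param erosion_iters erosion passes for the bundled VOI atlas
#'   (default 1).
#' @return object of class `phantom_anatomy`.
#' @export
make_reference_anatomy <- function(spec = phantom_spec(), erosion_iters = 1L) {
  grid <- centered_box_grid(spec$box, spec$spacing)
  xyz <- grid_coordinates(grid)
  ctr <- spec$box$extent / 2
  U <- sweep(sweep(xyz, 2, ctr, "-"), 2, spec$brain_semiaxes, "/")
  r2 <- rowSums(U^2)
  gap <- 0.1; th <- spec$skull_thickness_mm; soft <- 0.8
  r2_skull_in <- rowSums(sweep(sweep(xyz, 2, ctr, "-"), 2, spec$brain_semiaxes + gap, "/")^2)
  r2_skull_out <- rowSums(sweep(sweep(xyz, 2, ctr, "-"), 2, spec$brain_semiaxes + gap + th, "/")^2)
  r2_head <- rowSums(sweep(sweep(xyz, 2, ctr, "-"), 2, spec$brain_semiaxes + gap + th + soft, "/")^2)
  tissue <- integer(nrow(xyz))
  tissue[r2_head <= 1] <- 1L
  tissue[r2_skull_out <= 1 & r2_skull_in > 1] <- 2L
  tissue[r2 <= 1] <- 3L
  # Voronoi partition of the brain: seed order L-block, R-block, C-block
  # keeps tie-breaking mirror-consistent
  gr <- phantom_groups()
  leaves <- do.call(rbind, lapply(seq_len(nrow(gr)), function(i) {
    row <- gr[i, ]
    rbind(data.frame(id = row$id * 1000 + 1, ap = row$ap - 0.08, dv = row$dv,
                     ml = row$ml, lat = row$laterality),
          data.frame(id = row$id * 1000 + 2, ap = row$ap + 0.08, dv = row$dv,
                     ml = row$ml, lat = row$laterality))
  }))
  bil <- leaves$lat == "bilateral"
  seed_norm <- rbind(
    cbind(leaves$ap[bil], leaves$dv[bil], -leaves$ml[bil]),   # L block
    cbind(leaves$ap[bil], leaves$dv[bil], leaves$ml[bil]),    # R block
    cbind(leaves$ap[!bil], leaves$dv[!bil], 0))               # C block
  seed_ids <- c(leaves$id[bil], leaves$id[bil], leaves$id[!bil])
  seeds <- sweep(sweep(seed_norm, 2, spec$brain_semiaxes, "*"), 2, ctr, "+")
  ann <- integer(nrow(xyz))
  inb <- which(tissue == 3L)
  P <- xyz[inb, , drop = FALSE]
  D <- outer(rowSums(P^2), rep(1, nrow(seeds))) - 2 * P %*% t(seeds)
  D <- sweep(D, 2, rowSums(seeds^2), "+")
  ann[inb] <- seed_ids[max.col(-D, ties.method = "first")]
  annotation <- brainvol(array(ann, grid$shape), grid, modality = "annotation")
  atlas <- build_label_atlas(annotation, default_voi_specs(), phantom_ontology(),
                             erosion_iters = erosion_iters)
  structure(list(annotation = annotation,
                 tissue = brainvol(array(tissue, grid$shape), grid, modality = "label"),
                 ontology = phantom_ontology(), atlas = atlas,
                 spec = spec, grid = grid),
            class = "phantom_anatomy")
}

#' @export
print.phantom_anatomy <- function(x, ...) {
  cat(sprintf("<phantom_anatomy> %s grid @ %s mm, %d VOI regions, brain %.0f mm^3\n",
              paste(x$grid$shape, collapse = " x "),
              paste(format(x$grid$spacing), collapse = " x "),
              nrow(x$atlas$regions),
              sum(x$tissue$values == 3L) * prod(x$grid$spacing)))
  invisible(x)
}

lookup_by_id <- function(ids, values, arr) {
  out <- numeric(length(arr))
  idx <- match(arr, ids)
  hit <- !is.na(idx)
  out[hit] <- values[idx[hit]]
  out
}

# per-voxel PET uptake (relative units) for an annotation+tissue pair
uptake_volume <- function(annotation, tissue, multipliers = NULL) {
  gr <- phantom_groups()
  leaf_ids <- c(gr$id * 1000 + 1, gr$id * 1000 + 2)
  leaf_up <- rep(gr$uptake, 2)
  if (!is.null(multipliers)) {
    m <- match(rep(gr$acronym, 2), names(multipliers))
    hit <- !is.na(m)
    leaf_up[hit] <- leaf_up[hit] * (1 + multipliers[m[hit]])
  }
  up <- lookup_by_id(leaf_ids, leaf_up, as.vector(annotation$values))
  tis <- as.vector(tissue$values)
  up[tis == 1L] <- 0.15
  up[tis == 2L] <- 0.05
  brainvol(array(up, annotation$grid$shape), annotation$grid,
           modality = "PET", units = "relative")
}

#' Render CT, MR and PET images of a phantom anatomy
#'
#' CT maps tissue classes to intensities (bright skull), MR gives
#' per-region soft-tissue contrast with dark bone, PET assigns
#' per-region uptake convolved with the isotropic Gaussian PSF. Noise is
#' drawn from R's RNG only when `seed` is given (or `add_noise = TRUE`
#' with the current RNG state); the noiseless render is deterministic
#' and seed-independent.
#'
#' @param anatomy a `phantom_anatomy` (possibly warped; see
#'   [make_subject()]).
#' @param spec the [phantom_spec()].
#' @param seed optional integer; draws noise under a local RNG state.
#' @param add_noise add noise using the current RNG state (used inside
#'   cohort generation).
#' @param uptake_multipliers optional named vector (group acronym ->
#'   fractional change) applied to PET uptake.
#' @param which subset of `c("ct", "mr", "pet")` to render.
#' @param rigid,field optional subject transform (see [make_subject()]):
#'   the continuous intensity scenes are warped through it before
#'   post-processing, giving partial-volume (interpolated) tissue edges
#'   as a scanner would, instead of re-quantized label boundaries.
#' @return list with `ct`, `mr`, `pet` ([brainvol()]s on their modality
#'   grids; unrendered entries NULL).
#' @export
render_modalities <- function(anatomy, spec = anatomy$spec, seed = NULL,
                              add_noise = !is.null(seed),
                              uptake_multipliers = NULL,
                              which = c("ct", "mr", "pet"),
                              rigid = NULL, field = NULL) {
  place <- function(scene, target_grid) {
    if (is.null(rigid) && is.null(field))
      resample(scene, target_grid, "trilinear")
    else
      apply_transform(scene, rigid = rigid, field = field,
                      interpolation = "trilinear", target = target_grid)
  }
  render <- function() {
    ann <- anatomy$annotation; tis <- anatomy$tissue
    out <- list(ct = NULL, mr = NULL, pet = NULL)
    if ("ct" %in% which) {
      ctv <- c(0, spec$ct_intensities["soft"], spec$ct_intensities["skull"],
               spec$ct_intensities["brain"])[tis$values + 1L]
      scene <- brainvol(array(ctv, tis$grid$shape), tis$grid, "CT", units = "HU-like")
      ct <- place(scene, centered_box_grid(spec$box, spec$ct_spacing))
      ct <- gaussian_smooth(ct, spec$ct_spacing)
      if (add_noise && spec$ct_noise_sd > 0)
        ct$values <- ct$values + array(stats::rnorm(length(ct$values), 0, spec$ct_noise_sd),
                                       dim(ct$values))
      out$ct <- ct
    }
    if ("mr" %in% which) {
      gr <- phantom_groups()
      leaf_ids <- c(gr$id * 1000 + 1, gr$id * 1000 + 2)
      leaf_mr <- rep(gr$mr, 2) * c(rep(1, nrow(gr)), rep(0.96, nrow(gr)))
      mrv <- lookup_by_id(leaf_ids, leaf_mr, as.vector(ann$values))
      tv <- as.vector(tis$values)
      mrv[tv == 1L] <- 120
      mrv[tv == 2L] <- 30
      scene <- brainvol(array(mrv, ann$grid$shape), ann$grid, "MR", units = "a.u.")
      mr <- place(scene, centered_box_grid(spec$box, spec$mr_spacing))
      mr <- gaussian_smooth(mr, spec$mr_spacing)
      if (add_noise && spec$mr_noise_sd > 0)
        mr$values <- mr$values + array(stats::rnorm(length(mr$values), 0, spec$mr_noise_sd),
                                       dim(mr$values))
      out$mr <- mr
    }
    if ("pet" %in% which) {
      # uptake scene warped at anatomy resolution, PSF blur, then the
      # coarse PET grid
      up <- uptake_volume(ann, tis, uptake_multipliers)
      up <- place(up, up$grid)
      up <- gaussian_smooth(up, spec$pet_psf_fwhm)
      pet_grid <- centered_box_grid(spec$box, spec$pet_spacing)
      pet <- resample(up, pet_grid, "trilinear")
      if (add_noise && spec$pet_noise_coef > 0)
        pet$values <- pet$values +
          array(stats::rnorm(length(pet$values), 0,
                             spec$pet_noise_coef * sqrt(pmax(pet$values, 0))),
                dim(pet$values))
      out$pet <- pet
    }
    out
  }
  if (!is.null(seed)) with_seed(seed, render()) else render()
}

#' Generate one phantom subject with known ground truth
#'
#' Draws a bounded random rigid pose and a random smooth deformation
#' (low-order cosine coefficients rescaled so the maximum displacement
#' magnitude equals `deformation_amplitude`), warps the reference
#' anatomy through the mapping `x -> rigid(x + d(x))`, and renders the
#' three modalities with noise. The exact generating transform is
#' recorded; a normalization of this subject back to the reference
#' estimates the inverse mapping (see [invert_field()]).
#'
#' @param anatomy reference `phantom_anatomy`.
#' @param spec the [phantom_spec()].
#' @param deformation_amplitude max displacement magnitude in mm
#'   (default 0.5).
#' @param seed integer seed (pose, field and noise).
#' @param uptake_multipliers passed to [render_modalities()].
#' @param add_noise render with noise (default TRUE).
#' @param modalities subset of `c("ct", "mr", "pet")` to render.
#' @return object of class `phantom_subject`: `subject_id`,
#'   `true_rigid`, `true_field`, `ct`, `mr`, `pet`, `label_atlas`
#'   (warped, subject space), `anatomy` (warped).
#' @export
make_subject <- function(anatomy, spec = anatomy$spec, deformation_amplitude = 0.5,
                         seed = 1L, uptake_multipliers = NULL, add_noise = TRUE,
                         modalities = c("ct", "mr", "pet")) {
  stopifnot(deformation_amplitude >= 0)
  with_seed(seed, {
    tmax <- spec$max_translation_mm
    rmax <- spec$max_rotation_deg * pi / 180
    rt <- rigid_transform(stats::runif(3, -tmax, tmax),
                          stats::runif(3, -rmax, rmax),
                          center = spec$box$extent / 2)
    K <- spec$field_orders
    coef <- array(stats::rnorm(prod(K) * 3), c(K, 3L))
    fld <- deformation_field(anatomy$grid, coefficients = coef)
    mx <- max(sqrt(rowSums(matrix(fld$displacement, ncol = 3)^2)))
    coef <- if (deformation_amplitude > 0 && mx > 0) coef * (deformation_amplitude / mx)
            else coef * 0
    fld <- deformation_field(anatomy$grid, coefficients = coef)
    is_identity <- deformation_amplitude == 0 && tmax == 0 && rmax == 0
    if (is_identity) {
      warped <- anatomy
      atlas_w <- anatomy$atlas
    } else {
      warped <- anatomy
      warped$annotation <- apply_transform(anatomy$annotation, rigid = rt, field = fld,
                                           interpolation = "nearest")
      warped$tissue <- apply_transform(anatomy$tissue, rigid = rt, field = fld,
                                       interpolation = "nearest")
      lab <- apply_transform(anatomy$atlas$volume, rigid = rt, field = fld,
                             interpolation = "nearest")
      atlas_w <- anatomy$atlas
      atlas_w$volume <- lab
      counts <- tabulate(lab$values, nbins = max(atlas_w$regions$label, 1L))
      atlas_w$regions$volume_mm3 <- counts[atlas_w$regions$label] * prod(lab$grid$spacing)
    }
    mods <- render_modalities(anatomy, spec, add_noise = add_noise,
                              uptake_multipliers = uptake_multipliers,
                              which = modalities,
                              rigid = if (is_identity) NULL else rt,
                              field = if (is_identity) NULL else fld)
    structure(list(subject_id = sprintf("s%03d", seed %% 1000L),
                   true_rigid = rt, true_field = fld,
                   ct = mods$ct, mr = mods$mr, pet = mods$pet,
                   label_atlas = atlas_w, anatomy = warped),
              class = "phantom_subject")
  })
}

#' @export
print.phantom_subject <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$true_field$displacement, ncol = 3)^2))
  cat(sprintf("<phantom_subject> %s: |d| max %.3f mm, t = (%s) mm\n",
              x$subject_id, max(mag),
              paste(sprintf("%.2f", x$true_rigid$translation), collapse = ", ")))
  invisible(x)
}

#' Generate a paired test-retest phantom cohort
#'
#' Each subject receives one anatomy deformation shared by both
#' conditions; PET noise is independent per condition, and the second
#' condition's uptake is multiplied by `1 + effect` in the specified
#' regions. Injected activities and body weights are drawn from
#' plausible ranges and recorded in the manifest; PET images are stored
#' as activity concentration (kBq/mL) so that SUV conversion is
#' exercised downstream.
#'
#' @param anatomy reference `phantom_anatomy`.
#' @param spec the [phantom_spec()].
#' @param n_subjects number of paired subjects (>= 2).
#' @param effect named numeric vector, VOI group acronym -> fractional
#'   uptake change at the second condition (e.g. `c(STRd = 0.2)`);
#'   empty for a null cohort.
#' @param seed integer seed.
#' @param deformation_amplitude per-subject anatomy deformation (mm).
#' @param conditions labels of the two paired conditions.
#' @param modalities modalities rendered for the per-subject reference
#'   images (condition images are always PET).
#' @return object of class `phantom_cohort`: `manifest` (data.frame:
#'   subject_id, condition, injected_activity_mbq, body_weight_g),
#'   `images` (named list of PET [brainvol()]s, `"<subject>_<cond>"`),
#'   `subjects` (list of [make_subject()] results), `atlas` (reference,
#'   template space), `effect`.
#' @export
make_paired_cohort <- function(anatomy, spec = anatomy$spec, n_subjects = 6L,
                               effect = numeric(0), seed = 1L,
                               deformation_amplitude = 0.5,
                               conditions = c("d0", "d7"),
                               modalities = c("ct", "mr", "pet")) {
  if (n_subjects < 2L) stop("validation error: need at least 2 paired subjects")
  if (length(conditions) != 2L) stop("validation error: paired design needs exactly 2 conditions")
  if (length(effect)) {
    known <- phantom_groups()$acronym
    bad <- setdiff(names(effect), known)
    if (length(bad))
      stop("validation error: effect region(s) not in the atlas: ",
           paste(bad, collapse = ", "))
  }
  rows <- list(); images <- list(); subjects <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("s%03d", i)
    sseed <- seed * 1000L + i
    subj <- make_subject(anatomy, spec, deformation_amplitude, seed = sseed,
                         add_noise = FALSE, modalities = modalities)
    subj$subject_id <- sid
    subjects[[sid]] <- subj
    aw <- with_seed(sseed + 500L,
                    c(stats::rnorm(1, 4.7, 0.3), stats::rnorm(1, 26, 1.5)))
    for (ci in 1:2) {
      mult <- if (ci == 2L) effect else numeric(0)
      warp_args <- if (max(abs(subj$true_field$displacement)) == 0 &&
                       max(abs(subj$true_rigid$translation),
                           abs(subj$true_rigid$rotation)) == 0)
        list(rigid = NULL, field = NULL)
      else list(rigid = subj$true_rigid, field = subj$true_field)
      mods <- render_modalities(anatomy, spec, seed = sseed + ci * 7L,
                                uptake_multipliers = if (length(mult)) mult else NULL,
                                which = "pet", rigid = warp_args$rigid,
                                field = warp_args$field)
      pet <- mods$pet
      pet$values <- pet$values * (aw[1] * 1000 / aw[2])  # uptake -> kBq/mL
      pet$units <- "kBq/mL"
      key <- paste0(sid, "_", conditions[ci])
      images[[key]] <- pet
      rows[[key]] <- data.frame(subject_id = sid, condition = conditions[ci],
                                injected_activity_mbq = aw[1],
                                body_weight_g = aw[2], stringsAsFactors = FALSE)
    }
  }
  structure(list(manifest = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 images = images, subjects = subjects,
                 atlas = anatomy$atlas, effect = effect, conditions = conditions),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects x 2 conditions (%s)%s\n",
              length(x$subjects), paste(x$conditions, collapse = ", "),
              if (length(x$effect))
                paste0("; effect: ", paste(names(x$effect), x$effect,
                                           sep = "=", collapse = ", "))
              else "; null cohort"))
  invisible(x)
}
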