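#' Normalize a subject image to a template
#'
#' The package's standard two-step spatial normalization: a rigid stage
#' followed by the cosine-basis elastic stage, both against the given
#' template. Returns the component transforms and the total deformation
#' field `x' -> rigid(x' + d(x'))` on the template grid, ready to warp
#' any co-registered image of the subject into template space.
#'
#' @param moving subject [brainvol()].
#' @param template template [brainvol()] (same modality for the SSD
#'   elastic stage).
#' @param settings a [registration_settings()]; `rigid_metric` may
#'   override the metric for the rigid stage only (e.g. MI for
#'   cross-modality initialization).
#' @param rigid_metric metric for the rigid stage (default
#'   `settings$metric`).
#' @return list of class `normalization`: `rigid`
#'   ([rigid_transform()]), `elastic` (`elastic_reg`), `field_total`
#'   ([deformation_field()]), `converged`, `final_objective`.
#' @export
normalize_to_template <- function(moving, template,
                                  settings = registration_settings(),
                                  rigid_metric = settings$metric) {
  rset <- settings
  rset$metric <- rigid_metric
  rr <- register_rigid(moving, template, rset)
  er <- register_elastic(moving, template, settings, rigid = rr$transform)
  total <- compose_fields(er$field, rr$transform)
  structure(list(rigid = rr$transform, elastic = er, field_total = total,
                 converged = er$converged,
                 final_objective = utils::tail(er$trace[[length(er$trace)]], 1)),
            class = "normalization")
}

#' @export
print.normalization <- function(x, ...) {
  cat("<normalization>\n  ")
  print(x$rigid)
  cat("  ")
  print(x$elastic)
  invisible(x)
}

#' CT-based normalization of a subject
#'
#' The toolbox's headline pipeline: register the subject CT (rigid +
#' elastic, SSD) to the CT template and return the total deformation,
#' which — because PET and CT share the scanner frame — also warps the
#' subject's PET into template space without any MR.
#'
#' @param ct subject CT [brainvol()] (or a session list with an `$ct`).
#' @param ct_template CT template [brainvol()].
#' @param settings a [registration_settings()].
#' @return a `normalization` (see [normalize_to_template()]).
#' @export
normalize_subject_ct <- function(ct, ct_template, settings = registration_settings()) {
  if (!inherits(ct, "brainvol")) ct <- ct$ct
  if (is.null(ct)) stop("validation error: session has no CT")
  normalize_to_template(ct, ct_template, settings)
}

#' MR-based normalization of a subject
#'
#' Gold-standard counterpart of [normalize_subject_ct()]: registers the
#' subject MR to the MR template. If the MR does not share the PET-CT
#' scanner frame, supply `rigid_mr_to_petct` so the total field lands in
#' that frame.
#'
#' @param mr subject MR [brainvol()] (or a session list with `$mr`).
#' @param mr_template MR template [brainvol()].
#' @param settings a [registration_settings()].
#' @param rigid_mr_to_petct optional [rigid_transform()] mapping MR-frame
#'   points to the PET-CT frame, composed into the total field.
#' @return a `normalization`.
#' @export
normalize_subject_mr <- function(mr, mr_template, settings = registration_settings(),
                                 rigid_mr_to_petct = NULL) {
  if (!inherits(mr, "brainvol")) { rigid_mr_to_petct <- rigid_mr_to_petct %||% mr$rigid_mr_to_petct; mr <- mr$mr }
  if (is.null(mr)) stop("validation error: session has no MR")
  out <- normalize_to_template(mr, mr_template, settings)
  if (!is.null(rigid_mr_to_petct))
    out$field_total <- compose_fields(out$field_total, rigid_mr_to_petct)
  out
}

#' Stage-1 template: mean of MRs elastically normalized to a reference
#'
#' Every subject MR is registered (rigid, then elastic) to the reference
#' volume and warped onto the reference grid; the voxel-wise arithmetic
#' mean is returned. Subjects whose elastic stage is flagged
#' non-converged are excluded with a report.
#'
#' @param mrs list of subject MR [brainvol()]s (>= 2).
#' @param reference reference [brainvol()] (e.g. the Allen-style MR
#'   average embedded in the extended box).
#' @param settings a [registration_settings()].
#' @param rigid_metric rigid-stage metric (MI for true cross-modality
#'   references).
#' @return the mean [brainvol()] on the reference grid.
#' @export
build_stage1_mean <- function(mrs, reference, settings = registration_settings(),
                              rigid_metric = settings$metric) {
  if (length(mrs) == 0L) stop("validation error: empty subject list")
  if (length(mrs) < 2L) stop("validation error: need at least 2 subjects")
  acc <- NULL; used <- 0L
  for (i in seq_along(mrs)) {
    nr <- normalize_to_template(mrs[[i]], reference, settings, rigid_metric)
    if (!isTRUE(nr$converged)) {
      message("subject ", i, " excluded: elastic registration did not converge")
      next
    }
    w <- apply_transform(mrs[[i]], rigid = nr$rigid, field = nr$elastic$field)
    acc <- if (is.null(acc)) w$values else acc + w$values
    used <- used + 1L
  }
  if (used == 0L) stop("registration-failure error: no subject converged")
  brainvol(acc / used, reference$grid, modality = "MR", units = mrs[[1]]$units)
}

#' Final template set: second-pass normalization and CT/PET propagation
#'
#' Each session's MR is normalized (intra-modality SSD) to the stage-1
#' mean; the MR template is the mean of the warped MRs on the output
#' grid (default: the same box resampled to 0.2 mm). The deformation
#' found on the MR — composed with the session's MR-to-scanner rigid
#' link when present — is then applied to the co-registered CT and PET,
#' whose warped images are averaged into CT and PET templates on the
#' same grid (PET after global-mean scaling over its foreground).
#'
#' @param sessions list of session lists: `subject_id`, `ct`, `pet`,
#'   `mr`, optional `rigid_mr_to_petct` ([rigid_transform()]).
#' @param stage1_mean the [build_stage1_mean()] output.
#' @param settings a [registration_settings()].
#' @param output_spacing_mm spacing of the final template grid (default
#'   0.2).
#' @return object of class `template_set`: `mr_template`, `ct_template`,
#'   `pet_template`, `per_subject_deformations` (named list of total
#'   [deformation_field()]s), `qc` (data.frame), `stage = "final"`.
#' @export
build_final_templates <- function(sessions, stage1_mean,
                                  settings = registration_settings(),
                                  output_spacing_mm = 0.2) {
  if (length(sessions) == 0L) stop("validation error: empty session list")
  out_grid <- level_grid(stage1_mean$grid, output_spacing_mm)
  ref <- resample(stage1_mean, out_grid, "trilinear")
  accs <- list(mr = NULL, ct = NULL, pet = NULL)
  fields <- list(); qc <- list()
  for (s in sessions) {
    if (is.null(s$mr)) stop("validation error: session ", s$subject_id, " has no MR")
    nr <- normalize_to_template(s$mr, ref, settings)
    total <- nr$field_total
    if (!is.null(s$rigid_mr_to_petct))
      total <- compose_fields(total, s$rigid_mr_to_petct)
    fields[[s$subject_id]] <- total
    wm <- apply_transform(s$mr, rigid = nr$rigid, field = nr$elastic$field,
                          target = out_grid)
    accs$mr <- if (is.null(accs$mr)) wm$values else accs$mr + wm$values
    if (!is.null(s$ct)) {
      wc <- apply_transform(s$ct, field = total, target = out_grid)
      accs$ct <- if (is.null(accs$ct)) wc$values else accs$ct + wc$values
    }
    if (!is.null(s$pet)) {
      wp <- apply_transform(s$pet, field = total, target = out_grid)
      fg <- wp$values > 0.05 * max(wp$values)
      if (any(fg)) wp$values <- wp$values / mean(wp$values[fg])
      accs$pet <- if (is.null(accs$pet)) wp$values else accs$pet + wp$values
    }
    qc[[s$subject_id]] <- data.frame(
      subject_id = s$subject_id, final_objective = nr$final_objective,
      mean_disp_mm = mean(sqrt(rowSums(matrix(total$displacement, ncol = 3)^2))),
      max_disp_mm = max(sqrt(rowSums(matrix(total$displacement, ncol = 3)^2))),
      converged = nr$converged, stringsAsFactors = FALSE)
  }
  n <- length(sessions)
  mk <- function(a, modality, units = "") {
    if (is.null(a)) NULL else brainvol(a / n, out_grid, modality, units)
  }
  structure(list(mr_template = mk(accs$mr, "MR"),
                 ct_template = mk(accs$ct, "CT"),
                 pet_template = mk(accs$pet, "PET", "global-mean ratio"),
                 per_subject_deformations = fields,
                 qc = do.call(rbind, qc), stage = "final"),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  g <- x$mr_template$grid
  cat(sprintf("<template_set> stage %s, grid %s @ %s mm, %d subject deformation(s)\n",
              x$stage, paste(g$shape, collapse = " x "),
              paste(format(g$spacing), collapse = " x "),
              length(x$per_subject_deformations)))
  invisible(x)
}

#' Compare CT-based and MR-based normalizations of a cohort
#'
#' For every subject with both CT and MR, runs the two normalization
#' pipelines against their respective templates, measures the pointwise
#' displacement between the two total deformation fields, and pools the
#' per-subject maps into the regional RMS displacement table (global
#' value attached as an attribute).
#'
#' @param subjects list of subjects; each needs `$ct` and `$mr`
#'   [brainvol()]s (e.g. [make_subject()] output). Subjects lacking MR
#'   are excluded with a note.
#' @param ct_template,mr_template template [brainvol()]s.
#' @param atlas a `label_atlas` on the comparison grid.
#' @param settings a [registration_settings()].
#' @param comparison_grid grid for the displacement maps (default the
#'   atlas grid).
#' @return the [regional_displacement()] table; per-subject maps in
#'   `attr(, "maps")`, pooled global RMS in `attr(, "global_mm")`.
#' @export
validate_pipelines <- function(subjects, ct_template, mr_template, atlas,
                               settings = registration_settings(),
                               comparison_grid = atlas$volume$grid) {
  maps <- list()
  for (s in subjects) {
    if (is.null(s$mr)) { message("subject without MR excluded from comparison"); next }
    nct <- normalize_subject_ct(s$ct, ct_template, settings)
    nmr <- normalize_subject_mr(s$mr, mr_template, settings)
    fa <- resample_field(nct$field_total, comparison_grid)
    fb <- resample_field(nmr$field_total, comparison_grid)
    maps[[length(maps) + 1L]] <- pointwise_displacement(fa, fb)
  }
  if (length(maps) == 0L) stop("validation error: no subject has both CT and MR")
  out <- regional_displacement(maps, atlas)
  attr(out, "maps") <- maps
  out
}

# resample a deformation field's displacement onto another grid
# (component-wise trilinear; coefficients re-synthesized when present)
resample_field <- function(field, grid) {
  if (grids_equal(field$grid, grid)) return(field)
  if (!is.null(field$coefficients))
    return(deformation_field(grid, coefficients = field$coefficients,
                             domain = field$domain))
  xyz <- grid_coordinates(grid)
  deformation_field(grid, array(sample_field(field, xyz), c(grid$shape, 3L)))
}
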