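# registration tests run on the coarse phantom wherever sub-voxel accuracy
# is not the property under test; pose- and field-recovery accuracy checks
# use the full-resolution CT

test_that("self-registration returns the identity pose", {
  tmpl <- fine_templates()
  rr <- register_rigid(tmpl$ct, tmpl$ct, registration_settings(mask = "fixed"))
  expect_lt(max(abs(rr$transform$translation)), 1e-3)
  expect_lt(max(abs(rr$transform$rotation)), 1e-3)
})

test_that("a known pure shift is recovered within 0.1 mm", {
  tmpl <- fine_templates()
  s <- c(0.4, -0.6, 0.2)
  moved <- apply_transform(tmpl$ct, rigid = rigid_transform(s))
  rr <- register_rigid(moved, tmpl$ct, registration_settings(mask = "fixed"))
  # moved(x) = ct(x + s), so the estimated map must be the inverse shift
  expect_lt(max(abs(rr$transform$translation - (-s))), 0.1)
  expect_lt(max(abs(rr$transform$rotation)), 0.01)
})

test_that("random known poses are recovered with sub-quarter-voxel median error", {
  anat <- fine_anatomy()
  tmpl <- fine_templates()
  settings <- registration_settings(mask = "fixed")
  pts <- grid_coordinates(anat$grid)[as.vector(anat$tissue$values == 3L), , drop = FALSE]
  pts <- pts[seq(1, nrow(pts), by = 37), , drop = FALSE]
  errs <- vapply(1:5, function(i) {
    s <- make_subject(anat, deformation_amplitude = 0, seed = 400 + i,
                      modalities = "ct")
    rr <- register_rigid(s$ct, tmpl$ct, settings)
    truth <- ccfpet:::rigid_inverse(s$true_rigid)
    mean(sqrt(rowSums((ccfpet:::apply_rigid_mat(rr$transform, pts) -
                       ccfpet:::apply_rigid_mat(truth, pts))^2)))
  }, numeric(1))
  expect_lt(median(errs), 0.25 * 0.2)   # 0.25 voxel at the 0.2 mm CT grid
})

test_that("MI registers MR to CT of the same subject across modalities", {
  tmpl <- fine_templates()
  rt <- rigid_transform(c(0.3, -0.4, 0.25), c(0.02, -0.015, 0.01),
                        center = extended_head_box()$extent / 2)
  mr_moved <- apply_transform(tmpl$mr, rigid = rt)
  rr <- register_rigid(mr_moved, tmpl$ct,
                       registration_settings(metric = "MI", mask = "fixed",
                                             pyramid_mm = c(0.8, 0.4, 0.25)))
  inv <- ccfpet:::rigid_inverse(rt)
  expect_lt(max(abs(rr$transform$translation - inv$translation)), 0.2)
  Rerr <- t(ccfpet:::rotation_matrix(rr$transform$rotation)) %*% ccfpet:::rt_matrix(inv)
  angle <- acos(pmin(1, (sum(diag(Rerr)) - 1) / 2)) * 180 / pi
  expect_lt(angle, 0.5)
})

test_that("elastic self-registration stays near zero displacement", {
  tmpl <- fine_templates()
  er <- register_elastic(tmpl$ct, tmpl$ct, registration_settings(mask = "fixed"))
  mag <- sqrt(rowSums(matrix(er$field$displacement, ncol = 3)^2))
  expect_lt(mean(mag), 0.05)
})

test_that("an in-span synthetic field is recovered to sub-voxel accuracy", {
  anat <- fine_anatomy()
  tmpl <- fine_templates()
  set.seed(41)
  coef <- array(rnorm(27 * 3), c(3, 3, 3, 3))
  fld <- deformation_field(anat$grid, coefficients = coef)
  mx <- max(sqrt(rowSums(matrix(fld$displacement, ncol = 3)^2)))
  fld <- deformation_field(anat$grid, coefficients = coef * (0.5 / mx))
  fixed <- apply_transform(tmpl$mr, field = ccfpet:::resample_field(fld, tmpl$mr$grid))
  er <- register_elastic(tmpl$mr, fixed, registration_settings(mask = "fixed"))
  head_mask <- brainvol(array(as.integer(anat$tissue$values > 0), anat$grid$shape),
                        anat$grid, modality = "mask")
  rms <- field_rms_in_mask(er$field, fld, head_mask)
  expect_lt(rms, 0.2)
})

test_that("the accepted-step objective is monotone and regularization shrinks the field", {
  anat <- coarse_anatomy()
  tmpl <- memo("coarse_templates", render_modalities(coarse_anatomy()))
  # zero pose: with no rigid offset to absorb, a large penalty must drive
  # the whole field (including the unpenalized bulk-shift terms) to zero
  s <- make_subject(anat, coarse_spec(max_translation_mm = 0, max_rotation_deg = 0),
                    deformation_amplitude = 0.4, seed = 55, add_noise = FALSE,
                    modalities = "ct")
  # the bending weights scale as |omega|^4 ~ (pi k / L)^4, so on a ~16 mm
  # box "large" lambda means >> 1/w(k=1) ~ 1e2
  norms <- c(1e-5, 1e-2, 1e3)
  mags <- numeric(0)
  for (lam in norms) {
    er <- register_elastic(s$ct, tmpl$ct,
                           registration_settings(regularization_weight = lam,
                                                 mask = "fixed"))
    for (tr in er$trace) expect_true(all(diff(tr) <= 1e-12))
    fin <- er$trace[[length(er$trace)]]
    expect_lte(fin[length(fin)], fin[1])
    # magnitude of the penalized (non-constant) part of the field; the
    # zero-frequency bulk shift carries no bending energy
    d <- matrix(er$field$displacement, ncol = 3)
    d <- sweep(d, 2, colMeans(d), "-")
    mags <- c(mags, mean(sqrt(rowSums(d^2))))
  }
  expect_true(all(diff(mags) < 0))     # fluctuation decreases with lambda
  expect_lt(mags[3], 0.02)             # lambda -> large flattens the field
})

test_that("registration is deterministic and fails loudly on bad input", {
  anat <- coarse_anatomy()
  tmpl <- memo("coarse_templates", render_modalities(coarse_anatomy()))
  s <- make_subject(anat, deformation_amplitude = 0.3, seed = 77, modalities = "ct")
  e1 <- register_elastic(s$ct, tmpl$ct, registration_settings(mask = "fixed"))
  e2 <- register_elastic(s$ct, tmpl$ct, registration_settings(mask = "fixed"))
  expect_identical(e1$coefficients, e2$coefficients)
  r1 <- register_rigid(s$ct, tmpl$ct, registration_settings(mask = "fixed"))
  r2 <- register_rigid(s$ct, tmpl$ct, registration_settings(mask = "fixed"))
  expect_identical(r1$transform, r2$transform)
  # volumes that do not overlap in world space
  far <- s$ct
  far$grid$origin <- far$grid$origin + 100
  expect_error(register_rigid(far, tmpl$ct, registration_settings()), "overlap")
  # all-zero image has no signal to register
  zero <- brainvol(array(0, tmpl$ct$grid$shape), tmpl$ct$grid, "CT")
  expect_error(register_rigid(zero, tmpl$ct, registration_settings()), "no signal")
  expect_error(register_elastic(zero, tmpl$ct, registration_settings()), "no signal")
  # MI is not permitted for the elastic stage
  expect_error(register_elastic(s$ct, tmpl$ct, registration_settings(metric = "MI")),
               "SSD")
})
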