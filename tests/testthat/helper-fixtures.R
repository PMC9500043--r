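# Shared fixtures, memoized so expensive objects are built once per run.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# coarse phantom (0.4 mm everywhere): fast, used wherever sub-voxel
# accuracy is not the point
coarse_spec <- function(...) {
  phantom_spec(spacing = 0.4, ct_spacing = 0.4, mr_spacing = 0.4,
               pet_spacing = 0.4, ...)
}

coarse_anatomy <- function() memo("coarse_anatomy", {
  make_reference_anatomy(coarse_spec())
})

# full-resolution phantom (0.2 mm working grid) and its noiseless renders
fine_anatomy <- function() memo("fine_anatomy", {
  make_reference_anatomy(phantom_spec())
})

fine_templates <- function() memo("fine_templates", {
  render_modalities(fine_anatomy())
})

# study-conditions cohort: n = 6 subjects, 0.5 mm deformation amplitude,
# normalized with both the CT-based and the MR-based pipeline
pipeline_fixture <- function() memo("pipeline_fixture", {
  anat <- fine_anatomy()
  tmpl <- fine_templates()
  settings <- registration_settings(mask = "fixed")
  subjects <- lapply(1:6, function(i)
    make_subject(anat, deformation_amplitude = 0.5, seed = 7000L + i))
  norms_ct <- lapply(subjects, function(s)
    normalize_subject_ct(s$ct, tmpl$ct, settings))
  norms_mr <- lapply(subjects, function(s)
    normalize_subject_mr(s$mr, tmpl$mr, settings))
  list(anatomy = anat, templates = tmpl, settings = settings,
       subjects = subjects, norms_ct = norms_ct, norms_mr = norms_mr)
})

random_brainvol <- function(shape = c(8, 9, 10), spacing = 0.5, seed = 1,
                            modality = "MR") {
  set.seed(seed)
  brainvol(array(rnorm(prod(shape)), shape), grid3d(shape, spacing),
           modality = modality)
}

# hand-built two-region label atlas on an arbitrary grid
toy_atlas <- function(shape = c(6, 6, 6), spacing = 0.5) {
  lab <- array(0L, shape)
  lab[2:3, 2:3, 2:3] <- 1L
  lab[4:5, 4:5, 4:5] <- 2L
  regions <- data.frame(label = 1:2, name = c("Region A", "Region B"),
                        abbreviation = c("RA", "RB"), side = c("L", "R"),
                        volume_mm3 = c(8, 8) * spacing^3,
                        stringsAsFactors = FALSE)
  structure(list(volume = brainvol(lab, grid3d(shape, spacing), modality = "label"),
                 regions = regions, dropped = NULL),
            class = "label_atlas")
}

# ontology JSON of a 3-node toy tree written to a temp file
toy_ontology_json <- function(dup_id = FALSE) {
  path <- tempfile(fileext = ".json")
  leaf2_id <- if (dup_id) 2 else 3
  writeLines(sprintf('
    {"msg": [{"id": 1, "acronym": "root", "name": "root", "children": [
      {"id": 2, "acronym": "A", "name": "region A", "children": []},
      {"id": %d, "acronym": "B", "name": "region B", "children": []}
    ]}]}', leaf2_id), path)
  path
}

field_rms_in_mask <- function(field_a, field_b, mask_vol) {
  fb <- if (!isTRUE(all.equal(field_b$grid, field_a$grid)))
    ccfpet:::resample_field(field_b, field_a$grid) else field_b
  d <- matrix(field_a$displacement, ncol = 3) - matrix(fb$displacement, ncol = 3)
  m <- as.vector(resample(mask_vol, field_a$grid, "nearest")$values) > 0
  sqrt(mean(rowSums(d^2)[m]))
}
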