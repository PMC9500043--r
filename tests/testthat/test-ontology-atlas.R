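test_that("ontology parsing validates structure and finds descendants", {
  root <- load_ontology(toy_ontology_json())
  expect_s3_class(root, "ontology_node")
  expect_equal(length(root$children), 2L)
  expect_error(load_ontology(toy_ontology_json(dup_id = TRUE)), "duplicate")
  expect_equal(collect_substructures(root, 2), 2L)            # leaf -> itself
  expect_equal(collect_substructures(root, 1), c(1L, 2L, 3L)) # root -> all
  expect_error(collect_substructures(root, 99), "not found")
})

test_that("descendant union over disjoint subtrees matches brute force", {
  tree <- phantom_ontology()
  # brute-force oracle: flatten all (id, parent) pairs, chase parents
  flatten <- function(node, acc = NULL) {
    acc <- rbind(acc, data.frame(id = node$id, parent = ifelse(is.na(node$parent_id),
                                                               -1L, node$parent_id)))
    for (ch in node$children) acc <- flatten(ch, acc)
    acc
  }
  tab <- flatten(tree)
  oracle_desc <- function(root_id) {
    out <- root_id
    repeat {
      more <- tab$id[tab$parent %in% out & !tab$id %in% out]
      if (!length(more)) break
      out <- c(out, more)
    }
    sort(out)
  }
  ids_hb <- acronyms_to_ids(tree, c("P", "MY"))
  got <- collect_substructures(tree, ids_hb)
  want <- sort(unique(c(oracle_desc(ids_hb[1]), oracle_desc(ids_hb[2]))))
  expect_identical(got, as.integer(want))
  expect_equal(length(got), 6L)    # two groups x (group + 2 leaves)
  # disjoint subtrees: union size is the sum of subtree sizes
  ids2 <- acronyms_to_ids(tree, c("TH", "CB"))
  expect_equal(length(collect_substructures(tree, ids2)),
               length(oracle_desc(ids2[1])) + length(oracle_desc(ids2[2])))
})

test_that("6-connected erosion matches direct enumeration on a cube", {
  m <- array(0L, c(9, 9, 9))
  m[3:7, 3:7, 3:7] <- 1L
  mask <- brainvol(m, grid3d(c(9, 9, 9), 0.1), modality = "mask")
  er <- erode_mask(mask)
  # oracle: voxels whose 6 face neighbours are all inside the cube
  expect_equal(sum(er$values), 27L)
  expect_true(all(er$values[4:6, 4:6, 4:6] == 1L))
  single <- brainvol(array(c(rep(0L, 13), 1L, rep(0L, 13)), c(3, 3, 3)),
                     grid3d(c(3, 3, 3), 1), modality = "mask")
  expect_equal(sum(erode_mask(single)$values), 0L)
})

test_that("erosion is anti-extensive and decreasing in iterations", {
  set.seed(21)
  for (rep in 1:3) {
    m <- array(as.integer(runif(12^3) > 0.35), c(12, 12, 12))
    mask <- brainvol(m, grid3d(c(12, 12, 12), 0.2), modality = "mask")
    e1 <- erode_mask(mask, 1)
    e2 <- erode_mask(mask, 2)
    expect_true(all(e1$values <= mask$values))
    expect_true(all(e2$values <= e1$values))
    e26 <- erode_mask(mask, 1, connectivity = 26)
    expect_true(all(e26$values <= e1$values))  # bigger element erodes more
  }
})

test_that("hemisphere masks split the ML axis symmetrically", {
  anat <- coarse_anatomy()
  tree <- phantom_ontology()
  ids <- collect_substructures(tree, acronyms_to_ids(tree, "TH"))
  L <- build_voi_mask(anat$annotation, ids, "L")
  R <- build_voi_mask(anat$annotation, ids, "R")
  W <- build_voi_mask(anat$annotation, ids, "whole")
  expect_equal(sum(L$values), sum(R$values))     # mirror-symmetric phantom
  expect_equal(sum(L$values) + sum(R$values), sum(W$values))  # even ML dim
  expect_true(all((L$values & R$values) == 0))
  expect_error(build_voi_mask(anat$annotation, integer(0)), "empty")
  expect_message(build_voi_mask(anat$annotation, 999999L), "empty")
})

test_that("label atlas construction assigns disjoint labels and filters small VOIs", {
  anat <- coarse_anatomy()
  tree <- phantom_ontology()
  specs <- data.frame(
    name = c("Thalamus", "Striatum dorsal", "Cerebellum"),
    abbreviation = c("TH", "STRd", "CB"),
    laterality = c("bilateral", "bilateral", "central"),
    acronyms = c("TH", "STRd", "CB"), stringsAsFactors = FALSE)
  atlas <- build_label_atlas(anat$annotation, specs, tree, erosion_iters = 0)
  expect_equal(nrow(atlas$regions), 5L)   # 2 bilateral x 2 + 1 central
  expect_identical(atlas$regions$label, 1:5)
  expect_true(all(atlas$volume$values %in% 0:5))
  # heavy erosion pushes regions under the volume threshold -> rejected
  atlas2 <- build_label_atlas(anat$annotation, specs, tree, erosion_iters = 3)
  expect_true(!is.null(atlas2$dropped) && nrow(atlas2$dropped) >= 1)
  expect_lt(nrow(atlas2$regions), 5L)
  expect_identical(atlas2$regions$label, seq_len(nrow(atlas2$regions)))
  # deterministic re-run
  atlas3 <- build_label_atlas(anat$annotation, specs, tree, erosion_iters = 0)
  expect_identical(atlas3$volume$values, atlas$volume$values)
  expect_identical(atlas3$regions, atlas$regions)
})

test_that("the default VOI spec yields 27 regions with a voxel-wise partition", {
  anat <- fine_anatomy()
  atlas <- anat$atlas
  expect_equal(nrow(atlas$regions), 27L)
  expect_equal(sum(default_voi_specs()$laterality == "bilateral"), 12L)
  expect_equal(sum(default_voi_specs()$laterality == "central"), 3L)
  # every region clears the PET-resolution volume threshold
  expect_true(all(atlas$regions$volume_mm3 >= 1.5))
  # partition: one label per voxel, total labelled volume <= brain volume
  brain_mm3 <- sum(anat$tissue$values == 3L) * prod(anat$grid$spacing)
  expect_lte(sum(atlas$regions$volume_mm3), brain_mm3)
  # bilateral L/R equality on the mirror-symmetric anatomy
  bil <- atlas$regions[atlas$regions$side %in% c("L", "R"), ]
  vols <- tapply(bil$volume_mm3, list(bil$abbreviation, bil$side), sum)
  expect_equal(unname(vols[, "L"]), unname(vols[, "R"]), tolerance = 0)
})

test_that("region volumes are voxel count times voxel volume", {
  m <- array(0L, c(9, 9, 9))
  m[3:7, 3:7, 3:7] <- 1L
  mask <- erode_mask(brainvol(m, grid3d(c(9, 9, 9), 0.1), modality = "mask"))
  atlas <- structure(list(
    volume = brainvol(mask$values, mask$grid, modality = "label"),
    regions = data.frame(label = 1L, name = "cube", abbreviation = "CU",
                         side = "C", volume_mm3 = NA_real_)), class = "label_atlas")
  rv <- region_volumes(atlas)
  expect_equal(rv$volume_mm3, 27 * 0.001, tolerance = 1e-12)
  expect_false(0 %in% rv$label)
})
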