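test_that("SUV conversion follows the definition and its invariances", {
  g <- grid3d(c(4, 4, 4), 1)
  pet <- brainvol(array(200, c(4, 4, 4)), g, "PET", units = "kBq/mL")
  suv <- to_suv(pet, injected_activity_mbq = 5, body_weight_g = 25)
  expect_equal(as.vector(suv$values), rep(1, 64), tolerance = 1e-12)
  expect_equal(to_suv(brainvol(array(0, c(4, 4, 4)), g, "PET"), 5, 25)$values,
               array(0, c(4, 4, 4)))
  # doubling activity and weight together leaves SUV unchanged
  expect_equal(to_suv(pet, 10, 50)$values, suv$values, tolerance = 1e-12)
  expect_error(to_suv(pet, 0, 25), "positive")
  expect_error(to_suv(pet, 5, -1), "positive")
})

test_that("global-mean scaling normalizes exactly and cancels calibration", {
  set.seed(71)
  g <- grid3d(c(6, 6, 6), 0.5)
  vol <- brainvol(array(rexp(216) + 0.1, c(6, 6, 6)), g, "PET")
  mask <- brainvol(array(as.integer(runif(216) > 0.4), c(6, 6, 6)), g,
                   modality = "mask")
  sc <- scale_to_global_mean(vol, mask)
  expect_equal(mean(sc$values[mask$values > 0]), 1, tolerance = 1e-12)
  # positive multiplicative calibration cancels
  vol2 <- vol; vol2$values <- vol$values * 17.3
  expect_equal(scale_to_global_mean(vol2, mask)$values, sc$values,
               tolerance = 1e-12)
  # SUV then scaling equals raw scaling (constants cancel)
  suv <- to_suv(vol, 4.7, 26)
  expect_equal(scale_to_global_mean(suv, mask)$values, sc$values,
               tolerance = 1e-12)
  empty <- brainvol(array(0L, c(6, 6, 6)), g, modality = "mask")
  expect_error(scale_to_global_mean(vol, empty), "empty")
  neg <- vol; neg$values <- -vol$values
  expect_error(scale_to_global_mean(neg, mask), "global mean")
})

test_that("regional means match hand computation and ignore voxel order", {
  atlas <- toy_atlas()
  g <- atlas$volume$grid
  vals <- array(0, g$shape)
  vals[atlas$volume$values == 1L] <- 2.5
  vals[atlas$volume$values == 2L] <- seq_len(8)
  vol <- brainvol(vals, g, "PET")
  rm <- extract_regional_means(vol, atlas)
  expect_equal(rm$mean[1], 2.5, tolerance = 1e-12)
  expect_equal(rm$mean[2], mean(seq_len(8)), tolerance = 1e-12)
})

test_that("the paired t test matches its closed form and reference implementation", {
  d <- c(1, -1, 0, 2, 1, 3)
  x1 <- rep(0, 6); x2 <- d
  res <- paired_t_test(x1, x2)
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(6)), tolerance = 1e-15)
  expect_equal(res$df, 5)
  # antisymmetry
  swap <- paired_t_test(x2, x1)
  expect_equal(swap$t, -res$t, tolerance = 1e-15)
  expect_equal(swap$p, res$p, tolerance = 1e-15)
  # degenerate branches
  same <- paired_t_test(1:5, 1:5)
  expect_equal(same$t, 0); expect_equal(same$p, 1); expect_true(same$degenerate)
  shift <- paired_t_test(1:5, 1:5 + 2)
  expect_equal(shift$p, 0); expect_true(shift$degenerate)
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "unequal")
  # high-precision agreement with t.test over random cases
  set.seed(72)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    a <- rnorm(n); b <- rnorm(n, sd = runif(1, 0.5, 2))
    ours <- paired_t_test(a, b)
    ref <- t.test(b, a, paired = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH matches p.adjust and the exhaustive step-up definition", {
  bh_oracle <- function(p, q) {
    m <- length(p); ps <- sort(p)
    k <- 0
    for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
    p <= if (k > 0) ps[k] else -1
  }
  set.seed(73)
  for (i in 1:50) {
    m <- sample(2:10, 1)
    p <- runif(m)^sample(1:3, 1)
    res <- fdr_bh(p, q = 0.05)
    expect_equal(res$adjusted, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_identical(res$reject, bh_oracle(p, 0.05))
    # monotone in raw-p order
    o <- order(p)
    expect_true(all(diff(res$adjusted[o]) >= -1e-15))
  }
  allsame <- fdr_bh(rep(0.025, 7), q = 0.05)
  expect_equal(allsame$n_rejected, 7L)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_bh(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("cohort analysis validates the paired design and detects effects", {
  anat <- coarse_anatomy()
  spec0 <- coarse_spec(max_translation_mm = 0, max_rotation_deg = 0)
  coh <- make_paired_cohort(anat, spec0, n_subjects = 4,
                            effect = c(STRd = 0.2), seed = 91,
                            deformation_amplitude = 0, modalities = "pet")
  res <- analyze_cohort(coh)
  expect_s3_class(res, "uptake_stats")
  expect_equal(nrow(res), nrow(anat$atlas$regions))
  strd <- res[res$abbreviation == "STRd", ]
  expect_true(all(strd$significant_fdr))
  expect_true(all(strd$mean_d7 / strd$mean_d0 > 1.1))
  expect_true(all(res$p_adjusted >= res$p - 1e-15))
  expect_identical(res$significant_unadjusted, res$p < 0.05)
  # results invariant to a positive calibration of every PET image
  coh2 <- coh
  coh2$images <- lapply(coh$images, function(v) { v$values <- v$values * 3.7; v })
  res2 <- analyze_cohort(coh2)
  expect_equal(res2$t, res$t, tolerance = 1e-9)
  # three conditions are refused
  bad <- coh
  bad$manifest$condition[1] <- "d14"
  expect_error(analyze_cohort(bad), "2 conditions")
  # an unpaired subject is excluded with a report
  unp <- coh
  unp$manifest <- unp$manifest[-1, ]
  expect_message(res3 <- analyze_cohort(unp), "unpaired")
  expect_equal(attr(res3, "n_subjects"), 3L)
})
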