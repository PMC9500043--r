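#' Convert a PET activity image to standardized uptake values
#'
#' `SUV = concentration / (injected activity / body weight)`, with the
#' concentration in kBq/mL, activity in MBq (decay-corrected to scan
#' start) and weight in g, assuming 1 mL of tissue weighs 1 g. The
#' result is dimensionless.
#'
#' @param pet a [brainvol()] with PET concentration in kBq/mL.
#' @param injected_activity_mbq injected activity in MBq (> 0).
#' @param body_weight_g body weight in g (> 0).
#' @return a [brainvol()] in SUV units.
#' @export
to_suv <- function(pet, injected_activity_mbq, body_weight_g) {
  if (!is.finite(injected_activity_mbq) || injected_activity_mbq <= 0)
    stop("validation error: injected activity must be positive")
  if (!is.finite(body_weight_g) || body_weight_g <= 0)
    stop("validation error: body weight must be positive")
  out <- pet
  out$values <- pet$values / (injected_activity_mbq * 1000 / body_weight_g)
  out$units <- "SUV"
  out
}

#' Scale a volume by its global mean within a brain mask
#'
#' Divides the image by its mean over the mask (the "cerebral global
#' mean"), so the masked mean of the output is exactly 1 and any
#' positive multiplicative calibration of the input cancels.
#'
#' @param vol a [brainvol()].
#' @param brain_mask a [brainvol()] mask on the same grid.
#' @return the scaled [brainvol()] (units "global-mean ratio").
#' @export
scale_to_global_mean <- function(vol, brain_mask) {
  if (!all(brain_mask$grid$shape == vol$grid$shape))
    stop("validation error: mask and volume grids differ")
  sel <- brain_mask$values > 0
  if (!any(sel)) stop("validation error: empty brain mask")
  gm <- mean(vol$values[sel])
  if (!is.finite(gm) || gm <= 0)
    stop("validation error: non-positive global mean")
  out <- vol
  out$values <- vol$values / gm
  out$units <- "global-mean ratio"
  out
}

#' Mean uptake per atlas region
#'
#' @param vol a [brainvol()]; resampled (trilinear) onto the atlas grid
#'   if the grids differ.
#' @param atlas a `label_atlas`.
#' @return data.frame: label, name, abbreviation, side, mean (regions
#'   empty on this grid get NA with a warning).
#' @export
extract_regional_means <- function(vol, atlas) {
  if (!grids_equal(vol$grid, atlas$volume$grid))
    vol <- resample(vol, atlas$volume$grid, "trilinear")
  lab <- as.vector(atlas$volume$values)
  v <- as.vector(vol$values)
  out <- atlas$regions[, c("label", "name", "abbreviation", "side")]
  sums <- tapply(v, factor(lab, levels = out$label), sum)
  cnts <- tapply(rep(1, length(lab)), factor(lab, levels = out$label), sum)
  out$mean <- as.numeric(sums / cnts)
  if (any(is.na(out$mean)))
    warning("region(s) empty on this grid: ",
            paste(out$abbreviation[is.na(out$mean)], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Paired-sample Student's t test
#'
#' Closed form on the paired differences: `t = mean(d) / (sd(d)/sqrt(n))`
#' with `d = x2 - x1` and `n - 1` degrees of freedom; two-tailed p by
#' default. Degenerate variance (all differences equal) yields `t = 0,
#' p = 1` when the common difference is zero and `p = 0` with a flag
#' otherwise.
#'
#' @param x1,x2 numeric vectors of equal length (>= 2), matched by
#'   subject.
#' @param tails `"two"` (default) or `"one"` (alternative: `x2 > x1`).
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
paired_t_test <- function(x1, x2, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(x1) != length(x2)) stop("validation error: unequal lengths")
  n <- length(x1)
  if (n < 2L) stop("validation error: need at least 2 pairs")
  d <- x2 - x1
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = n - 1, degenerate = TRUE))
    return(list(t = sign(m) * Inf, p = 0, df = n - 1, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  p <- if (tails == "two") 2 * stats::pt(-abs(t), df = n - 1)
       else stats::pt(t, df = n - 1, lower.tail = FALSE)
  list(t = t, p = p, df = n - 1, degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: sort p ascending, find the largest `i` with
#' `p(i) <= i q / m`, reject hypotheses `1..i`. Adjusted p-values use
#' the standard monotone formula `adj(i) = min_{j >= i} p(j) m / j`
#' (clipped at 1), reported in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` (numeric), `reject` (logical), both in
#'   input order, and `n_rejected`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("validation error: p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- seq_len(m) * q / m
  below <- which(ps <= thresh)
  k <- if (length(below)) max(below) else 0L
  rej_sorted <- seq_len(m) <= k
  adj_sorted <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  adjusted <- numeric(m); adjusted[o] <- adj_sorted
  reject <- logical(m); reject[o] <- rej_sorted
  list(adjusted = adjusted, reject = reject, n_rejected = k)
}

#' Regional paired statistics for a test-retest PET cohort
#'
#' The full quantification stage: per subject and condition the PET
#' image is (optionally) warped into template space through the CT-based
#' pipeline, converted to SUV, scaled by the cerebral global mean (mean
#' over the union of all atlas labels), and averaged per VOI; per region
#' the two conditions are compared with a paired t test, and
#' Benjamini-Hochberg FDR is applied across the region set.
#'
#' @param cohort a `phantom_cohort`, or a list with `manifest`
#'   (subject_id, condition, injected_activity_mbq, body_weight_g) and
#'   `images` (named `"<subject>_<condition>"` -> PET [brainvol()]).
#' @param atlas a `label_atlas` in template space (defaults to the
#'   cohort's own).
#' @param normalization optional list(ct_template =, settings =): when
#'   given, each subject's CT (from `cohort$subjects`) is normalized to
#'   the CT template and the resulting total deformation warps that
#'   subject's PET images into template space; when NULL the images are
#'   taken to be in template space already.
#' @param q FDR level (default 0.05).
#' @param tails passed to [paired_t_test()] (default two-tailed).
#' @return data.frame of class `uptake_stats`: region, side, mean_1,
#'   mean_2, t, p, p_adjusted, significant_unadjusted, significant_fdr.
#' @export
analyze_cohort <- function(cohort, atlas = cohort$atlas, normalization = NULL,
                           q = 0.05, tails = "two") {
  man <- cohort$manifest
  conds <- unique(man$condition)
  if (length(conds) != 2L)
    stop("validation error: paired design requires exactly 2 conditions, got ",
         length(conds))
  tab <- table(man$subject_id)
  unpaired <- names(tab)[tab != 2L]
  if (length(unpaired)) {
    message("excluding unpaired subject(s): ", paste(unpaired, collapse = ", "))
    man <- man[!man$subject_id %in% unpaired, ]
    if (length(unique(man$subject_id)) < 2L)
      stop("validation error: fewer than 2 paired subjects remain")
  }
  bmask <- atlas_brain_mask(atlas)
  subjects <- unique(man$subject_id)
  fields <- list()
  if (!is.null(normalization)) {
    for (sid in subjects) {
      reg <- normalize_subject_ct(cohort$subjects[[sid]]$ct,
                                  normalization$ct_template,
                                  settings = normalization$settings)
      fields[[sid]] <- reg$field_total
    }
  }
  means <- array(NA_real_, c(nrow(atlas$regions), length(subjects), 2L))
  for (si in seq_along(subjects)) {
    sid <- subjects[si]
    for (ci in 1:2) {
      row <- man[man$subject_id == sid & man$condition == conds[ci], ]
      img <- cohort$images[[paste0(sid, "_", conds[ci])]]
      if (is.null(img)) stop("missing image for ", sid, " ", conds[ci])
      if (!is.null(normalization))
        img <- apply_transform(img, field = fields[[sid]],
                               target = atlas$volume$grid)
      else if (!grids_equal(img$grid, atlas$volume$grid))
        img <- resample(img, atlas$volume$grid, "trilinear")
      suv <- to_suv(img, row$injected_activity_mbq, row$body_weight_g)
      scl <- scale_to_global_mean(suv, bmask)
      means[, si, ci] <- extract_regional_means(scl, atlas)$mean
    }
  }
  res <- atlas$regions[, c("name", "abbreviation", "side")]
  res$mean_1 <- rowMeans(means[, , 1, drop = FALSE])
  res$mean_2 <- rowMeans(means[, , 2, drop = FALSE])
  tp <- lapply(seq_len(nrow(res)), function(r)
    paired_t_test(means[r, , 1], means[r, , 2], tails = tails))
  res$t <- vapply(tp, `[[`, numeric(1), "t")
  res$p <- vapply(tp, `[[`, numeric(1), "p")
  bh <- fdr_bh(res$p, q = q)
  res$p_adjusted <- bh$adjusted
  res$significant_unadjusted <- res$p < 0.05
  res$significant_fdr <- bh$reject
  names(res)[names(res) == "mean_1"] <- paste0("mean_", conds[1])
  names(res)[names(res) == "mean_2"] <- paste0("mean_", conds[2])
  rownames(res) <- NULL
  class(res) <- c("uptake_stats", "data.frame")
  attr(res, "conditions") <- conds
  attr(res, "n_subjects") <- length(subjects)
  res
}

#' @export
print.uptake_stats <- function(x, digits = 4, ...) {
  cat(sprintf("Regional paired uptake statistics (%d regions, n = %d pairs, %s vs %s)\n",
              nrow(x), attr(x, "n_subjects"),
              attr(x, "conditions")[2], attr(x, "conditions")[1]))
  df <- as.data.frame(x)
  df$t <- round(df$t, 2)
  df$p <- signif(df$p, 3)
  df$p_adjusted <- signif(df$p_adjusted, 3)
  print(df, digits = digits, row.names = FALSE)
  cat(sprintf("%d region(s) p < 0.05 unadjusted; %d significant after FDR\n",
              sum(x$significant_unadjusted), sum(x$significant_fdr)))
  invisible(x)
}
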