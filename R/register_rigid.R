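#' Rigid registration
#'
#' Estimates the rigid-body transform mapping fixed-space points onto the
#' moving image so that `moving(phi(x))` matches `fixed(x)`, by
#' minimizing either the mean squared intensity difference (SSD,
#' intra-modality) or negative mutual information (MI, inter-modality)
#' over a coarse-to-fine resolution pyramid. Optimization is
#' deterministic: fixed identity initialization, quasi-Newton (SSD) or
#' Nelder-Mead simplex (MI) with fixed control parameters, no random
#' restarts.
#'
#' @param moving,fixed [brainvol()] volumes overlapping in world space.
#' @param settings a [registration_settings()].
#' @param init optional initial [rigid_transform()].
#' @return object of class `rigid_reg`: list with `transform`
#'   ([rigid_transform()]), `metric`, `value` (final objective),
#'   `converged`, and `trace` (per-level objective values).
#' @export
register_rigid <- function(moving, fixed, settings = registration_settings(),
                           init = NULL) {
  check_overlap(moving, fixed)
  center <- fixed$grid$origin + (fixed$grid$shape - 1) * fixed$grid$spacing / 2
  theta <- if (is.null(init)) rep(0, 6)
           else c(init$translation, init$rotation)
  scale_f <- robust_max(fixed$values)
  scale_m <- robust_max(moving$values)
  trace <- numeric(0)
  for (lev in seq_along(settings$pyramid_mm)) {
    sp <- settings$pyramid_mm[lev]
    fw <- settings$smoothing_fwhm_mm[lev]
    fx <- pyramid_level(fixed, sp, fw)
    mv <- if (fw > 0) gaussian_smooth(moving, fw) else moving
    pts <- grid_coordinates(fx$grid)
    fvals <- as.vector(fx$values) / scale_f
    keep <- rep(TRUE, length(fvals))
    if (settings$mask == "fixed") {
      mk <- array(fvals > 0.01, fx$grid$shape)
      mk <- mk | shift_mask(mk, 1, 1) | shift_mask(mk, 1, -1) |
            shift_mask(mk, 2, 1) | shift_mask(mk, 2, -1) |
            shift_mask(mk, 3, 1) | shift_mask(mk, 3, -1)
      keep <- as.vector(mk)
    }
    P <- pts[keep, , drop = FALSE]
    fv <- fvals[keep]
    objective <- if (settings$metric == "SSD") {
      function(th) {
        rt <- rigid_transform(th[1:3], th[4:6], center)
        m <- sample_volume(mv, apply_rigid(rt, P)) / scale_m
        if (settings$intensity_scaling) {
          s <- sum(fv * m) / max(sum(m * m), 1e-12)
          mean((s * m - fv)^2)
        } else mean((m - fv)^2)
      }
    } else {
      function(th) {
        rt <- rigid_transform(th[1:3], th[4:6], center)
        m <- sample_volume(mv, apply_rigid(rt, P)) / scale_m
        -mutual_information(fv, m)
      }
    }
    ctrl <- list(parscale = c(1, 1, 1, 0.05, 0.05, 0.05),
                 reltol = 1e-12, maxit = 500L)
    if (settings$metric == "SSD") {
      fit <- stats::optim(theta, objective, method = "BFGS",
                          control = list(parscale = ctrl$parscale,
                                         reltol = 1e-9,
                                         maxit = settings$max_iterations * 3L))
      if (lev == length(settings$pyramid_mm)) {
        # restart at the finest level: BFGS rebuilds its curvature estimate,
        # which polishes the sub-voxel optimum
        fit <- stats::optim(fit$par, objective, method = "BFGS",
                            control = list(parscale = ctrl$parscale / 5,
                                           reltol = 1e-10,
                                           maxit = settings$max_iterations * 2L))
      }
    } else {
      fit <- stats::optim(theta, objective, method = "Nelder-Mead", control = ctrl)
      fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                          control = list(parscale = ctrl$parscale / 10,
                                         reltol = 1e-12, maxit = 500L))
    }
    theta <- fit$par
    trace <- c(trace, fit$value)
  }
  structure(list(transform = rigid_transform(theta[1:3], theta[4:6], center),
                 metric = settings$metric, value = trace[length(trace)],
                 converged = TRUE, trace = trace),
            class = "rigid_reg")
}

#' @export
print.rigid_reg <- function(x, ...) {
  cat(sprintf("<rigid_reg> metric %s, objective %.4g\n", x$metric, x$value))
  print(x$transform)
  invisible(x)
}

#' @export
coef.rigid_reg <- function(object, ...) {
  c(tx = object$transform$translation[1], ty = object$transform$translation[2],
    tz = object$transform$translation[3], rx = object$transform$rotation[1],
    ry = object$transform$rotation[2], rz = object$transform$rotation[3])
}

check_overlap <- function(moving, fixed) {
  lo_m <- moving$grid$origin - moving$grid$spacing / 2
  hi_m <- lo_m + grid_extent(moving$grid)
  lo_f <- fixed$grid$origin - fixed$grid$spacing / 2
  hi_f <- lo_f + grid_extent(fixed$grid)
  if (any(hi_m <= lo_f) || any(hi_f <= lo_m))
    stop("registration-failure error: volumes do not overlap in world space ",
         sprintf("(moving box [%s]-[%s], fixed box [%s]-[%s])",
                 paste(sprintf("%.1f", lo_m), collapse = ","),
                 paste(sprintf("%.1f", hi_m), collapse = ","),
                 paste(sprintf("%.1f", lo_f), collapse = ","),
                 paste(sprintf("%.1f", hi_f), collapse = ",")))
  invisible(TRUE)
}

# Mutual information from a 32 x 32 joint histogram with Parzen (Gaussian)
# smoothing of the counts.
mutual_information <- function(a, b, nbins = 32L, parzen_sigma = 0.7) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) <= 0 || diff(rb) <= 0) return(0)
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * nbins) + 1L, 1L), nbins)
  ib <- pmin(pmax(floor((b - rb[1]) / diff(rb) * nbins) + 1L, 1L), nbins)
  H <- matrix(tabulate((ib - 1L) * nbins + ia, nbins * nbins), nbins, nbins)
  K <- outer(seq_len(nbins), seq_len(nbins),
             function(i, j) exp(-(i - j)^2 / (2 * parzen_sigma^2)))
  K <- K / rowSums(K)
  H <- K %*% H %*% t(K)
  P <- H / sum(H)
  px <- rowSums(P); py <- colSums(P)
  nz <- P > 0
  sum(P[nz] * log(P[nz] / (px[row(P)[nz]] * py[col(P)[nz]])))
}
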