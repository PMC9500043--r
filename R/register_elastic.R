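#' Elastic (cosine-basis) registration
#'
#' Estimates a low-frequency deformation field mapping fixed-space points
#' into the moving image: displacement components are expanded in a
#' separable 3-D cosine (DCT-II) basis over the fixed image's bounding
#' box and fitted by Gauss-Newton with Levenberg damping, minimizing
#'
#'   `mean( (s * moving(rigid(x + d(x))) - fixed(x))^2 ) + lambda * B(d)`
#'
#' where `B` is the bending energy of `d` expressed analytically in
#' coefficient space and `s` an optional global intensity scale
#' (closed-form update each iteration). The data term is intra-modality
#' SSD; images are normalized internally to unit scale so `lambda` is
#' resolution- and calibration-independent. Coarse-to-fine over the
#' settings pyramid; fully deterministic (no randomness anywhere in the
#' optimizer), and the accepted-step objective is non-increasing within
#' each level.
#'
#' @param moving [brainvol()], subject-space image sampled from.
#' @param fixed [brainvol()], template-space image matched to.
#' @param settings a [registration_settings()] (`metric` must be SSD).
#' @param rigid optional pre-alignment [rigid_transform()] applied after
#'   the elastic displacement (the returned field excludes it; compose
#'   with [compose_fields()] for the total mapping).
#' @param init_coefficients optional warm-start coefficient array
#'   `c(K1, K2, K3, 3)`.
#' @return object of class `elastic_reg`: `field`
#'   ([deformation_field()] on the fixed grid, with coefficients),
#'   `coefficients`, `intensity_scale`, `converged`, `trace` (list of
#'   per-level accepted objective values).
#' @export
register_elastic <- function(moving, fixed, settings = registration_settings(),
                             rigid = NULL, init_coefficients = NULL) {
  if (settings$metric != "SSD")
    stop("validation error: the elastic stage is intra-modality SSD only")
  check_overlap(moving, fixed)
  K <- settings$basis_orders
  domain <- list(edge = fixed$grid$origin - fixed$grid$spacing / 2,
                 extent = grid_extent(fixed$grid))
  coef <- init_coefficients %||% array(0, c(K, 3L))
  if (!all(dim(coef) == c(K, 3L))) stop("init_coefficients has wrong dim")
  # bending-energy weight per basis function: (|omega|^2)^2, omega_a = pi k_a / L_a
  kk <- expand.grid(k1 = seq_len(K[1]) - 1, k2 = seq_len(K[2]) - 1, k3 = seq_len(K[3]) - 1)
  om2 <- (pi * kk$k1 / domain$extent[1])^2 + (pi * kk$k2 / domain$extent[2])^2 +
         (pi * kk$k3 / domain$extent[3])^2
  w <- om2^2
  wfull <- rep(w, 3L)
  scale_f <- robust_max(fixed$values)
  scale_m <- robust_max(moving$values)
  lam <- settings$regularization_weight
  R <- if (!is.null(rigid)) rt_matrix(rigid) else NULL
  trace <- vector("list", length(settings$pyramid_mm))
  converged <- TRUE
  s <- 1
  for (lev in seq_along(settings$pyramid_mm)) {
    sp <- settings$pyramid_mm[lev]
    fw <- settings$smoothing_fwhm_mm[lev]
    fx <- pyramid_level(fixed, sp, fw)
    mv <- if (fw > 0) gaussian_smooth(moving, fw) else moving
    grads <- gradient_arrays(mv$values, mv$grid$spacing)
    n <- fx$grid$shape
    fvals <- as.vector(fx$values) / scale_f
    keep <- rep(TRUE, length(fvals))
    if (settings$mask == "fixed") {
      mk <- array(fvals > 0.01, n)
      mk <- mk | shift_mask(mk, 1, 1) | shift_mask(mk, 1, -1) |
            shift_mask(mk, 2, 1) | shift_mask(mk, 2, -1) |
            shift_mask(mk, 3, 1) | shift_mask(mk, 3, -1)
      keep <- as.vector(mk)
    }
    pts <- grid_coordinates(fx$grid)[keep, , drop = FALSE]
    fv <- fvals[keep]
    # per-point axis basis values
    u <- grid_normalized_positions(fx$grid, domain)
    ii <- rep(seq_len(n[1]), times = n[2] * n[3])[keep]
    jj <- rep(rep(seq_len(n[2]), each = n[1]), times = n[3])[keep]
    ll <- rep(seq_len(n[3]), each = n[1] * n[2])[keep]
    P1 <- dct_basis(u[[1]], K[1])[ii, , drop = FALSE]
    P2 <- dct_basis(u[[2]], K[2])[jj, , drop = FALSE]
    P3 <- dct_basis(u[[3]], K[3])[ll, , drop = FALSE]
    N <- nrow(pts)
    Kp <- prod(K)
    B <- matrix(0, N, Kp)
    q <- 1L
    for (k3 in seq_len(K[3])) for (k2 in seq_len(K[2])) for (k1 in seq_len(K[1])) {
      B[, q] <- P1[, k1] * P2[, k2] * P3[, k3]
      q <- q + 1L
    }
    eval_state <- function(cf) {
      disp <- cbind(B %*% cf[, 1], B %*% cf[, 2], B %*% cf[, 3])
      y <- pts + disp
      z <- if (!is.null(R)) apply_rigid_mat(rigid, y) else y
      zi <- world_to_voxel(mv$grid, z)
      m <- interp3(mv$values, zi, "trilinear", 0) / scale_m
      sc <- if (settings$intensity_scaling) sum(fv * m) / max(sum(m * m), 1e-12) else 1
      r <- sc * m - fv
      cvec <- as.vector(cf)
      list(obj = mean(r^2) + lam * sum(wfull * cvec^2),
           r = r, m = m, sc = sc, zi = zi, z = z)
    }
    cf <- matrix(coef, Kp, 3L)
    st <- eval_state(cf)
    lev_trace <- st$obj
    mu <- NULL
    for (it in seq_len(settings$max_iterations)) {
      g1 <- interp3(grads[[1]], st$zi, "trilinear", 0) / scale_m
      g2 <- interp3(grads[[2]], st$zi, "trilinear", 0) / scale_m
      g3 <- interp3(grads[[3]], st$zi, "trilinear", 0) / scale_m
      G <- cbind(g1, g2, g3)
      if (!is.null(R)) G <- G %*% R
      J <- cbind(B * (st$sc * G[, 1]), B * (st$sc * G[, 2]), B * (st$sc * G[, 3]))
      H <- crossprod(J) / N
      gvec <- as.vector(crossprod(J, st$r)) / N + lam * wfull * as.vector(cf)
      diag(H) <- diag(H) + lam * wfull
      if (is.null(mu)) mu <- 1e-3 * mean(diag(H))
      accepted <- FALSE
      rel <- 0
      for (try in 1:8) {
        Hd <- H; diag(Hd) <- diag(Hd) + mu
        delta <- tryCatch(solve(Hd, gvec), error = function(e) NULL)
        if (!is.null(delta)) {
          cf_new <- cf - matrix(delta, Kp, 3L)
          st_new <- eval_state(cf_new)
          if (st_new$obj < st$obj) {
            rel <- (st$obj - st_new$obj) / max(st$obj, 1e-12)
            cf <- cf_new; st <- st_new
            lev_trace <- c(lev_trace, st$obj)
            mu <- mu / 3
            accepted <- TRUE
            break
          }
        }
        mu <- mu * 10
      }
      if (!accepted || rel < settings$convergence_tol) break
    }
    coef <- array(cf, c(K, 3L))
    s <- st$sc
    trace[[lev]] <- lev_trace
  }
  field <- deformation_field(fixed$grid, coefficients = coef, domain = domain)
  structure(list(field = field, coefficients = coef, intensity_scale = s,
                 converged = converged, trace = trace, settings = settings),
            class = "elastic_reg")
}

#' @export
print.elastic_reg <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$field$displacement, ncol = 3L)^2))
  fin <- x$trace[[length(x$trace)]]
  cat(sprintf("<elastic_reg> basis %s, objective %.4g -> %.4g, |d| mean %.3f max %.3f mm\n",
              paste(dim(x$coefficients)[1:3], collapse = "x"),
              fin[1], fin[length(fin)], mean(mag), max(mag)))
  invisible(x)
}

#' @export
coef.elastic_reg <- function(object, ...) object$coefficients
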