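# Distorted pinhole endoscope-camera model and planar (Zhang) calibration.
#
# Pixel convention: origin at the top-left corner, pixel centers at integer
# coordinates, 0-based; the camera looks along +z.  Distortion model: radial
# k1, k2 (k3 optional, default off) plus tangential p1, p2 applied in
# normalized image coordinates.

#' Camera intrinsics of a distorted pinhole camera
#'
#' @param fx,fy Focal lengths (px), > 0.
#' @param cx,cy Principal point (px), inside the image.
#' @param width,height Image size (px).
#' @param skew Skew term (px), default 0.
#' @param dist Distortion coefficients `c(k1, k2, p1, p2, k3)` (dimensionless);
#'   shorter vectors are zero-padded.
#' @return Object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height, skew = 0,
                              dist = c(0, 0, 0, 0, 0)) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("camera_intrinsics: principal point outside the image")
  dist <- c(as.numeric(dist), rep(0, 5))[1:5]
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, skew = skew,
                 dist = dist, width = width, height = height),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics %dx%d px  fx=%.2f fy=%.2f cx=%.2f cy=%.2f skew=%.3g\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy, x$skew))
  cat(sprintf("  dist k1=%.4g k2=%.4g p1=%.4g p2=%.4g k3=%.4g\n",
              x$dist[1], x$dist[2], x$dist[3], x$dist[4], x$dist[5]))
  invisible(x)
}

#' Rescale intrinsics to a different sensor resolution
#'
#' Multiplies all pixel-valued parameters by `s`; distortion coefficients act
#' on normalized coordinates and are unchanged.
#' @param K A `camera_intrinsics`.
#' @param s Scale factor.
#' @export
scale_intrinsics <- function(K, s) {
  camera_intrinsics(K$fx * s, K$fy * s, K$cx * s, K$cy * s,
                    K$width * s, K$height * s, skew = K$skew * s, dist = K$dist)
}

# Apply the distortion polynomial to normalized coordinates (n x 2).
distort_normalized <- function(K, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  k1 <- K$dist[1]; k2 <- K$dist[2]; p1 <- K$dist[3]; p2 <- K$dist[4]; k3 <- K$dist[5]
  r2 <- x^2 + y^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * radial + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  cbind(xd, yd)
}

#' Project camera-frame points to pixel coordinates
#'
#' Perspective division, lens distortion in normalized coordinates, then the
#' intrinsic matrix.
#'
#' @param K A `camera_intrinsics`.
#' @param p_cam 3-vector or n x 3 matrix of camera-frame points (mm), z > 0.
#' @return n x 2 matrix of pixel coordinates `(u, v)` (a 2-vector for a
#'   single point).
#' @export
project_points <- function(K, p_cam) {
  vec <- is.null(dim(p_cam))
  p <- if (vec) matrix(as.numeric(p_cam), 1, 3) else as.matrix(p_cam)
  if (any(p[, 3] <= 0)) stop("project_points: point(s) behind the camera (z <= 0)")
  xy <- distort_normalized(K, p[, 1:2, drop = FALSE] / p[, 3])
  u <- K$fx * xy[, 1] + K$skew * xy[, 2] + K$cx
  v <- K$fy * xy[, 2] + K$cy
  out <- cbind(u = u, v = v)
  if (vec) c(out) else out
}

#' Undistort pixel coordinates to normalized image coordinates
#'
#' Inverts the distortion polynomial by damped Newton iteration on the 2D
#' system; the returned `(x, y)` satisfy
#' `project(K, (x, y, 1)) == pixel` to about 1e-6 px.
#'
#' @param K A `camera_intrinsics`.
#' @param pixels 2-vector or n x 2 matrix of pixel coordinates.
#' @param max_iter Maximum Newton iterations before a non-convergence error.
#' @return n x 2 matrix of normalized undistorted coordinates.
#' @export
undistort_points <- function(K, pixels, max_iter = 50L) {
  vec <- is.null(dim(pixels))
  px <- if (vec) matrix(as.numeric(pixels), 1, 2) else as.matrix(pixels)
  yd <- (px[, 2] - K$cy) / K$fy
  xd <- (px[, 1] - K$cx - K$skew * yd) / K$fx
  tol <- arnav_tolerances()$undistort
  k1 <- K$dist[1]; k2 <- K$dist[2]; p1 <- K$dist[3]; p2 <- K$dist[4]; k3 <- K$dist[5]
  x <- xd; y <- yd
  for (it in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
    fx_ <- x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x^2) - xd
    fy_ <- y * radial + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y - yd
    if (max(abs(c(fx_, fy_))) < tol) break
    dr_dx <- 2 * x * (k1 + 2 * k2 * r2 + 3 * k3 * r2^2)
    dr_dy <- 2 * y * (k1 + 2 * k2 * r2 + 3 * k3 * r2^2)
    j11 <- radial + x * dr_dx + 2 * p1 * y + 6 * p2 * x
    j12 <- x * dr_dy + 2 * p1 * x + 2 * p2 * y
    j21 <- y * dr_dx + 2 * p2 * y + 2 * p1 * x
    j22 <- radial + y * dr_dy + 6 * p1 * y + 2 * p2 * x
    det <- j11 * j22 - j12 * j21
    if (any(abs(det) < 1e-14))
      stop("undistort_points: singular distortion Jacobian")
    x <- x - ( j22 * fx_ - j12 * fy_) / det
    y <- y - (-j21 * fx_ + j11 * fy_) / det
  }
  r2 <- x^2 + y^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  res <- c(x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x^2) - xd,
           y * radial + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y - yd)
  if (max(abs(res)) > 1e-8)
    stop("undistort_points: Newton iteration did not converge")
  out <- cbind(x = x, y = y)
  if (vec) c(out) else out
}

#' A planar calibration view
#'
#' One observation of a planar target: target-plane points (z = 0 in the
#' target frame) and their detected pixel positions, matched by index.
#'
#' @param object_points n x 2 or n x 3 matrix of target coordinates (mm);
#'   any third column must be zero.
#' @param image_points n x 2 matrix of pixel coordinates.
#' @export
planar_view <- function(object_points, image_points) {
  op <- as.matrix(object_points)
  if (ncol(op) == 3L) {
    if (any(abs(op[, 3]) > 1e-9)) stop("planar_view: object points must lie on z = 0")
    op <- op[, 1:2, drop = FALSE]
  }
  ip <- as.matrix(image_points)
  stopifnot(ncol(op) == 2L, ncol(ip) == 2L)
  if (nrow(op) != nrow(ip)) stop("planar_view: point count mismatch")
  if (nrow(op) < 4L) stop("planar_view: need at least 4 points")
  structure(list(object_points = op, image_points = ip), class = "planar_view")
}

# Normalized DLT homography: maps (X, Y, 1) -> image homogeneous coords.
homography_dlt <- function(object_xy, image_uv) {
  n <- nrow(object_xy)
  norm_pts <- function(p) {
    c0 <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, c0)^2))
    s <- sqrt(2) / mean(d)
    T_ <- matrix(c(s, 0, -s * c0[1], 0, s, -s * c0[2], 0, 0, 1), 3, 3, byrow = TRUE)
    list(T = T_, p = cbind(p, 1) %*% t(T_))
  }
  no <- norm_pts(object_xy); ni <- norm_pts(image_uv)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- no$p[i, ]; u <- ni$p[i, 1]; v <- ni$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * i, ]     <- c(0, 0, 0, -X, v * X)
  }
  h <- svd(A, nu = 0)$v[, 9]
  H <- solve(ni$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% no$T
  H / H[3, 3]
}

# Closed-form intrinsics from homographies (Zhang's B-matrix constraints).
zhang_closed_form <- function(Hs, estimate_skew = FALSE) {
  vij <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H)
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))))
  if (!estimate_skew) V <- rbind(V, c(0, 1, 0, 0, 0, 0) * max(abs(V)))
  sv <- svd(V, nu = 0)
  b <- sv$v[, 6]
  # conditioning check: near-fronto-parallel view sets make the system rank
  # deficient (two smallest singular values comparable)
  d <- sv$d
  if (d[5] / d[1] < 1e-10)
    stop("calibrate_intrinsics: degenerate view set (views too close to fronto-parallel)")
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  den <- B11 * B22 - B12^2
  v0 <- (B12 * B13 - B11 * B23) / den
  lambda <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  if (lambda / B11 < 0) { b <- -b
    B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
    den <- B11 * B22 - B12^2
    v0 <- (B12 * B13 - B11 * B23) / den
    lambda <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  }
  if (lambda / B11 < 0 || lambda * B11 / den < 0)
    stop("calibrate_intrinsics: closed-form step failed (degenerate geometry)")
  alpha <- sqrt(lambda / B11)
  beta  <- sqrt(lambda * B11 / den)
  gamma <- if (estimate_skew) -B12 * alpha^2 * beta / lambda else 0
  u0 <- gamma * v0 / beta - B13 * alpha^2 / lambda
  list(fx = alpha, fy = beta, cx = u0, cy = v0, skew = gamma)
}

# Extrinsics of one planar view from its homography and K.
extrinsics_from_homography <- function(H, K) {
  Km <- matrix(c(K$fx, K$skew, K$cx, 0, K$fy, K$cy, 0, 0, 1), 3, 3, byrow = TRUE)
  A <- solve(Km, H)
  lam <- 1 / sqrt(sum(A[, 1]^2))
  if (lam * A[3, 3] < 0) lam <- -lam   # target in front of the camera
  r1 <- lam * A[, 1]; r2 <- lam * A[, 2]
  R <- nearest_rotation(cbind(r1, r2, crossprod_vec(r1, r2)))
  t <- lam * A[, 3]
  rigid_transform(R, t, source = "target", target = "C")
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Planar intrinsic calibration (Zhang's method)
#'
#' Estimates the intrinsics of a distorted pinhole camera from views of a
#' planar target: per-view normalized-DLT homographies, closed-form intrinsics
#' from the homography constraints, distortion initialized at zero, then joint
#' Levenberg-Marquardt refinement of intrinsics, distortion and per-view poses
#' minimizing total squared reprojection error.
#'
#' @param views List of [planar_view()]s, at least 3 with distinct
#'   orientations.
#' @param width,height Image size stored in the result (px).
#' @param estimate_k3 Include the 6th-order radial term (default `FALSE`; a
#'   long-coupler endoscope is dominated by the low-order radial terms).
#' @param estimate_skew Estimate the skew term (default `FALSE`).
#' @param estimate_tangential Estimate p1, p2 (default `TRUE`).
#' @param max_iter Maximum LM iterations.
#' @return List with `intrinsics` (a [camera_intrinsics()]), `view_poses`
#'   (list of `rigid_transform`s, target frame -> camera), `rms_px` (RMS
#'   reprojection error per residual component, so i.i.d. pixel noise of SD
#'   sigma gives an expected RMS of about sigma), `per_view_rms_px`, and
#'   `initial_rms_px`.
#' @export
calibrate_intrinsics <- function(views, width, height,
                                 estimate_k3 = FALSE, estimate_skew = FALSE,
                                 estimate_tangential = TRUE, max_iter = 200L) {
  if (length(views) < 3L)
    stop("calibrate_intrinsics: at least 3 views are required")
  stopifnot(all(vapply(views, inherits, TRUE, "planar_view")))
  Hs <- lapply(views, function(v) homography_dlt(v$object_points, v$image_points))
  cf <- zhang_closed_form(Hs, estimate_skew = estimate_skew)
  K0 <- camera_intrinsics(cf$fx, cf$fy,
                          min(max(cf$cx, 0), width - 1e-6),
                          min(max(cf$cy, 0), height - 1e-6),
                          width, height, skew = cf$skew)
  poses0 <- lapply(Hs, extrinsics_from_homography, K = K0)

  n_int <- 4L + as.integer(estimate_skew) + 2L +
    2L * as.integer(estimate_tangential) + as.integer(estimate_k3)
  pack_K <- function(K) {
    p <- c(K$fx, K$fy, K$cx, K$cy)
    if (estimate_skew) p <- c(p, K$skew)
    p <- c(p, K$dist[1], K$dist[2])
    if (estimate_tangential) p <- c(p, K$dist[3], K$dist[4])
    if (estimate_k3) p <- c(p, K$dist[5])
    p
  }
  unpack_K <- function(p) {
    i <- 4L
    skew <- 0
    if (estimate_skew) { i <- i + 1L; skew <- p[i] }
    k1 <- p[i + 1L]; k2 <- p[i + 2L]; i <- i + 2L
    p1 <- 0; p2 <- 0; k3 <- 0
    if (estimate_tangential) { p1 <- p[i + 1L]; p2 <- p[i + 2L]; i <- i + 2L }
    if (estimate_k3) { k3 <- p[i + 1L] }
    list(fx = p[1], fy = p[2], cx = p[3], cy = p[4], skew = skew,
         dist = c(k1, k2, p1, p2, k3), width = width, height = height)
  }
  par0 <- c(pack_K(K0),
            unlist(lapply(poses0, function(T_)
              c(rotation_to_axis_angle(T_$rotation), T_$translation))))

  n_pts <- vapply(views, function(v) nrow(v$object_points), 1L)
  n_res <- 2L * sum(n_pts)
  res_off <- c(0L, cumsum(2L * n_pts))    # residual block offsets per view
  view_resid <- function(Kl, pose_par, v) {
    R <- axis_angle_to_rotation(pose_par[1:3])
    pc <- sweep(cbind(v$object_points, 0) %*% t(R), 2, pose_par[4:6], "+")
    if (any(pc[, 3] <= 1e-9)) return(rep(1e6, 2L * nrow(v$object_points)))
    as.numeric(project_points(Kl, pc) - v$image_points)
  }
  residual_fn <- function(par) {
    Kl <- structure(unpack_K(par), class = "camera_intrinsics")
    unlist(lapply(seq_along(views), function(i)
      view_resid(Kl, par[n_int + 6L * (i - 1L) + 1:6], views[[i]])))
  }
  # forward-difference Jacobian exploiting the block structure: intrinsic
  # parameters touch every residual, each view's pose only its own block
  jac_fn <- function(par) {
    J <- matrix(0, n_res, length(par))
    r0 <- residual_fn(par)
    for (j in seq_len(n_int)) {
      h <- 1e-7 * (1 + abs(par[j]))
      pj <- par; pj[j] <- pj[j] + h
      J[, j] <- (residual_fn(pj) - r0) / h
    }
    Kl <- structure(unpack_K(par), class = "camera_intrinsics")
    for (i in seq_along(views)) {
      cols <- n_int + 6L * (i - 1L) + 1:6
      rows <- (res_off[i] + 1L):res_off[i + 1L]
      rv0 <- r0[rows]
      for (k in 1:6) {
        h <- 1e-7 * (1 + abs(par[cols[k]]))
        pp <- par[cols]; pp[k] <- pp[k] + h
        J[rows, cols[k]] <- (view_resid(Kl, pp, views[[i]]) - rv0) / h
      }
    }
    J
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = residual_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-13, ptol = 1e-13, gtol = 0, maxfev = 100000))
  par <- fit$par
  Kf <- structure(unpack_K(par), class = "camera_intrinsics")
  Kf <- camera_intrinsics(Kf$fx, Kf$fy, Kf$cx, Kf$cy, width, height,
                          skew = Kf$skew, dist = Kf$dist)
  poses <- list(); per_view <- numeric(length(views))
  off <- n_int; n_tot <- 0L; ss <- 0
  for (i in seq_along(views)) {
    rv <- par[off + 1:3]; tv <- par[off + 4:6]; off <- off + 6L
    poses[[i]] <- rigid_transform(axis_angle_to_rotation(rv), tv,
                                  source = "target", target = "C")
    v <- views[[i]]
    pc <- sweep(cbind(v$object_points, 0) %*% t(poses[[i]]$rotation), 2, tv, "+")
    d2 <- rowSums((project_points(Kf, pc) - v$image_points)^2)
    per_view[i] <- sqrt(mean(d2) / 2)
    ss <- ss + sum(d2); n_tot <- n_tot + nrow(v$object_points)
  }
  init_res <- residual_fn(par0)
  # RMS is per residual component (u and v separately), so that with i.i.d.
  # pixel noise of SD sigma the expected RMS is ~sigma
  list(intrinsics = Kf, view_poses = poses,
       rms_px = sqrt(ss / (2 * n_tot)), per_view_rms_px = per_view,
       initial_rms_px = sqrt(mean(init_res^2)),
       niter = fit$niter, converged = fit$info %in% 1:4)
}
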