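# Camera pose (T_CO) estimation from 3D marker positions in the OTS/world
# frame and their 2D endoscopic projections: Grunert's P3P quartic on a
# well-conditioned triple, disambiguation by the surplus points, then
# Levenberg-Marquardt refinement over all correspondences.

# polynomial helpers: coefficient vectors in increasing degree
poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}
poly_sub <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) - c(b, numeric(n - length(b)))
}
poly_eval <- function(p, x) sum(p * x^(seq_along(p) - 1L))
poly_deriv <- function(p) if (length(p) <= 1L) 0 else p[-1L] * seq_len(length(p) - 1L)

#' Build a 2D-3D correspondence set
#'
#' @param world_points n x 3 matrix of marker positions in the OTS/world
#'   frame (mm).
#' @param image_points n x 2 matrix of pixel detections.
#' @param marker_id Optional labels (unique).
#' @export
correspondences_2d3d <- function(world_points, image_points, marker_id = NULL) {
  wp <- as.matrix(world_points); ip <- as.matrix(image_points)
  stopifnot(ncol(wp) == 3L, ncol(ip) == 2L, nrow(wp) == nrow(ip))
  if (!all(is.finite(wp)) || !all(is.finite(ip)))
    stop("correspondences_2d3d: non-finite values")
  if (is.null(marker_id)) marker_id <- as.character(seq_len(nrow(wp)))
  if (anyDuplicated(marker_id)) stop("correspondences_2d3d: duplicate marker_id")
  structure(list(world = wp, image = ip, marker_id = as.character(marker_id)),
            class = "correspondences_2d3d")
}

# Relative triangle area (vs squared longest side); collinearity measure.
triangle_area_rel <- function(P) {
  ab <- P[2, ] - P[1, ]; ac <- P[3, ] - P[1, ]
  a2 <- max(sum(ab^2), sum(ac^2), sum((P[3, ] - P[2, ])^2))
  sqrt(sum(crossprod_vec(ab, ac)^2)) / 2 / a2
}

#' Perspective-three-point pose solver (Grunert)
#'
#' Recovers the camera pose candidates from exactly three 2D-3D
#' correspondences.  The image points are undistorted internally, the
#' law-of-cosines system is reduced to Grunert's quartic in the distance
#' ratio (solved with [polyroot()], each real root polished by one Newton
#' step), and each distance solution is upgraded to a pose by rigid
#' alignment of the back-projected triangle.
#'
#' @param cs A [correspondences_2d3d()] with exactly 3 entries.
#' @param K A [camera_intrinsics()].
#' @return List of up to 4 candidate `rigid_transform`s (`O <- C`, the camera
#'   pose in the world frame), sorted by the lexicographic order of their
#'   rotation quaternions.
#' @export
p3p_solve <- function(cs, K) {
  stopifnot(inherits(cs, "correspondences_2d3d"))
  if (nrow(cs$world) != 3L) stop("p3p_solve: exactly 3 correspondences required")
  P <- cs$world
  if (triangle_area_rel(P) < arnav_tolerances()$collinear)
    stop("p3p_solve: degenerate (collinear) world points")
  xy <- undistort_points(K, cs$image)
  V <- cbind(xy, 1)
  V <- V / sqrt(rowSums(V^2))           # unit bearing vectors
  ca <- sum(V[2, ] * V[3, ])            # angle opposite side a = |P2-P3|
  cb <- sum(V[1, ] * V[3, ])
  cg <- sum(V[1, ] * V[2, ])
  a2 <- sum((P[2, ] - P[3, ])^2)
  b2 <- sum((P[1, ] - P[3, ])^2)
  c2 <- sum((P[1, ] - P[2, ])^2)
  K1 <- a2 / b2; K2 <- c2 / b2
  # monic quadratics in u with polynomial (in v) coefficients:
  #   F1: u^2 + B1(v) u + C1(v),  B1 = -2 ca v, C1 = v^2 - K1 (1 + v^2 - 2 cb v)
  #   F2: u^2 + B2    u + C2(v),  B2 = -2 cg,   C2 = 1 - K2 (1 + v^2 - 2 cb v)
  B1 <- c(0, -2 * ca)
  C1 <- c(-K1, 2 * K1 * cb, 1 - K1)
  B2 <- c(-2 * cg)
  C2 <- c(1 - K2, 2 * K2 * cb, -K2)
  # resultant of the two monic quadratics: (C1-C2)^2 - (B1-B2)(B2 C1 - B1 C2)
  quart <- poly_sub(poly_mul(poly_sub(C1, C2), poly_sub(C1, C2)),
                   poly_mul(poly_sub(B1, B2),
                            poly_sub(poly_mul(B2, C1), poly_mul(B1, C2))))
  quart <- quart[1:5]
  if (max(abs(quart)) < 1e-300) return(list())
  roots <- polyroot(quart / max(abs(quart)))  # increasing-degree coefficients
  dq <- poly_deriv(quart)
  cands <- list()
  for (z in roots) {
    if (abs(Im(z)) > 1e-7 * (1 + abs(Re(z)))) next
    v <- Re(z)
    for (np in 1:3) {                       # Newton polishing of the root
      dv <- poly_eval(dq, v)
      if (abs(dv) < 1e-6 * max(abs(quart))) break  # (near-)double root: keep
      step <- poly_eval(quart, v) / dv
      v <- v - step
      if (abs(step) < 1e-15 * (1 + abs(v))) break
    }
    if (v <= 0) next
    den <- 1 + v^2 - 2 * v * cb
    if (den <= 0) next
    # candidate u's: roots of either quadratic at this v (the resultant
    # guarantees a common root; in symmetric configurations the quadratics
    # coincide and both roots are genuine branches).  Each candidate pose is
    # validated by reprojecting the defining triple.
    b1 <- poly_eval(B1, v); c1 <- poly_eval(C1, v)
    b2v <- B2[1]; c2v <- poly_eval(C2, v)
    us <- numeric(0)
    for (qc in list(c(b1, c1), c(b2v, c2v))) {
      disc <- qc[1]^2 / 4 - qc[2]
      if (disc >= 0) us <- c(us, -qc[1] / 2 + c(-1, 1) * sqrt(disc))
    }
    us <- unique(us[us > 0])
    for (u in us) {
      s1 <- sqrt(b2 / den)
      s <- c(s1, u * s1, v * s1)
      # Newton polish in distance space: the law-of-cosines system is
      # regular here even where the resultant has a double root
      for (np in 1:5) {
        g <- c(s[2]^2 + s[3]^2 - 2 * s[2] * s[3] * ca - a2,
               s[1]^2 + s[3]^2 - 2 * s[1] * s[3] * cb - b2,
               s[1]^2 + s[2]^2 - 2 * s[1] * s[2] * cg - c2)
        if (max(abs(g)) < 1e-12 * max(a2, b2, c2)) break
        J <- 2 * rbind(c(0, s[2] - s[3] * ca, s[3] - s[2] * ca),
                       c(s[1] - s[3] * cb, 0, s[3] - s[1] * cb),
                       c(s[1] - s[2] * cg, s[2] - s[1] * cg, 0))
        step <- tryCatch(solve(J, g), error = function(e) NULL)
        if (is.null(step)) break
        s <- s - step
      }
      if (any(s <= 0)) next
      pc <- V * s                       # back-projected points, camera frame
      fit <- kabsch_fit(P, pc)          # C <- O on the triple
      T_co <- invert_transform(rigid_transform(fit$R, fit$t,
                                               source = "O", target = "C"))
      pcr <- transform_points(invert_transform(T_co), P)
      if (any(pcr[, 3] <= 0)) next
      uvr <- project_points(K, unclass(pcr))
      if (max(abs(uvr - cs$image)) > 1e-6) next   # candidate contract: exact interpolation
      cands[[length(cands) + 1L]] <- T_co
    }
  }
  if (!length(cands)) return(list())
  # deduplicate near-identical solutions (double roots), deterministic order
  qs <- lapply(cands, function(T_) rotation_to_quaternion(T_$rotation))
  keep <- rep(TRUE, length(cands))
  for (i in seq_along(cands)) {
    if (!keep[i]) next
    for (j in seq_along(cands)) {
      if (j <= i || !keep[j]) next
      tscale <- 1 + sqrt(sum(cands[[i]]$translation^2))
      if (max(abs(qs[[i]] - qs[[j]])) < 1e-6 &&
          max(abs(cands[[i]]$translation - cands[[j]]$translation)) < 1e-5 * tscale)
        keep[j] <- FALSE
    }
  }
  cands <- cands[keep]; qs <- qs[keep]
  ord <- do.call(order, as.data.frame(do.call(rbind, qs)))
  cands[ord]
}

# reprojection RMS (px) of world points under camera pose T_co (O <- C)
reprojection_rms <- function(T_co, cs, K) {
  T_oc <- invert_transform(T_co)
  pc <- transform_points(T_oc, cs$world)
  if (any(pc[, 3] <= 0)) return(Inf)
  sqrt(mean(rowSums((project_points(K, pc) - cs$image)^2)))
}

# maximal-area triple among correspondences (exhaustive up to n = 40)
select_triple <- function(wp) {
  n <- nrow(wp)
  idx <- if (n <= 40L) utils::combn(n, 3L) else
    utils::combn(sort(unique(round(seq(1, n, length.out = 40L)))), 3L)
  areas <- apply(idx, 2L, function(i) triangle_area_rel(wp[i, , drop = FALSE]) *
                   max(sum((wp[i[1], ] - wp[i[2], ])^2),
                       sum((wp[i[1], ] - wp[i[3], ])^2),
                       sum((wp[i[2], ] - wp[i[3], ])^2)))
  idx[, which.max(areas)]
}

#' Estimate the camera pose from n >= 4 correspondences
#'
#' P3P on the maximal-area triple, disambiguation by the reprojection error of
#' the remaining points, then Levenberg-Marquardt refinement over all
#' correspondences.  An optional RANSAC loop handles outlier-contaminated
#' input (off by default: the calibration-plate setting is controlled).
#'
#' @param cs A [correspondences_2d3d()] with at least 4 entries.
#' @param K A [camera_intrinsics()].
#' @param ransac Enable the RANSAC loop.
#' @param ransac_threshold_px Inlier gate (px).
#' @param ransac_iter Number of sampled triples.
#' @param max_rms_px Fail if the final RMS exceeds this (quality gate).
#' @return List: `pose` (`O <- C` `rigid_transform`), `rms_px`,
#'   `inliers` (logical, all `TRUE` without RANSAC).
#' @export
estimate_camera_pose <- function(cs, K, ransac = FALSE,
                                 ransac_threshold_px = 2, ransac_iter = 100L,
                                 max_rms_px = Inf) {
  stopifnot(inherits(cs, "correspondences_2d3d"))
  n <- nrow(cs$world)
  if (n < 4L) stop("estimate_camera_pose: at least 4 correspondences required")
  inliers <- rep(TRUE, n)
  if (ransac) {
    best_n <- -1L; best_err <- Inf
    for (it in seq_len(ransac_iter)) {
      tri <- sample.int(n, 3L)
      sub <- correspondences_2d3d(cs$world[tri, ], cs$image[tri, ],
                                  cs$marker_id[tri])
      if (triangle_area_rel(sub$world) < arnav_tolerances()$collinear) next
      cands <- tryCatch(p3p_solve(sub, K), error = function(e) list())
      for (T_co in cands) {
        T_oc <- invert_transform(T_co)
        pc <- transform_points(T_oc, cs$world)
        if (any(pc[, 3] <= 0)) next
        err <- sqrt(rowSums((project_points(K, pc) - cs$image)^2))
        ok <- err < ransac_threshold_px
        if (sum(ok) > best_n || (sum(ok) == best_n && mean(err[ok]) < best_err)) {
          best_n <- sum(ok); best_err <- mean(err[ok]); inliers <- ok
        }
      }
    }
    if (best_n < 4L) stop("estimate_camera_pose: RANSAC found no 4-point consensus")
  }
  csi <- correspondences_2d3d(cs$world[inliers, , drop = FALSE],
                              cs$image[inliers, , drop = FALSE],
                              cs$marker_id[inliers])
  tri <- select_triple(csi$world)
  sub <- correspondences_2d3d(csi$world[tri, ], csi$image[tri, ], csi$marker_id[tri])
  cands <- p3p_solve(sub, K)
  if (!length(cands)) stop("estimate_camera_pose: P3P produced no real solution")
  errs <- vapply(cands, reprojection_rms, 0, cs = csi, K = K)
  T0 <- cands[[which.min(errs)]]
  # LM refinement over all inlier correspondences
  par0 <- c(rotation_to_axis_angle(T0$rotation), T0$translation)
  n_res <- 2L * nrow(csi$world)
  fn <- function(par) {
    R <- axis_angle_to_rotation(par[1:3])
    pc <- sweep(csi$world %*% R, 2, -as.numeric(crossprod(R, par[4:6])), "+")
    # camera-frame coords of world points under pose (R = O<-C rotation):
    # p_c = R' (p_o - t)
    if (any(pc[, 3] <= 1e-9)) return(rep(1e6, n_res))
    as.numeric(project_points(K, pc) - csi$image)
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = 200L, ftol = 1e-15,
                                         ptol = 1e-15, gtol = 0))
  R <- axis_angle_to_rotation(fit$par[1:3])
  pose <- rigid_transform(R, fit$par[4:6], source = "C", target = "O")
  rms <- reprojection_rms(pose, csi, K)
  if (rms > max_rms_px)
    stop(sprintf("estimate_camera_pose: reprojection RMS %.3g px exceeds gate %.3g px",
                 rms, max_rms_px))
  full_inliers <- rep(FALSE, n); full_inliers[which(inliers)] <- TRUE
  list(pose = pose, rms_px = rms, inliers = full_inliers)
}
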