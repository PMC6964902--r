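# Hand-eye calibration: the fixed rigid transform T_CM (M <- C) between the
# endoscope-mounted marker disc (EM) and the camera, from paired observations
# (T_MO from the tracker, T_CO from pose estimation).
#
# Because the tracker expresses BOTH poses in the same world frame, each
# sample determines T_CM directly as T_MO^-1 T_CO; the DIRECT solver averages
# these per-sample estimates and is the default.  The classical AX = XB
# formulation over relative motions is provided as an independent cross-check;
# it requires at least two relative motions with non-parallel rotation axes.

#' A hand-eye calibration sample
#'
#' @param TMO Tracked endoscope-marker pose (`O <- M`).
#' @param TCO Camera pose from pose estimation (`O <- C`).
#' @export
hand_eye_sample <- function(TMO, TCO) {
  stopifnot(inherits(TMO, "rigid_transform"), inherits(TCO, "rigid_transform"))
  structure(list(TMO = TMO, TCO = TCO), class = "hand_eye_sample")
}

# Quaternion averaging: dominant eigenvector of the outer-product sum,
# signs aligned to the first sample (double-cover handling).
average_quaternions <- function(qs) {
  q1 <- qs[[1]]
  M <- matrix(0, 4, 4)
  for (q in qs) {
    if (sum(q * q1) < 0) q <- -q
    M <- M + tcrossprod(q)
  }
  q <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (q[1] < 0) q <- -q
  q
}

#' Solve the hand-eye calibration
#'
#' @param samples List of [hand_eye_sample()]s (>= 2; a single sample is
#'   accepted by the direct path and reduces to `TMO^-1 TCO`).
#' @param method `"direct"` (default): average the per-sample estimates
#'   `X_i = TMO_i^-1 TCO_i` (rotations by the quaternion eigen-method,
#'   translations by least squares, i.e. the mean).  `"axxb"`: classical
#'   relative-motion formulation `A X = X B` with
#'   `A_ij = TMO_i^-1 TMO_j`, `B_ij = TCO_i^-1 TCO_j`; the rotation is solved
#'   first by least squares over rotation-axis correspondences, the
#'   translation then by linear least squares.  If the relative rotation axes
#'   are (near-)parallel the AX=XB path is unidentifiable; with
#'   `fallback = TRUE` it falls back to the direct path, else it errors.
#' @param fallback Fall back to the direct path on AX=XB degeneracy.
#' @param min_axis_angle_rad Relative motions with smaller rotation angle are
#'   dropped from the axis fit (noise floor), default 1e-6.
#' @return List: `TCM` (`M <- C`), `method` (the path actually used), and
#'   `residuals`, a data.frame of per-sample rotation (rad) and translation
#'   (mm) deviations of `TMO_i TCM` from `TCO_i`.
#' @export
solve_hand_eye <- function(samples, method = c("direct", "axxb"),
                           fallback = FALSE, min_axis_angle_rad = 1e-6) {
  method <- match.arg(method)
  if (inherits(samples, "hand_eye_sample")) samples <- list(samples)
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, inherits, TRUE, "hand_eye_sample")))
  if (method == "axxb" && length(samples) < 2L)
    stop("solve_hand_eye: AX=XB path needs at least 2 samples")

  direct_solve <- function() {
    Xs <- lapply(samples, function(s)
      compose_transforms(invert_transform(s$TMO), s$TCO))
    if (length(Xs) == 1L) return(Xs[[1]])
    q <- average_quaternions(lapply(Xs, function(X) rotation_to_quaternion(X$rotation)))
    t_ <- colMeans(do.call(rbind, lapply(Xs, function(X) X$translation)))
    rigid_transform(quaternion_to_rotation(q), t_, source = "C", target = "M")
  }

  used <- method
  if (method == "direct") {
    TCM <- direct_solve()
  } else {
    # all consecutive relative motions (i, i+1); M <- M and C <- C motions
    n <- length(samples)
    pairs <- cbind(seq_len(n - 1L), seq.int(2L, n))
    axes_a <- list(); axes_b <- list(); As <- list(); Bs <- list()
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      A <- compose_transforms(invert_transform(samples[[i]]$TMO), samples[[j]]$TMO)
      B <- compose_transforms(invert_transform(samples[[i]]$TCO), samples[[j]]$TCO)
      As[[k]] <- A; Bs[[k]] <- B
      va <- rotation_to_axis_angle(A$rotation)
      vb <- rotation_to_axis_angle(B$rotation)
      if (sqrt(sum(va^2)) > min_axis_angle_rad &&
          sqrt(sum(vb^2)) > min_axis_angle_rad) {
        axes_a[[length(axes_a) + 1L]] <- va
        axes_b[[length(axes_b) + 1L]] <- vb
      }
    }
    degen <- FALSE
    if (length(axes_a) < 2L) {
      degen <- TRUE
    } else {
      Ma <- do.call(rbind, axes_a)
      # rank of the axis bundle: parallel axes leave the rotation about the
      # common axis unobservable
      if (svd(Ma)$d[2] < 1e-8 * max(svd(Ma)$d[1], 1)) degen <- TRUE
    }
    if (degen) {
      if (!fallback)
        stop(paste("solve_hand_eye: AX=XB degenerate - fewer than two relative",
                   "motions with non-parallel rotation axes; use the direct path",
                   "or fallback = TRUE"))
      used <- "direct (axxb degenerate)"
      TCM <- direct_solve()
    } else {
      # rotation: R_X maps camera-motion axes onto marker-motion axes
      # (R_A = R_X R_B R_X' implies axis_A = R_X axis_B); angle-weighted
      # least-squares rotation over the axis correspondences, no centering
      Mb <- do.call(rbind, axes_b)
      H <- crossprod(Mb, Ma)
      sv <- svd(H)
      dt <- sign(det(sv$v %*% t(sv$u))); if (dt == 0) dt <- 1
      RX <- sv$v %*% diag(c(1, 1, dt)) %*% t(sv$u)
      # translation: (R_Ak - I) t_X = R_X t_Bk - t_Ak
      C_ <- do.call(rbind, lapply(As, function(A) A$rotation - diag(3)))
      d_ <- unlist(lapply(seq_along(As), function(k)
        as.numeric(RX %*% Bs[[k]]$translation - As[[k]]$translation)))
      tX <- qr.solve(C_, d_)
      TCM <- rigid_transform(RX, tX, source = "C", target = "M")
    }
  }
  dev <- t(vapply(samples, function(s) {
    rec <- compose_transforms(s$TMO, TCM)
    c(rotation_rad = rotation_angle_between(rec$rotation, s$TCO$rotation),
      translation_mm = sqrt(sum((rec$translation - s$TCO$translation)^2)))
  }, c(rotation_rad = 0, translation_mm = 0)))
  list(TCM = TCM, method = used,
       residuals = as.data.frame(dev))
}
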