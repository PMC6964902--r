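# Rigid-transform algebra over named coordinate frames.
#
# Frame convention (used everywhere in this package): a transform labelled
# target<-source maps coordinates expressed in the source frame into the
# target frame.  The tracked poses are T_MO = O<-M (EM pose in OTS/world
# coordinates), T_CO = O<-C (camera pose), T_PO = O<-P (patient pose) and the
# hand-eye result T_CM = M<-C, so that O<-M composed with M<-C yields O<-C.

#' Construct a rigid transform between two named frames
#'
#' An element of SE(3): a proper rotation plus a translation in millimeters,
#' labelled with the source and target frame it maps between
#' (`target <- source` convention).
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric 3-vector (mm).
#' @param source,target Frame labels (single strings).
#' @return An object of class `rigid_transform` with fields `rotation`,
#'   `translation`, `source`, `target`.
#' @examples
#' T1 <- rigid_transform(diag(3), c(0, 0, 10), source = "C", target = "M")
#' compose_transforms(transform_identity("O", "M"), T1)
#' @export
rigid_transform <- function(rotation, translation, source = "src", target = "dst") {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite entries")
  tol <- arnav_tolerances()$orthonormal
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > tol)
    stop(sprintf("rigid_transform: rotation not orthonormal (deviation %.3g > %.3g)", err, tol))
  if (abs(det(rotation) - 1) > tol)
    stop("rigid_transform: rotation has determinant != +1 (reflection?)")
  structure(
    list(rotation = rotation, translation = translation,
         source = as.character(source), target = as.character(target)),
    class = "rigid_transform")
}

#' Identity transform between two frames
#' @param source,target Frame labels.
#' @export
transform_identity <- function(source = "src", target = source) {
  rigid_transform(diag(3), c(0, 0, 0), source = source, target = target)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: %s <- %s\n", x$target, x$source))
  m <- cbind(x$rotation, x$translation)
  dimnames(m) <- list(NULL, c("r1", "r2", "r3", "t_mm"))
  print(round(m, 6))
  invisible(x)
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param x A `rigid_transform`.
#' @param ... Unused.
#' @export
as.matrix.rigid_transform <- function(x, ...) {
  rbind(cbind(x$rotation, x$translation), c(0, 0, 0, 1))
}

#' Compose two rigid transforms
#'
#' `compose_transforms(A, B)` returns the transform applying `B` first, then
#' `A`; frame labels must chain (`A` maps from the frame `B` maps to).  The
#' rotation product is re-projected onto SO(3) only if numerical drift exceeds
#' the `reorthonormalize` tolerance.
#'
#' @param A Transform `X <- Y`.
#' @param B Transform `Y <- Z`.
#' @return Transform `X <- Z`.
#' @export
compose_transforms <- function(A, B) {
  stopifnot(inherits(A, "rigid_transform"), inherits(B, "rigid_transform"))
  if (!identical(A$source, B$target))
    stop(sprintf("compose_transforms: frame mismatch, %s<-[%s] vs [%s]<-%s",
                 A$target, A$source, B$target, B$source))
  R <- A$rotation %*% B$rotation
  drift <- max(abs(crossprod(R) - diag(3)))
  if (drift > arnav_tolerances()$reorthonormalize) R <- nearest_rotation(R)
  rigid_transform(R, as.numeric(A$rotation %*% B$translation + A$translation),
                  source = B$source, target = A$target)
}

#' Invert a rigid transform
#'
#' @param T_ A `rigid_transform` `X <- Y`.
#' @return The transform `Y <- X` (rotation transposed, translation `-R't`).
#' @export
invert_transform <- function(T_) {
  stopifnot(inherits(T_, "rigid_transform"))
  Rt <- t(T_$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% T_$translation),
                  source = T_$target, target = T_$source)
}

#' Apply a rigid transform to 3D points
#'
#' @param T_ A `rigid_transform`.
#' @param points Numeric 3-vector or n x 3 matrix of points in the source
#'   frame (mm).  A `frame` attribute, if present, must match `T_$source`.
#' @return Points in the target frame, same shape as the input, with the
#'   `frame` attribute set to the target frame.
#' @export
transform_points <- function(T_, points) {
  stopifnot(inherits(T_, "rigid_transform"))
  fr <- attr(points, "frame")
  if (!is.null(fr) && !identical(as.character(fr), T_$source))
    stop(sprintf("transform_points: point frame '%s' does not match transform source '%s'",
                 fr, T_$source))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), 1, 3) else as.matrix(points)
  stopifnot(ncol(p) == 3L)
  out <- p %*% t(T_$rotation)
  out <- sweep(out, 2, T_$translation, "+")
  if (vec) out <- as.numeric(out)
  attr(out, "frame") <- T_$target
  out
}

#' A labelled 3D point
#'
#' Plain numeric 3-vector carrying a `frame` attribute; a convenience for the
#' frame checks in [transform_points()].
#' @param x,y,z Coordinates (mm).
#' @param frame Frame label.
#' @export
point3 <- function(x, y, z, frame = "O") {
  v <- c(x, y, z)
  if (!all(is.finite(v))) stop("point3: non-finite coordinates")
  attr(v, "frame") <- frame
  v
}

#' Patient-model-to-camera fusion transform
#'
#' The overlay chain: the camera pose is reconstructed from the tracked
#' endoscope marker and the hand-eye calibration, `T_CO = T_MO T_CM`, and the
#' patient model is carried into the camera frame by
#' `T_CP = T_PO^-1 (T_MO T_CM)`.
#'
#' @param TPO Patient pose, `O <- P`.
#' @param TMO Endoscope-marker pose, `O <- M`.
#' @param TCM Hand-eye calibration, `M <- C`.
#' @return The transform `P <- C`: the camera pose expressed in the
#'   patient/CBCT frame.  The overlay path ([overlay_structures()]) applies
#'   its inverse (`C <- P`) to carry CBCT-frame structure coordinates into
#'   the camera frame before projection.
#' @export
patient_to_camera <- function(TPO, TMO, TCM) {
  TCO <- compose_transforms(TMO, TCM)                    # O <- C
  compose_transforms(invert_transform(TPO), TCO)         # P <- C
}

# Nearest rotation matrix in Frobenius norm (SVD projection onto SO(3)).
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

# ---- rotation representation converters -----------------------------------

#' Convert between rotation representations
#'
#' Converters between 3x3 rotation matrices, unit quaternions (scalar-first,
#' scalar part >= 0) and axis-angle vectors (axis * angle, rad).  Round trips
#' reproduce the input to 1e-10.
#'
#' @param R Rotation matrix.
#' @param q Quaternion `c(w, x, y, z)`.
#' @param v Axis-angle 3-vector (rad).
#' @return The requested representation.
#' @name rotation_convert
NULL

#' @rdname rotation_convert
#' @export
rotation_to_quaternion <- function(R) {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("rotation_to_quaternion: matrix not orthonormal")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q   # fixed sign convention: scalar part >= 0
  q
}

#' @rdname rotation_convert
#' @export
quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' @rdname rotation_convert
#' @export
rotation_to_axis_angle <- function(R) {
  q <- rotation_to_quaternion(R)
  s <- sqrt(sum(q[2:4]^2))
  ang <- 2 * atan2(s, q[1])
  if (s < 1e-300) return(c(0, 0, 0))
  q[2:4] / s * ang
}

#' @rdname rotation_convert
#' @export
axis_angle_to_rotation <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-300) return(diag(3))
  k <- v / ang
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# Geodesic angle (rad) between two rotations; quaternion route keeps full
# precision for small angles (acos of a near-1 trace loses ~1e-8).
rotation_angle_between <- function(R1, R2) {
  q <- rotation_to_quaternion(nearest_rotation(crossprod(R1, R2)))
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1]))
}

# ---- frame graph -----------------------------------------------------------

#' Frame graph of rigid transforms
#'
#' Holds rigid transforms keyed by (target, source) and answers path queries
#' by composing along registered edges (each edge usable in either direction).
#'
#' @param transforms Optional list of `rigid_transform`s to register.
#' @return An object of class `frame_graph`.
#' @export
frame_graph <- function(transforms = list()) {
  g <- structure(list(edges = list()), class = "frame_graph")
  for (T_ in transforms) g <- add_frame_transform(g, T_)
  g
}

#' @rdname frame_graph
#' @param graph A `frame_graph`.
#' @param T_ A `rigid_transform` to add as an edge.
#' @export
add_frame_transform <- function(graph, T_) {
  stopifnot(inherits(graph, "frame_graph"), inherits(T_, "rigid_transform"))
  graph$edges[[paste(T_$target, T_$source, sep = "<-")]] <- T_
  graph
}

#' @rdname frame_graph
#' @param target,source Frame labels to query.
#' @return `get_frame_transform`: the composed `target <- source` transform;
#'   error if no path exists.
#' @export
get_frame_transform <- function(graph, target, source) {
  stopifnot(inherits(graph, "frame_graph"))
  if (identical(target, source)) return(transform_identity(source, target))
  # breadth-first search over undirected edges
  adj <- list()
  for (T_ in graph$edges) {
    adj[[T_$source]] <- c(adj[[T_$source]], list(T_))
    adj[[T_$target]] <- c(adj[[T_$target]], list(invert_transform(T_)))
  }
  if (is.null(adj[[source]])) stop("get_frame_transform: unknown source frame")
  seen <- source
  queue <- list(list(frame = source, T_ = transform_identity(source)))
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (E in adj[[cur$frame]]) {
      if (E$source != cur$frame || E$target %in% seen) next
      Tn <- compose_transforms(E, cur$T_)
      if (identical(E$target, target)) return(Tn)
      seen <- c(seen, E$target)
      queue <- c(queue, list(list(frame = E$target, T_ = Tn)))
    }
  }
  stop(sprintf("get_frame_transform: no path %s <- %s", target, source))
}

#' Cycle consistency of a redundant edge
#'
#' Compares a directly registered transform with the composition along the
#' remaining edges; used to audit redundant calibrations.
#'
#' @param graph A `frame_graph`.
#' @param T_ A `rigid_transform` to check against the graph.
#' @return List with `rotation_rad` and `translation_mm` discrepancies.
#' @export
check_cycle_consistency <- function(graph, T_) {
  T_graph <- get_frame_transform(graph, T_$target, T_$source)
  list(rotation_rad = rotation_angle_between(T_graph$rotation, T_$rotation),
       translation_mm = sqrt(sum((T_graph$translation - T_$translation)^2)))
}

# ---- JSON I/O --------------------------------------------------------------

#' Read / write a rigid transform as JSON
#'
#' File format: `{source, target, rotation: 9 numbers row-major,
#' translation_mm: 3 numbers}`.  The reader validates orthonormality.
#'
#' @param path File path.
#' @param T_ A `rigid_transform`.
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(as.numeric(x$rotation), 3, 3, byrow = TRUE),
                  as.numeric(x$translation_mm),
                  source = x$source, target = x$target)
}

#' @rdname read_transform_json
#' @export
write_transform_json <- function(T_, path) {
  stopifnot(inherits(T_, "rigid_transform"))
  jsonlite::write_json(
    list(source = T_$source, target = T_$target,
         rotation = as.numeric(t(T_$rotation)),
         translation_mm = T_$translation),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
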