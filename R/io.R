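# Plain-text interchange formats: planar calibration views, 2D-3D
# correspondences, marker streams, intrinsics, segmented structures,
# hand-eye samples, TRE records.

#' Read / write planar calibration views as CSV
#'
#' Columns: `view_id, point_id, X_mm, Y_mm, u_px, v_px`.
#'
#' @param path CSV path.
#' @param views List of [planar_view()]s.
#' @return `read_planar_views`: a list of `planar_view`s, ordered by
#'   `view_id`.
#' @export
read_planar_views <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("view_id", "point_id", "X_mm", "Y_mm", "u_px", "v_px")
  if (!all(need %in% names(d))) stop("read_planar_views: missing columns")
  lapply(split(d, d$view_id), function(v)
    planar_view(cbind(v$X_mm, v$Y_mm), cbind(v$u_px, v$v_px)))
}

#' @rdname read_planar_views
#' @export
write_planar_views <- function(views, path) {
  rows <- do.call(rbind, lapply(seq_along(views), function(i) {
    v <- views[[i]]
    data.frame(view_id = i, point_id = seq_len(nrow(v$object_points)),
               X_mm = v$object_points[, 1], Y_mm = v$object_points[, 2],
               u_px = v$image_points[, 1], v_px = v$image_points[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read / write 2D-3D correspondences as CSV
#'
#' Columns: `marker_id, X_mm, Y_mm, Z_mm, u_px, v_px`.
#' @param path CSV path.
#' @param cs A [correspondences_2d3d()].
#' @export
read_correspondences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  correspondences_2d3d(cbind(d$X_mm, d$Y_mm, d$Z_mm),
                       cbind(d$u_px, d$v_px), d$marker_id)
}

#' @rdname read_correspondences
#' @export
write_correspondences <- function(cs, path) {
  utils::write.csv(data.frame(marker_id = cs$marker_id,
                              X_mm = cs$world[, 1], Y_mm = cs$world[, 2],
                              Z_mm = cs$world[, 3],
                              u_px = cs$image[, 1], v_px = cs$image[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write camera intrinsics as JSON
#'
#' Format: `{fx, fy, cx, cy, skew, dist: [k1, k2, p1, p2, k3], width,
#' height}`.
#' @param path JSON path.
#' @param K A [camera_intrinsics()].
#' @export
read_intrinsics_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_intrinsics(x$fx, x$fy, x$cx, x$cy, x$width, x$height,
                    skew = if (is.null(x$skew)) 0 else x$skew,
                    dist = as.numeric(x$dist))
}

#' @rdname read_intrinsics_json
#' @export
write_intrinsics_json <- function(K, path) {
  jsonlite::write_json(list(fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy,
                            skew = K$skew, dist = K$dist,
                            width = K$width, height = K$height),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a marker observation stream as CSV
#'
#' Columns: `t, marker_id, X_mm, Y_mm, Z_mm, visible`; one
#' [marker_observations()] frame per time stamp.
#' @param path CSV path.
#' @param frames Named list of `marker_observations` (names = time stamps).
#' @export
read_marker_stream <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$t), function(v)
    marker_observations(v$marker_id, cbind(v$X_mm, v$Y_mm, v$Z_mm),
                        visible = as.logical(v$visible)))
}

#' @rdname read_marker_stream
#' @export
write_marker_stream <- function(frames, path) {
  ts <- if (is.null(names(frames))) seq_along(frames) else names(frames)
  rows <- do.call(rbind, lapply(seq_along(frames), function(i)
    data.frame(t = ts[i], marker_id = frames[[i]]$marker_id,
               X_mm = frames[[i]]$x, Y_mm = frames[[i]]$y,
               Z_mm = frames[[i]]$z, visible = frames[[i]]$visible)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read / write segmented CBCT structures as JSON
#'
#' A list of `{type: "sphere"|"tube", id, center_mm | centerline_mm,
#' radius_mm}` in the CBCT frame.  Spheres are returned as the data.frame
#' [overlay_structures()] consumes.
#' @param path JSON path.
#' @param structures data.frame `sphere_id, x, y, z, diameter_mm`.
#' @export
read_structures_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  sph <- Filter(function(s) identical(s$type, "sphere"), x)
  data.frame(sphere_id = vapply(sph, function(s) as.character(s$id), ""),
             x = vapply(sph, function(s) as.numeric(s$center_mm[[1]]), 0),
             y = vapply(sph, function(s) as.numeric(s$center_mm[[2]]), 0),
             z = vapply(sph, function(s) as.numeric(s$center_mm[[3]]), 0),
             diameter_mm = vapply(sph, function(s) 2 * as.numeric(s$radius_mm), 0),
             stringsAsFactors = FALSE)
}

#' @rdname read_structures_json
#' @export
write_structures_json <- function(structures, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(structures)), function(i)
      list(type = "sphere", id = structures$sphere_id[i],
           center_mm = c(structures$x[i], structures$y[i], structures$z[i]),
           radius_mm = structures$diameter_mm[i] / 2)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write hand-eye samples as JSON
#'
#' A JSON list of `{TMO, TCO}` transform objects in the transform-file
#' dialect of [read_transform_json()].
#' @param path JSON path.
#' @param samples List of [hand_eye_sample()]s.
#' @export
read_handeye_samples_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(x, function(s) {
    mk <- function(t_) rigid_transform(
      matrix(as.numeric(unlist(t_$rotation)), 3, 3, byrow = TRUE),
      as.numeric(unlist(t_$translation_mm)),
      source = t_$source, target = t_$target)
    hand_eye_sample(mk(s$TMO), mk(s$TCO))
  })
}

#' @rdname read_handeye_samples_json
#' @export
write_handeye_samples_json <- function(samples, path) {
  enc <- function(T_) list(source = T_$source, target = T_$target,
                           rotation = as.numeric(t(T_$rotation)),
                           translation_mm = T_$translation)
  jsonlite::write_json(lapply(samples, function(s)
    list(TMO = enc(s$TMO), TCO = enc(s$TCO))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write TRE records as CSV
#'
#' Columns: `sphere_id, distance_mm, position_index, u_real, v_real, u_ovl,
#' v_ovl, diameter_px, tre_mm`.
#' @param path CSV path.
#' @param records TRE records from [evaluate_accuracy()].
#' @export
read_tre_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_tre_records
#' @export
write_tre_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write a rendered frame as PNG
#' @param image Grayscale matrix in [0, 1].
#' @param path PNG path.
#' @export
write_frame_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}
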