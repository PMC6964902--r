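# Virtual rig: synthetic phantoms, calibration targets, a noisy 3D marker
# sensor standing in for the optical tracker, endoscope image rendering, and
# the sphere-grid accuracy protocol (6 working distances x >= 100 positions).
#
# Everything is deterministic given a seed; noise enters as sigma * N(0,1)
# draws that are made even when sigma = 0, so outputs vary continuously in
# sigma with no branch flips at zero.

#' Default simulated endoscope intrinsics
#'
#' The sensor size matches the modeled endoscope camera (2590 x 1942 px);
#' focal length and distortion are plausible defaults for a rigid endoscope
#' with a 35-mm coupler, chosen for the simulator and configurable - they are
#' not measured values.  Use `scale = 0.25` for the 648 x 486 test-scale
#' sensor (all pixel quantities scale together).
#'
#' @param scale Sensor scale factor relative to 2590 x 1942.
#' @param k1,k2 Radial distortion defaults.
#' @export
default_endoscope_intrinsics <- function(scale = 1, k1 = -0.30, k2 = 0.10) {
  scale_intrinsics(
    camera_intrinsics(fx = 1800, fy = 1800, cx = 1295, cy = 971,
                      width = 2590, height = 1942, dist = c(k1, k2, 0, 0, 0)),
    scale)
}

#' Synthetic sphere-grid accuracy phantom
#'
#' A 60 x 60 mm plate carrying 13 steel spheres of 2 mm diameter inside the
#' central 20 x 20 mm region and 11 optical markers along the plate border.
#' Sphere centers are drawn from a jittered lattice with at least 3 mm
#' center-to-center spacing; the layout is deterministic per seed.  The plate
#' frame has its origin at the plate center, z = 0 on the plate plane.
#'
#' @param seed Integer seed for the layout.
#' @param n_spheres,n_markers Defaults 13 and 11.
#' @param sphere_diameter_mm Default 2 mm; machining tolerance can be modeled
#'   with `diameter_tol_mm` (uniform, default 0 - the physical 5 um tolerance
#'   is negligible at the modeled scales).
#' @param diameter_tol_mm Optional diameter jitter half-width (mm).
#' @return Object of class `grid_phantom`: `spheres` (data.frame
#'   `sphere_id, x, y, z, diameter_mm`), `markers` (data.frame
#'   `marker_id, x, y, z`), `plate_size_mm`, `roi_mm`.
#' @export
make_grid_phantom <- function(seed = 1L, n_spheres = 13L, n_markers = 11L,
                              sphere_diameter_mm = 2, diameter_tol_mm = 0) {
  stopifnot(n_spheres >= 1L, n_markers >= 3L)
  roi <- 20; plate <- 60
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # jittered lattice: 4x4 cells of 5 mm in the ROI, pick n_spheres cells;
  # +-0.8 mm jitter keeps spacing >= 5 - 1.6 = 3.4 mm > 3 mm
  cells <- expand.grid(ix = 0:3, iy = 0:3)
  pick <- cells[sample.int(nrow(cells), n_spheres), ]
  cx <- -roi / 2 + 2.5 + 5 * pick$ix + runif(n_spheres, -0.8, 0.8)
  cy <- -roi / 2 + 2.5 + 5 * pick$iy + runif(n_spheres, -0.8, 0.8)
  dia <- sphere_diameter_mm + runif(n_spheres, -diameter_tol_mm, diameter_tol_mm)
  spheres <- data.frame(sphere_id = sprintf("S%02d", seq_len(n_spheres)),
                        x = cx, y = cy, z = 0, diameter_mm = dia,
                        stringsAsFactors = FALSE)
  # markers on the plate border, equally spaced along the perimeter
  half <- plate / 2 - 2
  per <- seq(0, 1, length.out = n_markers + 1L)[seq_len(n_markers)]
  s <- per * 8 * half
  side <- pmin(floor(s / (2 * half)), 3)
  f <- s - side * 2 * half
  mx <- ifelse(side == 0, -half + f, ifelse(side == 1, half,
         ifelse(side == 2, half - f, -half)))
  my <- ifelse(side == 0, -half, ifelse(side == 1, -half + f,
         ifelse(side == 2, half, half - f)))
  markers <- data.frame(marker_id = sprintf("G%02d", seq_len(n_markers)),
                        x = mx, y = my, z = 0, stringsAsFactors = FALSE)
  structure(list(spheres = spheres, markers = markers,
                 plate_size_mm = plate, roi_mm = roi),
            class = "grid_phantom")
}

# save/restore the global RNG state so simulator calls are self-seeding
# without disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Planar calibration targets
#'
#' `make_calibration_plate()` builds the 25-marker planar plate used for
#' hand-eye calibration (5 x 5 layout); `make_checkerboard()` builds an inner
#' corner grid.  All points are coplanar with z = 0 in the target frame.
#'
#' @param spacing_mm Marker/corner spacing.
#' @return data.frame `marker_id, x, y, z`.
#' @export
make_calibration_plate <- function(spacing_mm = 10) {
  g <- expand.grid(ix = 0:4, iy = 0:4)
  data.frame(marker_id = sprintf("CP%02d", seq_len(25)),
             x = (g$ix - 2) * spacing_mm, y = (g$iy - 2) * spacing_mm, z = 0,
             stringsAsFactors = FALSE)
}

#' @rdname make_calibration_plate
#' @param rows,cols Inner corner counts.
#' @param square_mm Square size (mm).
#' @export
make_checkerboard <- function(rows = 7L, cols = 9L, square_mm = 5) {
  stopifnot(rows >= 2L, cols >= 2L, square_mm > 0)
  g <- expand.grid(ix = seq_len(cols) - 1L, iy = seq_len(rows) - 1L)
  data.frame(marker_id = sprintf("X%03d", seq_len(rows * cols)),
             x = (g$ix - (cols - 1) / 2) * square_mm,
             y = (g$iy - (rows - 1) / 2) * square_mm, z = 0,
             stringsAsFactors = FALSE)
}

#' Endoscope-marker disc layout
#'
#' Local marker layout of the EM: a 50-mm diameter disc with `n` markers on a
#' ring plus one center marker, z = 0 in the M frame.
#' @param n_ring Markers on the ring.
#' @param radius_mm Ring radius.
#' @export
make_em_disc <- function(n_ring = 5L, radius_mm = 22) {
  ang <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring
  data.frame(marker_id = c("EM0", sprintf("EM%d", seq_len(n_ring))),
             x = c(0, radius_mm * cos(ang)), y = c(0, radius_mm * sin(ang)),
             z = 0, stringsAsFactors = FALSE)
}

#' Scene state of the virtual rig
#'
#' @param camera_pose,em_pose,phantom_pose `rigid_transform`s `O <- C`,
#'   `O <- M`, `O <- P`.  `em_pose` defaults to the pose consistent with
#'   `camera_pose` and `tcm_true`.
#' @param intrinsics A [camera_intrinsics()].
#' @param tcm_true Ground-truth hand-eye transform (`M <- C`).
#' @param sigma_marker_mm Isotropic Gaussian noise of the 3D marker sensor.
#' @param sigma_pixel_px Image noise (additive Gaussian, 0..1 intensity
#'   units per 8-bit-equivalent sigma when rendering).
#' @param seed Base seed for all stochastic draws.
#' @export
scene_state <- function(camera_pose, intrinsics,
                        tcm_true = default_tcm(), em_pose = NULL,
                        phantom_pose = transform_identity("P", "O"),
                        sigma_marker_mm = 0, sigma_pixel_px = 0, seed = 1L) {
  stopifnot(sigma_marker_mm >= 0, sigma_pixel_px >= 0)
  if (is.null(em_pose))
    em_pose <- compose_transforms(camera_pose, invert_transform(tcm_true))
  structure(list(camera_pose = camera_pose, em_pose = em_pose,
                 phantom_pose = phantom_pose, intrinsics = intrinsics,
                 tcm_true = tcm_true,
                 noise = list(sigma_marker_mm = sigma_marker_mm,
                              sigma_pixel_px = sigma_pixel_px),
                 seed = as.integer(seed)),
            class = "scene_state")
}

#' Default ground-truth hand-eye transform of the virtual rig
#'
#' The EM disc sits on the endoscope collar: the camera is offset along the
#' scope axis and tilted slightly relative to the disc.
#' @export
default_tcm <- function() {
  R <- axis_angle_to_rotation(c(0.06, -0.04, 0.03))
  rigid_transform(R, c(12, -8, 55), source = "C", target = "M")
}

#' Observe object markers with the simulated 3D marker sensor
#'
#' Maps local marker coordinates through `pose` into the world frame and adds
#' isotropic Gaussian noise of `sigma_mm` (a draw is consumed even at
#' sigma = 0, for continuity in sigma).
#'
#' @param markers data.frame `marker_id, x, y, z` in the object frame.
#' @param pose `rigid_transform` `O <- object`.
#' @param sigma_mm Noise SD per axis (mm).
#' @param seed Optional seed (self-contained draw).
#' @param visible Logical vector of visibility flags.
#' @return [marker_observations()].
#' @export
observe_markers <- function(markers, pose, sigma_mm = 0, seed = NULL,
                            visible = TRUE) {
  p <- transform_points(pose, as.matrix(markers[, c("x", "y", "z")]))
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  noise <- matrix(rnorm(3L * nrow(p)), ncol = 3L) * sigma_mm
  marker_observations(markers$marker_id, unclass(p) + noise, visible = visible)
}

# Projected circle of a 3D sphere: center via full projection; radius as half
# the pixel distance between the projections of the diameter endpoints along
# the camera x-axis (tangent-cone small-sphere approximation that follows the
# local distortion scale).  Shared by the renderer's ground truth and the
# overlay path, so both agree exactly by construction.
project_sphere <- function(K, center_cam, radius_mm) {
  ctr <- project_points(K, center_cam)
  e1 <- project_points(K, center_cam + c(radius_mm, 0, 0))
  e2 <- project_points(K, center_cam - c(radius_mm, 0, 0))
  c(u = ctr[1], v = ctr[2], r_px = sqrt(sum((e1 - e2)^2)) / 2)
}

#' Render a synthetic endoscope image of the grid phantom
#'
#' Spheres are drawn as anti-aliased filled bright circles on a dark
#' background (grayscale in [0, 1]); the returned ground truth holds the
#' exact projected centers and radii.
#'
#' @param scene A [scene_state()].
#' @param phantom A [make_grid_phantom()].
#' @param seed Seed for the pixel noise draw.
#' @return List: `image` (height x width matrix), `ground_truth` (data.frame
#'   `sphere_id, u, v, r_px`, in-image spheres only).
#' @export
render_endoscope_image <- function(scene, phantom, seed = scene$seed) {
  K <- scene$intrinsics
  gt <- sphere_ground_truth(scene, phantom)
  if (nrow(gt) == 0 && nrow(phantom$spheres) > 0) {
    ctr_cam <- transform_points(
      compose_transforms(invert_transform(scene$camera_pose), scene$phantom_pose),
      as.matrix(phantom$spheres[, c("x", "y", "z")]))
    if (all(ctr_cam[, 3] <= 0))
      stop("render_endoscope_image: phantom behind the camera")
  }
  img <- matrix(0, nrow = K$height, ncol = K$width)
  for (i in seq_len(nrow(gt))) {
    img <- draw_disc(img, gt$u[i], gt$v[i], gt$r_px[i])
  }
  sp <- scene$noise$sigma_pixel_px
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  img <- img + matrix(rnorm(length(img)), nrow = nrow(img)) * (sp / 255)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, ground_truth = gt)
}

# exact projected circles of the phantom spheres under the true scene poses
sphere_ground_truth <- function(scene, phantom) {
  T_cp <- compose_transforms(invert_transform(scene$camera_pose),
                             scene$phantom_pose)        # C <- P
  ctr <- transform_points(T_cp, as.matrix(phantom$spheres[, c("x", "y", "z")]))
  K <- scene$intrinsics
  keep <- which(ctr[, 3] > 0)
  out <- do.call(rbind, lapply(keep, function(i)
    project_sphere(K, ctr[i, ], phantom$spheres$diameter_mm[i] / 2)))
  if (is.null(out)) out <- matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("u", "v", "r_px")))
  gt <- data.frame(sphere_id = phantom$spheres$sphere_id[keep],
                   u = out[, 1], v = out[, 2], r_px = out[, 3],
                   stringsAsFactors = FALSE)
  inimg <- gt$u >= 0 & gt$u < K$width & gt$v >= 0 & gt$v < K$height
  gt[inimg, , drop = FALSE]
}

# anti-aliased filled disc: linear coverage ramp of one pixel at the rim
draw_disc <- function(img, u, v, r) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(0L, floor(u - r - 2)); x1 <- min(w - 1L, ceiling(u + r + 2))
  y0 <- max(0L, floor(v - r - 2)); y1 <- min(h - 1L, ceiling(v + r + 2))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - v)^2, (xs - u)^2, "+"))
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  img[ys + 1L, xs + 1L] <- pmax(sub, cov)
  img
}

#' Simulate checkerboard calibration views
#'
#' Renders exact corner correspondences of a planar checkerboard under random
#' plausible endoscope poses (target roughly facing the camera, tilted up to
#' `max_tilt_deg`, fully inside the image), with optional pixel noise.
#'
#' @param K True [camera_intrinsics()].
#' @param n_views Number of views (the calibration protocol uses 15).
#' @param board A [make_checkerboard()] data.frame.
#' @param distance_mm Range of target distances.
#' @param max_tilt_deg Maximum out-of-plane tilt.
#' @param sigma_px Pixel noise SD.
#' @param seed Seed.
#' @return List of [planar_view()]s with a `poses` attribute (true
#'   target-to-camera transforms).
#' @export
simulate_calibration_views <- function(K, n_views = 15L,
                                       board = make_checkerboard(),
                                       distance_mm = c(45, 90),
                                       max_tilt_deg = 35, sigma_px = 0,
                                       seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  op <- as.matrix(board[, c("x", "y")])
  views <- list(); poses <- list()
  guard <- 0L
  while (length(views) < n_views) {
    guard <- guard + 1L
    if (guard > 200L * n_views)
      stop("simulate_calibration_views: could not place views inside the image")
    tilt <- runif(1, 0.15, 1) * max_tilt_deg * pi / 180
    ax <- runif(1, 0, 2 * pi); roll <- runif(1, 0, 2 * pi)
    R <- axis_angle_to_rotation(c(0, 0, roll)) %*%
      axis_angle_to_rotation(tilt * c(cos(ax), sin(ax), 0))
    R <- nearest_rotation(R)
    z <- runif(1, distance_mm[1], distance_mm[2])
    # lateral offset keeps the target near the view cone
    lim <- z * 0.25 / K$fx * K$width
    t_ <- c(runif(1, -lim, lim), runif(1, -lim, lim), z)
    pc <- sweep(cbind(op, 0) %*% t(R), 2, t_, "+")
    if (any(pc[, 3] < 20)) next
    uv <- project_points(K, pc)
    if (any(uv[, 1] < 2 | uv[, 1] > K$width - 3 |
            uv[, 2] < 2 | uv[, 2] > K$height - 3)) next
    noise <- matrix(rnorm(length(uv)), ncol = 2L) * sigma_px
    views[[length(views) + 1L]] <- planar_view(op, uv + noise)
    poses[[length(poses) + 1L]] <- rigid_transform(R, t_, source = "target",
                                                   target = "C")
  }
  attr(views, "poses") <- poses
  views
}

#' Simulate hand-eye calibration samples
#'
#' Emulates the hand-eye acquisition: the calibration plate (CP) and the
#' tracked endoscope marker (EM) are both seen by the marker sensor while the
#' endoscope photographs the CP.  Two motion modes are provided:
#' `"fixed"` mirrors the physical protocol (endoscope held by a surgical arm,
#' only the CP moved between views - the tracked poses are then constant and
#' only the direct solver is informative), `"moving"` repositions the
#' endoscope between views, producing the non-parallel relative rotations the
#' AX=XB path requires.
#'
#' @param n Number of views (protocol: 20).
#' @param tcm_true Ground-truth `M <- C` transform.
#' @param K Intrinsics used when `camera_pose_from = "pnp"`.
#' @param motion `"moving"` or `"fixed"`.
#' @param camera_pose_from `"exact"` takes T_CO from the scene geometry;
#'   `"pnp"` runs the full pipeline (project the CP markers, then
#'   [estimate_camera_pose()]).
#' @param sigma_rot_rad,sigma_trans_mm Observation noise applied to both
#'   tracked poses (random-axis rotation perturbation; isotropic translation).
#' @param sigma_px Pixel noise for the `"pnp"` route.
#' @param seed Seed.
#' @return List of [hand_eye_sample()]s with attribute `tcm_true`.
#' @export
simulate_handeye_samples <- function(n = 20L, tcm_true = default_tcm(),
                                     K = default_endoscope_intrinsics(0.25),
                                     motion = c("moving", "fixed"),
                                     camera_pose_from = c("exact", "pnp"),
                                     sigma_rot_rad = 0, sigma_trans_mm = 0,
                                     sigma_px = 0, seed = 1L) {
  motion <- match.arg(motion)
  camera_pose_from <- match.arg(camera_pose_from)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cp <- make_calibration_plate()
  perturb <- function(T_) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)) * rnorm(1) * sigma_rot_rad
    rigid_transform(nearest_rotation(axis_angle_to_rotation(ax) %*% T_$rotation),
                    T_$translation + rnorm(3) * sigma_trans_mm,
                    source = T_$source, target = T_$target)
  }
  samples <- list()
  # base camera pose: looking down +z of the world from z = -60
  base_cam <- rigid_transform(diag(3), c(0, 0, -60), source = "C", target = "O")
  guard <- 0L
  while (length(samples) < n) {
    guard <- guard + 1L
    if (guard > 500L * n) stop("simulate_handeye_samples: placement failed")
    if (motion == "moving") {
      dR <- axis_angle_to_rotation(rnorm(3) * 0.25)
      cam <- rigid_transform(nearest_rotation(dR %*% base_cam$rotation),
                             base_cam$translation + rnorm(3) * 25,
                             source = "C", target = "O")
    } else {
      cam <- base_cam
    }
    # CP placed in front of the camera at 60-110 mm
    z <- runif(1, 60, 110)
    tiltv <- rnorm(3) * 0.15
    Rcp_c <- axis_angle_to_rotation(tiltv)
    tcp_c <- c(runif(2, -8, 8), z)
    T_cp_in_cam <- rigid_transform(Rcp_c, tcp_c, source = "target", target = "C")
    pc <- transform_points(T_cp_in_cam, as.matrix(cp[, c("x", "y", "z")]))
    if (any(pc[, 3] < 20)) next
    uv <- project_points(K, unclass(pc))
    if (any(uv[, 1] < 2 | uv[, 1] > K$width - 3 |
            uv[, 2] < 2 | uv[, 2] > K$height - 3)) next
    T_cp_world <- compose_transforms(cam, T_cp_in_cam)   # O <- target
    TMO <- compose_transforms(cam, invert_transform(tcm_true))  # O <- M
    if (camera_pose_from == "pnp") {
      wp <- transform_points(T_cp_world, as.matrix(cp[, c("x", "y", "z")]))
      uv_obs <- uv + matrix(rnorm(length(uv)), ncol = 2L) * sigma_px
      est <- estimate_camera_pose(
        correspondences_2d3d(unclass(wp), uv_obs, cp$marker_id), K)
      TCO <- est$pose
    } else {
      TCO <- cam
    }
    if (sigma_rot_rad > 0 || sigma_trans_mm > 0) {
      TMO <- perturb(TMO); TCO <- perturb(TCO)
    }
    samples[[length(samples) + 1L]] <- hand_eye_sample(TMO, TCO)
  }
  attr(samples, "tcm_true") <- tcm_true
  samples
}

#' Run the sphere-grid accuracy protocol
#'
#' Emulates the accuracy experiment: the endoscope is fixed and the grid
#' phantom, kept perpendicular to the optical axis, is translated in its
#' plane through `n_positions` poses per working distance so the sphere
#' cluster covers the whole field of view.  Every frame carries the true
#' phantom pose, noisy marker-sensor observations of the grid border markers
#' and of the EM disc, and the exact projected ground-truth circles.
#'
#' @param distances_mm Working distances (protocol: 5, 10, 15, 20, 25, 30).
#' @param n_positions Positions per distance (protocol: >= 100).
#' @param intrinsics True camera intrinsics.
#' @param phantom A [make_grid_phantom()].
#' @param tcm_true Ground-truth hand-eye transform.
#' @param sigma_marker_mm 3D marker sensor noise.
#' @param sigma_pixel_px Image noise (only used when rendering).
#' @param in_plane_rotation Add a random in-plane rotation per position.
#' @param render Also rasterize each frame (slow; off by default - the
#'   ground-truth circles are exact either way).
#' @param seed Seed.
#' @return Object of class `accuracy_protocol`: `frames` (list), `phantom`,
#'   `em_disc`, `intrinsics`, `tcm_true`, `camera_pose`, `reference`
#'   (CBCT-time marker observations and phantom pose), `config`.
#' @export
run_accuracy_protocol <- function(distances_mm = c(5, 10, 15, 20, 25, 30),
                                  n_positions = 100L,
                                  intrinsics = default_endoscope_intrinsics(0.25),
                                  phantom = make_grid_phantom(seed = 1L),
                                  tcm_true = default_tcm(),
                                  sigma_marker_mm = 0, sigma_pixel_px = 0,
                                  in_plane_rotation = TRUE,
                                  render = FALSE, seed = 1L) {
  stopifnot(n_positions >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  K <- intrinsics
  em <- make_em_disc()
  cam <- rigid_transform(diag(3), c(0, 0, 0), source = "C", target = "O")
  # CBCT-time reference: grid centered at the farthest working distance
  ref_pose <- rigid_transform(diag(3), c(0, 0, max(distances_mm)),
                              source = "P", target = "O")
  reference_obs <- observe_markers(phantom$markers, ref_pose,
                                   sigma_mm = sigma_marker_mm)
  frames <- list()
  # in-plane targets: jittered lattice of image points covering the sensor
  side <- ceiling(sqrt(n_positions))
  for (d in distances_mm) {
    gu <- (expand.grid(i = seq_len(side), j = seq_len(side)) - 0.5) / side
    gu <- gu[seq_len(n_positions), , drop = FALSE]
    tu <- (gu$i + runif(n_positions, -0.25, 0.25) / side) * K$width
    tv <- (gu$j + runif(n_positions, -0.25, 0.25) / side) * K$height
    for (k in seq_len(n_positions)) {
      # plate center lands on the target image point (pinhole inversion,
      # distortion ignored for placement - placement need not be exact)
      x <- (tu[k] - K$cx) / K$fx * d
      y <- (tv[k] - K$cy) / K$fy * d
      Rp <- if (in_plane_rotation)
        axis_angle_to_rotation(c(0, 0, runif(1, 0, 2 * pi))) else diag(3)
      pose <- rigid_transform(Rp, c(x, y, d), source = "P", target = "O")
      scene <- scene_state(cam, K, tcm_true = tcm_true, phantom_pose = pose,
                           sigma_marker_mm = sigma_marker_mm,
                           sigma_pixel_px = sigma_pixel_px, seed = seed)
      fr <- list(distance_mm = d, position_index = k,
                 phantom_pose = pose,
                 grid_obs = observe_markers(phantom$markers, pose,
                                            sigma_mm = sigma_marker_mm),
                 em_obs = observe_markers(em, scene$em_pose,
                                          sigma_mm = sigma_marker_mm),
                 ground_truth = sphere_ground_truth(scene, phantom))
      if (render) fr$image <- render_endoscope_image(scene, phantom,
                                                     seed = NULL)$image
      frames[[length(frames) + 1L]] <- fr
    }
  }
  structure(list(frames = frames, phantom = phantom, em_disc = em,
                 intrinsics = K, tcm_true = tcm_true, camera_pose = cam,
                 reference = list(obs = reference_obs, pose = ref_pose),
                 config = list(distances_mm = distances_mm,
                               n_positions = n_positions,
                               sigma_marker_mm = sigma_marker_mm,
                               sigma_pixel_px = sigma_pixel_px,
                               seed = seed)),
            class = "accuracy_protocol")
}
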