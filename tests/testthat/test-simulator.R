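test_that("the grid phantom is deterministic and satisfies its layout constraints", {
  p1 <- make_grid_phantom(seed = 0)
  p2 <- make_grid_phantom(seed = 0)
  expect_identical(p1, p2)
  for (seed in 0:4) {
    p <- make_grid_phantom(seed = seed)
    expect_identical(nrow(p$spheres), 13L)
    expect_identical(nrow(p$markers), 11L)
    expect_true(all(abs(p$spheres$x) <= 10 & abs(p$spheres$y) <= 10))
    d <- as.matrix(dist(p$spheres[, c("x", "y")]))
    expect_gte(min(d[upper.tri(d)]), 3)
    expect_true(all(p$spheres$diameter_mm == 2))
    expect_true(all(abs(p$markers$x) <= 30 & abs(p$markers$y) <= 30))
    expect_true(all(pmax(abs(p$markers$x), abs(p$markers$y)) > 10))
  }
})

test_that("calibration targets are planar with the advertised layout", {
  cp <- make_calibration_plate()
  expect_identical(nrow(cp), 25L)
  expect_true(all(cp$z == 0))
  cb <- make_checkerboard(rows = 7, cols = 9, square_mm = 5)
  expect_identical(nrow(cb), 63L)
  expect_true(all(cb$z == 0))
  xs <- sort(unique(cb$x))
  expect_equal(diff(xs), rep(5, 8))
})

test_that("the marker sensor is exact at zero noise and calibrated in sigma", {
  em <- make_em_disc()
  pose <- rigid_transform(axis_angle_to_rotation(c(0.1, 0.2, -0.1)),
                          c(5, -10, 100), "M", "O")
  obs <- observe_markers(em, pose, sigma_mm = 0, seed = 1)
  truth <- unclass(transform_points(pose, as.matrix(em[, c("x", "y", "z")])))
  expect_equal(as.matrix(obs[, c("x", "y", "z")]), truth,
               ignore_attr = TRUE, tolerance = 1e-12)
  obs2 <- observe_markers(em, pose, sigma_mm = 0, seed = 1)
  expect_identical(obs, obs2)
  # sample SD per axis within 5% of sigma over 10^4 draws
  one <- em[1, , drop = FALSE]
  draws <- vapply(1:10000, function(s)
    as.numeric(observe_markers(one, pose, sigma_mm = 0.05, seed = s)[1, c("x", "y", "z")]),
    numeric(3))
  sds <- apply(draws, 1, sd)
  expect_true(all(abs(sds - 0.05) / 0.05 < 0.05))
})

test_that("rendered spheres follow pinhole geometry and the ground truth is exact", {
  K <- test_intrinsics(dist = rep(0, 5))
  ph <- make_grid_phantom(seed = 3)
  # single sphere on the optical axis at 25 mm
  ph1 <- ph
  ph1$spheres <- data.frame(sphere_id = "S01", x = 0, y = 0, z = 0,
                            diameter_mm = 2, stringsAsFactors = FALSE)
  cam <- rigid_transform(diag(3), c(0, 0, 0), "C", "O")
  scene <- scene_state(cam, K,
                       phantom_pose = rigid_transform(diag(3), c(0, 0, 25), "P", "O"))
  r <- render_endoscope_image(scene, ph1)
  expect_equal(r$ground_truth$u, K$cx, tolerance = 1e-9)
  expect_equal(r$ground_truth$v, K$cy, tolerance = 1e-9)
  expect_equal(r$ground_truth$r_px, K$fx * 1 / 25, tolerance = 1e-3)
  # ground-truth centers agree with project() of the 3D centers
  scene2 <- scene_state(cam, test_intrinsics(),
                        phantom_pose = rigid_transform(diag(3), c(1, -2, 25), "P", "O"))
  r2 <- render_endoscope_image(scene2, ph)
  ctr <- unclass(transform_points(
    compose_transforms(invert_transform(cam), scene2$phantom_pose),
    as.matrix(ph$spheres[, c("x", "y", "z")])))
  uv <- project_points(test_intrinsics(), ctr)
  keep <- match(r2$ground_truth$sphere_id, ph$spheres$sphere_id)
  expect_lt(max(abs(cbind(r2$ground_truth$u, r2$ground_truth$v) - uv[keep, ])), 1e-9)
  # behind-camera error
  bad <- scene_state(cam, K,
                     phantom_pose = rigid_transform(diag(3), c(0, 0, -25), "P", "O"))
  expect_error(render_endoscope_image(bad, ph1), "behind")
})

test_that("the accuracy protocol has the prescribed structure and coverage", {
  proto <- run_accuracy_protocol(n_positions = 100, seed = 2)
  expect_identical(length(proto$frames), 600L)
  expect_identical(sort(unique(vapply(proto$frames, `[[`, 0, "distance_mm"))),
                   c(5, 10, 15, 20, 25, 30))
  # grid plane normal parallel to the optical axis in every frame
  for (fr in proto$frames[seq(1, 600, by = 37)]) {
    n_plate <- fr$phantom_pose$rotation[, 3]
    expect_equal(abs(sum(n_plate * c(0, 0, 1))), 1, tolerance = 1e-12)
    expect_equal(fr$phantom_pose$translation[3], fr$distance_mm)
  }
  # determinism
  proto2 <- run_accuracy_protocol(n_positions = 100, seed = 2)
  expect_identical(proto$frames[[123]]$grid_obs, proto2$frames[[123]]$grid_obs)
  # coverage: projected sphere centers fill >= 90% of an 8x8 image binning
  K <- proto$intrinsics
  for (d in c(5, 30)) {
    frames_d <- Filter(function(f) f$distance_mm == d, proto$frames)
    uu <- unlist(lapply(frames_d, function(f) f$ground_truth$u))
    vv <- unlist(lapply(frames_d, function(f) f$ground_truth$v))
    iu <- pmin(pmax(ceiling(uu / K$width * 8), 1), 8)
    iv <- pmin(pmax(ceiling(vv / K$height * 8), 1), 8)
    expect_gte(length(unique(paste(iu, iv))), 0.9 * 64)
  }
})

test_that("the simulator is continuous in the noise amplitude at zero", {
  em <- make_em_disc()
  pose <- rigid_transform(diag(3), c(0, 0, 50), "M", "O")
  o0 <- observe_markers(em, pose, sigma_mm = 0, seed = 9)
  o1 <- observe_markers(em, pose, sigma_mm = 1e-9, seed = 9)
  expect_lt(max(abs(as.matrix(o1[, c("x", "y", "z")]) -
                    as.matrix(o0[, c("x", "y", "z")]))), 1e-7)
})
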