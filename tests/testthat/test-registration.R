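test_that("identical point sets register to the identity with zero FRE", {
  set.seed(1)
  p <- matrix(rnorm(15, sd = 20), 5, 3)
  reg <- register_point_sets(p, p)
  expect_equal(reg$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(reg$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(reg$fre_mm, 1e-12)
})

test_that("a known rigid motion is recovered to machine precision", {
  set.seed(2)
  for (k in 1:10) {
    src <- matrix(rnorm(30, sd = 25), 10, 3)
    G <- random_transform("A", "B")
    dst <- unclass(transform_points(G, src))
    reg <- register_point_sets(src, dst)
    expect_lt(max(abs(reg$transform$rotation - G$rotation)), 1e-10)
    expect_lt(max(abs(reg$transform$translation - G$translation)), 1e-10)
    expect_lt(reg$fre_mm, 1e-10)
  }
})

test_that("FRE under isotropic noise matches least-squares expectations", {
  # FRE is the RMS 3D residual; fitting 6 rigid parameters to 3n = 30 noisy
  # coordinates leaves E[FRE^2] = sigma^2 (3n - 6)/n, i.e. ~0.155 mm for
  # sigma = 0.1 mm and n = 10 (closed form; the Monte-Carlo mean must sit
  # within a few percent of it)
  set.seed(3)
  sigma <- 0.1; n <- 10
  fres <- sapply(1:50, function(s) {
    src <- matrix(rnorm(3 * n, sd = 25), n, 3)
    G <- random_transform()
    dst <- unclass(transform_points(G, src)) +
      matrix(rnorm(3 * n, sd = sigma), n, 3)
    register_point_sets(src, dst)$fre_mm
  })
  expected <- sigma * sqrt((3 * n - 6) / n)
  expect_gt(mean(fres), 0.85 * expected)
  expect_lt(mean(fres), 1.15 * expected)
})

test_that("the fit is optimal against random rigid alternatives", {
  set.seed(4)
  src <- matrix(rnorm(24, sd = 20), 8, 3)
  G <- random_transform()
  dst <- unclass(transform_points(G, src)) + matrix(rnorm(24, sd = 0.3), 8, 3)
  reg <- register_point_sets(src, dst)
  rms_of <- function(R, t_) {
    sqrt(mean(rowSums((sweep(src %*% t(R), 2, t_, "+") - dst)^2)))
  }
  for (i in 1:1000) {
    R <- random_rotation()
    t_ <- rnorm(3, sd = 20)
    expect_lte(reg$fre_mm, rms_of(R, t_) + 1e-12)
  }
})

test_that("degenerate registration inputs are rejected", {
  p2 <- matrix(rnorm(6), 2, 3)
  expect_error(register_point_sets(p2, p2), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(register_point_sets(line, line), "collinear")
  a <- matrix(rnorm(9), 3, 3)
  expect_error(register_point_sets(a, a, ids = c("a", "b", "c"),
                                   dst_ids = c("x", "y", "z")),
               "common")
})

test_that("near-planar sets never register to a reflection", {
  set.seed(5)
  for (k in 1:20) {
    src <- cbind(matrix(rnorm(10, sd = 20), 5, 2), rnorm(5, sd = 1e-4))
    G <- random_transform()
    dst <- unclass(transform_points(G, src)) + matrix(rnorm(15, sd = 0.5), 5, 3)
    reg <- register_point_sets(src, dst)
    expect_equal(det(reg$transform$rotation), 1, tolerance = 1e-9)
  }
})

test_that("the VRG stores the CBCT-time configuration and co-registration", {
  set.seed(6)
  pos <- matrix(rnorm(15, sd = 30), 5, 3)
  obs <- marker_observations(sprintf("m%d", 1:5), pos)
  # hybrid positions equal to the tracked ones: identity co-registration
  vrg <- build_vrg(obs, hybrid_cbct_positions = pos,
                   hybrid_ids = sprintf("m%d", 1:5))
  expect_equal(vrg$cbct_from_ots$rotation, diag(3), tolerance = 1e-10)
  expect_lt(vrg$registration_fre_mm, 1e-10)
  # hybrid positions under a known transform
  G <- random_transform("O", "P")
  vrg2 <- build_vrg(obs, hybrid_cbct_positions = unclass(transform_points(G, pos)),
                    hybrid_ids = sprintf("m%d", 1:5))
  expect_lt(max(abs(vrg2$cbct_from_ots$rotation - G$rotation)), 1e-10)
  expect_error(build_vrg(obs[1:2, ]), "fewer than 3")
})

test_that("patient pose tracking compensates rigid phantom motion", {
  set.seed(7)
  local_m <- matrix(rnorm(21, sd = 25), 7, 3)
  pose0 <- random_transform("P", "O")
  obs0 <- marker_observations(sprintf("m%d", 1:7),
                              unclass(transform_points(pose0, local_m)))
  vrg <- build_vrg(obs0)
  # unmoved: TPO maps CBCT coords (= OTS at acquisition) to themselves
  pp0 <- estimate_patient_pose(vrg, obs0)
  expect_false(pp0$tracking_lost)
  expect_equal(as.matrix(pp0$TPO), diag(4), tolerance = 1e-9)
  expect_lt(pp0$fre_mm, 1e-10)
  # moved by a known motion: TPO equals that motion
  mv <- random_transform("O", "O2")
  world0 <- unclass(transform_points(pose0, local_m))
  obs1 <- marker_observations(sprintf("m%d", 1:7),
                              world0 %*% t(mv$rotation) +
                                matrix(mv$translation, 7, 3, byrow = TRUE))
  pp1 <- estimate_patient_pose(vrg, obs1)
  expect_lt(max(abs(pp1$TPO$rotation - mv$rotation)), 1e-9)
  expect_lt(max(abs(pp1$TPO$translation - mv$translation)), 1e-8)
})

test_that("tracking survives occlusion of one marker and order shuffles", {
  set.seed(8)
  local_m <- matrix(rnorm(15, sd = 25), 5, 3)
  pose0 <- random_transform("P", "O")
  obs0 <- marker_observations(sprintf("m%d", 1:5),
                              unclass(transform_points(pose0, local_m)))
  vrg <- build_vrg(obs0)
  occl <- obs0; occl$visible[3] <- FALSE
  pp <- estimate_patient_pose(vrg, occl)
  expect_false(pp$tracking_lost)
  expect_identical(pp$n_markers, 4L)
  expect_equal(as.matrix(pp$TPO), diag(4), tolerance = 1e-9)
  shuf <- obs0[sample.int(5), ]
  pp2 <- estimate_patient_pose(vrg, shuf)
  expect_equal(as.matrix(pp2$TPO), as.matrix(pp$TPO), tolerance = 1e-9)
  # tracking loss is signaled, not thrown
  occl2 <- obs0; occl2$visible[1:3] <- FALSE
  lost <- estimate_patient_pose(vrg, occl2)
  expect_true(lost$tracking_lost)
  expect_null(lost$TPO)
})
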