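test_that("composition matches the homogeneous-matrix oracle and respects identities", {
  set.seed(11)
  I_ <- transform_identity("B", "A")
  T1 <- random_transform("B", "A")
  expect_equal(as.matrix(compose_transforms(transform_identity("A", "A"), T1)),
               as.matrix(T1), tolerance = 1e-12)
  expect_equal(as.matrix(compose_transforms(T1, invert_transform(T1))),
               diag(4), tolerance = 1e-12)
  for (k in 1:20) {
    A <- random_transform("B", "A")
    B <- random_transform("C", "B")
    expect_equal(as.matrix(compose_transforms(A, B)), hom(A) %*% hom(B),
                 tolerance = 1e-12)
  }
})

test_that("frame labels chain and mismatches are rejected", {
  A <- random_transform("B", "A")
  B <- random_transform("C", "B")
  AB <- compose_transforms(A, B)
  expect_identical(AB$target, "A")
  expect_identical(AB$source, "C")
  expect_error(compose_transforms(B, A), "frame mismatch")
  p <- point3(1, 2, 3, frame = "X")
  expect_error(transform_points(A, p), "frame")
})

test_that("inversion transposes the rotation, negates R't and is an involution", {
  Tz <- rigid_transform(diag(3), c(0, 0, 10), "B", "A")
  expect_equal(invert_transform(Tz)$translation, c(0, 0, -10))
  expect_identical(invert_transform(Tz)$source, "A")
  set.seed(5)
  for (k in 1:10) {
    T_ <- random_transform()
    expect_equal(as.matrix(invert_transform(invert_transform(T_))),
                 as.matrix(T_), tolerance = 1e-12)
  }
})

test_that("point transform matches the oracle and rotates axes correctly", {
  Rz90 <- axis_angle_to_rotation(c(0, 0, pi / 2))
  T_ <- rigid_transform(Rz90, c(0, 0, 0), "A", "B")
  expect_equal(as.numeric(transform_points(T_, c(1, 0, 0))), c(0, 1, 0),
               tolerance = 1e-12)
  set.seed(6)
  for (k in 1:10) {
    T_ <- random_transform()
    p <- rnorm(3)
    expect_equal(as.numeric(transform_points(T_, p)), hom_apply(hom(T_), p),
                 tolerance = 1e-10)
  }
})

test_that("the fusion transform equals the literal chain and both expansions agree", {
  expect_equal(as.matrix(patient_to_camera(transform_identity("P", "O"),
                                           transform_identity("M", "O"),
                                           transform_identity("C", "M"))),
               diag(4), tolerance = 1e-14)
  set.seed(21)
  TMO <- random_transform("M", "O")
  TCM <- random_transform("C", "M")
  red <- patient_to_camera(transform_identity("P", "O"), TMO, TCM)
  expect_equal(as.matrix(red), as.matrix(compose_transforms(TMO, TCM)),
               tolerance = 1e-12)
  for (k in 1:10) {
    TPO <- random_transform("P", "O")
    TMO <- random_transform("M", "O")
    TCM <- random_transform("C", "M")
    TCP <- patient_to_camera(TPO, TMO, TCM)
    oracle <- solve(hom(TPO)) %*% hom(TMO) %*% hom(TCM)
    expect_equal(as.matrix(TCP), oracle, tolerance = 1e-10)
    # step-by-step expansion on a point agrees with the one-shot chain
    p <- rnorm(3, sd = 30)
    step <- hom_apply(solve(hom(TCM)),
                      hom_apply(solve(hom(TMO)), hom_apply(hom(TPO), p)))
    one <- as.numeric(transform_points(invert_transform(TCP), p))
    expect_equal(one, step, tolerance = 1e-9)
  }
})

test_that("composition is associative and stored rotations stay proper", {
  set.seed(31)
  for (k in 1:10) {
    A <- random_transform("B", "A"); B <- random_transform("C", "B")
    C_ <- random_transform("D", "C")
    lhs <- compose_transforms(compose_transforms(A, B), C_)
    rhs <- compose_transforms(A, compose_transforms(B, C_))
    expect_equal(as.matrix(lhs), as.matrix(rhs), tolerance = 1e-10)
    expect_equal(det(lhs$rotation), 1, tolerance = 1e-9)
  }
})

test_that("rotation converters round-trip and follow their conventions", {
  aa <- rotation_to_axis_angle(diag(3))
  expect_equal(aa, c(0, 0, 0))
  Rz <- axis_angle_to_rotation(c(0, 0, pi / 2))
  expect_equal(as.numeric(Rz %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  set.seed(41)
  for (k in 1:100) {
    R <- random_rotation()
    q <- rotation_to_quaternion(R)
    expect_gte(q[1], 0)
    v <- rotation_to_axis_angle(quaternion_to_rotation(q))
    R2 <- axis_angle_to_rotation(v)
    expect_lt(max(abs(R2 - R)), 1e-10)
  }
  expect_error(rotation_to_quaternion(matrix(2 * diag(3), 3, 3)), "orthonormal")
})

test_that("constructor rejects improper rotations", {
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "determinant")
  M <- diag(3); M[1, 2] <- 1e-6
  expect_error(rigid_transform(M, c(0, 0, 0)), "orthonormal")
})

test_that("frame graph composes along paths and audits redundant edges", {
  set.seed(51)
  T_BA <- random_transform("B", "A")
  T_CB <- random_transform("C", "B")
  g <- frame_graph(list(T_BA, T_CB))
  got <- get_frame_transform(g, "A", "C")
  expect_equal(as.matrix(got), hom(T_BA) %*% hom(T_CB), tolerance = 1e-10)
  # inverse direction comes from the same edges
  back <- get_frame_transform(g, "C", "A")
  expect_equal(as.matrix(back), solve(hom(T_BA) %*% hom(T_CB)), tolerance = 1e-10)
  expect_error(get_frame_transform(g, "A", "Z"), "unknown|no path")
  chk <- check_cycle_consistency(g, compose_transforms(T_BA, T_CB))
  expect_lt(chk$rotation_rad, 1e-10)
  expect_lt(chk$translation_mm, 1e-9)
})

test_that("transform JSON round-trips and the reader validates orthonormality", {
  set.seed(61)
  T_ <- random_transform("M", "O")
  f <- withr::local_tempfile(fileext = ".json")
  write_transform_json(T_, f)
  T2 <- read_transform_json(f)
  expect_equal(as.matrix(T2), as.matrix(T_), tolerance = 1e-12)
  expect_identical(T2$source, "M")
  bad <- jsonlite::read_json(f, simplifyVector = TRUE)
  bad$rotation[1] <- 2
  jsonlite::write_json(bad, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_transform_json(f), "orthonormal")
})
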