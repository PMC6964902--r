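test_that("overlay projection matches the trivial camera-frame case", {
  K <- test_intrinsics()
  st <- data.frame(sphere_id = "S01", x = 0, y = 0, z = 25, diameter_mm = 2)
  ovl <- overlay_structures(st, transform_identity("P", "O"),
                            transform_identity("M", "O"),
                            transform_identity("C", "M"), K)
  expect_equal(ovl$u, K$cx, tolerance = 1e-9)
  expect_equal(ovl$v, K$cy, tolerance = 1e-9)
  st2 <- rbind(st, data.frame(sphere_id = "S02", x = 0, y = 0, z = -5,
                              diameter_mm = 2))
  ovl2 <- overlay_structures(st2, transform_identity("P", "O"),
                             transform_identity("M", "O"),
                             transform_identity("C", "M"), K)
  expect_identical(nrow(ovl2), 1L)
  expect_identical(attr(ovl2, "n_dropped"), 1L)
})

test_that("overlay circles coincide with rendered ground truth in a noiseless scene", {
  proto <- run_accuracy_protocol(distances_mm = c(10, 25), n_positions = 9, seed = 3)
  recs <- evaluate_accuracy(proto)
  # the master zero-noise coincidence, in pixels
  px_err <- sqrt((recs$u_real - recs$u_ovl)^2 + (recs$v_real - recs$v_ovl)^2)
  expect_lt(max(px_err), 1e-6)
  expect_lt(max(recs$tre_mm), 1e-6)
})

test_that("sphere detection recovers rendered circles to sub-0.1 px", {
  K <- test_intrinsics()
  ph <- make_grid_phantom(seed = 2)
  cam <- rigid_transform(diag(3), c(0, 0, 0), "C", "O")
  scene <- scene_state(cam, K,
                       phantom_pose = rigid_transform(diag(3), c(0, 0, 25), "P", "O"))
  r <- render_endoscope_image(scene, ph)
  det <- detect_spheres(r$image)
  expect_identical(nrow(det), 13L)
  gt <- data.frame(sphere_id = r$ground_truth$sphere_id, u = r$ground_truth$u,
                   v = r$ground_truth$v, r_px = r$ground_truth$r_px,
                   source = "overlay", stringsAsFactors = FALSE)
  m <- match_circles(det, gt)
  expect_identical(nrow(m$pairs), 13L)
  expect_lt(max(m$pairs$offset_px), 0.1)
  # radii good to a couple of percent (anti-aliased area estimator)
  rr <- gt$r_px[match(m$pairs$overlay_id, gt$sphere_id)]
  expect_lt(max(abs(m$pairs$diameter_px / 2 - rr) / rr), 0.03)
})

test_that("detection is robust to pixel noise and empty on blank images", {
  blank <- matrix(0, 200, 300)
  expect_identical(nrow(detect_spheres(blank)), 0L)
  K <- test_intrinsics()
  ph <- make_grid_phantom(seed = 2)
  cam <- rigid_transform(diag(3), c(0, 0, 0), "C", "O")
  scene <- scene_state(cam, K, sigma_pixel_px = 2,
                       phantom_pose = rigid_transform(diag(3), c(0, 0, 25), "P", "O"))
  r <- render_endoscope_image(scene, ph, seed = 21)
  det <- detect_spheres(r$image)
  expect_identical(nrow(det), 13L)
  gt <- data.frame(sphere_id = r$ground_truth$sphere_id, u = r$ground_truth$u,
                   v = r$ground_truth$v, r_px = r$ground_truth$r_px,
                   source = "overlay", stringsAsFactors = FALSE)
  m <- match_circles(det, gt)
  expect_lt(max(m$pairs$offset_px), 0.5)
})

test_that("circle matching pairs mutual neighbors and reports strays", {
  a <- data.frame(sphere_id = c("a", "b"), u = c(10, 100), v = c(10, 100),
                  r_px = c(5, 5), source = "real", stringsAsFactors = FALSE)
  m0 <- match_circles(a, transform(a, source = "overlay"))
  expect_identical(nrow(m0$pairs), 2L)
  expect_equal(m0$pairs$offset_px, c(0, 0))
  shifted <- transform(a, u = u + 3, v = v + 4, source = "overlay")
  m1 <- match_circles(a, shifted)
  expect_equal(m1$pairs$offset_px, c(5, 5))
  spurious <- rbind(a, data.frame(sphere_id = "ghost", u = 200, v = 10,
                                  r_px = 5, source = "real"))
  m2 <- match_circles(spurious, transform(a, source = "overlay"))
  expect_identical(nrow(m2$pairs), 2L)
  expect_identical(m2$unpaired_real$sphere_id, "ghost")
  far <- transform(a, u = u + 80, source = "overlay")
  m3 <- match_circles(a, far, max_distance_px = 50)
  expect_identical(nrow(m3$pairs), 0L)
})

test_that("the TRE conversion formula is exact and geometrically consistent", {
  expect_equal(compute_tre(0, 40), 0)
  expect_equal(compute_tre(10, 40, 2), 0.5)
  expect_error(compute_tre(10, 0), "non-positive")
  # a known in-plane 3D offset of the overlay reappears as tre_mm
  K <- test_intrinsics(dist = rep(0, 5))
  d <- 25
  delta <- c(0.3, -0.2, 0)
  st <- data.frame(sphere_id = "S01", x = 2, y = 1, z = d, diameter_mm = 2)
  real <- overlay_structures(st, transform_identity("P", "O"),
                             transform_identity("M", "O"),
                             transform_identity("C", "M"), K)
  st_off <- transform(st, x = x + delta[1], y = y + delta[2])
  ovl <- overlay_structures(st_off, transform_identity("P", "O"),
                            transform_identity("M", "O"),
                            transform_identity("C", "M"), K)
  off_px <- sqrt((real$u - ovl$u)^2 + (real$v - ovl$v)^2)
  tre <- compute_tre(off_px, 2 * real$r_px)
  expect_equal(tre, sqrt(sum(delta^2)), tolerance = 0.02)
})

test_that("TRE summaries report the documented statistics", {
  recs <- data.frame(sphere_id = "s", distance_mm = rep(c(5, 10), each = 4),
                     position_index = 1, u_real = 100, v_real = 100,
                     u_ovl = 100, v_ovl = 100, diameter_px = 40,
                     tre_mm = c(rep(0.5, 4), c(0.2, 0.4, 0.6, 0.8)))
  s <- summarize_tre(recs, test_intrinsics(), heatmap_bins = 4)
  expect_equal(s$overall$mean, mean(recs$tre_mm))
  pd <- s$per_distance
  expect_equal(pd$sd[pd$distance_mm == 5], 0)
  expect_equal(pd$q1[pd$distance_mm == 5], 0.5)
  expect_equal(pd$median[pd$distance_mm == 10], 0.5)
  expect_equal(pd$mean[pd$distance_mm == 10], 0.5)
  expect_equal(pd$q1[pd$distance_mm == 10],
               as.numeric(quantile(c(0.2, 0.4, 0.6, 0.8), 0.25)))
  expect_true(all(pd$q1 <= pd$median & pd$median <= pd$q3))
  # heat map: all records fall into the (1,1) bin; corner bins lie outside
  # the circular endoscopic field; empty valid bins stay NA, not zero
  h <- s$heatmap
  expect_identical(sum(h$count), nrow(recs))
  expect_identical(h$count[1, 1], nrow(recs))
  expect_equal(h$mean_mm[1, 1], mean(recs$tre_mm))
  expect_false(h$valid[1, 1])
  expect_true(h$valid[2, 2])
  expect_true(is.na(h$mean_mm[2, 2]))
})

test_that("one-way ANOVA with Tukey-Kramer behaves on canonical cases", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  out <- anova_tukey(g)
  expect_equal(out$F, 0, tolerance = 1e-12)
  expect_true(all(!out$pairwise$significant))
  # two groups: F equals the square of the pooled t statistic
  set.seed(12)
  x <- rnorm(14); y <- rnorm(11, mean = 0.7)
  out2 <- anova_tukey(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(out2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(out2$p, tt$p.value, tolerance = 1e-9)
  # Tukey-Kramer intervals are centered on the group mean differences
  g3 <- list(a = rnorm(8), b = rnorm(12, 0.5), c = rnorm(6, 1))
  out3 <- anova_tukey(g3)
  ctr <- (out3$pairwise$lwr + out3$pairwise$upr) / 2
  expect_equal(ctr, out3$pairwise$mean_diff, tolerance = 1e-9)
  expect_error(anova_tukey(list(a = 1:3)), "2 groups")
  expect_error(anova_tukey(list(a = 1:3, b = 2)), "at least 2 values")
})

test_that("doubling the sensor resolution leaves tre_mm unchanged", {
  p1 <- run_accuracy_protocol(distances_mm = c(10, 25), n_positions = 9,
                              intrinsics = default_endoscope_intrinsics(0.25),
                              sigma_marker_mm = 0.1, seed = 4)
  p2 <- run_accuracy_protocol(distances_mm = c(10, 25), n_positions = 9,
                              intrinsics = default_endoscope_intrinsics(0.5),
                              sigma_marker_mm = 0.1, seed = 4)
  r1 <- evaluate_accuracy(p1)
  r2 <- evaluate_accuracy(p2)
  expect_identical(nrow(r1), nrow(r2))
  expect_lt(max(abs(r1$tre_mm - r2$tre_mm) / pmax(r1$tre_mm, 1e-9)), 0.01)
  # pixel quantities scale with the sensor
  expect_equal(r2$diameter_px / r1$diameter_px, rep(2, nrow(r1)),
               tolerance = 1e-9)
})
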