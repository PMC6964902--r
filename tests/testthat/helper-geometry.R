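# Shared fixtures: random rigid transforms, a small test-scale endoscope, and
# an independent homogeneous-matrix oracle for the transform algebra.

random_rotation <- function() axis_angle_to_rotation(stats::rnorm(3))

random_transform <- function(source = "src", target = "dst", t_scale = 20) {
  rigid_transform(random_rotation(), stats::rnorm(3, sd = t_scale),
                  source = source, target = target)
}

# independent oracle: plain 4x4 homogeneous matrix product
hom <- function(T_) rbind(cbind(T_$rotation, T_$translation), c(0, 0, 0, 1))
hom_apply <- function(M, p) as.numeric(M %*% c(p, 1))[1:3]

test_intrinsics <- function(dist = c(-0.3, 0.1, 0, 0, 0)) {
  camera_intrinsics(fx = 450, fy = 450, cx = 324, cy = 243,
                    width = 648, height = 486, dist = dist)
}

rot_err <- function(R1, R2) {
  # quaternion route: keeps precision at small angles where acos(trace) floors
  q <- rotation_to_quaternion(crossprod(R1, R2))
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1]))
}

trans_err <- function(T1, T2) sqrt(sum((T1$translation - T2$translation)^2))
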