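test_that("internal-coordinate placement reproduces its bond, angle and dihedral", {
  a <- c(0, 0, 0); b <- c(1.5, 0, 0); c3 <- c(2.1, 1.3, 0.2)
  for (ang in c(60, 109.47, 150)) for (dih in c(-120, 0, 35, 180)) {
    d <- place_atom(a, b, c3, 1.33, ang, dih)
    expect_equal(sqrt(sum((d - c3)^2)), 1.33, tolerance = 1e-9)
    expect_equal(angle_deg(b, c3, d), ang, tolerance = 1e-7)
    got <- dihedral_deg(a, b, c3, d)
    expect_equal(((got - dih + 180) %% 360) - 180, 0, tolerance = 1e-7)
  }
  expect_error(place_atom(a, b, c(3, 0, 0), 1, 109, 0), "collinear")
})

test_that("rigid transforms are rigid, composable and invertible", {
  tr <- rigid_transform(rot_axis_angle(unit_vec_test(c(1, 2, 3)), 73), c(1, -2, 0.5))
  pts <- matrix(rnorm(30, sd = 3), 10, 3)
  moved <- apply_transform(tr, pts)
  expect_equal(as.numeric(dist(moved)), as.numeric(dist(pts)), tolerance = 1e-9)
  expect_equal(apply_transform(transform_identity(), pts), pts)
  expect_equal(apply_transform(rigid_transform(diag(3), c(1, 0, 0)), c(0, 0, 0)),
               c(1, 0, 0))
  back <- transform_compose(transform_inverse(tr), tr)
  expect_equal(back$R, diag(3), tolerance = 1e-9)
  expect_equal(back$t, c(0, 0, 0), tolerance = 1e-9)
  expect_error(rigid_transform(matrix(1:9, 3)), "orthonormal")
})

test_that("superpose_frames recovers known motions and rejects degenerate input", {
  src <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.3, 1.2, 0))
  expect_equal(superpose_frames(src, src)$R, diag(3), tolerance = 1e-9)
  Rz <- rot_axis_angle(c(0, 0, 1), 90)
  dst <- src %*% t(Rz)
  tr <- superpose_frames(src, dst)
  expect_equal(apply_transform(tr, src), dst, tolerance = 1e-6)
  expect_equal(tr$R, Rz, tolerance = 1e-6)
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(superpose_frames(collinear, collinear), "collinear|congruent")
  expect_error(superpose_frames(src, src * 1.4), "congruent")
})

test_that("grid snapping rounds half away from zero and is spacing-checked", {
  expect_identical(snap_to_grid(c(0, 0, 0), 0.2), c(0L, 0L, 0L))
  expect_identical(snap_to_grid(c(0.31, -0.11, 0.50), 0.2), c(2L, -1L, 3L))
  # two points within g/2 of the same node share a key
  expect_identical(snap_to_grid(c(0.19, 0.21, -0.19), 0.2),
                   snap_to_grid(c(0.21, 0.19, -0.21), 0.2))
  expect_error(snap_to_grid(c(0, 0, 0), 0), "positive")
  expect_error(snap_to_grid(c(0, 0, 0), -1), "positive")
})

test_that("hydrogen-bond windows, score ramp and base symmetry behave as specified", {
  p <- hbond_params()
  D <- c(0, 0, 0); H <- c(0.98, 0, 0)
  mkA <- function(d) c(d, 0, 0)
  base_of <- function(A, psi) A + 1.4 * c(cos((180 - psi) * pi / 180),
                                          sin((180 - psi) * pi / 180), 0)
  # ideal geometry: accepted with the minimal (most favourable) score
  ev <- hbond_eval(D, H, mkA(2.8), base_of(mkA(2.8), 120), p)
  expect_true(ev$ok)
  expect_equal(ev$score, -1)
  # outside the distance window
  expect_false(hbond_eval(D, H, mkA(3.5), base_of(mkA(3.5), 120), p)$ok)
  expect_false(hbond_eval(D, H, mkA(2.4), base_of(mkA(2.4), 120), p)$ok)
  # donor angle below theta_min: bend the hydrogen
  Hb <- c(0.98 * cos(pi / 2), 0.98 * sin(pi / 2), 0)  # theta = 90 at H
  A <- mkA(2.8)
  evb <- hbond_eval(D, Hb, A, base_of(A, 120), p)
  expect_false(evb$ok)
  expect_identical(evb$score, 0)
  # score vanishes on the distance boundary and is continuous inside
  s_edge <- hbond_eval(D, H, mkA(3.2), base_of(mkA(3.2), 120), p)$score
  expect_equal(s_edge, 0, tolerance = 1e-12)
  s_near <- hbond_eval(D, H, mkA(3.199), base_of(mkA(3.199), 120), p)$score
  expect_lt(abs(s_near), 0.02)
  expect_lt(s_near, 0)
  # symmetric under relabeling of equivalent bases (best base is used)
  A <- mkA(2.8)
  b_good <- base_of(A, 150); b_bad <- A + 1.4 * c(-1, 0.05, 0)
  ev1 <- hbond_eval(D, H, A, rbind(b_good, b_bad), p)
  ev2 <- hbond_eval(D, H, A, rbind(b_bad, b_good), p)
  expect_equal(ev1, ev2)
  # overlapping atoms: error by default, rejectable for bulk scans
  expect_error(hbond_eval(D, H, c(0.2, 0, 0), c(1, 1, 1), p), "overlapping")
  expect_false(hbond_eval(D, H, c(0.2, 0, 0), c(1, 1, 1), p, overlap = "reject")$ok)
})

test_that("hbond_params validates its window ordering", {
  expect_error(hbond_params(d_min = 3.0, ideal_d = 2.8), "d_min")
  expect_silent(hbond_params(d_min = 2.4, d_max = 3.6))
})
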