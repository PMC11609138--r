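test_that("landmarks follow the clinical definitions", {
  # single 15 mm root: RC at the 1/3 root level, 5 mm apical of the cervix
  cfg <- dentition_config(root_lengths = c(13, 13, 16, 15, 14, 12, 11))
  den <- generate_quadrant(cfg)
  t4 <- den$teeth[[4]]
  lm <- tooth_landmarks(t4)
  cervix_z <- t4$crown_height
  expect_equal(lm$rc_body[3] - cervix_z, 5, tolerance = 1e-12)
  expect_equal(lm$rp_body[3] - cervix_z, 15, tolerance = 1e-12)

  # three-rooted molar: RP is the arithmetic midpoint of the apexes, RC sits
  # 1 mm apical of the furcation (itself 3 mm apical of the cervix)
  t6 <- den$teeth[[6]]
  lm6 <- tooth_landmarks(t6)
  apexes <- t(vapply(t6$surfaces[-1],
                     function(s) s$base + s$axis * s$length, numeric(3)))
  expect_equal(lm6$rp_body, colMeans(apexes), tolerance = 1e-12)
  expect_equal(lm6$rc_body[3], t6$crown_height + 3 + 1, tolerance = 1e-12)

  # symmetric teeth: CP, RP, RC collinear on the long axis
  for (t in den$teeth) {
    l <- tooth_landmarks(t)
    expect_lt(max(abs(l$cp_body[1:2])), 1e-9)
    expect_lt(max(abs(l$rp_body[1:2])), 1e-9)
    expect_lt(max(abs(l$rc_body[1:2])), 1e-9)
    expect_equal(l$la_body, c(0, 0, 1), tolerance = 1e-12)
  }
})

test_that("local frames are right-handed orthonormal with the global Z", {
  den <- default_dentition()
  for (t in den$teeth) {
    fr <- build_local_frame(t, den$arch)
    B <- cbind(fr$X, fr$Y, fr$Z)
    expect_lt(max(abs(t(B) %*% B - diag(3))), 1e-9)
    expect_equal(det(B), 1, tolerance = 1e-9)
    expect_identical(fr$Z, c(0, 0, 1))
  }
  # the incisor's mesio-distal axis is perpendicular to the median plane
  fr1 <- build_local_frame(den$teeth[[1]], den$arch)
  expect_equal(abs(fr1$X[1]), 1, tolerance = 1e-3)
})

test_that("motion decomposition honours the reporting sign conventions", {
  den <- default_dentition()
  t5 <- den$teeth[[5]]
  fr <- build_local_frame(t5, den$arch)
  lm <- tooth_landmarks(t5)
  pose <- t5$current_pose

  r0 <- decompose_motion(pose, pose, fr, lm)
  expect_equal(max(abs(as.numeric(r0))), 0, tolerance = 1e-15)

  # pure 2 mm distal translation: md = -2.0, everything else 0
  p_d <- pose
  p_d[1:3, 4] <- pose[1:3, 4] - 2.0 * fr$X
  rd <- decompose_motion(pose, p_d, fr, lm)
  expect_equal(rd$md_displacement, -2.0, tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(rd)[-1])), 1e-12)

  # +4 degrees about the local Y axis tips the crown distally: tipping = +4
  phi <- fr$Y * (4 * pi / 180)
  p_r <- alignersim:::rt_apply_twist(pose, c(0, 0, 0, phi),
                                     alignersim:::rt_apply(pose, lm$cp_body))
  rr <- decompose_motion(pose, p_r, fr, lm)
  expect_equal(rr$md_tipping, 4.0, tolerance = 1e-9)
  expect_lt(abs(rr$md_displacement), 1e-9) # CP is the rotation point here
  # geometric check: a point apical of CP (toward the root) moves mesially,
  # so the crown (occlusal side) tips distally
  apical_pt <- alignersim:::rt_apply(pose, c(0, 0, 5))
  moved <- alignersim:::rt_apply(p_r %*% alignersim:::rt_inverse(pose),
                                 apical_pt)
  expect_gt(sum((moved - apical_pt) * fr$X), 0)

  # rotations above the small-angle range are rejected
  phi_big <- fr$Y * (35 * pi / 180)
  p_big <- alignersim:::rt_apply_twist(pose, c(0, 0, 0, phi_big),
                                       alignersim:::rt_apply(pose, lm$cp_body))
  expect_error(decompose_motion(pose, p_big, fr, lm), "30 degrees")
})

test_that("compose/decompose round-trip for angles up to 6 degrees", {
  den <- default_dentition()
  t3 <- den$teeth[[3]]
  fr <- build_local_frame(t3, den$arch)
  lm <- tooth_landmarks(t3)
  pose <- t3$current_pose
  set.seed(21)
  for (rep in 1:10) {
    ang <- runif(1, 0, 6) * pi / 180
    phi <- alignersim:::unit3(rnorm(3)) * ang
    tw <- c(rnorm(3) * 0.5, phi)
    p2 <- alignersim:::rt_apply_twist(pose, tw,
                                      alignersim:::rt_apply(pose, lm$cp_body))
    rec <- decompose_motion(pose, p2, fr, lm)
    p2_re <- recompose_motion(rec, pose, fr, lm)
    expect_lt(max(abs(p2_re - p2)), 1e-9)
  }
})

test_that("records are frame equivariant, additive for translations and
           antisymmetric", {
  den <- default_dentition()
  t2 <- den$teeth[[2]]
  fr <- build_local_frame(t2, den$arch)
  lm <- tooth_landmarks(t2)
  pose <- t2$current_pose
  tw <- c(0.4, -0.2, 0.3, 0.01, 0.02, -0.015)
  p2 <- alignersim:::rt_apply_twist(pose, tw,
                                    alignersim:::rt_apply(pose, lm$cp_body))

  # rotate the whole scene (poses and frame together): record unchanged
  Q <- alignersim:::rt_make(alignersim:::rot_exp(c(0.3, -0.2, 0.5)),
                            c(5, -3, 2))
  fr_rot <- list(origin = alignersim:::rt_apply(Q, fr$origin),
                 X = alignersim:::rt_apply_vec(Q, fr$X),
                 Y = alignersim:::rt_apply_vec(Q, fr$Y),
                 Z = alignersim:::rt_apply_vec(Q, fr$Z))
  r1 <- decompose_motion(pose, p2, fr, lm)
  r2 <- decompose_motion(Q %*% pose, Q %*% p2, fr_rot, lm)
  expect_equal(as.numeric(r1), as.numeric(r2), tolerance = 1e-9)

  # translations add exactly
  pa <- pose; pa[1:3, 4] <- pa[1:3, 4] + c(0.3, 0.1, -0.2)
  pb <- pa; pb[1:3, 4] <- pb[1:3, 4] + c(-0.1, 0.4, 0.25)
  ra <- decompose_motion(pose, pa, fr, lm)
  rb <- decompose_motion(pa, pb, fr, lm)
  rab <- decompose_motion(pose, pb, fr, lm)
  expect_equal(as.numeric(ra)[1:3] + as.numeric(rb)[1:3],
               as.numeric(rab)[1:3], tolerance = 1e-12)

  # antisymmetry (exact for translations, first order for rotations)
  fwd <- decompose_motion(pose, p2, fr, lm)
  bwd <- decompose_motion(p2, pose, fr, lm)
  expect_equal(as.numeric(fwd)[4:6], -as.numeric(bwd)[4:6], tolerance = 1e-3)
  expect_equal(as.numeric(fwd)[1:3], -as.numeric(bwd)[1:3], tolerance = 1e-9)
})
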