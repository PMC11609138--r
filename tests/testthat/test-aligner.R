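test_that("trim designs set walls and half-wrap scales", {
  den <- default_dentition()
  con <- build_aligner(den, "con")
  expect_true(all(vapply(con$sockets, `[[`, logical(1), "has_mesial_wall")))
  expect_true(all(vapply(con$sockets, `[[`, logical(1), "has_distal_wall")))
  expect_true(all(vapply(con$sockets, `[[`, numeric(1),
                         "stiffness_scale") == 1))

  smhw <- build_aligner(den, "smhw")
  expect_false(smhw$sockets[[7]]$has_distal_wall)
  expect_equal(smhw$sockets[[7]]$stiffness_scale, 0.5)
  for (i in 1:6) {
    expect_true(smhw$sockets[[i]]$has_distal_wall)
    expect_equal(smhw$sockets[[i]]$stiffness_scale, 1.0)
  }

  mhw <- build_aligner(den, "mhw")
  expect_false(mhw$sockets[[6]]$has_distal_wall)
  expect_false(mhw$sockets[[7]]$has_distal_wall)
  expect_equal(mhw$sockets[[6]]$stiffness_scale, 0.5)
  expect_equal(mhw$sockets[[7]]$stiffness_scale, 0.5)
  expect_true(all(vapply(mhw$sockets, `[[`, logical(1), "has_mesial_wall")))

  expect_error(build_aligner(den, "open-bite"))
})

test_that("staging shortens span (5,6) and lengthens span (3,4) by the
           increment", {
  den <- default_dentition()
  alg <- build_aligner(den, "con")
  plan <- staging_plan()
  span56_0 <- alignersim:::socket_span(alg, 5, 6)
  span34_0 <- alignersim:::socket_span(alg, 3, 4)

  # spans are measured along the mean mesio-distal direction of the pair;
  # the increment is exact along each socket's own axis (checked below), so
  # the span change agrees with the increment up to the small angle between
  # adjacent socket axes on the curved arch (< 0.3%)
  a1 <- apply_staging(alg, plan, 1)
  expect_equal(alignersim:::socket_span(a1, 5, 6) - span56_0, -0.20,
               tolerance = 0.003)
  expect_equal(alignersim:::socket_span(a1, 3, 4) - span34_0, +0.20,
               tolerance = 0.015)

  a10 <- apply_staging(alg, plan, 10)
  expect_equal(alignersim:::socket_span(a10, 5, 6) - span56_0, -2.0,
               tolerance = 0.003)
  expect_equal(alignersim:::socket_span(a10, 3, 4) - span34_0, +2.0,
               tolerance = 0.015)

  # staging is purely mesio-distal: no vertical or bucco-lingual component
  d <- a1$sockets[[5]]$rest_pose[1:3, 4] - alg$sockets[[5]]$rest_pose[1:3, 4]
  ax <- alg$sockets[[5]]$axes
  expect_equal(abs(sum(d * ax[, 1])), 0.2, tolerance = 1e-12)
  expect_lt(abs(sum(d * ax[, 2])), 1e-12)
  expect_lt(abs(sum(d * ax[, 3])), 1e-12)

  # step 0 is the identity; staging is absolute (linear in the step index)
  a0 <- apply_staging(a10, plan, 0)
  for (i in 1:7) {
    expect_equal(a0$sockets[[i]]$rest_pose, alg$sockets[[i]]$rest_pose,
                 tolerance = 1e-15)
  }
  a7a <- apply_staging(apply_staging(alg, plan, 3), plan, 7)
  a7b <- apply_staging(alg, plan, 7)
  for (i in 1:7) {
    expect_equal(a7a$sockets[[i]]$rest_pose, a7b$sockets[[i]]$rest_pose,
                 tolerance = 1e-15)
  }
  expect_error(apply_staging(alg, plan, -1), "negative")
})

test_that("temperature-changing-method bookkeeping", {
  expect_equal(tcm_temperature(U = 0.2, delta = 0, k = 0.01, d = 2), 10)
  # cross-check the linear relation: k * d * t recovers U - delta
  expect_equal(0.01 * 2 * tcm_temperature(0.2, 0, 0.01, 2), 0.2)
  expect_equal(tcm_temperature(0.5, 0.5, 0.01, 2), 0)
  expect_lt(tcm_temperature(0.1, 0.3, 0.01, 2), 0)
  expect_error(tcm_temperature(0.2, 0, 0, 2), "> 0")
})

test_that("socket wrench: bilinear wrap, unilateral walls, third law", {
  den <- default_dentition()
  alg <- build_aligner(den, "con")
  s5 <- alg$sockets[[5]]
  pose <- den$teeth[[5]]$current_pose

  # tooth exactly at the socket rest pose: no wrench
  w0 <- socket_wrench(s5, pose, diag(4))
  expect_lt(max(abs(w0$wrench_on_tooth)), 1e-9)

  # socket 0.1 mm mesial of the tooth with a 100 N/mm distal wall:
  # 10 N mesially-directed force on the tooth (wall in compression)
  s_manual <- s5
  s_manual$k_wall <- 100
  s_manual$rest_pose <- s5$rest_pose
  s_manual$rest_pose[1:3, 4] <- s5$rest_pose[1:3, 4] + 0.1 * s5$axes[, 1]
  w <- socket_wrench(s_manual, pose, diag(4))
  expect_equal(w$md_force, 10, tolerance = 1e-9)
  expect_true(w$md_active)

  # same mismatch with the distal wall absent: mesio-distal force vanishes
  s_cut <- s_manual
  s_cut$has_distal_wall <- FALSE
  w_cut <- socket_wrench(s_cut, pose, diag(4))
  expect_identical(w_cut$md_force, 0)
  expect_false(w_cut$md_active)

  # action-reaction holds exactly for arbitrary mismatches
  set.seed(5)
  for (rep in 1:5) {
    p2 <- alignersim:::rt_apply_twist(pose, rnorm(6) * 0.05,
                                      alignersim:::rt_apply(pose, s5$ref_body))
    w2 <- socket_wrench(s5, p2, diag(4))
    expect_identical(w2$wrench_on_tooth + w2$wrench_on_aligner, numeric(6))
  }
})

test_that("no wall ever pulls: unilaterality over random mismatches", {
  den <- default_dentition()
  mhw <- build_aligner(den, "mhw")
  set.seed(9)
  for (i in c(6, 7)) {
    s <- mhw$sockets[[i]]
    pose <- den$teeth[[i]]$current_pose
    for (rep in 1:20) {
      p2 <- alignersim:::rt_apply_twist(
        pose, rnorm(6) * 0.1, alignersim:::rt_apply(pose, s$ref_body))
      w <- socket_wrench(s, p2, diag(4))
      # distal wall is absent: the mesio-distal force can push distally
      # (negative) but never mesially
      expect_lte(w$md_force, 1e-12)
    }
  }
})

test_that("aligner serializes to JSON", {
  den <- default_dentition()
  alg <- apply_staging(build_aligner(den, "smhw"), staging_plan(), 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_aligner_json(alg, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$design, "smhw")
  expect_equal(j$staging_step, 2)
  expect_false(j$sockets$has_distal_wall[7])
})
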