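test_that("default quadrant leaves a 2 mm space between positions 5 and 6", {
  den <- default_dentition()
  expect_equal(gap_premolar_molar(den), 2.0, tolerance = 0.01)
  # all other adjacent pairs are in contact
  for (i in c(1:4, 6)) {
    expect_lt(alignersim:::contact_gap(den, i), 0.01)
  }
})

test_that("generator is deterministic and honours a degenerate gap", {
  d1 <- generate_quadrant(dentition_config(seed = 7))
  d2 <- generate_quadrant(dentition_config(seed = 7))
  for (i in 1:7) {
    expect_identical(d1$teeth[[i]]$stress_free_pose,
                     d2$teeth[[i]]$stress_free_pose)
    expect_identical(d1$teeth[[i]]$contact_mesial_body,
                     d2$teeth[[i]]$contact_mesial_body)
  }
  expect_identical(d1$tad$location, d2$tad$location)
  # jitter is seed-deterministic too
  j1 <- generate_quadrant(dentition_config(seed = 3, jitter_sd = 0.05))
  j2 <- generate_quadrant(dentition_config(seed = 3, jitter_sd = 0.05))
  expect_identical(j1$teeth[[4]]$stress_free_pose,
                   j2$teeth[[4]]$stress_free_pose)

  d0 <- generate_quadrant(dentition_config(gap_premolar2_molar1 = 0))
  expect_lte(abs(gap_premolar_molar(d0)), 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(dentition_config(crown_widths = rep(-1, 7)), "positive")
  expect_error(dentition_config(gap_premolar2_molar1 = -0.5), ">= 0")
  expect_error(dentition_config(crown_widths = 1:6), "length 7")
  expect_error(dentition_config(pdl_thickness = 0), "positive")
  expect_error(dentition_config(root_count = c(1, 1, 1, 1, 1, 2, 3)),
               "1 or 3")
})

test_that("arch placement is mesio-distally monotone and midline-anchored", {
  den <- default_dentition()
  s <- vapply(den$teeth, `[[`, numeric(1), "arc_s")
  expect_true(all(diff(s) > 0))
  # mesial contact face of the central incisor sits on the median plane
  cm <- alignersim:::world_contact(den$teeth[[1]], "mesial")
  expect_lt(abs(cm[1]), 0.05)
  # occlusal plane is z = 0: crown points at z = 0
  for (t in den$teeth) {
    cp <- alignersim:::rt_apply(t$current_pose, t$cp_body)
    expect_equal(cp[3], 0, tolerance = 1e-9)
  }
})

test_that("root-surface sampling matches the closed-form cone area", {
  tooth <- bare_cone_tooth(length = 13, r_base = 3)
  s <- sample_root_surface(tooth, 500, frame = "body")
  analytic <- pi * 3 * sqrt(13^2 + 3^2)
  expect_equal(sum(s$area), analytic, tolerance = 0.02 * analytic)
  expect_lt(max(abs(sqrt(s$nx^2 + s$ny^2 + s$nz^2) - 1)), 1e-9)
  expect_true(all(s$area > 0))
  # refinement stability: doubling the count changes the total by < 1%
  s2 <- sample_root_surface(tooth, 1000, frame = "body")
  expect_lt(abs(sum(s2$area) - sum(s$area)) / sum(s$area), 0.01)
  expect_error(alignersim:::frustum(c(0, 0, 0), c(0, 0, 1), 0, 1, 0),
               "degenerate")
})

test_that("tributary areas are pose-invariant under rigid updates", {
  den <- default_dentition()
  tooth <- den$teeth[[5]]
  a0 <- sample_root_surface(tooth, 300, frame = "world")$area
  tooth$current_pose <- alignersim:::rt_apply_twist(
    tooth$current_pose, c(0.5, -0.3, 0.2, 0.05, 0.02, -0.04), c(0, 0, 0))
  a1 <- sample_root_surface(tooth, 300, frame = "world")$area
  expect_identical(a0, a1)
})

test_that("sampled areas of the default dentition match the configured
           attachment areas", {
  cfg <- dentition_config()
  den <- generate_quadrant(cfg)
  for (i in c(1, 4, 6)) {
    s <- sample_root_surface(den$teeth[[i]], 400, frame = "body")
    expect_equal(sum(s$area), cfg$root_surface_areas[i],
                 tolerance = 1e-6 * cfg$root_surface_areas[i])
  }
})

test_that("TAD sits 4 mm above the crest, buccally, between the molar roots", {
  den <- default_dentition()
  tad <- den$tad
  expect_equal(tad$location[3] - den$crest_z, 4.0, tolerance = 1e-9)
  expect_gt(tad$arc_s, den$teeth[[6]]$arc_s)
  expect_lt(tad$arc_s, den$teeth[[7]]$arc_s)
  # buccal of the arch curve: farther from the arch than the on-curve point
  on_curve <- as.numeric(den$arch$point(tad$arc_s))
  lingual <- alignersim:::cross3(c(0, 0, 1),
                                 -as.numeric(den$arch$tangent(tad$arc_s)))
  expect_gt(sum((tad$location - on_curve) * (-lingual)), 0)
})

test_that("scene export writes PLY meshes and a landmark JSON", {
  den <- default_dentition()
  dir <- withr::local_tempdir()
  files <- export_scene(den, dir)
  expect_length(files, 8) # 7 teeth + landmarks.json
  expect_true(all(file.exists(files)))
  ply1 <- readLines(files[1], n = 2)
  expect_identical(ply1, c("ply", "format ascii 1.0"))
  lm <- jsonlite::read_json(file.path(dir, "landmarks.json"),
                            simplifyVector = TRUE)
  expect_length(lm$teeth$position, 7)
})
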