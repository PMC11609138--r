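test_that("foundation moduli reproduce the thin-layer closed forms", {
  # hand arithmetic: 0.67 * 0.55 / (1.45 * 0.10 * 0.30) = 8.4713...
  fm <- foundation_moduli(material(0.67, 0.45), 0.30)
  expect_equal(fm$k_normal, 0.67 * (1 - 0.45) / (1.45 * 0.1 * 0.3),
               tolerance = 1e-12)
  expect_equal(fm$k_normal, 8.47, tolerance = 1e-3 * 8.47)
  expect_equal(fm$k_tangential, 0.770, tolerance = 1e-3 * 0.770)
  # nu = 0 collapses the confined modulus to E/t
  fm0 <- foundation_moduli(material(2.0, 0), 0.5)
  expect_equal(fm0$k_normal, 2.0 / 0.5, tolerance = 1e-12)
  # 1/t scaling
  fm2 <- foundation_moduli(material(0.67, 0.45), 0.60)
  expect_equal(fm2$k_normal, fm$k_normal / 2, tolerance = 1e-12)
  expect_equal(fm2$k_tangential, fm$k_tangential / 2, tolerance = 1e-12)
  expect_error(material(0.67, 0.5), "incompressible")
  expect_error(foundation_moduli(material(1, 0.3), 0), "thickness")
})

test_that("assembled stiffness is symmetric PSD with the single-spring
           spectrum", {
  fm <- foundation_moduli(material(0.67, 0.45), 0.30)
  one <- tibble::tibble(px = 1, py = 2, pz = 3,
                        nx = 0.6, ny = 0.8, nz = 0, area = 2.5)
  K <- assemble_stiffness(one, fm, c(1, 2, 3)) # reference at the sample
  expect_lt(max(abs(K$matrix - t(K$matrix))) / max(abs(K$matrix)), 1e-12)
  ev <- sort(eigen(K$matrix[1:3, 1:3], symmetric = TRUE)$values)
  expect_equal(ev, 2.5 * c(fm$k_tangential, fm$k_tangential, fm$k_normal),
               tolerance = 1e-9)
  expect_error(assemble_stiffness(dplyr::mutate(one, area = 0), fm, c(0, 0, 0)),
               "area")
})

test_that("assembled stiffness matches the energy-Hessian oracle", {
  fm <- foundation_moduli(material(0.67, 0.45), 0.30)
  tooth <- bare_cone_tooth(length = 13, r_base = 3)
  s <- sample_root_surface(tooth, 2000, frame = "body")
  ref <- c(0.5, -0.2, 10) # deliberately off-axis
  K <- assemble_stiffness(s, fm, ref)$matrix
  H <- energy_hessian(s, fm, ref)
  expect_lt(max(abs(H - K)) / max(abs(K)), 1e-4)
})

test_that("stiffness converges under mesh refinement and shifts congruently", {
  fm <- foundation_moduli(material(0.67, 0.45), 0.30)
  tooth <- bare_cone_tooth()
  K1 <- assemble_stiffness(sample_root_surface(tooth, 1000, frame = "body"),
                           fm, c(0, 0, 0))$matrix
  K2 <- assemble_stiffness(sample_root_surface(tooth, 2000, frame = "body"),
                           fm, c(0, 0, 0))$matrix
  expect_lt(max(abs(K2 - K1)) / max(abs(K1)), 0.01)

  K <- assemble_stiffness(sample_root_surface(tooth, 500, frame = "body"),
                          fm, c(0, 0, 0))
  ref2 <- c(2, -1, 4)
  K_shifted <- shift_reference(K, ref2)
  K_direct <- assemble_stiffness(K$samples, fm, ref2)
  expect_lt(max(abs(K_shifted$matrix - K_direct$matrix)) /
              max(abs(K_direct$matrix)), 1e-12)
})

test_that("energy consistency: quadratic form equals summed spring energy", {
  fm <- foundation_moduli(material(0.67, 0.45), 0.30)
  tooth <- bare_cone_tooth()
  s <- sample_root_surface(tooth, 300, frame = "body")
  ref <- c(0, 0, 8)
  K <- assemble_stiffness(s, fm, ref)$matrix
  P <- as.matrix(s[, c("px", "py", "pz")])
  N <- as.matrix(s[, c("nx", "ny", "nz")])
  D <- sweep(P, 2, ref)
  set.seed(11)
  for (rep in 1:5) {
    tw <- rnorm(6) * 0.1
    eq <- 0.5 * sum(tw * (K %*% tw))
    # independent per-spring summation under the rigid point-velocity map
    U <- matrix(tw[1:3], nrow(P), 3, byrow = TRUE) +
      alignersim:::cross_rows(matrix(tw[4:6], nrow(P), 3, byrow = TRUE), D)
    un <- rowSums(U * N)
    e_springs <- 0.5 * sum(s$area * (fm$k_normal * un^2 +
                                       fm$k_tangential *
                                         (rowSums(U^2) - un^2)))
    expect_equal(e_springs, eq, tolerance = 1e-9 * eq)
  }
})

test_that("resistance center of an axisymmetric root lies on the axis and is
           frame independent", {
  fm <- foundation_moduli(material(0.67, 0.45), 0.30)
  tooth <- bare_cone_tooth(length = 14, r_base = 3, cervix = 8)
  s <- sample_root_surface(tooth, 2000, frame = "body")
  K <- assemble_stiffness(s, fm, c(0, 0, 0))
  rc <- resistance_center(K)
  expect_lt(max(abs(rc[1:2])), 1e-6)

  # brute-force oracle: minimize the coupling norm along the axis
  coupling <- function(z) {
    Ks <- shift_reference(K, c(0, 0, z))$matrix
    sqrt(sum(Ks[1:3, 4:6]^2))
  }
  zgrid <- seq(8, 22, by = 0.25)
  z0 <- zgrid[which.min(vapply(zgrid, coupling, numeric(1)))]
  zopt <- stats::optimize(coupling, c(z0 - 0.5, z0 + 0.5), tol = 1e-9)$minimum
  expect_equal(rc[3], zopt, tolerance = 1e-5)
  # residual coupling at the optimum vanishes for the axisymmetric support
  expect_lt(coupling(rc[3]) / max(abs(K$matrix)), 1e-6)

  # invariance under a change of assembly reference point
  K2 <- assemble_stiffness(s, fm, c(3, -2, 5))
  expect_lt(max(abs(resistance_center(K2) - rc)), 1e-9)

  # a force through the RC produces translation without rotation
  Krc <- shift_reference(K, rc)
  for (f in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    tw <- respond(Krc, c(f, 0, 0, 0))
    expect_lt(sqrt(sum(tw[4:6]^2)), 1e-8)
  }
})

test_that("respond is linear and reports singularity; strain of zero twist is
           zero", {
  fm <- foundation_moduli(material(0.67, 0.45), 0.30)
  tooth <- bare_cone_tooth()
  s <- sample_root_surface(tooth, 400, frame = "body")
  K <- assemble_stiffness(s, fm, c(0, 0, 10))
  W <- c(1, 0.5, -0.2, 3, -1, 0.7)
  expect_equal(respond(K, 2 * W), 2 * respond(K, W), tolerance = 1e-12)
  expect_equal(respond(K, numeric(6)), numeric(6), tolerance = 1e-15)

  st <- strain_and_traction(s, numeric(6), fm, c(0, 0, 10))
  expect_identical(st$max_strain_fraction, 0)

  # one spring at the reference point cannot resist rotation about its normal
  one <- tibble::tibble(px = 0, py = 0, pz = 0, nx = 0, ny = 0, nz = 1,
                        area = 1)
  K1 <- assemble_stiffness(one, fm, c(0, 0, 0))
  expect_error(respond(K1, c(0, 0, 1, 0, 0, 0)), "singular|rank")
})

test_that("spring-field CSV round-trips", {
  tooth <- bare_cone_tooth()
  s <- sample_root_surface(tooth, 100, frame = "body")
  f <- withr::local_tempfile(fileext = ".csv")
  write_spring_field(s, f)
  s2 <- read_spring_field(f)
  expect_equal(as.data.frame(s2), as.data.frame(s), tolerance = 1e-12)
})
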