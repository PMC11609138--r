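# Periodontal ligament as a linear elastic spring foundation (Winkler
# reduction of a thin elastic layer): confined modulus normal to the root
# surface, shear modulus tangential. Assembles the 6x6 rigid-body support
# stiffness of a tooth about a reference point.

#' Linear elastic material properties
#'
#' @param elastic_modulus Young's modulus E, MPa.
#' @param poisson_ratio Poisson's ratio (0 <= nu < 0.5).
#' @return object of class `material`.
#' @export
#' @examples
#' pdl <- material(0.67, 0.45)     # periodontal ligament
#' ca  <- material(1500, 0.30)     # clear-aligner thermoplastic
material <- function(elastic_modulus, poisson_ratio) {
  if (elastic_modulus <= 0) stop("E must be > 0", call. = FALSE)
  if (poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop("poisson_ratio must be in [0, 0.5); the incompressible limit ",
         "nu = 0.5 makes the confined modulus diverge", call. = FALSE)
  }
  structure(list(elastic_modulus = elastic_modulus,
                 poisson_ratio = poisson_ratio), class = "material")
}

#' Default material set
#'
#' Periodontal ligament E = 0.67 MPa, nu = 0.45; clear aligner E = 1500 MPa,
#' nu = 0.30; attachment resin E = 20000 MPa, nu = 0.30.
#' @return named list of [material()] objects.
#' @export
default_materials <- function() {
  list(pdl = material(0.67, 0.45),
       aligner = material(1500, 0.30),
       attachment = material(20000, 0.30))
}

#' Foundation moduli of a thin elastic layer
#'
#' Winkler (thin-layer) reduction of an elastic layer of the given thickness
#' bonded to rigid bone: the normal stiffness per unit area is the confined
#' (oedometric) modulus over the thickness,
#' `k_n = E (1 - nu) / ((1 + nu) (1 - 2 nu) t)`, and the tangential
#' stiffness per unit area is the shear modulus over the thickness,
#' `k_t = E / (2 (1 + nu) t)`.
#'
#' @param mat a [material()].
#' @param thickness layer thickness, mm.
#' @return object of class `foundation_moduli` with `k_normal`,
#'   `k_tangential` (N/mm^3) and `thickness` (mm).
#' @export
#' @examples
#' foundation_moduli(material(0.67, 0.45), 0.30)
foundation_moduli <- function(mat, thickness) {
  stopifnot(inherits(mat, "material"))
  if (thickness <= 0) stop("thickness must be > 0", call. = FALSE)
  E <- mat$elastic_modulus
  nu <- mat$poisson_ratio
  k_n <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu) * thickness)
  k_t <- E / (2 * (1 + nu) * thickness)
  structure(list(k_normal = k_n, k_tangential = k_t, thickness = thickness),
            class = "foundation_moduli")
}

#' Assemble the 6x6 rigid-body support stiffness from a spring field
#'
#' Each sample contributes `area * (k_n n n' + k_t (I - n n'))` acting at its
#' point; the rigid-body point-velocity map `J = [I, -skew(p - ref)]`
#' congruence-assembles these into the symmetric positive-semidefinite 6x6
#' operator `K = sum(J' k J)` about `reference_point`. Twist ordering is
#' `(v, omega)`; units N/mm, N, N*mm.
#'
#' @param samples spring-field tibble as from [sample_root_surface()].
#' @param moduli a [foundation_moduli()].
#' @param reference_point 3-vector, mm.
#' @return object of class `support_stiffness` with fields `matrix`,
#'   `reference_point`, `moduli` and the `samples` used.
#' @export
assemble_stiffness <- function(samples, moduli, reference_point) {
  stopifnot(inherits(moduli, "foundation_moduli"))
  if (nrow(samples) < 1) stop("need at least one sample", call. = FALSE)
  if (any(samples$area <= 0)) {
    stop("zero or negative tributary areas rejected", call. = FALSE)
  }
  P <- as.matrix(samples[, c("px", "py", "pz")])
  N <- as.matrix(samples[, c("nx", "ny", "nz")])
  a <- samples$area
  kn <- moduli$k_normal
  kt <- moduli$k_tangential
  D <- sweep(P, 2, reference_point) # p - ref
  C <- cross_rows(D, N)             # d x n
  dk <- kn - kt
  sa <- sum(a)
  K_tt <- kt * sa * diag(3) + dk * crossprod(N * sqrt(a))
  K_tr <- -kt * skew(colSums(D * a)) + dk * t(N * a) %*% C
  K_rr <- kt * (sum(a * rowSums(D^2)) * diag(3) - t(D * a) %*% D) +
    dk * crossprod(C * sqrt(a))
  K <- rbind(cbind(K_tt, K_tr), cbind(t(K_tr), K_rr))
  K <- (K + t(K)) / 2
  structure(list(matrix = K, reference_point = reference_point,
                 moduli = moduli, samples = samples),
            class = "support_stiffness")
}

#' Shift the reference point of a support stiffness
#'
#' Exact congruence transform `K(new) = T' K(old) T` with the rigid twist
#' transport between the two reference points.
#'
#' @param K a `support_stiffness`.
#' @param new_reference 3-vector, mm.
#' @return a `support_stiffness` about `new_reference`.
#' @export
shift_reference <- function(K, new_reference) {
  Tm <- twist_transport(K$reference_point, new_reference)
  structure(list(matrix = t(Tm) %*% K$matrix %*% Tm,
                 reference_point = new_reference,
                 moduli = K$moduli, samples = K$samples),
            class = "support_stiffness")
}

#' Center of resistance of a supported tooth
#'
#' The point about which the translation-rotation coupling block of the
#' support stiffness is smallest (Frobenius norm); for an axisymmetric
#' support the residual coupling vanishes and a force through this point
#' produces pure translation. Solved in closed form as a linear least-squares
#' problem in the shift vector.
#'
#' @param K a `support_stiffness` (full rank).
#' @return 3-vector, mm (world coordinates).
#' @export
resistance_center <- function(K) {
  M <- K$matrix
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-9 * max(ev)) {
    vec <- eigen(M, symmetric = TRUE)$vectors[, 6]
    stop(sprintf(
      "support stiffness is rank deficient; unconstrained twist direction (%s)",
      paste(sprintf("%.3f", vec), collapse = ", ")), call. = FALSE)
  }
  K_tt <- M[1:3, 1:3]
  K_tr <- M[1:3, 4:6]
  # coupling after shifting the reference by c: C(c) = K_tt skew(c) + K_tr
  G <- list(skew(c(1, 0, 0)), skew(c(0, 1, 0)), skew(c(0, 0, 1)))
  A <- vapply(G, function(g) as.numeric(K_tt %*% g), numeric(9))
  cvec <- solve(crossprod(A), -crossprod(A, as.numeric(K_tr)))
  K$reference_point + as.numeric(cvec)
}

#' Quasi-static twist response to an applied wrench
#'
#' Small-displacement solve `twist = K^-1 wrench` about the stiffness
#' reference point. A singular stiffness is reported, not regularized.
#'
#' @param K a `support_stiffness`.
#' @param wrench length-6 `c(F, M)` about `K$reference_point`, N and N*mm.
#' @return length-6 twist `c(v, omega)`, mm and rad.
#' @export
respond <- function(K, wrench) {
  stopifnot(length(wrench) == 6)
  ev <- eigen(K$matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(ev)) {
    stop("singular support stiffness; cannot respond", call. = FALSE)
  }
  as.numeric(solve(K$matrix, wrench))
}

#' Per-spring strain and traction under a rigid twist
#'
#' Displaces every spring sample by the rigid twist and reports the
#' engineering strain of each foundation spring (elongation magnitude over
#' layer thickness) and its traction vector. Normal traction is positive in
#' compression (root surface displacing along its outward normal squeezes
#' the ligament against bone).
#'
#' @param samples spring-field tibble.
#' @param twist length-6 `c(v, omega)` about `reference_point`.
#' @param moduli a [foundation_moduli()].
#' @param reference_point 3-vector the twist is referenced at.
#' @return list with `max_strain_fraction` (dimensionless),
#'   `max_strain_percent`, and a tibble `field` (per-sample displacement,
#'   strain, normal traction `t_n` [MPa, compression +] and tangential
#'   traction magnitude `t_t`).
#' @export
strain_and_traction <- function(samples, twist, moduli, reference_point) {
  P <- as.matrix(samples[, c("px", "py", "pz")])
  N <- as.matrix(samples[, c("nx", "ny", "nz")])
  D <- sweep(P, 2, reference_point)
  v <- twist[1:3]
  w <- twist[4:6]
  U <- matrix(v, nrow(P), 3, byrow = TRUE) + cross_rows(
    matrix(w, nrow(P), 3, byrow = TRUE), D)
  un <- rowSums(U * N)
  Ut <- U - N * un
  strain <- sqrt(rowSums(U^2)) / moduli$thickness
  field <- tibble::tibble(
    px = P[, 1], py = P[, 2], pz = P[, 3],
    ux = U[, 1], uy = U[, 2], uz = U[, 3],
    strain = strain,
    t_n = moduli$k_normal * un,
    t_t = moduli$k_tangential * sqrt(rowSums(Ut^2)))
  list(max_strain_fraction = max(strain),
       max_strain_percent = 100 * max(strain),
       field = field)
}

# Total elastic energy of the spring field under a FINITE rigid displacement
# (rotation via the full rotation matrix). Used by tests as an independent
# oracle for the assembled stiffness (its Hessian at zero is K).
spring_field_energy <- function(samples, moduli, reference_point, twist) {
  P <- as.matrix(samples[, c("px", "py", "pz")])
  N <- as.matrix(samples[, c("nx", "ny", "nz")])
  R <- rot_exp(twist[4:6])
  D <- sweep(P, 2, reference_point)
  Pnew <- D %*% t(R) + matrix(reference_point + twist[1:3], nrow(P), 3,
                              byrow = TRUE)
  U <- Pnew - P
  un <- rowSums(U * N)
  ut2 <- rowSums(U^2) - un^2
  0.5 * sum(samples$area * (moduli$k_normal * un^2 +
                              moduli$k_tangential * ut2))
}

#' Write / read a spring field as CSV
#'
#' Plain CSV with columns `px, py, pz, nx, ny, nz, area` for debugging and
#' oracle tests.
#' @param samples spring-field tibble.
#' @param path file path.
#' @return `write_spring_field` returns `path` invisibly;
#'   `read_spring_field` returns the tibble.
#' @export
write_spring_field <- function(samples, path) {
  readr::write_csv(samples[, c("px", "py", "pz", "nx", "ny", "nz", "area")],
                   path)
  invisible(path)
}

#' @rdname write_spring_field
#' @export
read_spring_field <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_double()))
}

#' @export
print.support_stiffness <- function(x, ...) {
  cat("<support_stiffness> 6x6 about (",
      paste(sprintf("%.2f", x$reference_point), collapse = ", "), ") mm\n",
      sep = "")
  cat(sprintf("  %d springs | k_n %.3f, k_t %.3f N/mm^3\n",
              nrow(x$samples), x$moduli$k_normal, x$moduli$k_tangential))
  invisible(x)
}
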