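# Deterministic fixtures used by the test suite, the examples and the
# acceptance checks.

#' Published benchmark displacement table
#'
#' Space-closed-step displacements (mm) and rotations (degrees) of teeth 1..7
#' for the three trim designs, transcribed from the full-scale
#' patient-specific finite-element study of staged premolar distalization
#' that this package's reduced-order model emulates. Signs follow the
#' standard conventions (mesial +, lingual +, gingival +, lingual torque +,
#' distal tipping +, mesial axial rotation +). Used as the worked-example
#' input for the efficiency/anchorage metrics.
#'
#' @return long tibble with columns `design`, `quantity`, `tooth`, `value`.
#' @export
reference_displacements <- function() {
  val <- list(
    md_displacement = list(
      con = c(0.11, 0.35, 0.73, -1.69, -1.70, 0.41, 0.41),
      smhw = c(0.14, 0.44, 0.92, -1.50, -1.51, 0.60, 0.11),
      mhw = c(0.18, 0.57, 1.19, -1.91, -1.93, 0.17, 0.02)),
    bl_displacement = list(
      con = c(-0.66, -0.66, -0.35, 0.16, 0.16, -0.02, -0.01),
      smhw = c(-0.83, -0.83, -0.43, 0.15, 0.14, -0.11, -0.04),
      mhw = c(-1.08, -1.06, -0.51, 0.13, 0.14, -0.02, -0.01)),
    axial_displacement = list(
      con = c(0.03, 0.02, -0.07, 0.22, 0.29, 0.17, 0.17),
      smhw = c(0.05, 0.02, -0.07, 0.20, 0.24, 0.21, 0.06),
      mhw = c(0.06, 0.02, -0.08, 0.19, 0.23, 0.13, 0.01)),
    bl_torque = list(
      con = c(-1.82, -1.44, -1.27, 1.73, 1.71, 0.44, 0.88),
      smhw = c(-2.38, -1.68, -1.39, 1.51, 1.22, 0.20, 0.19),
      mhw = c(-3.19, -2.81, -1.48, 1.40, 1.12, 0.06, 0.02)),
    md_tipping = list(
      con = c(-0.18, -0.38, -2.15, 4.10, 4.55, -1.78, -1.93),
      smhw = c(-0.19, -0.59, -2.31, 3.65, 4.18, -2.02, -0.80),
      mhw = c(-0.22, -0.73, -2.62, 5.49, 5.08, -1.52, -0.20)),
    axial_rotation = list(
      con = c(0.53, 0.59, 0.63, 1.23, 2.13, 0.16, 0.20),
      smhw = c(0.42, 0.37, 0.44, 1.07, 1.95, 0.22, 0.12),
      mhw = c(0.53, 0.38, 0.38, 1.11, 1.92, 0.14, 0.04))
  )
  purrr::map_dfr(names(val), function(q) {
    purrr::map_dfr(names(val[[q]]), function(d) {
      tibble::tibble(design = d, quantity = q, tooth = 1:7,
                     value = val[[q]][[d]])
    })
  })
}

#' Single-tooth scalar test scene
#'
#' A minimal simulation state whose equilibrium has an exact closed form:
#' one rigid tooth on an isotropic, fully decoupled spring support
#' (an octahedral spring field about the reference point), one socket with
#' bilateral walls offset mesially by `delta`, and a clamped aligner frame.
#' Each degree of freedom is a pair of scalar springs in series, so the tooth
#' displacement along the offset axis is
#' `delta * k_socket / (k_pdl + k_socket)`.
#'
#' @param delta socket offset along the mesio-distal axis, mm.
#' @param k_socket wall stiffness, N/mm.
#' @param spring_radius radius of the octahedral spring layout, mm.
#' @return list with the `state`, the effective scalar `k_pdl`, `k_socket`
#'   and the `expected` displacement.
#' @export
one_tooth_scene <- function(delta = 0.1, k_socket = 1000,
                            spring_radius = 5) {
  moduli <- foundation_moduli(default_materials()$pdl, 0.30)
  a <- spring_radius
  P <- rbind(c(a, 0, 0), c(-a, 0, 0), c(0, a, 0),
             c(0, -a, 0), c(0, 0, a), c(0, 0, -a))
  N <- P / a
  samples <- tibble::tibble(px = P[, 1], py = P[, 2], pz = P[, 3],
                            nx = N[, 1], ny = N[, 2], nz = N[, 3],
                            area = 1)
  k_pdl <- 2 * moduli$k_normal + 4 * moduli$k_tangential # per translation dof
  pose <- rt_identity()
  tooth <- list(position = 1L, width = 7, bl_width = 7, crown_height = 7,
                root_length = 10, root_count = 1L,
                surfaces = list(frustum(c(0, 0, 7), c(0, 0, 1), 10, 2.5, 0)),
                cp_body = c(0, 0, 0), ref_body = c(0, 0, 0),
                contact_mesial_body = c(3.5, 0, 2.8),
                contact_distal_body = c(-3.5, 0, 2.8),
                arc_s = 0, frame0 = diag(3), has_attachment = FALSE,
                stress_free_pose = pose, current_pose = pose)
  rest <- rt_identity()
  rest[1, 4] <- delta # socket offset mesially (+x)
  socket <- list(position = 1L, rest_pose_base = rest, rest_pose = rest,
                 axes = diag(3), ref_body = c(0, 0, 0),
                 k_wall = k_socket, k_bl = k_socket, k_vertical = k_socket,
                 k_rot = rep(k_socket * 10, 3),
                 has_mesial_wall = TRUE, has_distal_wall = TRUE,
                 stiffness_scale = 1.0)
  aligner <- structure(list(sockets = list(socket), design = "con",
                            frame_pose = rt_identity(), staging_step = 0L,
                            traction_attachment_point = c(0, 0, 0)),
                       class = "aligner")
  eng <- engine_config(aligner_dof = "fixed")
  state <- structure(list(
    dentition = list(teeth = list(tooth), arch = NULL, tad = NULL,
                     config = list(pdl_thickness = 0.30)),
    aligner = aligner, traction = NULL, engine = eng, moduli = moduli,
    body_samples = list(samples),
    step_index = 0L, iteration_index = 0L,
    active_wall_set = NULL, last_solve = NULL
  ), class = "simulation_state")
  list(state = state, k_pdl = k_pdl, k_socket = k_socket, delta = delta,
       expected = delta * k_socket / (k_pdl + k_socket))
}

#' Materialize a named fixture
#'
#' Known fixtures: `"reference_displacements"` (the published benchmark
#' displacement CSV), `"one_tooth"` (the scalar springs-in-series scene;
#' serialized as a JSON description) and `"default_arch"` (the default
#' synthetic quadrant, exported as PLY + JSON scene files).
#'
#' @param name fixture name.
#' @param dir output directory.
#' @return list with `files` written and the fixture `object`.
#' @export
make_fixture <- function(name, dir = tempfile("fixture")) {
  known <- c("reference_displacements", "one_tooth", "default_arch")
  if (!name %in% known) {
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (name == "reference_displacements") {
    obj <- reference_displacements()
    f <- file.path(dir, "reference_displacements.csv")
    readr::write_csv(obj, f)
    return(list(files = f, object = obj))
  }
  if (name == "one_tooth") {
    obj <- one_tooth_scene()
    f <- file.path(dir, "one_tooth.json")
    jsonlite::write_json(list(delta = obj$delta, k_pdl = obj$k_pdl,
                              k_socket = obj$k_socket,
                              expected = obj$expected),
                         f, auto_unbox = TRUE, digits = NA)
    return(list(files = f, object = obj))
  }
  den <- generate_quadrant(dentition_config())
  files <- export_scene(den, dir)
  list(files = files, object = den)
}

#' Path to the installed benchmark displacement CSV
#' @return file path.
#' @export
reference_displacements_path <- function() {
  system.file("extdata", "reference_displacements.csv",
              package = "alignersim", mustWork = TRUE)
}
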