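# Rigid-frame clear aligner: per-tooth sockets with unilateral mesial/distal
# walls and bilateral wrap springs. Three trimline designs:
#   con  - conventional full coverage, both walls on every tooth;
#   smhw - second-molar half wrap: distal wall removed and socket stiffness
#          halved at position 7;
#   mhw  - all-molar half wrap: the same at positions 6 and 7.
# Removing a distal wall removes the aligner's ability to push that tooth
# mesially while retaining its ability to block mesial drift elsewhere - the
# anchorage-preservation mechanism this package exists to study.

TRIM_DESIGNS <- c("con", "smhw", "mhw")

#' Build a clear aligner on the current dentition
#'
#' Socket rest poses equal the current crown poses, so the freshly built
#' aligner is stress-free. Wall flags and the half-wrap stiffness scale are
#' set by the trim design. Default stiffness magnitudes come from a
#' shell-compression heuristic (see Details); they are calibration
#' parameters, exposed via `stiffness`.
#'
#' @details
#' The socket stiffness is estimated as through-thickness compression of the
#' shell material across the engaged crown face,
#' `k_wall = E_a * A_wall / t_shell` with `A_wall = h_crown * w_bl`, applied
#' to all three translational components; rotational stiffnesses are
#' `k_wall * h_crown^2 / 2` (opposing wall pairs acting over the crown
#' height). An attachment multiplies vertical and rotational
#' stiffness by its grip factor. Half-wrap sockets scale all components by
#' 0.5. These defaults are calibrated so that the aligner-tooth coupling is
#' stiff relative to the periodontal foundation, reproducing the near-complete
#' per-step expression and the rapid iteration-to-iteration stabilization
#' characteristic of full contact finite-element models of aligner seating.
#'
#' @param dentition a [generate_quadrant()] dentition.
#' @param design `"con"`, `"smhw"` or `"mhw"`.
#' @param material aligner [material()] (default E = 1500 MPa, nu = 0.30).
#' @param shell_thickness aligner shell thickness, mm (default 0.7).
#' @param stiffness optional named list overriding per-tooth stiffness
#'   components: function(tooth) -> list(wall, bl, vertical, rot) or a fixed
#'   list applied to all teeth.
#' @return object of class `aligner`.
#' @export
build_aligner <- function(dentition,
                          design = c("con", "smhw", "mhw"),
                          material = default_materials()$aligner,
                          shell_thickness = 0.7,
                          stiffness = NULL) {
  design <- match.arg(design)
  if (length(dentition$teeth) != 7) stop("7 teeth required", call. = FALSE)
  half <- switch(design, con = integer(0), smhw = 7L, mhw = c(6L, 7L))
  sockets <- lapply(dentition$teeth, function(tooth) {
    p <- tooth$position
    k <- socket_stiffness(tooth, material, shell_thickness, stiffness)
    grip <- if (tooth$has_attachment) {
      dentition$config$attachment_grip
    } else 1.0
    list(
      position = p,
      rest_pose_base = tooth$current_pose,  # in aligner frame (identity at build)
      rest_pose = tooth$current_pose,
      axes = tooth$frame0,                  # local X (mesial+), Y (lingual+), Z
      ref_body = tooth$ref_body,
      k_wall = k$wall,
      k_bl = k$bl,
      k_vertical = k$vertical * grip,
      k_rot = k$rot * c(grip, grip, 1),
      has_mesial_wall = TRUE,
      has_distal_wall = !(p %in% half),
      stiffness_scale = if (p %in% half) 0.5 else 1.0
    )
  })
  canine <- dentition$teeth[[3]]
  hook_body <- c(canine$width / 2, -canine$bl_width / 2, canine$crown_height)
  structure(list(
    sockets = sockets,
    design = design,
    frame_pose = rt_identity(),
    staging_step = 0L,
    material = material,
    shell_thickness = shell_thickness,
    # buccal mesial cervical point of the canine socket, in the aligner frame
    traction_attachment_point = rt_apply(canine$current_pose, hook_body)
  ), class = "aligner")
}

socket_stiffness <- function(tooth, material, shell_thickness, override) {
  if (is.function(override)) return(override(tooth))
  if (!is.null(override)) return(override)
  wall_area <- tooth$crown_height * tooth$bl_width
  k_wall <- material$elastic_modulus * wall_area / shell_thickness
  list(wall = k_wall,
       bl = k_wall,
       vertical = k_wall,
       rot = rep(k_wall * tooth$crown_height^2 / 2, 3))
}

#' Staging plan for the premolar-distalization protocol
#'
#' Ten steps of 0.2 mm distal bodily movement prescribed to both premolars:
#' at each step the aligner's rest gap across span (5,6) shrinks by the
#' increment and the span (3,4) grows by the same amount, restricted to the
#' mesio-distal direction.
#'
#' @param n_steps planned number of steps (default 10).
#' @param step_increment per-step prescribed movement, mm (default 0.2).
#' @return object of class `staging_plan`.
#' @export
staging_plan <- function(n_steps = 10L, step_increment = 0.2) {
  stopifnot(n_steps >= 1, step_increment > 0)
  structure(list(n_steps = as.integer(n_steps),
                 step_increment = step_increment,
                 shortened_span = c(5L, 6L),
                 lengthened_span = c(3L, 4L),
                 direction = "mesio-distal"),
            class = "staging_plan")
}

#' Apply a staging step to the aligner rest geometry
#'
#' Sets the aligner to the rest geometry of staging step `step` (absolute,
#' from the as-built geometry): the premolar sockets (positions 4 and 5) are
#' translated distally by `step * step_increment` along their local
#' mesio-distal axes, so the rest gap of span (5,6) shrinks and span (3,4)
#' grows by the same amount, with no bucco-lingual or vertical component.
#' Steps beyond `n_steps` continue with identical increments (space-closure
#' extension).
#'
#' @param aligner an [build_aligner()] aligner.
#' @param plan a [staging_plan()].
#' @param step non-negative integer; `step = 0` restores the as-built rest
#'   geometry.
#' @return the staged aligner.
#' @export
apply_staging <- function(aligner, plan, step) {
  stopifnot(inherits(aligner, "aligner"), inherits(plan, "staging_plan"))
  if (step < 0) stop("negative staging step rejected", call. = FALSE)
  shift <- step * plan$step_increment
  for (i in seq_along(aligner$sockets)) {
    s <- aligner$sockets[[i]]
    if (s$position %in% c(4L, 5L)) {
      mesial <- s$axes[, 1]
      s$rest_pose <- s$rest_pose_base
      s$rest_pose[1:3, 4] <- s$rest_pose_base[1:3, 4] - shift * mesial
    } else {
      s$rest_pose <- s$rest_pose_base
    }
    aligner$sockets[[i]] <- s
  }
  aligner$staging_step <- as.integer(step)
  aligner
}

# Rest gap between the facing walls of two sockets along the mesio-distal
# direction, used to verify staging bookkeeping.
socket_span <- function(aligner, i, j) {
  si <- aligner$sockets[[i]]; sj <- aligner$sockets[[j]]
  d <- sj$rest_pose[1:3, 4] - si$rest_pose[1:3, 4]
  mid_axis <- unit3(si$axes[, 1] + sj$axes[, 1]) # mean mesial direction
  -sum(d * mid_axis) # distal separation is positive
}

#' Temperature-changing-method bookkeeping
#'
#' The staged rest-geometry deformation can be realized in a thermal
#' finite-element setting by heating a deformation zone of width `d` with a
#' linear expansion coefficient `k` until it produces the outstanding
#' deformation: `t = (U - delta) / (k * d)`. The simulation engine consumes
#' the rest-length change `U - delta` directly; this function reproduces the
#' temperature bookkeeping.
#'
#' @param U preset (target cumulative) deformation magnitude, mm.
#' @param delta deformation already realized in previous steps, mm.
#' @param k coefficient of linear expansion, 1/degC (> 0).
#' @param d width of the deformation zone, mm (> 0).
#' @return temperature change, degC (negative = contraction).
#' @export
#' @examples
#' tcm_temperature(U = 0.2, delta = 0, k = 0.01, d = 2) # 10 degC
tcm_temperature <- function(U, delta, k, d) {
  if (k <= 0 || d <= 0) stop("k and d must be > 0", call. = FALSE)
  (U - delta) / (k * d)
}

#' Socket wrench on a tooth (and its reaction on the aligner)
#'
#' Computes the pose mismatch between the socket's staged rest pose (carried
#' by the aligner frame) and the tooth's current pose, as a 6-twist at the
#' crown reference point, and converts it to a wrench. Bucco-lingual,
#' vertical and rotational components are bilinear wrap springs; the
#' mesio-distal component is unilateral: the mesial wall only pushes the
#' tooth distally (active when the tooth sits mesial of the socket), the
#' distal wall only pushes mesially (tooth distal of the socket); an absent
#' wall transmits nothing.
#'
#' @param socket a socket of an [build_aligner()] aligner.
#' @param tooth_pose current 4x4 tooth pose.
#' @param aligner_frame_pose current 4x4 aligner frame pose.
#' @return list with `wrench_on_tooth` (at the crown reference point, world
#'   axes), `wrench_on_aligner` (equal and opposite, same point),
#'   `mismatch` (local-axis components), `md_force` (signed mesio-distal
#'   force on the tooth, mesial +) and `md_active`.
#' @export
socket_wrench <- function(socket, tooth_pose, aligner_frame_pose) {
  rest_world <- aligner_frame_pose %*% socket$rest_pose
  r <- rt_apply(tooth_pose, socket$ref_body)
  m <- rt_twist_between(tooth_pose, rest_world, r) # socket rest minus tooth
  R <- socket$axes
  m_loc <- c(t(R) %*% m[1:3], t(R) %*% m[4:6])
  act <- md_wall_active(socket, m_loc[1])
  sc <- socket$stiffness_scale
  f_loc <- c(if (act) sc * socket$k_wall * m_loc[1] else 0,
             sc * socket$k_bl * m_loc[2],
             sc * socket$k_vertical * m_loc[3])
  t_loc <- sc * socket$k_rot * m_loc[4:6]
  w <- c(R %*% f_loc, R %*% t_loc)
  list(wrench_on_tooth = w,
       wrench_on_aligner = -w,
       point = r,
       mismatch = m_loc,
       md_force = f_loc[1],
       md_active = act)
}

# A mesio-distal mismatch m1 > 0 means the socket sits mesial of the tooth
# (equivalently the tooth sits distal of the socket): only the distal wall
# can push, and it pushes mesially. m1 < 0 engages the mesial wall.
md_wall_active <- function(socket, m1) {
  if (m1 > 0) socket$has_distal_wall
  else if (m1 < 0) socket$has_mesial_wall
  else FALSE
}

#' @export
print.aligner <- function(x, ...) {
  cat(sprintf("<aligner> design %s, staging step %d\n",
              toupper(x$design), x$staging_step))
  walls <- vapply(x$sockets, function(s) {
    paste0(if (s$has_mesial_wall) "M" else "-",
           if (s$has_distal_wall) "D" else "-")
  }, character(1))
  cat("  walls 1..7: ", paste(walls, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Serialize an aligner to JSON
#'
#' @param aligner an `aligner`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_aligner_json <- function(aligner, path) {
  sk <- lapply(aligner$sockets, function(s) {
    list(position = s$position,
         rest_pose = as.numeric(t(s$rest_pose)),
         has_mesial_wall = s$has_mesial_wall,
         has_distal_wall = s$has_distal_wall,
         stiffness_scale = s$stiffness_scale,
         k_wall = s$k_wall, k_bl = s$k_bl, k_vertical = s$k_vertical,
         k_rot = s$k_rot)
  })
  jsonlite::write_json(
    list(design = aligner$design, staging_step = aligner$staging_step,
         frame_pose = as.numeric(t(aligner$frame_pose)), sockets = sk),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
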