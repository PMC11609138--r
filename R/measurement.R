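# Landmarks, per-tooth local coordinate frames and the signed six-component
# decomposition of tooth motion (displacement of the crown point, rotation of
# the long axis) used in clinical reporting of aligner simulations.
#
# Sign conventions: mesio-distal displacement mesial (+) / distal (-);
# bucco-lingual buccal (-) / lingual (+); axial gingival (+) / occlusal (-);
# bucco-lingual torque buccal (-) / lingual (+); mesio-distal tipping
# mesial (-) / distal (+); axial rotation mesial (+) / distal (-).

#' Landmarks of a tooth
#'
#' Crown point (CP): midpoint of the incisal edge / cusp / occlusal surface -
#' the body-frame origin of the generated teeth. Root point (RP): root apex
#' for single-rooted teeth, arithmetic midpoint of the apexes for multirooted
#' teeth. Resistance-center landmark (RC): midpoint of the root section at
#' the 1/3 root level (single-rooted) or 1 mm apical of the furcation
#' (multirooted). Long axis (LA): unit vector from CP through RP.
#'
#' @param tooth a tooth of a [generate_quadrant()] dentition.
#' @return list with `cp_body`, `rp_body`, `rc_body` (body-frame 3-vectors)
#'   and `la_body` (unit vector), plus world-frame counterparts under the
#'   current pose (`cp`, `rp`, `rc`, `la`).
#' @export
tooth_landmarks <- function(tooth) {
  h <- tooth$crown_height
  L <- tooth$root_length
  cp <- tooth$cp_body
  if (tooth$root_count == 1L) {
    s <- tooth$surfaces[[1]]
    rp <- s$base + s$axis * s$length
    rc <- c(0, 0, h + L / 3)
  } else {
    cones <- tooth$surfaces[-1] # drop the trunk
    if (length(cones) < 2) stop("multirooted tooth without furcation cones",
                                call. = FALSE)
    apexes <- t(vapply(cones, function(s) s$base + s$axis * s$length,
                       numeric(3)))
    rp <- colMeans(apexes)
    fur_z <- tooth$surfaces[[1]]$base[3] + tooth$surfaces[[1]]$length
    rc <- c(0, 0, fur_z + 1)
  }
  la <- unit3(rp - cp)
  list(cp_body = cp, rp_body = rp, rc_body = rc, la_body = la,
       cp = rt_apply(tooth$current_pose, cp),
       rp = rt_apply(tooth$current_pose, rp),
       rc = rt_apply(tooth$current_pose, rc),
       la = rt_apply_vec(tooth$current_pose, la))
}

#' Local coordinate frame of a tooth
#'
#' X is the arch tangent at the tooth projected to the occlusal plane and
#' oriented mesially; Z equals the global occluso-gingival axis (gingival +);
#' Y = Z x X points lingually. The triad is right-handed orthonormal. Frames
#' are built on the initial arch geometry and held fixed while motion is
#' decomposed.
#'
#' @param tooth a tooth entry (uses its arc position on the arch).
#' @param arch the dentition's arch curve.
#' @return list with `origin` (world CP) and unit axes `X`, `Y`, `Z`.
#' @export
build_local_frame <- function(tooth, arch) {
  tang <- as.numeric(arch$tangent(tooth$arc_s))
  tang[3] <- 0
  if (sqrt(sum(tang^2)) < 1e-9) stop("degenerate arch tangent", call. = FALSE)
  X <- -unit3(tang)       # mesial +
  Z <- c(0, 0, 1)         # gingival +
  Y <- cross3(Z, X)       # lingual +
  list(origin = rt_apply(tooth$current_pose, tooth$cp_body),
       X = X, Y = Y, Z = Z)
}

#' Decompose a rigid motion into the six signed clinical quantities
#'
#' Displacement components are the crown-point displacement projected on the
#' local axes; rotation components are the rotation vector (axis-angle) of
#' the relative rotation expressed in the local frame, in degrees. The
#' rotation-vector decomposition is order-free and agrees with any Euler
#' sequence to well below reporting precision for the < 6 degree rotations
#' produced here.
#'
#' @param pose_before,pose_after 4x4 rigid transforms.
#' @param frame a [build_local_frame()] local frame.
#' @param landmarks a [tooth_landmarks()] result for the same tooth (its
#'   body-frame crown point is tracked).
#' @return tibble row with `md_displacement`, `bl_displacement`,
#'   `axial_displacement` (mm), `bl_torque`, `md_tipping`, `axial_rotation`
#'   (degrees).
#' @export
decompose_motion <- function(pose_before, pose_after, frame, landmarks) {
  stopifnot(is_rigid_transform(pose_before), is_rigid_transform(pose_after))
  d <- rt_apply(pose_after, landmarks$cp_body) -
    rt_apply(pose_before, landmarks$cp_body)
  R_rel <- rt_rot(pose_after) %*% t(rt_rot(pose_before))
  phi <- rot_log(R_rel)
  ang <- sqrt(sum(phi^2))
  if (ang > 30 * pi / 180) {
    stop("relative rotation exceeds 30 degrees; outside the small-rotation ",
         "decomposition range", call. = FALSE)
  }
  B <- cbind(frame$X, frame$Y, frame$Z)
  phi_loc <- as.numeric(t(B) %*% phi) * 180 / pi
  d_loc <- as.numeric(t(B) %*% d)
  tibble::tibble(
    md_displacement = d_loc[1],
    bl_displacement = d_loc[2],
    axial_displacement = d_loc[3],
    bl_torque = phi_loc[1],
    md_tipping = phi_loc[2],
    axial_rotation = phi_loc[3]
  )
}

#' Recompose a displacement record into a relative rigid transform
#'
#' Inverse of [decompose_motion()] (up to the small-angle rotation-vector
#' convention): returns the pose reached by applying the record to
#' `pose_before`.
#'
#' @param record one-row tibble from [decompose_motion()].
#' @param pose_before 4x4 pose.
#' @inheritParams decompose_motion
#' @return 4x4 pose.
#' @export
recompose_motion <- function(record, pose_before, frame, landmarks) {
  B <- cbind(frame$X, frame$Y, frame$Z)
  phi <- as.numeric(B %*% (as.numeric(record[1, 4:6]) * pi / 180))
  d <- as.numeric(B %*% as.numeric(record[1, 1:3]))
  cp0 <- rt_apply(pose_before, landmarks$cp_body)
  rt_apply_twist(pose_before, c(d, phi), cp0)
}
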