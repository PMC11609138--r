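# Parametric right-maxillary-quadrant generator. FDI quadrant 1, positions
# 1..7 (central incisor .. second molar). Global frame: median sagittal plane
# x = 0, anterior +y, occlusal plane z = 0 with the apical (gingival)
# direction positive; all lengths mm.

#' Configuration for the synthetic dentition generator
#'
#' Defines the parametric right maxillary quadrant used in place of a
#' patient-specific model: a quartic arch curve in the occlusal plane, seven
#' teeth with box crowns and tapered-cone roots, a 0.30 mm periodontal
#' ligament layer on the root surfaces, rectangular attachments and an
#' inter-radicular mini-implant (TAD) site. The starting configuration has a
#' `gap_premolar2_molar1` space (default 2 mm) between the second premolar
#' and first molar, i.e. the state after molar distalization in a staged
#' distalization treatment.
#'
#' @param arch_depth antero-posterior depth of the arch curve, mm.
#' @param arch_width full inter-molar arch width (twice the lateral extent of
#'   the quadrant), mm.
#' @param crown_widths mesio-distal crown widths for positions 1..7, mm.
#' @param crown_bl_widths bucco-lingual crown widths for positions 1..7, mm.
#' @param crown_heights occlusal-cervical crown heights for positions 1..7, mm.
#' @param root_lengths cervix-to-apex root lengths for positions 1..7, mm.
#' @param root_count number of roots per position (1 or 3; molars default to
#'   three tapered cones sharing a furcation 3 mm apical of the cervix).
#' @param root_surface_areas target periodontal attachment area per tooth,
#'   mm^2. Smooth tapered cones under-represent the oval, curved surfaces of
#'   real roots, so the generator scales the tributary areas of the sampled
#'   spring field to these targets (defaults are standard published mean
#'   root-surface areas for the maxillary teeth); `NULL` disables the
#'   correction and uses the raw parametric areas.
#' @param gap_premolar2_molar1 inter-proximal space between positions 5 and 6,
#'   mm (default 2.0).
#' @param pdl_thickness periodontal-ligament layer thickness, mm (default 0.30).
#' @param alveolar_crest_level depth of the alveolar crest plane below the
#'   occlusal plane, mm.
#' @param attachment_positions positions carrying a rectangular buccal
#'   attachment.
#' @param attachment_grip dimensionless multiplier applied to socket
#'   rotational/vertical stiffness where an attachment is present (>= 1).
#' @param jitter_sd standard deviation of optional Gaussian jitter applied to
#'   tooth placements, mm (default 0 = off; used for robustness testing only).
#' @param seed integer seed making the generator deterministic.
#' @return an object of class `dentition_config`.
#' @export
dentition_config <- function(arch_depth = 46,
                             arch_width = 64,
                             crown_widths = c(8.5, 6.5, 7.5, 7.0, 7.0, 10.0, 9.5),
                             crown_bl_widths = c(7.0, 6.5, 8.0, 9.0, 9.0, 11.0, 10.5),
                             crown_heights = c(10, 9, 10, 8, 8, 7, 7),
                             root_lengths = c(13, 13, 16, 14, 14, 12, 11),
                             root_count = c(1, 1, 1, 1, 1, 3, 3),
                             root_surface_areas = c(204, 179, 273, 234,
                                                    220, 433, 431),
                             gap_premolar2_molar1 = 2.0,
                             pdl_thickness = 0.30,
                             alveolar_crest_level = 9,
                             attachment_positions = 4:7,
                             attachment_grip = 1.5,
                             jitter_sd = 0,
                             seed = 1L) {
  cfg <- list(
    arch_depth = arch_depth, arch_width = arch_width,
    crown_widths = crown_widths, crown_bl_widths = crown_bl_widths,
    crown_heights = crown_heights, root_lengths = root_lengths,
    root_count = as.integer(root_count),
    root_surface_areas = root_surface_areas,
    gap_premolar2_molar1 = gap_premolar2_molar1,
    pdl_thickness = pdl_thickness,
    alveolar_crest_level = alveolar_crest_level,
    attachment_positions = as.integer(attachment_positions),
    attachment_grip = attachment_grip,
    jitter_sd = jitter_sd, seed = as.integer(seed)
  )
  validate_dentition_config(cfg)
  structure(cfg, class = "dentition_config")
}

validate_dentition_config <- function(cfg) {
  len7 <- c("crown_widths", "crown_bl_widths", "crown_heights",
            "root_lengths", "root_count")
  for (f in len7) {
    if (length(cfg[[f]]) != 7) {
      stop(sprintf("`%s` must have length 7 (exactly 7 teeth)", f),
           call. = FALSE)
    }
  }
  pos <- c("arch_depth", "arch_width", "pdl_thickness",
           "alveolar_crest_level", "attachment_grip")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop(sprintf("`%s` must be a positive scalar", f), call. = FALSE)
    }
  }
  if (any(cfg$crown_widths <= 0) || any(cfg$crown_bl_widths <= 0) ||
      any(cfg$crown_heights <= 0) || any(cfg$root_lengths <= 0)) {
    stop("all tooth dimensions must be positive", call. = FALSE)
  }
  if (cfg$gap_premolar2_molar1 < 0) {
    stop("`gap_premolar2_molar1` must be >= 0", call. = FALSE)
  }
  if (!all(cfg$root_count %in% c(1L, 3L))) {
    stop("`root_count` entries must be 1 or 3", call. = FALSE)
  }
  if (!is.null(cfg$root_surface_areas) &&
      (length(cfg$root_surface_areas) != 7 ||
         any(cfg$root_surface_areas <= 0))) {
    stop("`root_surface_areas` must be 7 positive areas or NULL",
         call. = FALSE)
  }
  if (cfg$attachment_grip < 1) {
    stop("`attachment_grip` must be >= 1", call. = FALSE)
  }
  if (cfg$jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)
  invisible(cfg)
}

# ---- arch curve --------------------------------------------------------------

#' Quartic arch curve in the occlusal plane
#'
#' The arch form is `y(x) = depth * (1 - (x / (width/2))^4)` for
#' `x in [0, width/2]` (right quadrant), arc-length parameterized
#' numerically. Exposed mainly for plotting and for local-frame construction.
#'
#' @param width full arch width, mm.
#' @param depth arch depth, mm.
#' @return list with `point(s)`, `tangent(s)` (unit, direction of increasing
#'   arc length, i.e. disto-posterior), `total_length`, and the generating
#'   parameters.
#' @export
arch_curve <- function(width, depth) {
  xm <- width / 2
  xs <- seq(0, xm, length.out = 4001)
  ys <- depth * (1 - (xs / xm)^4)
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  s <- c(0, cumsum(seg))
  x_of_s <- stats::splinefun(s, xs, method = "hyman")
  point <- function(sv) {
    x <- x_of_s(sv)
    cbind(x, depth * (1 - (x / xm)^4), 0)
  }
  tangent <- function(sv) {
    x <- x_of_s(sv)
    dydx <- -4 * depth * x^3 / xm^4
    t <- cbind(1, dydx, 0)
    t / sqrt(rowSums(t^2))
  }
  list(point = point, tangent = tangent, total_length = s[length(s)],
       width = width, depth = depth)
}

# ---- generator ---------------------------------------------------------------

#' Generate the parametric right maxillary quadrant
#'
#' Places 7 rigid teeth along the arch curve with adjacent crowns in
#' inter-proximal contact except for the configured space between the second
#' premolar (position 5) and the first molar (position 6). The occlusal plane
#' is the global `z = 0` plane; the apical (gingival) direction is `+z`.
#' Deterministic for a fixed seed.
#'
#' @param config a [dentition_config()].
#' @return an object of class `dentition`: teeth with body-frame geometry and
#'   stress-free/current poses, the arch curve, the alveolar-crest level and
#'   attachment specifications.
#' @export
generate_quadrant <- function(config = dentition_config()) {
  if (!inherits(config, "dentition_config")) {
    config <- do.call(dentition_config, config)
  }
  validate_dentition_config(config)
  arch <- arch_curve(config$arch_width, config$arch_depth)

  w <- config$crown_widths
  gaps <- c(0, 0, 0, 0, config$gap_premolar2_molar1, 0) # between i and i+1
  s <- numeric(7)
  s[1] <- w[1] / 2
  for (i in 2:7) s[i] <- s[i - 1] + (w[i - 1] + w[i]) / 2 + gaps[i - 1]
  if (s[7] + w[7] / 2 > arch$total_length) {
    stop("arch curve too short for the configured crown widths and gap; ",
         "increase `arch_depth`/`arch_width`", call. = FALSE)
  }

  jit <- matrix(0, 7, 3)
  if (config$jitter_sd > 0) {
    jit <- with_local_seed(config$seed, {
      matrix(stats::rnorm(21, sd = config$jitter_sd), 7, 3)
    })
  }

  teeth <- vector("list", 7)
  for (i in 1:7) {
    origin <- as.numeric(arch$point(s[i])) + jit[i, ]
    tang <- as.numeric(arch$tangent(s[i]))
    X <- -tang                      # mesial (+)
    Z <- c(0, 0, 1)                 # apical / gingival (+)
    Y <- cross3(Z, X)               # lingual (+)
    R <- cbind(X, Y, Z)
    pose <- rt_make(R, origin)
    inv <- rt_inverse(pose)

    h <- config$crown_heights[i]
    zc <- 3 # common inter-proximal contact height below the occlusal plane
    cm_world <- as.numeric(arch$point(s[i] - w[i] / 2)) + c(0, 0, zc)
    cd_world <- as.numeric(arch$point(s[i] + w[i] / 2)) + c(0, 0, zc)

    surfaces <- root_surfaces_body(config, i)
    smooth_area <- sum(vapply(surfaces, frustum_lateral_area, numeric(1)))
    area_scale <- if (is.null(config$root_surface_areas)) 1 else
      config$root_surface_areas[i] / smooth_area
    teeth[[i]] <- list(
      position = i,
      width = w[i],
      bl_width = config$crown_bl_widths[i],
      crown_height = h,
      root_length = config$root_lengths[i],
      root_count = config$root_count[i],
      surfaces = surfaces,
      area_scale = area_scale,
      cp_body = c(0, 0, 0),
      contact_mesial_body = rt_apply(inv, cm_world),
      contact_distal_body = rt_apply(inv, cd_world),
      ref_body = c(0, 0, h / 2),   # crown mid-height centroid
      arc_s = s[i],
      frame0 = R,
      has_attachment = i %in% config$attachment_positions,
      stress_free_pose = pose,
      current_pose = pose
    )
  }

  den <- structure(list(
    config = config, arch = arch, teeth = teeth,
    crest_z = config$alveolar_crest_level,
    attachments = attachment_specs(config),
    tad = NULL
  ), class = "dentition")
  den$tad <- place_tad(den)
  den
}

# Root surface set (frustums) in the tooth body frame. Single-rooted teeth get
# one full cone on the long axis; three-rooted teeth get a short cervical
# trunk plus three diverging cones sharing a furcation 3 mm apical of the
# cervix (supports the "1 mm above the furcation" resistance-center landmark).
root_surfaces_body <- function(config, i) {
  h <- config$crown_heights[i]
  L <- config$root_lengths[i]
  r0 <- 0.35 * min(config$crown_widths[i], config$crown_bl_widths[i])
  if (config$root_count[i] == 1L) {
    return(list(frustum(base = c(0, 0, h), axis = c(0, 0, 1),
                        length = L, r_base = r0, r_tip = 0)))
  }
  f_depth <- 3 # furcation depth below cervix, mm
  if (L <= f_depth + 1) {
    stop("multirooted tooth needs root_length > 4 mm (furcation at 3 mm)",
         call. = FALSE)
  }
  trunk <- frustum(base = c(0, 0, h), axis = c(0, 0, 1),
                   length = f_depth, r_base = r0, r_tip = 0.95 * r0)
  dirs <- rbind(c(0.25, -0.20, 1),   # mesio-buccal
                c(-0.25, -0.20, 1),  # disto-buccal
                c(0.00, 0.40, 1))    # palatal
  fur <- c(0, 0, h + f_depth)
  cones <- lapply(seq_len(3), function(k) {
    d <- unit3(dirs[k, ])
    len <- (L - f_depth) / d[3]
    frustum(base = fur, axis = d, length = len,
            r_base = 0.45 * r0, r_tip = 0)
  })
  c(list(trunk), cones)
}

frustum <- function(base, axis, length, r_base, r_tip) {
  if (length <= 0 || (r_base <= 0 && r_tip <= 0)) {
    stop("degenerate root surface (zero length or radius)", call. = FALSE)
  }
  list(base = base, axis = unit3(axis), length = length,
       r_base = r_base, r_tip = r_tip)
}

frustum_lateral_area <- function(f) {
  slant <- sqrt(f$length^2 + (f$r_base - f$r_tip)^2)
  pi * (f$r_base + f$r_tip) * slant
}

attachment_specs <- function(config) {
  lapply(config$attachment_positions, function(p) {
    list(position = p, shape = c(3, 2, 1), face = "buccal",
         grip_multiplier = config$attachment_grip)
  })
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# ---- surface sampling --------------------------------------------------------

#' Sample the root surface of a tooth into a spring field
#'
#' Discretizes the lateral surface of each root frustum into quadrature
#' points with outward unit normals and exact tributary areas (the sum of
#' areas equals the closed-form lateral area). These samples carry the
#' periodontal-ligament foundation springs. Tributary areas are computed in
#' the body frame and are therefore invariant under rigid pose updates.
#'
#' @param tooth a tooth entry of a [generate_quadrant()] dentition.
#' @param target_count requested total number of samples (>= 20); the actual
#'   count may differ slightly due to the per-surface grid layout.
#' @param frame `"world"` (default, uses the tooth's current pose) or
#'   `"body"`.
#' @return tibble with columns `px, py, pz` (point), `nx, ny, nz` (outward
#'   unit normal) and `area` (mm^2).
#' @export
sample_root_surface <- function(tooth, target_count = 400, frame = "world") {
  stopifnot(target_count >= 20)
  frame <- match.arg(frame, c("world", "body"))
  areas <- vapply(tooth$surfaces, frustum_lateral_area, numeric(1))
  counts <- pmax(12, round(target_count * areas / sum(areas)))
  parts <- lapply(seq_along(tooth$surfaces), function(k) {
    sample_frustum(tooth$surfaces[[k]], counts[k])
  })
  pts <- do.call(rbind, lapply(parts, `[[`, "p"))
  nrm <- do.call(rbind, lapply(parts, `[[`, "n"))
  scale <- if (is.null(tooth$area_scale)) 1 else tooth$area_scale
  area <- unlist(lapply(parts, `[[`, "a")) * scale
  if (frame == "world") {
    pts <- rt_apply(tooth$current_pose, pts)
    nrm <- rt_apply_vec(tooth$current_pose, nrm)
  }
  tibble::tibble(px = pts[, 1], py = pts[, 2], pz = pts[, 3],
                 nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
                 area = area)
}

# Midpoint quadrature on a frustum lateral surface; strip areas are exact so
# the total equals pi*(r0+r1)*slant to floating-point accuracy.
sample_frustum <- function(f, count) {
  n_ax <- max(3L, floor(sqrt(count / 3)))
  n_th <- max(6L, ceiling(count / n_ax))
  # orthonormal basis around the axis
  a <- f$axis
  e1 <- if (abs(a[1]) < 0.9) unit3(cross3(a, c(1, 0, 0))) else
    unit3(cross3(a, c(0, 1, 0)))
  e2 <- cross3(a, e1)
  slant <- sqrt(f$length^2 + (f$r_base - f$r_tip)^2)
  tb <- seq(0, 1, length.out = n_ax + 1)
  tm <- (tb[-1] + tb[-(n_ax + 1)]) / 2
  r_of <- function(t) f$r_base + (f$r_tip - f$r_base) * t
  strip_area <- pi * (r_of(tb[-(n_ax + 1)]) + r_of(tb[-1])) * slant * diff(tb)
  th <- (seq_len(n_th) - 0.5) * 2 * pi / n_th
  m <- (f$r_tip - f$r_base) / f$length # dr/ds along axis
  grid <- expand.grid(j = seq_len(n_ax), l = seq_len(n_th))
  rad_dir <- cbind(cos(th[grid$l]), sin(th[grid$l])) # in (e1, e2)
  radial <- rad_dir[, 1, drop = FALSE] %*% rbind(e1) +
    rad_dir[, 2, drop = FALSE] %*% rbind(e2)
  p <- matrix(f$base, nrow(grid), 3, byrow = TRUE) +
    outer(tm[grid$j] * f$length, a) + radial * r_of(tm[grid$j])
  n_raw <- radial - outer(rep(m, nrow(grid)), a)
  n <- n_raw / sqrt(rowSums(n_raw^2))
  list(p = p, n = n, a = strip_area[grid$j] / n_th)
}

# ---- TAD ---------------------------------------------------------------------

#' Place the temporary anchorage device (mini-implant)
#'
#' The TAD sits in the buccal inter-radicular space between the first and
#' second molars (positions 6 and 7), 4 mm apical of the alveolar-crest
#' plane, offset buccally from the arch curve.
#'
#' @param dentition a [generate_quadrant()] result.
#' @param height_above_crest apical offset from the crest plane, mm.
#' @param buccal_offset buccal offset from the arch curve, mm.
#' @return list with `location` (3-vector, mm), `arc_s` and a description.
#' @export
place_tad <- function(dentition, height_above_crest = 4, buccal_offset = 3) {
  teeth <- dentition$teeth
  if (length(teeth) < 7) stop("teeth 6 and 7 required", call. = FALSE)
  s_tad <- (teeth[[6]]$arc_s + teeth[[7]]$arc_s) / 2
  p <- as.numeric(dentition$arch$point(s_tad))
  tang <- as.numeric(dentition$arch$tangent(s_tad))
  lingual <- cross3(c(0, 0, 1), -tang)
  buccal <- -lingual
  loc <- p + buccal_offset * buccal
  loc[3] <- dentition$crest_z + height_above_crest
  list(location = loc, arc_s = s_tad,
       description = "buccal inter-radicular TAD between positions 6 and 7")
}

# ---- measurements on the dentition ------------------------------------------

world_contact <- function(tooth, which = c("mesial", "distal")) {
  which <- match.arg(which)
  p <- if (which == "mesial") tooth$contact_mesial_body else
    tooth$contact_distal_body
  rt_apply(tooth$current_pose, p)
}

#' Signed inter-proximal gap between positions 5 and 6
#'
#' Distance from the distal contact point of the second premolar to the
#' mesial contact point of the first molar, projected on the local distal
#' direction (positive = open space, ~0 = contact, negative = overlap).
#'
#' @param dentition a `dentition`.
#' @return signed gap, mm.
#' @export
gap_premolar_molar <- function(dentition) {
  c5 <- world_contact(dentition$teeth[[5]], "distal")
  c6 <- world_contact(dentition$teeth[[6]], "mesial")
  s_mid <- (dentition$teeth[[5]]$arc_s + dentition$teeth[[6]]$arc_s) / 2
  distal_dir <- as.numeric(dentition$arch$tangent(s_mid))
  sum((c6 - c5) * distal_dir)
}

contact_gap <- function(dentition, i) {
  # Euclidean gap between distal contact of tooth i and mesial of i + 1
  ci <- world_contact(dentition$teeth[[i]], "distal")
  cj <- world_contact(dentition$teeth[[i + 1]], "mesial")
  sqrt(sum((cj - ci)^2))
}

#' Tidy summary of a dentition
#'
#' @param x a `dentition`.
#' @param ... unused.
#' @return tibble, one row per tooth.
#' @method tidy dentition
#' @export
tidy.dentition <- function(x, ...) {
  tibble::tibble(
    position = vapply(x$teeth, `[[`, integer(1), "position"),
    arc_s = vapply(x$teeth, `[[`, numeric(1), "arc_s"),
    width = vapply(x$teeth, `[[`, numeric(1), "width"),
    crown_height = vapply(x$teeth, `[[`, numeric(1), "crown_height"),
    root_length = vapply(x$teeth, `[[`, numeric(1), "root_length"),
    root_count = vapply(x$teeth, `[[`, integer(1), "root_count"),
    has_attachment = vapply(x$teeth, `[[`, logical(1), "has_attachment")
  )
}

#' @export
print.dentition <- function(x, ...) {
  cat("<dentition> right maxillary quadrant, 7 teeth\n")
  cat(sprintf("  gap(5,6): %.3f mm | PDL %.2f mm | crest %.1f mm | TAD at (%.1f, %.1f, %.1f)\n",
              gap_premolar_molar(x), x$config$pdl_thickness, x$crest_z,
              x$tad$location[1], x$tad$location[2], x$tad$location[3]))
  invisible(x)
}

# ---- scene export ------------------------------------------------------------

#' Export the dentition scene to PLY surfaces and a JSON landmark file
#'
#' Writes one ASCII PLY triangle mesh per tooth (crown box + root frustums,
#' in world coordinates under the current poses) plus `landmarks.json`
#' holding positions, contact points, landmark points and 4x4 pose matrices
#' (row-major).
#'
#' @param dentition a `dentition`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
export_scene <- function(dentition, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (tooth in dentition$teeth) {
    mesh <- tooth_mesh(tooth)
    f <- file.path(dir, sprintf("tooth_%d.ply", tooth$position))
    write_ply(mesh$v, mesh$f, f)
    files <- c(files, f)
  }
  lm <- lapply(dentition$teeth, function(t) {
    marks <- tooth_landmarks(t)
    list(position = t$position,
         CP = rt_apply(t$current_pose, marks$cp_body),
         RP = rt_apply(t$current_pose, marks$rp_body),
         RC = rt_apply(t$current_pose, marks$rc_body),
         contact_mesial = world_contact(t, "mesial"),
         contact_distal = world_contact(t, "distal"),
         pose = as.numeric(t(t$current_pose)))
  })
  jf <- file.path(dir, "landmarks.json")
  jsonlite::write_json(list(teeth = lm, tad = dentition$tad$location),
                       jf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, jf))
}

tooth_mesh <- function(tooth, n_theta = 24, n_axial = 8) {
  w2 <- tooth$width / 2; b2 <- tooth$bl_width / 2; h <- tooth$crown_height
  v <- rbind(c(-w2, -b2, 0), c(w2, -b2, 0), c(w2, b2, 0), c(-w2, b2, 0),
             c(-w2, -b2, h), c(w2, -b2, h), c(w2, b2, h), c(-w2, b2, h))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(5, 7, 6), c(5, 8, 7),
             c(1, 5, 6), c(1, 6, 2), c(2, 6, 7), c(2, 7, 3),
             c(3, 7, 8), c(3, 8, 4), c(4, 8, 5), c(4, 5, 1))
  for (s in tooth$surfaces) {
    a <- s$axis
    e1 <- if (abs(a[1]) < 0.9) unit3(cross3(a, c(1, 0, 0))) else
      unit3(cross3(a, c(0, 1, 0)))
    e2 <- cross3(a, e1)
    th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
    tt <- seq(0, 1, length.out = n_axial)
    rr <- s$r_base + (s$r_tip - s$r_base) * tt
    ring <- function(j) {
      ctr <- s$base + tt[j] * s$length * a
      t(vapply(th, function(q) ctr + rr[j] * (cos(q) * e1 + sin(q) * e2),
               numeric(3)))
    }
    base_idx <- nrow(v)
    for (j in seq_len(n_axial)) v <- rbind(v, ring(j))
    for (j in seq_len(n_axial - 1)) {
      for (k in seq_len(n_theta)) {
        k2 <- if (k == n_theta) 1 else k + 1
        i1 <- base_idx + (j - 1) * n_theta + k
        i2 <- base_idx + (j - 1) * n_theta + k2
        i3 <- base_idx + j * n_theta + k
        i4 <- base_idx + j * n_theta + k2
        f <- rbind(f, c(i1, i2, i4), c(i1, i4, i3))
      }
    }
  }
  list(v = rt_apply(tooth$current_pose, v), f = f)
}

write_ply <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(vertices, digits = 8, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
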