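# Coupled quasi-static equilibrium of 7 rigid teeth on PDL foundations plus a
# rigid aligner frame with unilateral socket walls and TAD traction, solved as
# one symmetric linear system per active-set sweep. The iterative
# bone-remodeling loop re-grounds the PDL at each equilibrium; the staged
# protocol drives the aligner rest geometry through the 10-step plan and on
# to space closure.

GRAVITY_MS2 <- 9.80665

#' Elastic traction configuration
#'
#' Elastic force from the aligner hook (buccal mesial cervical region of the
#' canine socket) to the TAD. Applied to the aligner frame; the direction is
#' recomputed from current geometry before every solve.
#'
#' @param magnitude_gf force magnitude in gram-force (default 150 g,
#'   per side).
#' @return object of class `traction_config` with both gram-force and Newton
#'   magnitudes (150 gf = 1.4710 N).
#' @export
traction_config <- function(magnitude_gf = 150) {
  stopifnot(magnitude_gf > 0)
  structure(list(magnitude_gf = magnitude_gf,
                 magnitude_n = magnitude_gf * GRAVITY_MS2 / 1000),
            class = "traction_config")
}

#' Engine configuration
#'
#' @param iterations_per_step remodeling iterations per staging step
#'   (default 2).
#' @param residual_tolerance equilibrium residual tolerance, N and N*mm.
#' @param max_active_set_sweeps cap on unilateral-wall sweeps per solve.
#' @param space_closed_tolerance inter-proximal gap below which the space
#'   counts as closed, mm.
#' @param max_extension_steps extra staging steps allowed beyond the plan to
#'   reach space closure.
#' @param samples_per_tooth PDL spring samples per tooth.
#' @param aligner_dof `"symmetric"` (default: the median-section symmetry
#'   boundary condition reduces the aligner frame to translations in the
#'   median sagittal plane plus rotation about its normal), `"fixed"` (frame
#'   clamped; single-tooth test scenes) or `"full"` (all 6, no symmetry).
#' @return object of class `engine_config`.
#' @export
engine_config <- function(iterations_per_step = 2L,
                          residual_tolerance = 1e-6,
                          max_active_set_sweeps = 50L,
                          space_closed_tolerance = 0.01,
                          max_extension_steps = 10L,
                          samples_per_tooth = 400L,
                          aligner_dof = c("symmetric", "fixed", "full")) {
  aligner_dof <- match.arg(aligner_dof)
  vals <- c(iterations_per_step, residual_tolerance, max_active_set_sweeps,
            space_closed_tolerance, max_extension_steps, samples_per_tooth)
  if (any(vals <= 0)) stop("engine parameters must be positive", call. = FALSE)
  structure(list(iterations_per_step = as.integer(iterations_per_step),
                 residual_tolerance = residual_tolerance,
                 max_active_set_sweeps = as.integer(max_active_set_sweeps),
                 space_closed_tolerance = space_closed_tolerance,
                 max_extension_steps = as.integer(max_extension_steps),
                 samples_per_tooth = as.integer(samples_per_tooth),
                 aligner_dof = aligner_dof),
            class = "engine_config")
}

# Selector P (6 x n) mapping the reduced aligner coordinates to a world twist
# at the origin. Symmetric subspace: translations with zero lateral (x)
# component and rotation about the lateral axis - the rigid motions invariant
# under reflection in the median sagittal plane x = 0.
aligner_dof_matrix <- function(kind) {
  switch(kind,
         symmetric = {
           P <- matrix(0, 6, 3)
           P[2, 1] <- 1 # ty
           P[3, 2] <- 1 # tz
           P[4, 3] <- 1 # rx
           P
         },
         fixed = matrix(0, 6, 0),
         full = diag(6))
}

#' Assemble a simulation state
#'
#' @param dentition a [generate_quadrant()] dentition.
#' @param aligner a [build_aligner()] aligner on that dentition.
#' @param traction a [traction_config()] (or `NULL` for no traction).
#' @param engine an [engine_config()].
#' @param pdl_material PDL [material()] (default E = 0.67 MPa, nu = 0.45).
#' @return object of class `simulation_state`.
#' @export
simulation_state <- function(dentition, aligner,
                             traction = traction_config(),
                             engine = engine_config(),
                             pdl_material = default_materials()$pdl) {
  moduli <- foundation_moduli(pdl_material, dentition$config$pdl_thickness)
  body_samples <- lapply(dentition$teeth, sample_root_surface,
                         target_count = engine$samples_per_tooth,
                         frame = "body")
  structure(list(
    dentition = dentition,
    aligner = aligner,
    traction = traction,
    engine = engine,
    moduli = moduli,
    body_samples = body_samples,
    step_index = 0L,
    iteration_index = 0L,
    active_wall_set = NULL,
    last_solve = NULL
  ), class = "simulation_state")
}

# World spring field of tooth i under its current pose (areas are body-frame
# quantities and therefore pose-invariant).
world_samples <- function(state, i) {
  s <- state$body_samples[[i]]
  pose <- state$dentition$teeth[[i]]$current_pose
  P <- rt_apply(pose, as.matrix(s[, c("px", "py", "pz")]))
  N <- rt_apply_vec(pose, as.matrix(s[, c("nx", "ny", "nz")]))
  tibble::tibble(px = P[, 1], py = P[, 2], pz = P[, 3],
                 nx = N[, 1], ny = N[, 2], nz = N[, 3], area = s$area)
}

traction_wrench_origin <- function(state) {
  if (is.null(state$traction)) return(numeric(6))
  hook <- rt_apply(state$aligner$frame_pose,
                   state$aligner$traction_attachment_point)
  dir <- unit3(state$dentition$tad$location - hook)
  F <- state$traction$magnitude_n * dir
  c(F, cross3(hook, F))
}

# Socket stiffness in world axes about the crown reference point, given the
# current mesio-distal wall activation.
socket_matrix <- function(socket, md_active) {
  R <- socket$axes
  sc <- socket$stiffness_scale
  dt <- sc * c(if (md_active) socket$k_wall else 0,
               socket$k_bl, socket$k_vertical)
  dr <- sc * socket$k_rot
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- R %*% diag(dt) %*% t(R)
  S[4:6, 4:6] <- R %*% diag(dr) %*% t(R)
  S
}

#' Solve one quasi-static equilibrium
#'
#' Joint linear solve over the 7 x 6 tooth twists and the reduced aligner
#' frame twist such that every tooth's PDL wrench balances its socket wrench
#' and the aligner's socket reactions balance the TAD traction. Unilateral
#' mesial/distal walls are handled by active-set sweeps (all walls engaged
#' initially; walls whose contact would carry tension are released and the
#' system re-solved) until the active set is stable. Tooth poses and the
#' aligner frame pose are advanced by the converged twists.
#'
#' @param state a [simulation_state()].
#' @param config optional [engine_config()] override.
#' @return the updated state; diagnostics (per-tooth twists, socket wrenches,
#'   PDL strains, residual norms, the active wall set and the gap) are in
#'   `state$last_solve`.
#' @export
solve_equilibrium <- function(state, config = NULL) {
  eng <- if (is.null(config)) state$engine else config
  teeth <- state$dentition$teeth
  sockets <- state$aligner$sockets
  n <- length(teeth)
  P <- aligner_dof_matrix(eng$aligner_dof)
  na <- ncol(P)

  refs <- lapply(teeth, function(t) rt_apply(t$current_pose, t$ref_body))
  Ks <- vector("list", n)
  d0 <- vector("list", n) # socket rest mismatch twist
  dp <- vector("list", n) # prestrain twist (stress-free -> current)
  Ts <- vector("list", n)
  for (i in seq_len(n)) {
    Ks[[i]] <- assemble_stiffness(world_samples(state, i), state$moduli,
                                  refs[[i]])$matrix
    rest_world <- state$aligner$frame_pose %*% sockets[[i]]$rest_pose
    d0[[i]] <- rt_twist_between(teeth[[i]]$current_pose, rest_world, refs[[i]])
    dp[[i]] <- rt_twist_between(teeth[[i]]$stress_free_pose,
                                teeth[[i]]$current_pose, refs[[i]])
    Ts[[i]] <- twist_transport(refs[[i]], c(0, 0, 0))
  }
  W_tad <- traction_wrench_origin(state)

  # initial active set: every present wall engaged
  act <- vapply(sockets, function(s) s$has_mesial_wall || s$has_distal_wall,
                logical(1))
  seen <- list()
  sol <- NULL
  for (sweep in seq_len(eng$max_active_set_sweeps)) {
    Smats <- lapply(seq_len(n), function(i) socket_matrix(sockets[[i]], act[i]))
    dim_t <- 6L * n
    A <- matrix(0, dim_t + na, dim_t + na)
    b <- numeric(dim_t + na)
    for (i in seq_len(n)) {
      ix <- (6 * (i - 1) + 1):(6 * i)
      A[ix, ix] <- Ks[[i]] + Smats[[i]]
      b[ix] <- Smats[[i]] %*% d0[[i]] - Ks[[i]] %*% dp[[i]]
      if (na > 0) {
        Cpl <- -Smats[[i]] %*% Ts[[i]] %*% P
        A[ix, dim_t + seq_len(na)] <- Cpl
        A[dim_t + seq_len(na), ix] <- t(Cpl)
      }
    }
    if (na > 0) {
      aa <- matrix(0, na, na)
      ba <- as.numeric(t(P) %*% W_tad)
      for (i in seq_len(n)) {
        TSP <- t(P) %*% t(Ts[[i]]) %*% Smats[[i]]
        aa <- aa + TSP %*% Ts[[i]] %*% P
        ba <- ba - as.numeric(TSP %*% d0[[i]])
      }
      A[dim_t + seq_len(na), dim_t + seq_len(na)] <- aa
      b[dim_t + seq_len(na)] <- ba
    }
    x <- tryCatch(solve(A, b), error = function(e) {
      ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
      idx <- which.min(abs(ev$values))
      stop(sprintf(
        "singular equilibrium system; unconstrained direction dof index %d (%s)",
        idx, paste(sprintf("%.2f", ev$vectors[1:6, idx]), collapse = ", ")),
        call. = FALSE)
    })
    u <- lapply(seq_len(n), function(i) x[(6 * (i - 1) + 1):(6 * i)])
    q <- if (na > 0) x[dim_t + seq_len(na)] else numeric(0)

    # wall consistency at the solution
    m_loc1 <- numeric(n)
    new_act <- logical(n)
    for (i in seq_len(n)) {
      m <- d0[[i]] + (if (na > 0) as.numeric(Ts[[i]] %*% P %*% q) else 0) -
        u[[i]]
      m_loc1[i] <- sum(sockets[[i]]$axes[, 1] * m[1:3])
      new_act[i] <- md_wall_active(sockets[[i]], m_loc1[i])
    }
    sol <- list(u = u, q = q, m_loc1 = m_loc1, act = new_act, Smats = Smats)
    if (all(new_act == act)) break
    key <- paste(new_act, collapse = "")
    if (key %in% seen && sweep > 2) {
      stop(sprintf("active set oscillates; walls of sockets [%s] do not settle",
                   paste(which(new_act != act), collapse = ", ")),
           call. = FALSE)
    }
    seen <- c(seen, key)
    act <- new_act
    if (sweep == eng$max_active_set_sweeps) {
      stop("active-set sweeps did not converge", call. = FALSE)
    }
  }

  # diagnostics at the converged solution (before pose update, consistent
  # with the linearized solve)
  u <- sol$u; q <- sol$q
  strains <- numeric(n)
  wrenches <- vector("list", n)
  md_force <- numeric(n)
  resid_tooth <- numeric(n)
  aligner_reac <- numeric(6)
  for (i in seq_len(n)) {
    m <- d0[[i]] + (if (na > 0) as.numeric(Ts[[i]] %*% P %*% q) else 0) - u[[i]]
    w <- as.numeric(sol$Smats[[i]] %*% m)
    wrenches[[i]] <- w
    md_force[i] <- sum(sockets[[i]]$axes[, 1] * w[1:3])
    st <- strain_and_traction(world_samples(state, i), dp[[i]] + u[[i]],
                              state$moduli, refs[[i]])
    strains[i] <- st$max_strain_percent
    resid_tooth[i] <- max(abs(Ks[[i]] %*% (dp[[i]] + u[[i]]) - w))
    aligner_reac <- aligner_reac - as.numeric(t(Ts[[i]]) %*% w)
  }
  resid_aligner <- if (na > 0) {
    max(abs(t(P) %*% (aligner_reac + W_tad)))
  } else 0
  tol <- eng$residual_tolerance
  if (max(resid_tooth) > tol * 100 || resid_aligner > tol * 100) {
    warning("equilibrium residual above tolerance: ",
            signif(max(max(resid_tooth), resid_aligner), 3))
  }

  # advance poses
  for (i in seq_len(n)) {
    state$dentition$teeth[[i]]$current_pose <-
      rt_apply_twist(teeth[[i]]$current_pose, u[[i]], refs[[i]])
  }
  if (na > 0) {
    state$aligner$frame_pose <- rt_apply_twist(
      state$aligner$frame_pose, as.numeric(P %*% q), c(0, 0, 0))
  }
  state$active_wall_set <- sol$act
  state$last_solve <- list(
    twists = u, aligner_twist = q,
    refs = refs, traction_wrench = W_tad,
    max_strain_percent = strains,
    socket_wrench = wrenches,
    md_force = md_force,
    md_active = sol$act,
    residual_tooth = resid_tooth,
    residual_aligner = resid_aligner,
    gap = if (n >= 6 && !is.null(state$dentition$arch)) {
      gap_premolar_molar(state$dentition)
    } else NA_real_
  )
  state
}

#' Bone-remodeling update
#'
#' Adopts each tooth's current equilibrium pose as its new stress-free pose
#' and regenerates the PDL spring field about it (the sample field is carried
#' in body coordinates, so regeneration preserves tributary areas exactly).
#' The aligner is unchanged. A following solve under unchanged loads yields a
#' strictly smaller displacement increment.
#'
#' @param state a [simulation_state()] at equilibrium.
#' @return the remodeled state.
#' @export
remodel <- function(state) {
  for (i in seq_along(state$dentition$teeth)) {
    state$dentition$teeth[[i]]$stress_free_pose <-
      state$dentition$teeth[[i]]$current_pose
  }
  state
}

#' Space-closure test
#'
#' TRUE when the signed inter-proximal gap between the distal contact point
#' of the second premolar and the mesial contact point of the first molar is
#' at or below `tol`.
#'
#' @param state a [simulation_state()] (or a `dentition`).
#' @param tol closure tolerance, mm (default from the engine config, 0.01).
#' @return logical flag.
#' @export
detect_space_closed <- function(state, tol = NULL) {
  den <- if (inherits(state, "dentition")) state else state$dentition
  if (is.null(tol)) {
    tol <- if (inherits(state, "simulation_state")) {
      state$engine$space_closed_tolerance
    } else 0.01
  }
  gap_premolar_molar(den) <= tol
}

#' Third-iteration convergence diagnostic
#'
#' Runs `n_iterations` solve/remodel cycles on a copy of the state (the input
#' state is not advanced) and reports the maximum PDL strain observed in each
#' iteration. Used to verify that the model stabilizes within the two
#' remodeling iterations matched to each staging step: the third-iteration
#' strain stays below 0.1% of the ligament thickness.
#'
#' @param state a [simulation_state()] with the staged aligner applied.
#' @param n_iterations number of diagnostic iterations (default 3).
#' @return tibble with `iteration` and `max_strain_percent`.
#' @export
convergence_diagnostic <- function(state, n_iterations = 3L) {
  out <- numeric(n_iterations)
  for (k in seq_len(n_iterations)) {
    state <- solve_equilibrium(state)
    out[k] <- max(state$last_solve$max_strain_percent)
    state <- remodel(state)
  }
  tibble::tibble(iteration = seq_len(n_iterations), max_strain_percent = out)
}

#' Scenario configuration
#'
#' Bundles everything a reproducible run needs.
#'
#' @param dentition a [dentition_config()].
#' @param design trim design (or several for [compare_designs()]).
#' @param staging a [staging_plan()].
#' @param traction a [traction_config()] or `NULL`.
#' @param engine an [engine_config()].
#' @param seed integer seed (also forwarded to the dentition config).
#' @param check_convergence run the third-iteration strain diagnostic at each
#'   step (recorded in the trajectory, state not advanced by it).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(dentition = dentition_config(),
                            design = "con",
                            staging = staging_plan(),
                            traction = traction_config(),
                            engine = engine_config(),
                            seed = 1L,
                            check_convergence = FALSE) {
  if (!inherits(dentition, "dentition_config")) {
    dentition <- do.call(dentition_config, dentition)
  }
  dentition$seed <- as.integer(seed)
  stopifnot(all(design %in% TRIM_DESIGNS))
  structure(list(dentition = dentition, design = design, staging = staging,
                 traction = traction, engine = engine, seed = as.integer(seed),
                 check_convergence = isTRUE(check_convergence)),
            class = "scenario_config")
}

#' Run the staged distalization protocol
#'
#' For steps 1..`n_steps`: stage the aligner, then run
#' `iterations_per_step` solve/remodel cycles. After the planned steps,
#' identical extension steps continue until the inter-proximal space is
#' closed (up to `max_extension_steps`; an error carrying the final gap is
#' raised if it never closes). Records per-step, per-iteration, per-tooth
#' displacement records (relative to the initial configuration, in the fixed
#' local frames), socket forces, PDL strains, the active wall set and the
#' gap.
#'
#' @param scenario a [scenario_config()] with a single `design`.
#' @return object of class `alignersim_trajectory`.
#' @export
run_protocol <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"), length(scenario$design) == 1)
  den <- generate_quadrant(scenario$dentition)
  alg <- build_aligner(den, scenario$design)
  state <- simulation_state(den, alg, scenario$traction, scenario$engine)
  run_protocol_state(state, scenario)
}

run_protocol_state <- function(state, scenario) {
  plan <- scenario$staging
  eng <- state$engine
  den0 <- state$dentition
  frames <- lapply(den0$teeth, build_local_frame, arch = den0$arch)
  marks <- lapply(den0$teeth, tooth_landmarks)
  poses0 <- lapply(den0$teeth, `[[`, "current_pose")

  rows <- list()
  conv <- list()
  tcm <- list()
  space_closed_step <- NA_integer_
  max_steps <- plan$n_steps + eng$max_extension_steps
  for (s in seq_len(max_steps)) {
    state$aligner <- apply_staging(state$aligner, plan, s)
    state$step_index <- s
    tcm[[s]] <- tibble::tibble(
      step = s, U = s * plan$step_increment,
      delta = (s - 1) * plan$step_increment,
      temperature = tcm_temperature(s * plan$step_increment,
                                    (s - 1) * plan$step_increment,
                                    k = 0.01, d = 2))
    for (it in seq_len(eng$iterations_per_step)) {
      state$iteration_index <- it
      state <- solve_equilibrium(state)
      ls <- state$last_solve
      rec <- purrr::map_dfr(seq_along(state$dentition$teeth), function(i) {
        tooth <- state$dentition$teeth[[i]]
        r <- decompose_motion(poses0[[i]], tooth$current_pose,
                              frames[[i]], marks[[i]])
        w <- ls$socket_wrench[[i]]
        B <- tooth$frame0
        f_loc <- as.numeric(t(B) %*% w[1:3])
        dplyr::bind_cols(
          tibble::tibble(step = s, iteration = it, tooth = i,
                         design = state$aligner$design),
          r,
          tibble::tibble(f_md = f_loc[1], f_bl = f_loc[2], f_vert = f_loc[3],
                         md_active = ls$md_active[i],
                         max_strain_percent = ls$max_strain_percent[i],
                         gap = ls$gap))
      })
      rows[[length(rows) + 1]] <- rec
      state <- remodel(state)
    }
    if (scenario$check_convergence) {
      cd <- convergence_diagnostic(state, 1L) # one extra diagnostic iteration
      conv[[length(conv) + 1]] <- tibble::tibble(
        step = s, iteration = eng$iterations_per_step + 1L,
        max_strain_percent = max(cd$max_strain_percent))
    }
    if (s >= plan$n_steps &&
        detect_space_closed(state, eng$space_closed_tolerance)) {
      space_closed_step <- s
      break
    }
  }
  if (is.na(space_closed_step)) {
    stop(sprintf(
      "space did not close within %d extension steps; final gap %.3f mm",
      eng$max_extension_steps, gap_premolar_molar(state$dentition)),
      call. = FALSE)
  }
  structure(list(
    records = dplyr::bind_rows(rows),
    convergence = dplyr::bind_rows(conv),
    tcm = dplyr::bind_rows(tcm),
    space_closed_step = space_closed_step,
    design = state$aligner$design,
    scenario = scenario,
    final_state = state
  ), class = "alignersim_trajectory")
}

#' Run all trim designs on one generated arch
#'
#' @param scenario a [scenario_config()]; its `design` field is ignored.
#' @param designs designs to run (default all three).
#' @return named list of `alignersim_trajectory` objects.
#' @export
compare_designs <- function(scenario, designs = TRIM_DESIGNS) {
  stopifnot(all(designs %in% TRIM_DESIGNS))
  out <- lapply(designs, function(d) {
    sc <- scenario
    sc$design <- d
    run_protocol(sc)
  })
  stats::setNames(out, designs)
}

#' @export
print.alignersim_trajectory <- function(x, ...) {
  cat(sprintf(
    "<alignersim_trajectory> design %s | %d steps (space closed at step %d)\n",
    toupper(x$design), max(x$records$step), x$space_closed_step))
  cat(sprintf("  final gap %.4f mm | %d records\n",
              x$records$gap[nrow(x$records)], nrow(x$records)))
  invisible(x)
}
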