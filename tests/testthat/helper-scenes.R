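# Shared lazily-built scenes; heavy objects are computed once per test run.

.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .scene_cache)) {
    assign(key, builder(), envir = .scene_cache)
  }
  get(key, envir = .scene_cache)
}

default_dentition <- function() {
  cached("dentition", function() generate_quadrant(dentition_config()))
}

default_trajectories <- function() {
  cached("trajectories", function() {
    compare_designs(scenario_config(seed = 1))
  })
}

# A bare single-cone "tooth" for oracle tests (no dentition context).
bare_cone_tooth <- function(length = 13, r_base = 3, cervix = 7) {
  list(surfaces = list(alignersim:::frustum(c(0, 0, cervix), c(0, 0, 1),
                                            length, r_base, 0)),
       current_pose = diag(4))
}

# Central-difference Hessian of the finite-displacement spring-field energy;
# independent oracle for the assembled 6x6 stiffness.
energy_hessian <- function(samples, moduli, ref, h = 1e-5) {
  E <- function(tw) alignersim:::spring_field_energy(samples, moduli, ref, tw)
  H <- matrix(0, 6, 6)
  for (k in 1:6) {
    for (l in k:6) {
      ek <- numeric(6); ek[k] <- h
      el <- numeric(6); el[l] <- h
      H[k, l] <- (E(ek + el) - E(ek - el) - E(el - ek) + E(-ek - el)) /
        (4 * h^2)
      H[l, k] <- H[k, l]
    }
  }
  H
}

space_closed_records <- function(tr) {
  r <- tr$records
  r[r$step == tr$space_closed_step & r$iteration == max(r$iteration), ]
}
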