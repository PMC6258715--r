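# Shared small fixtures; everything is generated in code.

ref_section <- section_props(1.5e-3)
ref_material <- material_props()

# straight chain clamped at the base, n spheres, optional tip force
straight_chain_model <- function(n_spheres = 41, tip_force = NULL,
                                 L = 0.14) {
  asm <- nail_assembly(1, tip_offset = 0, base_radius = 0, L = L)
  m <- assemble_system(asm, params = default_contact_params()["canal"],
                       max_spacing = L / (n_spheres - 1))
  if (!is.null(tip_force))
    m$cpp$point_forces <- matrix(c(0, n_spheres - 1, tip_force), ncol = 1)
  m
}

# random small rigid-state perturbation of a chain, for property tests
perturb_chain_state <- function(chain, scale = 1e-4, rng_seed = 1) {
  set.seed(rng_seed)
  n <- chain$n_spheres
  pos <- chain$positions + matrix(rnorm(3 * n, sd = scale), n, 3)
  quats <- chain$quats
  for (i in seq_len(n)) {
    dq <- mvnail:::quat_from_axis_angle(rnorm(3), rnorm(1, sd = scale * 50))
    quats[i, ] <- mvnail:::quat_normalize(mvnail:::quat_mult(dq, quats[i, ]))
  }
  vel <- matrix(rnorm(3 * n, sd = scale), n, 3)
  ang <- matrix(rnorm(3 * n, sd = scale * 10), n, 3)
  list(positions = pos, quats = quats, velocities = vel, angvels = ang)
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(abs(a - b) / max(abs(b), .Machine$double.eps), tol)
}
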