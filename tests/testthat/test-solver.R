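test_that("a free pre-curved chain stays at its stress-free shape", {
  asm <- nail_assembly(1)
  m <- assemble_system(asm, params = default_contact_params()["canal"])
  sched <- stage_schedule(list(sim_stage("hold", 1)))
  r <- simulate(m, sched)
  expect_equal(r$status, "completed")
  un <- state_unpack(m, r$state)
  drift <- max(abs(un$nails[[1]]$positions - m$chains[[1]]$positions))
  expect_lt(drift, 1e-6)
})

test_that("settled cantilever matches the closed-form tip deflection", {
  m <- straight_chain_model(41, tip_force = c(0, 0, 1))
  s <- settle_static(m, f_tol = 1e-5)
  expect_true(s$converged)
  un <- state_unpack(m, s$state)
  EI <- ref_material$E * ref_section$I
  expect_rel_equal(un$nails[[1]]$positions[41, 3], 0.14^3 / (3 * EI), 0.02)
})

test_that("doubling the sphere count changes the tip deflection < 1%", {
  tip <- vapply(c(21, 41), function(n) {
    m <- straight_chain_model(n, tip_force = c(0, 0, 1))
    s <- settle_static(m, f_tol = 1e-5)
    state_unpack(m, s$state)$nails[[1]]$positions[n, 3]
  }, numeric(1))
  expect_rel_equal(tip[1], tip[2], 0.01)
})

test_that("energy is non-increasing during free damped motion", {
  # deflect the tip, release, and integrate without external input
  m <- straight_chain_model(21, tip_force = c(0, 0, 2))
  s <- settle_static(m, f_tol = 1e-4)
  m$cpp$point_forces <- NULL            # release the load
  sched <- stage_schedule(list(sim_stage("release", 0.25)))
  r <- simulate(m, sched, state = s$state,
                control = list(out_dt = 2e-3))
  expect_equal(r$status, "completed")
  etot <- rowSums(r$energy)
  # small tolerance absorbs the output-sampling discretization
  expect_true(all(diff(etot) < 1e-9 + 1e-6 * etot[1]))
  expect_lt(etot[length(etot)], etot[1])
})

test_that("simulation results are deterministic", {
  asm <- nail_assembly(1)
  ring <- ring_model("pin", n_guides = 1)
  m <- assemble_system(asm, ring = ring,
                       params = default_contact_params("validation"))
  sched <- stage_schedule(list(sim_stage("closure", 0.8,
                                         ring_travel = 0.05,
                                         motion_duration = 5)))
  r1 <- simulate(m, sched, ring_start = -3.5e-3)
  r2 <- simulate(m, sched, ring_start = -3.5e-3)
  expect_identical(r1$base_reaction, r2$base_reaction)
  expect_identical(r1$state, r2$state)
})

test_that("beam damping does not bias settled static forces", {
  # quasi-static contract: halving beta changes the settled contact force
  # by well under 1%
  force_with_beta <- function(beta) {
    asm <- nail_assembly(1)
    ring <- ring_model("pin", n_guides = 1)
    m <- assemble_system(asm, ring = ring,
                         params = default_contact_params("validation"),
                         beta = beta)
    st <- closed_state(m)
    s <- settle_static(m, state = st, ring_y = 0.06, drag = 600,
                       f_tol = 1e-3)
    res <- mvnail:::cpp_residual(m$cpp, s$state, 0, list(
      t0 = 0, t1 = 1, ring_y0 = 0.06, travel = 0, m_t0 = 0, m_t1 = 1,
      load_peak = 0, load_t0 = 0, load_t1 = 1, load_dir = c(1, 0, 0),
      frag_free = FALSE, drag = 0))
    # settled base reaction magnitude
    un <- state_unpack(m, s$state)
    f <- chain_internal_forces(m$chains[[1]], un$nails[[1]]$positions,
                               un$nails[[1]]$quats)
    sqrt(sum(f$force[1, ]^2))
  }
  f1 <- force_with_beta(1e-4)
  f2 <- force_with_beta(5e-5)
  expect_rel_equal(f1, f2, 0.01)
})

test_that("excessive penetration terminates the run with a diagnosis", {
  # drive a nail chain straight into a much-too-narrow canal
  asm <- nail_assembly(1, base_radius = 0)
  canal <- canal_model(radius_proximal = 2.1e-3,
                       radius_distal = c(2.1e-3, 2.1e-3),
                       bow_sagitta = 0)
  m <- assemble_system(asm, canal = canal,
                       params = default_contact_params(),
                       min_abort_depth = 1e-4)
  sched <- stage_schedule(list(sim_stage("hold", 2)))
  r <- simulate(m, sched)
  expect_equal(r$status, "excessive_penetration")
})

test_that("solver tolerance tightening leaves force peaks unchanged", {
  run <- function(rtol) {
    asm <- nail_assembly(1)
    ring <- ring_model("pin", n_guides = 1)
    m <- assemble_system(asm, ring = ring,
                         params = default_contact_params("validation"),
                         control = list(rtol = rtol, atol_v = rtol))
    sched <- stage_schedule(list(
      sim_stage("closure", 2.5, ring_travel = 0.07, motion_duration = 2.5)))
    r <- simulate(m, sched, ring_start = -3.5e-3)
    max(abs(r$base_reaction[, 3]))
  }
  p1 <- run(1e-3)
  p2 <- run(1e-4)
  expect_rel_equal(p1, p2, 0.005)
})
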