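test_that("straight mesh under a small tip force matches FL^3/3EI", {
  mesh <- beam_mesh(nail_centreline(tip_offset = 0), 30)
  sol <- static_solve(mesh, loads = data.frame(node = 31, dof = 2,
                                               value = 1))
  expect_true(sol$converged)
  EI <- ref_material$E * ref_section$I
  expect_rel_equal(sol$displacements[31, 2], 1 * 0.14^3 / (3 * EI), 0.01)
})

test_that("zero imposed displacement produces zero reactions", {
  mesh <- beam_mesh(nail_centreline(), 30)
  sol <- static_solve(mesh)
  expect_equal(max(abs(sol$reactions$reaction)), 0)
})

test_that("solution is path-independent in the increment count", {
  mesh <- beam_mesh(nail_centreline(), 24)
  cons <- data.frame(node = 17, dof = 2, value = -mesh$nodes[17, 2])
  s10 <- static_solve(mesh, cons, n_increments = 10)
  s40 <- static_solve(mesh, cons, n_increments = 40)
  expect_true(s10$converged && s40$converged)
  r10 <- s10$reactions$reaction[s10$reactions$node == 17]
  r40 <- s40$reactions$reaction[s40$reactions$node == 17]
  expect_rel_equal(r10, r40, 0.005)
})

test_that("node-pull sweep has the rise / interior-peak / fall pattern", {
  mesh <- beam_mesh(nail_centreline(), 30)
  sw <- sweep_node_pull(mesh)
  expect_false(any(is.na(sw$y)))
  # nodes on the straight run need no force
  straight <- sw$x < 0.035 - 1e-9
  expect_true(all(sw$y[straight] < 1e-9))
  pk <- which.max(sw$y)
  expect_gt(pk, sum(straight) + 2)       # interior maximum, not an edge
  expect_lt(pk, nrow(sw))
  expect_gt(sw$y[pk], sw$y[nrow(sw)])    # decreases after the peak
  # rises monotonically from the straight run to the peak
  expect_true(all(diff(sw$y[(sum(straight) + 1):pk]) > -1e-9))
  # base clamp balances the pulled node (only two force inlets)
  expect_equal(abs(sw$base_z), sw$y, tolerance = 1e-6)
})

test_that("mesh refinement leaves the sweep peak unchanged within 1%", {
  p1 <- max(sweep_node_pull(beam_mesh(nail_centreline(), 25))$y)
  p2 <- max(sweep_node_pull(beam_mesh(nail_centreline(), 50))$y)
  expect_rel_equal(p1, p2, 0.01)
})

test_that("cumulative (ring-like) sweep also yields a finite unimodal curve", {
  mesh <- beam_mesh(nail_centreline(), 20)
  sw <- sweep_node_pull(mesh, cumulative = TRUE)
  expect_false(any(is.na(sw$y)))
  pk <- which.max(sw$y)
  expect_gt(sw$y[pk], 0)
})

test_that("static benchmark and dynamic settle agree on a small instance", {
  # 10-element mesh vs 11-sphere chain with the same single-node constraint
  n_el <- 10
  cl <- nail_centreline()
  mesh <- beam_mesh(cl, n_el)
  k <- 8                                   # pulled node (1-based)
  cons <- data.frame(node = k, dof = 2, value = -mesh$nodes[k, 2])
  sol <- static_solve(mesh, cons, n_increments = 20)
  expect_true(sol$converged)
  f_oracle <- abs(sol$reactions$reaction[sol$reactions$node == k])

  asm <- nail_assembly(1, base_radius = 0)
  m <- assemble_system(asm, params = default_contact_params()["canal"],
                       max_spacing = cl$L / n_el)
  # prescribe the sphere's z to the axis with a quintic approach, then hold
  z0 <- m$chains[[1]]$positions[k, 3]
  m$cpp$prescribed <- matrix(c(0, k - 1, 2, z0, 0, 0, 0.25), ncol = 1)
  # chunk longer than the prescribed ramp (settle restarts stage time at 0)
  s <- settle_static(m, ring_y = 0, drag = 800, f_tol = 1e-3, chunk = 0.3)
  expect_true(s$converged)
  stage <- list(t0 = 1, t1 = 2, ring_y0 = 0, travel = 0, m_t0 = 0,
                m_t1 = 1, load_peak = 0, load_t0 = 0, load_t1 = 1,
                load_dir = c(1, 0, 0), frag_free = FALSE, drag = 0)
  # reaction at the prescribed DOF = minus the applied force there
  un <- state_unpack(m, s$state)
  f <- chain_internal_forces(m$chains[[1]], un$nails[[1]]$positions,
                             un$nails[[1]]$quats)
  f_mb <- abs(f$force[k, 3])
  expect_rel_equal(f_mb, f_oracle, 0.02)
})
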