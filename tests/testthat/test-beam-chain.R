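test_that("discretization rule places spheres at <= max spacing", {
  # 7 mm hole => 3.5 mm spacing => 41 spheres on the 140 mm nail
  ch <- discretize(nail_centreline(L = 0.14), 3.5e-3)
  expect_equal(ch$n_spheres, 41L)
  expect_equal(ch$L0, 0.14 / 40, tolerance = 1e-12)

  expect_equal(discretize(nail_centreline(L = 7e-3, straight_fraction = 0,
                                          tip_offset = 1e-3),
                          3.5e-3)$n_spheres, 3L)
  expect_equal(discretize(nail_centreline(L = 10e-3, straight_fraction = 0,
                                          tip_offset = 1e-3),
                          3.5e-3)$n_spheres, 4L)  # ceil(10/3.5) + 1
  expect_error(discretize(nail_centreline(L = 3e-3, straight_fraction = 0,
                                          tip_offset = 1e-4), 3.5e-3),
               "degenerate")
})

test_that("lumped masses match the half-segment rule", {
  ch <- discretize(nail_centreline(), 3.5e-3)
  rho <- ch$material$rho; A <- ch$section$A
  m_seg <- rho * A * 3.5e-3                      # 1.979e-4 kg
  expect_equal(m_seg, 1.9792e-4, tolerance = 1e-4)
  expect_equal(sum(ch$mass), rho * A * 0.14, tolerance = 1e-9)
  expect_equal(sum(ch$mass), 7.9168e-3, tolerance = 1e-4)
  expect_equal(ch$mass[1], m_seg / 2, tolerance = 1e-12)
  expect_equal(ch$mass[41], m_seg / 2, tolerance = 1e-12)
  expect_true(all(abs(ch$mass[2:40] - m_seg) < 1e-15))
  # end spheres carry half the interior rotational inertia slice
  expect_true(all(ch$inertia > 0))
})

test_that("beam stiffness matrix has the textbook structure", {
  K <- beam_stiffness(ref_section, ref_material, 3.5e-3)
  expect_equal(K[1, 1], 2e11 * pi * 1.5e-3^2 / 3.5e-3, tolerance = 1e-9)
  expect_equal(K, t(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  # 6 rigid-body modes: numerically ~1e-5 vs smallest elastic mode ~1e2
  expect_equal(sum(abs(ev) < 1), 6)
  expect_true(all(ev > -1e-6 * max(ev)))          # positive semidefinite
  # rigid translation of both ends produces no force
  u <- rep(c(1e-3, 2e-3, -1e-3, 0, 0, 0), 2)
  expect_lt(max(abs(K %*% u)), 1e-9 * max(K))
  # Euler-Bernoulli limit: bending term stiffer without shear flexibility
  Ke <- beam_stiffness(section_props(kappa = Inf), ref_material, 3.5e-3)
  expect_gt(Ke[2, 2], K[2, 2])
  expect_equal(Ke[2, 2], 12 * ref_material$E * ref_section$I / 3.5e-3^3,
               tolerance = 1e-12)
})

test_that("internal forces vanish at the stress-free reference", {
  for (tip in c(0, 0.025)) {
    ch <- discretize(nail_centreline(tip_offset = tip), 7e-3)
    f <- chain_internal_forces(ch)
    expect_lt(max(abs(f$force)), 1e-8)
    expect_lt(max(abs(f$moment)), 1e-10)
  }
})

test_that("each segment's wrench pair is self-equilibrated", {
  ch <- discretize(nail_centreline(), 3.5e-3)
  for (seed in 1:5) {
    st <- perturb_chain_state(ch, scale = 2e-4, rng_seed = seed)
    f <- chain_internal_forces(ch, st$positions, st$quats,
                               st$velocities, st$angvels)
    # total force and total moment about the origin must vanish
    # (massless elements, action-reaction with moment transport)
    expect_lt(max(abs(colSums(f$force))), 1e-6 * max(abs(f$force), 1))
    mom <- colSums(f$moment) +
      colSums(cbind(st$positions[, 2] * f$force[, 3] -
                      st$positions[, 3] * f$force[, 2],
                    st$positions[, 3] * f$force[, 1] -
                      st$positions[, 1] * f$force[, 3],
                    st$positions[, 1] * f$force[, 2] -
                      st$positions[, 2] * f$force[, 1]))
    expect_lt(max(abs(mom)), 1e-6 * max(abs(f$moment), 1))
  }
})

test_that("distal-sphere wrench matches the explicit 12-DOF matrix", {
  # independently assembled textbook matrix vs the corotational kernel:
  # displace only the last sphere of a short straight chain, so its whole
  # wrench comes from one segment with a fixed proximal end
  cl <- nail_centreline(L = 0.01, straight_fraction = 0, tip_offset = 0)
  ch <- discretize(cl, 0.006)
  expect_equal(ch$n_spheres, 3L)
  L0 <- ch$L0
  K <- beam_stiffness(ref_section, ref_material, L0)
  set.seed(42)
  for (trial in 1:4) {
    d <- rnorm(3, sd = 1e-8)                 # displacement of sphere 3
    th <- rnorm(3, sd = 1e-8)                # rotation of sphere 3
    pos <- ch$positions
    pos[3, ] <- pos[3, ] + d
    quats <- ch$quats
    quats[3, ] <- mvnail:::quat_normalize(
      mvnail:::quat_mult(mvnail:::quat_from_axis_angle(th, sqrt(sum(th^2))),
                         quats[3, ]))
    f <- chain_internal_forces(ch, pos, quats)
    # express in the element frame of segment 2 (proximal sphere 2)
    R <- mvnail:::quat_to_rot(ch$quats[2, ])
    E0 <- matrix(ch$E0[2, ], 3, 3)
    Re <- R %*% E0
    u_loc <- as.numeric(t(Re) %*% d)
    th_loc <- as.numeric(t(Re) %*% th)
    fexp <- -K[7:12, 7:12] %*% c(u_loc, th_loc)
    f3_loc <- as.numeric(t(Re) %*% f$force[3, ])
    m3_loc <- as.numeric(t(Re) %*% f$moment[3, ])
    expect_equal(c(f3_loc, m3_loc), as.numeric(fexp), tolerance = 1e-5)
  }
})

test_that("internal wrenches are objective under rigid rotation", {
  ch <- discretize(nail_centreline(), 7e-3)
  st <- perturb_chain_state(ch, scale = 5e-4, rng_seed = 3)
  f0 <- chain_internal_forces(ch, st$positions, st$quats,
                              st$velocities, st$angvels)
  q <- mvnail:::quat_from_axis_angle(c(1, 2, -1), 1.1)
  R <- mvnail:::quat_to_rot(q)
  pos <- t(R %*% t(st$positions))
  quats <- t(apply(st$quats, 1, function(qq) mvnail:::quat_mult(q, qq)))
  vel <- t(R %*% t(st$velocities))
  ang <- t(R %*% t(st$angvels))
  f1 <- chain_internal_forces(ch, pos, quats, vel, ang)
  expect_equal(f1$force, t(R %*% t(f0$force)), tolerance = 1e-9)
  expect_equal(f1$moment, t(R %*% t(f0$moment)), tolerance = 1e-9)
})

test_that("non-finite states are rejected", {
  ch <- discretize(nail_centreline(), 7e-3)
  bad <- ch$positions; bad[3, 1] <- NaN
  expect_error(chain_internal_forces(ch, bad), "non-finite")
})
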