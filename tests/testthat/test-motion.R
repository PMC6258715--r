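test_that("quintic motion law: endpoints, midpoint, derivatives", {
  m <- quintic_motion(c(0, 2.5, 5), travel = 0.33, duration = 5)
  expect_equal(m$displacement, c(0, 0.165, 0.33))
  expect_equal(m$velocity[c(1, 3)], c(0, 0))
  expect_equal(m$acceleration[c(1, 3)], c(0, 0))
  # midpoint velocity = 1.875 * travel / duration
  expect_equal(m$velocity[2], 1.875 * 0.33 / 5, tolerance = 1e-12)
  # before the start and after the end the law is clamped
  m2 <- quintic_motion(c(-1, 7), travel = 0.33, duration = 5)
  expect_equal(m2$displacement, c(0, 0.33))
  # numerical derivative check of the analytic velocity
  ts <- seq(0.5, 4.5, by = 0.25)
  v_num <- (quintic_motion(ts + 1e-6, 0.33, 5)$displacement -
              quintic_motion(ts - 1e-6, 0.33, 5)$displacement) / 2e-6
  expect_equal(quintic_motion(ts, 0.33, 5)$velocity, v_num,
               tolerance = 1e-6)
})

test_that("external load ramp follows the quintic step to 200 N", {
  l <- external_load(c(0, 5, 10, 12), peak = 200, duration = 10)
  expect_equal(l$magnitude, c(0, 100, 200, 200))
  expect_equal(l$fx, l$magnitude)           # default dip direction +x
  l2 <- external_load(5, peak = 200, duration = 10,
                      direction = c(0, 0, 2))
  expect_equal(l2$fz, 100)
  expect_equal(l2$fx, 0)
})

test_that("bushing wrench is linear and self-equilibrated", {
  b <- bushing_element(k_trans = 1e3, k_rot = 10, c_trans = 10, c_rot = 0.1)
  w0 <- bushing_wrench(c(0, 0, 0), c(0, 0, 0), bushing = b)
  expect_equal(w0$force, c(0, 0, 0))
  expect_equal(w0$moment, c(0, 0, 0))
  # pure normal translation
  w1 <- bushing_wrench(c(0, 0, 1e-3), c(0, 0, 0), bushing = b)
  expect_equal(w1$force, c(0, 0, -1))
  # superposition with a normal velocity: k d + c v
  w2 <- bushing_wrench(c(0, 0, 1e-3), c(0, 0, 0), vel = c(0, 0, 0.01),
                       bushing = b)
  expect_equal(w2$force[3], -(1e3 * 1e-3 + 10 * 0.01))
  # explicit matrix product cross-check on a mixed state
  d <- c(1e-3, -2e-3, 5e-4); r <- c(0.01, 0.02, -0.01)
  v <- c(0.1, 0, -0.05); w <- c(0.5, -0.2, 0.1)
  ww <- bushing_wrench(d, r, v, w, b)
  expect_equal(ww$force, -(diag(rep(1e3, 3)) %*% d + diag(rep(10, 3)) %*% v)[, 1])
  expect_equal(ww$moment, -(diag(rep(10, 3)) %*% r +
                              diag(rep(0.1, 3)) %*% w)[, 1])
})

test_that("stage schedules assign contiguous time windows", {
  sch <- stage_schedule(list(
    sim_stage("closure", 5, ring_travel = 0.33),
    sim_stage("expansion", 5, ring_travel = -0.33),
    sim_stage("loading", 10, load_peak = 200, fragments_free = TRUE)))
  expect_equal(sch$duration, 20)
  expect_equal(sch$stages[[2]]$t0, 5)
  expect_equal(sch$stages[[3]]$t1, 20)
  expect_true(sch$stages[[3]]$fragments_free)
  expect_error(sim_stage("x", -1), "must be >")
})
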