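test_that("zero-phase Butterworth filter has the analytic response", {
  t <- seq(0, 20, by = 0.01)
  # constant signal passes unchanged (DC gain 1)
  cst <- force_curve(t, rep(3.5, length(t)))
  f <- butterworth_lowpass(cst, cutoff = 1)
  expect_equal(f$y, cst$y, tolerance = 1e-5)
  # sinusoid at the cut-off: two passes of 1/sqrt(2) -> amplitude 1/2
  sn <- force_curve(t, sin(2 * pi * 1 * t))
  fs <- butterworth_lowpass(sn, cutoff = 1)
  mid <- t > 5 & t < 15                 # ignore filter edge transients
  expect_equal(max(abs(fs$y[mid])), 0.5, tolerance = 0.02)
  # zero phase: a symmetric pulse keeps its peak sample
  pulse <- force_curve(t, exp(-(t - 10)^2 / 0.5))
  fp <- butterworth_lowpass(pulse, cutoff = 2)
  expect_equal(fp$x[which.max(fp$y)], 10, tolerance = 0.011)
  # guards
  expect_error(butterworth_lowpass(force_curve(t, t), cutoff = 100),
               "Nyquist")
  expect_error(butterworth_lowpass(force_curve(c(0, 1, 3, 6, 7, 8, 9, 10,
                                                 11),
                                               rep(0, 9)), 0.01),
               "uniform")
})

test_that("peak comparison reports the documented percentage", {
  a <- force_curve(1:100, sin((1:100) / 15) * 5.16)
  b <- force_curve(1:100, sin((1:100) / 15) * 5.30)
  cp <- compare_peaks(a, b)
  expect_equal(cp$rel_diff_percent, 100 * (5.30 - 5.16) / 5.30,
               tolerance = 1e-9)
  expect_equal(cp$rel_diff_percent, 2.6415, tolerance = 1e-3)
  expect_equal(cp$x_offset, 0)
  ident <- compare_peaks(a, a)
  expect_equal(ident$rel_diff_percent, 0)
  expect_error(compare_peaks(a, force_curve(1:10, rep(0, 10))),
               "zero peak")
})

test_that("force_curve rejects a non-monotone abscissa", {
  expect_error(force_curve(c(1, 3, 2), c(0, 0, 0)), "monotone")
})

test_that("relative rotation recovers an injected rotation", {
  # synthetic minimal result: fragment rotated 5 degrees about x
  q5 <- mvnail:::quat_from_axis_angle(c(1, 0, 0), 5 * pi / 180)
  fake <- structure(list(
    time = c(0, 1), load = c(0, 100),
    frag_pose = rbind(c(0.07 * 0, 0.07, 0, 1, 0, 0, 0),
                      c(0, 0.07, 0, q5)),
    n_nails = 6L), class = "sim_result")
  rr <- relative_rotation(fake)
  expect_equal(rr$rotation_deg, c(0, 5), tolerance = 1e-9)
  expect_equal(rr$load, c(0, 100))
})

test_that("net distal force is a vector (not scalar) sum", {
  # two equal and opposite radial forces on the fragment cancel in the
  # net curve but not in the accompanying sum of magnitudes
  cd <- rbind(c(1, 0, 0, -1, 0, 0), c(2, 0, 0, -2, 0, 0))
  fake <- structure(list(
    time = c(0, 1), ring_y = c(0.1, 0.05), load = c(0, 0),
    canal_dist = cd, n_nails = 2L,
    stages = data.frame(name = "expansion", t0 = 0, t1 = 1)),
    class = "sim_result")
  nd <- net_distal_force(fake)
  expect_equal(nd$y, c(0, 0))
  expect_equal(nd$sum_mag, c(4, 2))       # sorted by ring position
  fake$canal_dist <- NULL
  expect_error(net_distal_force(fake), "no nail-canal")
})
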