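test_that("closed state lays every chain straight along its guide axis", {
  asm <- nail_assembly(6)
  ring <- ring_model("conceptual")
  m <- assemble_system(asm, ring = ring,
                       params = default_contact_params("conceptual"))
  st <- closed_state(m)
  un <- state_unpack(m, st)
  for (k in 1:6) {
    p <- un$nails[[k]]$positions
    # all spheres on the base vertical line, arclength preserved
    expect_lt(max(abs(sweep(p[, c(1, 3)], 2, p[1, c(1, 3)]))), 1e-12)
    expect_equal(p[, 2] - p[1, 2], m$chains[[k]]$s, tolerance = 1e-12)
  }
  # straightening stores elastic energy in the beams
  f <- chain_internal_forces(m$chains[[1]], un$nails[[1]]$positions,
                             un$nails[[1]]$quats)
  expect_gt(max(abs(f$moment)), 0.1)
})

test_that("lateral loading stiffens the fracture (finite rotation)", {
  ex <- run_expansion()
  expect_equal(ex$result$status, "completed")
  ld <- run_loading(ex, peak = 60, duration = 1.5)
  expect_equal(ld$result$status, "completed")
  rot <- ld$rotation
  expect_equal(rot$rotation_deg[1], 0, tolerance = 1e-6)
  # rotation grows with load but stays finite (the device carries the load)
  expect_gt(rot$rotation_deg[nrow(rot)], 0)
  expect_lt(rot$rotation_deg[nrow(rot)], 45)
  expect_gt(max(rot$displacement), 0)
  # nails push back on the displaced proximal fragment
  cp <- ld$result$canal_prox
  expect_gt(max(abs(cp[nrow(cp), ])), 0)
})
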