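test_that("centreline preserves arclength and reaches the tip offset", {
  cl <- nail_centreline(L = 0.14, straight_fraction = 0.25,
                        tip_offset = 0.025)
  # polyline arclength equals L (closed-form arc sampled at equal arclength)
  seg <- sqrt(rowSums(diff(cl$points)^2))
  expect_equal(sum(seg), 0.14, tolerance = 1e-5)
  expect_equal(max(cl$s) , 0.14, tolerance = 1e-12)
  # tip reaches the radial offset; radial coordinate is monotone
  # non-decreasing along the curve and maximal at the tip (dense check
  # against the closed form)
  s_dense <- seq(0, cl$L, length.out = 4001)
  r_dense <- sqrt(centreline_point(cl, s_dense)$points[, 1]^2 +
                  centreline_point(cl, s_dense)$points[, 3]^2)
  expect_equal(r_dense[length(r_dense)], 0.025, tolerance = 1e-9)
  expect_true(all(diff(r_dense) > -1e-12))
  expect_equal(which.max(r_dense), length(r_dense))
  # straight proximal run
  expect_true(all(abs(r_dense[s_dense <= 0.035]) < 1e-12))
})

test_that("zero tip offset gives a straight line and tangents stay unit", {
  cl <- nail_centreline(tip_offset = 0)
  expect_true(all(abs(cl$points[, c(1, 3)]) < 1e-15))
  expect_equal(cl$points[, 2], cl$s)
  cl2 <- nail_centreline(plane_angle = 33)
  expect_equal(rowSums(cl2$tangents^2), rep(1, nrow(cl2$tangents)),
               tolerance = 1e-12)
  # C1 tangent continuity at the straight/arc junction
  g <- centreline_point(cl2, c(0.035 - 1e-9, 0.035 + 1e-9))
  expect_lt(max(abs(g$tangents[1, ] - g$tangents[2, ])), 1e-6)
})

test_that("unreachable tip offset is a parameter error", {
  expect_error(nail_centreline(L = 0.14, straight_fraction = 0.25,
                               tip_offset = 0.08), "unreachable")
  expect_error(nail_centreline(L = -1), "must be >")
})

test_that("assembly offsets, reproducibility and perturbation bounds", {
  a <- nail_assembly(6)
  expect_equal(a$offsets_deg, c(0, 60, 120, 180, 240, 300))
  expect_true(all(a$perturb_deg == 0))

  a1 <- nail_assembly(6, perturb_max = 10, seed = 7)
  a2 <- nail_assembly(6, perturb_max = 10, seed = 7)
  expect_identical(a1$perturb_deg, a2$perturb_deg)
  expect_true(all(a1$perturb_deg >= 0 & a1$perturb_deg <= 10))
  a3 <- nail_assembly(6, perturb_max = 10, seed = 8)
  expect_false(identical(a1$perturb_deg, a3$perturb_deg))
})

test_that("ideal assembly is invariant under 60-degree rotation", {
  a <- nail_assembly(6)
  Ry <- mvnail:::rot_y(60 * pi / 180)
  for (k in 1:5) {
    rotated <- t(Ry %*% t(a$centrelines[[k]]$points))
    expect_lt(max(abs(rotated - a$centrelines[[k + 1]]$points)), 1e-12)
  }
})

test_that("ring variants expose the expected primitives", {
  seg <- ring_model("segmented", n_guides = 6)
  expect_equal(seg$n_primitives, 48)   # 8 wall patches per guide
  expect_setequal(ring_classes(seg), "ring_wall")

  con <- ring_model("conceptual", n_guides = 6)
  expect_setequal(ring_classes(con),
                  c("ring_central", "ring_cylinders", "ring_boxes"))
  # one central cylinder + per guide: 3 rim circles + 2 boxes
  expect_equal(con$n_primitives, 1 + 6 * 5)

  pin <- ring_model("pin", n_guides = 6)
  expect_equal(pin$n_primitives, 6)

  # guide axes co-located across variants
  segc <- vapply(Filter(function(p) p$guide == 1, seg$primitives),
                 function(p) p$center, numeric(3))
  conc <- vapply(Filter(function(p) !is.null(p$guide) && p$guide == 1 &&
                          p$type == "rim", con$primitives),
                 function(p) p$center, numeric(3))
  expect_equal(segc[, 1], conc[, 1], tolerance = 1e-15)

  # hole axial extent
  wall <- seg$primitives[[1]]
  expect_equal(wall$length, 7e-3)
  expect_error(ring_model("hexagonal"), "arg")
})

test_that("canal geometry: fracture plane, radius profile, extents", {
  cn <- canal_model(proximal_len = 0.1, distal_len = 0.12,
                    fracture_angle = 30, fracture_y = 0.07)
  # plane normal at 60 degrees from the tube axis (+y)
  ang <- acos(sum(cn$fracture$normal * c(0, 1, 0))) * 180 / pi
  expect_equal(ang, 60, tolerance = 1e-9)
  expect_equal(diff(cn$proximal), 0.1)
  expect_equal(diff(cn$distal), 0.12)
  # constant proximal radius, tapering distal radius
  expect_equal(canal_radius(cn, c(0, 0.05)), rep(6.5e-3, 2))
  expect_equal(canal_radius(cn, 0.19), 5.5e-3, tolerance = 1e-9)
  mid <- canal_radius(cn, 0.13)
  expect_true(mid < 6.5e-3 && mid > 5.5e-3)
  expect_error(canal_model(fracture_angle = 0), "must be >")
  expect_error(canal_model(fracture_angle = 95), "must be <")
  expect_error(canal_model(radius_proximal = 1e-3), "exceed")
})

test_that("canal fragments partition the tube surface", {
  cn <- canal_model()
  # sample points on the unsplit tube; each belongs to exactly one fragment
  ys <- seq(cn$proximal[1] + 1e-6, cn$distal[2] - 1e-6, length.out = 101)
  for (y in ys) {
    side <- sum((c(0, y, 0) - cn$fracture$point) * cn$fracture$normal)
    expect_true(is.finite(canal_radius(cn, y)))
    expect_true(abs(side) >= 0)       # side is defined everywhere
  }
  # radius lookup agrees across the split except on the fracture plane
  expect_equal(canal_radius(cn, cn$proximal[2] - 1e-9),
               canal_radius(cn, cn$distal[1] + 1e-9), tolerance = 1e-6)
})

test_that("material and section invariants", {
  mt <- material_props()
  expect_equal(mt$G, mt$E / (2 * (1 + mt$nu)), tolerance = 1e-13)
  sc <- section_props(1.5e-3)
  expect_equal(sc$J, 2 * sc$I, tolerance = 1e-13)
  expect_equal(sc$A, pi * 1.5e-3^2)
  expect_error(material_props(nu = 0.6), "must be <")
  expect_error(section_props(-1), "must be >")
})

test_that("centreline CSV export round-trips", {
  cl <- nail_centreline(n = 21)
  f <- tempfile(fileext = ".csv")
  write_centreline_csv(cl, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 21)
  expect_equal(df$z[21], 0.025, tolerance = 1e-8)
  unlink(f)
})
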