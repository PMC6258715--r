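#' Discretize a centreline into a lumped sphere-beam chain
#'
#' The flexible nail is modelled as ordered rigid spheres joined by massless
#' linear beam segments. Spheres are placed at equal arclength spacing not
#' exceeding `max_spacing`, so that `ceil(L / max_spacing) + 1` spheres
#' result; with the 7 mm guide hole this spacing is chosen as 3.5 mm so at
#' least two spheres are always engaged in the hole, which on the 140 mm
#' reference nail yields 41 spheres. Each segment stores the stress-free
#' relative pose of its two end frames taken from the curved reference
#' shape, so the pre-curved configuration is exactly stress-free.
#'
#' @param centreline A [nail_centreline()] (possibly transformed into the
#'   device frame by [nail_assembly()]).
#' @param max_spacing Maximum sphere spacing (m).
#' @param section A [section_props()].
#' @param material A [material_props()].
#' @param beta Stiffness-proportional damping coefficient of the beams (s).
#' @param shear Logical: include Timoshenko shear flexibility (default) or
#'   degenerate to Euler-Bernoulli.
#' @return An object of class `nail_chain`; masses and inertias are filled
#'   by [lump_masses()], which is called automatically.
#' @examples
#' ch <- discretize(nail_centreline(), 3.5e-3)
#' ch$n_spheres
#' @export
discretize <- function(centreline, max_spacing, section = section_props(),
                       material = material_props(), beta = 1e-4,
                       shear = TRUE) {
  stopifnot(inherits(centreline, "centreline"))
  check_num(max_spacing, "max_spacing", lower = 0, strict_lower = TRUE)
  L <- centreline$L
  if (max_spacing >= L)
    stop_param("max_spacing %g m >= nail arclength %g m: degenerate chain",
               max_spacing, L)
  n <- as.integer(ceiling(L / max_spacing - 1e-9)) + 1L
  s <- seq(0, L, length.out = n)
  L0 <- L / (n - 1)

  geo <- centreline_point(centreline, s)
  quats <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    R <- cbind(geo$tangents[i, ], geo$normals[i, ], geo$binormals[i, ])
    quats[i, ] <- rot_to_quat(R)
  }

  ## stress-free relative pose of each segment, in the proximal sphere frame
  r_rel0 <- matrix(0, n - 1, 3)
  q_rel0 <- matrix(0, n - 1, 4)
  E0 <- matrix(0, n - 1, 9)          # element frame (cols x,y,z), row-major
  for (i in seq_len(n - 1)) {
    Ra <- quat_to_rot(quats[i, ])
    Rb <- quat_to_rot(quats[i + 1, ])
    r_rel0[i, ] <- as.numeric(t(Ra) %*% (geo$points[i + 1, ] - geo$points[i, ]))
    q_rel0[i, ] <- rot_to_quat(t(Ra) %*% Rb)
    ex <- r_rel0[i, ] / sqrt(sum(r_rel0[i, ]^2))
    ez <- c(t(Ra) %*% geo$binormals[i, ])      # plane normal in a-frame
    ez <- ez - sum(ez * ex) * ex
    ez <- ez / sqrt(sum(ez^2))
    ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
            ez[3] * ex[1] - ez[1] * ex[3],
            ez[1] * ex[2] - ez[2] * ex[1])
    E0[i, ] <- c(ex, ey, ez)                   # column-stacked
  }

  chain <- structure(list(
    n_spheres = n, s = s, positions = geo$points, quats = quats,
    L0 = L0, L = L, contact_radius = section$radius,
    section = section, material = material, beta = beta, shear = shear,
    r_rel0 = r_rel0, q_rel0 = q_rel0, E0 = E0,
    mass = rep(NA_real_, n), inertia = matrix(NA_real_, n, 3)),
    class = "nail_chain")
  lump_masses(chain)
}

#' Lumped mass and inertia assignment
#'
#' End spheres carry half the mass of their adjacent beam segment; interior
#' spheres carry the sum of the two adjacent half-segment masses. Rotational
#' inertia comes from the rigid cylinder slice each sphere replaces (axis
#' along the local tangent).
#'
#' @param chain A [discretize()]d `nail_chain`.
#' @return The chain with `mass` (kg) and `inertia` (kg m^2, body-frame
#'   diagonal, tangent first) filled in.
#' @export
lump_masses <- function(chain) {
  stopifnot(inherits(chain, "nail_chain"))
  n <- chain$n_spheres
  rho <- chain$material$rho
  A <- chain$section$A
  r <- chain$section$radius
  m_seg <- rho * A * chain$L0
  m <- rep(m_seg, n)
  m[c(1, n)] <- m_seg / 2
  slice <- ifelse(seq_len(n) %in% c(1, n), chain$L0 / 2, chain$L0)
  I_ax <- m * r^2 / 2
  I_tr <- m * (3 * r^2 + slice^2) / 12
  chain$mass <- m
  chain$inertia <- cbind(I_ax, I_tr, I_tr)
  chain
}

#' 12-DOF Timoshenko beam stiffness matrix
#'
#' Standard two-node 3D beam element stiffness in the element frame (beam
#' axis along local x), DOF order `(ux, uy, uz, rx, ry, rz)` per node:
#' axial `EA/L`, torsion `GJ/L`, and coupled bending/shear in the two
#' transverse planes with shear parameter `Phi = 12 E I kappa / (G A L^2)`.
#' With `kappa = Inf` disabled (`Phi = 0`) it degenerates to the
#' Euler-Bernoulli matrix.
#'
#' @param section A [section_props()].
#' @param material A [material_props()].
#' @param L0 Element reference length (m, > 0).
#' @param shear Logical: include shear flexibility.
#' @return A symmetric positive semidefinite `12 x 12` matrix with exactly
#'   six zero-energy (rigid-body) modes.
#' @examples
#' K <- beam_stiffness(section_props(), material_props(), 3.5e-3)
#' K[1, 1]  # EA/L
#' @export
beam_stiffness <- function(section, material, L0, shear = TRUE) {
  stopifnot(inherits(section, "section_props"),
            inherits(material, "material_props"))
  check_num(L0, "L0", lower = 0, strict_lower = TRUE)
  E <- material$E; G <- material$G
  A <- section$A; I <- section$I; J <- section$J
  Phi <- if (shear && is.finite(section$kappa))
    12 * E * I * section$kappa / (G * A * L0^2) else 0

  K <- matrix(0, 12, 12)
  ax <- E * A / L0
  K[c(1, 7), c(1, 7)] <- ax * matrix(c(1, -1, -1, 1), 2)
  to <- G * J / L0
  K[c(4, 10), c(4, 10)] <- to * matrix(c(1, -1, -1, 1), 2)

  b1 <- 12 * E * I / ((1 + Phi) * L0^3)
  b2 <- 6 * E * I / ((1 + Phi) * L0^2)
  b3 <- (4 + Phi) * E * I / ((1 + Phi) * L0)
  b4 <- (2 - Phi) * E * I / ((1 + Phi) * L0)

  ## bending in the x-y plane: (uy1, rz1, uy2, rz2)
  iy <- c(2, 6, 8, 12)
  K[iy, iy] <- matrix(c(b1,  b2, -b1,  b2,
                        b2,  b3, -b2,  b4,
                       -b1, -b2,  b1, -b2,
                        b2,  b4, -b2,  b3), 4, byrow = TRUE)
  ## bending in the x-z plane: (uz1, ry1, uz2, ry2), opposite rotation sign
  iz <- c(3, 5, 9, 11)
  K[iz, iz] <- matrix(c(b1, -b2, -b1, -b2,
                       -b2,  b3,  b2,  b4,
                       -b1,  b2,  b1,  b2,
                       -b2,  b4,  b2,  b3), 4, byrow = TRUE)
  K
}

#' Internal beam wrenches of a chain at a given state
#'
#' For each massless segment, the relative displacement and rotation of the
#' distal sphere are measured in the frame of its proximal sphere against
#' the stress-free relative pose; the restoring wrench `-K u - C udot`
#' (with `C = beta K`) is applied to the distal sphere and the equilibrating
#' reaction (force and transported moment) to the proximal one.
#'
#' @param chain A `nail_chain`.
#' @param positions `n x 3` sphere positions (m); defaults to the reference.
#' @param quats `n x 4` sphere orientation quaternions (w, x, y, z).
#' @param velocities,angvels `n x 3` linear / angular velocities.
#' @return List with `force` and `moment` (`n x 3`, N and N m): the total
#'   beam wrench on each sphere.
#' @examples
#' ch <- discretize(nail_centreline(), 3.5e-3)
#' f <- chain_internal_forces(ch)      # stress-free reference: all zero
#' max(abs(f$force))
#' @export
chain_internal_forces <- function(chain, positions = chain$positions,
                                  quats = chain$quats,
                                  velocities = NULL, angvels = NULL) {
  stopifnot(inherits(chain, "nail_chain"))
  n <- chain$n_spheres
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(angvels)) angvels <- matrix(0, n, 3)
  if (!all(is.finite(positions)) || !all(is.finite(quats)) ||
      !all(is.finite(velocities)) || !all(is.finite(angvels)))
    stop_param("non-finite chain state")
  stopifnot(nrow(positions) == n, nrow(quats) == n,
            nrow(velocities) == n, nrow(angvels) == n)
  cpp_chain_forces(chain_cpp_spec(chain), t(positions), t(quats),
                   t(velocities), t(angvels))
}

## Pack the chain description for the C++ kernels.
chain_cpp_spec <- function(chain) {
  sec <- chain$section; mat <- chain$material
  Phi <- if (chain$shear && is.finite(sec$kappa))
    12 * mat$E * sec$I * sec$kappa / (mat$G * sec$A * chain$L0^2) else 0
  list(n = chain$n_spheres, L0 = chain$L0,
       EA = mat$E * sec$A, GJ = mat$G * sec$J, EI = mat$E * sec$I,
       Phi = Phi, beta = chain$beta,
       r_rel0 = t(chain$r_rel0), q_rel0 = t(chain$q_rel0),
       E0 = t(chain$E0),
       mass = chain$mass, inertia = t(chain$inertia),
       contact_radius = chain$contact_radius)
}

#' @export
print.nail_chain <- function(x, ...) {
  cat(sprintf("<nail_chain> %d spheres at %.3g mm spacing, total mass %.4g kg\n",
              x$n_spheres, 1e3 * x$L0, sum(x$mass)))
  invisible(x)
}
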