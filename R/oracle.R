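#' Static curved-beam benchmark mesh
#'
#' Independent validation model: the nail centreline meshed by two-node
#' beam elements and solved as a geometrically nonlinear (corotational)
#' static problem. The pre-curved centreline is planar, and the node-pull
#' procedure keeps the deformation in that plane, so the benchmark works in
#' the curvature plane with three DOF per node (axial displacement,
#' transverse displacement, rotation); the base node is fully clamped.
#'
#' @param centreline A [nail_centreline()] (its own frame is used; any
#'   assembly transform is ignored).
#' @param n_elements Number of beam elements (default 50).
#' @param section A [section_props()].
#' @param material A [material_props()].
#' @return Object of class `beam_mesh`: `nodes` (n+1 x 2, columns axial y
#'   and transverse z), `s` node arclengths, element reference lengths and
#'   angles, and section/material constants.
#' @export
beam_mesh <- function(centreline, n_elements = 50,
                      section = section_props(),
                      material = material_props()) {
  stopifnot(inherits(centreline, "centreline"))
  if (n_elements < 2) stop_param("`n_elements` must be >= 2")
  cl <- centreline
  cl$transform <- NULL
  s <- seq(0, cl$L, length.out = n_elements + 1)
  a0 <- cl$plane_angle * pi / 180
  geo <- centreline_point(cl, s)
  ## in-plane coordinates: axial y, transverse z (radial offset magnitude)
  z <- geo$points[, 1] * sin(a0) + geo$points[, 3] * cos(a0)
  nodes <- cbind(y = geo$points[, 2], z = z)
  d <- diff(nodes[, 1]) + 1i * diff(nodes[, 2])
  L0 <- Mod(d)
  beta0 <- Arg(d)
  E <- material$E; G <- material$G
  A <- section$A; I <- section$I
  Phi <- if (is.finite(section$kappa))
    12 * E * I * section$kappa / (G * A * mean(L0)^2) else 0
  structure(list(nodes = nodes, s = s, n_elements = n_elements, L0 = L0,
                 beta0 = beta0, EA = E * A, EI = E * I, Phi = Phi,
                 section = section, material = material),
            class = "beam_mesh")
}

## element internal force (6-vector) in global plane coordinates
oracle_elem_force <- function(mesh, e, pe1, pe2, th1, th2) {
  da <- pe2[1] - pe1[1]; db <- pe2[2] - pe1[2]
  Ln <- sqrt(da^2 + db^2)
  beta <- atan2(db, da)
  c <- da / Ln; s <- db / Ln
  ubar <- Ln - mesh$L0[e]
  ## unwrap the chord rotation relative to the reference angle
  dbeta <- beta - mesh$beta0[e]
  dbeta <- dbeta - 2 * pi * round(dbeta / (2 * pi))
  tl1 <- th1 - dbeta
  tl2 <- th2 - dbeta
  P <- mesh$Phi
  k11 <- (4 + P) / (1 + P); k12 <- (2 - P) / (1 + P)
  EIl <- mesh$EI / mesh$L0[e]
  N <- mesh$EA * ubar / mesh$L0[e]
  M1 <- EIl * (k11 * tl1 + k12 * tl2)
  M2 <- EIl * (k12 * tl1 + k11 * tl2)
  t6 <- c(-c, -s, 0, c, s, 0)
  r6 <- c(s, -c, 0, -s, c, 0)
  N * t6 - (M1 + M2) / Ln * r6 + M1 * c(0, 0, 1, 0, 0, 0) +
    M2 * c(0, 0, 0, 0, 0, 1)
}

oracle_assemble <- function(mesh, q, tangent = TRUE) {
  nn <- mesh$n_elements + 1
  Fv <- numeric(3 * nn)
  K <- if (tangent) matrix(0, 3 * nn, 3 * nn) else NULL
  eps <- 1e-8
  for (e in seq_len(mesh$n_elements)) {
    i1 <- 3 * (e - 1) + 1:3
    i2 <- 3 * e + 1:3
    qe <- q[c(i1, i2)]
    pe1 <- mesh$nodes[e, ] + qe[1:2]
    pe2 <- mesh$nodes[e + 1, ] + qe[4:5]
    fe <- oracle_elem_force(mesh, e, pe1, pe2, qe[3], qe[6])
    Fv[c(i1, i2)] <- Fv[c(i1, i2)] + fe
    if (tangent) {
      Ke <- matrix(0, 6, 6)
      for (j in 1:6) {
        qp <- qe; qp[j] <- qp[j] + eps
        fp <- oracle_elem_force(mesh, e,
                                mesh$nodes[e, ] + qp[1:2],
                                mesh$nodes[e + 1, ] + qp[4:5],
                                qp[3], qp[6])
        Ke[, j] <- (fp - fe) / eps
      }
      K[c(i1, i2), c(i1, i2)] <- K[c(i1, i2), c(i1, i2)] + Ke
    }
  }
  list(F = Fv, K = K)
}

#' Geometrically nonlinear static solve of a beam mesh
#'
#' Incremental-iterative solution: prescribed displacements (and loads) are
#' scaled up over `n_increments` steps, each equilibrated by Newton
#' iteration on the free DOF; the reaction is reported at every constrained
#' DOF. DOF are numbered (axial y, transverse z, rotation) per node.
#'
#' @param mesh A [beam_mesh()].
#' @param constraints Data frame with columns `node`, `dof` (1 = axial,
#'   2 = transverse, 3 = rotation), `value` (target displacement). The base
#'   clamp (node 1, all three DOF at 0) is always added.
#' @param loads Optional data frame with columns `node`, `dof`, `value`
#'   (force N / moment N m).
#' @param n_increments Number of load/displacement increments.
#' @param tol Relative residual tolerance.
#' @param max_iter Newton iterations per increment.
#' @return List: `q` (displacement vector), `displacements` (n+1 x 3),
#'   `reactions` (data frame for all constrained DOF), `converged`,
#'   `increments`.
#' @export
static_solve <- function(mesh, constraints = NULL, loads = NULL,
                         n_increments = 10, tol = 1e-9, max_iter = 30,
                         q0 = NULL) {
  stopifnot(inherits(mesh, "beam_mesh"))
  nn <- mesh$n_elements + 1
  ndof <- 3 * nn
  base <- data.frame(node = 1, dof = 1:3, value = 0)
  cons <- if (is.null(constraints)) base else {
    stopifnot(all(c("node", "dof", "value") %in% names(constraints)))
    rbind(base, constraints[, c("node", "dof", "value")])
  }
  ci <- 3 * (cons$node - 1) + cons$dof
  if (anyDuplicated(ci))
    stop_param("a DOF is constrained more than once")
  fext <- numeric(ndof)
  if (!is.null(loads))
    fext[3 * (loads$node - 1) + loads$dof] <- loads$value
  free <- setdiff(seq_len(ndof), ci)

  q <- if (is.null(q0)) numeric(ndof) else q0
  fscale <- sqrt(mesh$EA * mesh$EI) / mean(mesh$L0)   # force reference
  converged <- TRUE
  for (m in seq_len(n_increments)) {
    lam <- m / n_increments
    q[ci] <- lam * cons$value
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      asm <- oracle_assemble(mesh, q)
      R <- asm$F - lam * fext
      rn <- max(abs(R[free]))
      if (rn < tol * fscale) { ok <- TRUE; break }
      dq <- solve(asm$K[free, free, drop = FALSE], -R[free])
      ## damp very large rotation increments for robustness
      mx <- max(abs(dq))
      if (mx > 0.2 * max(mesh$L0) * mesh$n_elements)
        dq <- dq * (0.2 * max(mesh$L0) * mesh$n_elements / mx)
      q[free] <- q[free] + dq
    }
    if (!ok) { converged <- FALSE; break }
  }
  asm <- oracle_assemble(mesh, q, tangent = FALSE)
  reac <- asm$F - fext
  list(q = q,
       displacements = matrix(q, ncol = 3, byrow = TRUE,
                              dimnames = list(NULL, c("uy", "uz", "rot"))),
       reactions = data.frame(node = cons$node, dof = cons$dof,
                              reaction = reac[ci]),
       converged = converged, increments = n_increments)
}

#' Sequential node-pull sweep of the curved beam
#'
#' For each node in turn, an independent static analysis imposes a
#' transverse displacement equal to minus the node's transverse coordinate
#' (the node is brought onto the device axis) and records the magnitude of
#' the constraining force. With `cumulative = TRUE`, all previous nodes are
#' simultaneously held on the axis (ring-like reading); the default
#' constrains only the examined node.
#'
#' @param mesh A [beam_mesh()].
#' @param nodes Nodes to pull (default all but the clamped base).
#' @param cumulative Also hold nodes `2..k-1` on the axis.
#' @param n_increments Increments per solve (scaled with the imposed
#'   displacement).
#' @return A [force_curve()] over node arclength, with columns `node`, `s`,
#'   `z0` (imposed displacement magnitude), `force` (N, reaction at the
#'   pulled node) and `base_z` (transverse base-clamp reaction, N).
#' @export
sweep_node_pull <- function(mesh, nodes = NULL, cumulative = FALSE,
                            n_increments = NULL) {
  stopifnot(inherits(mesh, "beam_mesh"))
  nn <- mesh$n_elements + 1
  if (is.null(nodes)) nodes <- 2:nn
  out <- data.frame(node = nodes, s = mesh$s[nodes],
                    z0 = mesh$nodes[nodes, 2], force = NA_real_,
                    base_z = NA_real_)
  q_prev <- NULL
  for (i in seq_along(nodes)) {
    k <- nodes[i]
    held <- if (cumulative) 2:k else k
    cons <- data.frame(node = held, dof = 2, value = -mesh$nodes[held, 2])
    ## warm start from the previous node's solution (shapes are similar),
    ## falling back to cold incremental continuation when Newton fails
    sol <- NULL
    if (!is.null(q_prev)) {
      sol <- static_solve(mesh, cons, n_increments = 1, q0 = q_prev)
      if (!sol$converged) sol <- NULL
    }
    if (is.null(sol)) {
      ninc <- if (is.null(n_increments))
        max(4, ceiling(abs(mesh$nodes[k, 2]) / 1.5e-3)) else n_increments
      sol <- static_solve(mesh, cons, n_increments = ninc)
      for (try in 1:3) {          # stiffer paths: refine the incrementation
        if (sol$converged) break
        ninc <- ninc * 3
        sol <- static_solve(mesh, cons, n_increments = ninc, max_iter = 60)
      }
    }
    if (!sol$converged) next
    q_prev <- sol$q
    rk <- sol$reactions
    out$force[i] <- abs(rk$reaction[rk$node == k & rk$dof == 2])
    out$base_z[i] <- rk$reaction[rk$node == 1 & rk$dof == 2]
  }
  force_curve(out$s, out$force, abscissa = "arclength",
              label = if (cumulative) "node pull (cumulative)"
              else "node pull", extra = out)
}
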