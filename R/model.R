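#' Assemble a full simulation model
#'
#' Combines a nail assembly, an optional retention ring, an optional canal
#' and a stage schedule into a simulation model: chains are discretized,
#' contact pairs are enumerated per class (nail-ring primitives restricted
#' to each nail's own guide, nail-nail between adjacent chains, nail-canal
#' per fragment), the base sphere of every nail is clamped to the stub, and
#' the prescribed ring motion is attached as a rheonomic degree of freedom.
#'
#' @param assembly A [nail_assembly()].
#' @param ring A [ring_model()] or `NULL`.
#' @param canal A [canal_model()] or `NULL`.
#' @param schedule A [stage_schedule()] (may be replaced at [simulate()]
#'   time).
#' @param params Named list of [contact_params()], one per contact class
#'   (see [default_contact_params()]). Classes present in the ring model
#'   must all have parameters.
#' @param max_spacing Sphere spacing of the chains (m); 3.5 mm (half the
#'   7 mm guide hole) gives the standard 41-sphere discretization of the
#'   140 mm reference nail.
#' @param section,material Beam section and material.
#' @param beta Stiffness-proportional beam damping (s).
#' @param subdiv Contact collocation refinement along each segment: 1 =
#'   sphere centers only (spiky force signal), 2 = spheres + midpoints
#'   (default; smooth).
#' @param gravity Gravity vector (m/s^2); off by default.
#' @param fragment_mass,fragment_inertia Proximal fragment rigid-body
#'   properties (kg, kg m^2 diagonal).
#' @param bushing A [bushing_element()] joining the fragments.
#' @param min_abort_depth Absolute floor (m) of the per-class excessive
#'   penetration threshold `max(10 * d_max, min_abort_depth)`.
#' @param control Named list of solver settings overriding
#'   [solver_control()] defaults.
#' @return An object of class `sim_model`.
#' @export
assemble_system <- function(assembly, ring = NULL, canal = NULL,
                            schedule = NULL,
                            params = default_contact_params(),
                            max_spacing = 3.5e-3,
                            section = section_props(),
                            material = material_props(), beta = 1e-4,
                            subdiv = 2, gravity = c(0, 0, 0),
                            fragment_mass = 0.15,
                            fragment_inertia = c(2e-4, 5e-5, 2e-4),
                            bushing = bushing_element(),
                            min_abort_depth = 1e-3,
                            control = list()) {
  stopifnot(inherits(assembly, "nail_assembly"))
  if (!is.null(ring)) stopifnot(inherits(ring, "ring_model"))
  if (!is.null(canal)) stopifnot(inherits(canal, "canal_model"))
  if (!is.null(schedule)) stopifnot(inherits(schedule, "stage_schedule"))

  chains <- lapply(assembly$centrelines, discretize, max_spacing = max_spacing,
                   section = section, material = material, beta = beta)

  classes <- names(params)
  class_id <- function(cl) {
    i <- match(cl, classes)
    if (is.na(i)) stop_param("no contact parameters for class '%s'", cl)
    i - 1L
  }
  pmat <- vapply(params, function(p)
    c(p$K, p$e, p$C_max, p$d_max, max(10 * p$d_max, min_abort_depth)),
    numeric(5))

  ring_list <- NULL
  if (!is.null(ring)) {
    if (ring$n_guides < assembly$n_nails)
      stop_param("ring has %d guides for %d nails", ring$n_guides,
                 assembly$n_nails)
    prim <- vapply(ring$primitives, function(p) {
      row <- numeric(18)
      row[1] <- switch(p$type, wall_patch = 1, central_cylinder = 2,
                       rim = 3, box = 4)
      row[2] <- class_id(p$class)
      row[3] <- if (is.null(p$guide)) -1 else p$guide - 1L
      if (p$type == "wall_patch")
        row[4:10] <- c(p$center, p$radius, p$length, p$a0, p$a1)
      else if (p$type == "central_cylinder")
        row[7:8] <- c(p$radius, p$length)
      else if (p$type == "rim")
        row[4:9] <- c(p$center, p$circle_radius, p$tube_radius, p$y_local)
      else
        row[4:18] <- c(p$center, p$half, as.numeric(p$axes))
      row
    }, numeric(18))
    ring_list <- list(prim = prim, hole_length = ring$hole_length,
                      guide_of_nail = as.integer(seq_len(assembly$n_nails) - 1L))
  }

  canal_list <- NULL
  frag_list <- NULL
  if (!is.null(canal)) {
    pr <- canal$profile
    canal_list <- list(
      prox = c(canal$proximal, pr$R[1], pr$R[2]),
      dist = c(canal$distal, pr$R[3], pr$R[4]),
      bow = c(canal$proximal[1], canal$distal[2], canal$bow_sagitta),
      frac_point = canal$fracture$point,
      frac_normal = canal$fracture$normal,
      frame = as.numeric(canal$fracture$frame),
      class_id = class_id("canal"))
    frag_list <- list(mass = fragment_mass, inertia = fragment_inertia,
                      k = bushing$k_trans, kr = bushing$k_rot,
                      c = bushing$c_trans, cr = bushing$c_rot)
  }

  n_nails <- assembly$n_nails
  pairs <- NULL
  nn_class <- -1L
  if (n_nails > 1 && "nail_nail" %in% classes) {
    nn_class <- class_id("nail_nail")
    idx <- seq_len(n_nails) - 1L
    pairs <- rbind(idx, c(idx[-1], idx[1]))
    if (n_nails == 2) pairs <- pairs[, 1, drop = FALSE]
    storage.mode(pairs) <- "integer"
  }

  nails_cpp <- lapply(chains, function(ch) {
    sp <- chain_cpp_spec(ch)
    sp$clamped <- 0L                 # base sphere fixed to the stub
    sp
  })

  state0 <- pack_state_r(chains, !is.null(canal),
                         frag_x = if (!is.null(canal)) canal$fracture$point
                                  else NULL)

  structure(list(
    cpp = list(nails = nails_cpp, params = pmat, ring = ring_list,
               canal = canal_list, fragment = frag_list, pairs = pairs,
               nn_class = as.integer(nn_class), subdiv = as.integer(subdiv),
               gravity = gravity, prescribed = NULL),
    chains = chains, assembly = assembly, ring = ring, canal = canal,
    schedule = schedule, classes = classes, params = params,
    n_nails = n_nails,
    n_pairs = if (is.null(pairs)) 0L else ncol(pairs),
    control = do.call(solver_control, control),
    state0 = state0),
    class = "sim_model")
}

#' Solver settings
#'
#' @param h0,hmin,hmax Initial / minimum / maximum step size (s).
#' @param rtol Relative tolerance of the local error test.
#' @param atol_v,atol_w Absolute velocity tolerances (m/s, rad/s).
#' @param out_dt Output sampling interval (s); the default records 100
#'   samples per second.
#' @param max_pen_ratio Excessive-penetration abort threshold, as a multiple
#'   of the per-class abort depth.
#' @param save_states Keep full body states at every sample.
#' @return Named list of settings.
#' @export
solver_control <- function(h0 = 1e-5, hmin = 1e-10, hmax = 5e-3,
                           rtol = 1e-3, atol_v = 1e-3, atol_w = 1e-1,
                           out_dt = 0.01, max_pen_ratio = 10,
                           save_states = FALSE) {
  list(h0 = h0, hmin = hmin, hmax = hmax, rtol = rtol, atol_v = atol_v,
       atol_w = atol_w, out_dt = out_dt, max_pen_ratio = max_pen_ratio,
       save_states = save_states, record = TRUE)
}

## flat state vector: per nail sphere (x3 q4 v3 w3), then fragment if present
pack_state_r <- function(chains, has_frag, frag_x = NULL) {
  parts <- lapply(chains, function(ch) {
    as.numeric(t(cbind(ch$positions, ch$quats,
                       matrix(0, ch$n_spheres, 6))))
  })
  st <- unlist(parts)
  if (has_frag)
    st <- c(st, frag_x, c(1, 0, 0, 0), rep(0, 6))
  st
}

#' Unpack a flat state vector
#'
#' @param model A `sim_model`.
#' @param state Flat state vector (defaults to the initial state).
#' @return List with per-nail elements (`positions`, `quats`, `velocities`,
#'   `angvels`) and, when a canal is present, `fragment` (pose and
#'   velocity).
#' @export
state_unpack <- function(model, state = model$state0) {
  out <- list(nails = vector("list", model$n_nails))
  idx <- 0
  for (k in seq_len(model$n_nails)) {
    n <- model$chains[[k]]$n_spheres
    m <- matrix(state[idx + seq_len(13 * n)], ncol = 13, byrow = TRUE)
    out$nails[[k]] <- list(positions = m[, 1:3, drop = FALSE],
                           quats = m[, 4:7, drop = FALSE],
                           velocities = m[, 8:10, drop = FALSE],
                           angvels = m[, 11:13, drop = FALSE])
    idx <- idx + 13 * n
  }
  if (!is.null(model$canal)) {
    fr <- state[idx + 1:13]
    out$fragment <- list(x = fr[1:3], q = fr[4:7], v = fr[8:10],
                         w = fr[11:13])
  }
  out
}

#' @export
print.sim_model <- function(x, ...) {
  cat(sprintf("<sim_model> %d nails (%d spheres each), ring: %s, canal: %s\n",
              x$n_nails, x$chains[[1]]$n_spheres,
              if (is.null(x$ring)) "none" else x$ring$variant,
              if (is.null(x$canal)) "none" else "present"))
  invisible(x)
}
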