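#' Run a staged simulation
#'
#' Integrates the assembled model through the stage schedule with the stiff
#' linearly-implicit adaptive-step solver. The ring's axial coordinate is a
#' rheonomic (prescribed) degree of freedom following the quintic motion law
#' of each stage; its contact reaction on every nail is reported. The run
#' terminates early with status `"excessive_penetration"` when any contact
#' exceeds its per-class penetration threshold, or `"nonconvergence"` when
#' the step-size floor is reached.
#'
#' @param model A [assemble_system()] model.
#' @param schedule A [stage_schedule()]; defaults to the one stored in the
#'   model.
#' @param state Initial flat state vector (defaults to the stress-free
#'   reference assembly).
#' @param ring_start Initial ring axial position (m); defaults to the ring
#'   model's `position`.
#' @param control List of [solver_control()] overrides.
#' @return An object of class `sim_result`: uniformly sampled time series
#'   (`time`, `ring_y`, `load`, per-nail base reactions / ring forces /
#'   canal forces, per-pair nail-nail forces, fragment pose, energies,
#'   maximum penetration ratio), `stages` markers, `status`, and the final
#'   `state`.
#' @export
simulate <- function(model, schedule = model$schedule, state = model$state0,
                     ring_start = NULL, control = list()) {
  stopifnot(inherits(model, "sim_model"))
  if (is.null(schedule))
    stop_param("no stage schedule given or stored in the model")
  ctl <- utils::modifyList(model$control, control)
  ring_y <- if (!is.null(ring_start)) ring_start
            else if (!is.null(model$ring)) model$ring$position else 0

  out <- NULL
  status <- "completed"
  pen_class <- NULL
  for (sg in schedule$stages) {
    stage <- list(t0 = sg$t0, t1 = sg$t1, ring_y0 = ring_y,
                  travel = sg$ring_travel, m_t0 = sg$t0,
                  m_t1 = sg$t0 + sg$motion_duration,
                  load_peak = sg$load_peak, load_t0 = sg$t0,
                  load_t1 = sg$t0 + sg$duration,
                  load_dir = sg$load_direction,
                  frag_free = sg$fragments_free, drag = sg$drag)
    res <- cpp_simulate(model$cpp, state, stage, ctl)
    state <- res$state_final
    ## ring position actually reached (stages may truncate the motion law)
    ring_y <- ring_y + quintic_motion(res$t_end, sg$ring_travel,
                                      sg$motion_duration, sg$t0)$displacement
    out <- append_result(out, res)
    pen_class <- if (is.null(pen_class)) res$pen_class
                 else pmax(pen_class, res$pen_class)
    if (res$status != 0) {
      status <- c("completed", "excessive_penetration",
                  "nonconvergence")[res$status + 1]
      break
    }
  }

  stages <- data.frame(
    name = vapply(schedule$stages, `[[`, "", "name"),
    t0 = vapply(schedule$stages, `[[`, 0, "t0"),
    t1 = vapply(schedule$stages, `[[`, 0, "t1"))

  structure(list(time = out$t, ring_y = out$ring_y, load = out$load,
                 base_reaction = out$base_reaction,
                 ring_force = out$ring_force, ring_fmag = out$ring_fmag,
                 nn_sum = out$nn_sum, nn_vecmag = out$nn_vecmag,
                 canal_prox = out$canal_prox, canal_dist = out$canal_dist,
                 frag_pose = out$frag_pose, energy = out$energy,
                 max_pen = out$max_pen, states = out$states,
                 pen_class = stats::setNames(pen_class, model$classes),
                 stages = stages, status = status, state = state,
                 ring_end = ring_y, n_nails = model$n_nails,
                 n_pairs = model$n_pairs,
                 n_steps = out$n_steps, n_rejects = out$n_rejects),
            class = "sim_result")
}

append_result <- function(acc, res) {
  pieces <- c("t", "ring_y", "load", "base_reaction", "ring_force",
              "ring_fmag", "nn_sum", "nn_vecmag", "canal_prox", "canal_dist",
              "frag_pose", "energy", "max_pen", "states")
  if (is.null(acc)) {
    acc <- res[pieces]
    acc$n_steps <- res$n_steps
    acc$n_rejects <- res$n_rejects
    return(acc)
  }
  for (p in pieces) {
    ## the first sample of a follow-on stage duplicates the previous
    ## stage's final sample; drop it to keep the series uniform
    if (is.matrix(res[[p]])) {
      m <- res[[p]]
      if (nrow(m) > 0) m <- m[-1, , drop = FALSE]
      acc[[p]] <- rbind(acc[[p]], m)
    } else {
      acc[[p]] <- c(acc[[p]], res[[p]][-1])
    }
  }
  acc$n_steps <- acc$n_steps + res$n_steps
  acc$n_rejects <- acc$n_rejects + res$n_rejects
  acc
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d samples over %.3g s, %d nails, status: %s\n",
              length(x$time), diff(range(x$time)), x$n_nails, x$status))
  cat(sprintf("  steps: %d accepted, %d rejected\n",
              as.integer(x$n_steps), as.integer(x$n_rejects)))
  invisible(x)
}

#' Relax a model to static equilibrium
#'
#' Dynamic relaxation: the model is integrated with a strong
#' mass-proportional drag (and the ring held still) in successive chunks
#' until the kinetic energy falls below `ke_floor` and the residual force on
#' every free body is below `f_tol`.
#'
#' @param model A [assemble_system()] model.
#' @param state Starting flat state.
#' @param ring_y Ring position held during the settle (m).
#' @param drag Drag rate (1/s).
#' @param chunk Chunk duration (s).
#' @param ke_floor Kinetic-energy floor (J).
#' @param f_tol Residual force tolerance (N).
#' @param max_chunks Iteration budget.
#' @param control Solver overrides.
#' @return List with `state`, `residual` (N), `ke` (J), `converged`,
#'   `chunks`.
#' @export
settle_static <- function(model, state = model$state0, ring_y = 0,
                          drag = 2000, chunk = 0.02, ke_floor = 1e-10,
                          f_tol = 1e-4, max_chunks = 60, control = list()) {
  stopifnot(inherits(model, "sim_model"))
  ctl <- utils::modifyList(model$control, control)
  ctl$record <- FALSE
  stage <- list(t0 = 0, t1 = chunk, ring_y0 = ring_y, travel = 0,
                m_t0 = 0, m_t1 = chunk, load_peak = 0, load_t0 = 0,
                load_t1 = chunk, load_dir = c(1, 0, 0), frag_free = FALSE,
                drag = drag)
  converged <- FALSE
  res <- NULL
  for (i in seq_len(max_chunks)) {
    run <- cpp_simulate(model$cpp, state, stage, ctl)
    state <- run$state_final
    if (run$status != 0)
      stop_param("settle_static: solver status %d", run$status)
    ke <- state_kinetic_energy(model, state)
    res <- cpp_residual(model$cpp, state, 0, stage)
    if (ke < ke_floor && res$max_force < f_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("settle_static: no equilibrium within the iteration budget (",
            sprintf("KE %.3g J, residual %.3g N", ke, res$max_force), ")")
  list(state = state, residual = res$max_force, ke = ke,
       converged = converged, chunks = i)
}

state_kinetic_energy <- function(model, state) {
  un <- state_unpack(model, state)
  ke <- 0
  for (k in seq_len(model$n_nails)) {
    ch <- model$chains[[k]]
    v <- un$nails[[k]]$velocities
    w <- un$nails[[k]]$angvels
    ke <- ke + 0.5 * sum(ch$mass * rowSums(v^2)) +
      0.5 * sum(ch$inertia * w^2)   # body-diagonal approximation
  }
  ke
}

#' Evaluate the contact force set of a model state
#'
#' Runs a single force evaluation (no integration) and returns the net
#' applied force on every sphere plus the residual summary, for inspecting
#' action-reaction and equilibrium properties.
#'
#' @param model A `sim_model`.
#' @param state Flat state vector.
#' @param ring_y Ring position (m).
#' @return List from the core: `max_force`, `max_torque`, `max_pen`.
#' @export
evaluate_contacts <- function(model, state = model$state0, ring_y = 0) {
  stage <- list(t0 = 0, t1 = 1, ring_y0 = ring_y, travel = 0, m_t0 = 0,
                m_t1 = 1, load_peak = 0, load_t0 = 0, load_t1 = 1,
                load_dir = c(1, 0, 0), frag_free = FALSE, drag = 0)
  cpp_residual(model$cpp, state, 0, stage)
}
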