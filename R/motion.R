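#' Quintic smooth-step motion law
#'
#' The prescribed ring displacement follows the standard quintic smooth step
#' `s(tau) = travel * (6 tau^5 - 15 tau^4 + 10 tau^3)` with
#' `tau = clamp((t - start) / duration, 0, 1)`, which has zero velocity and
#' zero acceleration at both endpoints.
#'
#' @param t Time (s), vectorized.
#' @param travel Total displacement (m); may be negative.
#' @param duration Motion duration (s, > 0).
#' @param start Start time (s).
#' @return A data.frame with columns `t`, `displacement`, `velocity`,
#'   `acceleration`.
#' @examples
#' quintic_motion(2.5, travel = 0.33, duration = 5)
#' @export
quintic_motion <- function(t, travel, duration, start = 0) {
  check_num(travel, "travel")
  check_num(duration, "duration", lower = 0, strict_lower = TRUE)
  check_num(start, "start")
  tau <- pmin(pmax((t - start) / duration, 0), 1)
  s <- 6 * tau^5 - 15 * tau^4 + 10 * tau^3
  v <- (30 * tau^4 - 60 * tau^3 + 30 * tau^2) / duration
  a <- (120 * tau^3 - 180 * tau^2 + 60 * tau) / duration^2
  inside <- t > start & t < start + duration
  data.frame(t = t, displacement = travel * s,
             velocity = ifelse(inside, travel * v, 0),
             acceleration = ifelse(inside, travel * a, 0))
}

#' External lateral load schedule
#'
#' Horizontal force ramp applied to the proximal bone fragment during the
#' loading stage: magnitude rises from 0 to `peak` with a quintic smooth
#' step.
#'
#' @param t Time (s), vectorized.
#' @param peak Peak force magnitude (N); the reference scenario ramps to
#'   200 N.
#' @param duration Ramp duration (s).
#' @param start Ramp start time (s).
#' @param direction Unit load direction (default the fracture-plane dip
#'   direction, `+x`).
#' @return A data.frame with columns `t`, `magnitude`, `fx`, `fy`, `fz`.
#' @examples
#' external_load(c(0, 5, 10), peak = 200, duration = 10)
#' @export
external_load <- function(t, peak = 200, duration = 10, start = 0,
                          direction = c(1, 0, 0)) {
  check_num(peak, "peak")
  direction <- direction / sqrt(sum(direction^2))
  m <- quintic_motion(t, travel = peak, duration = duration,
                      start = start)$displacement
  data.frame(t = t, magnitude = m, fx = m * direction[1],
             fy = m * direction[2], fz = m * direction[3])
}

#' Fracture bushing element
#'
#' Massless 6-DOF linear spring/damper joining the two bone fragments across
#' the fracture plane, expressed in the fracture frame. It governs the
#' initial relative position of the fragments and transmits a wrench linear
#' in the 6 relative displacements and 6 relative velocities; the wrench on
#' one fragment is minus the transported wrench on the other.
#'
#' @param k_trans Translational stiffness (N/m), scalar or length-3 (fracture
#'   frame x, y, z).
#' @param k_rot Rotational stiffness (N m/rad), scalar or length-3.
#' @param c_trans Translational damping (N s/m), scalar or length-3.
#' @param c_rot Rotational damping (N m s/rad), scalar or length-3.
#' @return An object of class `bushing_element`.
#' @export
bushing_element <- function(k_trans = 1e3, k_rot = 10, c_trans = 10,
                            c_rot = 0.1) {
  expand <- function(x, nm) {
    if (length(x) == 1) x <- rep(x, 3)
    if (length(x) != 3 || any(!is.finite(x)) || any(x < 0))
      stop_param("`%s` must be 1 or 3 non-negative numbers", nm)
    x
  }
  structure(list(k_trans = expand(k_trans, "k_trans"),
                 k_rot = expand(k_rot, "k_rot"),
                 c_trans = expand(c_trans, "c_trans"),
                 c_rot = expand(c_rot, "c_rot")),
            class = "bushing_element")
}

#' Bushing wrench for a given relative state
#'
#' @param disp Relative displacement of the proximal fragment frame,
#'   expressed in the fracture frame (length 3, m).
#' @param rot Relative rotation (small-angle vector, rad, fracture frame).
#' @param vel,angvel Relative velocities (fracture frame).
#' @param bushing A [bushing_element()].
#' @return List with `force` and `moment` applied to the proximal fragment
#'   (fracture frame); the distal fragment receives the opposite wrench.
#' @export
bushing_wrench <- function(disp, rot, vel = c(0, 0, 0),
                           angvel = c(0, 0, 0), bushing = bushing_element()) {
  stopifnot(inherits(bushing, "bushing_element"))
  list(force = -(bushing$k_trans * disp + bushing$c_trans * vel),
       moment = -(bushing$k_rot * rot + bushing$c_rot * angvel))
}

#' Stage schedule for a simulation run
#'
#' Ordered closure / expansion / loading stages. Each stage prescribes the
#' ring motion (quintic law), whether the bone fragments are clamped, the
#' external load ramp, and an optional settling drag. Fragments are fully
#' fixed during closure and expansion; the proximal fragment is released and
#' loaded during the loading stage.
#'
#' @param stages List of stage descriptions as returned by [sim_stage()].
#' @return Object of class `stage_schedule`.
#' @export
stage_schedule <- function(stages) {
  stopifnot(length(stages) >= 1,
            all(vapply(stages, inherits, TRUE, "sim_stage")))
  t0 <- 0
  for (i in seq_along(stages)) {
    stages[[i]]$t0 <- t0
    t0 <- t0 + stages[[i]]$duration
    stages[[i]]$t1 <- t0
  }
  structure(list(stages = stages, duration = t0), class = "stage_schedule")
}

#' Single simulation stage
#'
#' @param name Stage label (`"settle"`, `"closure"`, `"expansion"`,
#'   `"loading"`, ...).
#' @param duration Stage duration (s).
#' @param ring_travel Signed ring travel during the stage (m, along +y).
#' @param motion_duration Duration of the quintic motion within the stage
#'   (s); defaults to the stage duration.
#' @param load_peak Peak external load during the stage (N, 0 = none).
#' @param load_direction Unit direction of the external load.
#' @param fragments_free Logical: is the proximal fragment released?
#' @param drag Mass-proportional settling drag rate (1/s, 0 = none).
#' @return Object of class `sim_stage`.
#' @export
sim_stage <- function(name, duration, ring_travel = 0,
                      motion_duration = NULL, load_peak = 0,
                      load_direction = c(1, 0, 0), fragments_free = FALSE,
                      drag = 0) {
  check_num(duration, "duration", lower = 0, strict_lower = TRUE)
  if (is.null(motion_duration)) motion_duration <- duration
  structure(list(name = name, duration = duration,
                 ring_travel = ring_travel,
                 motion_duration = motion_duration, load_peak = load_peak,
                 load_direction = load_direction / sqrt(sum(load_direction^2)),
                 fragments_free = isTRUE(fragments_free), drag = drag),
            class = "sim_stage")
}

#' @export
print.stage_schedule <- function(x, ...) {
  cat(sprintf("<stage_schedule> %d stages, %g s total\n",
              length(x$stages), x$duration))
  for (s in x$stages)
    cat(sprintf("  [%g, %g] s: %-10s travel %+g m, load %g N, fragments %s\n",
                s$t0, s$t1, s$name, s$ring_travel, s$load_peak,
                if (s$fragments_free) "free" else "fixed"))
  invisible(x)
}
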