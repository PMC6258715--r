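#' Retention ring model
#'
#' The sliding ring nut is rigid; only its contact surfaces are modelled, as
#' a set of primitives rigidly attached to the ring frame. Two variants are
#' provided:
#'
#' * `"segmented"`: each guide hole wall (a cylinder of radius
#'   `guide_radius`, length `hole_length`) is split into 8 angular wall
#'   patches, so contact detection works on small bounded surfaces instead
#'   of two long coaxial cylinders.
#' * `"conceptual"`: distributed hole-wall contact is replaced by localized
#'   primitives — one shared solid central cylinder (the ring core, radius
#'   `guide_circle_radius - guide_radius`, whose surface coincides with the
#'   inner wall of the guide holes), three rim rings per guide — at the two
#'   hole mouths and at mid-hole — sampling the hole wall at localized
#'   circles (torus-shaped edges of tube radius `rim_radius`, where the
#'   bending nail actually bears; the mid-hole circle carries the wall's
#'   interior support), and two lateral boxes per guide tangent to the hole
#'   sides (engaged only if a nail drifts circumferentially).
#'
#' The ring slides axially (+y); `position` is the world y coordinate of the
#' proximal hole mouth.
#'
#' A third variant, `"pin"`, reduces each guide to a single rounded rim ring
#' (a knife-edge guide): a pure position constraint with no slope coupling,
#' used by the oracle-validation scenario where the simulated constraint
#' must match the static benchmark's node pin.
#'
#' @param variant `"segmented"`, `"conceptual"` or `"pin"`.
#' @param guide_radius Guide hole radius (m). Default 2.2 mm (0.7 mm radial
#'   clearance around the 1.5 mm nail): a curved blade must slide through
#'   the collar without jamming, which bounds the clearance from below by
#'   the blade's slope change across the hole.
#' @param hole_length Axial length of each guide hole (m); the device's holes
#'   are 7 mm long.
#' @param n_guides Number of guide holes.
#' @param guide_circle_radius Distance of the guide hole axes from the ring
#'   axis (m).
#' @param nail_radius Nail radius (m), used to size the conceptual core.
#' @param rim_radius Tube radius of the conceptual rim rings (m).
#' @param n_segments Wall patches per guide in the segmented variant.
#' @param position Initial axial position of the ring (m).
#' @return An object of class `ring_model` with the primitive list; each
#'   primitive carries a `class` label (`"ring_wall"`, `"ring_central"`,
#'   `"ring_cylinders"`, `"ring_boxes"`) that selects its contact parameter
#'   set.
#' @examples
#' ring_model("segmented")$n_primitives
#' @export
ring_model <- function(variant = c("conceptual", "segmented", "pin"),
                       guide_radius = 2.2e-3, hole_length = 7e-3,
                       n_guides = 6, guide_circle_radius = 4e-3,
                       nail_radius = 1.5e-3, rim_radius = 1e-4,
                       n_segments = 8, position = 0) {
  variant <- match.arg(variant)
  check_num(guide_radius, "guide_radius", lower = 0, strict_lower = TRUE)
  check_num(hole_length, "hole_length", lower = 0, strict_lower = TRUE)
  if (n_guides < 1) stop_param("`n_guides` must be >= 1")
  if (guide_circle_radius < 0) stop_param("`guide_circle_radius` must be >= 0")

  angles <- (seq_len(n_guides) - 1) * 360 / n_guides
  prim <- list()
  add <- function(p) prim[[length(prim) + 1L]] <<- p

  guide_center <- function(a) {
    Ry <- rot_y(a * pi / 180)
    as.numeric(Ry %*% c(0, 0, guide_circle_radius))
  }

  if (variant == "pin") {
    for (g in seq_len(n_guides)) {
      cg <- guide_center(angles[g])
      add(list(type = "rim", class = "ring_cylinders", guide = g,
               center = cg, circle_radius = guide_radius + rim_radius,
               tube_radius = rim_radius, y_local = hole_length / 2))
    }
  } else if (variant == "segmented") {
    for (g in seq_len(n_guides)) {
      cg <- guide_center(angles[g])
      for (j in seq_len(n_segments)) {
        add(list(type = "wall_patch", class = "ring_wall", guide = g,
                 center = cg, radius = guide_radius, length = hole_length,
                 a0 = (j - 1) * 2 * pi / n_segments,
                 a1 = j * 2 * pi / n_segments))
      }
    }
  } else {
    core_r <- guide_circle_radius - guide_radius
    if (core_r <= 0)
      stop_param("conceptual core radius must be positive (guide circle %g m, hole radius %g m)",
                 guide_circle_radius, guide_radius)
    add(list(type = "central_cylinder", class = "ring_central",
             radius = core_r, length = hole_length))
    for (g in seq_len(n_guides)) {
      cg <- guide_center(angles[g])
      for (yl in c(0, hole_length / 2, hole_length)) {
        add(list(type = "rim", class = "ring_cylinders", guide = g,
                 center = cg, circle_radius = guide_radius + rim_radius,
                 tube_radius = rim_radius, y_local = yl))
      }
      ## lateral boxes tangent to the hole sides, normals circumferential
      a <- angles[g] * pi / 180
      e_rad <- c(sin(a), 0, cos(a))
      e_circ <- c(cos(a), 0, -sin(a))
      half <- c(guide_radius, hole_length / 2, 2 * guide_radius)
      for (sgn in c(-1, 1)) {
        ctr <- cg + sgn * (guide_radius + half[1]) * e_circ +
          c(0, hole_length / 2, 0)
        add(list(type = "box", class = "ring_boxes", guide = g,
                 center = ctr, half = half,
                 axes = cbind(e_circ, c(0, 1, 0), e_rad)))
      }
    }
  }

  structure(list(variant = variant, guide_radius = guide_radius,
                 hole_length = hole_length, n_guides = n_guides,
                 guide_circle_radius = guide_circle_radius,
                 nail_radius = nail_radius, rim_radius = rim_radius,
                 n_segments = if (variant == "segmented") n_segments else NA_real_,
                 position = position, primitives = prim,
                 n_primitives = length(prim)),
            class = "ring_model")
}

#' @export
print.ring_model <- function(x, ...) {
  cat(sprintf("<ring_model> %s, %d guides, %d primitives, hole %g mm x r %g mm at y = %g m\n",
              x$variant, x$n_guides, x$n_primitives, 1e3 * x$hole_length,
              1e3 * x$guide_radius, x$position))
  invisible(x)
}

#' Primitive classes present in a ring model
#' @param ring A [ring_model()].
#' @return Character vector of contact class labels.
#' @export
ring_classes <- function(ring) {
  stopifnot(inherits(ring, "ring_model"))
  unique(vapply(ring$primitives, `[[`, "", "class"))
}
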