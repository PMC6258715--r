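#' Nail assembly specification
#'
#' Places `n_nails` pre-curved nails around the device axis. Ideal
#' centrelines sit at exact `360/n_nails` degree steps; an optional
#' per-nail angular placement error, drawn uniformly from
#' `[0, perturb_max]` degrees, rotates the whole nail (base position and
#' curvature plane) about the device axis, emulating assembly tolerance.
#' The ring's guide holes stay at the ideal angles, so the perturbed
#' straight runs sit off their guide axes by `base_radius * sin(error)` —
#' up to 0.7 mm at 10 degrees, which the default guide clearance admits.
#'
#' @param n_nails Number of nails (the device has 6).
#' @param perturb_max Maximum angular placement error (degrees, >= 0).
#' @param seed Integer seed for the perturbation draws, or `NULL` for an
#'   ideal assembly. Identical seeds give identical assemblies.
#' @param base_radius Radius of the guide circle on which the nail bases sit
#'   (m).
#' @param L,straight_fraction,tip_offset,n_samples Centreline parameters,
#'   passed to [nail_centreline()].
#' @return An object of class `nail_assembly`: fields `n_nails`,
#'   `offsets_deg` (ideal), `perturb_deg`, `base_radius`, `seed`, the
#'   centreline parameters, and `centrelines` (list of world-frame
#'   [nail_centreline()]-like objects, one per nail).
#' @examples
#' a <- nail_assembly(6)
#' a$offsets_deg
#' @export
nail_assembly <- function(n_nails = 6, perturb_max = 0, seed = NULL,
                          base_radius = 4e-3, L = 0.14,
                          straight_fraction = 0.25, tip_offset = 0.025,
                          n_samples = 201) {
  if (n_nails < 1) stop_param("`n_nails` must be >= 1")
  check_num(perturb_max, "perturb_max", lower = 0)
  check_num(base_radius, "base_radius", lower = 0)

  offsets <- (seq_len(n_nails) - 1) * 360 / n_nails
  perturb <- if (!is.null(seed) && perturb_max > 0)
    with_seed(seed, runif(n_nails, 0, perturb_max)) else rep(0, n_nails)

  centrelines <- lapply(seq_len(n_nails), function(k) {
    ## whole-nail angular placement error about the device axis
    cl <- nail_centreline(L, straight_fraction, tip_offset,
                          plane_angle = 0, n = n_samples)
    transform_centreline(cl, offsets[k] + perturb[k], base_radius)
  })

  structure(list(n_nails = n_nails, offsets_deg = offsets,
                 perturb_deg = perturb, angles_deg = offsets + perturb,
                 base_radius = base_radius, seed = seed, L = L,
                 straight_fraction = straight_fraction,
                 tip_offset = tip_offset, centrelines = centrelines),
            class = "nail_assembly")
}

## Rigid placement of a nail-frame centreline into the device frame:
## translate the base onto the guide circle, then rotate about the device
## axis (+y) by the ideal offset angle.
transform_centreline <- function(cl, offset_deg, base_radius) {
  Ry <- rot_y(offset_deg * pi / 180)
  shift <- c(0, 0, base_radius)
  tf <- function(m, translate = FALSE) {
    out <- m
    if (translate) out <- sweep(out, 2, shift, "+")
    t(Ry %*% t(out))
  }
  out <- cl
  out$points <- tf(cl$points, translate = TRUE)
  out$tangents <- tf(cl$tangents)
  out$normals <- tf(cl$normals)
  out$binormals <- tf(cl$binormals)
  out$offset_deg <- offset_deg
  out$base_radius <- base_radius
  out$transform <- list(R = Ry, shift = shift)  # used by centreline_point()
  out
}

#' @export
print.nail_assembly <- function(x, ...) {
  cat(sprintf("<nail_assembly> %d nails on a %g mm guide circle\n",
              x$n_nails, 1e3 * x$base_radius))
  cat(sprintf("  ideal offsets: %s deg\n",
              paste(round(x$offsets_deg, 1), collapse = ", ")))
  if (any(x$perturb_deg != 0))
    cat(sprintf("  plane perturbations: %s deg (seed %s)\n",
                paste(round(x$perturb_deg, 3), collapse = ", "),
                format(x$seed)))
  invisible(x)
}
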