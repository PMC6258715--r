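#' Parametric pre-curved nail centreline
#'
#' Builds the stress-free reference shape of one nail blade: a straight
#' proximal run along the device axis (+y) followed by a single-curvature
#' circular arc that carries the tip to a prescribed radial offset. The curve
#' is planar; `plane_angle` rotates the curvature plane about the device axis.
#' Arclength is preserved exactly by construction (the polyline samples the
#' closed-form arc at equal arclength).
#'
#' @param L Straightened arclength of the nail (m).
#' @param straight_fraction Fraction of `L` occupied by the straight proximal
#'   run, in `[0, 1)`.
#' @param tip_offset Radial offset of the tip from the device axis (m).
#' @param plane_angle Orientation of the curvature plane about the device
#'   axis (degrees).
#' @param n Number of sample points.
#' @return An object of class `centreline`: fields `s` (arclength, m),
#'   `points` (`n x 3`, m), `tangents`, `normals`, `binormals` (`n x 3` unit
#'   vectors, the per-point material frame), plus the generating parameters
#'   (`L`, `straight_fraction`, `tip_offset`, `plane_angle`, `s0` straight
#'   length, `Rc` arc radius, `phi` total bend angle).
#' @examples
#' cl <- nail_centreline()
#' range(cl$s)
#' @export
nail_centreline <- function(L = 0.14, straight_fraction = 0.25,
                            tip_offset = 0.025, plane_angle = 0, n = 201) {
  check_num(L, "L", lower = 0, strict_lower = TRUE)
  check_num(straight_fraction, "straight_fraction", lower = 0, upper = 1,
            strict_upper = TRUE)
  check_num(tip_offset, "tip_offset", lower = 0)
  check_num(plane_angle, "plane_angle")
  if (n < 2) stop_param("`n` must be >= 2")

  s0 <- straight_fraction * L
  La <- L - s0                       # arc length of the curved portion

  if (tip_offset == 0) {
    phi <- 0; Rc <- Inf
  } else {
    ## solve Rc*(1 - cos(phi)) = tip_offset with Rc = La/phi, phi in (0, pi]
    f <- function(phi) La * (1 - cos(phi)) / phi - tip_offset
    fmax <- La * 2 / pi              # offset attained at phi = pi
    if (tip_offset >= fmax)
      stop_param("tip_offset %g m unreachable with curved arclength %g m (max %g m)",
                 tip_offset, La, fmax)
    phi <- uniroot(f, c(1e-12, pi), tol = 1e-15)$root
    Rc <- La / phi
  }

  s <- seq(0, L, length.out = n)
  ## bend angle psi(s): 0 on the straight run, (s - s0)/Rc on the arc
  psi <- ifelse(s <= s0 | !is.finite(Rc), 0, (s - s0) / Rc)
  ## in-plane coordinates (axial y, radial z before plane rotation)
  y <- ifelse(s <= s0 | !is.finite(Rc), s, s0 + Rc * sin(psi))
  z <- ifelse(s <= s0 | !is.finite(Rc), 0, Rc * (1 - cos(psi)))

  a <- plane_angle * pi / 180
  e <- c(sin(a), 0, cos(a))          # radial offset direction
  pts <- cbind(z * e[1], y, z * e[3])
  tangents <- cbind(sin(psi) * e[1], cos(psi), sin(psi) * e[3])
  normals <- cbind(cos(psi) * e[1], -sin(psi), cos(psi) * e[3])
  binormals <- matrix(rep(c(cos(a), 0, -sin(a)), each = n), ncol = 3)

  structure(list(s = s, points = pts, tangents = tangents, normals = normals,
                 binormals = binormals, L = L,
                 straight_fraction = straight_fraction,
                 tip_offset = tip_offset, plane_angle = plane_angle,
                 s0 = s0, Rc = Rc, phi = phi),
            class = "centreline")
}

#' Evaluate a centreline at arbitrary arclengths (closed form)
#'
#' @param cl A [nail_centreline()] object.
#' @param s Arclength values (m), in `[0, L]`.
#' @return List with `points`, `tangents`, `normals`, `binormals`
#'   (`length(s) x 3`).
#' @export
centreline_point <- function(cl, s) {
  stopifnot(inherits(cl, "centreline"))
  if (any(s < -1e-12 | s > cl$L + 1e-12))
    stop_param("arclength out of range [0, %g]", cl$L)
  s <- pmin(pmax(s, 0), cl$L)
  n <- length(s)
  Rc <- cl$Rc
  psi <- ifelse(s <= cl$s0 | !is.finite(Rc), 0, (s - cl$s0) / Rc)
  y <- ifelse(s <= cl$s0 | !is.finite(Rc), s, cl$s0 + Rc * sin(psi))
  z <- ifelse(s <= cl$s0 | !is.finite(Rc), 0, Rc * (1 - cos(psi)))
  a <- cl$plane_angle * pi / 180
  e <- c(sin(a), 0, cos(a))
  out <- list(points = cbind(z * e[1], y, z * e[3]),
              tangents = cbind(sin(psi) * e[1], cos(psi), sin(psi) * e[3]),
              normals = cbind(cos(psi) * e[1], -sin(psi), cos(psi) * e[3]),
              binormals = matrix(rep(c(cos(a), 0, -sin(a)), each = n),
                                 ncol = 3))
  if (!is.null(cl$transform)) {
    Ry <- cl$transform$R
    shift <- cl$transform$shift
    out$points <- t(Ry %*% t(sweep(out$points, 2, shift, "+")))
    out$tangents <- t(Ry %*% t(out$tangents))
    out$normals <- t(Ry %*% t(out$normals))
    out$binormals <- t(Ry %*% t(out$binormals))
  }
  out
}

#' Write a centreline as a CSV polyline
#'
#' @param cl A [nail_centreline()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_centreline_csv <- function(cl, path) {
  stopifnot(inherits(cl, "centreline"))
  df <- data.frame(s = cl$s, x = cl$points[, 1], y = cl$points[, 2],
                   z = cl$points[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.centreline <- function(x, ...) {
  cat(sprintf(
    "<centreline> L = %g m (straight %g m + arc %g m), tip offset %g m, plane %g deg\n",
    x$L, x$s0, x$L - x$s0, x$tip_offset, x$plane_angle))
  invisible(x)
}
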