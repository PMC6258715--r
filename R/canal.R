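#' Parametric medullary canal with an oblique fracture
#'
#' A stand-in for the (unpublished) femoral canal: two rigid bone fragments,
#' each the inner cortical tube surface, split by an oblique fracture plane.
#' The tube axis runs along +y; the radius profile is piecewise linear in y
#' (constant along the proximal fragment, linearly tapering along the distal
#' fragment by default). An optional single-plane bow displaces the tube axis
#' in the x-y plane by a sine bump of amplitude `bow_sagitta`, emulating the
#' anterior bow of a femoral shaft; it is what breaks the axial symmetry that
#' would otherwise make all six nails equivalent.
#'
#' The device base sits at y = 0; the fracture plane passes through the tube
#' axis point at `fracture_y`. Following the package's interface convention,
#' `fracture_angle` is measured from the bone's long axis, so the plane
#' normal makes an angle of `90 - fracture_angle` degrees with the tube axis.
#'
#' @param proximal_len,distal_len Axial extents of the two fragments (m).
#' @param radius_proximal Inner radius of the proximal fragment (m).
#' @param radius_distal Inner radius at the start and end of the distal
#'   fragment (length-2 vector, m); the default tapers 6.5 to 5.5 mm.
#' @param fracture_angle Fracture obliquity (degrees, in (0, 90)).
#' @param fracture_y Axial position of the fracture (m).
#' @param bow_sagitta Mid-span bow of the tube axis (m, default 0 = straight).
#' @param nail_radius Nail radius (m); the profile must clear it everywhere.
#' @return An object of class `canal_model`: knot tables `profile`
#'   (`y`, `R`) and `bow` (`y`, `x`), the fracture plane (`point`, `normal`,
#'   unit, pointing from distal into proximal), fragment extents, and the
#'   fracture frame used by the bushing.
#' @examples
#' canal_model()
#' @export
canal_model <- function(proximal_len = 0.1, distal_len = 0.12,
                        radius_proximal = 6.5e-3,
                        radius_distal = c(6.5e-3, 5.5e-3),
                        fracture_angle = 30, fracture_y = 0.07,
                        bow_sagitta = 0, nail_radius = 1.5e-3) {
  check_num(proximal_len, "proximal_len", lower = 0, strict_lower = TRUE)
  check_num(distal_len, "distal_len", lower = 0, strict_lower = TRUE)
  check_num(fracture_angle, "fracture_angle", lower = 0, upper = 90,
            strict_lower = TRUE, strict_upper = TRUE)
  if (length(radius_distal) == 1) radius_distal <- rep(radius_distal, 2)
  if (min(radius_proximal, radius_distal) <= nail_radius)
    stop_param("canal radius must exceed the nail radius everywhere")

  y0 <- fracture_y - proximal_len
  y1 <- fracture_y + distal_len
  profile <- data.frame(
    y = c(y0, fracture_y, fracture_y, y1),
    R = c(radius_proximal, radius_proximal, radius_distal[1],
          radius_distal[2]))

  yb <- seq(y0, y1, length.out = 21)
  bow <- data.frame(y = yb,
                    x = bow_sagitta * sin(pi * (yb - y0) / (y1 - y0)))

  ## plane normal at (90 - fracture_angle) deg from the +y axis, dipping in +x
  th <- (90 - fracture_angle) * pi / 180
  normal <- c(sin(th), cos(th), 0)
  xf <- bow$x[which.min(abs(bow$y - fracture_y))]
  point <- c(xf, fracture_y, 0)

  ## fracture frame: z along the plane normal, x along the dip direction
  ez <- normal
  ex <- c(cos(th), -sin(th), 0)
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  frame <- cbind(ex, ey, ez)

  structure(list(profile = profile, bow = bow,
                 fracture = list(point = point, normal = normal,
                                 angle = fracture_angle, frame = frame),
                 proximal = c(y0, fracture_y),
                 distal = c(fracture_y, y1),
                 bow_sagitta = bow_sagitta, nail_radius = nail_radius),
            class = "canal_model")
}

#' Canal inner radius at given axial positions
#' @param canal A [canal_model()].
#' @param y Axial positions (m).
#' @return Radii (m); `NA` outside the modelled extent.
#' @export
canal_radius <- function(canal, y) {
  stopifnot(inherits(canal, "canal_model"))
  ## the profile duplicates the fracture knot; interpolate per fragment
  r <- rep(NA_real_, length(y))
  pr <- y >= canal$proximal[1] - 1e-12 & y <= canal$proximal[2]
  di <- y > canal$distal[1] & y <= canal$distal[2] + 1e-12
  if (any(pr))
    r[pr] <- stats::approx(canal$profile$y[1:2], canal$profile$R[1:2],
                           y[pr], rule = 2)$y
  if (any(di))
    r[di] <- stats::approx(canal$profile$y[3:4], canal$profile$R[3:4],
                           y[di], rule = 2)$y
  r
}

#' @export
print.canal_model <- function(x, ...) {
  cat(sprintf("<canal_model> y in [%g, %g] m, fracture at %g m (%g deg), bow %g mm\n",
              x$proximal[1], x$distal[2], x$fracture$point[2],
              x$fracture$angle, 1e3 * x$bow_sagitta))
  invisible(x)
}
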