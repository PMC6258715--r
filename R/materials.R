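#' Material properties of the nail stock
#'
#' Defaults are the handbook values for implant-grade AISI 316 LVM stainless
#' steel: Young's modulus 200 GPa, density 8000 kg/m^3, Poisson ratio 0.3.
#' The shear modulus is derived as `G = E / (2 * (1 + nu))`.
#'
#' @param E Young's modulus (Pa).
#' @param rho Density (kg/m^3).
#' @param nu Poisson ratio (dimensionless, in (0, 0.5)).
#' @return An object of class `material_props` with fields `E`, `rho`, `nu`,
#'   `G`.
#' @examples
#' material_props()
#' @export
material_props <- function(E = 2e11, rho = 8000, nu = 0.3) {
  check_num(E, "E", lower = 0, strict_lower = TRUE)
  check_num(rho, "rho", lower = 0, strict_lower = TRUE)
  check_num(nu, "nu", lower = 0, upper = 0.5,
            strict_lower = TRUE, strict_upper = TRUE)
  structure(list(E = E, rho = rho, nu = nu, G = E / (2 * (1 + nu))),
            class = "material_props")
}

#' Section properties of a circular nail cross-section
#'
#' @param radius Section radius (m); the device blades have radius 1.5 mm.
#' @param kappa Timoshenko shear correction factor (10/9 for a solid circular
#'   section). Set to `Inf` to disable shear flexibility (Euler-Bernoulli).
#' @return An object of class `section_props` with fields `radius`, `A`
#'   (area, m^2), `I` (bending inertia, m^4), `J` (torsion constant, m^4),
#'   `kappa`.
#' @examples
#' section_props(1.5e-3)
#' @export
section_props <- function(radius = 1.5e-3, kappa = 10 / 9) {
  check_num(radius, "radius", lower = 0, strict_lower = TRUE)
  if (!identical(kappa, Inf))
    check_num(kappa, "kappa", lower = 0, strict_lower = TRUE)
  structure(list(radius = radius,
                 A = pi * radius^2,
                 I = pi * radius^4 / 4,
                 J = pi * radius^4 / 2,
                 kappa = kappa),
            class = "section_props")
}

#' @export
print.material_props <- function(x, ...) {
  cat(sprintf("<material_props> E = %.3g Pa, G = %.3g Pa, rho = %g kg/m^3, nu = %g\n",
              x$E, x$G, x$rho, x$nu))
  invisible(x)
}

#' @export
print.section_props <- function(x, ...) {
  cat(sprintf("<section_props> r = %g m, A = %.4g m^2, I = %.4g m^4, J = %.4g m^4\n",
              x$radius, x$A, x$I, x$J))
  invisible(x)
}
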