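#' Penalty contact parameter set
#'
#' The IMPACT-style penalty normal force is
#' `Fn = K * g^e + STEP(g, 0, 0, d_max, C_max) * dg/dt` for penetration
#' `g > 0`, floored at zero so damping never produces adhesion.
#'
#' @param K Penalty stiffness (N/m^e).
#' @param e Force exponent (>= 1).
#' @param C_max Damping coefficient at full penetration depth (N s/m).
#' @param d_max Penetration depth at which damping saturates (m).
#' @return An object of class `contact_params`.
#' @examples
#' contact_params(2e8, 2.2, 1e4, 1e-4)
#' @export
contact_params <- function(K, e = 2.2, C_max = 1e4, d_max = 1e-4) {
  check_num(K, "K", lower = 0, strict_lower = TRUE)
  check_num(e, "e", lower = 1)
  check_num(C_max, "C_max", lower = 0)
  check_num(d_max, "d_max", lower = 0, strict_lower = TRUE)
  structure(list(K = K, e = e, C_max = C_max, d_max = d_max),
            class = "contact_params")
}

#' @export
print.contact_params <- function(x, ...) {
  cat(sprintf("<contact_params> K = %.3g N/m^e, e = %g, C_max = %.3g Ns/m, d_max = %.3g m\n",
              x$K, x$e, x$C_max, x$d_max))
  invisible(x)
}

#' Default per-class contact parameter tables
#'
#' Returns the identified contact parameter sets for each contact class:
#'
#' * Segmented (real-geometry) ring: nail-to-ring and nail-to-nail sets for
#'   the single-, two- and six-nail models.
#' * Conceptual ring: separate sets for the central cylinder, the rim
#'   "cylinders" and the lateral boxes.
#' * Canal: nails against the cortical inner wall reuse the six-nail
#'   nail-to-ring set.
#'
#' The `"validation"` table is a penalty-converged set (stiff, lightly
#' damped) used only by the single-nail oracle-validation scenario, where the
#' simulation is compared against a rigid-constraint static benchmark and
#' contact compliance must not pollute the comparison.
#'
#' @param table One of `"conceptual"`, `"segmented"`, `"validation"`.
#' @param n_nails Assembly size (1, 2 or 6); selects the row of the
#'   segmented-ring table.
#' @return Named list of [contact_params()], one per contact class present.
#' @examples
#' names(default_contact_params("conceptual"))
#' @export
default_contact_params <- function(table = c("conceptual", "segmented",
                                             "validation"),
                                   n_nails = 6) {
  table <- match.arg(table)
  ## segmented-ring (real geometry) sets, per assembly size
  seg <- switch(as.character(n_nails),
    "1" = list(ring = contact_params(2e8, 2.2, 1e4, 1e-4), nail = NULL),
    "2" = list(ring = contact_params(5e8, 2.2, 1e4, 1e-4),
               nail = contact_params(1e8, 2.2, 1e3, 1e-4)),
    list(ring = contact_params(4e8, 2.2, 1e4, 1e-4),
         nail = contact_params(1e8, 2.2, 1e4, 1e-4)))
  canal <- contact_params(4e8, 2.2, 1e4, 1e-4)   # six-nail nail-to-ring set

  if (table == "segmented") {
    out <- list(ring_wall = seg$ring, nail_nail = seg$nail, canal = canal)
  } else if (table == "conceptual") {
    ## the conceptual-ring table is the final optimized set, including its
    ## own (stiffer) nail-to-nail row
    out <- list(ring_central = contact_params(4e8, 2.2, 1e4, 1e-4),
                ring_cylinders = contact_params(4e8, 2.2, 1e4, 1e-6),
                ring_boxes = contact_params(1e10, 2.2, 1e3, 1e-6),
                nail_nail = if (n_nails > 1)
                  contact_params(2e9, 2.2, 1e4, 1e-5) else NULL,
                canal = canal)
  } else {
    stiff <- contact_params(1e10, 2.2, 1e3, 1e-6)
    out <- list(ring_central = stiff, ring_cylinders = stiff,
                ring_boxes = stiff, ring_wall = stiff,
                nail_nail = seg$nail, canal = canal)
  }
  out[!vapply(out, is.null, TRUE)]
}
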