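#' @useDynLib mvnail, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif uniroot
#' @importFrom utils head tail modifyList write.csv
NULL

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_num <- function(x, name, lower = -Inf, upper = Inf,
                      strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_param("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_param("`%s` must be >= %g (got %g)", name, lower, x)
  if (strict_upper && x >= upper)
    stop_param("`%s` must be < %g (got %g)", name, upper, x)
  if (!strict_upper && x > upper)
    stop_param("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Saves and restores the caller's RNG state so that fixture generation with an
#' explicit seed never disturbs an ongoing analysis.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## ---- quaternion helpers (scalar-first convention, w x y z) ----

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-300) return(quat_identity())
  axis <- axis / n
  c(cos(angle / 2), sin(angle / 2) * axis)
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  quat_normalize(q)
}

#' Rotation angle between two orientation quaternions, in degrees
#' @keywords internal
quat_angle_deg <- function(qa, qb) {
  d <- abs(sum(qa * qb))
  d <- min(max(d, -1), 1)
  2 * acos(d) * 180 / pi
}

rot_y <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), nrow = 3, byrow = TRUE)
}
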