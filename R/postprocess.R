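#' Force curve container
#'
#' A labelled force-versus-abscissa curve (time, ring position, or node
#' arclength) used by the comparison and filtering utilities.
#'
#' @param x Abscissa values (monotone).
#' @param y Force values (N).
#' @param abscissa Abscissa label (`"time"`, `"ring_position"`,
#'   `"arclength"`, ...).
#' @param label Curve label.
#' @param extra Optional data frame with additional columns.
#' @return Object of class `force_curve` (a data frame with attributes).
#' @export
force_curve <- function(x, y, abscissa = "time", label = "", extra = NULL) {
  keep <- is.finite(x)
  x <- x[keep]; y <- y[keep]
  if (is.unsorted(x, strictly = FALSE))
    stop_param("force_curve abscissa must be monotone")
  df <- data.frame(x = x, y = y)
  if (!is.null(extra)) df <- cbind(df, extra[keep, setdiff(names(extra),
                                                           c("x", "y")),
                                             drop = FALSE])
  structure(df, abscissa = abscissa, label = label,
            class = c("force_curve", "data.frame"))
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> '%s' over %s: %d points, peak |y| = %.4g N\n",
              attr(x, "label"), attr(x, "abscissa"), nrow(x),
              max(abs(x$y), na.rm = TRUE)))
  invisible(x)
}

#' Zero-phase second-order Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) filtering of a uniformly sampled force
#' curve; the sphere-mode ring contact signal shows spikes as spheres enter
#' and leave the guide hole, and a low-pass at about 1 Hz recovers the
#' underlying quasi-static force pattern. Zero-phase filtering preserves
#' the peak location used by [compare_peaks()].
#'
#' @param curve A [force_curve()] (or data frame with `x`, `y`).
#' @param cutoff Cut-off frequency (Hz).
#' @param order Filter order (applied once forward and once backward, so
#'   the net attenuation at the cut-off is 1/2 for `order = 2`).
#' @return The filtered [force_curve()].
#' @export
butterworth_lowpass <- function(curve, cutoff = 1, order = 2) {
  x <- curve$x; y <- curve$y
  dx <- diff(x)
  if (length(dx) < 8) stop_param("curve too short to filter")
  if (max(abs(dx - mean(dx))) > 1e-6 * mean(dx))
    stop_param("butterworth_lowpass requires uniform sampling; resample first")
  fs <- 1 / mean(dx)
  if (cutoff >= fs / 2)
    stop_param("cutoff %g Hz is not below the Nyquist frequency %g Hz",
               cutoff, fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  ## odd-reflection padding suppresses the start/end transients of the
  ## forward-backward pass (filtfilt itself applies no initial conditions)
  n <- length(y)
  npad <- min(n - 1, ceiling(6 * fs / cutoff))
  head_pad <- 2 * y[1] - y[(npad + 1):2]
  tail_pad <- 2 * y[n] - y[(n - 1):(n - npad)]
  yf <- signal::filtfilt(bf, c(head_pad, y, tail_pad))
  yf <- yf[npad + seq_len(n)]
  force_curve(x, yf, abscissa = attr(curve, "abscissa"),
              label = paste0(attr(curve, "label"), " (filtered)"))
}

#' Net force on the distal fragment versus ring position
#'
#' Vector sum of all nail-on-distal-fragment contact forces at each output
#' sample; the magnitude is reported against the ring axial position (so
#' the choice of motion law cancels out of comparisons). The sum of
#' magnitudes is also carried along as column `sum_mag`.
#'
#' @param result A [simulate()] result from a run with a canal.
#' @param stage Optional stage name to restrict to (e.g. `"expansion"`).
#' @param after Optional time (s); keep only samples at `t >= after`.
#' @return A [force_curve()] over ring position.
#' @export
net_distal_force <- function(result, stage = NULL, after = NULL) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$canal_dist) || ncol(result$canal_dist) == 0)
    stop_param("run has no nail-canal contact records")
  idx <- seq_along(result$time)
  if (!is.null(stage)) {
    st <- result$stages[result$stages$name == stage, ]
    if (nrow(st) == 0) stop_param("no stage named '%s'", stage)
    idx <- which(result$time >= st$t0[1] & result$time <= st$t1[1])
  }
  if (!is.null(after)) idx <- idx[result$time[idx] >= after]
  nc <- result$n_nails
  ## forces ON the nails; the fragment sees the opposite
  fx <- -rowSums(result$canal_dist[idx, 3 * seq_len(nc) - 2, drop = FALSE])
  fy <- -rowSums(result$canal_dist[idx, 3 * seq_len(nc) - 1, drop = FALSE])
  fz <- -rowSums(result$canal_dist[idx, 3 * seq_len(nc), drop = FALSE])
  mag <- sqrt(fx^2 + fy^2 + fz^2)
  summag <- numeric(length(idx))
  for (k in seq_len(nc)) {
    cols <- 3 * (k - 1) + 1:3
    summag <- summag + sqrt(rowSums(result$canal_dist[idx, cols,
                                                      drop = FALSE]^2))
  }
  ord <- order(result$ring_y[idx])
  force_curve(result$ring_y[idx][ord], mag[ord], abscissa = "ring_position",
              label = "net distal force",
              extra = data.frame(sum_mag = summag[ord],
                                 time = result$time[idx][ord]))
}

#' Relative rotation between the bone fragments versus applied load
#'
#' Axis-angle magnitude of the rotation between the proximal fragment frame
#' and the (fixed) distal fragment, paired with the instantaneous external
#' load magnitude.
#'
#' @param result A [simulate()] result with a loading stage.
#' @return Data frame with columns `load` (N), `rotation_deg`,
#'   `displacement` (m, fragment origin translation) and `time`.
#' @export
relative_rotation <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$frag_pose) || ncol(result$frag_pose) == 0)
    stop_param("run has no fragment states")
  q <- result$frag_pose[, 4:7, drop = FALSE]
  ang <- 2 * acos(pmin(1, abs(q[, 1]))) * 180 / pi
  x0 <- result$frag_pose[1, 1:3]
  disp <- sqrt((result$frag_pose[, 1] - x0[1])^2 +
               (result$frag_pose[, 2] - x0[2])^2 +
               (result$frag_pose[, 3] - x0[3])^2)
  data.frame(load = result$load, rotation_deg = ang, displacement = disp,
             time = result$time)
}

#' Compare the peaks of two force curves
#'
#' @param a,b [force_curve()]s (peak of `|y|`); `b` is the reference.
#' @return List: `peak_a`, `peak_b` (N), `rel_diff_percent`
#'   (`100 |peak_a - peak_b| / peak_b`), `x_a`, `x_b` (argmax abscissae)
#'   and `x_offset`.
#' @export
compare_peaks <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) stop_param("empty force curve")
  pa <- max(abs(a$y), na.rm = TRUE)
  pb <- max(abs(b$y), na.rm = TRUE)
  if (pb <= 0) stop_param("reference curve has zero peak")
  xa <- a$x[which.max(abs(a$y))]
  xb <- b$x[which.max(abs(b$y))]
  list(peak_a = pa, peak_b = pb,
       rel_diff_percent = 100 * abs(pa - pb) / pb,
       x_a = xa, x_b = xb, x_offset = xa - xb)
}

#' Ring contact force curve of one nail
#'
#' Constraint-force style curve: either the reaction force at the nail's
#' clamped base (`source = "base"`, the force the reference validation procedure
#' tracks) or the net nail-ring contact force (`source = "ring"`), against
#' ring position or time.
#'
#' @param result A [simulate()] result.
#' @param nail Nail index.
#' @param source `"base"` or `"ring"`.
#' @param component `"mag"` for the magnitude, `"trans"` for the transverse
#'   (bending-plane) magnitude `sqrt(x^2 + z^2)`, or a single axis.
#' @param against `"ring_position"` or `"time"`.
#' @param stage Optional stage name filter.
#' @return A [force_curve()].
#' @export
nail_force_curve <- function(result, nail = 1,
                             source = c("base", "ring"),
                             component = c("mag", "trans", "z", "y", "x"),
                             against = c("ring_position", "time"),
                             stage = NULL) {
  stopifnot(inherits(result, "sim_result"))
  source <- match.arg(source)
  component <- match.arg(component)
  against <- match.arg(against)
  idx <- seq_along(result$time)
  if (!is.null(stage)) {
    st <- result$stages[result$stages$name == stage, ]
    if (nrow(st) == 0) stop_param("no stage named '%s'", stage)
    idx <- which(result$time >= st$t0[1] & result$time <= st$t1[1])
  }
  m <- if (source == "base") result$base_reaction else result$ring_force
  cols <- 3 * (nail - 1) + 1:3
  v <- m[idx, cols, drop = FALSE]
  y <- switch(component,
              mag = sqrt(rowSums(v^2)),
              trans = sqrt(v[, 1]^2 + v[, 3]^2),
              x = v[, 1], y = v[, 2], z = v[, 3])
  x <- if (against == "time") result$time[idx] else result$ring_y[idx]
  ord <- order(x)
  force_curve(x[ord], y[ord], abscissa = against,
              label = sprintf("nail %d %s force (%s)", nail, source,
                              component))
}
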