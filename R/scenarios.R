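#' Closed-device state (nails straightened in their guides)
#'
#' Analytic construction of the closed configuration: every chain is laid
#' straight along its guide axis (the pre-curvature becomes stored bending
#' strain), the way the ring holds the device before expansion. A short
#' [settle_static()] pass should follow to equilibrate against the ring and
#' canal before a withdrawal stage.
#'
#' @param model A [assemble_system()] model.
#' @return Flat state vector.
#' @export
closed_state <- function(model) {
  stopifnot(inherits(model, "sim_model"))
  st <- model$state0
  idx <- 0
  for (k in seq_len(model$n_nails)) {
    ch <- model$chains[[k]]
    n <- ch$n_spheres
    base <- ch$positions[1, ]
    q0 <- ch$quats[1, ]
    m <- matrix(0, n, 13)
    m[, 1] <- base[1]
    m[, 2] <- base[2] + ch$s
    m[, 3] <- base[3]
    m[, 4:7] <- matrix(q0, n, 4, byrow = TRUE)
    st[idx + seq_len(13 * n)] <- as.numeric(t(m))
    idx <- idx + 13 * n
  }
  st
}

#' Single-nail ring-withdrawal validation scenario
#'
#' The simulator-versus-benchmark check: one pre-curved nail is closed by
#' the sliding ring (quintic motion to the tip) and then released by the
#' reverse withdrawal, while the transverse reaction at the clamped base is
#' recorded against ring position. The same centreline is swept with the
#' independent static node-pull benchmark, and the two force peaks are
#' compared. A knife-edge ("pin") guide and a penalty-converged contact set
#' are used so the simulated constraint matches the benchmark's rigid node
#' pin; see the methods vignette.
#'
#' @param n_spheres Chain resolution (81 = discretization-converged for
#'   this comparison; 41 is the standard device discretization).
#' @param n_elements Benchmark mesh resolution.
#' @param guide_radius Pin guide radius (m).
#' @param stage_duration Duration of each motion stage (s).
#' @param control Solver overrides.
#' @return List: `curve_mb` (transverse base reaction vs engaged arclength,
#'   a [force_curve()]), `curve_oracle` (node-pull sweep), `comparison`
#'   (from [compare_peaks()]), `result` (the [simulate()] output), `sweep`
#'   data frame.
#' @export
run_withdrawal_validation <- function(n_spheres = 81, n_elements = 80,
                                      guide_radius = 1.6e-3,
                                      stage_duration = 5,
                                      control = list()) {
  asm <- nail_assembly(1, n_samples = 401)
  L <- asm$L
  ring <- ring_model("pin", guide_radius = guide_radius, n_guides = 1)
  model <- assemble_system(asm, ring = ring,
                           params = default_contact_params("validation"),
                           max_spacing = L / (n_spheres - 1),
                           control = control)
  travel <- L
  sched <- stage_schedule(list(
    sim_stage("closure", stage_duration, ring_travel = travel),
    sim_stage("expansion", stage_duration, ring_travel = -travel)))
  hl <- ring$hole_length / 2             # pin circle offset in the ring frame
  res <- simulate(model, sched, ring_start = -hl)
  cv <- nail_force_curve(res, source = "base", component = "z",
                         stage = "expansion")
  curve_mb <- force_curve(cv$x + hl, abs(cv$y), abscissa = "arclength",
                          label = "withdrawal base reaction")

  mesh <- beam_mesh(nail_centreline(L = L,
                                    straight_fraction = asm$straight_fraction,
                                    tip_offset = asm$tip_offset),
                    n_elements = n_elements)
  sweep <- sweep_node_pull(mesh)
  comparison <- compare_peaks(curve_mb, sweep)
  list(curve_mb = curve_mb, curve_oracle = sweep, comparison = comparison,
       result = res, sweep = as.data.frame(sweep))
}

#' Ring-model equivalence scenario
#'
#' Runs the six-nail closure/withdrawal twice — once with the segmented
#' (real-geometry) ring, once with the conceptual ring — under the
#' identified per-class contact parameters, records the constraint force at
#' a bounded nail end, and compares the two curve peaks.
#'
#' The contact-force signal carries impulsive components (spheres entering
#' and leaving contact, and the saturated damping of the localized rim
#' contacts), so both constraint-force series are low-pass filtered
#' (zero-phase second-order Butterworth, 1 Hz) before their quasi-static
#' peaks are compared, as in the reference validation procedure.
#'
#' @param n_nails Assembly size.
#' @param max_spacing Chain discretization (m).
#' @param nail Which nail's base reaction to compare.
#' @param stage_duration Stage duration (s).
#' @param cutoff Low-pass cut-off frequency (Hz).
#' @param control Solver overrides.
#' @return List: `curve_segmented`, `curve_conceptual` (filtered
#'   [force_curve()]s over ring position), `raw` (unfiltered),
#'   `comparison`, `peak_rel_diff_percent`, `results`.
#' @export
run_ring_comparison <- function(n_nails = 6, max_spacing = 3.5e-3, nail = 1,
                                stage_duration = 5, cutoff = 1,
                                control = list()) {
  one <- function(variant) {
    asm <- nail_assembly(n_nails)
    ring <- ring_model(variant, n_guides = max(n_nails, 6))
    tbl <- if (variant == "segmented") "segmented" else "conceptual"
    params <- default_contact_params(tbl, n_nails)
    ## identical nail-to-nail parameters in both runs (the ring-model
    ## equivalence check predates the conceptual table's own optimization)
    if (n_nails > 1)
      params$nail_nail <- contact_params(1e8, 2.2, 1e4, 1e-4)
    model <- assemble_system(asm, ring = ring, params = params,
                             max_spacing = max_spacing, control = control)
    ## closed position: tip flush with the distal hole mouth (full hole
    ## engaged over the blade end)
    travel <- asm$L - ring$hole_length / 2
    sched <- stage_schedule(list(
      sim_stage("closure", stage_duration, ring_travel = travel),
      sim_stage("expansion", stage_duration, ring_travel = -travel)))
    res <- simulate(model, sched, ring_start = -ring$hole_length / 2)
    raw <- nail_force_curve(res, nail = nail, source = "base",
                            component = "mag", against = "time",
                            stage = "expansion")
    filt <- butterworth_lowpass(raw, cutoff = cutoff)
    ## re-express against ring position (monotone during withdrawal)
    ry <- stats::approx(res$time, res$ring_y, xout = filt$x)$y
    ord <- order(ry)
    curve <- force_curve(ry[ord], filt$y[ord], abscissa = "ring_position",
                         label = sprintf("%s ring, nail %d base reaction",
                                         variant, nail))
    list(curve = curve, raw = raw, result = res)
  }
  seg <- one("segmented")
  con <- one("conceptual")
  comparison <- compare_peaks(con$curve, seg$curve)
  list(curve_segmented = seg$curve, curve_conceptual = con$curve,
       raw = list(segmented = seg$raw, conceptual = con$raw),
       comparison = comparison,
       peak_rel_diff_percent = comparison$rel_diff_percent,
       results = list(segmented = seg$result, conceptual = con$result))
}

#' Six-nail expansion into the fractured canal
#'
#' The device is initialized in the closed configuration ([closed_state()]),
#' settled against ring and canal, and the ring is withdrawn (33 cm in 5 s
#' by default) so the nails expand against the cortical wall. Nail-nail
#' and nail-fragment contact forces are recorded throughout.
#'
#' @param seed Perturbation seed (`NULL` = ideal assembly).
#' @param perturb_max Maximum angular placement error (deg).
#' @param bow_sagitta Canal bow (m). The default 0.8 mm is the largest
#'   single-plane bow that still admits the closed bundle (guide circle +
#'   nail radius + bow must clear the 6.5 mm canal wall) — an insertable
#'   stand-in for the femoral anterior bow; it is what makes the six nails
#'   non-equivalent.
#' @param travel Ring withdrawal travel (m, the full quintic stroke).
#' @param duration Simulated portion of the withdrawal stage (s); the
#'   motion law itself is always the full `travel` in `motion_duration`
#'   seconds, and the stage ends once the ring has fully disengaged.
#' @param motion_duration Quintic stroke duration (s).
#' @param max_spacing Chain discretization (m).
#' @param settle_time Settling stage duration before withdrawal (s).
#' @param dwell Post-withdrawal dwell stage (s).
#' @param canal A [canal_model()] overriding the default fixture.
#' @param nail_contact Model blade-to-blade contact (default). `FALSE`
#'   makes the six blades mutually independent, which is the configuration
#'   for solver-symmetry checks: with frictionless mutual contact the
#'   six-fold symmetric equilibrium is unstable (the blades clump), so
#'   identical per-blade forces can only be expected without it.
#' @param control Solver overrides.
#' @return List: `result` ([simulate()] output), `model`, `nn_peaks`
#'   (per adjacent pair, peak of the summed nail-nail contact force over
#'   the withdrawal, N), `net_distal` (force curve over ring position,
#'   withdrawal samples only), `assembly`.
#' @export
run_expansion <- function(seed = NULL, perturb_max = 0, bow_sagitta = 8e-4,
                          travel = 0.33, duration = 2.8,
                          motion_duration = 5, max_spacing = 3.5e-3,
                          settle_time = 0.3, dwell = 0.4, canal = NULL,
                          nail_contact = TRUE, control = list()) {
  asm <- nail_assembly(6, perturb_max = perturb_max, seed = seed)
  ring <- ring_model("conceptual")
  if (is.null(canal)) canal <- canal_model(bow_sagitta = bow_sagitta)
  params <- default_contact_params("conceptual")
  if (!nail_contact) params$nail_nail <- NULL
  model <- assemble_system(asm, ring = ring, canal = canal,
                           params = params,
                           max_spacing = max_spacing, control = control)
  ring_closed <- asm$L - ring$hole_length
  st <- closed_state(model)
  sched <- stage_schedule(list(
    sim_stage("settle", settle_time, drag = 500),
    sim_stage("expansion", duration, ring_travel = -travel,
              motion_duration = motion_duration),
    sim_stage("dwell", dwell)))
  res <- simulate(model, sched, state = st, ring_start = ring_closed)
  t_exp <- sched$stages[[2]]$t0
  exp_idx <- which(res$time >= t_exp)
  nn_raw <- nn_filt <- numeric(0)
  if (res$n_pairs > 0) {
    raw <- res$nn_sum[exp_idx, , drop = FALSE]
    nn_raw <- apply(raw, 2, max)
    ## peaks of the 1-Hz zero-phase filtered series: the raw signal carries
    ## impulsive saturated-damping components (see the methods vignette)
    tt <- res$time[exp_idx]
    nn_filt <- apply(raw, 2, function(y)
      max(abs(butterworth_lowpass(force_curve(tt, y), cutoff = 1)$y)))
  }
  nd <- net_distal_force(res, after = t_exp)
  list(result = res, model = model, nn_peaks = nn_filt,
       nn_peaks_raw = nn_raw, net_distal = nd, assembly = asm)
}

#' Assembly-tolerance perturbation study
#'
#' Runs the six-nail expansion for the ideal assembly and for `n_seeds`
#' randomly perturbed assemblies (per-nail angular placement errors uniform
#' in `[0, perturb_max]` degrees), compares per-pair peak nail-to-nail
#' contact forces against the ideal assembly, and reports the relative
#' differences. Pairs whose ideal peak is below `floor_force` are excluded
#' from relative comparison (a relative difference against a zero baseline
#' is meaningless).
#'
#' @param n_seeds Number of perturbed assemblies (>= 20 for the headline
#'   statistic).
#' @param perturb_max Maximum angular error (deg).
#' @param base_seed Seed from which per-run seeds are derived.
#' @param floor_force Baseline floor (N).
#' @param ... Passed to [run_expansion()].
#' @return List: `ideal_peaks`, `per_seed` (data frame: seed, per-pair
#'   peaks, max relative difference %), `max_rel_diff_percent`,
#'   `rel_diff_matrix` (seeds x pairs, %).
#' @export
run_perturbation_study <- function(n_seeds = 20, perturb_max = 10,
                                   base_seed = 1, floor_force = 0.05, ...) {
  ideal <- run_expansion(seed = NULL, perturb_max = 0, ...)
  ip <- ideal$nn_peaks
  usable <- which(ip > floor_force)
  if (length(usable) == 0)
    warning("ideal assembly develops no nail-to-nail force above the floor")
  seeds <- with_seed(base_seed,
                     sample.int(.Machine$integer.max / 2, n_seeds))
  rel <- matrix(NA_real_, n_seeds, length(ip))
  peaks <- matrix(NA_real_, n_seeds, length(ip))
  status <- character(n_seeds)
  for (i in seq_len(n_seeds)) {
    run <- run_expansion(seed = seeds[i], perturb_max = perturb_max, ...)
    peaks[i, ] <- run$nn_peaks
    rel[i, usable] <- 100 * abs(run$nn_peaks[usable] - ip[usable]) /
      ip[usable]
    status[i] <- run$result$status
  }
  per_seed <- data.frame(seed = seeds, status = status,
                         max_rel_diff = apply(rel, 1, function(r)
                           if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)))
  list(ideal_peaks = ip, seeds = seeds, peaks = peaks,
       rel_diff_matrix = rel, per_seed = per_seed,
       max_rel_diff_percent = suppressWarnings(max(rel, na.rm = TRUE)),
       usable_pairs = usable)
}

#' Lateral-loading scenario of the stabilized fracture
#'
#' Continues an expansion run: the fragments' fixed joints are released (the
#' distal fragment stays clamped, the proximal is held only by the fracture
#' bushing and the expanded nails), and a horizontal force ramps from 0 to
#' `peak` N with the quintic law while the relative fragment rotation is
#' recorded.
#'
#' @param expansion A [run_expansion()] output (run if `NULL`).
#' @param peak Peak lateral force (N).
#' @param duration Ramp duration (s).
#' @param control Solver overrides.
#' @param ... Passed to [run_expansion()] when `expansion` is `NULL`.
#' @return List: `result`, `rotation` (from [relative_rotation()]),
#'   `expansion`.
#' @export
run_loading <- function(expansion = NULL, peak = 200, duration = 10,
                        control = list(), ...) {
  if (is.null(expansion)) expansion <- run_expansion(...)
  model <- expansion$model
  sched <- stage_schedule(list(
    sim_stage("loading", duration, load_peak = peak,
              fragments_free = TRUE)))
  res <- simulate(model, sched, state = expansion$result$state,
                  ring_start = expansion$result$ring_end, control = control)
  list(result = res, rotation = relative_rotation(res),
       expansion = expansion)
}
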