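#' Default run configuration
#'
#' The structured-text (YAML) run configuration drives the command-line
#' scenarios. Every field has a default; [read_run_config()] rejects
#' unknown keys so typos cannot silently fall back to defaults.
#'
#' @param scenario One of `"simulate"`, `"oracle"`,
#'   `"withdrawal-validation"`, `"compare-rings"`,
#'   `"sweep-ring-position"`, `"perturb"`, `"loading"`.
#' @return Nested named list (class `run_config`).
#' @export
default_run_config <- function(scenario = "simulate") {
  structure(list(
    scenario = scenario,
    seed = 1L,
    output_dir = "mvnail-out",
    fixture = list(n_nails = 6L, L = 0.14, straight_fraction = 0.25,
                   tip_offset = 0.025, base_radius = 4e-3,
                   nail_radius = 1.5e-3, perturb_max = 0, n_samples = 201L),
    material = list(E = 2e11, rho = 8000, nu = 0.3),
    ring = list(variant = "conceptual", guide_radius = 2.2e-3,
                hole_length = 7e-3, rim_radius = 1e-4,
                guide_circle_radius = 4e-3, n_segments = 8L),
    canal = list(present = TRUE, proximal_len = 0.1, distal_len = 0.12,
                 radius_proximal = 6.5e-3,
                 radius_distal = c(6.5e-3, 5.5e-3), fracture_angle = 30,
                 fracture_y = 0.07, bow_sagitta = 8e-4),
    contact = list(table = "conceptual", subdiv = 2L, beta = 1e-4,
                   min_abort_depth = 1e-3),
    chain = list(max_spacing = 3.5e-3, shear = TRUE),
    schedule = list(
      list(name = "settle", duration = 0.4, drag = 500),
      list(name = "expansion", duration = 5, ring_travel = -0.33)),
    loading = list(peak = 200, duration = 10),
    oracle = list(n_elements = 50L, cumulative = FALSE),
    perturb = list(n_seeds = 20L, perturb_max = 10),
    solver = list(rtol = 1e-3, atol_v = 1e-3, atol_w = 1e-1,
                  hmax = 5e-3, out_dt = 0.01, max_pen_ratio = 10)),
    class = "run_config")
}

check_config_keys <- function(cfg, tmpl, path = "") {
  if (!is.list(cfg) || !is.list(tmpl)) return(invisible())
  unknown <- setdiff(names(cfg), names(tmpl))
  ## schedule/stage lists are positional, not named templates
  if (length(unknown) > 0)
    stop_param("unknown configuration key%s under '%s': %s",
               if (length(unknown) > 1) "s" else "", path,
               paste(unknown, collapse = ", "))
  for (nm in intersect(names(cfg), names(tmpl)))
    if (is.list(tmpl[[nm]]) && !is.null(names(tmpl[[nm]])) &&
        nm != "schedule")
      check_config_keys(cfg[[nm]], tmpl[[nm]], paste0(path, nm, "/"))
  invisible()
}

#' Read a run configuration from YAML
#'
#' Missing fields take their defaults; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tmpl <- default_run_config()
  check_config_keys(raw, tmpl)
  cfg <- utils::modifyList(tmpl, raw)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to YAML
#'
#' Round-trips losslessly through [read_run_config()].
#'
#' @param config A `run_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## Build fixtures + model from a configuration
config_build <- function(cfg) {
  fx <- cfg$fixture
  asm <- nail_assembly(fx$n_nails, perturb_max = fx$perturb_max,
                       seed = if (fx$perturb_max > 0) cfg$seed else NULL,
                       base_radius = fx$base_radius, L = fx$L,
                       straight_fraction = fx$straight_fraction,
                       tip_offset = fx$tip_offset,
                       n_samples = fx$n_samples)
  rg <- cfg$ring
  ring <- ring_model(rg$variant, guide_radius = rg$guide_radius,
                     hole_length = rg$hole_length,
                     n_guides = max(fx$n_nails, 6L),
                     guide_circle_radius = rg$guide_circle_radius,
                     nail_radius = fx$nail_radius,
                     rim_radius = rg$rim_radius,
                     n_segments = rg$n_segments)
  canal <- NULL
  if (isTRUE(cfg$canal$present)) {
    cn <- cfg$canal
    canal <- canal_model(proximal_len = cn$proximal_len,
                         distal_len = cn$distal_len,
                         radius_proximal = cn$radius_proximal,
                         radius_distal = unlist(cn$radius_distal),
                         fracture_angle = cn$fracture_angle,
                         fracture_y = cn$fracture_y,
                         bow_sagitta = cn$bow_sagitta,
                         nail_radius = fx$nail_radius)
  }
  mt <- cfg$material
  params <- default_contact_params(cfg$contact$table, fx$n_nails)
  model <- assemble_system(
    asm, ring = ring, canal = canal, params = params,
    max_spacing = cfg$chain$max_spacing,
    section = section_props(fx$nail_radius,
                            kappa = if (isTRUE(cfg$chain$shear)) 10 / 9
                                    else Inf),
    material = material_props(mt$E, mt$rho, mt$nu),
    beta = cfg$contact$beta, subdiv = cfg$contact$subdiv,
    min_abort_depth = cfg$contact$min_abort_depth,
    control = cfg$solver)
  list(assembly = asm, ring = ring, canal = canal, model = model)
}

config_schedule <- function(cfg) {
  stage_schedule(lapply(cfg$schedule, function(s) {
    do.call(sim_stage, s)
  }))
}
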