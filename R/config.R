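#' Default pipeline configuration
#'
#' Nested list of every tunable in the heat -> simulate -> analyze
#' pipeline, in the interface units of the config file (micrometres,
#' milliwatts, degrees Celsius where marked); [load_config()] converts to
#' SI. The defaults reproduce the reference chamber: 8 um water between
#' 150 um borosilicate coverslips, a 27.6 um laser spot, 1000 particles of
#' 500 nm diameter simulated for 1200 s at dt = 0.05 s.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    chamber = list(water_um = 8, glass_um = 150, spot_fwhm_um = 27.6,
                   domain_radius_um = 300),
    laser = list(power_mw = 20.5, alpha_per_m = 967),
    thermal = list(k0 = 0.61, k_slope = 0.0012, T_ref = 298,
                   k_glass = 1.14, ambient_C = 24),
    particle = list(radius_nm = 250, dt_table = NULL),
    sim = list(dt_s = 0.05, duration_s = 1200, record_every_s = 1,
               n_particles = 1000, seed = 1, init_halfwidth_um = 50,
               domain_halfwidth_um = 150, T_room_K = 297,
               thermophoresis = TRUE),
    analysis = list(bins = 100, r_max_um = 100, window_s = c(600, 1200),
                    pool_center = FALSE, force_n = 3000,
                    force_halfwidth_um = 25, force_bins = 100,
                    force_r_max_um = 50, force_seed = 1),
    field = list(half_extent_um = 150, spacing_um = 0.5),
    solver = list(nr_source = 18, nr_near = 30, nr_far = 24,
                  nz_water = 6, nz_glass = 30, tol = 1e-6, max_iter = 100)
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      abort(sprintf("unknown config key '%s'.", full))
    if (is.list(base[[key]]) && !is.data.frame(base[[key]]) &&
        !is.null(base[[key]]) && !identical(key, "dt_table") &&
        !identical(key, "window_s")) {
      if (!is.list(user[[key]]))
        abort(sprintf("config key '%s' must be a mapping.", full))
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Load and validate a pipeline configuration file
#'
#' Reads a structured YAML file, applies defaults for every omitted key,
#' rejects unknown keys, and enforces the cross-field invariants
#' (initialisation region inside the domain, domain inside the field
#' extent, spot inside the solved radius). A minimal file setting only
#' `laser: {power_mw: ...}` yields the full default configuration at that
#' power.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides optional nested list merged after the file.
#' @return validated configuration list (interface units).
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file '%s' not found.", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  ch <- cfg$chamber; si <- cfg$sim; fl <- cfg$field
  if (any(c(ch$water_um, ch$glass_um, ch$spot_fwhm_um,
            ch$domain_radius_um) <= 0))
    abort("config error: chamber lengths must be positive.")
  if (ch$spot_fwhm_um / 2 >= ch$domain_radius_um)
    abort("config error: laser spot must fit inside the solved radius.")
  if (cfg$laser$power_mw < 0 || cfg$laser$alpha_per_m < 0)
    abort("config error: laser power and alpha must be non-negative.")
  if (si$init_halfwidth_um > si$domain_halfwidth_um)
    abort("config error: init region larger than the domain.")
  if (si$domain_halfwidth_um > fl$half_extent_um)
    abort("config error: domain larger than the field extent.")
  if (sqrt(2) * fl$half_extent_um > ch$domain_radius_um)
    abort("config error: field extent larger than the solved radius.")
  if (si$dt_s <= 0 || si$dt_s > si$record_every_s)
    abort("config error: need 0 < dt_s <= record_every_s.")
  # materialise the default mobility table so configs and manifests are
  # self-contained
  if (is.null(cfg$particle$dt_table))
    cfg$particle$dt_table <- lapply(default_dt_table(), as.numeric)
  else
    cfg$particle$dt_table <- lapply(as.list(cfg$particle$dt_table), as.numeric)
  cfg
}

#' @rdname load_config
#' @param cfg a configuration list.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Named presets for the four reference laser powers
#'
#' @param name one of `"20.5mW"`, `"40.5mW"`, `"79.8mW"`, `"114mW"`.
#' @return configuration list at that laser power.
#' @export
mst_preset <- function(name = c("20.5mW", "40.5mW", "79.8mW", "114mW")) {
  name <- match.arg(name)
  power <- c("20.5mW" = 20.5, "40.5mW" = 40.5, "79.8mW" = 79.8,
             "114mW" = 114)[[name]]
  load_config(overrides = list(laser = list(power_mw = power)))
}

config_to_si <- function(cfg) {
  list(
    geometry = chamber_geometry(
      water_thickness = cfg$chamber$water_um * 1e-6,
      glass_thickness = cfg$chamber$glass_um * 1e-6,
      source_diameter = cfg$chamber$spot_fwhm_um * 1e-6,
      lateral_radius = cfg$chamber$domain_radius_um * 1e-6),
    thermal = thermal_model(
      k0 = cfg$thermal$k0, k_slope = cfg$thermal$k_slope,
      T_ref = cfg$thermal$T_ref, k_glass = cfg$thermal$k_glass,
      T_ambient = cfg$thermal$ambient_C + 273.15),
    particle = particle_model(
      radius = cfg$particle$radius_nm * 1e-9,
      dt_table = as_tibble(cfg$particle$dt_table)),
    settings = solver_settings(
      nr_source = cfg$solver$nr_source, nr_near = cfg$solver$nr_near,
      nr_far = cfg$solver$nr_far, nz_water = cfg$solver$nz_water,
      nz_glass = cfg$solver$nz_glass, tol = cfg$solver$tol,
      max_iter = cfg$solver$max_iter),
    power_in = cfg$laser$power_mw * 1e-3
  )
}

#' Run the full heat -> simulate -> analyze pipeline
#'
#' Builds the volumetric source from the laser settings, solves the
#' steady-state chamber temperature, extracts the mid-plane field, runs
#' the thermophoretic simulation and its seed-matched Brownian-only
#' control, and computes the radial concentration profile, the force
#' profile, and the inverted Soret / mobility estimates. Returns all
#' intermediate objects plus a run manifest from which the run can be
#' reproduced exactly.
#'
#' @param cfg configuration list from [load_config()] / [mst_preset()].
#' @param out_dir optional directory; when given, profiles and fields are
#'   written there as delimited text together with `manifest.json`.
#' @param quiet suppress stage progress messages.
#' @return object of class `mst_pipeline`.
#' @export
run_pipeline <- function(cfg = load_config(), out_dir = NULL, quiet = TRUE) {
  cfg <- validate_config(cfg)
  si <- config_to_si(cfg)
  stage <- function(msg) if (!quiet) message(sprintf("[mstbds] %s", msg))

  stage("building volumetric source")
  q_v <- volumetric_source(si$power_in, cfg$laser$alpha_per_m,
                           si$geometry$water_thickness,
                           si$geometry$source_diameter)
  stage("solving steady-state temperature")
  heat <- solve_steady_temperature(si$geometry, si$thermal, q_v, si$settings)
  stage("extracting mid-plane field")
  field <- midplane_field(heat,
                          half_extent = cfg$field$half_extent_um * 1e-6,
                          spacing = cfg$field$spacing_um * 1e-6)
  sim <- cfg$sim
  run1 <- function(tph) simulate_particles(
    field, si$particle, n_particles = sim$n_particles,
    duration = sim$duration_s, dt = sim$dt_s,
    record_every = sim$record_every_s, seed = sim$seed,
    init_halfwidth = sim$init_halfwidth_um * 1e-6,
    domain = sim$domain_halfwidth_um * 1e-6, T_room = sim$T_room_K,
    thermophoresis = tph)
  stage("simulating thermophoretic run")
  traj_tph <- run1(sim$thermophoresis)
  stage("simulating Brownian-only control (same seed)")
  traj_ref <- run1(FALSE)
  stage("analysing profiles")
  an <- cfg$analysis
  profile <- radial_concentration(
    traj_tph, traj_ref, bins = an$bins, r_max = an$r_max_um * 1e-6,
    window = pmin(an$window_s, sim$duration_s), pool_center = an$pool_center)
  force <- force_profile(
    field, si$particle, n_particles = an$force_n,
    half_width = an$force_halfwidth_um * 1e-6, bins = an$force_bins,
    r_max = an$force_r_max_um * 1e-6, seed = an$force_seed)
  center <- attr(profile, "center_ratio")
  S_T_est <- if (is.finite(center) && center > 0 && heat$dT_max > 0)
    estimate_soret(min(center, 1), heat$dT_max) else NA_real_
  D_T_est <- if (is.finite(S_T_est))
    estimate_dt_from_soret(S_T_est, sim$T_room_K, si$particle) else NA_real_

  manifest <- list(
    package = "mstbds",
    version = as.character(packageVersion("mstbds")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = sim$seed,
    config = cfg,
    results = list(q_v_W_m3 = q_v, dT_max_K = heat$dT_max,
                   center_ratio = center, S_T_per_K = S_T_est,
                   D_T_m2_per_K_s = D_T_est,
                   force_peak_fN = attr(force, "peak_fN"))
  )
  out <- structure(list(config = cfg, q_v = q_v, heat = heat, field = field,
                        traj_tph = traj_tph, traj_ref = traj_ref,
                        profile = profile, force = force,
                        manifest = manifest),
                   class = "mst_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_field_csv(pipeline$field, p("field.csv"))
  write_trajectories_csv(pipeline$traj_tph, p("trajectories_tph.csv"))
  write_trajectories_csv(pipeline$traj_ref, p("trajectories_ref.csv"))
  write.csv(as.data.frame(pipeline$profile), p("radial_profile.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(pipeline$force), p("force_profile.csv"),
            row.names = FALSE)
  manifest <- pipeline$manifest
  manifest$file_hashes <- as.list(tools::md5sum(
    c(p("field.csv"), p("trajectories_tph.csv"), p("trajectories_ref.csv"),
      p("radial_profile.csv"), p("force_profile.csv"))))
  names(manifest$file_hashes) <- basename(names(manifest$file_hashes))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mst_pipeline <- function(x, ...) {
  r <- x$manifest$results
  cat("<mst_pipeline>\n")
  cat(sprintf("  q_v       = %.4g W/m^3\n", r$q_v_W_m3))
  cat(sprintf("  dT_max    = %.4g K\n", r$dT_max_K))
  cat(sprintf("  c/c0(0)   = %.3f\n", r$center_ratio))
  cat(sprintf("  S_T       = %.3g /K\n", r$S_T_per_K))
  cat(sprintf("  D_T       = %.3g m^2/(K s)\n", r$D_T_m2_per_K_s))
  cat(sprintf("  |F| peak  = %.3g fN\n", r$force_peak_fN))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x an `mst_pipeline` object.
#' @param ... unused.
#' @method glance mst_pipeline
#' @export
glance.mst_pipeline <- function(x, ...) {
  r <- x$manifest$results
  tibble(q_v_W_m3 = r$q_v_W_m3, dT_max_K = r$dT_max_K,
         center_ratio = r$center_ratio, S_T_per_K = r$S_T_per_K,
         D_T_m2_per_K_s = r$D_T_m2_per_K_s, force_peak_fN = r$force_peak_fN)
}

#' Re-run a pipeline from its manifest
#'
#' Manifests capture the fully resolved configuration and seed; replaying
#' one reproduces the run bit for bit.
#'
#' @param manifest a manifest list or a path to `manifest.json`.
#' @param out_dir optional output directory, as in [run_pipeline()].
#' @return an `mst_pipeline` object.
#' @export
replay_manifest <- function(manifest, out_dir = NULL) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  cfg <- merge_config(default_config(), manifest$config)
  cfg$analysis$window_s <- as.numeric(cfg$analysis$window_s)
  run_pipeline(cfg, out_dir = out_dir)
}
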