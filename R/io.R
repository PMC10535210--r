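## Configuration loading/validation, fixture presets and report writers.
## YAML for configuration, CSV for time series, JSON for reports; SI units
## with unit-suffixed field names throughout.

SCENARIO_SCHEMA <- list(
  schema_version = "number",
  pedestrian = list(stature_m = "number", mass_kg = "number",
                    speed_mps = "number", heading_deg = "number"),
  vehicle = list(preset = "string", speed_mps = "number",
                 angle_deg = "number"),
  friction = list(car_ground = "number", ped_ground = "number",
                  car_ped = "number"),
  mode = "string",
  simulation = list(dt_s = "number", max_time_s = "number",
                    t_lead_s = "number", impact_phase = "any"))

REQUIRED_KEYS <- c("pedestrian", "vehicle", "mode")

validate_block <- function(x, schema, path) {
  for (key in names(x)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!(key %in% names(schema)))
      stopf("scenario schema violation: unknown key '%s'", full)
    spec <- schema[[key]]
    if (is.list(spec)) {
      if (!is.list(x[[key]]))
        stopf("scenario schema violation: '%s' must be a mapping", full)
      validate_block(x[[key]], spec, full)
    } else if (spec == "number") {
      if (!is.numeric(x[[key]]) || length(x[[key]]) != 1L)
        stopf("scenario schema violation: '%s' must be a number", full)
    } else if (spec == "string") {
      if (!is.character(x[[key]]) || length(x[[key]]) != 1L)
        stopf("scenario schema violation: '%s' must be a string", full)
    }
  }
  invisible(TRUE)
}

#' Load and validate a scenario YAML file
#'
#' Unknown keys are rejected (naming the key); missing optional keys get
#' package defaults.
#'
#' @param path YAML file path.
#' @return a [scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stopf("scenario file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y) || !is.list(y) || !length(y))
    stopf("scenario schema violation: empty scenario file '%s'", path)
  validate_block(y, SCENARIO_SCHEMA, "")
  for (k in REQUIRED_KEYS)
    if (is.null(y[[k]]))
      stopf("scenario schema violation: missing required key '%s'", k)
  veh <- sedan_profile(speed = y$vehicle$speed_mps %||% 18.5)
  fr <- y$friction %||% list()
  sim <- y$simulation %||% list()
  scenario(
    stature = y$pedestrian$stature_m %||% 1.74,
    mass = y$pedestrian$mass_kg %||% 68,
    ped_speed = y$pedestrian$speed_mps %||% 4.5,
    ped_heading_deg = y$pedestrian$heading_deg %||% 0,
    vehicle = veh,
    vehicle_speed = y$vehicle$speed_mps %||% veh$speed,
    vehicle_angle_deg = y$vehicle$angle_deg %||% 2.7,
    friction = friction_spec(fr$car_ground %||% 0.7,
                             fr$ped_ground %||% 0.6,
                             fr$car_ped %||% 0.3),
    mode = y$mode,
    impact_phase = sim$impact_phase %||% "mid_stance",
    dt = sim$dt_s %||% 1e-4,
    max_time = sim$max_time_s %||% 3,
    t_lead = sim$t_lead_s %||% 0.06)
}

#' Path to a shipped fixture file
#'
#' Shipped fixtures: `case1.yaml` (the reconstructed crossing case:
#' 18.5 m/s vehicle, 4.5 m/s runner, 2.7 deg approach, frictions
#' 0.7/0.6/0.3), `table2_pose.csv` (published collision-moment pose
#' table) and `contact_curve_example.csv`.
#'
#' @param name fixture file name.
#' @return absolute path.
#' @export
pedrecon_fixture <- function(name) {
  p <- system.file("extdata", name, package = "pedrecon")
  if (p == "") stopf("fixture not found: %s", name)
  p
}

#' Read a contact curve CSV (`penetration_m, force_N`)
#'
#' @param path file path.
#' @param hysteresis unloading factor.
#' @return a [contact_curve()].
#' @export
read_contact_curve_csv <- function(path, hysteresis = 0.5) {
  df <- utils::read.csv(path)
  contact_curve(df$penetration_m, df$force_N, hysteresis)
}

#' Write a reconstruction report bundle (JSON + CSV)
#'
#' Writes `report.json` (metrics, injury criteria, events, software
#' version, scenario checksum) and `trajectory.csv` (time, COM and head
#' positions, kinetic energy) into `dir`. Outputs are deterministic given
#' the result (no timestamps inside the data files).
#'
#' @param result a `"pedrecon_reconstruction"`.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "pedrecon_reconstruction"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scn <- result$scenario
  cfg <- list(stature = scn$stature, mass = scn$mass,
              ped_speed = scn$ped_speed,
              vehicle_speed = scn$vehicle_speed,
              vehicle_angle_deg = scn$vehicle_angle_deg, mode = scn$mode,
              dt = scn$dt, max_time = scn$max_time)
  tmp <- tempfile()
  writeLines(paste(names(cfg), unlist(cfg), sep = "="), tmp)
  checksum <- unname(tools::md5sum(tmp))
  unlink(tmp)
  m <- result$metrics
  report <- list(
    software = list(package = "pedrecon",
                    version = as.character(utils::packageVersion("pedrecon")),
                    config_checksum = checksum),
    scenario = cfg,
    metrics = list(
      hic = m$hic, chest_3ms_g = m$chest_3ms,
      tibia_stress_mpa = unname(m$bone_stress[["tibia"]]),
      femur_stress_mpa = unname(m$bone_stress[["femur"]]),
      max_airborne_height_m = m$max_airborne_height,
      slide_distance_m = m$slide_distance,
      thrown_distance_m = m$thrown_distance,
      rest_position_m = as.numeric(m$rest_position),
      body_heading_deg = m$body_heading_deg,
      duration_s = m$duration, partial = m$partial),
    injury = result$injury$criteria,
    events = result$events)
  jpath <- file.path(dir, "report.json")
  jsonlite::write_json(report, jpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  tcsv <- data.frame(time_s = result$samples$t,
                     com_x_m = result$samples$com[, 1L],
                     com_y_m = result$samples$com[, 2L],
                     com_z_m = result$samples$com[, 3L],
                     head_x_m = result$samples$head[, 1L],
                     head_y_m = result$samples$head[, 2L],
                     head_z_m = result$samples$head[, 3L],
                     kinetic_energy_J = result$samples$ke)
  cpath <- file.path(dir, "trajectory.csv")
  utils::write.csv(tcsv, cpath, row.names = FALSE)
  invisible(c(jpath, cpath))
}

#' Read back a report bundle written by [write_report()]
#'
#' @param dir report directory.
#' @return list with `report` (parsed JSON) and `trajectory` (data.frame).
#' @export
read_report <- function(dir) {
  list(report = jsonlite::read_json(file.path(dir, "report.json"),
                                    simplifyVector = TRUE),
       trajectory = utils::read.csv(file.path(dir, "trajectory.csv")))
}
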