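# Session readers/writers (CSV streams, JSON segment plan, GeoJSON track)
# and the umbrella pipeline. All files are UTF-8; CSVs carry a '#' metadata
# header (package version, seed, config hash) and ISO-8601 UTC timestamps
# next to a full-precision relative-seconds column used for round-tripping.

meta_header <- function(seed = NULL, config_hash = NULL) {
  c(sprintf("# pape %s", as.character(utils::packageVersion("pape"))),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    if (!is.null(config_hash)) sprintf("# config_hash: %s", config_hash))
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)  # scratch file only; never shipped
  unname(tools::md5sum(f))
}

write_csv_meta <- function(df, path, seed = NULL, cfg_hash = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_header(seed, cfg_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

iso_ts <- function(start_time, t_s) {
  format(start_time + t_s, "%Y-%m-%dT%H:%M:%OS1Z", tz = "UTC")
}

#' Write a sensor session to a directory
#'
#' Writes `env.csv`, `physio.csv` (ISO-8601 timestamps plus a `t_s`
#' relative-seconds column) and `segment_plan.json`.
#'
#' @param session a `sensor_session`.
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the metadata headers.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, seed = NULL) {
  stopifnot(inherits(session, "sensor_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  env <- session$env_stream
  physio <- session$physio_stream
  env_out <- cbind(timestamp = iso_ts(session$start_time, env$timestamp),
                   t_s = env$timestamp, env[-1])
  phy_out <- cbind(timestamp = iso_ts(session$start_time, physio$timestamp),
                   t_s = physio$timestamp, physio[-1])
  h <- config_hash(session$segment_plan)
  write_csv_meta(env_out, file.path(dir, "env.csv"), seed, h)
  write_csv_meta(phy_out, file.path(dir, "physio.csv"), seed, h)
  plan <- list(
    `_meta` = list(tool = paste("pape", as.character(utils::packageVersion("pape"))),
                   seed = seed, config_hash = h),
    participant = session$profile[c("participant_id", "sex_code", "age",
                                    "height", "weight", "fvc")],
    time_of_day = session$time_of_day,
    start_time = format(session$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    segments = session$segment_plan
  )
  jsonlite::write_json(plan, file.path(dir, "segment_plan.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

read_csv_meta <- function(path, required) {
  if (!file.exists(path))
    abort_pape(sprintf("missing file: %s", path), "pape_io_error")
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) abort_pape(sprintf("parse error in %s: %s",
                                           path, conditionMessage(e)),
                                   "pape_io_error"),
    warning = function(w) abort_pape(sprintf("parse error in %s: %s",
                                             path, conditionMessage(w)),
                                     "pape_io_error")
  )
  miss <- setdiff(required, names(df))
  if (length(miss))
    abort_pape(sprintf("%s is missing column(s): %s", path,
                       paste(miss, collapse = ", ")), "pape_io_error")
  num <- setdiff(required, c("timestamp"))
  for (col in num) {
    if (!is.numeric(df[[col]]) && !is.logical(df[[col]]))
      abort_pape(sprintf("%s: column '%s' is not numeric (truncated or corrupt file?)",
                         path, col), "pape_io_error")
    if (anyNA(df[[col]]))
      abort_pape(sprintf("%s: missing values in column '%s' (line %d)",
                         path, col, which(is.na(df[[col]]))[1]), "pape_io_error")
  }
  df
}

#' Read a sensor session from a directory
#'
#' Inverse of [write_session()]; every structural invariant (monotone
#' timestamps, PM size ordering, non-negative concentrations, segment plan
#' inside the stream span) is enforced on load and violations raise typed
#' errors naming the file and offending row.
#'
#' @param dir directory holding `env.csv`, `physio.csv`,
#'   `segment_plan.json`.
#' @return a validated `sensor_session`.
#' @export
read_session <- function(dir) {
  env_cols <- c("timestamp", "t_s", "pm1", "pm2_5", "pm10", "co2", "tvoc",
                "co", "no2", "co_censored", "no2_censored", "temp_c",
                "rh_pct", "pressure_hpa", "lat", "lon")
  env <- read_csv_meta(file.path(dir, "env.csv"), env_cols)
  phy <- read_csv_meta(file.path(dir, "physio.csv"), c("timestamp", "t_s", "pr", "rr"))
  plan_path <- file.path(dir, "segment_plan.json")
  if (!file.exists(plan_path))
    abort_pape(sprintf("missing file: %s", plan_path), "pape_io_error")
  plan_doc <- jsonlite::read_json(plan_path, simplifyVector = TRUE)
  for (fld in c("participant", "segments", "time_of_day", "start_time"))
    if (is.null(plan_doc[[fld]]))
      abort_pape(sprintf("%s: missing field '%s'", plan_path, fld), "pape_io_error")

  p <- plan_doc$participant
  profile <- validate_profile(structure(list(
    participant_id = p$participant_id, sex_code = as.integer(p$sex_code),
    age = p$age, height = p$height, weight = p$weight, fvc = p$fvc
  ), class = "participant_profile"))

  env_df <- env[, setdiff(env_cols, "timestamp")]
  names(env_df)[names(env_df) == "t_s"] <- "timestamp"
  env_df$co_censored <- as.logical(env_df$co_censored)
  env_df$no2_censored <- as.logical(env_df$no2_censored)
  phy_df <- data.frame(timestamp = phy$t_s, pr = phy$pr, rr = phy$rr)

  session <- structure(list(
    profile = profile, env_stream = env_df, physio_stream = phy_df,
    segment_plan = as.data.frame(plan_doc$segments),
    time_of_day = plan_doc$time_of_day,
    start_time = as.POSIXct(plan_doc$start_time, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%SZ")
  ), class = "sensor_session")
  tryCatch(validate_session(session), pape_session_error = function(e)
    abort_pape(sprintf("%s: %s", dir, conditionMessage(e)), "pape_io_error"))
}

#' Export a session (and optionally its exposure) as GeoJSON
#'
#' Builds a FeatureCollection with one LineString following the
#' environmental records' GPS track and one Point per static acquisition
#' point carrying the segment label, per-pollutant median concentrations
#' within the dwell window, and — when an exposure table is supplied — the
#' per-segment doses.
#'
#' @param session a `sensor_session` with coordinates.
#' @param exposure optional `exposure_table` for the same session.
#' @param file optional path; when given the document is written there.
#' @param pollutants channels summarised on the Point features.
#' @return the GeoJSON document as a list (invisibly when `file` is given).
#' @export
export_geojson <- function(session, exposure = NULL, file = NULL,
                           pollutants = c("pm1", "pm2_5", "pm10", "co2", "tvoc")) {
  env <- session$env_stream
  if (is.null(env$lat) || is.null(env$lon) || anyNA(env$lat) || anyNA(env$lon))
    abort_pape("session has no usable coordinates", "pape_io_error")
  track <- list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = mapply(c, env$lon, env$lat, SIMPLIFY = FALSE)),
    properties = list(participant = session$profile$participant_id,
                      time_of_day = session$time_of_day)
  )
  points <- lapply(seq_len(nrow(session$segment_plan)), function(i) {
    p <- session$segment_plan[i, ]
    sel <- env$timestamp >= p$arrive_ts & env$timestamp < p$leave_ts
    props <- list(label = p$label, arrive_ts = p$arrive_ts, leave_ts = p$leave_ts)
    for (pol in pollutants)
      props[[paste0(pol, "_median")]] <- stats::median(env[[pol]][sel])
    if (!is.null(exposure)) {
      ex <- exposure[exposure$segment == p$label, ]
      for (j in seq_len(nrow(ex)))
        props[[paste0("pape_", ex$pollutant[j])]] <- ex$pape[j]
    }
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(stats::median(env$lon[sel]),
                                         stats::median(env$lat[sel]))),
         properties = props)
  })
  doc <- list(type = "FeatureCollection", features = c(list(track), points))
  if (!is.null(file)) {
    jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
    return(invisible(doc))
  }
  doc
}

#' Build and validate a pipeline run configuration
#'
#' @param scenario a `scenario_config`.
#' @param standard_inputs a `standard_inputs` object (fixed-station daily
#'   concentrations + tabulated-ventilation duration); the per-sex
#'   tabulated ventilation itself is taken from [tabulated_vm()].
#' @param n_participants cohort size.
#' @param sex_ratio probability of drawing a man.
#' @param seed master seed; per-participant seeds are derived from it.
#' @param out_dir output directory.
#' @param samples_per_minute normalization density.
#' @param ventilation_mode `"integral"` or `"constant"` dose mode.
#' @param env_factor_mode `"per_minute"` or `"segment_mean"`.
#' @param write_sessions whether to persist every generated session.
#' @return object of class `run_config`.
#' @export
run_config <- function(scenario = scenario_config(),
                       standard_inputs,
                       n_participants = 20, sex_ratio = 0.7, seed = 1,
                       out_dir = tempfile("pape_run_"),
                       samples_per_minute = 3,
                       ventilation_mode = c("integral", "constant"),
                       env_factor_mode = c("per_minute", "segment_mean"),
                       write_sessions = TRUE) {
  validate_scenario_config(scenario)
  if (!inherits(standard_inputs, "standard_inputs"))
    abort_pape("standard_inputs must be built with standard_inputs()", "pape_config_error")
  if (n_participants < 1) abort_pape("n_participants must be >= 1", "pape_config_error")
  structure(list(
    scenario = scenario, standard_inputs = standard_inputs,
    n_participants = n_participants, sex_ratio = sex_ratio, seed = seed,
    out_dir = out_dir, samples_per_minute = samples_per_minute,
    ventilation_mode = match.arg(ventilation_mode),
    env_factor_mode = match.arg(env_factor_mode),
    write_sessions = write_sessions
  ), class = "run_config")
}

#' Run the full pipeline: simulate, preprocess, ventilate, expose, compare
#'
#' For each participant: draw a profile and a session, preprocess all
#' channels, evaluate the ventilation model on the physiological segments,
#' compute per-segment and total doses, and derive the participant's
#' Standard-Method dose from the configured fixed-station concentration and
#' the sex-tabulated ventilation. Ends with the paired method comparison
#' across the cohort. Outputs (per-participant doses CSV, comparison JSON,
#' manifest with seed/config hash/file hashes) are written under
#' `config$out_dir`.
#'
#' @param config a `run_config`.
#' @return invisible list with `doses` (data.frame), `comparison`
#'   (`method_comparison`), `exposures` (per-participant exposure tables),
#'   `manifest`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dose_pol <- names(config$standard_inputs$c_std)[1]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(config[setdiff(names(config), "out_dir")])

  doses <- list(); exposures <- list()
  for (i in seq_len(config$n_participants)) {
    p_seed <- config$seed + 1000L * i
    profile <- generate_profile(p_seed, config$sex_ratio,
                                participant_id = sprintf("P%02d", i))
    session <- generate_session(profile, config$scenario, seed = p_seed + 1L)
    if (config$write_sessions)
      write_session(session, file.path(config$out_dir, profile$participant_id),
                    seed = p_seed + 1L)
    segs <- preprocess_session(session,
                               samples_per_minute = config$samples_per_minute)
    vm <- vm_series(segs$pr, segs$rr, profile)
    ex <- session_exposure(segs, vm,
                           dose_pollutant = dose_pol,
                           env_factor = config$env_factor_mode,
                           ventilation = config$ventilation_mode)
    exposures[[profile$participant_id]] <- ex
    # Standard dose uses the participant's sex-specific tabulated ventilation
    id_std <- standard_dose(
      standard_inputs(config$standard_inputs$c_std,
                      tabulated_vm(profile$sex_code),
                      config$standard_inputs$duration_min),
      dose_pol)
    doses[[i]] <- data.frame(
      participant = profile$participant_id,
      sex_code = profile$sex_code,
      id_new = attr(ex, "id_new"),
      id_std = id_std,
      vm_std_lpm = tabulated_vm(profile$sex_code),
      stringsAsFactors = FALSE
    )
  }
  doses <- do.call(rbind, doses)
  comparison <- compare_methods(doses$id_new, doses$id_std)

  write_csv_meta(doses, file.path(config$out_dir, "doses.csv"),
                 seed = config$seed, cfg_hash = cfg_hash)
  jsonlite::write_json(
    c(list(`_meta` = list(tool = paste("pape", as.character(utils::packageVersion("pape"))),
                          seed = config$seed, config_hash = cfg_hash)),
      unclass(comparison)),
    file.path(config$out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    tool = paste("pape", as.character(utils::packageVersion("pape"))),
    seed = config$seed, config_hash = cfg_hash,
    n_participants = config$n_participants,
    dose_pollutant = dose_pol,
    files = as.list(stats::setNames(unname(tools::md5sum(sort(files))),
                                    sub(paste0("^", config$out_dir, "/?"), "",
                                        sort(files))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(doses = doses, comparison = comparison, exposures = exposures,
                 manifest = manifest, out_dir = config$out_dir))
}
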