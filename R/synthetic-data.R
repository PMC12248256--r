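# Seeded generator for body-sensor-network walking sessions: one environmental
# record every 24 s, physiological streams at 10 Hz, seven 5-minute static
# acquisition points (A..G, distinct microenvironments) joined by walking
# transits. Regime defaults emulate the study's published per-point medians
# and IQRs: indoor (A, a laboratory) high CO2/tVOC and low PM, outdoor the
# reverse, and CO/NO2 permanently below a 20 ppb detection limit.

#' Default per-point pollutant regimes
#'
#' Median and IQR for each channel at each static acquisition point. Point A
#' is indoors (laboratory: high CO2 and tVOC, low PM); B–G are outdoor
#' microenvironments (gas station, park, traffic intersection, train
#' station, small park hosting the regional fixed station, low-traffic
#' street). CO and NO2 are modelled as low-level channels that stay below
#' the 20 ppb detection limit.
#'
#' @return data.frame, one row per point label.
#' @export
default_regimes <- function() {
  data.frame(
    label     = c("A", "B", "C", "D", "E", "F", "G"),
    co2_med   = c(1010.4, 615.9, 628.7, 619.4, 628.5, 626.6, 650.0),
    co2_iqr   = c(214.2, 56.3, 73.5, 74.7, 72.0, 64.6, 79.1),
    tvoc_med  = c(586.1, 167.7, 161.8, 160.4, 86.1, 134.5, 205.8),
    tvoc_iqr  = c(207.5, 215.0, 254.2, 259.9, 134.7, 319.6, 440.0),
    pm1_med   = c(8.4, 22.7, 19.7, 21.5, 20.7, 21.7, 24.4),
    pm1_iqr   = c(7.8, 22.8, 23.3, 24.8, 23.5, 20.2, 17.8),
    pm2_5_med = c(9.9, 24.2, 23.0, 21.7, 23.3, 21.8, 26.2),
    pm2_5_iqr = c(8.6, 16.0, 17.5, 16.9, 21.9, 17.0, 15.1),
    pm10_med  = c(10.4, 24.6, 23.3, 22.0, 23.7, 22.1, 26.6),
    pm10_iqr  = c(8.9, 16.9, 17.3, 18.9, 21.6, 17.1, 15.1),
    co_med    = rep(8, 7),
    co_iqr    = rep(4, 7),
    no2_med   = rep(10, 7),
    no2_iqr   = rep(5, 7),
    stringsAsFactors = FALSE
  )
}

#' Default per-point physiological regimes
#'
#' Respiratory rate (breaths/min) and pulse rate (beats/min) medians and
#' IQRs per static point. RR is highest at the first point (participants
#' are instrumented and seated indoors) and settles along the walk; PR is
#' lowest indoors.
#'
#' @return data.frame, one row per point label.
#' @export
default_physio <- function() {
  data.frame(
    label  = c("A", "B", "C", "D", "E", "F", "G"),
    rr_med = c(24.0, 17.1, 14.3, 14.6, 14.3, 11.1, 11.3),
    rr_iqr = c(16.9, 16.6, 9.67, 9.6, 9.7, 8.6, 9.6),
    pr_med = c(86.7, 98.8, 98.1, 97.7, 105.1, 99.0, 101.0),
    pr_iqr = c(13.1, 19.2, 18.6, 19.0, 21.0, 21.5, 25.0),
    stringsAsFactors = FALSE
  )
}

#' Default waypoint coordinates for the walking route
#'
#' Seven synthetic waypoints laid out in the university district the study
#' route covers (approx. 45.48 N, 9.23 E); straight-line GPS interpolation
#' between them during transits.
#'
#' @return data.frame with label, lat, lon.
#' @export
default_waypoints <- function() {
  data.frame(
    label = c("A", "B", "C", "D", "E", "F", "G"),
    lat = c(45.4790, 45.4812, 45.4841, 45.4858, 45.4867, 45.4838, 45.4806),
    lon = c(9.2271, 9.2296, 9.2312, 9.2281, 9.2243, 9.2221, 9.2247),
    stringsAsFactors = FALSE
  )
}

#' Build a scenario configuration
#'
#' Bundles every knob of the synthetic session generator: sampling cadences,
#' the segment-plan template (dwell and transit durations), per-point
#' pollutant and physiological regimes, morning/afternoon level shifts, the
#' CO/NO2 detection floor and noise-model parameters.
#'
#' @param env_period_s seconds between environmental records (default 24,
#'   i.e. 0.042 Hz).
#' @param physio_rate_hz physiological sampling rate (default 10 Hz).
#' @param dwell_min static dwell at each point, minutes (default 5).
#' @param transit_min walking-transit durations in minutes, length 7: the six
#'   interior transits A→B … F→G plus the final return transit after G.
#' @param regime_params per-point pollutant regimes, see [default_regimes()].
#' @param physio_params per-point RR/PR regimes, see [default_physio()].
#' @param waypoints per-point GPS coordinates, see [default_waypoints()].
#' @param time_of_day `"morning"` or `"afternoon"`.
#' @param tod_shift afternoon-vs-morning level shifts: `pm_factor` and
#'   `tvoc_factor` multiply the PM and tVOC medians, `co2_offset_ppm` is
#'   added to the CO2 medians (negative: CO2 is higher in the morning).
#'   Directions follow the study's findings; magnitudes are configuration,
#'   not claims.
#' @param lod_ppb detection floor for CO and NO2, ppb (default 20).
#' @param ar_env lag-1 autocorrelation of environmental fluctuations between
#'   consecutive 24-s records.
#' @param ar_physio lag-1 autocorrelation of physiological fluctuations
#'   between consecutive 10 Hz samples.
#' @param between_subject_sd log-scale SD of the per-participant random
#'   level of RR and PR (between-participant variability).
#' @param start_date calendar date of the session (character, ISO).
#' @param noise_scale global multiplier on all within-segment spreads
#'   (1 = configured IQRs; 0 = deterministic medians).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(env_period_s = 24,
                            physio_rate_hz = 10,
                            dwell_min = 5,
                            transit_min = c(6, 5, 4, 5, 5, 6, 8),
                            regime_params = default_regimes(),
                            physio_params = default_physio(),
                            waypoints = default_waypoints(),
                            time_of_day = c("morning", "afternoon"),
                            tod_shift = list(pm_factor = 1.35,
                                             tvoc_factor = 1.25,
                                             co2_offset_ppm = -40),
                            lod_ppb = 20,
                            ar_env = 0.6,
                            ar_physio = 0.995,
                            between_subject_sd = 0.12,
                            start_date = "2022-11-07",
                            noise_scale = 1) {
  time_of_day <- match.arg(time_of_day)
  cfg <- structure(list(
    env_period_s = env_period_s, physio_rate_hz = physio_rate_hz,
    dwell_min = dwell_min, transit_min = transit_min,
    regime_params = regime_params, physio_params = physio_params,
    waypoints = waypoints, time_of_day = time_of_day, tod_shift = tod_shift,
    lod_ppb = lod_ppb, ar_env = ar_env, ar_physio = ar_physio,
    between_subject_sd = between_subject_sd, start_date = start_date,
    noise_scale = noise_scale
  ), class = "scenario_config")
  validate_scenario_config(cfg)
}

#' @rdname scenario_config
#' @param cfg object to validate.
#' @export
validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$env_period_s <= 0) abort_pape("env_period_s must be > 0", "pape_config_error")
  if (cfg$physio_rate_hz <= 0) abort_pape("physio_rate_hz must be > 0", "pape_config_error")
  if (cfg$dwell_min <= 0 || any(cfg$transit_min <= 0))
    abort_pape("all dwell/transit durations must be > 0", "pape_config_error")
  if (length(cfg$transit_min) != 7L)
    abort_pape("transit_min must have length 7 (A>B .. F>G plus the return transit)",
               "pape_config_error")
  if (cfg$lod_ppb < 0) abort_pape("lod_ppb must be >= 0", "pape_config_error")
  labels <- c("A", "B", "C", "D", "E", "F", "G")
  for (lb in labels) {
    if (!lb %in% cfg$regime_params$label)
      abort_pape(sprintf("regime_params is missing point '%s'", lb), "pape_config_error")
    if (!lb %in% cfg$physio_params$label)
      abort_pape(sprintf("physio_params is missing point '%s'", lb), "pape_config_error")
    if (!lb %in% cfg$waypoints$label)
      abort_pape(sprintf("waypoints is missing point '%s'", lb), "pape_config_error")
  }
  cfg
}

#' Sample a participant profile
#'
#' Draws sex, age, height and weight from distributions emulating the study
#' cohort (14 men / 6 women; median age 25.5 y with a few older outliers;
#' median height 179 cm for men) and fills FVC from the packaged linear
#' reference unless `fvc` is supplied.
#'
#' @param seed integer seed.
#' @param sex_ratio probability of drawing a man (sex code 1); the cohort
#'   fraction 14/20 = 0.7 by default.
#' @param participant_id identifier; default derived from the seed.
#' @param fvc optional forced vital capacity (L) overriding the reference.
#' @return object of class `participant_profile` with fields
#'   `participant_id`, `sex_code` (1 = man, 2 = woman), `age` (y),
#'   `height` (cm), `weight` (kg), `fvc` (L).
#' @export
generate_profile <- function(seed, sex_ratio = 0.7,
                             participant_id = sprintf("P%04d", seed %% 10000L),
                             fvc = NULL) {
  stopifnot(sex_ratio >= 0, sex_ratio <= 1)
  with_seed(seed, {
    sex_code <- if (stats::runif(1) < sex_ratio) 1L else 2L
    # young cohort with occasional older outliers (study: 3/20 aged 32-55)
    age <- if (stats::runif(1) < 0.15) {
      stats::runif(1, 30, 60)
    } else {
      stats::rnorm(1, mean = 25.5, sd = 2.2)
    }
    age <- min(max(age, 18), 75)
    height <- if (sex_code == 1L) stats::rnorm(1, 179, 6) else stats::rnorm(1, 166, 6)
    height <- max(height, 145)
    weight <- if (sex_code == 1L) stats::rnorm(1, 73, 8) else stats::rnorm(1, 62, 7)
    weight <- max(weight, 40)
    prof <- structure(list(
      participant_id = participant_id,
      sex_code = sex_code,
      age = age, height = height, weight = weight,
      fvc = fvc %||% predict_fvc(sex_code, age, height)
    ), class = "participant_profile")
    validate_profile(prof)
  })
}

validate_profile <- function(profile) {
  stopifnot(inherits(profile, "participant_profile"))
  if (!profile$sex_code %in% c(1L, 2L))
    abort_pape("sex_code must be 1 (man) or 2 (woman)", "pape_profile_error")
  if (profile$age < 18 || profile$age > 75)
    abort_pape("age must be within the 18-75 y eligibility window", "pape_profile_error")
  if (profile$height <= 0 || profile$weight <= 0 || profile$fvc <= 0)
    abort_pape("height, weight and fvc must be > 0", "pape_profile_error")
  profile
}

#' Stand-in linear FVC reference coefficients
#'
#' Per-sex coefficients (a, b, c) of `fvc = a * height_cm + b * age_y + c`.
#' These are classic European adult spirometry reference equations used as a
#' documented stand-in: they are NOT the GLI-2012 spline reference the study
#' used, which needs lookup tables out of scope here.
#'
#' @return named list with `male` and `female` coefficient vectors.
#' @export
fvc_reference_coefs <- function() {
  list(
    male   = c(a = 0.0576, b = -0.0260, c = -4.34),
    female = c(a = 0.0443, b = -0.0260, c = -2.89)
  )
}

#' Predict forced vital capacity from sex, age and height
#'
#' Linear per-sex reference `a * height + b * age + c` (stand-in, not GLI;
#' see [fvc_reference_coefs()]). Coefficients can be overridden.
#'
#' @param sex_code 1 = man, 2 = woman.
#' @param age years.
#' @param height cm.
#' @param coefs coefficient list as returned by [fvc_reference_coefs()].
#' @return FVC in litres.
#' @export
predict_fvc <- function(sex_code, age, height, coefs = fvc_reference_coefs()) {
  if (any(!sex_code %in% c(1, 2)))
    abort_pape("sex_code must be 1 or 2", "pape_profile_error")
  if (any(height <= 0)) abort_pape("height must be > 0", "pape_profile_error")
  if (any(age < 0)) abort_pape("age must be >= 0", "pape_profile_error")
  cf <- ifelse(sex_code == 1, list(coefs$male), list(coefs$female))
  out <- mapply(function(c1, h, a) c1["a"] * h + c1["b"] * a + c1["c"],
                cf, height, age)
  unname(out)
}

# ---- session generation ------------------------------------------------------

# Segment plan (label, arrive_ts, leave_ts in seconds) implied by a config:
# arrive at A at t = 0, dwell, walk, ..., final return transit after G.
build_segment_plan <- function(config) {
  labels <- c("A", "B", "C", "D", "E", "F", "G")
  dwell_s <- config$dwell_min * 60
  transit_s <- config$transit_min * 60
  arrive <- numeric(7)
  t <- 0
  for (i in seq_len(7)) {
    arrive[i] <- t
    t <- t + dwell_s
    t <- t + transit_s[i]
  }
  data.frame(label = labels, arrive_ts = arrive, leave_ts = arrive + dwell_s,
             stringsAsFactors = FALSE)
}

# For every time point: the active regime row index (static label) or, in
# transit, the pair of flanking labels with an interpolation weight.
locate_times <- function(times, plan, session_end) {
  n <- length(times)
  seg <- character(n); w <- numeric(n); from <- character(n); to <- character(n)
  labels <- plan$label
  for (j in seq_len(n)) {
    t <- times[j]
    i <- findInterval(t, plan$arrive_ts)
    if (i >= 1 && t < plan$leave_ts[i]) {
      seg[j] <- labels[i]; from[j] <- labels[i]; to[j] <- labels[i]; w[j] <- 0
    } else {
      # transit after point i (i = 7: return transit towards A)
      i <- max(i, 1)
      from[j] <- labels[i]
      to[j] <- if (i < 7) labels[i + 1] else labels[1]
      t0 <- plan$leave_ts[i]
      t1 <- if (i < 7) plan$arrive_ts[i + 1] else session_end
      seg[j] <- paste0(from[j], ">", to[j])
      w[j] <- if (t1 > t0) (t - t0) / (t1 - t0) else 0
    }
  }
  list(segment = seg, from = from, to = to, w = w)
}

# Per-time median and log-sd for one channel: static points use the label's
# regime; transits blend the flanking labels' parameters linearly.
channel_params <- function(loc, regimes, med_col, iqr_col) {
  med <- regimes[[med_col]][match(loc$from, regimes$label)]
  iqr <- regimes[[iqr_col]][match(loc$from, regimes$label)]
  med2 <- regimes[[med_col]][match(loc$to, regimes$label)]
  iqr2 <- regimes[[iqr_col]][match(loc$to, regimes$label)]
  med <- (1 - loc$w) * med + loc$w * med2
  iqr <- (1 - loc$w) * iqr + loc$w * iqr2
  list(med = med, sigma = mapply(sigma_from_iqr, med, iqr))
}

apply_tod_shift <- function(regimes, config) {
  if (config$time_of_day != "afternoon") return(regimes)
  s <- config$tod_shift
  for (col in c("pm1_med", "pm2_5_med", "pm10_med"))
    regimes[[col]] <- regimes[[col]] * (s$pm_factor %||% 1)
  regimes$tvoc_med <- regimes$tvoc_med * (s$tvoc_factor %||% 1)
  regimes$co2_med <- pmax(regimes$co2_med + (s$co2_offset_ppm %||% 0), 0)
  regimes
}

#' Generate one synthetic body-sensor-network session
#'
#' Produces the environmental stream (one record per `env_period_s`), the
#' physiological stream (10 Hz pulse and respiratory rate), the A–G segment
#' plan and the GPS track for one participant's walk. Pollutant channels
#' follow each microenvironment's configured regime with first-order
#' autoregressive lognormal fluctuations around the configured medians;
#' PM1/PM2.5/PM10 share one fluctuation path scaled by the configured median
#' ratios so the size ordering always holds; CO and NO2 below the detection
#' floor are reported at the floor with a censored flag.
#'
#' @param profile a `participant_profile`.
#' @param config a `scenario_config`.
#' @param seed integer seed; identical (profile, config, seed) gives a
#'   byte-identical session.
#' @return object of class `sensor_session`: list with `profile`,
#'   `env_stream` (data.frame), `physio_stream` (data.frame),
#'   `segment_plan` (label, arrive_ts, leave_ts in seconds),
#'   `time_of_day`, and `start_time` (POSIXct, UTC).
#' @export
generate_session <- function(profile, config, seed) {
  validate_scenario_config(config)
  validate_profile(profile)
  plan <- build_segment_plan(config)
  session_end <- plan$leave_ts[7] + config$transit_min[7] * 60
  regimes <- apply_tod_shift(config$regime_params, config)
  ns <- config$noise_scale

  with_seed(seed, {
    ## environmental stream
    te <- seq(0, session_end, by = config$env_period_s)
    loc_e <- locate_times(te, plan, session_end)
    n_e <- length(te)

    draw_env <- function(med_col, iqr_col, rg = regimes) {
      p <- channel_params(loc_e, rg, med_col, iqr_col)
      z <- ar1_path(n_e, config$ar_env)
      p$med * exp(ns * p$sigma * z)
    }

    co2 <- draw_env("co2_med", "co2_iqr")
    tvoc <- draw_env("tvoc_med", "tvoc_iqr")
    # shared fluctuation path for the PM size fractions
    p25 <- channel_params(loc_e, regimes, "pm2_5_med", "pm2_5_iqr")
    zpm <- ar1_path(n_e, config$ar_env)
    pm2_5 <- p25$med * exp(ns * p25$sigma * zpm)
    r1 <- channel_params(loc_e, regimes, "pm1_med", "pm1_iqr")$med / p25$med
    r10 <- channel_params(loc_e, regimes, "pm10_med", "pm10_iqr")$med / p25$med
    pm1 <- pm2_5 * pmin(r1, 1)
    pm10 <- pm2_5 * pmax(r10, 1)
    co_raw <- draw_env("co_med", "co_iqr")
    no2_raw <- draw_env("no2_med", "no2_iqr")
    co_cens <- co_raw < config$lod_ppb
    no2_cens <- no2_raw < config$lod_ppb
    co <- ifelse(co_cens, config$lod_ppb, co_raw)
    no2 <- ifelse(no2_cens, config$lod_ppb, no2_raw)

    temp_base <- if (config$time_of_day == "morning") 11 else 14.5
    temp_c <- temp_base + 0.8 * ar1_path(n_e, config$ar_env)
    rh_pct <- pmin(pmax(72 + 4 * ar1_path(n_e, config$ar_env), 20), 100)
    pressure_hpa <- 1012 + 1.5 * ar1_path(n_e, config$ar_env)

    wp <- config$waypoints
    lat1 <- wp$lat[match(loc_e$from, wp$label)]
    lat2 <- wp$lat[match(loc_e$to, wp$label)]
    lon1 <- wp$lon[match(loc_e$from, wp$label)]
    lon2 <- wp$lon[match(loc_e$to, wp$label)]
    lat <- (1 - loc_e$w) * lat1 + loc_e$w * lat2
    lon <- (1 - loc_e$w) * lon1 + loc_e$w * lon2

    env <- data.frame(
      timestamp = te, pm1 = pm1, pm2_5 = pm2_5, pm10 = pm10,
      co2 = co2, tvoc = tvoc, co = co, no2 = no2,
      co_censored = co_cens, no2_censored = no2_cens,
      temp_c = temp_c, rh_pct = rh_pct, pressure_hpa = pressure_hpa,
      lat = lat, lon = lon
    )

    ## physiological stream (10 Hz) with a per-participant level
    tp <- seq(0, session_end, by = 1 / config$physio_rate_hz)
    loc_p <- locate_times(tp, plan, session_end)
    n_p <- length(tp)
    b_rr <- stats::rnorm(1, 0, config$between_subject_sd)
    b_pr <- stats::rnorm(1, 0, config$between_subject_sd)
    prr <- channel_params(loc_p, config$physio_params, "rr_med", "rr_iqr")
    ppr <- channel_params(loc_p, config$physio_params, "pr_med", "pr_iqr")
    rr <- prr$med * exp(b_rr * min(ns, 1) + ns * prr$sigma * ar1_path(n_p, config$ar_physio))
    pr <- ppr$med * exp(b_pr * min(ns, 1) + ns * ppr$sigma * ar1_path(n_p, config$ar_physio))
    physio <- data.frame(timestamp = tp, pr = pr, rr = rr)

    start_hm <- if (config$time_of_day == "morning") "10:00:00" else "14:30:00"
    session <- structure(list(
      profile = profile, env_stream = env, physio_stream = physio,
      segment_plan = plan, time_of_day = config$time_of_day,
      start_time = as.POSIXct(paste(config$start_date, start_hm), tz = "UTC")
    ), class = "sensor_session")
    validate_session(session)
  })
}

#' Validate a sensor session's structural invariants
#'
#' Checks strictly increasing timestamps in both streams, non-overlapping
#' ordered segment intervals inside the stream span, non-negative
#' concentrations and the PM size ordering pm1 <= pm2.5 <= pm10.
#'
#' @param session a `sensor_session`.
#' @return the session, invisibly usable in a pipe; errors describe the
#'   first violated record.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "sensor_session"))
  env <- session$env_stream
  if (any(diff(env$timestamp) <= 0))
    abort_pape("env_stream timestamps are not strictly increasing", "pape_session_error")
  if (any(diff(session$physio_stream$timestamp) <= 0))
    abort_pape("physio_stream timestamps are not strictly increasing", "pape_session_error")
  conc <- c("pm1", "pm2_5", "pm10", "co2", "tvoc", "co", "no2")
  for (ch in conc) {
    bad <- which(env[[ch]] < 0)
    if (length(bad))
      abort_pape(sprintf("negative %s concentration at row %d", ch, bad[1]),
                 "pape_session_error")
  }
  bad <- which(!(env$pm1 <= env$pm2_5 & env$pm2_5 <= env$pm10))
  if (length(bad))
    abort_pape(sprintf("PM size ordering violated at row %d (need pm1 <= pm2_5 <= pm10)",
                       bad[1]), "pape_session_error")
  plan <- session$segment_plan
  if (any(plan$leave_ts <= plan$arrive_ts) ||
      any(diff(plan$arrive_ts) <= 0) ||
      any(utils::head(plan$leave_ts, -1) > utils::tail(plan$arrive_ts, -1)))
    abort_pape("segment intervals must be ordered and non-overlapping", "pape_session_error")
  span <- range(env$timestamp)
  if (plan$arrive_ts[1] < span[1] || plan$leave_ts[7] > span[2] + 1e-9)
    abort_pape("segment plan extends beyond the stream time span", "pape_session_error")
  session
}

#' Simulate per-point summary matrices for statistical calibration
#'
#' Draws the summary value (e.g. a per-point median concentration) of one
#' channel for `n_participants` participants at the 7 static points, with a
#' per-participant lognormal random level plus independent within-cell
#' noise. Under `effect = "null"` every point shares one common median, so
#' the 7 within-participant values are exchangeable — the regime used for
#' type-I-error calibration of the across-point tests. Under
#' `effect = "regime"` each point keeps its configured median (point A's
#' indoor CO2 offset is then the injected effect).
#'
#' @param n_participants rows of the summary matrix.
#' @param config a `scenario_config` supplying regimes.
#' @param seed integer seed.
#' @param channel one of `"co2"`, `"tvoc"`, `"pm1"`, `"pm2_5"`, `"pm10"`.
#' @param effect `"regime"` (configured per-point medians) or `"null"`
#'   (common median across points).
#' @return matrix `n_participants x 7`, columns named A..G.
#' @export
simulate_point_summaries <- function(n_participants, config = scenario_config(),
                                     seed, channel = "co2",
                                     effect = c("regime", "null")) {
  effect <- match.arg(effect)
  med_col <- paste0(channel, "_med")
  iqr_col <- paste0(channel, "_iqr")
  rg <- apply_tod_shift(config$regime_params, config)
  if (!med_col %in% names(rg))
    abort_pape(sprintf("unknown channel '%s'", channel), "pape_config_error")
  med <- rg[[med_col]]
  iqr <- rg[[iqr_col]]
  if (effect == "null") {
    med <- rep(stats::median(med), 7)
    iqr <- rep(stats::median(iqr), 7)
  }
  # summaries of ~minutes of data fluctuate less than single samples
  sigma <- mapply(sigma_from_iqr, med, iqr) * config$noise_scale / 2
  with_seed(seed, {
    b <- stats::rnorm(n_participants, 0, config$between_subject_sd)
    e <- matrix(stats::rnorm(n_participants * 7), n_participants, 7)
    m <- sweep(exp(sweep(e, 2, sigma, `*`)), 2, med, `*`) * exp(b)
    colnames(m) <- c("A", "B", "C", "D", "E", "F", "G")
    rownames(m) <- sprintf("P%02d", seq_len(n_participants))
    m
  })
}
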