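# Dose computation. The aggregated pollution value over a period is the
# trapezoidal time integral of concentration,
#   SZ_p = sum_i 0.5 * (Z_{t_i+1} + Z_{t_i}) * (t_{i+1} - t_i),
# valid only while consecutive samples are less than 10 minutes apart; the
# personal exposure (inhaled dose) over the period is SZ * V'm with minute
# ventilation converted from L/min to m3/min. For time-varying ventilation
# the product Z(t) * V'm(t) is integrated instead, which degenerates to the
# constant form when V'm is constant.

#' Trapezoidal concentration-time aggregation
#'
#' @param values pollutant concentrations at the sample times.
#' @param times_min sample times in minutes, strictly increasing; every gap
#'   must be shorter than `max_gap_min`.
#' @param max_gap_min largest admissible sampling gap (default 10 minutes);
#'   a longer gap means the trapezoid no longer approximates the exposure
#'   and is an error, not a warning.
#' @return aggregated value in concentration x minutes (e.g. ug.min/m3).
#' @export
aggregate_sz <- function(values, times_min, max_gap_min = 10) {
  n <- length(values)
  if (n != length(times_min))
    abort_pape("values and times_min must have equal length", "pape_exposure_error")
  if (n < 2)
    abort_pape("need at least 2 samples to aggregate", "pape_exposure_error")
  dt <- diff(times_min)
  if (any(dt <= 0))
    abort_pape("times_min must be strictly increasing", "pape_exposure_error")
  if (any(dt >= max_gap_min))
    abort_pape(sprintf(
      "sampling gap of %.3g min at index %d violates the < %g min aggregation constraint",
      max(dt), which.max(dt), max_gap_min), "pape_exposure_error")
  sum(0.5 * (values[-1] + values[-n]) * dt)
}

#' Inhaled dose from aggregated concentration and ventilation
#'
#' `dose = sz * vm_lpm / 1000`: ventilation is converted from L/min to
#' m3/min before multiplying, so a SZ in ug.min/m3 yields ug.
#'
#' @param sz concentration-time aggregate from [aggregate_sz()] (times in
#'   minutes).
#' @param vm_lpm minute ventilation, L/min.
#' @return dose in the concentration's mass/amount unit.
#' @export
compute_pape <- function(sz, vm_lpm) {
  if (any(vm_lpm <= 0))
    abort_pape("vm_lpm must be > 0", "pape_exposure_error")
  sz * vm_lpm / 1000
}

#' Inhaled dose with time-varying ventilation
#'
#' Trapezoidal integral of `Z(t) * V'm(t) / 1000` over the sample times;
#' equals `compute_pape(aggregate_sz(values, times), vm)` whenever `vm_lpm`
#' is constant.
#'
#' @param values concentrations at the sample times.
#' @param vm_lpm ventilation (L/min) at the same times.
#' @param times_min sample times in minutes.
#' @param max_gap_min passed to the gap check.
#' @return dose.
#' @export
compute_pape_series <- function(values, vm_lpm, times_min, max_gap_min = 10) {
  if (length(vm_lpm) != length(values))
    abort_pape("values and vm_lpm must share the node grid", "pape_exposure_error")
  if (any(vm_lpm <= 0))
    abort_pape("vm_lpm must be > 0", "pape_exposure_error")
  aggregate_sz(values * vm_lpm / 1000, times_min, max_gap_min)
}

#' Standard-Method inputs
#'
#' The comparator dose uses a fixed monitoring station's daily concentration,
#' a sex/activity tabulated ventilation, and the total static exposure time
#' (7 points x 5 minutes = 35 minutes by default).
#'
#' @param c_std named vector of daily fixed-station concentrations (ug/m3
#'   for PM), e.g. `c(pm2_5 = 19)`.
#' @param vm_std_lpm tabulated minute ventilation, L/min (see
#'   [tabulated_vm()]).
#' @param duration_min total exposure duration, minutes.
#' @return object of class `standard_inputs`.
#' @export
standard_inputs <- function(c_std, vm_std_lpm, duration_min = 35) {
  if (any(c_std < 0)) abort_pape("c_std must be >= 0", "pape_exposure_error")
  if (duration_min <= 0) abort_pape("duration_min must be > 0", "pape_exposure_error")
  if (vm_std_lpm <= 0) abort_pape("vm_std_lpm must be > 0", "pape_exposure_error")
  if (is.null(names(c_std)) || any(!nzchar(names(c_std))))
    abort_pape("c_std must be a named vector (pollutant names)", "pape_exposure_error")
  structure(list(c_std = c_std, vm_std_lpm = vm_std_lpm,
                 duration_min = duration_min),
            class = "standard_inputs")
}

#' Standard-Method inhaled dose
#'
#' `c_std * (vm_std_lpm / 1000) * duration_min` — the fixed-station daily
#' concentration held constant over the whole exposure window.
#'
#' @param inputs a `standard_inputs` object.
#' @param pollutant name to look up in `inputs$c_std`.
#' @return dose (ug for PM concentrations in ug/m3).
#' @export
standard_dose <- function(inputs, pollutant) {
  stopifnot(inherits(inputs, "standard_inputs"))
  if (!pollutant %in% names(inputs$c_std))
    abort_pape(sprintf("no Standard-Method concentration for pollutant '%s'", pollutant),
               "pape_exposure_error")
  unname(inputs$c_std[[pollutant]] * (inputs$vm_std_lpm / 1000) * inputs$duration_min)
}

# Collapse a segment's normalized nodes to per-minute means and return the
# boundary-padded minute grid on which they are integrated: the five
# per-minute means are treated as a step function over the full dwell, so a
# constant segment integrates to exactly concentration x dwell.
per_minute_grid <- function(nodes, samples_per_minute, dwell_min) {
  n_min <- as.integer(round(dwell_min))
  if (length(nodes) != n_min * samples_per_minute)
    abort_pape(sprintf("expected %d nodes (%d min x %d per min), got %d",
                       n_min * samples_per_minute, n_min, samples_per_minute,
                       length(nodes)), "pape_exposure_error")
  m <- colMeans(matrix(nodes, nrow = samples_per_minute))
  centres <- seq_len(n_min) - 0.5
  list(times = c(0, centres, n_min), values = c(m[1], m, m[n_min]),
       minute_means = m)
}

#' Per-segment and total exposure for one session
#'
#' For each static acquisition point: the normalized concentration nodes are
#' collapsed to per-minute means (the environmental factor), aggregated to
#' SZ by [aggregate_sz()] over the dwell, and multiplied with ventilation to
#' a dose. `ventilation = "integral"` (default) integrates the product of
#' concentration and the node-wise ventilation series;
#' `ventilation = "constant"` multiplies SZ with the segment's mean
#' ventilation, the literal constant-ventilation form. `env_factor =
#' "segment_mean"` replaces the five per-minute means by one 5-minute mean.
#'
#' The session total `id_new` sums the static-point doses of the dose
#' pollutant (PM2.5 by default); dynamic (walking) segments carry no
#' physiological data in the study design and are never part of the total.
#'
#' @param segments named list of `segmented_channel`s from
#'   [preprocess_session()].
#' @param vm a `ventilation_series` aligned with the segment node grids.
#' @param participant_id identifier for the output rows.
#' @param pollutants channels to tabulate.
#' @param dose_pollutant channel whose static-point doses sum to `id_new`.
#' @param env_factor `"per_minute"` (default) or `"segment_mean"`.
#' @param ventilation `"integral"` (default) or `"constant"`.
#' @return object of class `exposure_table`: data.frame with columns
#'   participant, segment, pollutant, duration_min, sz, vm_mean_lpm, pape;
#'   attributes `totals` (named per-pollutant dose totals) and `id_new`
#'   (the `dose_pollutant` total).
#' @export
session_exposure <- function(segments, vm, participant_id = NULL,
                             pollutants = c("pm1", "pm2_5", "pm10", "co2", "tvoc"),
                             dose_pollutant = "pm2_5",
                             env_factor = c("per_minute", "segment_mean"),
                             ventilation = c("integral", "constant")) {
  env_factor <- match.arg(env_factor)
  ventilation <- match.arg(ventilation)
  stopifnot(inherits(vm, "ventilation_series"))
  participant_id <- participant_id %||% vm$participant_id
  missing <- setdiff(pollutants, names(segments))
  if (length(missing))
    abort_pape(sprintf("segments are missing channel(s): %s",
                       paste(missing, collapse = ", ")), "pape_exposure_error")
  if (!dose_pollutant %in% pollutants)
    abort_pape("dose_pollutant must be among pollutants", "pape_exposure_error")

  rows <- list()
  for (pol in pollutants) {
    sc <- segments[[pol]]
    labels <- names(sc$static)
    if (!all(labels %in% names(vm$static)))
      abort_pape(sprintf("ventilation series lacks segment(s) of channel '%s'", pol),
                 "pape_exposure_error")
    for (k in seq_along(labels)) {
      lb <- labels[k]
      dwell <- sc$dwell_min[k]
      nodes <- sc$static[[lb]]
      spm <- sc$samples_per_minute
      if (env_factor == "segment_mean") {
        zg <- list(times = c(0, dwell), values = rep(mean(nodes), 2),
                   minute_means = mean(nodes))
      } else {
        zg <- per_minute_grid(nodes, spm, dwell)
      }
      vnodes <- vm$static[[lb]]
      if (length(vnodes) != length(nodes))
        abort_pape(sprintf("ventilation/concentration node mismatch in segment '%s'", lb),
                   "pape_exposure_error")
      if (env_factor == "segment_mean") {
        vg <- rep(mean(vnodes), 2)
      } else {
        vg <- per_minute_grid(vnodes, spm, dwell)$values
      }
      sz <- aggregate_sz(zg$values, zg$times)
      pape <- if (ventilation == "constant") {
        compute_pape(sz, mean(vnodes))
      } else {
        compute_pape_series(zg$values, vg, zg$times)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = participant_id, segment = lb, pollutant = pol,
        duration_min = dwell, sz = sz, vm_mean_lpm = mean(vnodes),
        pape = pape, stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  totals <- tapply(tab$pape, tab$pollutant, sum)
  structure(tab, class = c("exposure_table", "data.frame"),
            totals = totals, id_new = unname(totals[[dose_pollutant]]))
}
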