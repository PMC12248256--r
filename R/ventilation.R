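# Minute ventilation. The personalized model is a power function of heart
# rate (pulse rate is used as its proxy), respiratory rate, age, sex and
# forced vital capacity, fitted elsewhere on a large pooled dataset:
#
#   V'm = exp(-8.75) * HR^1.72 * RR^0.611 * age^0.298 * sex^(-0.206) * FVC^0.614
#
# with V'm in L/min, HR in beats/min, RR in breaths/min, FVC in L and sex
# coded 1 for men, 2 for women. The comparator "Standard Method" instead
# uses activity-level-3 tabulated values (15.14 L/min men, 13.26 L/min
# women).

VM_COEFS <- c(intercept = -8.75, hr = 1.72, rr = 0.611, age = 0.298,
              sex = -0.206, fvc = 0.614)

#' Personalized minute ventilation (power model)
#'
#' @param hr heart rate, beats/min (pulse rate is used as the proxy).
#' @param rr respiratory rate, breaths/min.
#' @param age years.
#' @param sex_code 1 = man, 2 = woman.
#' @param fvc forced vital capacity, litres.
#' @return minute ventilation in L/min; vectorized over `hr` and `rr`.
#' @examples
#' compute_vm(hr = 90, rr = 15, age = 25, sex_code = 1, fvc = 5)
#' @export
compute_vm <- function(hr, rr, age, sex_code, fvc) {
  if (any(!sex_code %in% c(1, 2)))
    abort_pape("sex_code must be 1 (man) or 2 (woman)", "pape_ventilation_error")
  if (any(hr <= 0) || any(rr <= 0) || any(age <= 0) || any(fvc <= 0))
    abort_pape("hr, rr, age and fvc must all be > 0 (power model undefined otherwise)",
               "pape_ventilation_error")
  unname(exp(VM_COEFS[["intercept"]]) * hr^VM_COEFS[["hr"]] *
           rr^VM_COEFS[["rr"]] * age^VM_COEFS[["age"]] *
           sex_code^VM_COEFS[["sex"]] * fvc^VM_COEFS[["fvc"]])
}

#' Tabulated minute ventilation for the Standard Method
#'
#' Activity-level-3 table values: 15.14 L/min for men, 13.26 L/min for
#' women. Other activity levels require a user-supplied lookup.
#'
#' @param sex_code 1 = man, 2 = woman.
#' @param table optional named lookup `c("1" = ..., "2" = ...)` overriding
#'   the activity-level-3 defaults.
#' @return minute ventilation in L/min.
#' @export
tabulated_vm <- function(sex_code, table = c("1" = 15.14, "2" = 13.26)) {
  if (any(!as.character(sex_code) %in% names(table)))
    abort_pape("sex_code must be 1 (man) or 2 (woman)", "pape_ventilation_error")
  unname(table[as.character(sex_code)])
}

#' Per-node ventilation series from segmented physiological channels
#'
#' Evaluates the power model at every normalized node of the static
#' segments, pairing the pulse-rate and respiratory-rate channels
#' node-by-node (their grids must match). With `mode = "segment_median"`
#' each segment instead carries one value: the model evaluated at the
#' segment's median PR and RR — a coarser alternative for sensitivity
#' checks.
#'
#' @param pr_segments `segmented_channel` of pulse rate.
#' @param rr_segments `segmented_channel` of respiratory rate.
#' @param profile a `participant_profile`.
#' @param mode `"node"` (default) or `"segment_median"`.
#' @return object of class `ventilation_series`: list with
#'   `participant_id`, `static` (named list of L/min vectors aligned with
#'   the concentration node grids), `samples_per_minute`, `source = "model"`
#'   and `mode`.
#' @export
vm_series <- function(pr_segments, rr_segments, profile,
                      mode = c("node", "segment_median")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pr_segments, "segmented_channel"),
            inherits(rr_segments, "segmented_channel"))
  validate_profile(profile)
  labels <- names(pr_segments$static)
  if (!identical(labels, names(rr_segments$static)))
    abort_pape("PR and RR segmented channels carry different segments",
               "pape_ventilation_error")
  static <- lapply(labels, function(lb) {
    pr <- pr_segments$static[[lb]]
    rr <- rr_segments$static[[lb]]
    if (length(pr) != length(rr))
      abort_pape(sprintf("node-grid mismatch in segment '%s' (%d PR vs %d RR nodes)",
                         lb, length(pr), length(rr)), "pape_ventilation_error")
    if (mode == "segment_median") {
      rep(compute_vm(stats::median(pr), stats::median(rr), profile$age,
                     profile$sex_code, profile$fvc), length(pr))
    } else {
      compute_vm(pr, rr, profile$age, profile$sex_code, profile$fvc)
    }
  })
  names(static) <- labels
  vm <- structure(list(
    participant_id = profile$participant_id, static = static,
    samples_per_minute = pr_segments$samples_per_minute,
    source = "model", mode = mode
  ), class = "ventilation_series")
  if (any(unlist(static) <= 0))
    abort_pape("ventilation must be > 0 at every node", "pape_ventilation_error")
  vm
}

#' Constant ventilation series from the Standard-Method table
#'
#' @param labels static segment labels to cover.
#' @param n_nodes nodes per segment.
#' @param sex_code 1 = man, 2 = woman.
#' @param samples_per_minute node density matching the concentration grid.
#' @return a `ventilation_series` with `source = "tabulated"`.
#' @export
tabulated_vm_series <- function(labels, n_nodes, sex_code, samples_per_minute = 3) {
  v <- tabulated_vm(sex_code)
  static <- stats::setNames(lapply(labels, function(lb) rep(v, n_nodes)), labels)
  structure(list(participant_id = NA_character_, static = static,
                 samples_per_minute = samples_per_minute,
                 source = "tabulated", mode = "node"),
            class = "ventilation_series")
}
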