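# Shared fixtures: small deterministic profiles/configs so tests build their
# inputs in code. A "quiet" scenario has zero within-segment noise (every
# sample equals its segment's configured median).

fixture_profile <- function(sex_code = 1L, age = 25, height = 179,
                            fvc = 5.0, id = "TP01") {
  structure(list(participant_id = id, sex_code = sex_code, age = age,
                 height = height, weight = 72, fvc = fvc),
            class = "participant_profile")
}

quiet_scenario <- function(...) {
  scenario_config(noise_scale = 0, ...)
}

# a segmented_channel built directly from per-segment node vectors
manual_segments <- function(static, samples_per_minute = 3, dwell_min = 5) {
  structure(list(channel = "manual", samples_per_minute = samples_per_minute,
                 static = static, dynamic = list(),
                 dwell_min = rep(dwell_min, length(static))),
            class = "segmented_channel")
}

constant_vm_series <- function(labels, n_nodes, vm, samples_per_minute = 3) {
  structure(list(participant_id = "TP01",
                 static = stats::setNames(
                   lapply(labels, function(l) rep(vm, n_nodes)), labels),
                 samples_per_minute = samples_per_minute,
                 source = "model", mode = "node"),
            class = "ventilation_series")
}

# independent piecewise-linear evaluation (oracle for interpolation paths)
plin_eval <- function(x, y, xout) {
  vapply(xout, function(t) {
    if (t <= x[1]) return(y[1])
    if (t >= x[length(x)]) return(y[length(y)])
    i <- max(which(x <= t))
    if (x[i] == t) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (t - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}
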