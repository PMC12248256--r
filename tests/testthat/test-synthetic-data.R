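# Generator: seeded determinism, cohort emulation, regime structure,
# censoring and the PM size-ordering invariant.

test_that("profiles are seeded-deterministic and respect degenerate sex ratios", {
  expect_identical(generate_profile(11), generate_profile(11))
  for (s in 1:20) {
    expect_identical(generate_profile(s, sex_ratio = 1.0)$sex_code, 1L)
    expect_identical(generate_profile(s, sex_ratio = 0.0)$sex_code, 2L)
  }
  p <- generate_profile(3)
  expect_s3_class(p, "participant_profile")
  expect_true(p$age >= 18 && p$age <= 75)
  expect_true(p$fvc > 0)
})

test_that("sex draws follow the requested ratio", {
  sexes <- vapply(1:10000, function(s)
    generate_profile(s, sex_ratio = 0.7)$sex_code, integer(1))
  expect_lt(abs(mean(sexes == 1L) - 0.7), 0.02)
})

test_that("the FVC stand-in reference evaluates its linear form", {
  # zeroed coefficients isolate the height term
  cf <- list(male = c(a = 0.05, b = 0, c = 0), female = c(a = 0.05, b = 0, c = 0))
  expect_equal(predict_fvc(1, age = 30, height = 100, coefs = cf), 5.0)
  # grid of inputs against direct hand evaluation of a*h + b*age + c
  coefs <- fvc_reference_coefs()
  grid <- expand.grid(sex = c(1, 2), age = c(20, 30, 45, 60),
                      height = c(155, 165, 175, 185, 195))
  for (i in seq_len(nrow(grid))) {
    cf_i <- if (grid$sex[i] == 1) coefs$male else coefs$female
    expect_equal(
      predict_fvc(grid$sex[i], grid$age[i], grid$height[i]),
      unname(cf_i["a"] * grid$height[i] + cf_i["b"] * grid$age[i] + cf_i["c"]))
    # men's reference exceeds women's at the same adult height/age
    expect_gte(predict_fvc(1, grid$age[i], grid$height[i]),
               predict_fvc(2, grid$age[i], grid$height[i]))
  }
  expect_error(predict_fvc(1, 25, height = -5), class = "pape_profile_error")
  expect_error(predict_fvc(3, 25, 170), class = "pape_profile_error")
})

test_that("sessions are byte-identical under identical (profile, config, seed)", {
  p <- fixture_profile()
  cfg <- scenario_config()
  expect_identical(generate_session(p, cfg, seed = 5),
                   generate_session(p, cfg, seed = 5))
  s1 <- generate_session(p, cfg, seed = 5)
  s2 <- generate_session(p, cfg, seed = 6)
  expect_false(identical(s1$env_stream, s2$env_stream))
})

test_that("zero-variance regimes reproduce configured medians exactly", {
  p <- fixture_profile()
  s <- generate_session(p, quiet_scenario(), seed = 1)
  env <- s$env_stream
  plan <- s$segment_plan
  rg <- default_regimes()
  for (lb in c("A", "D", "G")) {
    sel <- env$timestamp >= plan$arrive_ts[plan$label == lb] &
      env$timestamp < plan$leave_ts[plan$label == lb]
    expect_equal(unique(env$co2[sel]), rg$co2_med[rg$label == lb])
    expect_equal(unique(env$pm2_5[sel]), rg$pm2_5_med[rg$label == lb])
  }
  phys <- s$physio_stream
  selA <- phys$timestamp < plan$leave_ts[1]
  expect_equal(unique(phys$rr[selA]), default_physio()$rr_med[1])
})

test_that("session structure matches the cadences and plan", {
  p <- fixture_profile()
  cfg <- scenario_config()
  s <- generate_session(p, cfg, seed = 2)
  expect_equal(unique(diff(s$env_stream$timestamp)), 24)
  expect_equal(diff(s$physio_stream$timestamp)[1], 0.1, tolerance = 1e-9)
  # one env record every 24 s in a half-open 300 s window: 12 or 13 records
  plan <- s$segment_plan
  for (i in 1:7) {
    n <- sum(s$env_stream$timestamp >= plan$arrive_ts[i] &
               s$env_stream$timestamp < plan$leave_ts[i])
    expect_true(n %in% c(12L, 13L))
  }
})

test_that("PM size ordering holds in every generated record", {
  p <- fixture_profile()
  cfg <- scenario_config()
  for (s in c(3, 17, 91)) {
    env <- generate_session(p, cfg, seed = s)$env_stream
    expect_true(all(env$pm1 <= env$pm2_5 & env$pm2_5 <= env$pm10))
  }
})

test_that("CO and NO2 below the detection floor are censored at the floor", {
  p <- fixture_profile()
  env <- generate_session(p, scenario_config(), seed = 4)$env_stream
  expect_true(all(env$co[env$co_censored] == 20))
  expect_true(all(env$no2[env$no2_censored] == 20))
  expect_true(all(env$co >= 20))
  # default regime sits well below the floor: censoring dominates
  expect_gt(mean(env$co_censored), 0.95)
  # raising the floor above everything censors everything
  env2 <- generate_session(p, scenario_config(lod_ppb = 1000), seed = 4)$env_stream
  expect_true(all(env2$co_censored))
})

test_that("indoor point A exceeds every outdoor point's CO2 median across seeded sessions", {
  p <- fixture_profile()
  cfg <- scenario_config()
  meds <- replicate(50, NA_real_)
  out_meds <- matrix(NA_real_, 50, 6)
  for (k in 1:50) {
    s <- generate_session(p, cfg, seed = 100 + k)
    env <- s$env_stream; plan <- s$segment_plan
    per_point <- vapply(1:7, function(i) {
      sel <- env$timestamp >= plan$arrive_ts[i] & env$timestamp < plan$leave_ts[i]
      stats::median(env$co2[sel])
    }, numeric(1))
    meds[k] <- per_point[1]
    out_meds[k, ] <- per_point[2:7]
  }
  expect_true(all(meds > apply(out_meds, 1, max)))
  # pooled indoor median within 5% of the configured 1010.4 ppm
  expect_lt(abs(stats::median(meds) - 1010.4) / 1010.4, 0.05)
})

test_that("afternoon sessions shift PM/tVOC up and CO2 down", {
  p <- fixture_profile()
  am <- generate_session(p, quiet_scenario(time_of_day = "morning"), seed = 1)
  pm <- generate_session(p, quiet_scenario(time_of_day = "afternoon"), seed = 1)
  sel <- am$env_stream$timestamp < 300  # point A dwell
  expect_gt(mean(pm$env_stream$pm2_5[sel]), mean(am$env_stream$pm2_5[sel]))
  expect_gt(mean(pm$env_stream$tvoc[sel]), mean(am$env_stream$tvoc[sel]))
  expect_lt(mean(pm$env_stream$co2[sel]), mean(am$env_stream$co2[sel]))
})

test_that("configs missing a point's regime are rejected", {
  rg <- default_regimes()
  expect_error(scenario_config(regime_params = rg[rg$label != "C", ]),
               class = "pape_config_error")
  expect_error(scenario_config(env_period_s = 0), class = "pape_config_error")
  expect_error(scenario_config(lod_ppb = -1), class = "pape_config_error")
})

test_that("summary matrices are reproducible and respect the effect switch", {
  cfg <- scenario_config()
  m1 <- simulate_point_summaries(20, cfg, seed = 9, channel = "co2")
  expect_identical(m1, simulate_point_summaries(20, cfg, seed = 9, channel = "co2"))
  expect_equal(dim(m1), c(20L, 7L))
  # regime effect: indoor column dominates
  expect_true(all(m1[, "A"] > apply(m1[, -1], 1, max)))
  m0 <- simulate_point_summaries(200, cfg, seed = 10, channel = "co2", effect = "null")
  expect_lt(abs(stats::median(m0[, "A"]) - stats::median(m0[, "G"])) /
              stats::median(m0[, "G"]), 0.1)
})
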