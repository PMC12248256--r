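# Dose computation: trapezoidal aggregation with the 10-minute gap
# constraint, dose conversion, the Standard-Method closed form, and the
# session-level composition with its reduction/additivity/scaling
# properties.

test_that("trapezoidal aggregation handles the elementary cases", {
  # constant 10 ug/m3 over 5 min
  expect_equal(aggregate_sz(rep(10, 6), 0:5), 50)
  # single trapezoid 0.5 * (0 + 10) * 2
  expect_equal(aggregate_sz(c(0, 10), c(0, 2)), 10)
})

test_that("aggregation matches a fine-grid quadrature oracle on random series", {
  skip_if_not_installed("pracma")
  set.seed(14)
  for (k in 1:20) {
    t <- sort(stats::runif(15, 0, 5))
    t <- t + seq(0, 28, length.out = 15)  # strictly increasing, gaps < 10
    z <- stats::runif(15, 0, 80)
    fine <- sort(unique(c(t, seq(t[1], t[15], length.out = 20001))))
    zf <- stats::approx(t, z, xout = fine)$y
    expect_equal(aggregate_sz(z, t), pracma::trapz(fine, zf), tolerance = 1e-9)
  }
})

test_that("gaps of 10 minutes or more violate the aggregation constraint", {
  expect_error(aggregate_sz(c(1, 2, 3), c(0, 5, 15.1)), "10",
               class = "pape_exposure_error")
  expect_error(aggregate_sz(c(1, 2), c(0, 10)), class = "pape_exposure_error")
  expect_error(aggregate_sz(5, 0), class = "pape_exposure_error")
  expect_error(aggregate_sz(c(1, 2), c(3, 3)), class = "pape_exposure_error")
})

test_that("aggregation is additive over adjacent windows", {
  set.seed(15)
  t <- seq(0, 10, by = 0.5)
  z <- stats::runif(length(t), 0, 50)
  cut <- 11  # shared endpoint handled once
  expect_equal(aggregate_sz(z, t),
               aggregate_sz(z[1:cut], t[1:cut]) +
                 aggregate_sz(z[cut:length(z)], t[cut:length(t)]))
})

test_that("doses scale with concentration and convert L/min to m3/min", {
  expect_equal(compute_pape(0, 15), 0)
  # constant 19 ug/m3 over 35 min at 15.14 L/min: the printed P02 dose
  sz <- aggregate_sz(rep(19, 36), 0:35)
  expect_equal(round(compute_pape(sz, 15.14), 2), 10.07)
  set.seed(16)
  z <- stats::runif(15, 0, 40); t <- seq(0, 5, length.out = 15)
  k <- 3.7
  expect_equal(aggregate_sz(k * z, t), k * aggregate_sz(z, t))
  expect_equal(compute_pape(aggregate_sz(k * z, t), 12),
               k * compute_pape(aggregate_sz(z, t), 12))
})

test_that("time-varying dose equals a fine-grid integral of the product", {
  skip_if_not_installed("pracma")
  set.seed(17)
  t <- seq(0, 5, length.out = 15)
  z <- stats::runif(15, 5, 60)
  vm <- stats::runif(15, 8, 25)
  fine <- sort(unique(c(t, seq(0, 5, length.out = 20001))))
  prod_fine <- stats::approx(t, z * vm / 1000, xout = fine)$y
  expect_equal(compute_pape_series(z, vm, t),
               pracma::trapz(fine, prod_fine), tolerance = 1e-9)
  # constant ventilation degenerates to the constant-V'm form
  expect_equal(compute_pape_series(z, rep(14, 15), t),
               compute_pape(aggregate_sz(z, t), 14), tolerance = 1e-12)
})

test_that("the Standard Method reproduces the printed doses", {
  expect_equal(round(standard_dose(standard_inputs(c(pm2_5 = 17), 13.26), "pm2_5"), 2),
               7.89)
  expect_equal(round(standard_dose(standard_inputs(c(pm2_5 = 40), 15.14), "pm2_5"), 2),
               21.20)
  expect_equal(standard_dose(standard_inputs(c(pm2_5 = 0), 15.14), "pm2_5"), 0)
  expect_error(standard_dose(standard_inputs(c(pm2_5 = 17), 13.26), "pm10"),
               class = "pape_exposure_error")
  expect_error(standard_inputs(c(pm2_5 = -1), 13.26), class = "pape_exposure_error")
})

test_that("session exposure reduces to the closed form for constant inputs", {
  labels <- c("A", "B", "C", "D", "E", "F", "G")
  c0 <- 19; vm0 <- 15.14
  segs <- list(pm2_5 = manual_segments(stats::setNames(
    lapply(labels, function(l) rep(c0, 15)), labels)))
  vm <- constant_vm_series(labels, 15, vm0)
  ex <- session_exposure(segs, vm, pollutants = "pm2_5")
  expect_equal(attr(ex, "id_new"), c0 * vm0 / 1000 * 35, tolerance = 1e-14)
  expect_equal(ex$sz, rep(c0 * 5, 7))
  # equals the Standard-Method formula with the same inputs
  expect_equal(attr(ex, "id_new"),
               standard_dose(standard_inputs(c(pm2_5 = c0), vm0, 35), "pm2_5"),
               tolerance = 1e-14)
  # "constant" ventilation mode agrees for constant inputs
  ex2 <- session_exposure(segs, vm, pollutants = "pm2_5", ventilation = "constant")
  expect_equal(attr(ex2, "id_new"), attr(ex, "id_new"), tolerance = 1e-14)
})

test_that("a zero-concentration segment contributes zero dose", {
  labels <- c("A", "B", "C", "D", "E", "F", "G")
  vals <- stats::setNames(lapply(labels, function(l) rep(10, 15)), labels)
  vals$D <- rep(0, 15)
  segs <- list(pm2_5 = manual_segments(vals))
  vm <- constant_vm_series(labels, 15, 12)
  ex <- session_exposure(segs, vm, pollutants = "pm2_5")
  expect_equal(ex$pape[ex$segment == "D"], 0)
  expect_equal(attr(ex, "id_new"), 6 * 10 * 12 / 1000 * 5, tolerance = 1e-12)
})

test_that("per-segment doses match a hand-composed oracle", {
  set.seed(18)
  labels <- c("A", "B", "C", "D", "E", "F", "G")
  zs <- stats::setNames(lapply(labels, function(l) stats::runif(15, 0, 60)), labels)
  vs <- stats::setNames(lapply(labels, function(l) stats::runif(15, 8, 25)), labels)
  segs <- list(pm2_5 = manual_segments(zs))
  vm <- structure(list(participant_id = "TP01", static = vs,
                       samples_per_minute = 3, source = "model", mode = "node"),
                  class = "ventilation_series")
  ex <- session_exposure(segs, vm, pollutants = "pm2_5")
  for (i in seq_along(labels)) {
    zm <- colMeans(matrix(zs[[labels[i]]], nrow = 3))   # per-minute means
    vmm <- colMeans(matrix(vs[[labels[i]]], nrow = 3))
    tt <- c(0, seq_len(5) - 0.5, 5)
    zz <- c(zm[1], zm, zm[5]); vv <- c(vmm[1], vmm, vmm[5])
    sz_hand <- sum(0.5 * (zz[-1] + zz[-7]) * diff(tt))
    pape_hand <- sum(0.5 * ((zz * vv / 1000)[-1] + (zz * vv / 1000)[-7]) * diff(tt))
    expect_equal(ex$sz[i], sz_hand, tolerance = 1e-12)
    expect_equal(ex$pape[i], pape_hand, tolerance = 1e-12)
  }
  # totals are the sum of included segments' doses
  expect_equal(attr(ex, "id_new"), sum(ex$pape), tolerance = 1e-12)
})

test_that("missing segments or channels are reported", {
  segs <- list(pm2_5 = manual_segments(list(A = rep(1, 15))))
  vm <- constant_vm_series("B", 15, 10)
  expect_error(session_exposure(segs, vm, pollutants = "pm2_5"),
               class = "pape_exposure_error")
  expect_error(session_exposure(segs, constant_vm_series("A", 15, 10),
                                pollutants = c("pm2_5", "pm10")),
               class = "pape_exposure_error")
})
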