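flat_trace <- function(R = 1.5, f380 = 100, n = 601, protocol = "suspension") {
  t <- seq(0, n - 1)
  fura_trace(t, rep(R * f380, n), rep(f380, n), protocol = protocol)
}

test_that("ratio computation is element-wise division", {
  tr <- flat_trace(R = 1)
  expect_equal(compute_ratio(tr), rep(1, 601))
  tr2 <- flat_trace(R = 2)
  expect_equal(compute_ratio(tr2), rep(2, 601))
  set.seed(3)
  f340 <- runif(601, 50, 200); f380 <- runif(601, 50, 200)
  tr3 <- fura_trace(seq(0, 600), f340, f380)
  expect_equal(compute_ratio(tr3), f340 / f380)
})

test_that("trace validation enforces positivity, ordering and events", {
  t <- seq(0, 600)
  expect_error(fura_trace(t, rep(1, 601), c(0, rep(1, 600))), "index 1")
  expect_error(fura_trace(t, rep(1, 601), rep(1, 601),
                          events = list(egta_add = 200, tg_add = 100,
                                        ca_addback = 400)),
               "ordered")
  expect_error(fura_trace(t, rep(1, 601), rep(1, 601),
                          events = list(egta_add = 100, tg_add = 180,
                                        ca_addback = 700)),
               "within the record")
})

test_that("F/F0 normalisation uses the pre-TG time window", {
  tr <- flat_trace(R = 1.4)
  norm <- normalize_f_over_f0(tr)
  expect_equal(norm$f0, 1.4)
  expect_equal(norm$f_over_f0, rep(1, 601))
  expect_equal(norm$window, c(130, 180))

  # doubling after addback gives plateau F/F0 = 2
  t <- seq(0, 600)
  R <- ifelse(t >= 400, 2.8, 1.4)
  tr2 <- fura_trace(t, R * 100, rep(100, 601))
  norm2 <- normalize_f_over_f0(tr2)
  expect_equal(mean(norm2$f_over_f0[t >= 450 & t <= 550]), 2)

  # windowed mean against independent summation
  ft <- gen_fura_trace(seed = 21)
  Rt <- compute_ratio(ft$trace)
  sel <- ft$trace$time >= 130 & ft$trace$time < 180
  expect_equal(normalize_f_over_f0(ft$trace)$f0, sum(Rt[sel]) / sum(sel))

  # plate protocol: 80-s baseline, trace kept un-normalised
  trp <- flat_trace(R = 1.4, protocol = "plate")
  normp <- normalize_f_over_f0(trp)
  expect_equal(normp$window, c(100, 180))
  expect_equal(normp$ratio, rep(1.4, 601))
})

test_that("gain invariance: common scaling of both channels cancels", {
  ft <- gen_fura_trace(seed = 22)
  tr <- ft$trace
  tr2 <- fura_trace(tr$time, tr$f340 * 3.7, tr$f380 * 3.7,
                    events = attr(tr, "events"))
  expect_equal(normalize_f_over_f0(tr2)$f_over_f0,
               normalize_f_over_f0(tr)$f_over_f0)
})

test_that("Grynkiewicz calibration converts ratios to nM", {
  cal <- calibration_params(kd = 225, r_min = 0.3, r_max = 6, beta = 1)
  expect_equal(calibrate_concentration(0.3, cal), 0)
  # at the arithmetic midpoint with beta = 1 the ratio term is 1: Kd itself
  expect_equal(calibrate_concentration((0.3 + 6) / 2, cal), 225)
  # algebraic inversion round trip at 118 nM with beta = 2
  cal2 <- calibration_params(kd = 225, r_min = 0.3, r_max = 6, beta = 2)
  kb <- 225 * 2
  R118 <- (118 * 6 + kb * 0.3) / (118 + kb)
  expect_equal(calibrate_concentration(R118, cal2), 118)
  # monotone increasing, diverging toward r_max
  Rs <- seq(0.31, 5.99, length.out = 50)
  expect_true(all(diff(calibrate_concentration(Rs, cal)) > 0))
  expect_gt(calibrate_concentration(5.999, cal), 1e5)
  expect_error(calibrate_concentration(6, cal), "saturated")
  expect_warning(out <- calibrate_concentration(0.1, cal), "clamped")
  expect_equal(out, 0)
})

test_that("basal concentration recovers generator ground truth", {
  ft <- gen_fura_trace(fura_truth(basal_nM = 118, noise_sd = 0.05),
                       seed = 30)
  cal <- ft$truth$calib
  expect_equal(basal_concentration(ft$trace, cal), 118, tolerance = 0.01)
  tr <- flat_trace(R = 0.3)
  expect_equal(basal_concentration(
    tr, calibration_params(225, 0.3, 6, 1)), 0)
})

test_that("relative basal is the difference of two windowed means", {
  # no EGTA-induced drop: zero
  trp <- flat_trace(R = 1.5, protocol = "plate")
  expect_equal(relative_basal(trp), 0)
  # a 0.2 ratio-unit drop at EGTA
  t <- seq(0, 600)
  R <- ifelse(t >= 100, 1.3, 1.5)
  trp2 <- fura_trace(t, R * 100, rep(100, 601), protocol = "plate")
  # independent computation of the two windowed means (half-open windows:
  # the sample at the addition instant belongs to the post-addition phase)
  Rt <- compute_ratio(trp2)
  f_basal <- mean(Rt[t >= 70 & t < 100])
  f0 <- mean(Rt[t >= 100 & t < 180])
  expect_equal(relative_basal(trp2), f_basal - f0)
  expect_equal(relative_basal(trp2), 0.2, tolerance = 1e-10)
})

test_that("peak SOCE is the windowed F/F0 mean (or ratio difference)", {
  tr <- flat_trace(R = 1.4)
  expect_equal(peak_soce(tr), 1)
  t <- seq(0, 600)
  R <- ifelse(t >= 420, 3.5, 1.4)
  tr2 <- fura_trace(t, R * 100, rep(100, 601))
  expect_equal(peak_soce(tr2), 2.5)
  # ramp through the window equals the brute-force average
  R3 <- 1.4 + pmax(0, t - 400) * 0.002
  tr3 <- fura_trace(t, R3 * 100, rep(100, 601))
  ff0 <- (R3 / 1.4)[t >= 450 & t <= 550]
  expect_equal(peak_soce(tr3), mean(ff0))
  # plate protocol: F_SOCE - F0
  trp <- fura_trace(t, ifelse(t >= 420, 2.1, 1.4) * 100, rep(100, 601),
                    protocol = "plate")
  expect_equal(peak_soce(trp), 0.7)
  expect_error(peak_soce(tr, window = c(300, 550)), "after the Ca")
})

test_that("calibration constants are recovered from calibration segments", {
  cal <- derive_calibration(rep(6, 30), rep(0.3, 30), rep(100, 30),
                            rep(100, 30))
  expect_equal(cal$r_max, 6)
  expect_equal(cal$r_min, 0.3)
  expect_equal(cal$beta, 1)
  expect_equal(cal$kd, 225)
  ft <- gen_fura_trace(seed = 31)
  seg <- ft$calib_segments
  cal2 <- derive_calibration(seg$triton_ratio, seg$egta_ratio,
                             seg$f380_triton, seg$f380_egta)
  expect_equal(cal2$r_max, ft$truth$calib$r_max, tolerance = 0.01)
  expect_equal(cal2$r_min, ft$truth$calib$r_min, tolerance = 0.01)
  expect_equal(cal2$beta, ft$truth$calib$beta, tolerance = 0.01)
  expect_error(derive_calibration(rep(0.3, 30), rep(6, 30)), "swapped")
  expect_warning(derive_calibration(rep(6, 30), rep(0.3, 30)), "beta")
})

test_that("fura traces round-trip through CSV", {
  ft <- gen_fura_trace(seed = 33)
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = ft$trace$time, f340 = ft$trace$f340,
                       f380 = ft$trace$f380), path, row.names = FALSE)
  back <- read_fura_trace(path)
  expect_equal(back$f340, ft$trace$f340)
  expect_equal(compute_ratio(back), compute_ratio(ft$trace))
})
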