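# retention-index computation, inversion, RRT and retention time locking

test_that("RI equals 100 x carbon number at every anchor", {
  a <- nominal_fap_ladder(18:26)
  ri <- compute_ri_fap(as.numeric(a), a)
  expect_equal(as.numeric(ri), 100 * (18:26), tolerance = 1e-12)
})

test_that("hand-evaluated bracket and its algebraic inverse agree", {
  a <- fap_anchor_set(c("23" = 30.000, "24" = 32.972))
  expect_equal(as.numeric(compute_ri_fap(31.486, a)), 2350)
  expect_equal(invert_ri_fap(2350, a), 31.486)
  expect_equal(invert_ri_fap(2300, a), 30.000)
})

test_that("stigmasterol RRT bracket reproduces the printed index within 6", {
  # anchors given in RRT units; the index is unit-free
  a <- fap_anchor_set(c("22" = 1.38, "23" = 1.47))
  ri <- ri_report(compute_ri_fap(1.42, a))
  expect_lte(abs(ri - 2247), 6)
})

test_that("printed RRTs of all 30 compounds reproduce printed indices within 6", {
  rrt_anchors <- fap_anchor_set(c("18" = 0.93, "19" = 1.03, "20" = 1.14,
                                  "21" = 1.26, "22" = 1.38, "23" = 1.47,
                                  "24" = 1.57, "25" = 1.70, "26" = 1.85))
  e <- builtin_library()$entries
  ri <- ri_report(compute_ri_fap(e$rrt, rrt_anchors))
  expect_true(all(abs(ri - e$ri_fap) <= 6))
})

test_that("forward/inverse round trip is exact on random ladders", {
  set.seed(42)
  for (k in 1:25) {
    rts <- sort(20 + cumsum(runif(6, 1.5, 3.5)))
    a <- fap_anchor_set(stats::setNames(rts, 20:25))
    t <- runif(20, min(rts), max(rts))
    ri <- compute_ri_fap(t, a)
    expect_equal(invert_ri_fap(as.numeric(ri), a), t, tolerance = 1e-9)
    ri2 <- compute_ri_fap(invert_ri_fap(as.numeric(ri), a), a)
    expect_equal(as.numeric(ri2), as.numeric(ri), tolerance = 1e-9)
    expect_true(all(diff(as.numeric(compute_ri_fap(sort(t), a))) >= 0))
  }
})

test_that("RI is invariant under affine transforms of the time axis", {
  a <- nominal_fap_ladder()
  t <- seq(21, 35, by = 0.5)
  ri0 <- as.numeric(compute_ri_fap(t, a))
  for (ab in list(c(1.03, 0), c(0.95, 2.5), c(1.2, -3))) {
    a2 <- fap_anchor_set(stats::setNames(ab[1] * as.numeric(a) + ab[2],
                                         names(a)))
    ri2 <- as.numeric(compute_ri_fap(ab[1] * t + ab[2], a2))
    expect_equal(ri2, ri0, tolerance = 1e-9)
  }
})

test_that("out-of-ladder and gapped ladders raise informative errors", {
  a <- nominal_fap_ladder()
  expect_error(compute_ri_fap(40, a), "26:0-P")
  expect_error(compute_ri_fap(10, a), "outside")
  g <- fap_anchor_set(c("21" = 26.462, "22" = 28.982, "24" = 32.972))
  expect_error(compute_ri_fap(30.5, g), "gap")
  expect_error(invert_ri_fap(2350, g), "gap")
  expect_error(invert_ri_fap(1500, a), "outside")
})

test_that("RRT is the plain ratio with a positive reference", {
  expect_equal(compute_rrt(32.972, 32.972), 1)
  expect_error(compute_rrt(30, 0), "positive")
  run <- oil_runs()$rapeseed
  anch <- extract_fap_anchors(run$chromatogram)
  istd_rt <- 32.972 / 1.57
  expect_equal(compute_rrt(anch[["24"]], istd_rt), 1.57, tolerance = 1e-9)
  rrts <- compute_rrt(run$truth$true_rt, istd_rt)
  expect_true(all(diff(rrts[order(run$truth$true_rt)]) >= 0))
})

test_that("the RTL quadratic fit behaves as the physics oracle predicts", {
  p <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  rt <- 5 + 28.5 / p # holdup-time physics, rt(1.0) = 33.5
  cal <- fit_rtl_calibration(data.frame(pressure = p, rt = rt),
                             lock_target = 33.5)
  # oracle: residuals of an independently fitted quadratic
  oracle <- stats::lm(rt ~ p + I(p^2))
  expect_equal(max(abs(cal$residuals)), max(abs(stats::resid(oracle))),
               tolerance = 1e-9)
  expect_lt(max(abs(cal$residuals)), 0.1)
  expect_true(cal$monotone)
  expect_false(cal$degenerate)
  expect_equal(cal$lock_target, 33.5)

  flat <- fit_rtl_calibration(data.frame(pressure = p, rt = rep(33.5, 5)))
  expect_true(flat$degenerate)
  expect_error(solve_lock_pressure(flat), "degenerate")
  expect_error(fit_rtl_calibration(data.frame(pressure = p[1:4],
                                              rt = rt[1:4])), "5 calibration")
  expect_error(fit_rtl_calibration(data.frame(pressure = rep(1, 5), rt = rt)),
               "distinct")
})

test_that("lock solve is the identity at the nominal point", {
  p <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  rt <- 5 + 28.5 / p
  cal <- fit_rtl_calibration(data.frame(pressure = p, rt = rt),
                             lock_target = 33.5)
  sol <- solve_lock_pressure(cal, measure = function(x) 5 + 28.5 / x)
  expect_equal(as.numeric(sol), 1.0, tolerance = 1e-3)
  expect_equal(5 + 28.5 / as.numeric(sol), 33.5, tolerance = 5e-4)
})

test_that("locking restores a drifted instrument to the target within 0.005 min", {
  lad <- nominal_fap_ladder()
  u24 <- as.numeric(lad)[names(lad) == "24"]
  st <- drift_state(drift_model("column_trim", 1.5))
  pg <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  cal <- fit_rtl_calibration(
    data.frame(pressure = pg, rt = instrument_rt(rep(u24, 5), pg, st)),
    lock_target = 32.972)
  sol <- solve_lock_pressure(cal,
                             measure = function(p) instrument_rt(u24, p, st))
  expect_lt(abs(instrument_rt(u24, as.numeric(sol), st) - 32.972), 0.005)

  # a target outside the calibrated envelope is an extrapolation error
  far <- fit_rtl_calibration(
    data.frame(pressure = pg, rt = instrument_rt(rep(u24, 5), pg, st)),
    lock_target = 45)
  expect_error(solve_lock_pressure(far), "outside the calibrated")
})

test_that("calibration files round-trip through the documented TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  p <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  utils::write.table(data.frame(pressure_rel = p, rt_min = 5 + 28.5 / p), f,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cal <- read_rtl_calibration(f, lock_target = 33.5)
  expect_s3_class(cal, "rtl_calibration")
  expect_equal(cal$lock_target, 33.5)
})
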