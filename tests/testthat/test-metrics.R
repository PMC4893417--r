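test_that("trapezoidal AUC matches hand values and a dense-grid oracle", {
  expect_equal(trapezoid_auc(c(0, 2), c(0, 4)), 4)
  expect_equal(trapezoid_auc(c(0, 12, 24), c(5, 5, 5), normalize = TRUE), 5)
  ## random piecewise-linear signal vs independent Riemann-sum oracle
  set.seed(51)
  t <- sort(runif(50, 0, 48))
  v <- rnorm(50, 10, 4)
  expect_equal(trapezoid_auc(t, v), dense_grid_auc(t, v), tolerance = 1e-4)
  ## window clipping interpolates at the edges
  expect_equal(trapezoid_auc(c(0, 10), c(0, 10), window = c(2, 8)), 30)
  expect_error(trapezoid_auc(5, 1), "at least 2")
  expect_error(trapezoid_auc(c(2, 1), c(0, 1)), "increasing")
})

test_that("AUC operators are linear and collinear-sample invariant", {
  set.seed(52)
  t <- sort(runif(20, 0, 24))
  v1 <- rnorm(20); v2 <- rnorm(20)
  expect_equal(trapezoid_auc(t, 2 * v1 + 3 * v2),
               2 * trapezoid_auc(t, v1) + 3 * trapezoid_auc(t, v2))
  ## inserting a redundant collinear sample changes nothing
  tm <- (t[5] + t[6]) / 2
  vm <- approx(t, v1, tm)$y
  t2 <- append(t, tm, after = 5); v2b <- append(v1, vm, after = 5)
  expect_equal(trapezoid_auc(t2, v2b), trapezoid_auc(t, v1))
})

test_that("threshold-deficit AUC uses exact crossing points", {
  expect_equal(threshold_deficit_auc(c(0, 24), c(4, 4), 0.5), 0)
  ## crossing at t = 1: triangle with height 0.5 over 1 h
  expect_equal(threshold_deficit_auc(c(0, 2), c(1, 0), 0.5), 0.25)
  ## against the dense-grid oracle on a random signal
  set.seed(53)
  t <- sort(runif(40, 0, 24)); v <- rnorm(40, 1, 1)
  expect_equal(threshold_deficit_auc(t, v, 0.8, "below"),
               dense_grid_auc(t, v, transform = function(x) pmax(0.8 - x, 0)),
               tolerance = 1e-4)
  ## decomposition identity: below + above = integral of |v - thr|
  below <- threshold_deficit_auc(t, v, 0.8, "below")
  above <- threshold_deficit_auc(t, v, 0.8, "above")
  expect_equal(below + above,
               dense_grid_auc(t, v, transform = function(x) abs(x - 0.8)),
               tolerance = 1e-4)
  ## monotone in the threshold (direction below)
  expect_gte(threshold_deficit_auc(t, v, 1.2, "below"), below)
})

test_that("age-stratified pressure quintiles pool cohort samples", {
  ts <- data.frame(patient_id = rep(1:100, each = 1), variable = "sap",
                   time_h = 1, value = 1:100)
  ages <- setNames(rep(100, 100), 1:100)
  expect_warning(thr <- pressure_quintile_thresholds(ts, ages),
                 "empty age stratum")
  ## linear-interpolation 20th percentile of 1..100
  expect_equal(thr$threshold[thr$stratum == ">28d"], 20.8)
  expect_true(all(is.na(thr$threshold[thr$stratum != ">28d"])))
  ## identical pressures: threshold equals the constant, deficits vanish
  ts2 <- ts; ts2$value <- 42
  suppressWarnings(thr2 <- pressure_quintile_thresholds(ts2, ages))
  expect_equal(thr2$threshold[3], 42)
  expect_equal(threshold_deficit_auc(c(0, 24), c(42, 42), 42), 0)
})

test_that("creatinine variation metrics integrate the relative excess", {
  ## constant at baseline
  m0 <- delta_scr_metrics(c(0, 24), c(30, 30), baseline = 30)
  expect_equal(m0$rel_auc, 0)
  expect_equal(m0$gt50_auc, 0)
  ## doubled over 24 h: relative variation 1, excess 0.5 x 24 h
  m1 <- delta_scr_metrics(c(0, 24), c(60, 60), baseline = 30)
  expect_equal(m1$rel_auc, 1)
  expect_equal(m1$gt50_auc, 12)
  ## 1.4 x baseline never crosses the 50% line
  expect_equal(delta_scr_metrics(c(0, 24), c(42, 42), 30)$gt50_auc, 0)
  expect_error(delta_scr_metrics(c(0, 24), c(42, 42), 0), "positive")
})

test_that("vasoactive-inotropic score applies the published weights", {
  expect_equal(vis_score(), 0)
  expect_equal(vis_score(dopamine = 5, milrinone = 0.5), 10)
  expect_equal(vis_score(epinephrine = 0.05), 5)
  expect_equal(vis_score(vasopressin = 0.0005, dobutamine = 3), 8)
  expect_error(vis_score(dopamine = -1), "non-negative")
})

test_that("composite pre-operative score counts the eight conditions", {
  expect_equal(composite_preop_score(rep(FALSE, 8)), 0L)
  expect_equal(composite_preop_score(c(infection = TRUE,
                                       mechanical_ventilation = TRUE)), 2L)
  expect_equal(composite_preop_score(rep(TRUE, 8)), 8L)
  ## data frame input scores each patient
  flags <- data.frame(a = c(1, 0), b = c(1, 1), c = c(0, 0))
  expect_equal(composite_preop_score(flags), c(2L, 1L))
})

test_that("AKIN staging follows the creatinine and dialysis criteria", {
  expect_equal(akin_stage(c(0, 24), c(30, 42), baseline = 30), 0L)
  expect_equal(akin_stage(c(0, 24), c(30, 75), baseline = 30), 2L)  # 2.5x
  expect_equal(akin_stage(c(0, 24), c(30, 100), baseline = 30), 3L) # >3x
  expect_equal(akin_stage(c(0, 24), c(30, 46), baseline = 30), 1L)  # 1.53x
  ## absolute-rise criterion: +0.3 mg/dl = +26.5 umol/L at a high baseline
  expect_equal(akin_stage(c(0, 24), c(100, 128), baseline = 100), 1L)
  ## dialysis forces stage 3 regardless of creatinine
  expect_equal(akin_stage(c(0, 24), c(30, 31), baseline = 30,
                          dialysis = TRUE), 3L)
  expect_error(akin_stage(c(0, 24), c(30, 31), baseline = NA), "baseline")
  ## only samples within the staging window count
  expect_equal(akin_stage(c(24, 72), c(31, 95), baseline = 30), 0L)
})

test_that("fluid balance is net intake per kilogram", {
  expect_equal(fluid_balance(100, 100, 4), 0)
  expect_equal(fluid_balance(100, 240, 5), -28)
  expect_error(fluid_balance(100, 100, 0), "positive")
})

test_that("metrics are reproducible bit-exactly from CSV input", {
  cfg <- cohort_config(n_patients = 15, seed = 55)
  raw <- simulate_timeseries(simulate_latents(cfg), cfg)
  ts_path <- tempfile(fileext = ".csv"); st_path <- tempfile(fileext = ".csv")
  write_timeseries_csv(raw, ts_path, st_path)
  back <- read_timeseries_csv(ts_path, st_path)
  ## identical recomputation from the same CSV input
  m2 <- derive_metrics(back$timeseries, back$static)
  m3 <- derive_metrics(back$timeseries, back$static)
  expect_identical(m2, m3)
  ## and equal (to serialisation precision) to the in-memory originals
  m1 <- derive_metrics(raw$timeseries, raw$static)
  expect_equal(m1, m2, tolerance = 1e-10)
})
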