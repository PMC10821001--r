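test_that("ED is DLP times factor, with validation", {
  expect_equal(estimate_ed(500, 0.0040), 2.0)
  expect_equal(estimate_ed(0, 0.011), 0)
  expect_equal(estimate_ed(671, 0.011), 7.381)
  expect_error(estimate_ed(-1, 0.011), "non-negative")
  expect_error(estimate_ed(500, 0), "positive")
})

test_that("ED/DLP ratio inverts the product", {
  expect_equal(ed_dlp_ratio(2.0, 500), 0.0040)
  expect_equal(ed_dlp_ratio(0, 500), 0)
  expect_error(ed_dlp_ratio(1, 0), "positive")
  # round trip over random positive inputs
  set.seed(11)
  d <- runif(50, 1, 2000)
  f <- runif(50, 0.001, 0.02)
  expect_equal(ed_dlp_ratio(estimate_ed(d, f), d), f)
})

test_that("record conversion floors age and applies each method", {
  fit <- fit_kcurve(brain_anchors())
  rec <- data.frame(exam_id = "e1", age_years = 2.5, dlp_mgycm = 600)
  out <- convert_records(rec, model = fit, methods = c("curve", "simple"))
  expect_identical(out$integer_age, 2L)
  expect_equal(out$ed_simple, 600 * 0.0067)
  expect_equal(out$ed_simple, 4.02)
  expect_equal(out$ed_curve,
               600 * curve_factor(fit, 2, warn_infant = FALSE))
  # with the fitted curve this lands near 3.27 mSv
  expect_equal(out$ed_curve, 3.275, tolerance = 0.01)
})

test_that("continuous-age evaluation uses the decimal age for the curve", {
  fit <- fit_kcurve(brain_anchors())
  rec <- data.frame(exam_id = "e1", age_years = 2.5, dlp_mgycm = 600)
  out <- convert_records(rec, model = fit, continuous_age = TRUE,
                         methods = "curve")
  expect_equal(out$ed_curve,
               600 * curve_factor(fit, 2.5, warn_infant = FALSE))
})

test_that("missing device ED yields a marked absence, not an error", {
  rec <- data.frame(exam_id = c("a", "b"), age_years = c(1, 2),
                    dlp_mgycm = c(400, 500),
                    ed_device_msv = c(NA, 3.8))
  out <- convert_records(rec, methods = "device")
  expect_identical(out$ed_device, c(NA, 3.8))
  expect_equal(out$factor_device, c(NA, 3.8 / 500))
  # device column absent entirely
  out2 <- convert_records(rec[, 1:3], methods = "device")
  expect_true(all(is.na(out2$ed_device)))
})

test_that("batch conversion preserves length and order", {
  fit <- fit_kcurve(brain_anchors())
  set.seed(7)
  n <- 100
  rec <- data.frame(exam_id = sprintf("e%03d", 1:n),
                    age_years = runif(n, 0, 15),
                    dlp_mgycm = runif(n, 100, 1200))
  out <- convert_records(rec, model = fit)
  expect_equal(nrow(out), n)
  expect_identical(out$exam_id, rec$exam_id)
  expect_true(all(out$ed_curve >= 0))
  # per-record identity ed = dlp * factor for every method
  for (m in c("curve", "linear", "simple"))
    expect_equal(out[[paste0("ed_", m)]],
                 out$dlp_mgycm * out[[paste0("factor_", m)]])
})

test_that("simple method over- then under-shoots the curve at ages 2 and 3", {
  fit <- fit_kcurve(brain_anchors())
  dlp <- 600
  rec <- data.frame(exam_id = c("x", "y"), age_years = c(2, 3),
                    dlp_mgycm = dlp)
  out <- convert_records(rec, model = fit, methods = c("curve", "simple"))
  expect_gt(out$ed_simple[1], out$ed_curve[1])  # age 2: over-estimate
  expect_lt(out$ed_simple[2], out$ed_curve[2])  # age 3: under-estimate
})

test_that("dose-record reader computes ages from dates and skips bad rows", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("exam_id,birth_date,scan_date,dlp_mgycm",
               "e1,2020-01-01,2022-07-02,640",
               "e2,2021-05-01,2021-05-01,310"), path)
  rec <- read_dose_records(path)
  expect_equal(rec$age_years[1], as.numeric(as.Date("2022-07-02") -
                 as.Date("2020-01-01")) / 365.2425)
  expect_equal(rec$age_years[2], 0)

  writeLines(c("exam_id,age_years,dlp_mgycm",
               "e1,2.5,600", "e2,oops,500", "e3,7,450"), path)
  expect_warning(rec2 <- read_dose_records(path), "row 2")
  expect_identical(rec2$exam_id, c("e1", "e3"))

  writeLines(c("exam_id,age_years", "e1,2.5"), path)
  expect_error(read_dose_records(path), "dlp_mgycm")
})
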