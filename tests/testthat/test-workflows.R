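test_that("fit workflow reports constants and the integer-age factor table", {
  res <- run_fit(out = file.path(tempdir(), "factors.csv"))
  expect_s3_class(res$fit, "kcurve")
  expect_equal(nrow(res$table), 15)
  tab <- utils::read.csv(file.path(tempdir(), "factors.csv"))
  expect_equal(tab$curve, res$table$curve)
  out <- capture.output(run_fit())
  expect_true(any(grepl("a = 0.00", out)))
  expect_true(any(grepl("rel_linear", out)))
})

test_that("anchor and phantom-bin tables round-trip through JSON configs", {
  apath <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(region = "brain",
         anchors = data.frame(age = c(0, 1, 5, 10),
                              factor = c(0.011, 0.0067, 0.0040, 0.0032))),
    apath, auto_unbox = TRUE, digits = NA)
  expect_equal(read_anchor_table(apath), brain_anchors())

  bpath <- tempfile(fileext = ".json")
  jsonlite::write_json(list(bins = as.data.frame(default_phantom_bins())),
                       bpath, auto_unbox = TRUE, digits = NA)
  expect_equal(read_phantom_bins(bpath), default_phantom_bins())

  # malformed anchor entry is reported by row
  jsonlite::write_json(
    list(anchors = data.frame(age = c(0, 1), factor = c("x", "0.0067"))),
    apath, auto_unbox = TRUE)
  expect_error(read_anchor_table(apath), "row 1")
})

test_that("convert workflow preserves rows and appends method columns", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("exam_id,age_years,dlp_mgycm",
               "e1,2.5,600", "e2,0.4,350", "e3,11.0,900"), path)
  out_path <- tempfile(fileext = ".csv")
  conv <- run_convert(path, out = out_path)
  expect_equal(nrow(conv), 3)
  written <- utils::read.csv(out_path)
  expect_equal(nrow(written), 3)
  expect_true(all(c("factor_curve", "ed_curve", "factor_linear",
                    "ed_linear", "factor_simple", "ed_simple")
                  %in% names(written)))
  expect_equal(written$ed_simple[1], 4.02)

  writeLines(c("exam_id,age_years", "e1,2.5"), path)
  expect_error(run_convert(path), "dlp_mgycm")
})

test_that("summarize workflow emits per-bin rows for each scheme", {
  coh <- generate_cohort(cohort_config(seed = 31))
  s_drl <- run_summarize(coh, scheme = "drl_group")
  expect_equal(sort(unique(as.character(s_drl$summary$label))),
               sort(c("0", "1-4", "5-9", "10-14")))
  expect_equal(sum(s_drl$summary$n[s_drl$summary$quantity == "dlp"]),
               nrow(coh))
  s_int <- run_summarize(coh, scheme = "integer_year")
  expect_equal(nrow(s_int$summary[s_int$summary$quantity == "dlp", ]), 15)
  expect_s3_class(s_drl$ratio_profile, "cohort_summary")

  # device channel requested without device data: warn and omit
  coh$ed_device_msv <- NULL
  expect_warning(s_no <- run_summarize(coh, scheme = "drl_group"),
                 "device")
  expect_false("ed_device" %in% s_no$summary$quantity)
})

test_that("simulate workflow writes deterministic CSV plus a manifest", {
  out1 <- tempfile(fileext = ".csv")
  out2 <- tempfile(fileext = ".csv")
  suppressMessages({
    run_simulate(cohort_config(), out = out1, seed = 12)
    run_simulate(cohort_config(), out = out2, seed = 12)
  })
  expect_identical(readLines(out1), readLines(out2))
  manifest <- jsonlite::read_json(paste0(out1, ".manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$seed, 12)
  expect_equal(manifest$n_records, 980)
  # the written cohort feeds straight back into the pipeline
  rec <- read_dose_records(out1)
  expect_equal(nrow(rec), 980)

  out3 <- tempfile(fileext = ".csv")
  suppressMessages(
    run_simulate(cohort_config(counts_per_age = rep(0L, 15)), out = out3))
  expect_equal(nrow(utils::read.csv(out3)), 0)
})

test_that("simulate-convert-summarize chain satisfies the profile invariants", {
  out <- tempfile(fileext = ".csv")
  suppressMessages(run_simulate(cohort_config(), out = out))
  res <- run_summarize(out, scheme = "integer_year",
                       methods = c("curve", "simple", "device"))
  s <- res$summary
  dlp <- s$median[s$quantity == "dlp"]
  edc <- s$median[s$quantity == "ed_curve"]
  expect_true(all(diff(dlp) >= 0))
  expect_true(all(diff(edc[1:10]) <= 0))
  # device ratio profile recovers the phantom-bin table within noise
  expect_equal(res$ratio_profile$mean, default_phantom_bins()$ratio,
               tolerance = 0.01)
})
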