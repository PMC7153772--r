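test_that("csv dialect round-trips samples and metadata exactly", {
  rec <- make_test_record(band = c(0.08, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, path, "csv")
  back <- read_record(path, "csv")
  expect_equal(back$signals, rec$signals, tolerance = 1e-9)
  expect_identical(back$record_id, rec$record_id)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$gestation_at_recording, rec$gestation_at_recording)
  expect_equal(back$gestation_at_delivery, rec$gestation_at_delivery)
  expect_equal(back$prefiltered_band, rec$prefiltered_band)
  # first non-comment line names the channels
  body <- readLines(path)
  expect_match(body[!grepl("^#", body)][1], "ch1,ch2,ch3", fixed = TRUE)
})

test_that("tpehg (WFDB) dialect round-trips to ADC resolution", {
  rec <- make_test_record(n = 36000)
  base <- withr::local_tempfile()
  write_record(rec, base, "tpehg", adc_gain = 1000)
  back <- read_record(paste0(base, ".hea"), "tpehg")
  expect_equal(nrow(back$signals), 36000)
  expect_equal(ncol(back$signals), 3L)
  expect_lt(max(abs(back$signals - rec$signals)), 0.5 / 1000 + 1e-12)
  expect_equal(back$gestation_at_recording, rec$gestation_at_recording)
  expect_equal(back$gestation_at_delivery, rec$gestation_at_delivery)
})

test_that("malformed or incomplete headers are rejected, not defaulted", {
  rec <- make_test_record()
  base <- withr::local_tempfile()
  write_record(rec, base, "tpehg")
  hea <- readLines(paste0(base, ".hea"))
  # strip the delivery-week comment
  writeLines(hea[!grepl("^#Gestation", hea)], paste0(base, ".hea"))
  expect_error(read_record(paste0(base, ".hea"), "tpehg"), "Gestation")
  # wrong channel count
  writeLines(sub("^(\\S+) 3 ", "\\1 2 ", hea), paste0(base, ".hea"))
  expect_error(read_record(paste0(base, ".hea"), "tpehg"), "3 channels")
})

test_that("record invariants are enforced at construction", {
  sig <- matrix(rnorm(30), 10, 3)
  expect_error(ehg_record("r", sig, 20, NA, 39), "metadata")
  expect_error(ehg_record("r", sig, 20, 30, 28), "exceed")
  expect_error(ehg_record("r", sig[0, ], 20, 25, 39), "empty")
})

test_that("group assignment follows the <26-week and <37-week boundaries", {
  mk <- function(rec_wk, del_wk) make_test_record(n = 64, rec_wk = rec_wk,
                                                  del_wk = del_wk)
  expect_equal(assign_group(mk(25, 36))$combined, "PE")
  expect_equal(assign_group(mk(26, 37))$combined, "TL")
  expect_equal(assign_group(mk(30, 36))$combined, "PL")
  expect_equal(assign_group(mk(25.9, 37))$combined, "TE")
  g <- assign_group(mk(25, 36))
  expect_equal(g$timing, "EARLY")
  expect_equal(g$outcome, "PRETERM")
})

test_that("every valid record maps to exactly one of PE/TE/PL/TL", {
  set.seed(7)
  for (i in 1:50) {
    rec_wk <- runif(1, 20, 35)
    del_wk <- rec_wk + runif(1, 0.5, 15)
    g <- assign_group(make_test_record(n = 64, rec_wk = rec_wk,
                                       del_wk = del_wk))
    expect_length(g$combined, 1)
    expect_true(g$combined %in% c("PE", "TE", "PL", "TL"))
    expect_equal(g$combined,
                 paste0(if (del_wk < 37) "P" else "T",
                        if (rec_wk < 26) "E" else "L"))
  }
})

test_that("weeks+days conversion is weeks + days/7", {
  expect_equal(weeks_days(26, 3), 26 + 3 / 7)
  expect_equal(weeks_days(30), 30)
})

test_that("manifests round-trip and validate their columns", {
  m <- data.frame(record_id = c("a", "b"), file = c("a.csv", "b.csv"),
                  gestation_at_recording = c(24, 28),
                  gestation_at_delivery = c(36, 40),
                  group = c("PE", "TL"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(m, path)
  expect_equal(read_manifest(path), m)
  bad <- m[, -2]
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_manifest(path), "missing columns")
})
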