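# Short records keep the simulation studies fast; durations and counts
# here are reduced problem sizes, not the generator defaults.

test_that("generated records honour format, metadata and determinism", {
  cfg <- cohort_config(duration_min = 2)
  r1 <- generate_record("PRETERM", "EARLY", cfg, seed = 42)
  expect_s3_class(r1, "ehg_record")
  expect_equal(dim(r1$signals), c(2 * 60 * 20, 3))
  expect_lt(r1$gestation_at_recording, 26)
  expect_lt(r1$gestation_at_delivery, 37)
  expect_equal(assign_group(r1)$combined, "PE")
  r2 <- generate_record("PRETERM", "EARLY", cfg, seed = 42)
  expect_identical(r1$signals, r2$signals)
  r3 <- generate_record("TERM", "LATE", cfg, seed = 42)
  expect_gte(r3$gestation_at_recording, 26)
  expect_gte(r3$gestation_at_delivery, 37)
  expect_equal(assign_group(r3)$combined, "TL")
  expect_error(cohort_config(ar_background = c(1.2, 0, 0, 0, 0)),
               "stationary")
})

test_that("cohorts reproduce the requested group structure on disk", {
  cfg <- cohort_config(n_preterm_early = 4, n_term_early = 6,
                       n_preterm_late = 3, n_term_late = 5,
                       duration_min = 1, seed = 3)
  dir <- withr::local_tempdir()
  out <- generate_cohort(cfg, dir)
  m <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(m), 18)
  expect_equal(unname(c(table(m$group)[c("PE", "TE", "PL", "TL")])),
               c(4, 6, 3, 5))
  expect_equal(sum(file.exists(file.path(dir, m$file))), 18)
  # regenerating with the same seed is byte-identical
  dir2 <- withr::local_tempdir()
  generate_cohort(cfg, dir2)
  for (f in c(m$file, "manifest.tsv", "ground_truth.tsv")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("the amplitude dial shifts RMS in the published direction", {
  cfg <- cohort_config(duration_min = 1, amplitude_ratio = 1.5,
                       regularity_shift = 0, seed = 6)
  rms_of <- function(class, seeds) vapply(seeds, function(s) {
    rms(preprocess_record(generate_record(class, "EARLY", cfg, seed = s),
                          trim_minutes = 0)$samples)
  }, numeric(1))
  expect_gt(median(rms_of("PRETERM", 1:50)), median(rms_of("TERM", 51:100)))
})

test_that("the regularity dial lowers sample entropy of the regular class", {
  cfg <- cohort_config(duration_min = 2, amplitude_ratio = 1, seed = 6)
  se_of <- function(class, timing, seeds) vapply(seeds, function(s) {
    sample_entropy(preprocess_record(
      generate_record(class, timing, cfg, seed = s),
      trim_minutes = 0)$samples)
  }, numeric(1))
  # early stratum: preterm is the regular class
  expect_lt(median(se_of("PRETERM", "EARLY", 1:20)),
            median(se_of("TERM", "EARLY", 21:40)))
  # late stratum: term is the regular class
  expect_gt(median(se_of("PRETERM", "LATE", 41:60)),
            median(se_of("TERM", "LATE", 61:80)))
})

test_that("a null configuration leaves the classes indistinguishable", {
  cfg0 <- cohort_config(n_preterm_early = 12, n_term_early = 12,
                        n_preterm_late = 2, n_term_late = 2,
                        amplitude_ratio = 1, regularity_shift = 0,
                        duration_min = 1)
  pvals <- vapply(1:10, function(s) {
    cfg <- cfg0; cfg$seed <- s
    vals <- sapply(1:24, function(i) {
      cls <- if (i <= 12) "PRETERM" else "TERM"
      x <- preprocess_record(
        generate_record(cls, "EARLY", cfg, seed = s * 1000 + i),
        trim_minutes = 0)$samples
      c(rms(x), sample_entropy(x))
    })
    min(mann_whitney(vals[1, 1:12], vals[1, 13:24])$p_value,
        mann_whitney(vals[2, 1:12], vals[2, 13:24])$p_value)
  }, numeric(1))
  # the smaller of two null p-values exceeds 0.05 most of the time
  expect_gte(mean(pvals > 0.05), 0.6)
})

test_that("background-only records recover the AR coefficients", {
  cfg <- cohort_config(duration_min = 10, burst_rate = 0,
                       amplitude_ratio = 1, regularity_shift = 0,
                       amplitude_cv_log = 0)
  for (s in 1:3) {
    x <- select_channel(generate_record("TERM", "EARLY", cfg, seed = s), 3)
    a <- ar_features(x, 5)
    expect_true(all(abs(a[1:5] - cfg$ar_background) <= 0.05))
  }
})

test_that("generated cohorts yield finite features end to end", {
  cfg <- cohort_config(n_preterm_early = 2, n_term_early = 2,
                       n_preterm_late = 2, n_term_late = 2,
                       duration_min = 2, seed = 4)
  ds <- generate_cohort_features(cfg, trim_minutes = 0.25)
  expect_equal(dim(ds$features), c(8, 31))
  expect_true(all(is.finite(ds$features)))
  expect_equal(unname(c(table(ds$group)[c("PE", "TE", "PL", "TL")])),
               rep(2, 4))
})
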