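# Seeded generator of TPEHG-like synthetic cohorts.
#
# Each record's analysis channel is an AR(5)-filtered Gaussian background
# plus Gaussian-windowed sinusoidal bursts (contraction-like activity in
# 0.1-0.4 Hz, inside the 0.08-4 Hz analysis band). Class structure enters
# through two interpretable dials that reproduce the direction of the two
# strongest published contrasts: an amplitude ratio (preterm RMS larger
# than term in the early stratum) and a regularity shift (a deterministic
# sinusoidal component that lowers sample entropy, given to the preterm
# class in the early stratum and to the term class in the late stratum).
# Channels 1-2 are independent noise plus the shared bursts; only channel 3
# is analysed.

#' Synthetic cohort configuration
#'
#' Defaults mirror the public database's structure: 20 Hz, 30 minutes,
#' 19 preterm / 143 term early-recording subjects and 19 / 119 late.
#'
#' @param n_preterm_early,n_term_early,n_preterm_late,n_term_late Group
#'   sizes.
#' @param fs Sampling rate, Hz.
#' @param duration_min Record duration, minutes.
#' @param burst_rate Expected contraction-like bursts per recording.
#' @param burst_freq_band Burst carrier band, Hz.
#' @param amplitude_ratio Preterm/term RMS multiplier (applied in the
#'   early stratum, where the published amplitude contrast lies).
#' @param amplitude_cv_log SD of the per-record log-normal amplitude
#'   factor: between-subject amplitude variability, sized so that class
#'   amplitude distributions overlap the way the published quartiles do.
#' @param regularity_shift Amplitude of the deterministic low-entropy
#'   component, as a multiple of the background SD; 0 disables it.
#' @param regularity_class_early,regularity_class_late Which class
#'   receives the deterministic component in each stratum.
#' @param ar_background AR(5) coefficients of the background process
#'   (must be stationary).
#' @param noise_sd Innovation SD of the background, uV.
#' @param seed Integer root seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_preterm_early = 19L, n_term_early = 143L,
                          n_preterm_late = 19L, n_term_late = 119L,
                          fs = 20, duration_min = 30,
                          burst_rate = 4,
                          burst_freq_band = c(0.1, 0.4),
                          amplitude_ratio = 1.5,
                          amplitude_cv_log = 0.35,
                          regularity_shift = 6,
                          regularity_class_early = "PRETERM",
                          regularity_class_late = "TERM",
                          ar_background = c(0.55, -0.25, 0.15, -0.08, 0.04),
                          noise_sd = 3,
                          seed = 1L) {
  stopifnot(n_preterm_early >= 2L, n_term_early >= 2L,
            n_preterm_late >= 2L, n_term_late >= 2L,
            amplitude_ratio > 0, noise_sd > 0)
  if (any(Mod(polyroot(c(1, -ar_background))) <= 1)) {
    stop("ar_background is not stationary")
  }
  structure(as.list(environment()), class = "cohort_config")
}

ar_noise <- function(n, coefs, sd, burn = 200L) {
  eps <- stats::rnorm(n + burn, sd = sd)
  x <- as.numeric(stats::filter(eps, coefs, method = "recursive"))
  x[(burn + 1L):(n + burn)]
}

burst_train <- function(n, fs, rate, band) {
  x <- numeric(n)
  n_bursts <- stats::rpois(1, rate)
  if (n_bursts == 0L) return(x)
  tt <- seq_len(n) / fs
  for (b in seq_len(n_bursts)) {
    center <- stats::runif(1, 0, n / fs)
    width <- stats::runif(1, 20, 60)                  # seconds
    f0 <- stats::runif(1, band[1], band[2])
    amp <- stats::rexp(1, 1 / 6)                      # uV
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + amp * exp(-((tt - center)^2) / (2 * width^2)) *
      sin(2 * pi * f0 * tt + phase)
  }
  x
}

#' Generate one synthetic EHG record
#'
#' @param class `"PRETERM"` or `"TERM"`.
#' @param timing `"EARLY"` (recorded before week 26) or `"LATE"`.
#' @param cfg A [cohort_config()].
#' @param seed Integer seed for this record.
#' @param record_id Identifier; derived from class/timing/seed if omitted.
#' @return An [ehg_record()] whose metadata is consistent with
#'   (class, timing).
#' @export
generate_record <- function(class = c("PRETERM", "TERM"),
                            timing = c("EARLY", "LATE"),
                            cfg = cohort_config(), seed = 1L,
                            record_id = NULL) {
  class <- match.arg(class); timing <- match.arg(timing)
  set.seed(seed)
  n <- round(cfg$fs * cfg$duration_min * 60)
  amp <- if (class == "PRETERM" && timing == "EARLY") cfg$amplitude_ratio else 1
  amp <- amp * exp(stats::rnorm(1, 0, cfg$amplitude_cv_log))
  reg_class <- if (timing == "EARLY") cfg$regularity_class_early
               else cfg$regularity_class_late
  make_channel <- function(shared_burst) {
    bg <- ar_noise(n, cfg$ar_background, cfg$noise_sd)
    bg + shared_burst
  }
  shared <- burst_train(n, cfg$fs, cfg$burst_rate, cfg$burst_freq_band)
  ch3 <- amp * (ar_noise(n, cfg$ar_background, cfg$noise_sd) + shared)
  if (class == reg_class && cfg$regularity_shift > 0) {
    # stochastic/deterministic mixture: weight w -> 1 makes the channel
    # nearly deterministic (low sample entropy), w = 0 leaves it untouched
    w <- cfg$regularity_shift / (1 + cfg$regularity_shift)
    tt <- seq_len(n) / cfg$fs
    # carrier jittered per record so the regular class is not identifiable
    # from its spectral peak alone, only from its low irregularity
    f1 <- stats::runif(1, 0.2, 0.45)
    ph <- stats::runif(2, 0, 2 * pi)
    det <- sin(2 * pi * f1 * tt + ph[1]) + 0.5 * sin(pi * f1 * tt + ph[2])
    ch3 <- (1 - w) * ch3 + w * stats::sd(ch3) * sqrt(2) * det
  }
  ch1 <- make_channel(shared)
  ch2 <- make_channel(shared)
  gr <- if (timing == "EARLY") stats::runif(1, 22, 25.9)
        else stats::runif(1, 26, 33)
  gd <- if (class == "PRETERM") stats::runif(1, max(gr + 0.5, 29), 36.9)
        else stats::runif(1, 37, 42)
  gd <- max(gd, gr + 0.1)
  if (is.null(record_id)) {
    record_id <- sprintf("syn_%s_%s_%d", tolower(class), tolower(timing), seed)
  }
  ehg_record(record_id,
             cbind(ch1 = ch1, ch2 = ch2, ch3 = ch3),
             fs = cfg$fs,
             gestation_at_recording = gr,
             gestation_at_delivery = gd,
             prefiltered_band = c(0.08, 4))
}

#' Generate and write a synthetic cohort
#'
#' Writes one record file per subject plus a tab-separated cohort manifest
#' (`manifest.tsv`) and a ground-truth table (`ground_truth.tsv`) into
#' `out_dir`. Per-record seeds are derived deterministically from
#' `cfg$seed`, so the same configuration reproduces the cohort exactly.
#'
#' @param cfg A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @param dialect Record dialect for [write_record()].
#' @return Invisibly, a list with `manifest` (data frame) and
#'   `ground_truth`.
#' @export
generate_cohort <- function(cfg = cohort_config(), out_dir,
                            dialect = c("csv", "tpehg")) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plan <- rbind(
    data.frame(class = "PRETERM", timing = "EARLY",
               i = seq_len(cfg$n_preterm_early)),
    data.frame(class = "TERM", timing = "EARLY",
               i = seq_len(cfg$n_term_early)),
    data.frame(class = "PRETERM", timing = "LATE",
               i = seq_len(cfg$n_preterm_late)),
    data.frame(class = "TERM", timing = "LATE",
               i = seq_len(cfg$n_term_late)))
  n <- nrow(plan)
  manifest <- data.frame(record_id = character(n), file = character(n),
                         gestation_at_recording = numeric(n),
                         gestation_at_delivery = numeric(n),
                         group = character(n))
  truth <- data.frame(record_id = character(n), class = plan$class,
                      timing = plan$timing, seed = integer(n))
  for (r in seq_len(n)) {
    rec_seed <- cfg$seed * 10000L + r
    rid <- sprintf("syn%03d", r)
    rec <- generate_record(plan$class[r], plan$timing[r], cfg,
                           seed = rec_seed, record_id = rid)
    ext <- if (dialect == "csv") ".csv" else ".hea"
    fn <- paste0(rid, ext)
    write_record(rec, file.path(out_dir, fn), dialect)
    g <- assign_group(rec)
    manifest[r, ] <- list(rid, fn, rec$gestation_at_recording,
                          rec$gestation_at_delivery, g$combined)
    truth$record_id[r] <- rid
    truth$seed[r] <- rec_seed
  }
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, ground_truth = truth))
}

#' Generate a cohort's feature dataset in memory
#'
#' Convenience wrapper equivalent to [generate_cohort()] followed by
#' [extract_cohort()], but without touching the filesystem: each record is
#' generated, preprocessed and reduced to its 31 features directly.
#'
#' @param cfg A [cohort_config()].
#' @param feature_cfg A [feature_config()].
#' @param trim_minutes Transient trim passed to [preprocess_record()].
#' @return A [labeled_dataset()].
#' @export
generate_cohort_features <- function(cfg = cohort_config(),
                                     feature_cfg = feature_config(),
                                     trim_minutes = 5) {
  plan <- rbind(
    data.frame(class = "PRETERM", timing = "EARLY",
               i = seq_len(cfg$n_preterm_early)),
    data.frame(class = "TERM", timing = "EARLY",
               i = seq_len(cfg$n_term_early)),
    data.frame(class = "PRETERM", timing = "LATE",
               i = seq_len(cfg$n_preterm_late)),
    data.frame(class = "TERM", timing = "LATE",
               i = seq_len(cfg$n_term_late)))
  n <- nrow(plan)
  feats <- matrix(NA_real_, n, length(EHG_FEATURE_NAMES),
                  dimnames = list(NULL, EHG_FEATURE_NAMES))
  group <- character(n); rid <- character(n)
  for (r in seq_len(n)) {
    rec <- generate_record(plan$class[r], plan$timing[r], cfg,
                           seed = cfg$seed * 10000L + r,
                           record_id = sprintf("syn%03d", r))
    sig <- preprocess_record(rec, trim_minutes = trim_minutes)
    feats[r, ] <- extract_all(sig, feature_cfg)
    group[r] <- assign_group(rec)$combined
    rid[r] <- rec$record_id
  }
  labeled_dataset(feats, group, rid)
}
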