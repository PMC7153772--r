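# Record containers and on-disk dialects.
#
# Two dialects are supported: "tpehg" (a WFDB .hea/.dat pair, format 16,
# gestational metadata in header comment lines, as distributed by the public
# term-preterm EHG database) and "csv" (a '#key=value' metadata block then
# one microvolt column per channel; time is implicit from fs).

#' Construct an EHG record
#'
#' An `ehg_record` holds one subject's three bipolar abdominal channels
#' (microvolts) together with the gestational metadata needed for grouping:
#' gestational age at recording and at delivery, in (possibly fractional)
#' weeks. Channel 1 = E2-E1, channel 2 = E2-E3, channel 3 = E4-E3.
#'
#' @param record_id Character scalar identifying the subject/recording.
#' @param signals Numeric matrix, one column per channel, samples in uV.
#' @param fs Sampling rate in Hz (the database standard is 20 Hz).
#' @param gestation_at_recording Gestational age at recording, weeks.
#' @param gestation_at_delivery Gestational age at delivery, weeks.
#' @param prefiltered_band Optional length-2 numeric `(low_hz, high_hz)` if
#'   the stored signals are already band-pass filtered.
#' @return An object of class `ehg_record`.
#' @export
ehg_record <- function(record_id, signals, fs,
                       gestation_at_recording, gestation_at_delivery,
                       prefiltered_band = NULL) {
  signals <- as.matrix(signals)
  if (!is.numeric(signals) || anyNA(signals)) {
    stop("signals must be a numeric matrix without NA")
  }
  if (nrow(signals) < 1L) stop("record has empty signals")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (is.null(gestation_at_recording) || is.null(gestation_at_delivery) ||
      is.na(gestation_at_recording) || is.na(gestation_at_delivery)) {
    stop("gestation metadata missing: both recording and delivery weeks are required")
  }
  if (gestation_at_recording > gestation_at_delivery) {
    stop("gestation_at_recording must not exceed gestation_at_delivery")
  }
  if (!is.null(prefiltered_band)) {
    prefiltered_band <- as.numeric(prefiltered_band)
    stopifnot(length(prefiltered_band) == 2L,
              prefiltered_band[1] < prefiltered_band[2])
  }
  if (is.null(colnames(signals))) {
    colnames(signals) <- paste0("ch", seq_len(ncol(signals)))
  }
  structure(
    list(record_id = as.character(record_id),
         signals = signals,
         fs = as.numeric(fs),
         gestation_at_recording = as.numeric(gestation_at_recording),
         gestation_at_delivery = as.numeric(gestation_at_delivery),
         prefiltered_band = prefiltered_band),
    class = "ehg_record"
  )
}

#' @export
print.ehg_record <- function(x, ...) {
  cat(sprintf("<ehg_record %s: %d channels x %d samples @ %g Hz, rec %.1f wk, del %.1f wk>\n",
              x$record_id, ncol(x$signals), nrow(x$signals), x$fs,
              x$gestation_at_recording, x$gestation_at_delivery))
  invisible(x)
}

#' Convert weeks + days to fractional weeks
#'
#' TPEHG headers state gestational age as weeks plus days; these are stored
#' internally as `weeks + days / 7`.
#'
#' @param weeks,days Numeric scalars.
#' @return Fractional weeks.
#' @export
weeks_days <- function(weeks, days = 0) weeks + days / 7

#' Read an EHG record
#'
#' @param path For `dialect = "csv"` the CSV file; for `dialect = "tpehg"`
#'   the `.hea` header (or the base path without extension).
#' @param dialect `"tpehg"` (WFDB header + 16-bit signal pair) or `"csv"`.
#' @return An [ehg_record()].
#' @export
read_record <- function(path, dialect = c("tpehg", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") read_record_csv(path) else read_record_wfdb(path)
}

#' Write an EHG record
#'
#' `read_record(write_record(r, ...))` reproduces the samples (exactly for
#' CSV; to the ADC quantization step `1/adc_gain` uV for the WFDB dialect)
#' and the metadata exactly.
#'
#' @param record An [ehg_record()].
#' @param path Output path. For `"tpehg"` give the base path or `.hea` path;
#'   a sibling `.dat` is written next to it.
#' @param dialect `"tpehg"` or `"csv"`.
#' @param adc_gain ADC units per microvolt for the WFDB dialect.
#' @return The path written (header path for WFDB), invisibly.
#' @export
write_record <- function(record, path, dialect = c("tpehg", "csv"),
                         adc_gain = 100) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(record, "ehg_record"))
  if (nrow(record$signals) == 0L) stop("refusing to write empty-signal record")
  if (dialect == "csv") write_record_csv(record, path)
  else write_record_wfdb(record, path, adc_gain)
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), trimws(keys))
  need <- c("record_id", "fs", "gestation_at_recording", "gestation_at_delivery")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("csv header missing metadata: ", paste(miss, collapse = ", "))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  dat <- utils::read.table(text = body, header = TRUE, sep = ",",
                           colClasses = "numeric", check.names = FALSE)
  band <- NULL
  if (!is.null(meta$prefiltered_band) && nzchar(meta$prefiltered_band)) {
    band <- as.numeric(strsplit(meta$prefiltered_band, ";")[[1]])
  }
  ehg_record(meta$record_id, as.matrix(dat), as.numeric(meta$fs),
             as.numeric(meta$gestation_at_recording),
             as.numeric(meta$gestation_at_delivery),
             prefiltered_band = band)
}

write_record_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#record_id=%s", record$record_id),
    sprintf("#fs=%.17g", record$fs),
    sprintf("#gestation_at_recording=%.17g", record$gestation_at_recording),
    sprintf("#gestation_at_delivery=%.17g", record$gestation_at_delivery),
    if (!is.null(record$prefiltered_band))
      sprintf("#prefiltered_band=%.17g;%.17g",
              record$prefiltered_band[1], record$prefiltered_band[2])
  ), con)
  writeLines(paste(colnames(record$signals), collapse = ","), con)
  txt <- apply(record$signals, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, con)
  invisible(path)
}

wfdb_paths <- function(path) {
  base <- sub("\\.(hea|dat)$", "", path)
  list(hea = paste0(base, ".hea"), dat = paste0(base, ".dat"),
       name = basename(base))
}

# WFDB format 16: little-endian int16, channels interleaved per frame,
# physical value = (adc - baseline) / gain.
read_record_wfdb <- function(path) {
  p <- wfdb_paths(path)
  if (!file.exists(p$hea)) stop("no such header: ", p$hea)
  lines <- readLines(p$hea)
  lines <- lines[nzchar(trimws(lines))]
  rec_line <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec_line) < 4L) stop("malformed WFDB record line")
  n_sig <- as.integer(rec_line[2])
  fs <- as.numeric(rec_line[3])
  n_samp <- as.integer(rec_line[4])
  if (is.na(n_sig) || is.na(fs) || is.na(n_samp)) stop("malformed WFDB record line")
  if (n_sig != 3L) stop("tpehg dialect expects exactly 3 channels, got ", n_sig)
  sig_lines <- lines[2:(1 + n_sig)]
  gains <- numeric(n_sig); baselines <- integer(n_sig); ch_names <- character(n_sig)
  for (i in seq_len(n_sig)) {
    f <- strsplit(trimws(sig_lines[i]), "\\s+")[[1]]
    if (length(f) < 3L || f[2] != "16") stop("malformed signal line (only format 16 supported)")
    gspec <- f[3]                      # gain(baseline)/units
    base_i <- 0L
    if (grepl("\\(", gspec)) {
      base_i <- as.integer(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gspec))
    }
    gains[i] <- as.numeric(sub("[(/].*$", "", gspec))
    baselines[i] <- base_i
    ch_names[i] <- if (length(f) >= 9L) f[length(f)] else paste0("ch", i)
  }
  com <- sub("^#\\s*", "", grep("^#", lines, value = TRUE))
  meta <- list()
  for (cl in com) {
    parts <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(parts) >= 2L) meta[[parts[1]]] <- parts[2]
  }
  if (is.null(meta$Gestation)) stop("header missing '#Gestation' (delivery week) comment")
  if (is.null(meta$Rectime)) stop("header missing '#Rectime' (recording week) comment")
  raw <- readBin(p$dat, "integer", n = n_sig * n_samp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_sig * n_samp) stop("signal file shorter than header declares")
  adc <- matrix(raw, ncol = n_sig, byrow = TRUE)
  phys <- sweep(sweep(adc, 2L, baselines, "-"), 2L, gains, "/")
  colnames(phys) <- ch_names
  ehg_record(p$name, phys, fs,
             gestation_at_recording = as.numeric(meta$Rectime),
             gestation_at_delivery = as.numeric(meta$Gestation))
}

write_record_wfdb <- function(record, path, adc_gain = 100) {
  p <- wfdb_paths(path)
  if (ncol(record$signals) != 3L) {
    stop("tpehg dialect expects exactly 3 channels, got ", ncol(record$signals))
  }
  adc <- round(record$signals * adc_gain)
  if (any(abs(adc) > 32767)) stop("signal exceeds 16-bit ADC range at gain ", adc_gain)
  n_samp <- nrow(adc)
  ch <- colnames(record$signals)
  hea <- c(
    sprintf("%s 3 %.17g %d", p$name, record$fs, n_samp),
    sprintf("%s.dat 16 %.17g(0)/uV 16 0 0 0 0 %s", p$name, adc_gain, ch),
    sprintf("#Rectime %.17g", record$gestation_at_recording),
    sprintf("#Gestation %.17g", record$gestation_at_delivery)
  )
  writeLines(hea, p$hea)
  writeBin(as.integer(t(adc)), p$dat, size = 2L, endian = "little")
  invisible(p$hea)
}

#' Assign the Table-style timing/outcome group label
#'
#' Timing is EARLY when the recording was made strictly before gestational
#' week 26 and LATE at or after it; outcome is PRETERM when delivery
#' occurred before 37 completed weeks and TERM at or after. The combined
#' label is the cross: PE, TE, PL, TL.
#'
#' @param record An [ehg_record()], or a list with
#'   `gestation_at_recording` / `gestation_at_delivery`.
#' @return A list with `timing`, `outcome`, `combined`.
#' @export
assign_group <- function(record) {
  gr <- record$gestation_at_recording
  gd <- record$gestation_at_delivery
  if (is.null(gr) || is.null(gd) || is.na(gr) || is.na(gd)) {
    stop("gestation metadata missing")
  }
  timing <- if (gr < 26) "EARLY" else "LATE"
  outcome <- if (gd < 37) "PRETERM" else "TERM"
  combined <- paste0(substr(outcome, 1, 1), substr(timing, 1, 1))
  list(timing = timing, outcome = outcome, combined = combined)
}

#' Read or write a cohort manifest
#'
#' The manifest is a tab-separated table with columns `record_id`, `file`,
#' `gestation_at_recording`, `gestation_at_delivery`, `group`; `file` is
#' relative to the manifest's directory.
#'
#' @param path Manifest path.
#' @return `read_manifest`: a data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  m <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("record_id", "file", "gestation_at_recording",
            "gestation_at_delivery", "group")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  m
}

#' @rdname read_manifest
#' @param manifest Data frame as above.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
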