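# Assembly of the full 31-feature vector.

windowed_mean <- function(x, w, f) {
  nwin <- length(x) %/% w
  if (nwin < 1L) stop("window longer than signal")
  mean(vapply(seq_len(nwin), function(i) f(x[((i - 1L) * w + 1L):(i * w)]),
              numeric(1)))
}

#' Extract the 31 EHG features from a trimmed analysis signal
#'
#' Deterministic given `(signal, cfg)`. A feature whose definition fails on
#' the given signal (e.g. sample entropy with no matched templates) is
#' reported as a `NaN` sentinel and listed in the `flagged` attribute; a
#' feature is never silently dropped.
#'
#' @param signal An `analysis_signal` from [preprocess_record()], or any
#'   list with `samples` and `fs`.
#' @param cfg A [feature_config()].
#' @return Named numeric vector of length 31 in the order of
#'   [ehg_feature_names()], with attribute `flagged` naming sentinel
#'   entries (possibly empty).
#' @export
extract_all <- function(signal, cfg = feature_config()) {
  x <- signal$samples
  fs <- signal$fs
  v <- stats::setNames(rep(NA_real_, length(EHG_FEATURE_NAMES)),
                       EHG_FEATURE_NAMES)
  flagged <- character(0)
  put <- function(names, expr) {
    res <- tryCatch(expr, error = function(e) {
      structure(rep(NaN, length(names)), flagged = TRUE)
    })
    if (isTRUE(attr(res, "flagged"))) flagged <<- c(flagged, names)
    v[names] <<- as.numeric(res)
  }

  w <- cfg$window_samples
  if (is.null(w)) {
    put("RMS", rms(x))
    put(c("PF", "MDF", "MNF"), spectral_features(x, fs))
  } else {
    put("RMS", windowed_mean(x, w, rms))
    put(c("PF", "MDF", "MNF"), {
      nwin <- length(x) %/% w
      rowMeans(vapply(seq_len(nwin), function(i)
        spectral_features(x[((i - 1L) * w + 1L):(i * w)], fs), numeric(3)))
    })
  }
  put("tau_Rxx", autocorr_zero_crossing(x, fs))
  put(c(paste0("SE", 2:5), paste0("SM", 2:5), paste0("SS", 2:5),
        paste0("SV", 2:5)),
      wavelet_features(x, cfg$detail_levels, cfg$hankel_rows))
  put(c(paste0("a", seq_len(cfg$ar_order)), "e"),
      ar_features(x, cfg$ar_order))
  put("Tr", time_reversibility(x, cfg$tr_tau))
  put("LE", lyapunov_exponent(x, cfg))
  put("SampEn", sample_entropy(x, cfg$sampen_m, cfg$sampen_r_factor))
  put("CorrDim", correlation_dimension(x, cfg))

  structure(v, flagged = unique(flagged))
}

#' Extract features for every record in a manifest
#'
#' @param manifest Data frame from [read_manifest()] (column `file`
#'   resolved relative to `dir`).
#' @param dir Directory containing the record files.
#' @param dialect Record dialect passed to [read_record()].
#' @param cfg A [feature_config()].
#' @param channel,band,trim_minutes,force_filter Passed to
#'   [preprocess_record()].
#' @return A `labeled_dataset`: list with `features` (matrix, rows =
#'   records, 31 columns), `outcome` (factor TERM/PRETERM), `timing`
#'   (factor EARLY/LATE), `group` (PE/TE/PL/TL), `record_id`.
#' @export
extract_cohort <- function(manifest, dir, dialect = "csv",
                           cfg = feature_config(), channel = 3L,
                           band = c(0.08, 4), trim_minutes = 5,
                           force_filter = FALSE) {
  n <- nrow(manifest)
  feats <- matrix(NA_real_, n, length(EHG_FEATURE_NAMES),
                  dimnames = list(manifest$record_id, EHG_FEATURE_NAMES))
  group <- character(n)
  for (i in seq_len(n)) {
    rec <- read_record(file.path(dir, manifest$file[i]), dialect)
    sig <- preprocess_record(rec, channel, band, trim_minutes, force_filter)
    feats[i, ] <- extract_all(sig, cfg)
    group[i] <- assign_group(rec)$combined
  }
  labeled_dataset(feats, group, manifest$record_id)
}

#' Construct a labeled feature dataset
#'
#' @param features Numeric matrix, one row per record.
#' @param group Character vector of PE/TE/PL/TL labels.
#' @param record_id Optional record identifiers.
#' @return A `labeled_dataset` list with derived `outcome` and `timing`
#'   factors.
#' @export
labeled_dataset <- function(features, group, record_id = NULL) {
  features <- as.matrix(features)
  group <- as.character(group)
  stopifnot(nrow(features) == length(group),
            all(group %in% c("PE", "TE", "PL", "TL")))
  outcome <- factor(ifelse(substr(group, 1, 1) == "P", "PRETERM", "TERM"),
                    levels = c("TERM", "PRETERM"))
  timing <- factor(ifelse(substr(group, 2, 2) == "E", "EARLY", "LATE"),
                   levels = c("EARLY", "LATE"))
  if (is.null(record_id)) record_id <- paste0("rec", seq_len(nrow(features)))
  structure(list(features = features, group = group, outcome = outcome,
                 timing = timing, record_id = as.character(record_id)),
            class = "labeled_dataset")
}

#' Subset a labeled dataset to one timing contrast
#'
#' @param data A [labeled_dataset()].
#' @param contrast `"early"` (PE vs TE) or `"late"` (PL vs TL).
#' @return A [labeled_dataset()] restricted to the contrast's records.
#' @export
subset_contrast <- function(data, contrast = c("early", "late")) {
  contrast <- match.arg(contrast)
  keep <- data$timing == c(early = "EARLY", late = "LATE")[[contrast]]
  labeled_dataset(data$features[keep, , drop = FALSE], data$group[keep],
                  data$record_id[keep])
}

#' Write a feature table
#'
#' @param data A [labeled_dataset()].
#' @param path Output path; `.json` writes JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  df <- data.frame(record_id = data$record_id, group = data$group,
                   data$features, check.names = FALSE)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
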