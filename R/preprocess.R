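# Channel selection, band-pass verification/filtering, transient trimming.
#
# The public database distributes signals already band-passed to 0.08-4 Hz;
# by default a record whose prefiltered_band covers the requested band is
# passed through untouched, and force_filter = TRUE applies the filter to
# raw inputs. Filtering is zero-phase (forward-backward Butterworth) so the
# trim boundaries are not shifted in time.

#' Select one channel of an EHG record
#'
#' Channel 3 (electrode pair E4-E3, the lower electrodes) is the analysis
#' default: it is the channel reported most discriminative for term/preterm
#' classification.
#'
#' @param record An [ehg_record()].
#' @param channel Integer 1..3.
#' @return Numeric vector of samples (uV), unmodified.
#' @export
select_channel <- function(record, channel = 3L) {
  stopifnot(inherits(record, "ehg_record"))
  channel <- as.integer(channel)
  if (channel < 1L || channel > ncol(record$signals)) {
    stop("channel out of range: ", channel)
  }
  record$signals[, channel]
}

#' Zero-phase 0.08-4 Hz band-pass filter
#'
#' Cascade of 4th-order Butterworth high-pass (at `low`) and low-pass (at
#' `high`) sections, each applied forward-backward (`signal::filtfilt`), so
#' the net filter is zero-phase with doubled stopband attenuation.
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges, Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth section order.
#' @return Filtered vector, same length.
#' @export
bandpass <- function(samples, fs, low = 0.08, high = 4, order = 4L) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band must satisfy 0 < low < high < fs/2")
  }
  hp <- signal::butter(order, low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, samples)
  signal::filtfilt(lp, y)
}

#' Trim filter transients from both ends
#'
#' Removes exactly `round(trim_minutes * 60 * fs)` samples from each end;
#' the default 5 minutes turns a 30-min, 20 Hz record (36,000 samples) into
#' the 24,000-sample analysis segment.
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param trim_minutes Minutes removed from each end.
#' @return The central portion of `samples`.
#' @export
trim_transients <- function(samples, fs, trim_minutes = 5) {
  k <- round(trim_minutes * 60 * fs)
  if (k == 0L) return(samples)
  if (length(samples) <= 2 * k) {
    stop("signal too short: ", length(samples), " samples with ", k,
         " trimmed per end")
  }
  samples[(k + 1L):(length(samples) - k)]
}

#' Preprocess a record into an analysis signal
#'
#' Selects the analysis channel, ensures the 0.08-4 Hz band (trusting
#' `prefiltered_band` metadata unless `force_filter`), and trims transients.
#'
#' @param record An [ehg_record()].
#' @param channel Channel to analyse (default 3).
#' @param band Length-2 numeric band in Hz.
#' @param trim_minutes Minutes trimmed from each end (default 5).
#' @param force_filter Apply the band-pass even if metadata says the stored
#'   signal is already filtered.
#' @return An `analysis_signal`: list with `samples`, `fs`,
#'   `source_channel`, `band`.
#' @export
preprocess_record <- function(record, channel = 3L, band = c(0.08, 4),
                              trim_minutes = 5, force_filter = FALSE) {
  x <- select_channel(record, channel)
  already <- !is.null(record$prefiltered_band) &&
    record$prefiltered_band[1] <= band[1] + 1e-12 &&
    record$prefiltered_band[2] >= band[2] - 1e-12
  if (force_filter || !already) {
    x <- bandpass(x, record$fs, band[1], band[2])
  }
  x <- trim_transients(x, record$fs, trim_minutes)
  structure(
    list(samples = x, fs = record$fs, source_channel = as.integer(channel),
         band = as.numeric(band)),
    class = "analysis_signal"
  )
}
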