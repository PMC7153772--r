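# Time-, frequency-, wavelet- and AR-domain features.

#' Root mean square amplitude
#'
#' @param x Numeric vector (uV).
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) == 0L) stop("rms: empty input")
  sqrt(mean(x^2))
}

#' First zero-crossing of the autocorrelation
#'
#' Lag (seconds) at which the biased autocorrelation estimate, starting
#' from its peak at lag 0, first changes sign, with linear interpolation
#' between the bracketing integer lags. A signal whose autocorrelation
#' never crosses zero (e.g. a constant) yields the maximum-lag value with
#' attribute `flagged = TRUE`.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param max_lag Largest lag considered, samples; default `length(x) - 1`.
#' @return Seconds, possibly carrying `attr(, "flagged")`.
#' @export
autocorr_zero_crossing <- function(x, fs, max_lag = length(x) - 1L) {
  if (length(x) < 2L) stop("need at least 2 samples")
  max_lag <- min(max_lag, length(x) - 1L)
  if (stats::sd(x) == 0) {
    return(structure(max_lag / fs, flagged = TRUE))
  }
  r <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  s <- sign(r)
  idx <- which(s[-1] * s[-length(s)] < 0 | s[-1] == 0)[1]  # between lag idx-1, idx
  if (is.na(idx)) {
    return(structure(max_lag / fs, flagged = TRUE))
  }
  r0 <- r[idx]; r1 <- r[idx + 1]                # lags idx-1 and idx
  lag <- if (r1 == 0) idx else (idx - 1) + r0 / (r0 - r1)
  lag / fs
}

#' Periodogram-based spectral features
#'
#' Computes the one-sided periodogram of the mean-removed signal (plain
#' FFT, no taper, resolution `fs/N`) and returns the peak frequency (lowest
#' frequency on ties), the median frequency (first frequency where the
#' cumulative power reaches half the total) and the mean (centroid)
#' frequency. An all-zero/constant signal has no defined spectrum and
#' yields `NaN`s with attribute `flagged`.
#'
#' @param x Numeric vector, length >= 16.
#' @param fs Sampling rate, Hz.
#' @return Named numeric `c(PF=, MDF=, MNF=)`.
#' @export
spectral_features <- function(x, fs) {
  n <- length(x)
  if (n < 16L) stop("need at least 16 samples for spectral features")
  x <- x - mean(x)
  if (all(x == 0)) {
    return(structure(c(PF = NaN, MDF = NaN, MNF = NaN), flagged = TRUE))
  }
  spec <- Mod(stats::fft(x))^2 / n
  nf <- floor(n / 2) + 1L
  p <- spec[seq_len(nf)]
  f <- (seq_len(nf) - 1L) * fs / n
  pf <- f[which.max(p)]                       # which.max returns first max
  cum <- cumsum(p)
  mdf <- f[which(cum >= cum[nf] / 2)[1]]
  mnf <- sum(f * p) / sum(p)
  c(PF = pf, MDF = mdf, MNF = mnf)
}

# Symlet-5 orthonormal decomposition filters (standard published values).
SYM5_DEC_LO <- c(
  0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
  0.1993975339773936, 0.7234076904024206, 0.6339789634582119,
  0.01660210576452232, -0.17532808990845047, -0.021101834024758855,
  0.019538882735286728)
SYM5_DEC_HI <- rev(SYM5_DEC_LO) * c(1, -1)  # g[n] = (-1)^n h[L-1-n], n from 0

# One periodized analysis step: circular filter + dyadic downsample.
# Orthonormal for even input length, so energy is conserved exactly.
dwt_step <- function(x, h) {
  n <- length(x)
  if (n %% 2L == 1L) x <- c(x, 0)            # zero-pad odd lengths
  n <- length(x)
  y <- numeric(n)
  idx0 <- 0:(n - 1L)
  for (m in seq_along(h)) {
    y <- y + h[m] * x[((idx0 + (m - 1L)) %% n) + 1L]
  }
  y[seq(1L, n, by = 2L)]
}

#' Periodized symlet-5 wavelet decomposition
#'
#' @param x Numeric vector.
#' @param levels Number of decomposition levels.
#' @return List with `details` (list of detail-coefficient vectors, level 1
#'   = finest) and `approx` (final approximation coefficients).
#' @export
dwt_sym5 <- function(x, levels = 6L) {
  if (length(x) < 2^levels) stop("signal too short for ", levels, " levels")
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    details[[l]] <- dwt_step(a, SYM5_DEC_HI)
    a <- dwt_step(a, SYM5_DEC_LO)
  }
  list(details = details, approx = a)
}

hankel_top_sv <- function(v, nrow_h = 20L) {
  n <- length(v)
  nrow_h <- min(nrow_h, n)
  ncol_h <- n - nrow_h + 1L
  H <- matrix(0, nrow_h, ncol_h)
  for (i in seq_len(nrow_h)) H[i, ] <- v[i:(i + ncol_h - 1L)]
  svd(H, nu = 0, nv = 0)$d[1]
}

#' Wavelet-subband statistics (16 features)
#'
#' Decomposes the signal with a 6-level periodized symlet-5 DWT and, for
#' detail levels 3, 4, 5, 6 (reported as subbands W2, W3, W4, W5), computes
#' the subband energy SE (sum of squared coefficients), maximum SM (largest
#' absolute coefficient), singular value SS (largest singular value of the
#' coefficients arranged as a 20-row Hankel matrix) and variance SV.
#'
#' @param x Numeric vector, length >= 64.
#' @param detail_levels Integer vector of DWT detail levels used.
#' @param hankel_rows Rows of the Hankel arrangement for SS.
#' @return Named numeric vector of 16 values (SE2..SE5, SM2..SM5,
#'   SS2..SS5, SV2..SV5).
#' @export
wavelet_features <- function(x, detail_levels = c(3L, 4L, 5L, 6L),
                             hankel_rows = 20L) {
  dec <- dwt_sym5(x, levels = max(detail_levels))
  band_ids <- seq(2L, length.out = length(detail_levels))  # W2..W5
  out <- numeric(0)
  se <- sm <- ss <- sv <- stats::setNames(numeric(length(detail_levels)),
                                          paste0("W", band_ids))
  for (i in seq_along(detail_levels)) {
    d <- dec$details[[detail_levels[i]]]
    se[i] <- sum(d^2)
    sm[i] <- max(abs(d))
    ss[i] <- hankel_top_sv(d, hankel_rows)
    sv[i] <- if (length(d) > 1L) stats::var(d) else 0
  }
  c(stats::setNames(se, paste0("SE", band_ids)),
    stats::setNames(sm, paste0("SM", band_ids)),
    stats::setNames(ss, paste0("SS", band_ids)),
    stats::setNames(sv, paste0("SV", band_ids)))
}

#' Autoregressive model features
#'
#' Fits an AR(p) model by Yule-Walker (biased autocovariances, mean
#' removed) under the convention `x_m = sum_i a_i x_(m-i) + eps_m` and
#' returns the coefficients and the innovation-variance estimate.
#'
#' @param x Numeric vector, length much larger than `p`.
#' @param p Model order (default 5).
#' @return Named numeric `c(a1..ap, e)`.
#' @export
ar_features <- function(x, p = 5L) {
  if (stats::sd(x) == 0) stop("ar_features: constant signal")
  fit <- stats::ar(x, aic = FALSE, order.max = p, method = "yule-walker",
                   demean = TRUE)
  a <- fit$ar
  c(stats::setNames(a, paste0("a", seq_len(p))), e = unname(fit$var.pred))
}

#' Time reversibility
#'
#' Third moment of lagged differences,
#' `(1/(M - tau)) * sum_(m=tau+1)^(M) (x_m - x_(m-tau))^3`: zero in
#' expectation for any time-symmetric (e.g. Gaussian linear) process, and
#' exactly antisymmetric under time reversal of the series.
#'
#' @param x Numeric vector.
#' @param tau Lag in samples (default 1).
#' @return uV^3.
#' @export
time_reversibility <- function(x, tau = 1L) {
  m <- length(x)
  if (m <= tau) stop("time_reversibility: need length > tau")
  d <- x[(tau + 1L):m] - x[1L:(m - tau)]
  sum(d^3) / (m - tau)
}
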