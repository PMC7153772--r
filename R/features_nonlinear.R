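# Nonlinear features: sample entropy, correlation dimension, largest
# Lyapunov exponent. Pair counting is done in compiled code; the testthat
# suite checks the counts against plain-R brute-force oracles.

#' Feature-extraction configuration
#'
#' Collects every tunable of [extract_all()] with the analysis defaults:
#' full-record computation, AR order 5, sample-entropy `m = 2`,
#' `r = 0.1 * SD`, time-reversibility lag 1 sample, symlet-5 details
#' 3--6, scalar (dimension-1) correlation-dimension embedding with the
#' scaling region between the 0.05 and 0.5 pairwise-distance quantiles,
#' and a (2, 1) delay embedding for the Lyapunov estimator.
#'
#' @param window_samples Optional window length; when set, RMS and the
#'   spectral features are computed per non-overlapping window and
#'   averaged (the short-window mode); all other features always use the
#'   full signal.
#' @param ar_order AR model order.
#' @param sampen_m,sampen_r_factor Sample-entropy template length and
#'   tolerance as a fraction of the signal SD (must lie in \[0.1, 0.25\]).
#' @param tr_tau Time-reversibility lag, samples.
#' @param detail_levels DWT detail levels mapped to subbands W2..W5.
#' @param hankel_rows Rows of the Hankel matrix behind the SS features.
#' @param corrdim_embed_dim,corrdim_delay Correlation-dimension embedding.
#' @param corrdim_fit_quantiles Pairwise-distance quantiles bounding the
#'   scaling region.
#' @param corrdim_n_t Number of log-spaced thresholds in the scaling region.
#' @param corrdim_drop_last Drop the last point (use `M - 1` points) as in
#'   the published pair loop.
#' @param le_embed `c(dim, delay)` for the Lyapunov delay embedding.
#' @param le_exclude Temporal exclusion window (samples) for neighbour
#'   search.
#' @param le_fit_k Divergence steps used in the slope fit.
#' @param le_ref_max Cap on the number of (evenly strided) reference
#'   points whose neighbours are tracked; neighbours are always searched
#'   over every embedded point.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(window_samples = NULL,
                           ar_order = 5L,
                           sampen_m = 2L,
                           sampen_r_factor = 0.1,
                           tr_tau = 1L,
                           detail_levels = c(3L, 4L, 5L, 6L),
                           hankel_rows = 20L,
                           corrdim_embed_dim = 1L,
                           corrdim_delay = 1L,
                           corrdim_fit_quantiles = c(0.05, 0.5),
                           corrdim_n_t = 16L,
                           corrdim_drop_last = TRUE,
                           le_embed = c(2L, 1L),
                           le_exclude = 10L,
                           le_fit_k = 1:8,
                           le_ref_max = 2000L) {
  if (sampen_r_factor < 0.1 - 1e-12 || sampen_r_factor > 0.25 + 1e-12) {
    stop("sampen_r_factor must lie in [0.1, 0.25]")
  }
  stopifnot(ar_order >= 1L, sampen_m >= 1L, corrdim_embed_dim >= 1L)
  structure(as.list(environment()), class = "feature_config")
}

#' Sample entropy
#'
#' `-log(A/B)` where `B` counts template pairs of length `m` within
#' Chebyshev distance `r = r_factor * SD(x)` (self-matches excluded) and
#' `A` the same pairs still matching at length `m + 1`. A perfectly
#' regular series has `A = B` and entropy 0; if either count is zero the
#' value is undefined and a flagged sentinel (`NaN`) is returned.
#'
#' @param x Numeric vector, length > `m + 1`, non-constant.
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a fraction of `sd(x)`.
#' @return Dimensionless entropy; `NaN` with `attr(, "flagged")` when no
#'   matched pairs exist.
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.1) {
  if (length(x) <= m + 1L) stop("sample_entropy: series too short")
  s <- stats::sd(x)
  if (s == 0) stop("sample_entropy: constant signal")
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), r_factor * s)
  if (cnt[["A"]] == 0 || cnt[["B"]] == 0) {
    return(structure(NaN, flagged = TRUE))
  }
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Correlation sum
#'
#' Fraction of ordered point pairs (self-pairs excluded) whose distance is
#' at most `t`: `C(t) = 2 * #\{i<j : d_ij <= t\} / M_C^2`, with Chebyshev
#' distance on a delay embedding (plain absolute difference for the
#' default scalar embedding).
#'
#' @param x Numeric vector (the trajectory points).
#' @param t Numeric vector of distance thresholds.
#' @param dim,delay Delay-embedding dimension and lag.
#' @return Numeric vector, `C(t)` for each threshold.
#' @export
correlation_sum <- function(x, t, dim = 1L, delay = 1L) {
  np <- length(x) - (dim - 1L) * delay
  if (np < 2L) stop("correlation_sum: too few points")
  if (dim == 1L) {
    counts <- corr_count_sorted_cpp(sort(as.numeric(x)), as.numeric(t))
  } else {
    ord <- order(t)
    counts <- numeric(length(t))
    counts[ord] <- corr_sum_counts_cpp(as.numeric(x), as.integer(dim),
                                       as.integer(delay),
                                       as.numeric(t[ord]))
  }
  2 * counts / np^2
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Least-squares slope of `log C(t)` against `log t` over a log-spaced
#' threshold grid spanning the configured pairwise-distance quantiles
#' (default the 5th to 50th percentile, the scaling region). By default
#' the pair loop runs over `M - 1` points of an `M`-sample series.
#'
#' @param x Numeric vector, length >= 100.
#' @param cfg A [feature_config()].
#' @return Dimensionless slope with attributes `n_points` (trajectory
#'   points used) and `t_grid`.
#' @export
correlation_dimension <- function(x, cfg = feature_config()) {
  if (length(x) < 100L) stop("correlation_dimension: need >= 100 samples")
  if (isTRUE(cfg$corrdim_drop_last)) x <- x[-length(x)]
  if (stats::sd(x) == 0) stop("correlation_dimension: degenerate signal")
  dim <- cfg$corrdim_embed_dim; delay <- cfg$corrdim_delay
  np <- length(x) - (dim - 1L) * delay
  # place the scaling region from a strided subsample of points (the
  # quantiles of the pairwise-distance distribution are stable; the full
  # O(n^2) pass is reserved for the correlation sums themselves)
  nq <- 1500L
  xq <- if (np > nq) {
    stride <- seq(1L, np + (dim - 1L) * delay, length.out = nq + (dim - 1L) * delay)
    x[unique(round(stride))]
  } else x
  q <- pair_dist_quantiles_cpp(as.numeric(xq), as.integer(dim),
                               as.integer(delay),
                               as.numeric(cfg$corrdim_fit_quantiles), 512L)
  if (q[1] <= 0) q[1] <- q[2] / 100
  tg <- exp(seq(log(q[1]), log(q[2]), length.out = cfg$corrdim_n_t))
  ct <- correlation_sum(x, tg, dim = dim, delay = delay)
  keep <- ct > 0
  slope <- stats::coef(stats::lm(log(ct[keep]) ~ log(tg[keep])))[[2]]
  structure(slope, n_points = np, t_grid = tg)
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' Delay-embeds the series, pairs every point with its nearest neighbour
#' outside a temporal exclusion window, and regresses the mean log
#' distance between paired trajectories on the number of steps they are
#' followed; the slope is the divergence rate in nats per sample.
#'
#' @param x Numeric vector, length >= 1000.
#' @param cfg A [feature_config()].
#' @return Nats/sample.
#' @export
lyapunov_exponent <- function(x, cfg = feature_config()) {
  if (length(x) < 1000L) stop("lyapunov_exponent: need >= 1000 samples")
  dim <- as.integer(cfg$le_embed[1]); delay <- as.integer(cfg$le_embed[2])
  kmax <- max(cfg$le_fit_k)
  np <- length(x) - (dim - 1L) * delay
  stride <- max(1L, ceiling(np / cfg$le_ref_max))
  div <- lyap_divergence_cpp(as.numeric(x), dim, delay,
                             as.integer(cfg$le_exclude), as.integer(kmax),
                             as.integer(stride))
  k <- cfg$le_fit_k
  y <- div[k + 1L]
  ok <- is.finite(y)
  if (sum(ok) < 2L) return(structure(NaN, flagged = TRUE))
  stats::coef(stats::lm(y[ok] ~ k[ok]))[[2]]
}
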