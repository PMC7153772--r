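# Per-feature group summaries and Mann-Whitney U comparisons
# (PE vs TE and PL vs TL).

#' Summarize features per group
#'
#' Median and quartiles (linear-interpolation convention) of every feature
#' within each PE/TE/PL/TL group; optionally mean and SD instead.
#'
#' @param data A [labeled_dataset()].
#' @param mode `"median"` (median, 25th, 75th percentile; default) or
#'   `"mean"` (mean, mean - SD, mean + SD in the same columns).
#' @return Data frame with columns `feature`, `group`, `median`/`mean`,
#'   `q25`, `q75`, `n`.
#' @export
summarize_features <- function(data, mode = c("median", "mean")) {
  mode <- match.arg(mode)
  groups <- intersect(c("PE", "TE", "PL", "TL"), unique(data$group))
  out <- list()
  for (g in groups) {
    rows <- data$features[data$group == g, , drop = FALSE]
    if (nrow(rows) == 0L) stop("empty group: ", g)
    for (f in colnames(rows)) {
      v <- rows[, f]
      if (mode == "median") {
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
        out[[length(out) + 1L]] <- data.frame(
          feature = f, group = g, median = q[2], q25 = q[1], q75 = q[3],
          n = length(v))
      } else {
        out[[length(out) + 1L]] <- data.frame(
          feature = f, group = g, mean = mean(v), sd = stats::sd(v),
          n = length(v))
      }
    }
  }
  do.call(rbind, out)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when the smaller sample has at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections. `U` is reported for the first
#' sample (`U_a + U_b = n_a * n_b`).
#'
#' @param a,b Numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @return List with `U`, `p_value`, `significant`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, alpha = 0.05) {
  if (length(a) == 0L || length(b) == 0L) stop("mann_whitney: empty input")
  use_exact <- min(length(a), length(b)) <= 8L &&
    !any(duplicated(c(a, b)))
  wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < alpha,
       n_a = length(a), n_b = length(b))
}

#' Per-feature group comparison table
#'
#' Mann-Whitney comparison of every feature for the requested contrasts
#' (PE vs TE in the early-recording stratum, PL vs TL in the late), with
#' an optional Benjamini-Hochberg adjustment (off by default; the analysis
#' convention is per-feature alpha = 0.05 with no correction).
#'
#' @param data A [labeled_dataset()].
#' @param contrasts Any of `"PE_vs_TE"`, `"PL_vs_TL"`.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame: `feature`, `contrast`, `U`, `p_value`,
#'   `significant`.
#' @export
compare_groups <- function(data, contrasts = c("PE_vs_TE", "PL_vs_TL"),
                           alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pairs <- list(PE_vs_TE = c("PE", "TE"), PL_vs_TL = c("PL", "TL"))
  out <- list()
  for (ct in contrasts) {
    gg <- pairs[[ct]]
    ia <- data$group == gg[1]; ib <- data$group == gg[2]
    if (!any(ia) || !any(ib)) stop("contrast ", ct, " has an empty group")
    for (f in colnames(data$features)) {
      mw <- mann_whitney(data$features[ia, f], data$features[ib, f], alpha)
      out[[length(out) + 1L]] <- data.frame(
        feature = f, contrast = ct, U = mw$U, p_value = mw$p_value)
    }
  }
  res <- do.call(rbind, out)
  if (adjust == "BH") res$p_value <- stats::p.adjust(res$p_value, "BH")
  res$significant <- res$p_value < alpha
  res
}

#' Write a summary + comparison table
#'
#' One TSV shaped like the per-group feature summary (median and quartiles
#' for each group) with per-contrast significance flags appended.
#'
#' @param data A [labeled_dataset()].
#' @param path Output TSV path.
#' @param alpha Significance level.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(data, path, alpha = 0.05) {
  s <- summarize_features(data)
  wide <- stats::reshape(
    s[, c("feature", "group", "median", "q25", "q75")],
    direction = "wide", idvar = "feature", timevar = "group")
  contrasts <- c(if (all(c("PE", "TE") %in% data$group)) "PE_vs_TE",
                 if (all(c("PL", "TL") %in% data$group)) "PL_vs_TL")
  if (length(contrasts)) {
    cmp <- compare_groups(data, contrasts, alpha)
    for (ct in contrasts) {
      sub <- cmp[cmp$contrast == ct, c("feature", "p_value", "significant")]
      names(sub)[2:3] <- paste0(c("p_", "sig_"), ct)
      wide <- merge(wide, sub, by = "feature", sort = FALSE)
    }
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
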