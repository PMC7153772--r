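# End-to-end orchestration: read -> preprocess -> features -> grouping ->
# group statistics -> (per contrast) ADASYN + cross-validated random
# forest, with a provenance file so every reported number is recomputable.

#' Pipeline configuration
#'
#' @param manifest Path to a cohort manifest ([read_manifest()]).
#' @param dialect Record dialect.
#' @param channel Analysis channel (default 3).
#' @param band Analysis band, Hz.
#' @param trim_minutes Transient trim per end, minutes.
#' @param force_filter Re-apply the band-pass even to prefiltered records.
#' @param feature_cfg A [feature_config()].
#' @param adasyn_cfg An [adasyn_config()].
#' @param rf_cfg An [rf_config()].
#' @param folds Cross-validation folds.
#' @param oversample Oversampling placement (see [cross_validate()]).
#' @param contrast `"early"`, `"late"` or `"both"`.
#' @param out_dir Output directory.
#' @param seed Root seed; each stochastic stage derives its own seed from
#'   it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, dialect = "csv", channel = 3L,
                            band = c(0.08, 4), trim_minutes = 5,
                            force_filter = FALSE,
                            feature_cfg = feature_config(),
                            adasyn_cfg = adasyn_config(),
                            rf_cfg = rf_config(),
                            folds = 6L,
                            oversample = "within_fold",
                            contrast = c("both", "early", "late"),
                            out_dir = "ehg_run", seed = 1L) {
  contrast <- match.arg(contrast)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar keys map directly onto [pipeline_config()] arguments; the nested
#' blocks `features`, `adasyn`, `rf` are passed to the respective
#' constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("features", "adasyn", "rf"))]
  if (!is.null(y$features)) args$feature_cfg <- do.call(feature_config, y$features)
  if (!is.null(y$adasyn)) args$adasyn_cfg <- do.call(adasyn_config, y$adasyn)
  if (!is.null(y$rf)) args$rf_cfg <- do.call(rf_config, y$rf)
  do.call(pipeline_config, args)
}

stage_seed <- function(root, k) (as.integer(root) * 131L + k) %% .Machine$integer.max

#' Run the full pipeline
#'
#' Executes the analysis end to end and writes into `cfg$out_dir`:
#' `features.tsv` (31 features per record), `group_summary.tsv`
#' (per-group medians/quartiles with Mann-Whitney significance flags),
#' per-contrast CV reports (`cv_early*`, `cv_late*`: JSON, fold table,
#' importance table, ROC points) and `provenance.json` (configuration,
#' derived stage seeds, per-stage record counts, package version). Any
#' stage failure aborts with an error naming the stage.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `features` ([labeled_dataset()]),
#'   `summary`, `comparisons` and `cv` (named list of `cv_report`s).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- stage("manifest", read_manifest(cfg$manifest))
  counts <- list(records_in = nrow(manifest))
  data <- stage("features", extract_cohort(
    manifest, dirname(cfg$manifest), cfg$dialect, cfg$feature_cfg,
    cfg$channel, cfg$band, cfg$trim_minutes, cfg$force_filter))
  counts$records_featurized <- nrow(data$features)
  counts$groups <- as.list(table(data$group))
  stage("features_out",
        write_feature_table(data, file.path(cfg$out_dir, "features.tsv")))

  contrasts <- if (cfg$contrast == "both") c("early", "late") else cfg$contrast
  for (ct in contrasts) {
    need <- if (ct == "early") c("PE", "TE") else c("PL", "TL")
    missing_g <- setdiff(need, unique(data$group))
    if (length(missing_g)) {
      stop("pipeline stage 'grouping' failed: contrast '", ct,
           "' has empty group(s): ", paste(missing_g, collapse = ", "),
           call. = FALSE)
    }
  }
  stage("group_stats",
        write_group_table(data, file.path(cfg$out_dir, "group_summary.tsv")))
  summ <- summarize_features(data)
  cmp <- compare_groups(
    data, c("PE_vs_TE", "PL_vs_TL")[c("early", "late") %in% contrasts])

  cv <- list()
  for (k in seq_along(contrasts)) {
    ct <- contrasts[k]
    sub <- subset_contrast(data, ct)
    ad <- cfg$adasyn_cfg; ad$seed <- stage_seed(cfg$seed, 100L + k)
    rf <- cfg$rf_cfg; rf$seed <- stage_seed(cfg$seed, 200L + k)
    rep_ct <- stage(paste0("cv_", ct), cross_validate(
      sub, rf, cfg$folds, cfg$oversample, ad,
      seed = stage_seed(cfg$seed, 300L + k)))
    counts[[paste0("records_", ct)]] <- nrow(sub$features)
    counts[[paste0("adasyn_G_", ct)]] <- with(
      list(tab = table(sub$outcome)),
      round((max(tab) - min(tab)) * ad$beta))
    write_cv_report(rep_ct, file.path(cfg$out_dir, paste0("cv_", ct)))
    cv[[ct]] <- rep_ct
  }

  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  }
  prov <- list(
    package_version = as.character(utils::packageVersion("ehgforest")),
    config = strip(cfg),
    stage_seeds = list(
      adasyn = stage_seed(cfg$seed, 101L), rf = stage_seed(cfg$seed, 201L),
      cv = stage_seed(cfg$seed, 301L)),
    counts = counts)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(features = data, summary = summ, comparisons = cmp, cv = cv))
}
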