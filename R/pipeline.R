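# Stage runner tying the modules into the end-to-end pipeline:
# simulate -> build-gold -> annotate -> impute -> train -> evaluate ->
# select-threshold -> predict -> screen. Each stage reads and writes only
# the documented plain-text formats, so stages are independently runnable
# (and the CLI in inst/cli/snvpath.R is a thin flag parser over run_stage).

#' Default pipeline configuration
#'
#' All tunables of the pipeline with their catalog-scale defaults: coding
#' recurrence cutoffs (4, 2) and non-coding (3, 2); MAF cutoff 0.01;
#' 10-fold CV; target TPR 0.80 with region operating thresholds 0.55 /
#' 0.41; cohort recurrence and gene-burden minima 4 (coding) / 2
#' (non-coding); age cutoff 45; alpha 0.05. Every stochastic stage has an
#' explicit seed derived from `seed`.
#'
#' @param out_dir Directory for stage artifacts.
#' @param seed Master integer seed.
#' @param region `"coding"` or `"noncoding"`.
#' @param ... Overrides for any default field.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("snvpath_run_"), seed = 1L,
                            region = "coding", ...) {
  .assert_region(region)
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), region = region,
    f = if (region == "coding") 4L else 3L, c = 2L,
    maf_cutoff = 0.01,
    impute_iterations = 10L, impute_mode = "stochastic",
    algorithm = "svm_rbf", cv_folds = 10L, train_fraction = 2 / 3,
    target_tpr = 0.80,
    call_threshold = if (region == "coding") 0.55 else 0.41,
    recurrence_min = if (region == "coding") 4L else 2L,
    gene_min = if (region == "coding") 4L else 2L,
    age_cutoff = 45, alpha = 0.05,
    sim = list(n_variants = 2000L, n_samples = 500L,
               driver_fraction = 0.10, healthy_fraction = 0.25,
               d = 1.5, n_informative = 10L, missing_rate = 0.10,
               cohort_n = 300L, hr_young = 3, hr_old = 1)
  )
  over <- list(...)
  bad <- setdiff(names(over), c(names(cfg), names(cfg$sim)))
  if (length(bad)) {
    rlang::abort(sprintf("unknown configuration field(s): %s",
                         paste(bad, collapse = ", ")))
  }
  cfg$sim <- modifyList(cfg$sim, over[intersect(names(over),
                                                names(cfg$sim))])
  cfg <- modifyList(cfg, over[intersect(names(over), names(cfg))])
  structure(cfg, class = "pipeline_config")
}

.stage_path <- function(config, name) file.path(config$out_dir, name)

.write_manifest <- function(config, stage, outputs) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- .stage_path(config, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list()
  cfg_plain <- unclass(config)
  manifest[[stage]] <- list(
    config_hash = rlang::hash(cfg_plain),
    seed = config$seed,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs)))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(manifest_path)
}

.require_inputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    rlang::abort(sprintf("missing stage input(s): %s",
                         paste(missing, collapse = ", ")))
  }
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic catalog + frequencies + reference +
#' cohort), `build-gold`, `annotate` (feature assembly on the synthetic
#' world), `impute`, `train`, `evaluate` (held-out ROC + operating
#' threshold), `predict` (cohort calls + recurrent variants), `screen`
#' (age-stratified survival). Artifacts land in `config$out_dir` as
#' TSV/JSON; `manifest.json` accumulates config hashes, seeds and output
#' checksums per stage.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @return Named character vector of artifact paths, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "build-gold", "annotate",
                                "impute", "train", "evaluate", "predict",
                                "screen"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) .stage_path(config, name)
  outputs <- switch(stage,
    "simulate" = {
      sc <- sim_config(seed = config$seed,
                       n_variants = config$sim$n_variants,
                       n_samples = config$sim$n_samples,
                       driver_fraction = config$sim$driver_fraction,
                       healthy_fraction = config$sim$healthy_fraction,
                       region = config$region)
      sim <- simulate_catalog(sc)
      write_catalog(sim$catalog, p("catalog.tsv"))
      readr::write_tsv(sim$frequencies, p("frequencies.tsv"))
      readr::write_tsv(sim$truth, p("truth.tsv"))
      surv <- simulate_survival_cohort(n = config$sim$cohort_n,
                                       hr_young = config$sim$hr_young,
                                       hr_old = config$sim$hr_old,
                                       age_cutoff = config$age_cutoff,
                                       seed = config$seed + 7L)
      write_cohort(surv$cohort, p("cohort.tsv"))
      readr::write_tsv(tibble::tibble(patient_id = surv$carrier_ids),
                       p("cohort_carriers.tsv"))
      c(p("catalog.tsv"), p("frequencies.tsv"), p("truth.tsv"),
        p("cohort.tsv"), p("cohort_carriers.tsv"))
    },
    "build-gold" = {
      .require_inputs(c(p("catalog.tsv"), p("frequencies.tsv")))
      gs <- build_gold_standard(read_catalog(p("catalog.tsv")),
                                read_frequency_table(p("frequencies.tsv")),
                                region = config$region,
                                f = config$f, c = config$c,
                                maf_cutoff = config$maf_cutoff)
      write_gold_standard(gs, p("gold_standard.tsv"))
      c(p("gold_standard.tsv"), p("gold_standard.tsv.json"))
    },
    "annotate" = {
      .require_inputs(p("gold_standard.tsv"))
      gs <- readr::read_tsv(p("gold_standard.tsv"), show_col_types = FALSE)
      gs$chrom <- as.character(gs$chrom)
      schema <- schema_for_region(default_schema(), config$region)
      fm <- simulate_feature_matrix(gs, schema,
                                    d = config$sim$d,
                                    n_informative = config$sim$n_informative,
                                    missing_rate = config$sim$missing_rate,
                                    seed = config$seed + 13L)
      write_feature_matrix(fm, p("features.tsv"))
      readr::write_tsv(tibble::tibble(feature = attr(fm, "informative")),
                       p("informative_features.tsv"))
      c(p("features.tsv"), p("informative_features.tsv"))
    },
    "impute" = {
      .require_inputs(p("features.tsv"))
      fm <- read_feature_matrix(p("features.tsv"))
      plan <- imputation_plan(iterations = config$impute_iterations,
                              seed = config$seed + 17L,
                              mode = config$impute_mode)
      done <- mice_impute(fm, plan)
      write_feature_matrix(done, p("features_imputed.tsv"))
      rep <- attr(done, "impute_report")
      jsonlite::write_json(
        list(iterations = rep$iterations, mode = rep$mode,
             n_missing_total = sum(rep$columns$n_missing)),
        p("impute_report.json"), auto_unbox = TRUE)
      c(p("features_imputed.tsv"), p("impute_report.json"))
    },
    "train" = {
      .require_inputs(p("features_imputed.tsv"))
      fm <- read_feature_matrix(p("features_imputed.tsv"))
      y <- as.integer(fm$label == "positive")
      idx <- split_train_test(y, config$train_fraction,
                              seed = config$seed + 19L)
      model <- fit_pathogenicity_model(fm[idx$train, ],
                                       algorithm = config$algorithm,
                                       seed = config$seed + 23L)
      write_model(model, p("model.json"))
      readr::write_tsv(tibble::tibble(split = c("train", "test")[
        1L + as.integer(seq_along(y) %in% idx$test)]), p("split.tsv"))
      c(p("model.json"), p("split.tsv"))
    },
    "evaluate" = {
      .require_inputs(c(p("features_imputed.tsv"), p("model.json"),
                        p("split.tsv")))
      fm <- read_feature_matrix(p("features_imputed.tsv"))
      y <- as.integer(fm$label == "positive")
      split <- readr::read_tsv(p("split.tsv"), show_col_types = FALSE)$split
      model <- read_model(p("model.json"))
      feat <- fm[setdiff(names(fm), c(.key_cols, "region", "label"))]
      test <- split == "test"
      prob <- predict(model, feat[test, ], type = "prob")
      roc <- roc_and_auc(prob, y[test])
      op <- select_operating_threshold(roc, config$target_tpr)
      readr::write_tsv(tibble::as_tibble(roc), p("roc.tsv"))
      jsonlite::write_json(list(auc = attr(roc, "auc"),
                                operating_point = as.list(op)),
                           p("evaluation.json"), auto_unbox = TRUE,
                           digits = NA)
      c(p("roc.tsv"), p("evaluation.json"))
    },
    "predict" = {
      .require_inputs(c(p("features_imputed.tsv"), p("model.json"),
                        p("catalog.tsv")))
      fm <- read_feature_matrix(p("features_imputed.tsv"))
      model <- read_model(p("model.json"))
      preds <- predict_pathogenic(model,
                                  fm[setdiff(names(fm), c("label",
                                                          "region"))],
                                  threshold = config$call_threshold,
                                  region = config$region,
                                  catalog = read_catalog(p("catalog.tsv")))
      readr::write_tsv(tibble::as_tibble(preds), p("predictions.tsv"))
      rec <- recurrent_positive_variants(preds, config$recurrence_min)
      readr::write_tsv(rec, p("recurrent_variants.tsv"))
      c(p("predictions.tsv"), p("recurrent_variants.tsv"))
    },
    "screen" = {
      .require_inputs(c(p("cohort.tsv"), p("cohort_carriers.tsv")))
      cohort <- read_cohort(p("cohort.tsv"))
      carrier_ids <- readr::read_tsv(p("cohort_carriers.tsv"),
                                     show_col_types = FALSE)$patient_id
      carriers <- tibble::tibble(unit = "planted_unit",
                                 patient_id = carrier_ids)
      res <- age_stratified_screen(cohort, carriers,
                                   age_cutoff = config$age_cutoff,
                                   alpha = config$alpha)
      readr::write_tsv(res, p("screen.tsv"))
      p("screen.tsv")
    }
  )
  .write_manifest(config, stage, outputs)
  invisible(outputs)
}
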