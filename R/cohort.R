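# Cohort application: pathogenicity calls on cohort variants, recurrent-SNV
# and candidate-gene selection, and age-stratified Kaplan-Meier/log-rank
# survival screens at SNV and gene level.

#' Call pathogenic variants in a cohort
#'
#' Scores a cohort feature matrix with a trained model and converts
#' probabilities to binary calls at `probability >= threshold`. Default
#' thresholds are the region operating points chosen at a target TPR of
#' 0.80 on catalog-scale gold standards: 0.55 (coding) and 0.41
#' (non-coding); a stricter cutoff (e.g. 0.8) can be supplied. When
#' `catalog` is given, per-variant calls are expanded to per
#' (variant, sample) records for carrier counting.
#'
#' @param model An `snv_model`.
#' @param features Complete feature tibble with variant-key columns.
#' @param threshold Probability cutoff; `NULL` uses the region default.
#' @param region `"coding"` or `"noncoding"` (sets the default threshold).
#' @param catalog Optional variant-record tibble used to attach
#'   `sample_id`s to each called variant.
#' @return A `prediction_set` tibble: key columns, `probability`, `call`
#'   (`"positive"`/`"negative"`), plus `sample_id` when `catalog` is given;
#'   attribute `threshold` records the cutoff used.
#' @export
predict_pathogenic <- function(model, features, threshold = NULL,
                               region = c("coding", "noncoding"),
                               catalog = NULL) {
  region <- match.arg(region)
  if (is.null(threshold)) threshold <- if (region == "coding") 0.55 else 0.41
  .check_key_cols(features)
  feat_cols <- setdiff(names(features),
                       c(.key_cols, "region", "label", "sample_id"))
  prob <- predict(model, features[feat_cols], type = "prob")
  out <- dplyr::bind_cols(
    features[.key_cols],
    tibble::tibble(probability = prob,
                   call = ifelse(prob >= threshold, "positive", "negative"))
  )
  if (!is.null(catalog)) {
    out <- dplyr::inner_join(
      dplyr::distinct(catalog[c(.key_cols, "sample_id")]),
      out, by = .key_cols)
  }
  structure(out, threshold = threshold, region = region,
            class = c("prediction_set", class(out)))
}

#' Recurrent predicted-pathogenic variants
#'
#' Variants called positive in at least `min_count` distinct carriers
#' (patients), the cohort-side analogue of the recurrence rule used for
#' gold-standard positives: >=4 carriers in coding and >=2 in non-coding
#' data.
#'
#' @param predictions A `prediction_set` with `sample_id` (i.e. built with
#'   a catalog).
#' @param min_count Minimum distinct carriers (default 4, the coding rule).
#' @return Tibble of variant keys with `n_carriers`, sorted by decreasing
#'   count then key.
#' @export
recurrent_positive_variants <- function(predictions, min_count = 4L) {
  stopifnot(min_count >= 1)
  if (!"sample_id" %in% names(predictions)) {
    rlang::abort("predictions must carry sample_id (supply `catalog`)")
  }
  predictions |>
    dplyr::filter(.data$call == "positive") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(.key_cols))) |>
    dplyr::summarise(n_carriers = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop") |>
    dplyr::filter(.data$n_carriers >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$n_carriers), .data$chrom, .data$pos,
                   .data$ref, .data$alt)
}

#' Patient-by-gene mutation status
#'
#' A gene counts as mutated in a patient when the patient carries at least
#' one predicted-pathogenic SNV in that gene (binary, not a count).
#' Positive calls without a gene-map entry are logged and excluded.
#'
#' @param predictions A `prediction_set` with `sample_id`.
#' @param gene_map Tibble `chrom pos ref alt gene` mapping variants to
#'   genes.
#' @param patients Optional character vector fixing the patient universe
#'   (patients with no positive calls get all-zero rows).
#' @return A `gene_mutation_matrix`: tibble `patient_id gene mutated`
#'   (complete grid) with per-gene positive-SNV counts in attribute
#'   `gene_counts`.
#' @export
gene_mutation_matrix <- function(predictions, gene_map, patients = NULL) {
  if (!"sample_id" %in% names(predictions)) {
    rlang::abort("predictions must carry sample_id (supply `catalog`)")
  }
  pos <- dplyr::filter(predictions, .data$call == "positive")
  mapped <- dplyr::inner_join(pos, gene_map, by = .key_cols)
  n_unmapped <- nrow(dplyr::anti_join(pos, gene_map, by = .key_cols))
  if (n_unmapped > 0) {
    rlang::inform(sprintf(
      "gene_mutation_matrix: %d positive call(s) without a gene mapping excluded",
      n_unmapped))
  }
  gene_counts <- mapped |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c(.key_cols, "gene")))) |>
    dplyr::count(.data$gene, name = "n_positive_snvs")
  patients <- patients %||% sort(unique(predictions$sample_id))
  genes <- sort(unique(mapped$gene))
  carried <- dplyr::distinct(mapped, .data$sample_id, .data$gene)
  grid <- tidyr::expand_grid(patient_id = patients, gene = genes) |>
    dplyr::left_join(
      dplyr::mutate(carried, mutated = 1L),
      by = c(patient_id = "sample_id", "gene")) |>
    dplyr::mutate(mutated = dplyr::coalesce(.data$mutated, 0L))
  structure(grid, gene_counts = gene_counts, n_unmapped = n_unmapped,
            class = c("gene_mutation_matrix", class(grid)))
}

#' Candidate genes by positive-SNV burden
#'
#' Genes harboring at least `min_positive_snvs` distinct predicted
#' pathogenic SNVs - the gene-level analogue of the recurrence rule
#' (>=4 coding, >=2 non-coding).
#'
#' @param matrix A `gene_mutation_matrix`.
#' @param min_positive_snvs Minimum distinct positive SNVs (default 4).
#' @return Tibble `gene n_positive_snvs`, descending.
#' @export
select_candidate_genes <- function(matrix, min_positive_snvs = 4L) {
  stopifnot(min_positive_snvs >= 1)
  attr(matrix, "gene_counts") |>
    dplyr::filter(.data$n_positive_snvs >= min_positive_snvs) |>
    dplyr::arrange(dplyr::desc(.data$n_positive_snvs), .data$gene)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function under right censoring.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return Tibble `time n_risk n_event n_censor surv`, the step function
#'   S(t) evaluated at each observed time (S starts at 1).
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) rlang::abort("empty survival input")
  stopifnot(all(times >= 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square comparison of two survival
#' curves (hypergeometric variance at each event time, so tied event times
#' are handled exactly), 1 degree of freedom.
#'
#' @param times Follow-up times.
#' @param events 0/1 event indicators.
#' @param group Two-level group labels (carrier / non-carrier).
#' @return A `logrank_result`: list with `statistic`, `df`, `p_value`,
#'   `n` and `observed`/`expected` per group.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    rlang::abort("log-rank test needs exactly two non-empty groups")
  }
  if (sum(events) == 0) {
    rlang::abort("log-rank statistic undefined with zero events")
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  structure(list(
    statistic = unname(fit$chisq), df = 1L,
    p_value = stats::pchisq(fit$chisq, df = 1L, lower.tail = FALSE),
    n = as.integer(fit$n), observed = unname(fit$obs),
    expected = unname(fit$exp)
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chisq = %.4f on %d df, p = %.4g (n = %s)\n",
              x$statistic, x$df, x$p_value, paste(x$n, collapse = "+")))
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_result`.
#' @param ... Unused.
#' @export
tidy.logrank_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n_group1 = x$n[1L], n_group2 = x$n[2L],
                 observed1 = x$observed[1L], observed2 = x$observed[2L])
}

.stratum_logrank <- function(cohort, carrier_ids) {
  carrier <- cohort$patient_id %in% carrier_ids
  if (!any(carrier) || all(carrier) || sum(cohort$event) == 0) {
    return(list(evaluable = FALSE, statistic = NA_real_, p_value = NA_real_,
                n_carriers = sum(carrier), n_events = sum(cohort$event)))
  }
  lr <- logrank_test(cohort$time, cohort$event, carrier)
  list(evaluable = TRUE, statistic = lr$statistic, p_value = lr$p_value,
       n_carriers = sum(carrier), n_events = sum(cohort$event))
}

#' Age-stratified survival screen
#'
#' For every unit (an SNV or a gene), compares carriers against
#' non-carriers with a log-rank test separately in young (`age <
#' age_cutoff`, default 45) and old (`age >= age_cutoff`) patients, once
#' per endpoint present in the cohort table. A unit is flagged
#' *young-specific* when it is significant in the young stratum
#' (`p_young < alpha`) but not in the old (`p_old >= alpha`). Strata with
#' no carriers, no non-carriers or no events are not evaluable and are
#' never flagged. Raw p-values are used by default (matching screening at
#' alpha = 0.05 without correction); `p_adjust = "BH"` applies
#' Benjamini-Hochberg within each (endpoint, stratum).
#'
#' @param cohort Cohort tibble (`patient_id age time event endpoint`).
#' @param carriers Tibble `unit patient_id`: the patients carrying each
#'   unit.
#' @param age_cutoff Years separating young from old (default 45).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Tibble, one row per (endpoint, unit): carrier/event counts,
#'   chi-square and p per stratum, `evaluable`, `young_specific`.
#' @export
age_stratified_screen <- function(cohort, carriers, age_cutoff = 45,
                                  alpha = 0.05,
                                  p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(c("unit", "patient_id") %in% names(carriers)))
  if (any(is.na(cohort$age)) || any(is.na(cohort$time)) ||
      any(is.na(cohort$event))) {
    rlang::abort("every patient needs age, time and event")
  }
  units <- unique(carriers$unit)
  res <- purrr::map_dfr(split(cohort, cohort$endpoint), function(co) {
    young <- dplyr::filter(co, .data$age < age_cutoff)
    old <- dplyr::filter(co, .data$age >= age_cutoff)
    purrr::map_dfr(units, function(u) {
      ids <- carriers$patient_id[carriers$unit == u]
      ry <- .stratum_logrank(young, ids)
      ro <- .stratum_logrank(old, ids)
      tibble::tibble(
        endpoint = co$endpoint[1L], unit = u,
        n_young = nrow(young), n_old = nrow(old),
        n_young_carriers = ry$n_carriers, n_old_carriers = ro$n_carriers,
        chisq_young = ry$statistic, p_young = ry$p_value,
        chisq_old = ro$statistic, p_old = ro$p_value,
        evaluable = ry$evaluable & ro$evaluable
      )
    })
  })
  if (p_adjust == "BH") {
    res <- res |>
      dplyr::group_by(.data$endpoint) |>
      dplyr::mutate(p_young = stats::p.adjust(.data$p_young, "BH"),
                    p_old = stats::p.adjust(.data$p_old, "BH")) |>
      dplyr::ungroup()
  }
  dplyr::mutate(res, young_specific = .data$evaluable &
                  .data$p_young < alpha & .data$p_old >= alpha)
}

#' Kaplan-Meier comparison plot for one unit
#'
#' Carrier vs non-carrier survival curves within one age stratum - the
#' visual companion to [age_stratified_screen()].
#'
#' @param cohort Cohort tibble (one endpoint).
#' @param carrier_ids Patient ids carrying the unit.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_km_comparison <- function(cohort, carrier_ids, title = NULL) {
  carrier <- cohort$patient_id %in% carrier_ids
  dat <- dplyr::bind_rows(
    dplyr::mutate(km_curve(cohort$time[carrier], cohort$event[carrier]),
                  group = "carrier"),
    dplyr::mutate(km_curve(cohort$time[!carrier], cohort$event[!carrier]),
                  group = "non-carrier")
  )
  dat <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1,
                   group = c("carrier", "non-carrier")), dat)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$group)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL,
                  title = title)
}
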