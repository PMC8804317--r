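# Gold-standard construction: bi-dimensional recurrence labeling of
# pathogenic (positive) SNVs and the population-frequency rule for benign
# (negative) somatic SNVs.

#' Count recurrence of each variant across a catalog
#'
#' The bi-dimensional recurrence statistic behind positive labeling:
#' for every distinct variant, `frequency` is the number of *distinct
#' samples* carrying it and `cancer_type_count` the number of distinct
#' cancer types it occurs in. Counting distinct samples (rather than raw
#' rows) makes the statistic robust to duplicate catalog submissions.
#'
#' @param records Tibble of variant records (columns `chrom pos ref alt
#'   sample_id cancer_type`, e.g. from [read_catalog()]).
#' @return Tibble `chrom pos ref alt frequency cancer_type_count`, one row
#'   per distinct variant.
#' @export
count_recurrence <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          frequency = integer(),
                          cancer_type_count = integer()))
  }
  .check_key_cols(records, extra = c("sample_id", "cancer_type"))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(.key_cols))) |>
    dplyr::summarise(
      frequency = dplyr::n_distinct(.data$sample_id),
      cancer_type_count = dplyr::n_distinct(.data$cancer_type),
      .groups = "drop"
    )
}

#' Tabulate variants surviving candidate recurrence cutoffs
#'
#' Builds the grid used to pick recurrence thresholds: cell (f, c) holds the
#' number of distinct variants with `frequency >= f` and
#' `cancer_type_count >= c`. Counts are non-increasing along both axes and
#' cell (1, 1) equals the number of distinct variants.
#'
#' @param scores Recurrence tibble from [count_recurrence()].
#' @param f_max,c_max Largest cutoffs tabulated (defaults 10 and 5).
#' @return A `threshold_grid`: tibble `f c count` with the count matrix in
#'   attribute `matrix`.
#' @export
build_threshold_grid <- function(scores, f_max = 10L, c_max = 5L) {
  stopifnot(f_max >= 1L, c_max >= 1L)
  f_max <- as.integer(f_max); c_max <- as.integer(c_max)
  # joint table capped at the grid edge, then 2-D suffix sums
  f_cap <- pmin(scores$frequency, f_max)
  c_cap <- pmin(scores$cancer_type_count, c_max)
  joint <- matrix(0, f_max, c_max)
  for (i in seq_along(f_cap)) {
    joint[f_cap[i], c_cap[i]] <- joint[f_cap[i], c_cap[i]] + 1
  }
  grid <- joint
  if (f_max > 1) grid <- apply(grid, 2L, function(col) rev(cumsum(rev(col))))
  grid <- matrix(grid, f_max, c_max)
  if (c_max > 1) grid <- t(apply(grid, 1L, function(row) rev(cumsum(rev(row)))))
  grid <- matrix(grid, f_max, c_max,
                 dimnames = list(f = seq_len(f_max), c = seq_len(c_max)))
  out <- tidyr::expand_grid(f = seq_len(f_max), c = seq_len(c_max)) |>
    dplyr::mutate(count = grid[cbind(.data$f, .data$c)])
  structure(out, matrix = grid, class = c("threshold_grid", class(out)))
}

#' Select recurrence thresholds from a grid
#'
#' Formalizes "sufficient examples with minimum bias": among all cutoff
#' pairs retaining at least `min_positive_count` variants, take the largest
#' frequency cutoff `f`, breaking ties by the largest cancer-type cutoff
#' `c` - i.e. the strictest filter that still preserves the requested
#' training-set size.
#'
#' @param grid A `threshold_grid` from [build_threshold_grid()].
#' @param min_positive_count Minimum number of retained positive variants.
#' @return Named integer vector `c(f = , c = )`.
#' @export
select_recurrence_thresholds <- function(grid, min_positive_count) {
  stopifnot(min_positive_count >= 1)
  ok <- grid$count >= min_positive_count
  if (!any(ok)) {
    rlang::abort(paste0(
      "no cutoff pair retains ", min_positive_count,
      " variants; lower `min_positive_count` (grid maximum is ",
      max(grid$count), ")"
    ))
  }
  cand <- grid[ok, ]
  cand <- cand[order(-cand$f, -cand$c), ]
  c(f = cand$f[1L], c = cand$c[1L])
}

.key_id <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = "\r")

#' Label positive (pathogenic) variants
#'
#' A variant is labeled positive when it passes the bi-dimensional
#' recurrence cutoff (`frequency >= f` and `cancer_type_count >= c`) and was
#' never seen in healthy individuals: variants mutual between patients and
#' healthy carriers are excluded first.
#'
#' @param scores Recurrence tibble from [count_recurrence()].
#' @param healthy_keys Tibble of variant keys flagged "found in healthy
#'   individuals" (may have zero rows).
#' @param f,c Recurrence cutoffs; the catalog-scale defaults are (4, 2) for
#'   coding and (3, 2) for non-coding variants.
#' @return Tibble of positive variant keys.
#' @export
label_positives <- function(scores, healthy_keys, f, c) {
  stopifnot(f >= 1, c >= 1)
  hit <- scores$frequency >= f & scores$cancer_type_count >= c
  out <- scores[hit, .key_cols]
  if (!is.null(healthy_keys) && nrow(healthy_keys) > 0) {
    out <- out[!(.key_id(out) %in% .key_id(healthy_keys)), ]
  }
  tibble::as_tibble(out)
}

#' Label negative (benign somatic) variants
#'
#' A variant is labeled negative when (a) its minor allele frequency is at
#' least `maf_cutoff` (inclusive, default 1%) in at least one population of
#' the frequency table, and (b) it is also among the catalog's
#' healthy-flagged *somatic* variants - the intersection that removes
#' germline-only variants from the population-frequency mixture.
#'
#' @param healthy_somatic_keys Tibble of variant keys flagged as found in
#'   healthy individuals in the somatic catalog.
#' @param frequencies Population-frequency tibble from
#'   [read_frequency_table()].
#' @param maf_cutoff Inclusive MAF cutoff (default 0.01).
#' @return Tibble of negative variant keys.
#' @export
label_negatives <- function(healthy_somatic_keys, frequencies,
                            maf_cutoff = 0.01) {
  stopifnot(maf_cutoff > 0, maf_cutoff < 1)
  if (nrow(frequencies) == 0 || nrow(healthy_somatic_keys) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character()))
  }
  common <- frequencies |>
    dplyr::group_by(dplyr::across(dplyr::all_of(.key_cols))) |>
    dplyr::summarise(max_maf = max(.data$maf), .groups = "drop") |>
    dplyr::filter(.data$max_maf >= maf_cutoff)
  out <- common[.key_id(common) %in% .key_id(healthy_somatic_keys), .key_cols]
  tibble::as_tibble(out)
}

#' Build a labeled gold standard for one genomic region
#'
#' End-to-end labeling: restrict the catalog to one region, count
#' recurrence, label positives by the bi-dimensional cutoff (excluding
#' healthy-seen variants) and negatives by the MAF/healthy-somatic
#' intersection, and enforce disjointness (a variant qualifying for both
#' labels is dropped and counted). Cutoffs may be given directly, selected
#' from the threshold grid via `min_positive_count`, or left at the
#' region defaults (coding f=4, c=2; non-coding f=3, c=2).
#'
#' @param catalog Variant-record tibble (all regions; filtered internally).
#' @param frequencies Population-frequency tibble.
#' @param region `"coding"` or `"noncoding"`.
#' @param f,c Recurrence cutoffs; `NULL` = region default (or grid
#'   selection when `min_positive_count` is given).
#' @param maf_cutoff Inclusive MAF cutoff for negatives (default 0.01).
#' @param min_positive_count If non-`NULL`, cutoffs are chosen with
#'   [select_recurrence_thresholds()] under this size constraint.
#' @return A `gold_standard` object: tibble `chrom pos ref alt label` with
#'   attributes `region`, `cutoffs`, and `provenance` (filter counters).
#' @export
build_gold_standard <- function(catalog, frequencies,
                                region = c("coding", "noncoding"),
                                f = NULL, c = NULL, maf_cutoff = 0.01,
                                min_positive_count = NULL) {
  region <- match.arg(region)
  n_raw <- nrow(catalog)
  catalog <- dplyr::filter(catalog, .data$region == !!region)
  n_region <- nrow(catalog)

  healthy_keys <- catalog |>
    dplyr::filter(.data$healthy) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(.key_cols)))
  scores <- count_recurrence(catalog)

  if (!is.null(min_positive_count)) {
    grid <- build_threshold_grid(scores,
                                 f_max = max(scores$frequency, 1L),
                                 c_max = max(scores$cancer_type_count, 1L))
    fc <- select_recurrence_thresholds(grid, min_positive_count)
    f <- fc[["f"]]; c <- fc[["c"]]
  }
  if (is.null(f) || is.null(c)) {
    defaults <- if (region == "coding") c(4L, 2L) else c(3L, 2L)
    if (is.null(f)) f <- defaults[1L]
    if (is.null(c)) c <- defaults[2L]
  }

  pos_keys <- label_positives(scores, healthy_keys, f, c)
  neg_keys <- label_negatives(healthy_keys, frequencies, maf_cutoff)

  both <- intersect(.key_id(pos_keys), .key_id(neg_keys))
  n_conflict <- length(both)
  if (n_conflict > 0) {
    pos_keys <- pos_keys[!(.key_id(pos_keys) %in% both), ]
    neg_keys <- neg_keys[!(.key_id(neg_keys) %in% both), ]
  }
  if (nrow(pos_keys) == 0 || nrow(neg_keys) == 0) {
    rlang::abort(sprintf(
      "untrainable gold standard: %d positives, %d negatives after filtering",
      nrow(pos_keys), nrow(neg_keys)
    ))
  }
  entries <- dplyr::bind_rows(
    dplyr::mutate(pos_keys, label = "positive"),
    dplyr::mutate(neg_keys, label = "negative")
  )
  structure(
    entries,
    region = region,
    cutoffs = c(f = as.integer(f), c = as.integer(c),
                maf_cutoff = maf_cutoff),
    provenance = list(
      n_input_rows = n_raw,
      n_region_rows = n_region,
      n_distinct_variants = nrow(scores),
      n_healthy_flagged = nrow(healthy_keys),
      n_positive = sum(entries$label == "positive"),
      n_negative = sum(entries$label == "negative"),
      n_conflict_dropped = n_conflict,
      f = as.integer(f), c = as.integer(c), maf_cutoff = maf_cutoff
    ),
    class = c("gold_standard", class(entries))
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf(
    "<gold_standard> region=%s cutoffs=(f=%d, c=%d, MAF>=%.2g)\n",
    attr(x, "region"), p$f, p$c, p$maf_cutoff))
  cat(sprintf("  %d positive / %d negative (%d label conflicts dropped)\n",
              p$n_positive, p$n_negative, p$n_conflict_dropped))
  NextMethod()
}

#' @rdname build_gold_standard
#' @param x A `gold_standard` object.
#' @param ... Unused.
#' @export
tidy.gold_standard <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x)[c(.key_cols, "label")])
}

#' @rdname build_gold_standard
#' @export
glance.gold_standard <- function(x, ...) {
  p <- attr(x, "provenance")
  tibble::tibble(
    region = attr(x, "region"), f = p$f, c = p$c,
    maf_cutoff = p$maf_cutoff,
    n_positive = p$n_positive, n_negative = p$n_negative,
    n_conflict_dropped = p$n_conflict_dropped,
    n_distinct_variants = p$n_distinct_variants
  )
}

#' Write a gold standard (TSV entries + JSON provenance sidecar)
#'
#' @param gs A `gold_standard` object.
#' @param path Output TSV path; provenance goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gs, path) {
  out <- tidy(gs)
  out$region <- attr(gs, "region")
  readr::write_tsv(out[c(.key_cols, "region", "label")], path)
  jsonlite::write_json(attr(gs, "provenance"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
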