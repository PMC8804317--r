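# Genomic feature schema and per-variant feature assembly.
#
# Four feature groups describe each SNV: structural and genomic context
# (sequence attributes around the site), epigenetic (histone marks,
# methylation), genomic distance (distance to functional elements), and
# genomic conservation (evolutionary scores). A handful of context features
# are computed directly from the reference sequence and the catalog; the
# rest are consumed as pre-aggregated annotation tracks (ENCODE/CADD/VEP
# style) and are never recomputed here.

#' The default feature schema
#'
#' 65 features shared between coding and non-coding variants plus 15
#' coding-specific features (80 in total for the coding region), spread
#' over the four groups. Five shared context/distance features are computed
#' from sequence and catalog (`gc_pct_75`, `cpg_pct_75`,
#' `singleton_count_100`, `is_transition`, `min_dist_tss`); every other
#' feature is a named placeholder filled from an annotation track, so the
#' schema doubles as the contract for which tracks a run must supply.
#' The schema is an ordinary tibble: edit or subset it to define custom
#' feature sets (column order in assembled matrices follows schema order).
#'
#' @return Tibble `name group applicability value_kind source`, one row per
#'   feature definition; names are unique.
#' @examples
#' dplyr::count(default_schema(), group, applicability)
#' @export
default_schema <- function() {
  def <- function(name, group, applicability, value_kind, source) {
    tibble::tibble(name = name, group = group, applicability = applicability,
                   value_kind = value_kind, source = source)
  }
  computed <- dplyr::bind_rows(
    def("gc_pct_75", "structural_context", "shared", "continuous", "computed"),
    def("cpg_pct_75", "structural_context", "shared", "continuous", "computed"),
    def("singleton_count_100", "structural_context", "shared", "continuous",
        "computed"),
    def("is_transition", "structural_context", "shared", "binary", "computed"),
    def("min_dist_tss", "genomic_distance", "shared", "continuous", "computed")
  )

  histone_marks <- c("h3k4me1", "h3k4me2", "h3k4me3", "h3k9ac", "h3k9me3",
                     "h3k27ac", "h3k27me3", "h3k36me3", "h3k79me2", "h4k20me1")
  epigenetic <- dplyr::bind_rows(
    def(paste0(histone_marks, "_max"), "epigenetic", "shared", "continuous",
        "track"),
    def(paste0(histone_marks, "_mean"), "epigenetic", "shared", "continuous",
        "track"),
    def(c("dna_methylation_level", "dnase_hypersensitivity",
          "open_chromatin_flag", "ctcf_binding_flag", "tfbs_count",
          "chromhmm_active_flag"),
        "epigenetic", "shared",
        c("continuous", "continuous", "binary", "binary", "continuous",
          "binary"),
        "track")
  )

  context_extra <- def(
    c("repeat_masked_flag", "segmental_duplication_flag", "in_cpg_island",
      "dinucleotide_entropy", "homopolymer_run_length", "rare_variant_density",
      "mappability_score", "gc_skew_75", "bravo_allele_count",
      "trinucleotide_mutability"),
    "structural_context", "shared",
    c("binary", "binary", "binary", "continuous", "continuous", "continuous",
      "continuous", "continuous", "continuous", "continuous"),
    "track")

  distance <- def(
    c("min_dist_tes", "min_dist_splice_site", "min_dist_exon_boundary",
      "min_dist_enhancer", "min_dist_promoter", "min_dist_cpg_island",
      "min_dist_dnase_peak", "min_dist_ctcf_site", "relative_tss_position",
      "gene_density_1mb", "min_dist_utr", "min_dist_repeat"),
    "genomic_distance", "shared", "continuous", "track")

  conservation <- def(
    c("phastcons_primates", "phastcons_mammals", "phastcons_vertebrates",
      "phylop_primates", "phylop_mammals", "phylop_vertebrates",
      "gerp_rs", "gerp_n", "cadd_raw", "fitcons_score",
      "conserved_element_flag", "alignment_depth"),
    "conservation", "shared",
    c(rep("continuous", 10), "binary", "continuous"),
    "track")

  coding_only <- def(
    c("polyphen_score", "sift_score", "cadd_phred_coding", "grantham_distance",
      "blosum62_score", "aa_dist_coding_start", "codon_position",
      "synonymous_flag", "stop_gained_flag", "cds_relative_position",
      "protein_domain_flag", "exon_number", "transcript_count",
      "gerp_rs_pvalue", "missense_z_score"),
    c("structural_context", "structural_context", "conservation",
      "structural_context", "structural_context", "genomic_distance",
      "structural_context", "structural_context", "structural_context",
      "genomic_distance", "structural_context", "genomic_distance",
      "structural_context", "conservation", "conservation"),
    "coding_only",
    c("continuous", "continuous", "continuous", "continuous", "continuous",
      "continuous", "continuous", "binary", "binary", "continuous",
      "binary", "continuous", "continuous", "continuous", "continuous"),
    "track")

  schema <- dplyr::bind_rows(computed, epigenetic, context_extra, distance,
                             conservation, coding_only)
  stopifnot(!anyDuplicated(schema$name),
            sum(schema$applicability == "shared") == 65L,
            sum(schema$applicability == "coding_only") == 15L,
            dplyr::n_distinct(schema$group) == 4L)
  schema
}

#' Restrict a schema to the features applicable in a region
#' @param schema Feature schema tibble.
#' @param region `"coding"` (shared + coding-only) or `"noncoding"` (shared).
#' @return The filtered schema tibble.
#' @export
schema_for_region <- function(schema, region = c("coding", "noncoding")) {
  region <- match.arg(region)
  if (region == "coding") schema else
    dplyr::filter(schema, .data$applicability == "shared")
}

#' GC percentage of a sequence window
#'
#' `100 * (#G + #C) / (#non-N bases)`; `N`s are excluded from the
#' denominator, and an all-`N` window yields `NA` (a missing value for the
#' imputer). Vectorized over windows.
#'
#' @param window_sequence Character vector of A/C/G/T/N windows (typically
#'   the +/-75 bp window around the variant, 151 bases).
#' @return Numeric vector of percentages in \[0, 100\] (or `NA`).
#' @export
gc_percent <- function(window_sequence) {
  stopifnot(is.character(window_sequence), all(nchar(window_sequence) > 0))
  s <- toupper(window_sequence)
  if (any(grepl("[^ACGTN]", s))) {
    rlang::abort("window sequence may contain only A, C, G, T, N")
  }
  n_gc <- nchar(gsub("[^GC]", "", s))
  n_ok <- nchar(gsub("N", "", s))
  ifelse(n_ok == 0, NA_real_, 100 * n_gc / n_ok)
}

#' CpG dinucleotide percentage of a sequence window
#'
#' `100 * (#CG dinucleotides) / (window length - 1)` by an overlap-free
#' left-to-right scan - the desk-scale proxy for "percentage of CpG
#' islands" around a site. Windows shorter than 2 bases yield `NA`.
#'
#' @inheritParams gc_percent
#' @return Numeric vector of percentages in \[0, 100\] (or `NA`).
#' @export
cpg_percent <- function(window_sequence) {
  stopifnot(is.character(window_sequence))
  s <- toupper(window_sequence)
  if (any(grepl("[^ACGTN]", s))) {
    rlang::abort("window sequence may contain only A, C, G, T, N")
  }
  len <- nchar(s)
  n_cg <- vapply(s, function(x) {
    sum(gregexpr("CG", x, fixed = TRUE)[[1L]] > 0)
  }, 1, USE.NAMES = FALSE)
  ifelse(len < 2, NA_real_, 100 * n_cg / (len - 1))
}

#' Count rare singleton variants near a site
#'
#' Number of distinct catalog variants within `half_window` bases of the
#' query (same chromosome, the query itself excluded) whose maximum
#' population MAF is strictly below `maf_cutoff`. Captures the local
#' density of rare variation around a site.
#'
#' @param key One-row tibble with `chrom`, `pos` (and optionally
#'   `ref`/`alt`, used to exclude the query itself).
#' @param catalog_with_maf Tibble `chrom pos ref alt maf` - distinct catalog
#'   variants joined to their maximum population MAF (`NA` MAF counts as
#'   rare: absence from the frequency table means never seen in
#'   populations).
#' @param half_window Window half-width in bp (default 100).
#' @param maf_cutoff Strict MAF upper bound (default 0.05).
#' @return Integer count.
#' @export
singleton_neighbor_count <- function(key, catalog_with_maf,
                                     half_window = 100L, maf_cutoff = 0.05) {
  stopifnot(half_window >= 1)
  cat_keys <- dplyr::distinct(
    catalog_with_maf, dplyr::across(dplyr::all_of(c(.key_cols, "maf"))))
  near <- cat_keys$chrom == key$chrom[1L] &
    abs(cat_keys$pos - key$pos[1L]) <= half_window
  rare <- is.na(cat_keys$maf) | cat_keys$maf < maf_cutoff
  self <- .key_id(cat_keys) == .key_id(key[1L, ])
  sum(near & rare & !self)
}

#' Transition indicator of a nucleotide change
#'
#' 1 when the substitution stays within purines (\{A,G\}) or within
#' pyrimidines (\{C,T\}), 0 for a transversion. Vectorized.
#'
#' @param ref,alt Reference and alternate nucleotides (must differ).
#' @return Integer 0/1 vector.
#' @export
is_transition <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!.is_snv(ref, alt))) {
    rlang::abort("ref and alt must be distinct single nucleotides")
  }
  purine <- c("A", "G")
  as.integer((ref %in% purine) == (alt %in% purine))
}

#' Minimum distance from a position to a set of transcription start sites
#'
#' @param key One-row tibble with `chrom` and `pos`.
#' @param tss_positions Integer vector of TSS positions on the same
#'   chromosome (empty vector yields `NA`).
#' @return Distance in bp, or `NA_real_` when no TSS is supplied.
#' @export
min_distance_to_tss <- function(key, tss_positions) {
  if (length(tss_positions) == 0) return(NA_real_)
  min(abs(key$pos[1L] - tss_positions))
}

#' Define an annotation track
#'
#' A track supplies pre-aggregated values for one schema feature. Point
#' tracks (`chrom pos value`) support `value_at` and `min_distance`
#' aggregation; interval tracks (`chrom start end value`, half-open
#' \[start, end), 1-based start) support `value_at` (covering interval) and
#' `max_over_window`.
#'
#' @param name Feature name the track fills.
#' @param data Tibble of track entries.
#' @param aggregation `"value_at"`, `"min_distance"` or `"max_over_window"`.
#' @param window Half-window in bp for `max_over_window` (default 75).
#' @return An `annotation_track` list.
#' @export
annotation_track <- function(name, data,
                             aggregation = c("value_at", "min_distance",
                                             "max_over_window"),
                             window = 75L) {
  aggregation <- match.arg(aggregation)
  is_interval <- all(c("start", "end") %in% names(data))
  if (!is_interval && !"pos" %in% names(data)) {
    rlang::abort("track data needs either `pos` or `start`+`end` columns")
  }
  if (aggregation == "min_distance" && is_interval) {
    rlang::abort("min_distance aggregation requires a point track")
  }
  structure(list(name = name, data = tibble::as_tibble(data),
                 aggregation = aggregation, interval = is_interval,
                 window = as.integer(window)),
            class = "annotation_track")
}

.track_value <- function(track, chrom, pos) {
  d <- track$data[track$data$chrom == chrom, , drop = FALSE]
  if (nrow(d) == 0) return(NA_real_)
  switch(track$aggregation,
    value_at = {
      hit <- if (track$interval) {
        which(d$start <= pos & pos < d$end)
      } else which(d$pos == pos)
      if (length(hit) == 0) NA_real_ else as.numeric(d$value[hit[1L]])
    },
    min_distance = min(abs(d$pos - pos)),
    max_over_window = {
      hit <- if (track$interval) {
        d$start <= pos + track$window & d$end > pos - track$window
      } else abs(d$pos - pos) <= track$window
      if (!any(hit)) NA_real_ else max(as.numeric(d$value[hit]))
    }
  )
}

.fetch_window <- function(reference, chrom, pos, half = 75L) {
  seqs <- if (is.character(reference)) reference else
    as.character(reference) # DNAStringSet and friends
  if (!chrom %in% names(seqs)) return(NA_character_)
  s <- seqs[[chrom]]
  n <- nchar(s)
  lo <- max(1L, pos - half)
  hi <- min(n, pos + half)
  if (lo > n) return(NA_character_)
  if ((lo > pos - half || hi < pos + half)) {
    rlang::warn(sprintf(
      "window around %s:%d truncated at contig end", chrom, pos),
      .frequency = "once", .frequency_id = "snvpath_window_trunc")
  }
  substr(s, lo, hi)
}

#' Assemble a per-variant feature matrix
#'
#' One row per distinct variant, one column per schema feature applicable
#' to the region. Computed features are derived from the reference sequence
#' (+/-75 bp windows, clipped at contig ends), the catalog joined to
#' population MAFs, and the TSS list; track features are filled through
#' each track's aggregation rule. Any feature without a source stays
#' missing (`NA`) for the imputation step.
#'
#' @param variants Tibble of variant keys (`chrom pos ref alt`).
#' @param reference Named character vector (or `Biostrings::DNAStringSet`)
#'   of chromosome sequences; `NULL` leaves sequence features missing.
#' @param catalog_with_maf Tibble `chrom pos ref alt maf` for the
#'   singleton-density feature; `NULL` leaves it missing.
#' @param tss List mapping chromosome -> integer TSS positions (or `NULL`).
#' @param tracks List of [annotation_track()] objects.
#' @param schema Feature schema (default [default_schema()]).
#' @param region `"coding"` or `"noncoding"`.
#' @return Tibble: key columns followed by feature columns in schema order,
#'   with attribute `schema` (the region-restricted schema).
#' @export
assemble_features <- function(variants, reference = NULL,
                              catalog_with_maf = NULL, tss = NULL,
                              tracks = list(),
                              schema = default_schema(),
                              region = c("coding", "noncoding")) {
  region <- match.arg(region)
  .check_key_cols(variants)
  schema <- schema_for_region(schema, region)
  variants <- dplyr::distinct(
    tibble::as_tibble(variants)[.key_cols])
  n <- nrow(variants)
  track_names <- vapply(tracks, function(t) t$name, "")
  unknown <- setdiff(track_names, schema$name)
  if (length(unknown)) {
    rlang::abort(sprintf("tracks name features absent from the schema: %s",
                         paste(unknown, collapse = ", ")))
  }

  windows <- if (!is.null(reference)) {
    vapply(seq_len(n), function(i) {
      .fetch_window(reference, variants$chrom[i], variants$pos[i], 75L)
    }, "")
  } else rep(NA_character_, n)

  cols <- vector("list", nrow(schema))
  names(cols) <- schema$name
  for (j in seq_len(nrow(schema))) {
    fd <- schema[j, ]
    cols[[j]] <- if (fd$source == "computed") {
      switch(fd$name,
        gc_pct_75 = ifelse(is.na(windows), NA_real_,
                           gc_percent(ifelse(is.na(windows), "A", windows))),
        cpg_pct_75 = ifelse(is.na(windows), NA_real_,
                            cpg_percent(ifelse(is.na(windows), "AA", windows))),
        is_transition = as.numeric(is_transition(variants$ref, variants$alt)),
        singleton_count_100 = if (is.null(catalog_with_maf)) {
          rep(NA_real_, n)
        } else vapply(seq_len(n), function(i) {
          as.numeric(singleton_neighbor_count(variants[i, ], catalog_with_maf))
        }, 1),
        min_dist_tss = if (is.null(tss)) rep(NA_real_, n) else {
          vapply(seq_len(n), function(i) {
            min_distance_to_tss(variants[i, ],
                                tss[[variants$chrom[i]]] %||% integer())
          }, 1)
        },
        rep(NA_real_, n)
      )
    } else if (fd$name %in% track_names) {
      tr <- tracks[[match(fd$name, track_names)]]
      vapply(seq_len(n), function(i) {
        .track_value(tr, variants$chrom[i], variants$pos[i])
      }, 1)
    } else {
      rep(NA_real_, n)
    }
  }
  out <- dplyr::bind_cols(variants, tibble::as_tibble(cols))
  attr(out, "schema") <- schema
  out
}

#' Read/write a feature matrix TSV
#'
#' The on-disk form has the four variant-key columns first, then one column
#' per feature; missing cells are `NA`.
#'
#' @param x Feature-matrix tibble.
#' @param path File path.
#' @return `read_feature_matrix()` a tibble; `write_feature_matrix()` the
#'   path, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  tab$chrom <- as.character(tab$chrom)
  tab
}
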