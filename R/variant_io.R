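# Reading/writing somatic variant catalogs, population-frequency tables and
# clinical cohort tables, plus the "chrom:pos_ref>alt" variant-key notation
# used in database exports.

.nucs <- c("A", "C", "G", "T")

#' Parse a variant key string
#'
#' Variant identity throughout the package is the tuple
#' (chromosome, 1-based position, reference allele, alternate allele) on the
#' forward strand of GRCh38. The text form used by variant catalogs is
#' `"chrom:pos_ref>alt"`, with optional whitespace around the `>`
#' (e.g. `"14:104780214_C > T"`).
#'
#' @param text Character vector of variant-key strings.
#' @return A tibble with one row per key and columns `chrom` (character),
#'   `pos` (integer), `ref`, `alt` (single nucleotides).
#' @examples
#' parse_variant_key("17:7674220_C > T")
#' @export
parse_variant_key <- function(text) {
  stopifnot(is.character(text))
  m <- regmatches(
    text,
    regexec("^\\s*([0-9XYMT]+):([0-9]+)_([A-Za-z]+)\\s*>\\s*([A-Za-z]+)\\s*$",
            text)
  )
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    rlang::abort(sprintf(
      "malformed variant key: %s (expected \"chrom:pos_ref>alt\")",
      paste0('"', text[bad], '"', collapse = ", ")
    ))
  }
  parts <- do.call(rbind, m)
  ref <- toupper(parts[, 4L])
  alt <- toupper(parts[, 5L])
  bad_nuc <- !(ref %in% .nucs) | !(alt %in% .nucs)
  if (any(bad_nuc)) {
    rlang::abort(sprintf(
      "non-ACGT allele in variant key: %s",
      paste0('"', text[bad_nuc], '"', collapse = ", ")
    ))
  }
  same <- ref == alt
  if (any(same)) {
    rlang::abort(sprintf(
      "ref equals alt in variant key: %s",
      paste0('"', text[same], '"', collapse = ", ")
    ))
  }
  pos <- as.integer(parts[, 3L])
  if (any(pos < 1L)) rlang::abort("variant position must be >= 1")
  tibble::tibble(chrom = parts[, 2L], pos = pos, ref = ref, alt = alt)
}

#' Format variant keys back to their text form
#'
#' Inverse of [parse_variant_key()]: `parse_variant_key(format_variant_key(x))`
#' reproduces `x` for every valid key.
#'
#' @param keys A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param spaces Put spaces around `>` (the style used in published variant
#'   tables). Default `FALSE`.
#' @return Character vector `"chrom:pos_ref>alt"`.
#' @export
format_variant_key <- function(keys, spaces = FALSE) {
  .check_key_cols(keys)
  sep <- if (spaces) " > " else ">"
  paste0(keys$chrom, ":", keys$pos, "_", keys$ref, sep, keys$alt)
}

.key_cols <- c("chrom", "pos", "ref", "alt")

.check_key_cols <- function(x, extra = character()) {
  need <- c(.key_cols, extra)
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    rlang::abort(sprintf("missing required columns: %s",
                         paste(missing, collapse = ", ")))
  }
  invisible(x)
}

.is_snv <- function(ref, alt) {
  ref %in% .nucs & alt %in% .nucs & ref != alt
}

#' Read a somatic variant catalog
#'
#' Reads a catalog of per-observation somatic SNV records, one row per
#' (variant, sample) observation, in either a tab-separated table or a
#' minimal VCF 4.x dialect. Only true SNVs (single-nucleotide ref and alt,
#' ref != alt) are kept; other rows (indels, MNVs) are skipped and counted.
#' Duplicate rows are preserved: deduplication is the gold-standard builder's
#' job, so reading is lossless.
#'
#' The TSV dialect has a header row with columns
#' `chrom pos ref alt sample_id cancer_type region healthy`; `region` is
#' `"coding"`/`"noncoding"` (the VCF dialect uses `REGION=CD/NC`) and
#' `healthy` is 0/1, the catalog's "found in healthy individuals" flag.
#' The VCF dialect expects INFO keys `SAMPLE=`, `CTYPE=`, `HEALTHY=`,
#' `REGION=`.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`; `"auto"` (default) decides from the
#'   file extension.
#' @param columns Optional named character vector remapping TSV column names,
#'   e.g. `c(sample_id = "SAMPLE_NAME")`, for foreign exports.
#' @return A tibble of variant records (`chrom pos ref alt sample_id
#'   cancer_type region healthy`) with attribute `skipped` = number of
#'   non-SNV rows dropped.
#' @export
read_catalog <- function(path, format = c("auto", "tsv", "vcf"),
                         columns = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  raw <- if (format == "vcf") .read_catalog_vcf(path) else {
    .read_catalog_tsv(path, columns)
  }
  keep <- .is_snv(raw$ref, raw$alt)
  skipped <- sum(!keep)
  if (skipped > 0) {
    rlang::inform(sprintf("read_catalog: skipped %d non-SNV row(s)", skipped))
  }
  out <- raw[keep, , drop = FALSE]
  bad_region <- !out$region %in% .regions
  if (any(bad_region)) {
    rlang::abort(sprintf("unknown region label(s): %s",
                         paste(unique(out$region[bad_region]), collapse = ", ")))
  }
  out <- tibble::as_tibble(out)
  attr(out, "skipped") <- skipped
  out
}

.catalog_cols <- c(.key_cols, "sample_id", "cancer_type", "region", "healthy")

.read_catalog_tsv <- function(path, columns = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!is.null(columns)) {
    for (std in names(columns)) {
      if (columns[[std]] %in% names(tab)) {
        names(tab)[names(tab) == columns[[std]]] <- std
      }
    }
  }
  .check_key_cols(tab, extra = c("sample_id", "cancer_type", "region",
                                 "healthy"))
  tibble::tibble(
    chrom = as.character(tab$chrom),
    pos = as.integer(tab$pos),
    ref = toupper(tab$ref),
    alt = toupper(tab$alt),
    sample_id = as.character(tab$sample_id),
    cancer_type = as.character(tab$cancer_type),
    region = .expand_region(tab$region),
    healthy = as.logical(as.integer(tab$healthy))
  )
}

.expand_region <- function(x) {
  x <- tolower(as.character(x))
  x[x == "cd"] <- "coding"
  x[x == "nc"] <- "noncoding"
  x
}

.read_catalog_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    rlang::abort("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  alt <- vapply(as.list(rr$ALT), function(a) as.character(a)[1L], "")
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = as.integer(BiocGenerics::start(rr)),
    ref = as.character(rr$REF),
    alt = alt,
    sample_id = as.character(info$SAMPLE),
    cancer_type = as.character(info$CTYPE),
    region = .expand_region(as.character(info$REGION)),
    healthy = as.integer(info$HEALTHY) == 1L
  )
}

#' Write a variant catalog as TSV
#'
#' @param catalog Tibble of variant records as returned by [read_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  .check_key_cols(catalog, extra = c("sample_id", "cancer_type", "region",
                                     "healthy"))
  out <- dplyr::mutate(catalog, healthy = as.integer(.data$healthy))
  readr::write_tsv(out[.catalog_cols], path)
  invisible(path)
}

#' Read a population allele-frequency table
#'
#' One row per (variant, population) with the minor allele frequency in that
#' population; rows for the same variant are merged so the result has one row
#' per (variant, population) pair plus a precomputed per-variant maximum.
#' Columns: `chrom pos ref alt population maf`.
#'
#' @param path File path to the TSV.
#' @return A tibble `chrom pos ref alt population maf`.
#' @export
read_frequency_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(tab) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          population = character(), maf = double()))
  }
  .check_key_cols(tab, extra = c("population", "maf"))
  out <- tibble::tibble(
    chrom = as.character(tab$chrom), pos = as.integer(tab$pos),
    ref = toupper(tab$ref), alt = toupper(tab$alt),
    population = as.character(tab$population), maf = as.numeric(tab$maf)
  )
  if (any(is.na(out$maf)) || any(out$maf < 0 | out$maf > 1)) {
    rlang::abort("MAF values must lie in [0, 1]")
  }
  dplyr::distinct(out)
}

#' Read a clinical cohort table
#'
#' Per-patient survival records: `patient_id age time event endpoint`.
#' `time` is follow-up time in the unit declared by the data provider
#' (months in the bundled generators), `event` is 0/1 (1 = the endpoint
#' occurred), and `endpoint` is one of `OS`, `DSS`, `DFS`. A table may mix
#' endpoints; screens run once per endpoint.
#'
#' @param path File path to the TSV.
#' @return A tibble `patient_id age time event endpoint`.
#' @export
read_cohort <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("patient_id", "age", "time", "event", "endpoint")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    rlang::abort(sprintf("cohort table lacks columns: %s",
                         paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    patient_id = as.character(tab$patient_id),
    age = as.numeric(tab$age),
    time = as.numeric(tab$time),
    event = as.integer(tab$event),
    endpoint = as.character(tab$endpoint)
  )
  if (any(out$time < 0, na.rm = TRUE)) rlang::abort("survival time must be >= 0")
  if (any(out$age < 0, na.rm = TRUE)) rlang::abort("age must be >= 0")
  if (!all(out$endpoint %in% c("OS", "DSS", "DFS"))) {
    rlang::abort("endpoint must be one of OS, DSS, DFS")
  }
  out
}

#' Write a cohort table as TSV
#' @param cohort Tibble as returned by [read_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(
    cohort[c("patient_id", "age", "time", "event", "endpoint")], path)
  invisible(path)
}
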