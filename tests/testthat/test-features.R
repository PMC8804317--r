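# Feature schema and computed sequence/catalog features.

test_that("default schema has the documented shape", {
  sch <- default_schema()
  expect_equal(sum(sch$applicability == "shared"), 65L)
  expect_equal(sum(sch$applicability == "coding_only"), 15L)
  expect_equal(dplyr::n_distinct(sch$group), 4L)
  expect_false(anyDuplicated(sch$name) > 0)
  expect_true(all(c("gc_pct_75", "cpg_pct_75", "singleton_count_100",
                    "is_transition", "min_dist_tss") %in% sch$name))
  expect_equal(nrow(schema_for_region(sch, "coding")), 80L)
  expect_equal(nrow(schema_for_region(sch, "noncoding")), 65L)
})

test_that("gc_percent and cpg_percent handle composition, Ns and edges", {
  expect_equal(gc_percent(c("GGCCGGCC", "ATATATAT", "ACGT")),
               c(100, 0, 50))
  expect_equal(gc_percent("GCNN"), 100)  # N excluded from denominator
  expect_true(is.na(gc_percent("NNNN")))
  expect_error(gc_percent("ACGU"), "only A, C, G, T, N")

  expect_equal(cpg_percent("CGCG"), 100 * 2 / 3)
  expect_equal(cpg_percent("ATAT"), 0)
  expect_equal(cpg_percent("ACGT"), 100 * 1 / 3)
  expect_true(is.na(cpg_percent("C")))

  # property: both invariant under reverse complement
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  set.seed(11)
  for (i in 1:20) {
    w <- paste(sample(c("A", "C", "G", "T"), 151, replace = TRUE),
               collapse = "")
    expect_equal(gc_percent(w), gc_percent(revcomp(w)))
    expect_equal(cpg_percent(w), cpg_percent(revcomp(w)))
  }
})

test_that("singleton_neighbor_count applies window, MAF and self rules", {
  key <- tibble::tibble(chrom = "1", pos = 1000L, ref = "A", alt = "T")
  nb <- tibble::tibble(
    chrom = "1", pos = c(950L, 1050L, 1150L, 1000L),
    ref = c("C", "C", "C", "A"), alt = c("G", "G", "G", "T"),
    maf = c(0.01, 0.20, 0.01, 0.001))
  expect_equal(singleton_neighbor_count(key, nb), 1L)  # 1050 too common, 1150 too far, self excluded
  expect_equal(singleton_neighbor_count(key, nb[0, ]), 0L)
  nb$maf[1] <- 0.05  # boundary: strict <
  expect_equal(singleton_neighbor_count(key, nb), 0L)

  # equivalence with a plain O(n) scan on a larger random catalog
  set.seed(3)
  big <- tibble::tibble(
    chrom = sample(c("1", "2"), 5000, TRUE),
    pos = sample.int(20000, 5000, TRUE),
    ref = "C", alt = "G", maf = runif(5000, 0, 0.2))
  big <- dplyr::distinct(big, chrom, pos, .keep_all = TRUE)
  got <- singleton_neighbor_count(key, big)
  want <- sum(big$chrom == "1" & abs(big$pos - 1000) <= 100 &
                big$maf < 0.05 &
                !(big$pos == 1000 & big$ref == "A" & big$alt == "T"))
  expect_equal(got, want)
})

test_that("is_transition and min_distance_to_tss match their definitions", {
  expect_equal(is_transition(c("C", "A", "C", "G"), c("T", "G", "A", "T")),
               c(1L, 1L, 0L, 0L))
  expect_error(is_transition("A", "A"), "distinct")

  key <- tibble::tibble(chrom = "1", pos = 100L, ref = "A", alt = "T")
  expect_equal(min_distance_to_tss(key, c(90L, 250L)), 10)
  expect_equal(min_distance_to_tss(key, 100L), 0)
  expect_true(is.na(min_distance_to_tss(key, integer())))
})

test_that("assemble_features builds the full matrix with tracks and missingness", {
  ref <- c(`1` = strrep("GC", 500), `2` = strrep("AT", 500))
  vars <- tibble::tibble(chrom = c("1", "1", "2"),
                         pos = c(200L, 400L, 300L),
                         ref = c("G", "C", "A"), alt = c("A", "T", "G"))
  tss <- list(`1` = c(150L, 900L), `2` = 310L)
  tracks <- list(
    annotation_track("phastcons_vertebrates",
                     tibble::tibble(chrom = "1", start = 100L, end = 300L,
                                    value = 0.9),
                     "value_at"),
    annotation_track("h3k4me3_max",
                     tibble::tibble(chrom = c("1", "1"),
                                    pos = c(195L, 260L),
                                    value = c(2.5, 7)),
                     "max_over_window", window = 75L)
  )
  fm <- assemble_features(vars, reference = ref, tss = tss,
                          tracks = tracks, region = "coding")
  expect_equal(dim(fm), c(3L, 4L + 80L))
  expect_equal(fm$gc_pct_75, c(100, 100, 0))      # engineered composition
  expect_equal(fm$min_dist_tss, c(50, 250, 10))
  expect_equal(fm$phastcons_vertebrates, c(0.9, NA, NA)) # interval covers 200 only
  expect_equal(fm$h3k4me3_max, c(7, NA, NA))
  expect_true(all(is.na(fm$polyphen_score)))      # untracked -> missing
  expect_equal(attr(fm, "schema")$name,
               names(fm)[-(1:4)])                 # schema order preserved

  expect_error(
    assemble_features(vars, tracks = list(
      annotation_track("not_a_feature", tibble::tibble(chrom = "1",
                                                       pos = 1L, value = 1),
                       "value_at"))),
    "absent from the schema")
})

test_that("windows clip at contig ends with a warning, not an error", {
  ref <- c(`1` = strrep("G", 100))
  vars <- tibble::tibble(chrom = "1", pos = 10L, ref = "G", alt = "A")
  expect_warning(
    fm <- assemble_features(vars, reference = ref, region = "noncoding"),
    "truncated")
  expect_equal(fm$gc_pct_75, 100)
  expect_equal(ncol(fm), 4L + 65L)
})
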