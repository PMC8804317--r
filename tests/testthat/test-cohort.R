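# Cohort application: calls, recurrence, gene matrix, survival screens.

make_predictions <- function() {
  # hand-built prediction set: 3 variants across 5 patients
  keys <- tibble::tibble(
    chrom = c("1", "1", "2"), pos = c(100L, 200L, 300L),
    ref = c("A", "C", "G"), alt = c("T", "G", "A"))
  catalog <- tibble::tibble(
    chrom = rep(keys$chrom, c(4, 2, 1)),
    pos = rep(keys$pos, c(4, 2, 1)),
    ref = rep(keys$ref, c(4, 2, 1)),
    alt = rep(keys$alt, c(4, 2, 1)),
    sample_id = c("P1", "P2", "P3", "P4", "P1", "P5", "P1"))
  preds <- dplyr::inner_join(catalog, dplyr::mutate(
    keys, probability = c(0.9, 0.7, 0.3),
    call = c("positive", "positive", "negative")),
    by = c("chrom", "pos", "ref", "alt"))
  structure(preds, threshold = 0.55,
            class = c("prediction_set", class(preds)))
}

test_that("probability-to-call boundary and threshold monotonicity hold", {
  bl <- make_blobs(n = 60, sep = 3, seed = 71)
  m <- train_svm_rbf(bl$X, bl$y, seed = 72)
  fm <- dplyr::bind_cols(
    tibble::tibble(chrom = "1", pos = seq_len(60), ref = "A", alt = "T"),
    tibble::as_tibble(bl$X))
  p <- predict_pathogenic(m, fm, region = "coding")
  expect_equal(attr(p, "threshold"), 0.55)
  # boundary: probability exactly at threshold counts as positive
  t0 <- p$probability[5]
  p2 <- predict_pathogenic(m, fm, threshold = t0)
  expect_equal(p2$call[5], "positive")
  # positive count non-increasing along a threshold sweep
  counts <- vapply(seq(0, 1, by = 0.1), function(t) {
    sum(predict_pathogenic(m, fm, threshold = t)$call == "positive")
  }, 1)
  expect_true(all(diff(counts) <= 0))
  # non-coding default
  expect_equal(attr(predict_pathogenic(m, fm, region = "noncoding"),
                    "threshold"), 0.41)
})

test_that("recurrent positive variants count distinct carriers", {
  preds <- make_predictions()
  r4 <- recurrent_positive_variants(preds, 4)
  expect_equal(nrow(r4), 1L)
  expect_equal(r4$pos, 100L)
  expect_equal(r4$n_carriers, 4L)
  r2 <- recurrent_positive_variants(preds, 2)
  expect_equal(r2$pos, c(100L, 200L))      # sorted by count desc
  r1 <- recurrent_positive_variants(preds, 1)
  expect_equal(nrow(r1), 2L)               # negatives never counted
})

test_that("gene mutation matrix is binary with brute-force tallies", {
  preds <- make_predictions()
  gene_map <- tibble::tibble(
    chrom = c("1", "1"), pos = c(100L, 200L),
    ref = c("A", "C"), alt = c("T", "G"), gene = c("TP53", "TP53"))
  gmm <- suppressMessages(
    gene_mutation_matrix(preds, gene_map, patients = paste0("P", 1:5)))
  # P1 carries two positive SNVs in TP53 -> entry 1, not 2
  expect_equal(gmm$mutated[gmm$patient_id == "P1" & gmm$gene == "TP53"], 1L)
  expect_equal(sum(gmm$mutated), 5L)       # P1..P5 all carry >= 1
  counts <- attr(gmm, "gene_counts")
  expect_equal(counts$n_positive_snvs[counts$gene == "TP53"], 2L)
  # variant 2:300 is negative; a gene map ignoring it changes nothing
  expect_equal(attr(gmm, "n_unmapped"), 0L)

  cand <- select_candidate_genes(gmm, 2)
  expect_equal(cand$gene, "TP53")
  expect_equal(nrow(select_candidate_genes(gmm, 3)), 0L)
})

test_that("Kaplan-Meier estimates match hand products and censoring rules", {
  km <- km_curve(c(1, 2), c(1, 0))
  expect_equal(km$surv[km$time == 1], 0.5)
  expect_equal(tail(km$surv, 1), 0.5)      # censored tail stays flat

  km4 <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km4$surv, c(0.75, 0.5, 0.25, 0))

  kmn <- km_curve(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(kmn$surv == 1))
  expect_error(km_curve(numeric(), integer()), "empty")

  # property: non-increasing and matches the hand product-limit oracle
  set.seed(81)
  for (i in 1:5) {
    t <- round(rexp(40, 0.1), 1); e <- rbinom(40, 1, 0.7)
    km <- km_curve(t, e)
    expect_true(all(diff(km$surv) <= 1e-12))
    for (at in sample(t, 5)) {
      expect_equal(km$surv[max(which(km$time <= at))],
                   oracle_km(t, e, at), tolerance = 1e-12)
    }
  }
})

test_that("log-rank matches the explicit O/E/V oracle and its symmetries", {
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-9)   # = 2.882353
  expect_equal(lr$statistic,
               oracle_logrank(c(1, 2, 3, 4), c(1, 1, 1, 1),
                              c("A", "A", "B", "B")), tolerance = 1e-9)
  # identical groups -> statistic 0, p 1
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # label swap leaves the statistic unchanged
  lrs <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("B", "B", "A", "A"))
  expect_equal(lrs$statistic, lr$statistic, tolerance = 1e-12)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "zero events")
  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")), "two")

  # property: equals the hand oracle on random censored samples (with ties)
  set.seed(82)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    t <- sample(1:12, n, replace = TRUE)   # heavy ties
    e <- rbinom(n, 1, 0.7)
    g <- rbinom(n, 1, 0.5)
    if (sum(e) == 0 || length(unique(g)) < 2) next
    expect_equal(logrank_test(t, e, g)$statistic, oracle_logrank(t, e, g),
                 tolerance = 1e-9)
  }
})

test_that("age-stratified screen flags young-specific units and degenerates safely", {
  sim <- simulate_survival_cohort(n = 400, hr_young = 4, hr_old = 1,
                                  seed = 91)
  carriers <- dplyr::bind_rows(
    tibble::tibble(unit = "planted", patient_id = sim$carrier_ids),
    tibble::tibble(unit = "nobody", patient_id = "not_in_cohort"))
  res <- age_stratified_screen(sim$cohort, carriers)
  planted <- res[res$unit == "planted", ]
  expect_true(planted$evaluable)
  expect_lt(planted$p_young, 0.05)
  nobody <- res[res$unit == "nobody", ]
  expect_false(nobody$evaluable)           # no carriers -> not evaluable
  expect_false(nobody$young_specific)      # and never flagged

  # screen runs once per endpoint
  co2 <- dplyr::mutate(sim$cohort, endpoint = "DSS")
  both <- age_stratified_screen(dplyr::bind_rows(sim$cohort, co2),
                                carriers)
  expect_equal(nrow(both), 4L)
  expect_setequal(unique(both$endpoint), c("OS", "DSS"))

  expect_error(age_stratified_screen(
    dplyr::mutate(sim$cohort, age = NA_real_), carriers), "age")
})
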