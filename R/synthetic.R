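# Seeded synthetic-data generators: somatic variant catalogs with known
# driver/benign truth, population-frequency tables, reference sequence,
# class-conditional feature matrices, and survival cohorts with a planted
# young-carrier hazard. Every generator is a pure function of its
# configuration, so all downstream modules are testable without access to
# licensed variant databases.

#' Simulation configuration
#'
#' The stated world of the synthetic catalog. Defaults describe a
#' catalog-like mixture: mostly singleton passengers, a minority of
#' recurrent drivers whose carrier counts are heavy-tailed (shifted
#' negative binomial, always clearing the coding recurrence rule f>=4,
#' c>=2), and a slice of benign variants seen in healthy individuals with
#' population MAF >= 1%.
#'
#' @param seed Integer seed.
#' @param n_variants Distinct variants in the catalog (default 2000).
#' @param n_samples Patient pool size (default 500).
#' @param cancer_types Cancer-type labels (default 8 types).
#' @param driver_fraction Fraction of variants that are true drivers
#'   (default 0.10).
#' @param driver_extra_carriers Negative-binomial mean of driver carriers
#'   beyond the guaranteed 4 (default 4, dispersion 2).
#' @param passenger_extra_carriers Poisson mean of passenger carriers
#'   beyond 1 (default 0.2; passengers are mostly singletons).
#' @param healthy_fraction Fraction of passengers flagged "found in healthy
#'   individuals" and given MAF >= 1% - the true benign variants
#'   (default 0.25).
#' @param populations Population labels for the frequency table.
#' @param region `"coding"` or `"noncoding"` (written on every record).
#' @param contig_length Length of each synthetic contig in bp
#'   (default 100000).
#' @param gc_bias P(G or C) per reference base (default 0.41, the
#'   genome-wide GC content of the human reference).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_variants = 2000L, n_samples = 500L,
                       cancer_types = c("breast", "lung", "skin", "colon",
                                        "prostate", "ovary", "kidney",
                                        "liver"),
                       driver_fraction = 0.10,
                       driver_extra_carriers = 4,
                       passenger_extra_carriers = 0.2,
                       healthy_fraction = 0.25,
                       populations = c("AFR", "AMR", "EAS", "EUR", "SAS"),
                       region = "coding",
                       contig_length = 100000L,
                       gc_bias = 0.41) {
  stopifnot(driver_fraction >= 0, driver_fraction <= 1,
            healthy_fraction >= 0, healthy_fraction <= 1,
            gc_bias > 0, gc_bias < 1)
  .assert_region(region)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a somatic variant catalog with known truth
#'
#' Draws distinct variant keys on synthetic contigs, assigns each variant a
#' truth class (`driver`, `benign`, `passenger`), and expands it into
#' per-(variant, sample) records plus a population-frequency table:
#' * drivers: carriers = 4 + NB(mu = driver_extra_carriers), spread over
#'   >= 2 cancer types, never healthy-flagged, population MAF ~ 0;
#' * benign: healthy-flagged passengers with max population MAF >= 0.01;
#' * passengers: 1 + Poisson(passenger_extra_carriers) carriers, rare MAF.
#'
#' @param config A [sim_config()].
#' @return List `catalog` (variant-record tibble), `frequencies`
#'   (population-frequency tibble), `truth` (tibble `chrom pos ref alt
#'   truth`).
#' @export
simulate_catalog <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_variants
  n_contigs <- max(2L, min(8L, ceiling(n / 400)))
  contigs <- as.character(seq_len(n_contigs))

  # distinct keys: sample (contig, position) slots without replacement so
  # no two variants collide regardless of catalog size
  span <- config$contig_length - 200L
  if (n > n_contigs * span) rlang::abort("catalog larger than the genome")
  slots <- sample.int(n_contigs * span, n)
  chrom <- contigs[(slots - 1L) %/% span + 1L]
  pos <- (slots - 1L) %% span + 101L
  ref <- sample(.nucs, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.nucs, r), 1L), "")

  n_driver <- round(n * config$driver_fraction)
  truth <- rep("passenger", n)
  truth[seq_len(n_driver)] <- "driver"
  pass_idx <- which(truth == "passenger")
  n_benign <- round(length(pass_idx) * config$healthy_fraction)
  benign_idx <- sample(pass_idx, n_benign)
  truth[benign_idx] <- "benign"

  carriers <- integer(n)
  carriers[truth == "driver"] <-
    4L + stats::rnbinom(n_driver, size = 2, mu = config$driver_extra_carriers)
  n_other <- n - n_driver
  carriers[truth != "driver"] <-
    1L + stats::rpois(n_other, config$passenger_extra_carriers)
  carriers <- pmin(carriers, config$n_samples)

  n_types_v <- ifelse(
    truth == "driver",
    pmin(carriers, length(config$cancer_types), 2L + stats::rpois(n, 1)),
    pmin(carriers, 1L + stats::rpois(n, 0.05)))
  per_variant <- lapply(seq_len(n), function(i) {
    smp <- sample.int(config$n_samples, carriers[i])
    types <- sample(config$cancer_types, n_types_v[i])
    ct <- sample(types, carriers[i], replace = TRUE)
    ct[seq_len(n_types_v[i])] <- types # every drawn type is represented
    list(smp = smp, ct = ct)
  })
  idx <- rep(seq_len(n), carriers)
  records <- tibble::tibble(
    chrom = chrom[idx], pos = pos[idx], ref = ref[idx], alt = alt[idx],
    sample_id = sprintf("S%04d",
                        unlist(lapply(per_variant, `[[`, "smp"))),
    cancer_type = unlist(lapply(per_variant, `[[`, "ct")),
    region = config$region,
    healthy = (truth == "benign")[idx]
  )

  npop <- 1L + pmin(stats::rpois(n, 1.2),
                    length(config$populations) - 1L)
  pop_l <- lapply(npop, function(k) sample(config$populations, k))
  fidx <- rep(seq_len(n), npop)
  benign <- truth == "benign"
  base <- numeric(length(fidx))
  is_b <- benign[fidx]
  base[is_b] <- stats::runif(sum(is_b), 0.01, 0.35)
  base[!is_b] <- stats::rexp(sum(!is_b), rate = 600) # essentially absent
  # guarantee every benign variant clears the 1% rule in >= 1 population
  first_of <- c(TRUE, diff(fidx) != 0L)
  base[first_of & is_b] <- pmax(base[first_of & is_b], 0.015)
  freq_rows <- tibble::tibble(
    chrom = chrom[fidx], pos = pos[fidx], ref = ref[fidx], alt = alt[fidx],
    population = unlist(pop_l), maf = pmin(base, 0.5))

  list(
    catalog = records,
    frequencies = freq_rows,
    truth = tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                           truth = truth)
  )
}

#' Simulate a reference genome for the catalog's contigs
#'
#' I.i.d. bases with a configurable GC bias - enough for the computed
#' sequence features (GC/CpG windows), with no attempt at genome structure.
#'
#' @param config A [sim_config()].
#' @return Named character vector of contig sequences.
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(config$seed + 104729L) # decoupled stream, fixed offset
  n_contigs <- max(2L, min(8L, ceiling(config$n_variants / 400)))
  p <- c(A = (1 - config$gc_bias) / 2, C = config$gc_bias / 2,
         G = config$gc_bias / 2, T = (1 - config$gc_bias) / 2)
  stats::setNames(vapply(seq_len(n_contigs), function(i) {
    paste(sample(names(p), config$contig_length, replace = TRUE, prob = p),
          collapse = "")
  }, ""), as.character(seq_len(n_contigs)))
}

#' Simulate a class-conditional feature matrix
#'
#' Given labeled variants, draws a feature matrix under the schema:
#' `n_informative` continuous features carry a class-mean shift of `d`
#' standard deviations (positives higher), informative binary features a
#' carrier-rate shift; all remaining features are pure noise (standard
#' normal / Bernoulli(0.3)). Missing cells are then masked completely at
#' random at `missing_rate`.
#'
#' @param labels Tibble with key columns and a `label` column
#'   (`"positive"`/`"negative"`), e.g. `tidy(gold_standard)`.
#' @param schema Feature schema (region-restricted; default coding schema).
#' @param d Class-mean shift on informative continuous features, in SD
#'   units (default 1.5).
#' @param n_informative Number of informative features (default 10).
#' @param missing_rate MCAR missingness rate in \[0, 1) (default 0.10).
#' @param seed Integer seed.
#' @return Feature tibble (key columns, `label`, features) with attribute
#'   `informative` naming the informative features.
#' @export
simulate_feature_matrix <- function(labels,
                                    schema = schema_for_region(
                                      default_schema(), "coding"),
                                    d = 1.5, n_informative = 10L,
                                    missing_rate = 0.10, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (n_informative > nrow(schema)) {
    rlang::abort("n_informative exceeds the schema size")
  }
  set.seed(seed)
  n <- nrow(labels)
  pos <- labels$label == "positive"
  cont <- schema$name[schema$value_kind == "continuous"]
  if (n_informative > length(cont)) {
    rlang::abort("not enough continuous features for n_informative")
  }
  informative <- sample(cont, n_informative)
  cols <- lapply(seq_len(nrow(schema)), function(j) {
    fd <- schema[j, ]
    if (fd$value_kind == "binary") {
      stats::rbinom(n, 1L, 0.3)
    } else if (fd$name %in% informative) {
      stats::rnorm(n, mean = ifelse(pos, d, 0))
    } else {
      stats::rnorm(n)
    }
  })
  names(cols) <- schema$name
  X <- tibble::as_tibble(cols)
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n * ncol(X)) < missing_rate, n, ncol(X))
    for (j in seq_len(ncol(X))) {
      v <- X[[j]]
      v[mask[, j]] <- NA
      X[[j]] <- v
    }
  }
  out <- dplyr::bind_cols(labels[intersect(names(labels),
                                           c(.key_cols, "label"))], X)
  attr(out, "informative") <- informative
  out
}

#' Simulate a survival cohort with a planted young-carrier hazard
#'
#' Exponential event times with hazard `base_hazard`, multiplied by
#' `hr_young` for carriers younger than `age_cutoff` and by `hr_old` for
#' older carriers; censoring is independent exponential, tuned so that
#' roughly `censoring_rate` of patients are censored. Ages are uniform
#' within each age band with P(young) = `young_fraction`.
#'
#' @param n Number of patients (default 300).
#' @param carrier_fraction Fraction of patients carrying the unit
#'   (default 0.3).
#' @param hr_young,hr_old Carrier hazard ratios in the young / old stratum
#'   (defaults 3 and 1 - the planted young-specific effect).
#' @param young_fraction Fraction of patients under the cutoff
#'   (default 0.5).
#' @param age_cutoff Years (default 45).
#' @param base_hazard Baseline event hazard per month (default 0.02).
#' @param censoring_rate Target fraction censored (default 0.3).
#' @param endpoint Endpoint label (default `"OS"`).
#' @param seed Integer seed.
#' @return List `cohort` (cohort tibble) and `carrier_ids` (patients
#'   carrying the unit).
#' @export
simulate_survival_cohort <- function(n = 300L, carrier_fraction = 0.3,
                                     hr_young = 3, hr_old = 1,
                                     young_fraction = 0.5, age_cutoff = 45,
                                     base_hazard = 0.02,
                                     censoring_rate = 0.3,
                                     endpoint = "OS", seed = 1L) {
  stopifnot(hr_young > 0, hr_old > 0, censoring_rate >= 0,
            censoring_rate < 1)
  set.seed(seed)
  young <- stats::runif(n) < young_fraction
  age <- ifelse(young, stats::runif(n, 25, age_cutoff - 1e-9),
                stats::runif(n, age_cutoff, 80))
  carrier <- stats::runif(n) < carrier_fraction
  hr <- ifelse(carrier, ifelse(young, hr_young, hr_old), 1)
  t_event <- stats::rexp(n, rate = base_hazard * hr)
  # censoring hazard matched to the target marginal censoring share
  cens_rate <- if (censoring_rate > 0) {
    base_hazard * censoring_rate / (1 - censoring_rate)
  } else 0
  t_cens <- if (cens_rate > 0) stats::rexp(n, rate = cens_rate) else
    rep(Inf, n)
  ids <- sprintf("P%04d", seq_len(n))
  list(
    cohort = tibble::tibble(
      patient_id = ids, age = age,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      endpoint = endpoint
    ),
    carrier_ids = ids[carrier]
  )
}
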