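# Independent brute-force oracles used across the suite. These stay naive
# on purpose: set comprehensions, pairwise enumeration and explicit
# O/E/V sums, never the package's own code paths.

# AUC as the Mann-Whitney concordance probability, ties counted one half
oracle_auc <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# log-rank chi-square by explicit observed/expected/variance sums over the
# distinct event times (hypergeometric variance, group A vs B)
oracle_logrank <- function(times, events, group) {
  group <- as.character(group)
  gA <- unique(group)[1L]
  ts <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- times >= t
    nA <- sum(at_risk & group == gA)
    N <- sum(at_risk)
    d <- sum(times == t & events == 1)
    dA <- sum(times == t & events == 1 & group == gA)
    O <- O + dA
    E <- E + d * nA / N
    if (N > 1) V <- V + d * (N - d) * nA * (N - nA) / (N^2 * (N - 1))
  }
  (O - E)^2 / V
}

# Kaplan-Meier product-limit estimate by hand at the distinct event times
oracle_km <- function(times, events, at) {
  s <- 1
  for (t in sort(unique(times[events == 1]))) {
    if (t > at) break
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# brute-force gold-standard labeling straight from raw records
oracle_labels <- function(catalog, frequencies, region, f, c,
                          maf_cutoff = 0.01) {
  cat_r <- catalog[catalog$region == region, ]
  keyf <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  keys <- unique(keyf(cat_r))
  healthy <- unique(keyf(cat_r[cat_r$healthy, ]))
  pos <- Filter(function(k) {
    rows <- cat_r[keyf(cat_r) == k, ]
    length(unique(rows$sample_id)) >= f &&
      length(unique(rows$cancer_type)) >= c &&
      !(k %in% healthy)
  }, keys)
  fk <- keyf(frequencies)
  neg <- Filter(function(k) {
    maxmaf <- suppressWarnings(max(frequencies$maf[fk == k]))
    is.finite(maxmaf) && maxmaf >= maf_cutoff && k %in% healthy
  }, keys)
  both <- intersect(pos, neg)
  list(positive = setdiff(pos, both), negative = setdiff(neg, both))
}

# two well-separated 2-D gaussian blobs
make_blobs <- function(n = 200, sep = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n, sep), n / 2),
             matrix(rnorm(n, -sep), n / 2))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c(1L, 0L), each = n / 2))
}

# small labeled feature world built through the package's own generator
make_gold_world <- function(seed, n_variants = 2000, d = 1.5,
                            n_informative = 10, missing_rate = 0.10) {
  sim <- simulate_catalog(sim_config(seed = seed, n_variants = n_variants))
  gs <- build_gold_standard(sim$catalog, sim$frequencies, "coding")
  fm <- simulate_feature_matrix(tidy(gs), d = d,
                                n_informative = n_informative,
                                missing_rate = missing_rate,
                                seed = seed + 1)
  list(sim = sim, gold = gs, features = fm)
}
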