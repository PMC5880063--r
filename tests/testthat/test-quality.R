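# Dataset with one locus and explicit genotype counts.
counts_dataset <- function(genos, registry = toy_registry(1L)) {
  geno <- list()
  for (k in seq_along(genos)) {
    geno[[sprintf("i%03d", k)]] <- list(loc01 = genos[[k]])
  }
  toy_dataset(geno, registry)
}

# Exact HWE test oracle: enumerate every pairing of the allele multiset into
# n unordered pairs; P(config) = n! 2^h prod(a_c!) / ((2n)! prod(n_g!)).
hwe_exact_oracle <- function(genos) {
  alleles <- sort(unlist(genos))
  n <- length(genos)
  configs <- new.env()
  recurse <- function(rem, acc) {
    if (!length(rem)) {
      key <- paste(sort(vapply(acc, function(g)
        paste(sort(g), collapse = "/"), character(1))), collapse = ";")
      assign(key, acc, envir = configs)
      return(invisible(NULL))
    }
    a <- rem[1]
    rest <- rem[-1]
    for (j in seq_along(rest)) {
      recurse(rest[-j], c(acc, list(c(a, rest[j]))))
    }
  }
  recurse(alleles, list())
  a_counts <- table(alleles)
  log_const <- lgamma(n + 1) + sum(lgamma(a_counts + 1)) - lgamma(2 * n + 1)
  config_prob <- function(acc) {
    keys <- vapply(acc, function(g) paste(sort(g), collapse = "/"),
                   character(1))
    n_g <- table(keys)
    h <- sum(vapply(acc, function(g) g[1] != g[2], logical(1)))
    exp(log_const + h * log(2) - sum(lgamma(n_g + 1)))
  }
  obs_p <- config_prob(genos)
  total <- 0
  for (key in ls(configs)) {
    pr <- config_prob(get(key, envir = configs))
    if (pr <= obs_p + 1e-12) total <- total + pr
  }
  total
}

test_that("HWE test boundaries: monomorphic locus and homozygote excess", {
  mono <- counts_dataset(rep(list(c(110L, 110L)), 10))
  expect_equal(hwe_test(mono, "loc01", n_reps = 100)$p_value, 1)
  # 25 + 25 homozygotes at a two-allele locus, p = q = 0.5: extreme deficit
  homs <- counts_dataset(c(rep(list(c(110L, 110L)), 25),
                           rep(list(c(112L, 112L)), 25)))
  res <- hwe_test(homs, "loc01", n_reps = 5000, seed = 4)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$het_deficit, 0.4)
})

test_that("Monte-Carlo p agrees with full enumeration at tiny n", {
  cases <- list(
    list(c(110L, 110L), c(110L, 112L), c(112L, 112L), c(110L, 112L)),
    list(c(110L, 110L), c(112L, 112L), c(112L, 112L), c(110L, 110L)),
    list(c(110L, 112L), c(110L, 114L), c(112L, 114L), c(110L, 110L),
         c(114L, 114L))
  )
  for (genos in cases) {
    exact <- min(1, hwe_exact_oracle(genos))
    ds <- counts_dataset(genos)
    mc <- hwe_test(ds, "loc01", n_reps = 20000, seed = 11)$p_value
    se <- sqrt(max(0, exact * (1 - exact)) / 20000)
    expect_lt(abs(mc - exact), 4 * se + 2e-4)
  }
})

test_that("HWE p-values are roughly uniform under the null", {
  set.seed(99)
  cfg <- sim_config(seed = 1, n_loci = 1, n_L_only = 0, n_R_only = 0)
  freqs <- list(loc01 = c("5102" = 0.4, "5104" = 0.35, "5106" = 0.25))
  pvals <- vapply(1:200, function(b) {
    ds <- simulate_sexual_population(cfg, "R", 100, freqs = freqs)
    hwe_test(ds, "loc01", n_reps = 499, seed = b)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("null-allele estimator boundaries", {
  # perfect HWE-looking data, no blanks: r = 0
  hwe_like <- counts_dataset(c(rep(list(c(110L, 110L)), 25),
                               rep(list(c(110L, 112L)), 50),
                               rep(list(c(112L, 112L)), 25)))
  expect_equal(estimate_null_allele_freq(hwe_like, "loc01")$r_hat, 0)
  # all cells blank: r = 1
  blank <- counts_dataset(rep(list(c(NA_integer_, NA_integer_)), 12))
  expect_equal(estimate_null_allele_freq(blank, "loc01")$r_hat, 1)
})

test_that("ML estimate matches the moment estimator for one visible allele", {
  # 80 apparent homozygotes + 20 blanks: r-hat = sqrt(0.2)
  one <- counts_dataset(c(rep(list(c(110L, 110L)), 80),
                          rep(list(c(NA_integer_, NA_integer_)), 20)))
  est <- estimate_null_allele_freq(one, "loc01")
  expect_equal(est$r_hat, sqrt(0.2), tolerance = 1e-3)
  expect_equal(est$blanks_observed, 20L)
})

test_that("r-hat is invariant to allele relabeling", {
  genos <- c(rep(list(c(110L, 110L)), 30), rep(list(c(110L, 112L)), 20),
             rep(list(c(112L, 112L)), 20),
             rep(list(c(NA_integer_, NA_integer_)), 5))
  relab <- lapply(genos, function(g) ifelse(g == 110L, 500L,
                                            ifelse(g == 112L, 300L, g)))
  relab <- lapply(relab, as.integer)
  reg <- toy_registry(1L, L_alleles = c(110L, 112L, 300L, 500L))
  r1 <- estimate_null_allele_freq(counts_dataset(genos, reg), "loc01")$r_hat
  r2 <- estimate_null_allele_freq(counts_dataset(relab, reg), "loc01")$r_hat
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("the estimator recovers a simulated null-allele frequency", {
  cfg <- sim_config(seed = 17, n_loci = 1, n_L_only = 0, n_R_only = 0,
                    missing_rate = 0, null_allele_rate = 1, null_freq = 0.2,
                    populations = data.frame(
                      name = "p1", system_type = "R-E-male", n_RR = 500,
                      n_LL = 0, n_hybrid_males = 0, n_hybrid_females = 0))
  sim <- inject_artifacts(simulate_re_system(cfg), cfg)
  est <- estimate_null_allele_freq(sim$dataset, "loc01")
  expect_lt(abs(est$r_hat - 0.2), 0.05)
})

test_that("null correction recodes blanks, is idempotent, re-screens clean", {
  cfg <- sim_config(seed = 23, n_loci = 2, n_L_only = 0, n_R_only = 0,
                    missing_rate = 0, null_allele_rate = 1, null_freq = 0.2,
                    populations = data.frame(
                      name = "p1", system_type = "R-E-male", n_RR = 400,
                      n_LL = 0, n_hybrid_males = 0, n_hybrid_females = 0))
  ds <- inject_artifacts(simulate_re_system(cfg), cfg)$dataset
  qs <- quality_screen(ds, n_reps = 999, seed = 3)
  expect_true(all(qs$flagged))
  before_p <- qs$p_value
  expect_true(all(before_p < 0.05))
  corr <- apply_null_correction(ds, qs, seed = 8)
  # blanks became null homozygotes
  expect_false(any(is.na(corr$a1[, "loc01"]) & is.na(corr$a2[, "loc01"])))
  blanks <- is.na(ds$a1[, "loc01"]) & is.na(ds$a2[, "loc01"])
  expect_true(all(corr$a1[blanks, "loc01"] == corr$a2[blanks, "loc01"]))
  # idempotent
  corr2 <- apply_null_correction(corr, qs, seed = 9)
  expect_identical(corr2$a1, corr$a1)
  expect_identical(corr2$a2, corr$a2)
  # corrected data no longer reject HWE
  after <- quality_screen(corr, n_reps = 999, seed = 5)
  expect_true(all(!after$flagged))
  expect_true(all(after$p_value > 0.01))
})

test_that("no estimate above threshold leaves the dataset unchanged", {
  cfg <- small_re_config(29L, n_pops = 1L, n_RR = 60L, n_hyb = 0L,
                         missing_rate = 0)
  ds <- simulate_re_system(cfg)$dataset
  est <- estimate_null_allele_freq(ds, "loc01", "p1")
  est$r_hat <- 0.01  # below the 0.05 threshold
  corr <- apply_null_correction(ds, list(est), seed = 1)
  expect_identical(corr$a1, ds$a1)
  expect_identical(corr$a2, ds$a2)
  expect_error(apply_null_correction(ds, list(est), threshold = 1.2),
               "threshold")
})
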