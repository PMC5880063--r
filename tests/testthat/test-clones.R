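reg5 <- toy_registry(5L, L_alleles = seq(102L, 120L, 2L),
                     R_alleles = seq(202L, 220L, 2L))

# dataset of diploid records built from explicit rows: list of per-locus cells
rows_dataset <- function(rows, registry = reg5, population = "p1") {
  geno <- stats::setNames(rows, sprintf("r%03d", seq_along(rows)))
  toy_dataset(geno, registry, taxon = "RR", population = population)
}

full_row <- function(alleles) {
  stats::setNames(lapply(alleles, function(a) c(a, a)), reg5$loci$name)
}

test_that("exact MLG indexing separates missing-data variants", {
  base <- full_row(c(102L, 104L, 106L, 108L, 110L))
  with_missing <- base
  with_missing$loc03 <- c(NA_integer_, NA_integer_)
  ds <- rows_dataset(list(base, base, with_missing))
  idx <- index_mlgs(ds)
  expect_equal(length(idx$key), 2L)  # missing cell makes a distinct exact MLG
  expect_equal(sort(unname(lengths(idx$members))), c(1L, 2L))
})

test_that("simulated sexual individuals have individually unique MLGs", {
  cfg <- sim_config(seed = 150, n_loci = 10, n_L_only = 0, n_R_only = 0,
                    missing_rate = 0,
                    populations = data.frame(
                      name = "p1", system_type = "R-E-male", n_RR = 150,
                      n_LL = 0, n_hybrid_males = 0, n_hybrid_females = 0))
  ds <- simulate_re_system(cfg)$dataset
  expect_equal(length(index_mlgs(ds)$key), 150L)
})

test_that("eight missing-data variants of one haplotype merge into one clone", {
  reg7 <- toy_registry(7L, L_alleles = seq(102L, 120L, 2L),
                       R_alleles = seq(202L, 220L, 2L))
  haplo <- c(102L, 104L, 106L, 108L, 110L, 112L, 114L)
  base <- stats::setNames(lapply(haplo, function(a) c(a, a)), reg7$loci$name)
  variants <- c(list(base), lapply(1:7, function(k) {
    v <- base
    v[[k]] <- c(NA_integer_, NA_integer_)  # one missing locus per variant
    v
  }))
  ds <- rows_dataset(variants, reg7)
  merged <- merge_mlgs(index_mlgs(ds), min_shared_loci = 5L)
  expect_equal(length(merged$clones), 1L)
  expect_equal(length(merged$clones[[1]]$members), 8L)
  # consensus is the complete haplotype
  expect_equal(unname(merged$clones[[1]]$consensus_a1), haplo)
})

test_that("any co-scored conflict prevents merging", {
  a <- full_row(c(102L, 104L, 106L, 108L, 110L))
  b <- a; b$loc05 <- c(112L, 112L)   # conflicting co-scored state
  ds <- rows_dataset(list(a, b))
  merged <- merge_mlgs(index_mlgs(ds), min_shared_loci = 3L)
  expect_equal(length(merged$clones), 2L)
})

test_that("too few co-scored loci prevents merging", {
  a <- full_row(c(102L, 104L, 106L, 108L, 110L))
  a$loc04 <- a$loc05 <- c(NA_integer_, NA_integer_)
  b <- full_row(c(102L, 104L, 106L, 108L, 110L))
  b$loc01 <- b$loc02 <- b$loc03 <- c(NA_integer_, NA_integer_)
  ds <- rows_dataset(list(a, b))   # zero co-scored loci
  expect_equal(length(merge_mlgs(index_mlgs(ds), 1L)$clones), 2L)
})

test_that("non-clique chains split by the documented tie rule", {
  # A and C conflict at loc01; B is missing there and compatible with both.
  a <- full_row(c(102L, 104L, 106L, 108L, 110L))
  b <- a; b$loc01 <- c(NA_integer_, NA_integer_)
  c_ <- a; c_$loc01 <- c(104L, 104L)
  # exhaustive over the 3 insertion orders of the chain
  for (ord in list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))) {
    ds <- rows_dataset(list(a, b, c_)[ord])
    merged <- merge_mlgs(index_mlgs(ds), min_shared_loci = 3L)
    expect_equal(length(merged$clones), 2L)
    expect_equal(length(merged$split_log), 1L)
    sizes <- sort(vapply(merged$clones, function(cl)
      length(cl$members), integer(1)))
    expect_equal(sizes, c(1L, 2L))
    # tie rule: both maximal cliques have 2 members; the lexicographically
    # smaller consensus (A+B, starting 102/102) wins over B+C (104/104)
    big <- merged$clones[[which.max(vapply(merged$clones, function(cl)
      length(cl$members), integer(1)))]]
    expect_equal(unname(big$consensus_a1["loc01"]), 102L)
  }
})

test_that("merged MLGs never conflict at a co-scored locus (random fixtures)", {
  set.seed(404)
  for (rep in 1:25) {
    rows <- lapply(1:8, function(i) {
      r <- full_row(sample(c(102L, 104L), 5, replace = TRUE))
      drop <- sample(5, sample(0:3, 1))
      for (d in drop) r[[d]] <- c(NA_integer_, NA_integer_)
      r
    })
    ds <- rows_dataset(rows)
    idx <- index_mlgs(ds)
    merged <- merge_mlgs(idx, min_shared_loci = 2L)
    for (cl in merged$clones) {
      ks <- match(cl$member_mlgs, idx$key)
      for (i in ks) for (j in ks) {
        for (loc in reg5$loci$name) {
          x <- idx$a1[i, loc]; y <- idx$a1[j, loc]
          if (!is.na(x) && !is.na(y)) expect_equal(x, y)
        }
      }
    }
  }
})

test_that("round-robin frequencies collapse clonal pseudo-replication", {
  # one clone repeated 14x plus one distinct sexual record
  clone <- full_row(c(102L, 104L, 106L, 108L, 110L))
  sexual <- full_row(c(104L, 106L, 106L, 108L, 110L))
  ds <- rows_dataset(c(rep(list(clone), 14), list(sexual)))
  fr <- round_robin_frequencies(ds, "loc01")
  expect_equal(attr(fr, "n_representatives"), 2L)
  # hand computed: one clone representative (102/102) + the sexual (104/104)
  expect_equal(unname(fr[c("102", "104")]), c(0.5, 0.5))
  # all records distinct elsewhere: plain sample frequencies
  distinct <- lapply(1:6, function(i)
    full_row(c(102L + 2L * (i %% 3), 104L + 2L * i, 106L, 108L, 110L)))
  ds2 <- rows_dataset(distinct)
  fr2 <- round_robin_frequencies(ds2, "loc01")
  copies <- table(vapply(distinct, function(r) as.numeric(r$loc01[1]),
                         numeric(1)))
  expect_equal(as.numeric(fr2), as.numeric(copies) / sum(copies))
  # single-locus dataset: method undefined
  ds1 <- rows_dataset(list(list(loc01 = c(102L, 104L))), toy_registry(1L))
  expect_error(round_robin_frequencies(ds1, "loc01"), "single-locus")
})

test_that("representative choice cannot change frequencies when sub-MLG
           members agree at the focal locus", {
  clone <- full_row(c(102L, 104L, 106L, 108L, 110L))
  other <- full_row(c(104L, 106L, 106L, 108L, 110L))
  rows <- c(rep(list(clone), 4), rep(list(other), 3))
  ref <- NULL
  set.seed(9)
  for (perm in 1:6) {
    ds <- rows_dataset(rows[sample(length(rows))])
    fr <- sort(round_robin_frequencies(ds, "loc02"))
    if (is.null(ref)) ref <- fr else expect_equal(fr, ref)
  }
})

test_that("self-doubled haploids give F_IS 1 at polymorphic loci", {
  rows <- lapply(1:10, function(i)
    full_row(c(102L + 2L * (i %% 4), 104L + 2L * (i %% 3), 106L, 108L,
               110L)))
  ds <- rows_dataset(rows)  # every record homozygous at every locus
  fis <- estimate_fis(ds)
  poly <- fis$h_exp > 0
  expect_true(any(poly))
  expect_true(all(fis$fis[poly] == 1))
  expect_true(all(fis$fis[!poly] == 0))  # monomorphic: 0 by convention
})

test_that("F_IS is near zero for random-mating simulations", {
  cfg <- sim_config(seed = 3, n_loci = 5, n_L_only = 0, n_R_only = 0)
  freqs <- list()
  set.seed(55)
  ests <- vapply(1:100, function(b) {
    ds <- simulate_sexual_population(cfg, "R", 100)
    mean(estimate_fis(ds)$fis)
  }, numeric(1))
  expect_lt(abs(mean(ests)), 0.05)
})

test_that("P_GEN closed-form examples and the self-doubling identity", {
  freqs <- list(loc01 = c("102" = 0.5, "104" = 0.5))
  fis0 <- stats::setNames(0, "loc01")
  expect_equal(p_gen(c(loc01 = 102L), c(loc01 = 104L), freqs, fis0), 0.5)
  fis1 <- stats::setNames(1, "loc01")
  expect_equal(p_gen(c(loc01 = 102L), c(loc01 = 102L), freqs, fis1), 0.5)
  # self-doubled haploid over two loci with p = 0.2 and F_IS = 1:
  # P_GEN = prod p_a = 0.04 (haploid product identity)
  freqs2 <- list(loc01 = c("102" = 0.2, "104" = 0.8),
                 loc02 = c("102" = 0.2, "104" = 0.8))
  fis2 <- stats::setNames(c(1, 1), c("loc01", "loc02"))
  expect_equal(p_gen(c(loc01 = 102L, loc02 = 102L),
                     c(loc01 = 102L, loc02 = 102L), freqs2, fis2), 0.04)
  # allele absent from the table is an error
  expect_error(p_gen(c(loc01 = 999L), c(loc01 = 999L), freqs, fis0),
               "absent")
  # missing loci are skipped
  expect_equal(p_gen(c(loc01 = 102L, loc02 = NA),
                     c(loc01 = 104L, loc02 = NA), freqs, fis0), 0.5)
})

test_that("P_SEX equals brute-force enumeration for N <= 10", {
  expect_equal(p_sex(0.1, 2, 3), 0.028, tolerance = 1e-12)
  for (p in c(0, 0.1, 0.5, 0.9, 1)) {
    for (N in c(1, 3, 7, 10)) {
      for (n_obs in seq_len(N)) {
        expect_equal(p_sex(p, n_obs, N), psex_enum(p, n_obs, N),
                     tolerance = 1e-10)
      }
    }
  }
  # boundaries
  expect_equal(p_sex(0, 1, 5), 0)
  expect_equal(p_sex(1, 3, 5), 1)
  # the alternative tail convention starts one copy earlier
  expect_equal(p_sex(0.1, 2, 3, convention = "n_minus_1"),
               psex_enum(0.1, 1, 3))
})

test_that("P_SEX is monotone in n_obs and in p_gen", {
  for (N in c(10, 50)) {
    ps <- vapply(1:N, function(k) p_sex(0.2, k, N), numeric(1))
    expect_true(all(diff(ps) <= 1e-14))
    pg <- seq(0, 1, by = 0.05)
    ps2 <- vapply(pg, function(p) p_sex(p, 3, N), numeric(1))
    expect_true(all(diff(ps2) >= -1e-14))
  }
})

test_that("P_SEX stays accurate in the far tail", {
  lp <- stats::dbinom(20:80, 80, 1e-3, log = TRUE)
  oracle <- exp(max(lp) + log(sum(exp(lp - max(lp)))))  # log-sum-exp
  expect_equal(p_sex(1e-3, 20, 80), oracle, tolerance = 1e-8)
  expect_lt(p_sex(1e-3, 20, 80), 1e-38)
})

test_that("clone verdicts follow the decision table exhaustively", {
  base <- full_row(c(102L, 104L, 106L, 108L, 110L))
  loci <- reg5$loci$name
  # frequency tables that push P_GEN (hence P_SEX) low or high
  freqs_for <- function(p_base) {
    stats::setNames(lapply(seq_along(loci), function(j) {
      alle <- as.character(seq(102L, 120L, 2L))
      pr <- rep((1 - p_base) / (length(alle) - 1), length(alle))
      names(pr) <- alle
      pr[as.character(base[[j]][1])] <- p_base
      pr / sum(pr)
    }), loci)
  }
  fis0 <- structure(data.frame(locus = loci, fis = 0, h_obs = 0, h_exp = 0.5,
                               n_representatives = 5),
                    class = c("fis_table", "data.frame"))
  for (count in c(1L, 2L, 3L, 5L)) {
    others <- lapply(1:9, function(i)
      full_row(c(104L, 106L + 2L * (i %% 3), 108L, 110L,
                 112L + 2L * (i %% 5))))
    ds <- rows_dataset(c(rep(list(base), count), others))
    ct <- merge_mlgs(index_mlgs(ds), min_shared_loci = 3L)
    for (p_base in c(0.02, 0.97)) {
      calls <- call_clones(ct, freqs_for(p_base), fis0,
                           alpha = 0.05, min_copies = 3L)
      row <- calls[calls$n_members == count, ][1, ]
      sig <- row$p_sex_min <= 0.05
      expected <- if (count >= 3 && sig) "clonal"
        else if (count >= 3 && !sig) "putative"
        else if (count >= 2 && sig) "putative"
        else "sexual"
      expect_equal(row$verdict, expected,
                   info = sprintf("count=%d p=%.2f psex=%.3g",
                                  count, p_base, row$p_sex_min))
      # both significance regimes are exercised for repeated MLGs
      if (count >= 2 && p_base == 0.02) expect_true(sig)
      if (count >= 3 && p_base == 0.97) expect_false(sig)
    }
  }
})

test_that("locus summaries match closed forms", {
  mono <- rows_dataset(rep(list(full_row(c(102L, 102L, 102L, 102L, 102L))), 5))
  sm <- locus_summaries(mono)
  expect_true(all(sm$an == 1))
  expect_true(all(sm$h_obs == 0) && all(sm$h_exp == 0))
  # p = (0.5, 0.5), N = 10: unbiased H_EXP = (20/19) * 0.5
  rows <- c(rep(list(list(loc01 = c(102L, 102L))), 5),
            rep(list(list(loc01 = c(104L, 104L))), 5))
  ds <- rows_dataset(rows, toy_registry(1L))
  sm2 <- locus_summaries(ds)
  expect_equal(sm2$h_exp, (20 / 19) * 0.5, tolerance = 1e-12)
  expect_equal(sm2$h_obs, 0)
  # all-heterozygote sample
  het <- rows_dataset(rep(list(list(loc01 = c(102L, 104L))), 8),
                      toy_registry(1L))
  expect_equal(locus_summaries(het)$h_obs, 1)
})

test_that("the full clonality pipeline recovers a simulated hemiclone", {
  hits <- 0L
  for (seed in 1:5) {
    cfg <- small_re_config(seed, n_pops = 5L, n_RR = 8L, n_hyb = 4L,
                           n_loci = 10L, missing_rate = 0.05)
    ds <- inject_artifacts(simulate_re_system(cfg), cfg)$dataset
    part <- partition_hybrids(ds)
    ca <- detect_clones(pooled_record_set(ds, part))
    mem <- attr(ca$calls, "membership")
    clonal <- ca$calls[ca$calls$verdict == "clonal", ]
    l_ids <- paste0(ds$ind$id[ds$ind$taxon == "RL"], "_L")
    ok <- nrow(clonal) == 1 &&
      setequal(mem$id[mem$clone_id == clonal$clone_id], l_ids) &&
      clonal$p_sex_min < 1e-6
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
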