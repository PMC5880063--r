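# Fixture builders shared by the test files. Everything is generated in code;
# no data files.

# Registry with n both-genome loci named loc01..; L alleles 100+2k, R 200+2k.
toy_registry <- function(n_loci = 2L, L_alleles = c(110L, 112L, 114L),
                         R_alleles = c(210L, 212L, 214L),
                         shared_alleles = integer(0)) {
  loci <- sprintf("loc%02d", seq_len(n_loci))
  spec <- do.call(rbind, lapply(loci, function(loc) {
    rbind(
      data.frame(locus = loc, allele = L_alleles, specificity = "L",
                 stringsAsFactors = FALSE),
      data.frame(locus = loc, allele = R_alleles, specificity = "R",
                 stringsAsFactors = FALSE),
      if (length(shared_alleles))
        data.frame(locus = loc, allele = shared_alleles,
                   specificity = "shared", stringsAsFactors = FALSE))
  }))
  allele_registry(
    data.frame(name = loci, amplifies_in = "LR", stringsAsFactors = FALSE),
    spec)
}

# Dataset from a compact genotype list: geno[[id]] = list(locus = c(a1, a2)).
toy_dataset <- function(geno, registry, taxon = "RR", population = "p1",
                        sex = "f") {
  loci <- registry$loci$name
  ids <- names(geno)
  a1 <- matrix(NA_integer_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  for (id in ids) for (loc in names(geno[[id]])) {
    cell <- geno[[id]][[loc]]
    a1[id, loc] <- cell[1]
    if (length(cell) > 1L) a2[id, loc] <- cell[2]
  }
  ind <- data.frame(id = ids, population = rep_len(population, length(ids)),
                    taxon = rep_len(taxon, length(ids)),
                    sex = rep_len(sex, length(ids)), stringsAsFactors = FALSE)
  genotype_dataset(ind, a1, a2, registry)
}

# Small all-both-genome simulation config for end-to-end tests.
small_re_config <- function(seed, n_pops = 5L, n_RR = 8L, n_hyb = 4L,
                            n_loci = 10L, missing_rate = 0.05, ...) {
  sim_config(seed = seed, n_loci = n_loci, n_L_only = 0L, n_R_only = 0L,
             missing_rate = missing_rate,
             populations = data.frame(
               name = sprintf("p%d", seq_len(n_pops)),
               system_type = "R-E-male", n_RR = n_RR, n_LL = 0L,
               n_hybrid_males = n_hyb, n_hybrid_females = 0L,
               stringsAsFactors = FALSE),
             ...)
}

# Pool sexual residents with both doubled hybrid subgenomes (the record set
# clonality is judged on).
pooled_record_set <- function(ds, part) {
  bind_datasets(subset_dataset(ds, which(ds$ind$taxon %in% c("LL", "RR"))),
                double_haploid(part$L, "self-double"),
                double_haploid(part$R, "self-double"))
}

# Exact upper-tail binomial by brute-force enumeration of outcome counts.
psex_enum <- function(p, n_obs, N) {
  probs <- vapply(0:N, function(k) choose(N, k) * p^k * (1 - p)^(N - k),
                  numeric(1))
  sum(probs[(n_obs + 1):(N + 1)])
}
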