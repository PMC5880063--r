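#' Simulation configuration for hybridogenetic population systems
#'
#' Describes a set of mixed populations of two sexual parental species
#' (labelled L and R) and their diploid hemiclonal hybrids. The default
#' composition emulates the R-E male system: populations holding sexual RR
#' frogs of both sexes plus all-male RL hybrids that carry one frozen clonal
#' L haplotype and a freshly recombined R haplotype from the sympatric RR
#' pool.
#'
#' @param seed integer root seed; per-population substreams are derived
#'   deterministically from it.
#' @param n_loci number of marker loci.
#' @param n_L_only,n_R_only how many loci amplify in only one parental genome
#'   (the rest amplify in both).
#' @param alleles_per_locus integer range (length-2 vector) of distinct
#'   founder alleles per locus per species band.
#' @param L_base,R_base,band_width,motif_step integer layout of the disjoint
#'   per-species allele-size bands: species S alleles at locus j live in
#'   \code{S_base + (j-1)*band_width + motif_step*k}.
#' @param populations data.frame with columns \code{name}, \code{system_type}
#'   (\code{"R-E-male"}, \code{"L-E"} or \code{"other"}), \code{n_RR},
#'   \code{n_LL}, \code{n_hybrid_males}, \code{n_hybrid_females}. Default:
#'   five R-E male populations with the composition 17/12, 1/2, 8/4, 6/4, 9/5
#'   (RR / hybrid males).
#' @param n_clones number of distinct founding clonal haplotypes.
#' @param generations clonal transmissions separating sampled hybrids from the
#'   founding haplotype.
#' @param mutation_rate per-gamete per-locus stepwise mutation rate applied to
#'   clonal transmissions.
#' @param missing_rate per-cell probability of whole-cell missingness injected
#'   by \code{\link{inject_artifacts}}.
#' @param null_allele_rate per-locus probability that a locus segregates a
#'   null allele.
#' @param null_freq frequency of the null allele at a null-carrying locus.
#' @param fis_sexual target inbreeding coefficient of the sexual pools.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 17L, n_L_only = 3L, n_R_only = 3L,
                       alleles_per_locus = c(6L, 17L),
                       L_base = 100L, R_base = 5100L,
                       band_width = 200L, motif_step = 2L,
                       populations = NULL,
                       n_clones = 1L, generations = 1L,
                       mutation_rate = 0, missing_rate = 0.02,
                       null_allele_rate = 0, null_freq = 0.2,
                       fis_sexual = 0) {
  if (is.null(populations)) {
    populations <- data.frame(
      name = paste0("pop", 1:5),
      system_type = "R-E-male",
      n_RR = c(17L, 1L, 8L, 6L, 9L),
      n_LL = 0L,
      n_hybrid_males = c(12L, 2L, 4L, 4L, 5L),
      n_hybrid_females = 0L,
      stringsAsFactors = FALSE)
  }
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  need <- c("name", "system_type", "n_RR", "n_LL",
            "n_hybrid_males", "n_hybrid_females")
  stopifnot(all(need %in% names(populations)))
  counts <- as.matrix(populations[c("n_RR", "n_LL", "n_hybrid_males",
                                    "n_hybrid_females")])
  if (any(counts < 0)) stopf("population counts must be >= 0")
  bad <- populations$system_type == "R-E-male" & populations$n_LL > 0
  if (any(bad))
    stopf("R-E male system excludes the L parental species (population %s)",
          paste(populations$name[bad], collapse = ", "))
  rates <- c(mutation_rate, missing_rate, null_allele_rate, null_freq)
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0, 1]")
  if (fis_sexual < -1 || fis_sexual > 1) stopf("fis_sexual must lie in [-1, 1]")
  if (n_L_only + n_R_only > n_loci) stopf("more single-genome loci than loci")
  if (length(alleles_per_locus) == 1L)
    alleles_per_locus <- rep(alleles_per_locus, 2L)
  k_max <- max(alleles_per_locus)
  if (k_max * motif_step > band_width)
    stopf("allele band too narrow: increase band_width or reduce alleles")
  if (abs(R_base - L_base) < n_loci * band_width)
    stopf("L and R allele bands overlap: move R_base")
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 n_L_only = as.integer(n_L_only), n_R_only = as.integer(n_R_only),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 L_base = as.integer(L_base), R_base = as.integer(R_base),
                 band_width = as.integer(band_width),
                 motif_step = as.integer(motif_step),
                 populations = populations,
                 n_clones = as.integer(n_clones),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate, missing_rate = missing_rate,
                 null_allele_rate = null_allele_rate, null_freq = null_freq,
                 fis_sexual = fis_sexual),
            class = "sim_config")
}

sim_locus_names <- function(cfg) sprintf("loc%02d", seq_len(cfg$n_loci))

sim_band <- function(cfg, species, locus_index) {
  base <- if (species == "L") cfg$L_base else cfg$R_base
  k <- max(cfg$alleles_per_locus)
  base + (locus_index - 1L) * cfg$band_width + cfg$motif_step * seq_len(k)
}

#' Build the allele registry implied by a simulation configuration
#'
#' Loci are laid out with the first \code{n_L_only} amplifying only in the L
#' genome, the next \code{n_R_only} only in the R genome, and the remainder in
#' both; every allele in a species band is registered as specific to that
#' species (bands are disjoint by construction).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return An \code{\link{allele_registry}}.
#' @export
build_registry <- function(cfg) {
  loci <- sim_locus_names(cfg)
  amp <- c(rep("L", cfg$n_L_only), rep("R", cfg$n_R_only),
           rep("LR", cfg$n_loci - cfg$n_L_only - cfg$n_R_only))
  spec <- list()
  for (j in seq_len(cfg$n_loci)) {
    if (grepl("L", amp[j]))
      spec[[length(spec) + 1L]] <- data.frame(
        locus = loci[j], allele = sim_band(cfg, "L", j), specificity = "L",
        stringsAsFactors = FALSE)
    if (grepl("R", amp[j]))
      spec[[length(spec) + 1L]] <- data.frame(
        locus = loci[j], allele = sim_band(cfg, "R", j), specificity = "R",
        stringsAsFactors = FALSE)
  }
  allele_registry(
    data.frame(name = loci, amplifies_in = amp,
               motif_step = rep(cfg$motif_step, cfg$n_loci),
               stringsAsFactors = FALSE),
    if (length(spec)) do.call(rbind, spec) else NULL)
}

# Draw founder allele frequencies for one species over all loci:
# Dirichlet(1) over a random subset of the band, zero at non-amplifying loci.
sim_species_freqs <- function(cfg, species) {
  loci <- sim_locus_names(cfg)
  amp <- c(rep("L", cfg$n_L_only), rep("R", cfg$n_R_only),
           rep("LR", cfg$n_loci - cfg$n_L_only - cfg$n_R_only))
  out <- vector("list", cfg$n_loci)
  names(out) <- loci
  for (j in seq_len(cfg$n_loci)) {
    if (!grepl(species, amp[j])) next
    band <- sim_band(cfg, species, j)
    k <- sample(seq(cfg$alleles_per_locus[1], cfg$alleles_per_locus[2]), 1L)
    k <- min(k, length(band))
    alleles <- sort(sample(band, k))
    w <- stats::rgamma(k, 1, 1)
    out[[j]] <- stats::setNames(w / sum(w), alleles)
  }
  out
}

# Draw one diploid genotype matrix (n x loci, slots a1/a2) from per-locus
# frequencies with inbreeding coefficient F:
# P(hom a) = p_a^2 + F p_a (1 - p_a), P(het ab) = 2 p_a p_b (1 - F).
sim_genotypes <- function(freqs, loci, n, fis) {
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(NULL, loci))
  a2 <- a1
  for (loc in loci) {
    p <- freqs[[loc]]
    if (is.null(p)) next  # locus does not amplify in this species
    alle <- as.integer(names(p))
    x1 <- alle[sample.int(length(p), n, replace = TRUE, prob = p)]
    ibd <- stats::runif(n) < fis
    x2 <- alle[sample.int(length(p), n, replace = TRUE, prob = p)]
    x2[ibd] <- x1[ibd]
    a1[, loc] <- x1
    a2[, loc] <- x2
  }
  list(a1 = a1, a2 = a2)
}

#' Simulate a random-mating sexual population
#'
#' Genotypes are drawn independently per locus from supplied or freshly drawn
#' allele frequencies with the configured inbreeding coefficient
#' \code{fis_sexual}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param species \code{"L"} or \code{"R"}.
#' @param n number of individuals.
#' @param freqs optional per-locus named frequency vectors (as produced
#'   internally); drawn Dirichlet-flat over the species band when omitted.
#' @param population population name for the records.
#' @param id_prefix prefix for individual ids.
#' @return A \code{genotype_dataset} (taxon \code{"LL"} or \code{"RR"}).
#' @export
simulate_sexual_population <- function(cfg, species, n, freqs = NULL,
                                       population = "pop1",
                                       id_prefix = NULL) {
  if (n < 0) stopf("n must be >= 0")
  if (is.null(freqs)) freqs <- sim_species_freqs(cfg, species)
  loci <- sim_locus_names(cfg)
  g <- sim_genotypes(freqs, loci, n, cfg$fis_sexual)
  taxon <- if (species == "L") "LL" else "RR"
  if (is.null(id_prefix)) id_prefix <- paste0(population, "_", taxon)
  sexes <- if (n) rep_len(c("f", "m"), n) else character(0)
  ind <- data.frame(
    id = if (n) sprintf("%s_%03d", id_prefix, seq_len(n)) else character(0),
    population = rep_len(population, n), taxon = rep_len(taxon, n),
    sex = sexes, stringsAsFactors = FALSE)
  genotype_dataset(ind, g$a1, g$a2, build_registry(cfg),
                   data.frame(population = population, system_type = "other",
                              stringsAsFactors = FALSE))
}

# Apply stepwise mutations to a haploid vector: per locus, events ~
# Binomial(generations, rate), each event +/- one motif step.
mutate_haplotype <- function(h, cfg, events_out) {
  loci <- names(h)
  n_mut <- stats::rbinom(length(h), cfg$generations, cfg$mutation_rate)
  for (k in which(n_mut > 0L & !is.na(h))) {
    steps <- sample(c(-1L, 1L), n_mut[k], replace = TRUE) * cfg$motif_step
    h[k] <- h[k] + sum(steps)
    events_out[[length(events_out) + 1L]] <-
      data.frame(locus = loci[k], n_events = n_mut[k],
                 net_shift = sum(steps), stringsAsFactors = FALSE)
  }
  list(h = h, events = events_out)
}

#' Simulate a full hybridogenetic population system
#'
#' Generates every population in \code{cfg$populations}. In an R-E male
#' system, hybrids are all male and carry a frozen clonal L haplotype (one per
#' clone, optionally mutated stepwise along \code{generations} clonal
#' transmissions) plus a recombinant R gamete from the species-wide sexual R
#' pool; RR individuals are sexual. L-E populations are produced by the same
#' engine with the transmitted genome switched (R clonal, L sexual).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A list with elements \code{dataset} (a \code{genotype_dataset}
#'   covering all populations) and \code{truth} (a \code{truth_log}: founding
#'   clone haplotypes, per-individual membership, species allele frequencies,
#'   and the mutation/artifact event log).
#' @export
simulate_re_system <- function(cfg) {
  set.seed(cfg$seed)
  registry <- build_registry(cfg)
  loci <- sim_locus_names(cfg)
  freqs_L <- sim_species_freqs(cfg, "L")
  freqs_R <- sim_species_freqs(cfg, "R")

  draw_founder_haplotype <- function(freqs) {
    h <- stats::setNames(rep(NA_integer_, length(loci)), loci)
    for (loc in loci) {
      p <- freqs[[loc]]
      if (is.null(p)) next
      h[loc] <- as.integer(names(p))[sample.int(length(p), 1L, prob = p)]
    }
    h
  }
  clones_L <- lapply(seq_len(cfg$n_clones), function(i) draw_founder_haplotype(freqs_L))
  clones_R <- lapply(seq_len(cfg$n_clones), function(i) draw_founder_haplotype(freqs_R))
  names(clones_L) <- paste0("cloneL", seq_len(cfg$n_clones))
  names(clones_R) <- paste0("cloneR", seq_len(cfg$n_clones))

  draw_gamete <- function(freqs) {
    h <- stats::setNames(rep(NA_integer_, length(loci)), loci)
    for (loc in loci) {
      p <- freqs[[loc]]
      if (is.null(p)) next
      h[loc] <- as.integer(names(p))[sample.int(length(p), 1L, prob = p)]
    }
    h
  }

  parts <- list()
  membership <- character(0)
  mut_events <- list()
  for (pi in seq_len(nrow(cfg$populations))) {
    pop <- cfg$populations[pi, ]
    set.seed(derive_seed(cfg$seed, pi))
    clonal_genome <- if (pop$system_type == "L-E") "R" else "L"
    # sexual residents
    if (pop$n_RR > 0) {
      g <- sim_genotypes(freqs_R, loci, pop$n_RR, cfg$fis_sexual)
      ind <- data.frame(
        id = sprintf("%s_RR_%03d", pop$name, seq_len(pop$n_RR)),
        population = pop$name, taxon = "RR",
        sex = rep_len(c("f", "m"), pop$n_RR), stringsAsFactors = FALSE)
      parts[[length(parts) + 1L]] <- list(ind = ind, a1 = g$a1, a2 = g$a2)
      membership <- c(membership,
                      stats::setNames(rep("sexual", pop$n_RR), ind$id))
    }
    if (pop$n_LL > 0) {
      g <- sim_genotypes(freqs_L, loci, pop$n_LL, cfg$fis_sexual)
      ind <- data.frame(
        id = sprintf("%s_LL_%03d", pop$name, seq_len(pop$n_LL)),
        population = pop$name, taxon = "LL",
        sex = rep_len(c("f", "m"), pop$n_LL), stringsAsFactors = FALSE)
      parts[[length(parts) + 1L]] <- list(ind = ind, a1 = g$a1, a2 = g$a2)
      membership <- c(membership,
                      stats::setNames(rep("sexual", pop$n_LL), ind$id))
    }
    # hybrids
    n_hyb <- pop$n_hybrid_males + pop$n_hybrid_females
    if (n_hyb > 0) {
      hyb_sex <- c(rep("m", pop$n_hybrid_males), rep("f", pop$n_hybrid_females))
      a1 <- matrix(NA_integer_, n_hyb, length(loci), dimnames = list(NULL, loci))
      a2 <- a1
      ids <- sprintf("%s_RL_%03d", pop$name, seq_len(n_hyb))
      for (i in seq_len(n_hyb)) {
        cl <- ((i - 1L) %% cfg$n_clones) + 1L
        if (clonal_genome == "L") {
          clonal_h <- clones_L[[cl]]
          clone_id <- names(clones_L)[cl]
          sexual_h <- draw_gamete(freqs_R)
        } else {
          clonal_h <- clones_R[[cl]]
          clone_id <- names(clones_R)[cl]
          sexual_h <- draw_gamete(freqs_L)
        }
        mut <- mutate_haplotype(clonal_h, cfg, list())
        clonal_h <- mut$h
        if (length(mut$events)) {
          ev <- do.call(rbind, mut$events)
          ev$id <- ids[i]
          mut_events[[length(mut_events) + 1L]] <- ev
        }
        a1[i, ] <- clonal_h
        a2[i, ] <- sexual_h
        membership <- c(membership, stats::setNames(clone_id, ids[i]))
      }
      ind <- data.frame(id = ids, population = pop$name, taxon = "RL",
                        sex = hyb_sex, stringsAsFactors = FALSE)
      parts[[length(parts) + 1L]] <- list(ind = ind, a1 = a1, a2 = a2)
    }
  }
  ind <- do.call(rbind, lapply(parts, `[[`, "ind"))
  a1 <- do.call(rbind, lapply(parts, `[[`, "a1"))
  a2 <- do.call(rbind, lapply(parts, `[[`, "a2"))
  pops <- data.frame(population = cfg$populations$name,
                     system_type = cfg$populations$system_type,
                     stringsAsFactors = FALSE)
  ds <- genotype_dataset(ind, a1, a2, registry, pops)
  used_clones <- intersect(c(names(clones_L), names(clones_R)), membership)
  truth <- structure(list(
    clone_haplotypes = c(clones_L, clones_R)[used_clones],
    membership = membership,
    freqs_L = freqs_L, freqs_R = freqs_R,
    mutations = if (length(mut_events)) do.call(rbind, mut_events) else
      data.frame(locus = character(0), n_events = integer(0),
                 net_shift = integer(0), id = character(0)),
    artifacts = NULL, seed = cfg$seed
  ), class = "truth_log")
  list(dataset = ds, truth = truth)
}

#' @export
print.truth_log <- function(x, ...) {
  cat("Truth log:", length(x$clone_haplotypes), "clone haplotype(s),",
      sum(x$membership != "sexual"), "clonal individuals,",
      nrow(x$mutations), "mutation events\n")
  invisible(x)
}

#' Inject missingness and null-allele artifacts
#'
#' Whole cells are set missing with probability \code{missing_rate}. Each
#' locus carries a null allele with probability \code{null_allele_rate}; at a
#' null-carrying locus every allele copy independently becomes null with
#' probability \code{null_freq}. Two null copies leave the cell blank; a null
#' paired with a visible allele produces an apparent homozygote for the
#' visible allele. The event log records what was injected.
#'
#' @param sim list \code{(dataset, truth)} from
#'   \code{\link{simulate_re_system}}, or a bare \code{genotype_dataset}.
#' @param cfg a \code{\link{sim_config}}.
#' @param seed optional integer overriding \code{cfg$seed + 1} for the
#'   artifact stream.
#' @return Same shape as the input: list \code{(dataset, truth)} with the
#'   truth log's \code{artifacts} element filled, or a bare dataset.
#' @export
inject_artifacts <- function(sim, cfg, seed = NULL) {
  bare <- inherits(sim, "genotype_dataset")
  ds <- if (bare) sim else sim$dataset
  set.seed(if (is.null(seed)) derive_seed(cfg$seed, 999983L) else as.integer(seed))
  n <- nrow(ds$a1); loci <- loci_of(ds)
  null_loci <- loci[stats::runif(length(loci)) < cfg$null_allele_rate]
  events <- list()
  for (loc in null_loci) {
    null1 <- stats::runif(n) < cfg$null_freq
    null2 <- stats::runif(n) < cfg$null_freq
    # copies only exist where scored; a half-missing cell has one copy at risk
    null1 <- null1 & !is.na(ds$a1[, loc])
    null2 <- null2 & !is.na(ds$a2[, loc])
    blank <- null1 & null2
    one <- xor(null1, null2)
    if (any(blank)) {
      events[[length(events) + 1L]] <- data.frame(
        id = ds$ind$id[blank], locus = loc, event = "null_homozygote",
        stringsAsFactors = FALSE)
      ds$a1[blank, loc] <- NA_integer_
      ds$a2[blank, loc] <- NA_integer_
    }
    if (any(one)) {
      vis <- ifelse(null1[one], ds$a2[one, loc], ds$a1[one, loc])
      ds$a1[one, loc] <- vis
      ds$a2[one, loc] <- vis  # apparent homozygote for the visible allele
      events[[length(events) + 1L]] <- data.frame(
        id = ds$ind$id[one], locus = loc, event = "null_heterozygote",
        stringsAsFactors = FALSE)
    }
  }
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(n * length(loci)) < cfg$missing_rate,
                   n, length(loci))
    hit <- which(drop & !(is.na(ds$a1) & is.na(ds$a2)), arr.ind = TRUE)
    if (nrow(hit)) {
      events[[length(events) + 1L]] <- data.frame(
        id = ds$ind$id[hit[, 1]], locus = loci[hit[, 2]], event = "missing",
        stringsAsFactors = FALSE)
      ds$a1[drop] <- NA_integer_
      ds$a2[drop] <- NA_integer_
    }
  }
  cm <- canon_matrices(ds$a1, ds$a2)
  ds$a1 <- cm$a1; ds$a2 <- cm$a2
  art <- list(
    null_loci = null_loci,
    events = if (length(events)) do.call(rbind, events) else
      data.frame(id = character(0), locus = character(0), event = character(0)))
  if (bare) {
    attr(ds, "artifacts") <- art
    return(ds)
  }
  sim$dataset <- ds
  sim$truth$artifacts <- art
  sim
}
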