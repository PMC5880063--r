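# Fully scored diploid cells at one locus for one population.
locus_cells <- function(ds, locus, population = NULL) {
  keep <- rep(TRUE, nrow(ds$ind))
  if (!is.null(population)) keep <- ds$ind$population == population
  x1 <- ds$a1[keep, locus]; x2 <- ds$a2[keep, locus]
  full <- !is.na(x1) & !is.na(x2)
  blank <- is.na(x1) & is.na(x2)
  list(a1 = x1[full], a2 = x2[full], n_full = sum(full),
       n_blank = sum(blank), n_half = sum(!full & !blank))
}

# log conditional probability (up to the allele-count constant, which is
# invariant under permutation of copies) of a diploid genotype configuration
# given its allele counts, under the multinomial (HWE) genotype model.
hwe_config_stat <- function(a1, a2, code_of) {
  g <- code_of(pmin(a1, a2), pmax(a1, a2))
  counts <- tabulate(g)
  h <- sum(a1 != a2)
  h * log(2) - sum(lgamma(counts + 1))
}

#' Monte-Carlo exact test for Hardy-Weinberg equilibrium at one locus
#'
#' Allele copies are permuted among individuals \code{n_reps} times; the
#' p-value is \code{(1 + #permuted configurations with conditional probability
#' <= observed) / (n_reps + 1)} under the multinomial genotype model given the
#' allele counts. Only fully scored diploid cells enter the test.
#'
#' @param ds a \code{genotype_dataset}.
#' @param locus locus name.
#' @param population population name (\code{NULL} = all individuals).
#' @param n_reps number of permutation replicates (default 10000).
#' @param seed integer seed making the permutation stream reproducible.
#' @return list of class \code{hwe_result}: \code{locus}, \code{population},
#'   \code{p_value}, \code{n_reps}, \code{n} (scored individuals),
#'   \code{h_obs}, \code{h_exp} (unbiased), \code{het_deficit}
#'   (\code{h_exp - h_obs}).
#' @export
hwe_test <- function(ds, locus, population = NULL, n_reps = 10000L, seed = 1L) {
  lc <- locus_cells(ds, locus, population)
  if (lc$n_full < 2L) stopf("need >= 2 scored diploid individuals at %s", locus)
  alle <- c(lc$a1, lc$a2)
  ua <- sort(unique(alle))
  n <- lc$n_full
  p <- as.numeric(table(factor(alle, levels = ua))) / (2 * n)
  h_obs <- mean(lc$a1 != lc$a2)
  h_exp <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  res <- list(locus = locus, population = population %||% "all",
              n_reps = as.integer(n_reps), n = n,
              h_obs = h_obs, h_exp = h_exp, het_deficit = h_exp - h_obs)
  if (length(ua) < 2L) {            # monomorphic: p = 1 by convention
    res$p_value <- 1
    class(res) <- "hwe_result"
    return(res)
  }
  K <- length(ua)
  ai <- match(alle, ua)             # copies as small integers
  code_of <- function(g1, g2) (g1 - 1L) * K + g2
  obs <- hwe_config_stat(ai[seq_len(n)], ai[n + seq_len(n)], code_of)
  set.seed(as.integer(seed))
  le <- 0L
  for (b in seq_len(n_reps)) {
    perm <- sample(ai)
    s <- hwe_config_stat(perm[seq_len(n)], perm[n + seq_len(n)], code_of)
    if (s <= obs + 1e-9) le <- le + 1L
  }
  res$p_value <- (1 + le) / (n_reps + 1)
  class(res) <- "hwe_result"
  res
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE exact test  %s / %s:  p = %.4g  (n = %d, Hobs = %.3f, Hexp = %.3f)\n",
              x$locus, x$population, x$p_value, x$n, x$h_obs, x$h_exp))
  invisible(x)
}

# Observed-data log-likelihood of the HWE-with-null three-class model.
null_model_loglik <- function(n_het_ab, n_hom, n_blank, p, r) {
  ll <- 0
  if (nrow(n_het_ab)) {
    pr <- 2 * p[n_het_ab$i] * p[n_het_ab$j]
    ll <- ll + sum(n_het_ab$n * log(pr))
  }
  if (any(n_hom > 0)) {
    pr <- p^2 + 2 * p * r
    ll <- ll + sum(n_hom[n_hom > 0] * log(pr[n_hom > 0]))
  }
  if (n_blank > 0) ll <- ll + n_blank * log(r^2)
  ll
}

#' Null-allele frequency estimate (maximum likelihood, blanks as data)
#'
#' Fits the HWE-with-null model over the three observable classes — visible
#' heterozygote (expected 2 p_i p_j), visible homozygote for allele i
#' (expected p_i^2 + 2 p_i r), blank cell (expected r^2) with
#' \code{sum(p) = 1 - r} — by EM, treating the null as an extra allele and
#' nonamplified (blank) cells as null homozygotes, i.e. as data. Half-scored
#' cells are excluded.
#'
#' @param ds a \code{genotype_dataset}.
#' @param locus locus name.
#' @param population population name (\code{NULL} = all individuals).
#' @param min_n minimum scored-or-blank individuals required (default 10).
#' @param tol EM convergence tolerance on r (default 1e-8).
#' @return list of class \code{null_allele_estimate}: \code{locus},
#'   \code{population}, \code{r_hat}, \code{blanks_observed}, \code{n},
#'   \code{freqs} (visible-allele ML frequencies, summing to 1 - r_hat),
#'   \code{method}.
#' @export
estimate_null_allele_freq <- function(ds, locus, population = NULL,
                                      min_n = 10L, tol = 1e-8) {
  lc <- locus_cells(ds, locus, population)
  n_tot <- lc$n_full + lc$n_blank
  if (n_tot < min_n)
    stopf("locus %s scored in fewer than %d individuals", locus, min_n)
  mk <- function(r, freqs) {
    structure(list(locus = locus, population = population %||% "all",
                   r_hat = r, blanks_observed = lc$n_blank, n = n_tot,
                   freqs = freqs, method = "ml_three_class_em"),
              class = "null_allele_estimate")
  }
  if (lc$n_full == 0L) return(mk(1, numeric(0)))  # all blank
  ua <- sort(unique(c(lc$a1, lc$a2)))
  K <- length(ua)
  i1 <- match(lc$a1, ua); i2 <- match(lc$a2, ua)
  hom <- i1 == i2
  n_hom <- tabulate(i1[hom], K)
  het_tab <- if (any(!hom)) {
    agg <- stats::aggregate(list(n = rep(1L, sum(!hom))),
                            by = list(i = i1[!hom], j = i2[!hom]), FUN = sum)
    agg
  } else data.frame(i = integer(0), j = integer(0), n = integer(0))
  copy_counts <- tabulate(c(i1, i2), K)
  # init: visible freqs scaled by (1 - r0)
  r <- max(sqrt(lc$n_blank / n_tot), 0.05)
  r <- min(r, 0.95)
  p <- copy_counts / sum(copy_counts) * (1 - r)
  for (it in seq_len(20000L)) {
    z <- ifelse(n_hom > 0, n_hom * (2 * r) / (p + 2 * r), 0)  # null hets hidden in homs
    c_vis <- copy_counts - z           # each hidden null het loses one visible copy
    c_null <- sum(z) + 2 * lc$n_blank
    total <- sum(c_vis) + c_null       # = 2 * n_tot
    r_new <- c_null / total
    p <- c_vis / total
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  # boundary polish: prefer r = 0 when it explains the data as well
  p0 <- copy_counts / sum(copy_counts)
  ll0 <- if (lc$n_blank == 0L)
    null_model_loglik(het_tab, n_hom, 0L, p0, 0) else -Inf
  ll_hat <- null_model_loglik(het_tab, n_hom, lc$n_blank, p, r)
  if (ll0 >= ll_hat - 1e-6) {
    r <- 0; p <- p0
  }
  if (r < 1e-6) { r <- 0; p <- p / sum(p) }
  mk(r, stats::setNames(p, ua))
}

#' @export
print.null_allele_estimate <- function(x, ...) {
  cat(sprintf("Null-allele estimate  %s / %s:  r = %.4f  (%d blanks / %d)\n",
              x$locus, x$population, x$r_hat, x$blanks_observed, x$n))
  invisible(x)
}

#' Screen every locus x population for HWE departure and null alleles
#'
#' @param ds a \code{genotype_dataset}.
#' @param n_reps permutation replicates for the HWE test.
#' @param seed integer seed.
#' @param r_threshold null-frequency flag threshold (default 0.05).
#' @param alpha HWE p-value flag threshold (default 0.05).
#' @param min_n minimum individuals per cell of the screen (default 10).
#' @return data.frame of class \code{quality_screen}: one row per
#'   (locus, population) with \code{p_value}, \code{h_obs}, \code{h_exp},
#'   \code{r_hat}, \code{flagged} (TRUE when \code{r_hat >= r_threshold} and
#'   \code{p_value < alpha} with a heterozygote deficit). The fitted
#'   estimates are attached as attribute \code{estimates} for
#'   \code{\link{apply_null_correction}}.
#' @export
quality_screen <- function(ds, n_reps = 10000L, seed = 1L,
                           r_threshold = 0.05, alpha = 0.05, min_n = 10L) {
  rows <- list(); ests <- list()
  k <- 0L
  for (pop in ds$populations$population) {
    for (loc in loci_of(ds)) {
      lc <- locus_cells(ds, loc, pop)
      if (lc$n_full + lc$n_blank < min_n || lc$n_full < 2L) next
      k <- k + 1L
      hw <- hwe_test(ds, loc, pop, n_reps = n_reps,
                     seed = derive_seed(seed, k))
      est <- estimate_null_allele_freq(ds, loc, pop, min_n = min_n)
      flagged <- est$r_hat >= r_threshold && hw$p_value < alpha &&
        hw$het_deficit > 0
      rows[[k]] <- data.frame(
        locus = loc, population = pop, n = hw$n, p_value = hw$p_value,
        h_obs = hw$h_obs, h_exp = hw$h_exp, r_hat = est$r_hat,
        flagged = flagged, stringsAsFactors = FALSE)
      ests[[k]] <- est
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(0), population = character(0), n = integer(0),
               p_value = numeric(0), h_obs = numeric(0), h_exp = numeric(0),
               r_hat = numeric(0), flagged = logical(0))
  attr(out, "estimates") <- ests
  class(out) <- c("quality_screen", "data.frame")
  out
}

#' Correct a dataset for null alleles
#'
#' At each flagged (locus, population): blank cells are recoded as homozygous
#' for a reserved null allele state, and each apparent homozygote for a
#' visible allele a is reassigned to the (a, null) heterozygote with the
#' fitted posterior probability \code{2 r / (p_a + 2 r)} (seeded), so the
#' corrected data follow the fitted HWE-with-null model with the null allele
#' visible at frequency r. The correction is idempotent: already-corrected
#' (locus, population) pairs are skipped, as are cells already carrying the
#' null state.
#'
#' @param ds a \code{genotype_dataset}.
#' @param estimates list of \code{null_allele_estimate} objects (e.g. the
#'   \code{estimates} attribute of \code{\link{quality_screen}}), or a
#'   \code{quality_screen} result, in which case only flagged rows are used.
#' @param threshold only estimates with \code{r_hat >= threshold} are applied
#'   (default 0.05); must lie in [0, 1].
#' @param seed integer seed for the posterior reassignment.
#' @return The corrected \code{genotype_dataset}; attribute
#'   \code{null_corrections} records (locus, population, r_hat).
#' @export
apply_null_correction <- function(ds, estimates, threshold = 0.05, seed = 1L) {
  if (threshold < 0 || threshold > 1) stopf("threshold outside [0, 1]")
  if (inherits(estimates, "quality_screen")) {
    flagged <- estimates$flagged
    estimates <- attr(estimates, "estimates")[flagged]
  }
  done <- attr(ds, "null_corrections")
  if (is.null(done))
    done <- data.frame(locus = character(0), population = character(0),
                       r_hat = numeric(0), stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  for (est in estimates) {
    if (est$r_hat < threshold) next
    if (any(done$locus == est$locus & done$population == est$population)) next
    keep <- if (est$population == "all") rep(TRUE, nrow(ds$ind))
            else ds$ind$population == est$population
    loc <- est$locus
    x1 <- ds$a1[, loc]; x2 <- ds$a2[, loc]
    blank <- keep & is.na(x1) & is.na(x2)
    x1[blank] <- NULL_ALLELE; x2[blank] <- NULL_ALLELE
    hom <- keep & !is.na(x1) & !is.na(x2) & x1 == x2 & x1 != NULL_ALLELE
    if (any(hom) && est$r_hat > 0) {
      p_a <- est$freqs[as.character(x1[hom])]
      p_a[is.na(p_a)] <- min(est$freqs)  # allele unseen by the fit
      post <- 2 * est$r_hat / (p_a + 2 * est$r_hat)
      toss <- stats::runif(sum(hom)) < post
      x2[which(hom)[toss]] <- NULL_ALLELE
    }
    ds$a1[, loc] <- x1; ds$a2[, loc] <- x2
    done <- rbind(done, data.frame(locus = loc, population = est$population,
                                   r_hat = est$r_hat, stringsAsFactors = FALSE))
  }
  cm <- canon_matrices(ds$a1, ds$a2)
  ds$a1 <- cm$a1; ds$a2 <- cm$a2
  attr(ds, "null_corrections") <- done
  ds
}
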