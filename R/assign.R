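#' Assign a taxon from species-diagnostic alleles
#'
#' Each locus carrying at least one species-classified allele is classified by
#' its composition: alleles of only one species give \code{LL} or \code{RR},
#' one of each gives \code{RL}. The call is the majority class over
#' informative loci; support is the agreeing fraction. Sex never informs the
#' call.
#'
#' @param ds a \code{genotype_dataset}.
#' @param min_support calls with support below this fraction are reported as
#'   \code{ambiguous} (default 0.75).
#' @return data.frame of class \code{taxon_calls}: \code{id}, \code{call},
#'   \code{support}, \code{n_informative}, \code{discordant_loci}
#'   (comma-separated).
#' @export
assign_taxon <- function(ds, min_support = 0.75) {
  loci <- loci_of(ds)
  reg <- ds$registry
  out <- data.frame(id = ds$ind$id, call = "ambiguous", support = 0,
                    n_informative = 0L, discordant_loci = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ds$ind))) {
    classes <- character(0)
    class_locus <- character(0)
    for (loc in loci) {
      alle <- stats::na.omit(c(ds$a1[i, loc], ds$a2[i, loc]))
      if (!length(alle)) next
      sp <- allele_specificity(reg, loc, alle)
      has_L <- any(sp == "L"); has_R <- any(sp == "R")
      cls <- if (has_L && has_R) "RL" else if (has_L) "LL"
             else if (has_R) "RR" else NA_character_
      if (is.na(cls)) next  # no species-classified allele: uninformative
      classes <- c(classes, cls)
      class_locus <- c(class_locus, loc)
    }
    if (!length(classes)) next  # stays ambiguous, support 0
    tab <- sort(table(classes), decreasing = TRUE)
    # deterministic tie-break: RL > LL > RR among equal counts
    best_n <- tab[1]
    cands <- names(tab)[tab == best_n]
    call <- intersect(c("RL", "LL", "RR"), cands)[1]
    support <- sum(classes == call) / length(classes)
    out$n_informative[i] <- length(classes)
    out$support[i] <- support
    out$discordant_loci[i] <- paste(class_locus[classes != call], collapse = ",")
    out$call[i] <- if (support < min_support) "ambiguous" else call
  }
  class(out) <- c("taxon_calls", "data.frame")
  out
}

#' Parental allele-frequency tables from reference individuals
#'
#' Frequencies per locus from the scored allele copies of the given taxon,
#' with a pseudo-count added to every allele registered for that species (and
#' to shared/nonspecific alleles), so that downstream likelihoods stay finite.
#'
#' @param ds a \code{genotype_dataset}.
#' @param taxon \code{"LL"} or \code{"RR"}.
#' @param eps pseudo-count per registered allele; default \code{0.5 / (2N)}
#'   where N is the number of reference individuals.
#' @return named list: per locus, a named frequency vector summing to 1.
#' @export
reference_freqs <- function(ds, taxon, eps = NULL) {
  keep <- ds$ind$taxon == taxon
  if (!any(keep)) stopf("no reference individuals with taxon %s", taxon)
  n_ref <- sum(keep)
  if (is.null(eps)) eps <- 0.5 / (2 * n_ref)
  species <- if (taxon == "LL") "L" else "R"
  loci <- loci_of(ds)
  out <- vector("list", length(loci)); names(out) <- loci
  for (loc in loci) {
    sp <- ds$registry$spec
    reg_alle <- sp$allele[sp$locus == loc &
                          sp$specificity %in% c(species, "shared", "nonspecific")]
    obs <- stats::na.omit(c(ds$a1[keep, loc], ds$a2[keep, loc]))
    alle <- sort(unique(c(reg_alle, obs)))
    if (!length(alle)) { out[[loc]] <- stats::setNames(numeric(0), character(0)); next }
    counts <- stats::setNames(rep(eps, length(alle)), alle)
    if (length(obs)) {
      t0 <- table(obs)
      counts[names(t0)] <- counts[names(t0)] + as.numeric(t0)
    }
    out[[loc]] <- counts / sum(counts)
  }
  out
}

#' Supervised hybrid-index (admixture) estimate for one individual
#'
#' Maximizes, over the ancestry fraction q in [0, 1], the log-likelihood
#' \deqn{\sum_a \log(q f_R(a) + (1-q) f_L(a))}
#' summed over the individual's scored allele copies, where f_L and f_R are
#' parental allele-frequency tables (see \code{\link{reference_freqs}}).
#' The likelihood is concave in q, solved by 1-D optimization to 1e-6.
#'
#' @param ind_id individual id in \code{ds}.
#' @param ds a \code{genotype_dataset}.
#' @param freqs_L,freqs_R parental frequency tables (per-locus named vectors).
#' @return one-row data.frame: \code{id}, \code{q} (fraction of ancestry from
#'   the R gene pool), \code{loglik}, \code{n_alleles_used}, \code{flat}
#'   (TRUE when the likelihood does not depend on q).
#' @export
estimate_admixture <- function(ind_id, ds, freqs_L, freqs_R) {
  if (!length(freqs_L) || !length(freqs_R))
    stopf("empty parental frequency table")
  i <- match(ind_id, ds$ind$id)
  if (is.na(i)) stopf("unknown individual id %s", ind_id)
  fL <- numeric(0); fR <- numeric(0)
  for (loc in loci_of(ds)) {
    alle <- stats::na.omit(c(ds$a1[i, loc], ds$a2[i, loc]))
    for (a in alle) {
      l <- unname(freqs_L[[loc]][as.character(a)])
      r <- unname(freqs_R[[loc]][as.character(a)])
      if (is.na(l) || is.null(l)) l <- 0
      if (is.na(r) || is.null(r)) r <- 0
      if (l == 0 && r == 0) next  # allele absent from both tables: no signal
      fL <- c(fL, l); fR <- c(fR, r)
    }
  }
  n_used <- length(fL)
  if (n_used == 0L)
    return(data.frame(id = ind_id, q = NA_real_, loglik = NA_real_,
                      n_alleles_used = 0L, flat = TRUE,
                      stringsAsFactors = FALSE))
  ll <- function(q) sum(log(q * fR + (1 - q) * fL))
  flat <- all(abs(fR - fL) < .Machine$double.eps * pmax(fR, fL) * 4)
  if (flat) {
    q_hat <- 0.5
  } else {
    opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE,
                           tol = 1e-8)
    q_hat <- opt$maximum
    # concave in q: still compare against the boundaries explicitly
    cand <- c(0, q_hat, 1)
    vals <- vapply(cand, ll, numeric(1))
    q_hat <- cand[which.max(vals)]
    if (q_hat < 1e-6) q_hat <- 0
    if (q_hat > 1 - 1e-6) q_hat <- 1
  }
  data.frame(id = ind_id, q = q_hat, loglik = ll(q_hat),
             n_alleles_used = n_used, flat = flat, stringsAsFactors = FALSE)
}

#' Hybrid-index estimates for every individual in a dataset
#'
#' @param ds a \code{genotype_dataset}.
#' @param freqs_L,freqs_R parental frequency tables; estimated from the
#'   dataset's own LL/RR individuals when omitted.
#' @return data.frame, one row per individual (see
#'   \code{\link{estimate_admixture}}).
#' @export
admixture_table <- function(ds, freqs_L = NULL, freqs_R = NULL) {
  if (is.null(freqs_L)) freqs_L <- reference_freqs(ds, "LL")
  if (is.null(freqs_R)) freqs_R <- reference_freqs(ds, "RR")
  do.call(rbind, lapply(ds$ind$id, estimate_admixture, ds = ds,
                        freqs_L = freqs_L, freqs_R = freqs_R))
}
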