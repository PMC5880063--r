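#' Allele pools of sympatric sexual populations
#'
#' For each genome (L from LL individuals, R from RR individuals) and each
#' locus, the set of alleles observed in sexual individuals — per population
#' by default, or system-wide.
#'
#' @param ds a \code{genotype_dataset}.
#' @param scope \code{"population"} (default) or \code{"system"}.
#' @return nested list: \code{pool[[population]][[genome]][[locus]]} = integer
#'   vector of alleles (with \code{scope = "system"} the same pool is
#'   replicated for every population).
#' @export
sympatric_pools <- function(ds, scope = c("population", "system")) {
  scope <- match.arg(scope)
  loci <- loci_of(ds)
  pops <- ds$populations$population
  pool_for <- function(rows) {
    lapply(c(L = "LL", R = "RR"), function(tx) {
      keep <- rows & ds$ind$taxon == tx
      stats::setNames(lapply(loci, function(loc) {
        sort(unique(stats::na.omit(c(ds$a1[keep, loc], ds$a2[keep, loc]))))
      }), loci)
    })
  }
  if (scope == "system") {
    p <- pool_for(rep(TRUE, nrow(ds$ind)))
    return(stats::setNames(rep(list(p), length(pops)), pops))
  }
  stats::setNames(lapply(pops, function(pp) pool_for(ds$ind$population == pp)),
                  pops)
}

# Route the scored alleles of one cell to the two parental genomes.
# Returns list(L=, R=, resolution=, conflict=, violation=).
route_cell <- function(alleles, specificities, amp, poolL, poolR) {
  res <- list(L = NA_integer_, R = NA_integer_, resolution = "missing",
              conflict = FALSE, violation = FALSE)
  alleles <- alleles[!is.na(alleles)]
  if (!length(alleles)) return(res)
  sp <- specificities[seq_along(alleles)]
  # single-genome locus: everything belongs to the amplifying genome
  if (amp %in% c("L", "R")) {
    if (length(unique(alleles)) > 1L) {
      res$conflict <- TRUE; res$resolution <- "unresolved"
    } else {
      res[[amp]] <- alleles[1]
      res$resolution <- "specific"
    }
    return(res)
  }
  is_L <- sp == "L"; is_R <- sp == "R"
  idx_L <- which(is_L); idx_R <- which(is_R)
  if (length(idx_L) > 1L || length(idx_R) > 1L) {
    # two alleles classified to the same genome (unless a true duplicate)
    if (length(unique(alleles[idx_L])) > 1L ||
        length(unique(alleles[idx_R])) > 1L) {
      res$conflict <- TRUE; res$resolution <- "unresolved"
      return(res)
    }
  }
  in_pool <- function(a, pool) length(pool) > 0L && a %in% pool
  if (length(idx_L) && length(idx_R)) {
    res$L <- alleles[idx_L[1]]; res$R <- alleles[idx_R[1]]
    res$resolution <- "specific"
  } else if (length(idx_L) || length(idx_R)) {
    g <- if (length(idx_L)) "L" else "R"
    other_g <- if (g == "L") "R" else "L"
    gi <- c(idx_L, idx_R)[1]
    res[[g]] <- alleles[gi]
    res$resolution <- "specific"
    rest <- alleles[-gi]
    if (length(rest)) {
      pool <- if (other_g == "L") poolL else poolR
      if (in_pool(rest[1], pool)) {
        res[[other_g]] <- rest[1]
        res$resolution <- "pool-resolved"
      } else {
        res$resolution <- "unresolved"  # classified allele kept, partner unplaced
      }
    }
  } else {
    # no species-classified allele: pool membership must decide
    memL <- vapply(alleles, in_pool, logical(1), poolL)
    memR <- vapply(alleles, in_pool, logical(1), poolR)
    if (length(alleles) == 1L) {
      if (memL[1] && !memR[1]) { res$L <- alleles[1]; res$resolution <- "pool-resolved" }
      else if (memR[1] && !memL[1]) { res$R <- alleles[1]; res$resolution <- "pool-resolved" }
      else res$resolution <- "unresolved"
    } else {
      ok1 <- memL[1] && !memR[1] && memR[2] && !memL[2]
      ok2 <- memR[1] && !memL[1] && memL[2] && !memR[2]
      if (ok1) { res$L <- alleles[1]; res$R <- alleles[2]; res$resolution <- "pool-resolved" }
      else if (ok2) { res$R <- alleles[1]; res$L <- alleles[2]; res$resolution <- "pool-resolved" }
      else res$resolution <- "unresolved"  # both shared and ambiguous: never guessed
    }
  }
  res
}

#' Partition hybrid genotypes into parental haploid subgenomes
#'
#' For every hybrid (taxon \code{RL}) the diploid genotype is split, locus by
#' locus, into an L and an R haploid allele using the registry's species
#' specificities; an allele without species classification is routed to the
#' remaining genome only when it occurs in the sympatric sexual pool of that
#' genome's species (resolution \code{pool-resolved}), otherwise the locus is
#' left unresolved and surfaced, never imputed. An allele routed to the
#' sexually inherited genome that is absent from the sympatric sexual pool is
#' flagged as a violation.
#'
#' @param ds a \code{genotype_dataset}.
#' @param pools sympatric pools from \code{\link{sympatric_pools}}; computed
#'   from \code{ds} (population scope) when omitted.
#' @param clonal_genome \code{"L"} (R-E male system, default) or \code{"R"};
#'   labels which output is the clonally transmitted genome and which genome
#'   is checked against the sexual pool. Routing never assumes clonality.
#' @param individuals optional subset of hybrid ids.
#' @return list of class \code{partition_result}: \code{L}, \code{R}
#'   (each a \code{subgenome_set}: \code{ind}, haploid allele matrix \code{h},
#'   resolution matrix) and \code{report} (per-individual counts of
#'   specific / pool-resolved / unresolved loci plus conflicts and pool
#'   violations).
#' @export
partition_hybrids <- function(ds, pools = NULL, clonal_genome = c("L", "R"),
                              individuals = NULL) {
  clonal_genome <- match.arg(clonal_genome)
  sexual_genome <- if (clonal_genome == "L") "R" else "L"
  if (is.null(pools)) pools <- sympatric_pools(ds)
  keep <- ds$ind$taxon == "RL"
  if (!is.null(individuals)) keep <- keep & ds$ind$id %in% individuals
  idx <- which(keep)
  if (!length(idx)) stopf("no hybrid (RL) individuals to partition")
  loci <- loci_of(ds)
  reg <- ds$registry
  amp <- stats::setNames(reg$loci$amplifies_in[match(loci, reg$loci$name)], loci)
  hL <- matrix(NA_integer_, length(idx), length(loci),
               dimnames = list(ds$ind$id[idx], loci))
  hR <- hL
  resol <- matrix("missing", length(idx), length(loci),
                  dimnames = list(ds$ind$id[idx], loci))
  rep_rows <- list()
  for (k in seq_along(idx)) {
    i <- idx[k]
    pop <- ds$ind$population[i]
    pp <- pools[[pop]]
    n_conflict <- 0L; violations <- character(0)
    for (loc in loci) {
      alle <- c(ds$a1[i, loc], ds$a2[i, loc])
      sp <- allele_specificity(reg, loc, alle)
      sp[is.na(sp)] <- "missing"
      r <- route_cell(alle, sp, amp[[loc]],
                      pp$L[[loc]], pp$R[[loc]])
      hL[k, loc] <- r$L
      hR[k, loc] <- r$R
      resol[k, loc] <- r$resolution
      if (r$conflict) n_conflict <- n_conflict + 1L
      # the sexually inherited allele must occur in the sympatric sexual pool
      sex_allele <- if (sexual_genome == "L") r$L else r$R
      if (!is.na(sex_allele)) {
        pool <- if (sexual_genome == "L") pp$L[[loc]] else pp$R[[loc]]
        if (length(pool) > 0L && !(sex_allele %in% pool))
          violations <- c(violations, loc)
      }
    }
    counts <- table(factor(resol[k, ],
                           levels = c("specific", "pool-resolved",
                                      "unresolved", "missing")))
    rep_rows[[k]] <- data.frame(
      id = ds$ind$id[i], population = pop,
      specific = counts[["specific"]],
      pool_resolved = counts[["pool-resolved"]],
      unresolved = counts[["unresolved"]],
      missing = counts[["missing"]],
      conflicts = n_conflict,
      violations = paste(violations, collapse = ","),
      stringsAsFactors = FALSE)
  }
  ind <- ds$ind[idx, c("id", "population", "taxon", "sex"), drop = FALSE]
  mk <- function(h, genome) {
    structure(list(ind = ind, h = h, resolution = resol, genome = genome,
                   registry = reg),
              class = "subgenome_set")
  }
  structure(list(L = mk(hL, "L"), R = mk(hR, "R"),
                 report = do.call(rbind, rep_rows),
                 clonal_genome = clonal_genome),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Partition of", nrow(x$report), "hybrids (clonal genome:",
      x$clonal_genome, ")\n")
  cat("  loci specific:", sum(x$report$specific),
      " pool-resolved:", sum(x$report$pool_resolved),
      " unresolved:", sum(x$report$unresolved),
      " missing:", sum(x$report$missing), "\n")
  nv <- sum(nzchar(x$report$violations))
  cat("  individuals with pool violations:", nv, "\n")
  invisible(x)
}

#' @export
print.subgenome_set <- function(x, ...) {
  cat("Subgenome haplotypes:", nrow(x$h), "individuals x", ncol(x$h),
      "loci (genome", x$genome, ")\n")
  invisible(x)
}

#' Re-code haploid subgenomes as diploid records
#'
#' Diploid-only statistics require a diploid coding of haploid subgenomes.
#' \code{mode = "missing-partner"} writes (allele, missing) per locus (for
#' multilocus match tools and summaries); \code{mode = "self-double"} writes
#' (allele, allele) (for clonality statistics, where the self-doubling
#' identity makes P_GEN reduce to the haploid product of allele frequencies).
#'
#' @param h a \code{subgenome_set} from \code{\link{partition_hybrids}}.
#' @param mode \code{"missing-partner"} or \code{"self-double"}.
#' @param id_suffix appended to individual ids (default "_L" / "_R" by
#'   genome) so pooled datasets keep unique ids.
#' @return A \code{genotype_dataset} with taxon \code{"RL"}.
#' @export
double_haploid <- function(h, mode = c("missing-partner", "self-double"),
                           id_suffix = NULL) {
  mode <- match.arg(mode)
  if (is.null(id_suffix)) id_suffix <- paste0("_", h$genome)
  a1 <- h$h
  a2 <- if (mode == "self-double") h$h else
    matrix(NA_integer_, nrow(h$h), ncol(h$h), dimnames = dimnames(h$h))
  ind <- h$ind
  ind$id <- paste0(ind$id, id_suffix)
  rownames(a1) <- rownames(a2) <- ind$id
  genotype_dataset(ind, a1, a2, h$registry,
                   data.frame(population = unique(ind$population),
                              system_type = "other", stringsAsFactors = FALSE))
}
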