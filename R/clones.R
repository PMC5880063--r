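# --- record-set accessor -----------------------------------------------------
# clones-module operations accept either a genotype_dataset (diploid-coded,
# possibly containing doubled subgenomes) or a subgenome_set (haploid).
as_records <- function(x) {
  if (inherits(x, "genotype_dataset"))
    return(list(ind = x$ind, a1 = x$a1, a2 = x$a2, haploid = FALSE))
  if (inherits(x, "subgenome_set")) {
    a2 <- matrix(NA_integer_, nrow(x$h), ncol(x$h), dimnames = dimnames(x$h))
    return(list(ind = x$ind, a1 = x$h, a2 = a2, haploid = TRUE))
  }
  stopf("records must be a genotype_dataset or subgenome_set")
}

# --- MLG indexing ------------------------------------------------------------

#' Index exact multilocus genotypes
#'
#' Groups records by exact state equality of the canonical per-locus genotype
#' vector (sorted allele pairs; a missing slot is part of the state, so
#' records differing only at loci where either is missing form distinct exact
#' MLGs — merging across missing data is \code{\link{merge_mlgs}}).
#'
#' @param x a \code{genotype_dataset} or \code{subgenome_set}.
#' @return list of class \code{mlg_index}: \code{key} (character vector,
#'   sorted), \code{members} (list of id vectors), \code{a1}, \code{a2}
#'   (state matrices, one row per distinct MLG), \code{ind} (the records'
#'   metadata), \code{haploid}.
#' @export
index_mlgs <- function(x) {
  r <- as_records(x)
  keys <- mlg_keys(r$a1, r$a2)
  ord <- order(keys)
  ukeys <- sort(unique(keys))
  members <- split(r$ind$id, factor(keys, levels = ukeys))
  first <- match(ukeys, keys)
  structure(list(key = ukeys, members = members,
                 a1 = r$a1[first, , drop = FALSE],
                 a2 = r$a2[first, , drop = FALSE],
                 ind = r$ind, haploid = r$haploid),
            class = "mlg_index")
}

#' @export
print.mlg_index <- function(x, ...) {
  sizes <- lengths(x$members)
  cat("MLG index:", length(x$key), "distinct MLGs among", sum(sizes),
      "records; largest class:", max(sizes), "\n")
  invisible(x)
}

# --- compatibility / consensus ----------------------------------------------
# Two cells are compatible iff the scored multiset of one is a sub-multiset of
# the other (nested); within a clique this gives a unique most-complete
# consensus per locus. A locus is co-scored when both cells carry >= 1 scored
# allele.
cell_scored <- function(a1, a2) {
  v <- c(a1, a2)
  sort(v[!is.na(v)])
}

cells_nested <- function(x, y) {
  # x, y: sorted scored vectors
  if (length(x) > length(y)) { tmp <- x; x <- y; y <- tmp }
  if (length(x) == 0L) return(TRUE)
  if (length(x) == length(y)) return(identical(x, y))
  x[1] %in% y  # |x| = 1, |y| = 2
}

mlgs_compatible <- function(a1x, a2x, a1y, a2y, min_shared_loci) {
  shared <- 0L
  for (j in seq_along(a1x)) {
    sx <- cell_scored(a1x[j], a2x[j])
    sy <- cell_scored(a1y[j], a2y[j])
    if (length(sx) && length(sy)) {
      if (!cells_nested(sx, sy)) return(FALSE)
      shared <- shared + 1L
    }
  }
  shared >= min_shared_loci
}

consensus_of <- function(a1, a2, rows) {
  c1 <- a1[rows[1], ]; c2 <- a2[rows[1], ]
  for (i in rows[-1]) {
    for (j in seq_along(c1)) {
      n_old <- sum(!is.na(c(c1[j], c2[j])))
      n_new <- sum(!is.na(c(a1[i, j], a2[i, j])))
      if (n_new > n_old) { c1[j] <- a1[i, j]; c2[j] <- a2[i, j] }
    }
  }
  list(a1 = c1, a2 = c2)
}

#' Merge exact MLGs whose differences are only missing data
#'
#' Builds the compatibility graph over distinct MLGs (two MLGs are compatible
#' iff they conflict at no co-scored locus and share at least
#' \code{min_shared_loci} co-scored loci). A connected component is merged
#' into one clone only when it is a clique with a single conflict-free
#' consensus; otherwise the component is split into maximal cliques, chosen
#' greedily by largest total membership, ties by lexicographically smallest
#' consensus key (the decision is logged in the result). Transitive merging
#' through an intermediate MLG is deliberately rejected.
#'
#' @param idx an \code{mlg_index}.
#' @param min_shared_loci minimum co-scored loci for compatibility
#'   (default 5), preventing vacuous merges of mostly-missing records.
#' @return list of class \code{clone_table}: per merged clone \code{clone_id},
#'   \code{member_mlgs} (exact keys), \code{members} (ids),
#'   \code{consensus_a1}, \code{consensus_a2}, \code{consensus_key}; plus
#'   \code{split_log} describing non-clique components that had to be split.
#' @export
merge_mlgs <- function(idx, min_shared_loci = 5L) {
  m <- length(idx$key)
  if (m == 0L)
    return(structure(list(clones = list(), split_log = character(0)),
                     class = "clone_table"))
  adj <- matrix(FALSE, m, m)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      ok <- mlgs_compatible(idx$a1[i, ], idx$a2[i, ],
                            idx$a1[j, ], idx$a2[j, ], min_shared_loci)
      adj[i, j] <- adj[j, i] <- ok
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clones <- list()
  split_log <- character(0)
  clique_consensus_key <- function(rows) {
    cs <- consensus_of(idx$a1, idx$a2, rows)
    mlg_key_one(cs$a1, if (idx$haploid) NULL else cs$a2)
  }
  emit <- function(rows) {
    cs <- consensus_of(idx$a1, idx$a2, rows)
    # invariant check: consensus conflicts with no member at any co-scored locus
    for (i in rows)
      stopifnot(mlgs_compatible(cs$a1, cs$a2, idx$a1[i, ], idx$a2[i, ], 0L))
    list(member_mlgs = idx$key[rows],
         members = unlist(idx$members[rows], use.names = FALSE),
         consensus_a1 = cs$a1, consensus_a2 = cs$a2,
         consensus_key = mlg_key_one(cs$a1, if (idx$haploid) NULL else cs$a2))
  }
  for (cid in seq_len(max(comp))) {
    rows <- which(comp == cid)
    if (length(rows) == 1L) { clones[[length(clones) + 1L]] <- emit(rows); next }
    sub <- adj[rows, rows, drop = FALSE]
    is_clique <- all(sub[upper.tri(sub)])
    if (is_clique) { clones[[length(clones) + 1L]] <- emit(rows); next }
    # split into maximal cliques: greedy cover, largest membership first,
    # then lexicographic consensus key
    remaining <- rows
    split_log <- c(split_log, sprintf(
      "component {%s} is not a clique; split into maximal cliques",
      paste(idx$key[rows], collapse = " | ")))
    while (length(remaining)) {
      if (length(remaining) == 1L) {
        clones[[length(clones) + 1L]] <- emit(remaining)
        break
      }
      subg <- igraph::induced_subgraph(g, remaining)
      cl <- igraph::max_cliques(subg)
      cand <- lapply(cl, function(v) remaining[as.integer(v)])
      size <- vapply(cand, function(v)
        sum(lengths(idx$members[v])), integer(1))
      best <- which(size == max(size))
      if (length(best) > 1L) {
        keys <- vapply(cand[best], clique_consensus_key, character(1))
        best <- best[order(keys)[1]]
      }
      pick <- cand[[best[1]]]
      clones[[length(clones) + 1L]] <- emit(sort(pick))
      remaining <- setdiff(remaining, pick)
    }
  }
  # deterministic output order: by consensus key
  keys <- vapply(clones, `[[`, character(1), "consensus_key")
  clones <- clones[order(keys)]
  for (i in seq_along(clones)) clones[[i]]$clone_id <- sprintf("MLG%03d", i)
  structure(list(clones = clones, split_log = split_log,
                 ind = idx$ind, haploid = idx$haploid,
                 loci = colnames(idx$a1)),
            class = "clone_table")
}

#' @export
print.clone_table <- function(x, ...) {
  sizes <- vapply(x$clones, function(cl) length(cl$members), integer(1))
  cat("Clone table:", length(x$clones), "merged MLGs; sizes:",
      paste(sort(sizes, decreasing = TRUE), collapse = ", "), "\n")
  if (length(x$split_log)) cat("  splits:", length(x$split_log), "\n")
  invisible(x)
}

# --- round-robin allele frequencies and F_IS --------------------------------

#' Round-robin allele frequencies at one locus
#'
#' Sub-MLGs are defined over all loci except \code{locus}; one representative
#' per distinct sub-MLG (the first in record order) contributes its scored
#' allele copies at \code{locus}. This removes clonal pseudo-replication from
#' frequency estimates.
#'
#' @param x a \code{genotype_dataset} or \code{subgenome_set}.
#' @param locus locus name.
#' @param eps pseudo-count added for every allele observed at \code{locus}
#'   in the full record set (default 0: plain representative frequencies).
#' @return named numeric frequency vector (sums to 1), with attribute
#'   \code{n_representatives}.
#' @export
round_robin_frequencies <- function(x, locus, eps = 0) {
  r <- as_records(x)
  loci <- colnames(r$a1)
  if (length(loci) < 2L)
    stopf("round-robin frequencies undefined for a single-locus dataset")
  j <- match(locus, loci)
  if (is.na(j)) stopf("unknown locus %s", locus)
  sub_keys <- mlg_keys(r$a1[, -j, drop = FALSE],
                       if (r$haploid) NULL else r$a2[, -j, drop = FALSE])
  reps <- !duplicated(sub_keys)
  copies <- c(r$a1[reps, j], r$a2[reps, j])
  copies <- copies[!is.na(copies)]
  all_alleles <- sort(unique(stats::na.omit(c(r$a1[, j], r$a2[, j]))))
  if (!length(all_alleles) && !length(copies))
    return(structure(stats::setNames(numeric(0), character(0)),
                     n_representatives = sum(reps)))
  counts <- stats::setNames(rep(eps, length(all_alleles)), all_alleles)
  if (length(copies)) {
    t0 <- table(factor(copies, levels = all_alleles))
    counts <- counts + as.numeric(t0)
  }
  structure(counts / sum(counts), n_representatives = sum(reps))
}

#' Round-robin F_IS per locus
#'
#' Per locus: \code{F_IS = 1 - H_OBS / H_EXP} with \code{H_EXP = 1 - sum(p^2)}
#' from round-robin allele frequencies and \code{H_OBS} the heterozygote
#' fraction among fully scored records. Monomorphic loci (\code{H_EXP = 0})
#' take \code{F_IS = 0} by convention; estimates are clamped to [-1, 1].
#'
#' @param x a \code{genotype_dataset} or \code{subgenome_set} (diploid-coded
#'   records expected; use \code{\link{double_haploid}} first for haploids).
#' @param freqs optional list of per-locus round-robin frequency vectors;
#'   computed from \code{x} when omitted.
#' @param eps pseudo-count forwarded to
#'   \code{\link{round_robin_frequencies}}.
#' @return data.frame of class \code{fis_table}: \code{locus}, \code{fis},
#'   \code{h_obs}, \code{h_exp}, \code{n_representatives}; the frequency
#'   vectors are attached as attribute \code{freqs}.
#' @export
estimate_fis <- function(x, freqs = NULL, eps = 0) {
  r <- as_records(x)
  loci <- colnames(r$a1)
  if (is.null(freqs))
    freqs <- stats::setNames(
      lapply(loci, function(l) round_robin_frequencies(x, l, eps = eps)), loci)
  rows <- lapply(loci, function(loc) {
    p <- freqs[[loc]]
    h_exp <- if (length(p)) 1 - sum(p^2) else 0
    full <- !is.na(r$a1[, loc]) & !is.na(r$a2[, loc])
    h_obs <- if (any(full)) mean(r$a1[full, loc] != r$a2[full, loc]) else 0
    fis <- if (h_exp <= 0) 0 else 1 - h_obs / h_exp
    fis <- max(-1, min(1, fis))
    data.frame(locus = loc, fis = fis, h_obs = h_obs, h_exp = h_exp,
               n_representatives = attr(p, "n_representatives") %||% NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "freqs") <- freqs
  class(out) <- c("fis_table", "data.frame")
  out
}

# --- P_GEN / P_SEX -----------------------------------------------------------

#' Probability of a multilocus genotype under one sexual event (P_GEN)
#'
#' Product over scored loci of the F_IS-corrected genotype probability:
#' homozygote a — \code{p_a^2 + p_a (1 - p_a) F}; heterozygote ab —
#' \code{2 p_a p_b (1 - F)}. Each per-locus factor is clamped to [0, 1];
#' loci with a missing or half-scored cell are skipped. For self-doubled
#' haploids with F_IS = 1 this reduces to the haploid product of allele
#' frequencies.
#'
#' @param a1,a2 named integer vectors (one cell per locus; the consensus of a
#'   clone, or one record's genotype).
#' @param freqs list of per-locus named frequency vectors; every scored
#'   allele must have an entry (use pseudo-counted tables), otherwise an
#'   error is raised.
#' @param fis a \code{fis_table} (or named numeric vector of per-locus F_IS).
#' @return numeric scalar in [0, 1].
#' @export
p_gen <- function(a1, a2, freqs, fis) {
  if (inherits(fis, "fis_table"))
    fis <- stats::setNames(fis$fis, fis$locus)
  out <- 1
  for (loc in names(a1)) {
    x <- a1[[loc]]; y <- a2[[loc]]
    if (is.na(x) || is.na(y)) next  # missing or half-scored: skipped
    p <- freqs[[loc]]
    pa <- unname(p[as.character(x)]); pb <- unname(p[as.character(y)])
    if (is.na(pa) || is.na(pb))
      stopf("allele %s at locus %s absent from frequency table (use pseudo-counted tables)",
            ifelse(is.na(pa), x, y), loc)
    f <- unname(fis[loc]); if (is.na(f)) f <- 0
    factor_j <- if (x == y) pa^2 + pa * (1 - pa) * f else 2 * pa * pb * (1 - f)
    out <- out * max(0, min(1, factor_j))
  }
  out
}

#' Probability that a repeated MLG arose from independent sexual events (P_SEX)
#'
#' Binomial upper tail: the probability of observing the MLG at least
#' \code{n_obs} times among \code{n_sample} independent sexual draws, each
#' succeeding with probability \code{p_gen_value}. Computed through the
#' regularized incomplete beta function, numerically safe far below 1e-50.
#' With \code{convention = "n_minus_1"} the tail starts at \code{n_obs - 1}
#' (the probability of at least \code{n_obs - 1} further sexual draws given
#' one observation).
#'
#' @param p_gen_value MLG probability per sexual event, in [0, 1].
#' @param n_obs observed copies of the MLG (1 <= n_obs <= n_sample).
#' @param n_sample number of analyzed genomes.
#' @param convention \code{"n"} (default; tail from \code{n_obs}) or
#'   \code{"n_minus_1"}.
#' @return numeric scalar in [0, 1].
#' @export
p_sex <- function(p_gen_value, n_obs, n_sample, convention = c("n", "n_minus_1")) {
  convention <- match.arg(convention)
  if (n_obs < 1L || n_obs > n_sample) stopf("need 1 <= n_obs <= n_sample")
  if (p_gen_value < 0 || p_gen_value > 1) stopf("p_gen_value outside [0, 1]")
  k <- if (convention == "n") n_obs else max(1L, n_obs - 1L)
  stats::pbinom(k - 1L, n_sample, p_gen_value, lower.tail = FALSE)
}

# --- clone calling -----------------------------------------------------------

#' Attach clonality statistics and verdicts to merged MLGs
#'
#' For each merged clone: P_GEN of the consensus from round-robin frequencies
#' and F_IS; P_SEX per population (n_sample = genomes analyzed from that
#' population) and globally (n_sample = all analyzed genomes). Verdict:
#' \code{clonal} when the clone has at least \code{min_copies} members and
#' its smallest per-population P_SEX is at most \code{alpha}; \code{putative}
#' when it is repeated but only one of the two conditions holds (>=
#' \code{min_copies} copies with P_SEX above \code{alpha}, or 2 to
#' \code{min_copies}-1 copies with P_SEX at most \code{alpha}); otherwise
#' \code{sexual}.
#'
#' @param ct a \code{clone_table} from \code{\link{merge_mlgs}}.
#' @param freqs per-locus frequency list (pseudo-counted); typically the
#'   \code{freqs} attribute of \code{\link{estimate_fis}}.
#' @param fis a \code{fis_table}.
#' @param alpha P_SEX significance threshold (default 0.05).
#' @param min_copies minimum copies for a clear clonal verdict (default 3).
#' @param convention P_SEX tail convention, see \code{\link{p_sex}}.
#' @return data.frame of class \code{clone_calls}: one row per clone with
#'   \code{clone_id}, \code{consensus}, \code{n_members}, \code{n_mlgs},
#'   \code{p_gen}, \code{p_sex_min}, \code{p_sex_global}, \code{verdict},
#'   plus attribute \code{membership} (data.frame id, clone_id) and
#'   \code{per_population} (clone_id x population counts).
#' @export
call_clones <- function(ct, freqs, fis, alpha = 0.05, min_copies = 3L,
                        convention = "n") {
  pop_of <- stats::setNames(ct$ind$population, ct$ind$id)
  n_by_pop <- table(ct$ind$population)
  n_total <- nrow(ct$ind)
  rows <- list(); mem <- list(); per_pop <- list()
  for (cl in ct$clones) {
    pg <- p_gen(cl$consensus_a1, cl$consensus_a2, freqs, fis)
    n_obs <- length(cl$members)
    pops <- table(pop_of[cl$members])
    ps_pop <- vapply(names(pops), function(pp) {
      p_sex(pg, as.integer(pops[[pp]]),
            max(as.integer(n_by_pop[[pp]]), as.integer(pops[[pp]])),
            convention)
    }, numeric(1))
    ps_min <- min(ps_pop)
    ps_global <- p_sex(pg, n_obs, n_total, convention)
    verdict <- if (n_obs >= min_copies && ps_min <= alpha) "clonal"
      else if (n_obs >= min_copies && ps_min > alpha) "putative"
      else if (n_obs >= 2L && ps_min <= alpha) "putative"
      else "sexual"
    rows[[length(rows) + 1L]] <- data.frame(
      clone_id = cl$clone_id, consensus = cl$consensus_key,
      n_members = n_obs, n_mlgs = length(cl$member_mlgs),
      p_gen = pg, p_sex_min = ps_min, p_sex_global = ps_global,
      verdict = verdict, stringsAsFactors = FALSE)
    mem[[length(mem) + 1L]] <- data.frame(
      id = cl$members, clone_id = cl$clone_id, stringsAsFactors = FALSE)
    per_pop[[length(per_pop) + 1L]] <- data.frame(
      clone_id = cl$clone_id, population = names(pops),
      count = as.integer(pops), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "membership") <- do.call(rbind, mem)
  attr(out, "per_population") <- do.call(rbind, per_pop)
  class(out) <- c("clone_calls", "data.frame")
  out
}

# --- summaries ---------------------------------------------------------------

#' Per-locus diversity summaries
#'
#' Allele number (AN, distinct alleles among all scored copies), observed
#' heterozygosity (heterozygote fraction among fully scored cells) and
#' unbiased expected heterozygosity
#' \code{(2N / (2N - 1)) (1 - sum(p^2))} with N the number of fully scored
#' cells.
#'
#' @param x a \code{genotype_dataset} or \code{subgenome_set}.
#' @param by_population split summaries per population (default FALSE).
#' @return data.frame: \code{locus} (and \code{population}), \code{an},
#'   \code{h_obs}, \code{h_exp}, \code{n}; attribute \code{mean_an}.
#' @export
locus_summaries <- function(x, by_population = FALSE) {
  r <- as_records(x)
  groups <- if (by_population) unique(r$ind$population) else "all"
  rows <- list()
  for (gp in groups) {
    keep <- if (by_population) r$ind$population == gp else
      rep(TRUE, nrow(r$ind))
    for (loc in colnames(r$a1)) {
      copies <- stats::na.omit(c(r$a1[keep, loc], r$a2[keep, loc]))
      if (!length(copies)) next
      full <- keep & !is.na(r$a1[, loc]) & !is.na(r$a2[, loc])
      n_full <- sum(full)
      h_obs <- if (n_full) mean(r$a1[full, loc] != r$a2[full, loc]) else 0
      p <- as.numeric(table(copies)) / length(copies)
      h_exp <- if (n_full > 0 && length(copies) > 1)
        (2 * n_full / (2 * n_full - 1)) * (1 - sum(p^2)) else 0
      h_exp <- min(1, max(0, h_exp))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, population = gp, an = length(unique(copies)),
        h_obs = h_obs, h_exp = h_exp, n = n_full, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_an") <- mean(out$an)
  out
}

# --- top-level fit -----------------------------------------------------------

#' Detect clonally repeated multilocus genotypes in a record set
#'
#' The core inference: index exact MLGs, merge those differing only through
#' missing data, estimate round-robin allele frequencies and F_IS, compute
#' P_GEN and P_SEX per merged clone, and call verdicts. The record set should
#' contain the genomes under test together with the sexual reference
#' individuals they are evaluated against (clonal repetition is judged
#' relative to the allele frequencies of the whole analyzed set).
#'
#' @param x a \code{genotype_dataset} (diploid-coded; double haploid
#'   subgenomes first, see \code{\link{double_haploid}}).
#' @param alpha P_SEX significance threshold (default 0.05).
#' @param min_copies minimum copies for a clonal verdict (default 3).
#' @param min_shared_loci minimum co-scored loci for MLG merging (default 5).
#' @param eps pseudo-count for frequency tables; default \code{0.5 / (2N)}.
#' @param convention P_SEX tail convention (see \code{\link{p_sex}}).
#' @return object of class \code{clone_analysis}: list with \code{calls}
#'   (a \code{clone_calls} data.frame), \code{fis}, \code{index},
#'   \code{merged}, \code{params}.
#' @export
detect_clones <- function(x, alpha = 0.05, min_copies = 3L,
                          min_shared_loci = 5L, eps = NULL,
                          convention = "n") {
  r <- as_records(x)
  if (is.null(eps)) eps <- 0.5 / (2 * nrow(r$ind))
  idx <- index_mlgs(x)
  merged <- merge_mlgs(idx, min_shared_loci = min_shared_loci)
  fis <- estimate_fis(x, eps = eps)
  calls <- call_clones(merged, attr(fis, "freqs"), fis,
                       alpha = alpha, min_copies = min_copies,
                       convention = convention)
  structure(list(calls = calls, fis = fis, index = idx, merged = merged,
                 params = list(alpha = alpha, min_copies = min_copies,
                               min_shared_loci = min_shared_loci, eps = eps,
                               convention = convention)),
            class = "clone_analysis")
}

#' @export
print.clone_analysis <- function(x, ...) {
  v <- table(factor(x$calls$verdict, levels = c("clonal", "putative", "sexual")))
  cat("Clone analysis:", length(x$index$key), "exact MLGs ->",
      nrow(x$calls), "merged MLGs\n")
  cat("  verdicts: clonal", v[["clonal"]], " putative", v[["putative"]],
      " sexual", v[["sexual"]], "\n")
  cl <- x$calls[x$calls$verdict == "clonal", , drop = FALSE]
  if (nrow(cl)) {
    for (i in seq_len(nrow(cl)))
      cat(sprintf("  %s: %d copies, P_GEN = %.3g, P_SEX = %.3g (min) / %.3g (global)\n",
                  cl$clone_id[i], cl$n_members[i], cl$p_gen[i],
                  cl$p_sex_min[i], cl$p_sex_global[i]))
  }
  invisible(x)
}

#' @export
summary.clone_analysis <- function(object, ...) {
  out <- list(
    n_records = nrow(object$index$ind),
    n_exact_mlgs = length(object$index$key),
    n_merged = nrow(object$calls),
    calls = object$calls,
    mean_fis = mean(object$fis$fis),
    params = object$params)
  class(out) <- "summary.clone_analysis"
  out
}

#' @export
print.summary.clone_analysis <- function(x, ...) {
  cat("Records:", x$n_records, "  exact MLGs:", x$n_exact_mlgs,
      "  merged MLGs:", x$n_merged, "\n")
  cat(sprintf("Mean round-robin F_IS: %.3f\n", x$mean_fis))
  print(x$calls[order(x$calls$p_sex_min), ][seq_len(min(10, nrow(x$calls))),
        c("clone_id", "n_members", "p_gen", "p_sex_min", "verdict")],
        row.names = FALSE)
  invisible(x)
}
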