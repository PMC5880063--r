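# --- group allele frequencies ------------------------------------------------
# groups: named list of genotype_dataset / subgenome_set objects sharing loci.
group_freqs <- function(groups, loci) {
  lapply(groups, function(g) {
    r <- as_records(g)
    stats::setNames(lapply(loci, function(loc) {
      copies <- stats::na.omit(c(r$a1[, loc], r$a2[, loc]))
      if (!length(copies)) return(stats::setNames(numeric(0), character(0)))
      t0 <- table(copies)
      stats::setNames(as.numeric(t0) / length(copies), names(t0))
    }), loci)
  })
}

#' Nei's DA distance matrix between genome groups
#'
#' \deqn{D_A(x, y) = 1 - \frac{1}{L} \sum_{loci} \sum_{alleles}
#'   \sqrt{x_a y_a}}
#' with sample allele frequencies per group. Loci for which any group has no
#' scored copy are dropped (and recorded in the \code{dropped_loci}
#' attribute). By design, cross-genome comparisons should exclude loci
#' amplifying in only one parental genome (pass \code{loci} accordingly).
#'
#' @param groups named list of \code{genotype_dataset} / \code{subgenome_set}
#'   objects (one per terminal group).
#' @param loci loci to use; default: all loci of the first group.
#' @return object of class \code{dist_da}: list with \code{labels},
#'   symmetric matrix \code{d} in [0, 1] with zero diagonal, and the loci
#'   used.
#' @export
nei_da_matrix <- function(groups, loci = NULL) {
  stopifnot(length(groups) >= 2L, !is.null(names(groups)))
  r1 <- as_records(groups[[1]])
  if (is.null(loci)) loci <- colnames(r1$a1)
  fr <- group_freqs(groups, loci)
  has_data <- vapply(loci, function(loc)
    all(vapply(fr, function(f) length(f[[loc]]) > 0L, logical(1))), logical(1))
  dropped <- loci[!has_data]
  loci <- loci[has_data]
  if (!length(loci)) stopf("no locus scored in every group")
  n <- length(groups)
  d <- matrix(0, n, n, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- 0
    for (loc in loci) {
      x <- fr[[i]][[loc]]; y <- fr[[j]][[loc]]
      shared <- intersect(names(x), names(y))
      if (length(shared))
        s <- s + sum(sqrt(x[shared] * y[shared]))
    }
    d[i, j] <- d[j, i] <- 1 - s / length(loci)
  }
  d[d < 0] <- 0; d[d > 1] <- 1
  structure(list(labels = names(groups), d = d, loci = loci,
                 dropped_loci = dropped),
            class = "dist_da")
}

#' @export
print.dist_da <- function(x, ...) {
  cat("Nei DA distances over", length(x$loci), "loci\n")
  print(round(x$d, 4))
  invisible(x)
}

#' UPGMA tree from a distance matrix
#'
#' Size-weighted arithmetic-mean agglomeration (the classic UPGMA): at each
#' step the pair of clusters at smallest average distance is joined, ties
#' broken by the lexicographically smallest pair of cluster labels (a cluster
#' is labelled by its smallest member label). Heights are ultrametric; leaf
#' branch lengths are half the join distance.
#'
#' @param d a \code{dist_da}, \code{dist} or symmetric matrix with
#'   dimnames.
#' @return an \code{ape} \code{phylo} tree (rooted, ultrametric), with
#'   attribute \code{heights} (join heights in input distance units).
#' @export
upgma_tree <- function(d) {
  if (inherits(d, "dist_da")) { labels <- d$labels; dm <- d$d }
  else if (inherits(d, "dist")) { dm <- as.matrix(d); labels <- rownames(dm) }
  else { dm <- as.matrix(d); labels <- rownames(dm) }
  n <- length(labels)
  stopifnot(n >= 2L, isSymmetric(unname(dm)))
  # active clusters: negative = original leaf index (hclust convention)
  size <- rep(1, n)
  id <- -seq_len(n)                    # hclust merge codes
  lab <- labels                        # smallest member label per cluster
  D <- dm
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- NULL
    for (ii in seq_len(m - 1L)) for (jj in (ii + 1L):m) {
      a <- active[ii]; b <- active[jj]
      dij <- D[a, b]
      pair_lab <- sort(c(lab[a], lab[b]))
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
           (pair_lab[1] < best$lab[1] ||
            (pair_lab[1] == best$lab[1] && pair_lab[2] < best$lab[2])))) {
        best <- list(a = a, b = b, d = dij, lab = pair_lab)
      }
    }
    a <- best$a; b <- best$b
    merge[step, ] <- sort(c(id[a], id[b]))
    height[step] <- best$d
    # size-weighted average update into slot a
    for (k in setdiff(active, c(a, b))) {
      D[a, k] <- D[k, a] <-
        (size[a] * D[a, k] + size[b] * D[b, k]) / (size[a] + size[b])
    }
    size[a] <- size[a] + size[b]
    id[a] <- step
    lab[a] <- min(lab[a], lab[b])
    active <- setdiff(active, b)
  }
  leaf_order <- function(step) {
    out <- integer(0)
    for (code in merge[step, ]) {
      out <- c(out, if (code < 0L) -code else leaf_order(code))
    }
    out
  }
  hc <- structure(list(merge = merge, height = height,
                       order = leaf_order(n - 1L), labels = labels,
                       method = "upgma"), class = "hclust")
  tr <- ape::as.phylo(hc)   # branch lengths = height / 2 (ultrametric)
  attr(tr, "heights") <- height
  tr
}

# leaf-label sets of all internal nodes (clades) of a rooted phylo tree
clade_sets <- function(tr) {
  n_tip <- length(tr$tip.label)
  nodes <- (n_tip + 1L):(n_tip + tr$Nnode)
  lapply(nodes, function(nd) {
    tips <- ape::extract.clade(tr, nd)$tip.label
    paste(sort(tips), collapse = "|")
  })
}

#' Locus-bootstrap support for a UPGMA tree of genome groups
#'
#' Loci are resampled with replacement \code{n_reps} times; the DA matrix and
#' UPGMA tree are recomputed for each replicate, and the support of each
#' internal node of the original tree is the fraction of replicates containing
#' the same leaf set as a clade. Supports are written to the tree's node
#' labels. Bit-reproducible given the seed.
#'
#' @param groups named list of record sets (as for
#'   \code{\link{nei_da_matrix}}).
#' @param loci loci to use.
#' @param n_reps number of bootstrap replicates (0 = no annotation).
#' @param seed integer seed.
#' @return the original UPGMA \code{phylo} with node labels set to support
#'   fractions (root label empty), and attribute \code{support} (named
#'   numeric per clade).
#' @export
bootstrap_support <- function(groups, loci = NULL, n_reps = 7000L, seed = 1L) {
  da <- nei_da_matrix(groups, loci)
  tr <- upgma_tree(da)
  if (n_reps <= 0L) return(tr)
  if (length(da$loci) < 2L) stopf("bootstrap needs >= 2 usable loci")
  orig <- clade_sets(tr)
  hits <- stats::setNames(numeric(length(orig)), unlist(orig))
  set.seed(as.integer(seed))
  for (b in seq_len(n_reps)) {
    boot_loci <- sample(da$loci, length(da$loci), replace = TRUE)
    # resampled loci enter the average once per draw
    db <- nei_da_boot(groups, boot_loci)
    trb <- upgma_tree(db)
    present <- unlist(clade_sets(trb))
    hits[intersect(names(hits), present)] <-
      hits[intersect(names(hits), present)] + 1
  }
  support <- hits / n_reps
  n_tip <- length(tr$tip.label)
  labs <- character(tr$Nnode)
  for (i in seq_len(tr$Nnode)) labs[i] <- sprintf("%.3f", support[[orig[[i]]]])
  root_clade <- paste(sort(tr$tip.label), collapse = "|")
  labs[match(root_clade, unlist(orig))] <- ""
  tr$node.label <- labs
  attr(tr, "support") <- support
  tr
}

# DA over a locus multiset (bootstrap draw): loci may repeat
nei_da_boot <- function(groups, loci_draw) {
  fr <- group_freqs(groups, unique(loci_draw))
  n <- length(groups)
  d <- matrix(0, n, n, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- 0
    for (loc in loci_draw) {
      x <- fr[[i]][[loc]]; y <- fr[[j]][[loc]]
      shared <- intersect(names(x), names(y))
      if (length(shared)) s <- s + sum(sqrt(x[shared] * y[shared]))
    }
    d[i, j] <- d[j, i] <- 1 - s / length(loci_draw)
  }
  d[d < 0] <- 0
  structure(list(labels = names(groups), d = d, loci = unique(loci_draw),
                 dropped_loci = character(0)), class = "dist_da")
}

#' Write a tree to a Newick file
#'
#' Support values (node labels) are written as internal node labels; branch
#' lengths are the ultrametric heights.
#'
#' @param tr a \code{phylo}.
#' @param path output file.
#' @export
write_tree_newick <- function(tr, path) {
  ape::write.tree(tr, file = path)
  invisible(NULL)
}

#' PCA of multilocus genotypes on allele counts
#'
#' Records are coded as an entity x allele count matrix (diploid 0/1/2;
#' haploid records coded 0/2, matching the self-doubling convention). Missing
#' cells are imputed with the column mean; columns are centred and scaled to
#' unit variance (zero-variance columns dropped) before eigendecomposition of
#' the covariance matrix.
#'
#' @param x a \code{genotype_dataset} or \code{subgenome_set}, or a named
#'   list of them (rows pooled; group recorded per row).
#' @param loci loci to use (default all).
#' @return object of class \code{pca_mlg}: \code{coordinates} (entity x
#'   axis), \code{explained_pct} (per axis, sums to 100 over all axes),
#'   \code{group} (per entity), \code{n_columns}.
#' @export
pca_mlg <- function(x, loci = NULL) {
  xs <- if (inherits(x, c("genotype_dataset", "subgenome_set"))) list(all = x)
        else x
  rs <- lapply(xs, as_records)
  if (is.null(loci)) loci <- colnames(rs[[1]]$a1)
  # collect allele columns
  alleles <- stats::setNames(lapply(loci, function(loc) {
    sort(unique(unlist(lapply(rs, function(r)
      stats::na.omit(c(r$a1[, loc], r$a2[, loc]))))))
  }), loci)
  cols <- unlist(lapply(loci, function(loc)
    paste0(loc, ".", alleles[[loc]])), use.names = FALSE)
  rows <- list(); grp <- character(0); ids <- character(0)
  for (gname in names(rs)) {
    r <- rs[[gname]]
    for (i in seq_len(nrow(r$a1))) {
      v <- stats::setNames(rep(0, length(cols)), cols)
      for (loc in loci) {
        a <- r$a1[i, loc]; b <- r$a2[i, loc]
        if (is.na(a) && is.na(b)) {
          v[paste0(loc, ".", alleles[[loc]])] <- NA
        } else if (r$haploid || is.na(b)) {
          v[paste0(loc, ".", a)] <- 2  # haploid / half cell coded 0/2
        } else {
          v[paste0(loc, ".", a)] <- v[paste0(loc, ".", a)] + 1
          v[paste0(loc, ".", b)] <- v[paste0(loc, ".", b)] + 1
        }
      }
      rows[[length(rows) + 1L]] <- v
      grp <- c(grp, gname)
      ids <- c(ids, r$ind$id[i])
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- make.unique(ids)
  if (nrow(m) < 2L) stopf("PCA needs >= 2 records")
  # column-mean imputation of missing cells
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j], na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    m[is.na(m[, j]), j] <- mu
  }
  sdv <- apply(m, 2, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) {  # all records identical: every eigenvalue is 0
    co <- matrix(0, nrow(m), 1, dimnames = list(rownames(m), "PC1"))
    return(structure(list(coordinates = co, explained_pct = 0,
                          group = grp, n_columns = 0L),
                     class = "pca_mlg"))
  }
  m <- scale(m[, keep, drop = FALSE])
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(coordinates = pc$x,
                 explained_pct = 100 * ev / sum(ev),
                 group = grp, n_columns = sum(keep)),
            class = "pca_mlg")
}

#' @export
print.pca_mlg <- function(x, ...) {
  cat("MLG PCA:", nrow(x$coordinates), "records,", x$n_columns,
      "allele columns\n")
  k <- min(3, length(x$explained_pct))
  cat("  explained:", paste(sprintf("axis%d %.1f%%", seq_len(k),
                                    x$explained_pct[seq_len(k)]),
                            collapse = ", "), "\n")
  invisible(x)
}
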