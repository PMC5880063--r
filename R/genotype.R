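#' Construct a genotype dataset
#'
#' A genotype dataset holds diploid co-dominant genotypes (individual x locus,
#' up to two integer allele states per cell, missing allowed per slot) together
#' with individual metadata, population metadata and the allele registry. A
#' cell with a single scored allele is stored as (allele, missing), never
#' auto-doubled: homozygote vs single-amplification ambiguity is resolved only
#' by the explicit doubling operation (\code{\link{double_haploid}}).
#'
#' @param ind data.frame with columns \code{id}, \code{population},
#'   \code{taxon} (one of \code{"LL"}, \code{"RR"}, \code{"RL"}, \code{"KK"},
#'   \code{"unknown"}), \code{sex} (one of \code{"f"}, \code{"m"},
#'   \code{"juv"}, \code{"unknown"}); optional \code{ploidy} (default 2).
#' @param a1,a2 integer matrices (individuals x loci) of first/second allele
#'   slots, \code{NA} for a missing slot; column names are locus names.
#' @param registry an \code{\link{allele_registry}} covering all loci.
#' @param populations optional data.frame with columns \code{population} and
#'   \code{system_type} (e.g. \code{"R-E-male"}, \code{"L-E"}, \code{"other"}).
#' @return An object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(ind, a1, a2, registry, populations = NULL) {
  ind <- as.data.frame(ind, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "population", "taxon", "sex") %in% names(ind)))
  if (is.null(ind$ploidy)) ind$ploidy <- rep(2L, nrow(ind))
  if (any(ind$ploidy < 1L)) stopf("ploidy must be >= 1")
  if (!all(ind$taxon %in% c("LL", "RR", "RL", "KK", "unknown")))
    stopf("unknown taxon label: %s",
          paste(setdiff(ind$taxon, c("LL", "RR", "RL", "KK", "unknown")),
                collapse = ", "))
  if (anyDuplicated(ind$id)) stopf("duplicate individual id")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  stopifnot(nrow(a1) == nrow(ind), identical(dim(a1), dim(a2)),
            identical(colnames(a1), colnames(a2)))
  if (is.null(colnames(a1))) stopf("allele matrices need locus column names")
  missing_loci <- setdiff(colnames(a1), registry$loci$name)
  if (length(missing_loci))
    stopf("loci absent from registry: %s", paste(missing_loci, collapse = ", "))
  cm <- canon_matrices(a1, a2)
  rownames(cm$a1) <- rownames(cm$a2) <- ind$id
  if (is.null(populations)) {
    upop <- unique(ind$population)
    populations <- data.frame(population = upop,
                              system_type = rep("other", length(upop)),
                              stringsAsFactors = FALSE)
  }
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  stopifnot(all(c("population", "system_type") %in% names(populations)))
  bad_pop <- setdiff(ind$population, populations$population)
  if (length(bad_pop))
    stopf("individuals reference unknown population: %s",
          paste(bad_pop, collapse = ", "))
  structure(list(ind = ind, a1 = cm$a1, a2 = cm$a2, registry = registry,
                 populations = populations),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("Genotype dataset:", nrow(x$ind), "individuals,",
      ncol(x$a1), "loci,", nrow(x$populations), "populations\n")
  print(table(taxon = x$ind$taxon))
  miss <- mean(is.na(x$a1) & is.na(x$a2))
  cat(sprintf("  whole-cell missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

loci_of <- function(ds) colnames(ds$a1)

#' Subset a genotype dataset by individuals and/or loci
#'
#' @param ds a \code{genotype_dataset}.
#' @param individuals ids or logical/integer index over rows.
#' @param loci locus names to keep.
#' @return A \code{genotype_dataset}.
#' @export
subset_dataset <- function(ds, individuals = NULL, loci = NULL) {
  ri <- seq_len(nrow(ds$ind))
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) match(individuals, ds$ind$id)
          else seq_len(nrow(ds$ind))[individuals]
    if (anyNA(ri)) stopf("unknown individual id")
  }
  ci <- if (is.null(loci)) seq_len(ncol(ds$a1)) else match(loci, loci_of(ds))
  if (anyNA(ci)) stopf("unknown locus")
  genotype_dataset(ds$ind[ri, , drop = FALSE],
                   ds$a1[ri, ci, drop = FALSE], ds$a2[ri, ci, drop = FALSE],
                   ds$registry, ds$populations)
}

#' Concatenate genotype datasets over a common locus set
#'
#' Used to pool, e.g., sexual reference individuals with doubled hybrid
#' subgenomes before clonality analysis. All inputs must share the same loci
#' and registry; individual ids must be unique across inputs.
#'
#' @param ... \code{genotype_dataset} objects.
#' @return A \code{genotype_dataset}.
#' @export
bind_datasets <- function(...) {
  dss <- list(...)
  stopifnot(length(dss) >= 1L)
  loci <- loci_of(dss[[1]])
  for (ds in dss) stopifnot(identical(loci_of(ds), loci))
  ind <- do.call(rbind, lapply(dss, function(d) d$ind))
  a1 <- do.call(rbind, lapply(dss, function(d) d$a1))
  a2 <- do.call(rbind, lapply(dss, function(d) d$a2))
  pops <- do.call(rbind, lapply(dss, function(d) d$populations))
  pops <- pops[!duplicated(pops$population), , drop = FALSE]  # first wins
  genotype_dataset(ind, a1, a2, dss[[1]]$registry, pops)
}

#' Read a genotype table from CSV
#'
#' Dialect: header \code{id,population,taxon,sex} then one column per locus;
#' each cell is \code{a1/a2}, \code{a1/0} (half-missing) or \code{0/0}
#' (missing); \code{#} starts a comment line. A cell with more than two
#' alleles is a format error (diploid data).
#'
#' @param path file path.
#' @param registry an \code{allele_registry}; all locus columns must exist in
#'   it. Alleles absent from the registry are collected into the
#'   \code{unregistered} attribute of the result, never dropped.
#' @param populations optional population metadata passed through.
#' @return A \code{genotype_dataset} with attribute \code{unregistered}
#'   (data.frame id, locus, allele).
#' @export
read_genotype_table <- function(path, registry, populations = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE)
  need <- c("id", "population", "taxon", "sex")
  if (!all(need %in% names(df)))
    stopf("genotype table must start with columns %s", paste(need, collapse = ","))
  loci <- setdiff(names(df), c(need, "ploidy"))
  unknown <- setdiff(loci, registry$loci$name)
  if (length(unknown))
    stopf("unknown locus column: %s", paste(unknown, collapse = ", "))
  n <- nrow(df)
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(df$id, loci))
  a2 <- a1
  for (loc in loci) {
    cells <- as.character(df[[loc]])
    cells[is.na(cells) | cells == ""] <- "0/0"
    parts <- strsplit(cells, "/", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) > 2L
    if (any(bad))
      stopf("cell with >2 alleles at locus %s, row %d (diploid data)",
            loc, which(bad)[1])
    p1 <- vapply(parts, `[`, character(1), 1L)
    p2 <- vapply(parts, function(p) if (length(p) >= 2L) p[2] else MISSING_TOKEN,
                 character(1))
    v1 <- suppressWarnings(as.integer(p1))
    v2 <- suppressWarnings(as.integer(p2))
    if (anyNA(v1) || anyNA(v2))
      stopf("non-integer allele at locus %s, row %d", loc,
            which(is.na(v1) | is.na(v2))[1])
    v1[p1 == MISSING_TOKEN] <- NA_integer_
    v2[p2 == MISSING_TOKEN] <- NA_integer_
    a1[, loc] <- v1
    a2[, loc] <- v2
  }
  ind <- df[need]
  if (!is.null(df$ploidy)) ind$ploidy <- as.integer(df$ploidy)
  ds <- genotype_dataset(ind, a1, a2, registry, populations)
  # report unregistered alleles without dropping them
  unreg <- list()
  for (loc in loci) {
    vals <- unique(stats::na.omit(c(ds$a1[, loc], ds$a2[, loc])))
    sp <- allele_specificity(registry, loc, vals)
    for (v in vals[sp == "unregistered"]) {
      hit <- which(ds$a1[, loc] == v | ds$a2[, loc] == v)
      unreg[[length(unreg) + 1L]] <- data.frame(
        id = ds$ind$id[hit], locus = loc, allele = v, stringsAsFactors = FALSE)
    }
  }
  attr(ds, "unregistered") <- if (length(unreg)) do.call(rbind, unreg) else
    data.frame(id = character(0), locus = character(0), allele = integer(0))
  ds
}

#' Write a genotype table to CSV
#'
#' Round-trip safe with \code{\link{read_genotype_table}}: missing slots are
#' written with the reserved sentinel \code{0}.
#'
#' @param ds a \code{genotype_dataset}.
#' @param path output file path.
#' @export
write_genotype_table <- function(ds, path) {
  loci <- loci_of(ds)
  fmt <- function(x) ifelse(is.na(x), MISSING_TOKEN, as.character(x))
  out <- ds$ind[c("id", "population", "taxon", "sex")]
  for (loc in loci)
    out[[loc]] <- if (nrow(out)) paste0(fmt(ds$a1[, loc]), "/",
                                        fmt(ds$a2[, loc])) else character(0)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Validate a genotype dataset against its registry
#'
#' Report-only (the dataset is never modified): lists alleles whose species
#' specificity conflicts with the bearer's taxon label, loci scored in a
#' genome they should not amplify in, and per-locus missingness rates.
#'
#' @param ds a \code{genotype_dataset}.
#' @return A list of class \code{validation_report} with elements
#'   \code{atypical} (data.frame id, taxon, locus, allele, specificity),
#'   \code{bad_amplification} (data.frame id, taxon, locus) and
#'   \code{missingness} (named numeric, whole-cell missing rate per locus).
#' @export
validate_dataset <- function(ds) {
  reg <- ds$registry
  loci <- loci_of(ds)
  atyp <- list(); badamp <- list()
  genome_of_taxon <- c(LL = "L", RR = "R", KK = "R")  # KK carries R-like genomes
  for (loc in loci) {
    amp <- reg$loci$amplifies_in[match(loc, reg$loci$name)]
    for (i in seq_len(nrow(ds$ind))) {
      alle <- c(ds$a1[i, loc], ds$a2[i, loc])
      alle <- alle[!is.na(alle)]
      if (!length(alle)) next
      taxon <- ds$ind$taxon[i]
      # scored at a locus that does not amplify in this taxon's genome(s)
      if (taxon %in% c("LL", "RR")) {
        g <- genome_of_taxon[[taxon]]
        if (!grepl(g, amp, fixed = TRUE))
          badamp[[length(badamp) + 1L]] <- data.frame(
            id = ds$ind$id[i], taxon = taxon, locus = loc,
            stringsAsFactors = FALSE)
      }
      sp <- allele_specificity(reg, loc, alle)
      flag <- (taxon == "LL" & sp == "R") | (taxon == "RR" & sp == "L")
      for (k in which(flag))
        atyp[[length(atyp) + 1L]] <- data.frame(
          id = ds$ind$id[i], taxon = taxon, locus = loc, allele = alle[k],
          specificity = sp[k], stringsAsFactors = FALSE)
    }
  }
  miss <- colMeans(is.na(ds$a1) & is.na(ds$a2))
  structure(list(
    atypical = if (length(atyp)) do.call(rbind, atyp) else
      data.frame(id = character(0), taxon = character(0), locus = character(0),
                 allele = integer(0), specificity = character(0)),
    bad_amplification = if (length(badamp)) do.call(rbind, badamp) else
      data.frame(id = character(0), taxon = character(0), locus = character(0)),
    missingness = miss
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report:\n")
  cat("  atypical alleles:", nrow(x$atypical), "\n")
  cat("  bad amplification:", nrow(x$bad_amplification), "\n")
  cat(sprintf("  mean missingness: %.3f\n", mean(x$missingness)))
  invisible(x)
}
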