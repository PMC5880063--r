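#' Construct an allele registry
#'
#' An allele registry records, for each marker locus, which parental genomes
#' the locus amplifies in, and maps every registered allele state (an integer
#' fragment length) to a species specificity class: \code{"L"} (private to the
#' first parental species), \code{"R"} (private to the second),
#' \code{"shared"} (legitimately present in both gene pools), or
#' \code{"nonspecific"} (observed in both, uninformative).
#'
#' @param loci data.frame with columns \code{name} (unique locus identifiers),
#'   \code{amplifies_in} (one of \code{"L"}, \code{"R"}, \code{"LR"}) and
#'   optionally \code{motif_step} (integer repeat unit, \code{NA} allowed).
#' @param spec data.frame with columns \code{locus}, \code{allele} (integer)
#'   and \code{specificity} (one of \code{"L"}, \code{"R"}, \code{"shared"},
#'   \code{"nonspecific"}). One row per (locus, allele).
#' @return An object of class \code{allele_registry}.
#' @export
allele_registry <- function(loci, spec = NULL) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (!all(c("name", "amplifies_in") %in% names(loci)))
    stopf("loci must have columns 'name' and 'amplifies_in'")
  if (anyDuplicated(loci$name))
    stopf("duplicate locus name in registry: %s",
          paste(unique(loci$name[duplicated(loci$name)]), collapse = ", "))
  if (!all(loci$amplifies_in %in% c("L", "R", "LR")))
    stopf("amplifies_in must be one of 'L', 'R', 'LR'")
  if (is.null(loci$motif_step)) loci$motif_step <- NA_integer_

  if (is.null(spec)) {
    spec <- data.frame(locus = character(0), allele = integer(0),
                       specificity = character(0), stringsAsFactors = FALSE)
  }
  spec <- as.data.frame(spec, stringsAsFactors = FALSE)
  if (nrow(spec)) {
    if (!all(c("locus", "allele", "specificity") %in% names(spec)))
      stopf("spec must have columns 'locus', 'allele', 'specificity'")
    if (!all(spec$specificity %in% c("L", "R", "shared", "nonspecific")))
      stopf("unknown specificity class: %s",
            paste(setdiff(spec$specificity,
                          c("L", "R", "shared", "nonspecific")), collapse = ", "))
    if (!all(spec$locus %in% loci$name))
      stopf("spec references unknown locus: %s",
            paste(setdiff(spec$locus, loci$name), collapse = ", "))
    key <- paste(spec$locus, spec$allele)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)]
      conflicting <- vapply(unique(dup), function(k) {
        length(unique(spec$specificity[key == k])) > 1L
      }, logical(1))
      if (any(conflicting))
        stopf("conflicting specificity for (locus, allele): %s",
              paste(unique(dup)[conflicting], collapse = ", "))
      spec <- spec[!duplicated(key), , drop = FALSE]
    }
    spec$allele <- as.integer(spec$allele)
  }
  structure(list(loci = loci, spec = spec), class = "allele_registry")
}

#' @export
print.allele_registry <- function(x, ...) {
  cat("Allele registry:", nrow(x$loci), "loci,",
      nrow(x$spec), "registered alleles\n")
  tab <- table(factor(x$loci$amplifies_in, levels = c("L", "R", "LR")))
  cat("  amplifies in L only:", tab[["L"]],
      " R only:", tab[["R"]], " both:", tab[["LR"]], "\n")
  if (nrow(x$spec))
    print(table(specificity = x$spec$specificity))
  invisible(x)
}

#' Look up the specificity class of alleles
#'
#' @param registry an \code{allele_registry}.
#' @param locus locus name (scalar).
#' @param alleles integer vector of allele states.
#' @return Character vector: \code{"L"}, \code{"R"}, \code{"shared"},
#'   \code{"nonspecific"} or \code{"unregistered"}; \code{NA} for missing
#'   input alleles.
#' @export
allele_specificity <- function(registry, locus, alleles) {
  sp <- registry$spec
  idx <- match(paste(locus, alleles), paste(sp$locus, sp$allele))
  out <- ifelse(is.na(alleles), NA_character_,
                ifelse(is.na(idx), "unregistered", sp$specificity[idx]))
  out
}

#' Read an allele registry from a TSV file
#'
#' The dialect is tab-separated with columns
#' \code{locus}, \code{allele_or_range}, \code{specificity},
#' \code{amplifies_in}; \code{#} starts a comment line. \code{allele_or_range}
#' is either a single integer or an inclusive range \code{"lo-hi"}, expanded
#' to explicit allele entries at load (step 1; with a fifth optional column
#' \code{step} the range is expanded at that step and the step recorded as the
#' locus motif step). A locus may be declared without alleles by leaving
#' \code{allele_or_range} and \code{specificity} as \code{"."}.
#'
#' @param path file path.
#' @return An \code{allele_registry}.
#' @export
read_allele_registry <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  loci <- list()
  spec_rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L)
      stopf("registry parse error at line %d: expected >= 4 tab-separated fields",
            lineno[i])
    locus <- f[1]; allele_field <- f[2]; specificity <- f[3]; amp <- f[4]
    step <- if (length(f) >= 5L && nzchar(f[5])) as.integer(f[5]) else NA_integer_
    if (!amp %in% c("L", "R", "LR"))
      stopf("registry parse error at line %d: amplifies_in '%s'", lineno[i], amp)
    prev <- loci[[locus]]
    if (is.null(prev)) {
      loci[[locus]] <- list(amp = amp, step = step)
    } else {
      if (prev$amp != amp)
        stopf("registry parse error at line %d: locus %s declared with two amplifies_in values",
              lineno[i], locus)
      if (is.na(prev$step) && !is.na(step)) loci[[locus]]$step <- step
    }
    if (allele_field == "." || specificity == ".") next
    if (grepl("^-?[0-9]+--?[0-9]+$", allele_field)) {
      parts <- as.integer(strsplit(sub("^(-?[0-9]+)-", "\\1 ", allele_field), " ")[[1]])
      lo <- parts[1]; hi <- parts[2]
      if (hi < lo)
        stopf("registry parse error at line %d: empty range '%s'", lineno[i], allele_field)
      alleles <- seq(lo, hi, by = if (is.na(step)) 1L else step)
    } else if (grepl("^-?[0-9]+$", allele_field)) {
      alleles <- as.integer(allele_field)
    } else {
      stopf("registry parse error at line %d: bad allele field '%s'",
            lineno[i], allele_field)
    }
    spec_rows[[length(spec_rows) + 1L]] <-
      data.frame(locus = locus, allele = alleles, specificity = specificity,
                 stringsAsFactors = FALSE)
  }
  loci_df <- data.frame(
    name = as.character(names(loci)),
    amplifies_in = vapply(loci, `[[`, character(1), "amp", USE.NAMES = FALSE),
    motif_step = vapply(loci, function(l) as.integer(l$step), integer(1),
                        USE.NAMES = FALSE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  spec_df <- if (length(spec_rows)) do.call(rbind, spec_rows) else NULL
  # Same (locus, allele) marked both L and R is a conflict; an allele seen in
  # both gene pools must be registered once as shared or nonspecific.
  allele_registry(loci_df, spec_df)
}

#' Write an allele registry to a TSV file
#'
#' Explicit one-allele-per-row form; round-trips through
#' \code{\link{read_allele_registry}}.
#'
#' @param registry an \code{allele_registry}.
#' @param path output file path.
#' @export
write_allele_registry <- function(registry, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# locus\tallele_or_range\tspecificity\tamplifies_in\tstep", con)
  for (j in seq_len(nrow(registry$loci))) {
    loc <- registry$loci$name[j]
    amp <- registry$loci$amplifies_in[j]
    step <- registry$loci$motif_step[j]
    step_s <- if (is.na(step)) "" else as.integer(step)
    rows <- registry$spec[registry$spec$locus == loc, , drop = FALSE]
    if (nrow(rows) == 0L) {
      writeLines(paste(loc, ".", ".", amp, step_s, sep = "\t"), con)
    } else {
      writeLines(paste(loc, rows$allele, rows$specificity, amp, step_s,
                       sep = "\t"), con)
    }
  }
  invisible(NULL)
}
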