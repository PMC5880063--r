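# Internal helpers shared across modules.

MISSING_TOKEN <- "0"   # file sentinel for a missing allele slot
NULL_ALLELE <- -1L     # reserved in-memory state for a recoded null allele

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonicalize one diploid cell: scored alleles sorted ascending, NA slots last.
canon_cell <- function(a1, a2) {
  v <- c(a1, a2)
  v <- v[!is.na(v)]
  if (length(v) == 0) return(c(NA_integer_, NA_integer_))
  if (length(v) == 1) return(c(v, NA_integer_))
  sort(v)
}

# Canonicalize paired allele matrices in place (columns = loci).
canon_matrices <- function(a1, a2) {
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  shift <- is.na(a1) & !is.na(a2)
  if (any(shift)) {
    a1[shift] <- a2[shift]
    a2[shift] <- NA_integer_
  }
  list(a1 = a1, a2 = a2)
}

# String key for one record's multilocus genotype.
# Diploid: "a/b", half-scored "a/.", missing "."; haploid: "a" or ".".
mlg_key_one <- function(a1, a2 = NULL) {
  if (is.null(a2)) {
    cells <- ifelse(is.na(a1), ".", as.character(a1))
  } else {
    cells <- ifelse(
      is.na(a1), ".",
      ifelse(is.na(a2), paste0(a1, "/."), paste0(a1, "/", a2))
    )
  }
  paste(cells, collapse = ";")
}

mlg_keys <- function(a1, a2 = NULL) {
  n <- nrow(a1)
  vapply(seq_len(n), function(i) {
    mlg_key_one(a1[i, ], if (is.null(a2)) NULL else a2[i, ])
  }, character(1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Derive a reproducible 32-bit sub-seed from a root seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}
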