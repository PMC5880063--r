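#' Pipeline configuration
#'
#' Flat configuration for \code{\link{run_pipeline}}. Defaults mirror the
#' analysis workflow: quality screening, subgenome partitioning, clonality
#' analysis, then distance tree and PCA. Round-trips to a key = value text
#' file.
#'
#' @param seed root seed for every stochastic stage.
#' @param out_dir artifact directory.
#' @param genotypes,registry input file paths (ignored when
#'   \code{simulate = TRUE}).
#' @param simulate generate inputs with \code{\link{simulate_re_system}}
#'   using \code{sim} (default TRUE when no input paths are given).
#' @param sim a \code{\link{sim_config}} used when simulating.
#' @param clonal_genome \code{"L"} or \code{"R"}.
#' @param alpha,min_copies,min_shared_loci,null_r_threshold thresholds
#'   forwarded to the stages.
#' @param hwe_reps,bootstrap_reps replicate counts.
#' @param stages character vector of enabled stages, a subset of
#'   \code{c("quality", "partition", "clones", "tree", "pca")}.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("hemiclone_run_"),
                            genotypes = NULL, registry = NULL,
                            simulate = is.null(genotypes),
                            sim = sim_config(seed = seed),
                            clonal_genome = "L",
                            alpha = 0.05, min_copies = 3L,
                            min_shared_loci = 5L, null_r_threshold = 0.05,
                            hwe_reps = 2000L, bootstrap_reps = 7000L,
                            stages = c("quality", "partition", "clones",
                                       "tree", "pca")) {
  stopifnot(alpha >= 0, alpha <= 1, min_copies >= 1,
            null_r_threshold >= 0, null_r_threshold <= 1,
            clonal_genome %in% c("L", "R"),
            all(stages %in% c("quality", "partition", "clones", "tree", "pca")))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 genotypes = genotypes, registry = registry,
                 simulate = simulate, sim = sim,
                 clonal_genome = clonal_genome, alpha = alpha,
                 min_copies = as.integer(min_copies),
                 min_shared_loci = as.integer(min_shared_loci),
                 null_r_threshold = null_r_threshold,
                 hwe_reps = as.integer(hwe_reps),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 stages = stages),
            class = "pipeline_config")
}

#' Run the full hemiclone-detection pipeline
#'
#' Stage order: (simulate or load inputs) -> quality screen and null-allele
#' correction -> subgenome partition -> clonality analysis on the pooled
#' record set (sexual residents + doubled subgenomes) -> DA/UPGMA tree with
#' locus bootstrap -> PCA. Writes stage outputs and a machine-readable JSON
#' manifest (seeds, thresholds, per-stage results and decisions) into
#' \code{cfg$out_dir}; two runs with the same config produce identical
#' manifests.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return invisibly, a list of class \code{pipeline_result}: \code{manifest}
#'   (list also written as JSON), and the in-memory stage objects.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed,
                   thresholds = list(alpha = cfg$alpha,
                                     min_copies = cfg$min_copies,
                                     min_shared_loci = cfg$min_shared_loci,
                                     null_r_threshold = cfg$null_r_threshold),
                   stages_enabled = cfg$stages, decisions = character(0))
  result <- list()

  # inputs
  if (cfg$simulate) {
    sim <- simulate_re_system(cfg$sim)
    sim <- inject_artifacts(sim, cfg$sim)
    ds <- sim$dataset
    result$truth <- sim$truth
    write_genotype_table(ds, file.path(cfg$out_dir, "genotypes.csv"))
    write_allele_registry(ds$registry, file.path(cfg$out_dir, "registry.tsv"))
    manifest$input <- list(source = "simulated", seed = cfg$sim$seed)
  } else {
    registry <- read_allele_registry(cfg$registry)
    ds <- read_genotype_table(cfg$genotypes, registry)
    manifest$input <- list(source = "files", genotypes = cfg$genotypes,
                           registry = cfg$registry)
  }
  manifest$dataset <- list(n_individuals = nrow(ds$ind),
                           n_loci = ncol(ds$a1),
                           n_populations = nrow(ds$populations))
  result$dataset <- ds

  if ("quality" %in% cfg$stages) {
    # HWE / null-allele screening is defined for the sexual species; hybrids
    # are excluded from the screen but share the per-locus correction.
    sex_rows <- which(ds$ind$taxon %in% c("LL", "RR"))
    screen_ds <- if (length(sex_rows)) subset_dataset(ds, sex_rows) else ds
    qs <- quality_screen(screen_ds, n_reps = cfg$hwe_reps,
                         seed = derive_seed(cfg$seed, 11L),
                         r_threshold = cfg$null_r_threshold,
                         alpha = cfg$alpha)
    utils::write.table(qs, file.path(cfg$out_dir, "quality.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    n_flagged <- sum(qs$flagged)
    if (n_flagged > 0) {
      ds <- apply_null_correction(ds, qs, threshold = cfg$null_r_threshold,
                                  seed = derive_seed(cfg$seed, 12L))
      manifest$decisions <- c(manifest$decisions, sprintf(
        "null-allele correction applied to %d (locus, population) cells",
        n_flagged))
    }
    manifest$quality <- list(cells_screened = nrow(qs), flagged = n_flagged)
    result$quality <- qs
    result$dataset <- ds
  }

  part <- NULL
  if ("partition" %in% cfg$stages) {
    part <- partition_hybrids(ds, clonal_genome = cfg$clonal_genome)
    utils::write.table(part$report,
                       file.path(cfg$out_dir, "partition_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_genotype_table(double_haploid(part$L, "missing-partner"),
                         file.path(cfg$out_dir, "subgenome_L.csv"))
    write_genotype_table(double_haploid(part$R, "missing-partner"),
                         file.path(cfg$out_dir, "subgenome_R.csv"))
    manifest$partition <- list(
      n_hybrids = nrow(part$report),
      unresolved_loci = sum(part$report$unresolved),
      violations = sum(nzchar(part$report$violations)))
    result$partition <- part
  }

  if ("clones" %in% cfg$stages) {
    if (is.null(part)) stopf("clones stage requires the partition stage")
    sex_idx <- ds$ind$taxon %in% c("LL", "RR")
    sexual <- subset_dataset(ds, which(sex_idx))
    pooled <- bind_datasets(sexual,
                            double_haploid(part$L, "self-double"),
                            double_haploid(part$R, "self-double"))
    ca <- detect_clones(pooled, alpha = cfg$alpha,
                        min_copies = cfg$min_copies,
                        min_shared_loci = cfg$min_shared_loci)
    utils::write.table(ca$calls, file.path(cfg$out_dir, "clones.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(attr(ca$calls, "membership"),
                       file.path(cfg$out_dir, "clone_membership.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$clones <- list(
      n_records = nrow(pooled$ind),
      n_exact_mlgs = length(ca$index$key),
      n_merged_mlgs = nrow(ca$calls),
      n_clonal = sum(ca$calls$verdict == "clonal"),
      clonal_ids = ca$calls$clone_id[ca$calls$verdict == "clonal"],
      min_p_sex = if (nrow(ca$calls)) min(ca$calls$p_sex_min) else NA)
    if (length(ca$merged$split_log))
      manifest$decisions <- c(manifest$decisions, ca$merged$split_log)
    result$clones <- ca
  }

  if ("tree" %in% cfg$stages || "pca" %in% cfg$stages) {
    if (is.null(part)) stopf("tree/pca stages require the partition stage")
    both_loci <- ds$registry$loci$name[ds$registry$loci$amplifies_in == "LR"]
    groups <- list()
    if (any(ds$ind$taxon == "RR"))
      groups[["RR"]] <- subset_dataset(ds, which(ds$ind$taxon == "RR"))
    if (any(ds$ind$taxon == "LL"))
      groups[["LL"]] <- subset_dataset(ds, which(ds$ind$taxon == "LL"))
    groups[["hybrid_L"]] <- part$L
    groups[["hybrid_R"]] <- part$R
    if ("tree" %in% cfg$stages) {
      tr <- bootstrap_support(groups, loci = both_loci,
                              n_reps = cfg$bootstrap_reps,
                              seed = derive_seed(cfg$seed, 21L))
      write_tree_newick(tr, file.path(cfg$out_dir, "tree.nwk"))
      manifest$tree <- list(loci_used = length(both_loci),
                            n_reps = cfg$bootstrap_reps,
                            support = as.list(attr(tr, "support")))
      result$tree <- tr
    }
    if ("pca" %in% cfg$stages) {
      pc <- pca_mlg(groups, loci = both_loci)
      utils::write.table(
        data.frame(id = rownames(pc$coordinates), group = pc$group,
                   pc$coordinates[, seq_len(min(3, ncol(pc$coordinates))),
                                  drop = FALSE]),
        file.path(cfg$out_dir, "pca.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      manifest$pca <- list(
        explained_pct = round(pc$explained_pct[seq_len(min(3, length(pc$explained_pct)))], 3))
      result$pca <- pc
    }
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  result$manifest <- manifest
  class(result) <- "pipeline_result"
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (seed", x$manifest$seed, ")\n")
  if (!is.null(x$manifest$clones))
    cat("  clonal MLGs called:", x$manifest$clones$n_clonal,
        " min P_SEX:", format(x$manifest$clones$min_p_sex, digits = 3), "\n")
  invisible(x)
}
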