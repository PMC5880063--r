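reg3 <- toy_registry(3L, L_alleles = seq(102L, 130L, 2L),
                     R_alleles = seq(202L, 230L, 2L))

group_from_rows <- function(rows, registry = reg3) {
  geno <- stats::setNames(rows, sprintf("g%03d", seq_along(rows)))
  toy_dataset(geno, registry, taxon = "RR")
}

test_that("Nei DA boundaries and the closed-form toy value", {
  g1 <- group_from_rows(rep(list(list(loc01 = c(102L, 104L),
                                      loc02 = c(102L, 102L),
                                      loc03 = c(104L, 104L))), 4))
  # identical frequency profiles -> 0
  da0 <- nei_da_matrix(list(a = g1, b = g1))
  expect_equal(unname(da0$d["a", "b"]), 0)
  # fully disjoint allele sets at every locus -> 1
  g2 <- group_from_rows(rep(list(list(loc01 = c(110L, 112L),
                                      loc02 = c(110L, 110L),
                                      loc03 = c(112L, 112L))), 4))
  expect_equal(unname(nei_da_matrix(list(a = g1, b = g2))$d["a", "b"]), 1)
  # one locus, x = (1, 0), y = (0.25, 0.75): DA = 1 - sqrt(0.25) = 0.5
  reg1 <- toy_registry(1L)
  x <- group_from_rows(rep(list(list(loc01 = c(110L, 110L))), 2), reg1)
  y <- group_from_rows(c(list(list(loc01 = c(110L, 110L))),
                         rep(list(list(loc01 = c(112L, 112L))), 3)), reg1)
  expect_equal(unname(nei_da_matrix(list(x = x, y = y))$d["x", "y"]), 0.5)
})

test_that("DA is symmetric, bounded and zero only for identical profiles", {
  set.seed(77)
  for (rep in 1:5) {
    groups <- lapply(1:3, function(g)
      group_from_rows(lapply(1:5, function(i)
        list(loc01 = sort(sample(seq(102L, 110L, 2L), 2, replace = TRUE)),
             loc02 = sort(sample(seq(102L, 110L, 2L), 2, replace = TRUE)),
             loc03 = sort(sample(seq(102L, 110L, 2L), 2, replace = TRUE))))))
    names(groups) <- c("a", "b", "c")
    da <- nei_da_matrix(groups)
    expect_true(isSymmetric(da$d))
    expect_true(all(da$d >= 0 & da$d <= 1))
    expect_true(all(diag(da$d) == 0))
  }
})

test_that("UPGMA reproduces hand-computed small trees", {
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- upgma_tree(d2)
  expect_equal(sort(tr2$tip.label), c("A", "B"))
  expect_equal(unname(tr2$edge.length), c(1, 1))  # leaves at height 1
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgma_tree(d3)
  # ((A:1, B:1):1, C:2)
  expect_equal(attr(tr3, "heights"), c(2, 4))
  ab <- ape::getMRCA(tr3, c("A", "B"))
  expect_equal(unname(ape::node.depth.edgelength(tr3))[1:3], c(2, 2, 2))
  expect_true(ab != ape::getMRCA(tr3, c("A", "C")))
})

test_that("UPGMA agrees with average-linkage hclust on tie-free matrices", {
  set.seed(2024)
  n_checked <- 0
  for (rep in 1:1000) {
    d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    v <- stats::runif(6, 0.1, 1)
    d[lower.tri(d)] <- v
    d <- d + t(d)
    if (anyDuplicated(signif(v, 8))) next  # skip exact ties
    tr <- upgma_tree(d)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    oracle <- ape::as.phylo(hc)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(oracle))), 0)
    expect_equal(sort(attr(tr, "heights")), sort(hc$height), tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 990)
})

test_that("UPGMA is invariant to leaf-order permutation", {
  set.seed(5)
  d <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  v <- stats::runif(10, 0.1, 1)
  d[lower.tri(d)] <- v
  d <- d + t(d)
  tr <- upgma_tree(d)
  perm <- c(4, 1, 5, 3, 2)
  tr2 <- upgma_tree(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))), 0)
  expect_equal(sort(attr(tr, "heights")), sort(attr(tr2, "heights")))
})

test_that("bootstrap gives full support to cleanly separated clusters", {
  gA1 <- group_from_rows(rep(list(list(loc01 = c(102L, 102L),
                                       loc02 = c(102L, 102L),
                                       loc03 = c(102L, 102L))), 3))
  gA2 <- group_from_rows(rep(list(list(loc01 = c(102L, 104L),
                                       loc02 = c(102L, 104L),
                                       loc03 = c(102L, 104L))), 3))
  gB1 <- group_from_rows(rep(list(list(loc01 = c(120L, 120L),
                                       loc02 = c(120L, 120L),
                                       loc03 = c(120L, 120L))), 3))
  gB2 <- group_from_rows(rep(list(list(loc01 = c(120L, 122L),
                                       loc02 = c(120L, 122L),
                                       loc03 = c(120L, 122L))), 3))
  groups <- list(A1 = gA1, A2 = gA2, B1 = gB1, B2 = gB2)
  tr <- bootstrap_support(groups, n_reps = 200, seed = 12)
  sup <- attr(tr, "support")
  expect_equal(unname(sup[["A1|A2"]]), 1)
  expect_equal(unname(sup[["B1|B2"]]), 1)
  # reproducibility: identical seed, identical annotated tree
  tr2 <- bootstrap_support(groups, n_reps = 200, seed = 12)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # n_reps = 0: no annotation
  tr0 <- bootstrap_support(groups, n_reps = 0, seed = 12)
  expect_null(tr0$node.label)
})

test_that("the clonal-L branch separates with high support in simulations", {
  cfg <- small_re_config(31L, n_pops = 3L, n_RR = 12L, n_hyb = 6L,
                         missing_rate = 0)
  sim <- simulate_re_system(cfg)
  ds <- sim$dataset
  part <- partition_hybrids(ds)
  groups <- list(RR = subset_dataset(ds, which(ds$ind$taxon == "RR")),
                 hybrid_L = part$L, hybrid_R = part$R)
  tr <- bootstrap_support(groups, n_reps = 300, seed = 3)
  sup <- attr(tr, "support")
  # hybrid R genomes come from the RR pool: they pair against the L clone
  key <- paste(sort(c("RR", "hybrid_R")), collapse = "|")
  expect_equal(unname(sup[[key]]), 1, tolerance = 0.05)
})

test_that("Newick export round-trips through ape", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, f)
  tr2 <- ape::read.tree(f)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))), 0)
})

test_that("PCA separates disjoint groups and satisfies spectral identities", {
  gA <- group_from_rows(lapply(1:6, function(i)
    list(loc01 = c(102L, 102L + 2L * (i %% 2)), loc02 = c(102L, 104L),
         loc03 = c(102L, 102L))))
  gB <- group_from_rows(lapply(1:6, function(i)
    list(loc01 = c(120L, 120L + 2L * (i %% 2)), loc02 = c(120L, 122L),
         loc03 = c(120L, 120L))))
  pc <- pca_mlg(list(A = gA, B = gB))
  expect_equal(sum(pc$explained_pct), 100, tolerance = 1e-8)
  expect_gt(pc$explained_pct[1], 50)
  ax1 <- pc$coordinates[, 1]
  expect_true(max(ax1[pc$group == "A"]) < min(ax1[pc$group == "B"]) ||
              min(ax1[pc$group == "A"]) > max(ax1[pc$group == "B"]))
  # all records identical: every eigenvalue 0
  same <- group_from_rows(rep(list(list(loc01 = c(102L, 104L))), 4),
                          toy_registry(1L))
  pc0 <- pca_mlg(same)
  expect_true(all(pc0$explained_pct == 0))
  expect_true(all(pc0$coordinates == 0))
})
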