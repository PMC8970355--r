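# AAI matrices, allelic-class clustering, NJ trees, clade concordance and
# reciprocal monophyly.

test_that("pairwise AAI follows the gap-scoring rule", {
  m <- pairwise_aai(c(a = "MKLV", b = "MKLV"))
  expect_equal(m["a", "b"], 100)
  expect_equal(diag(unclass(m)), c(a = 100, b = 100))
  expect_equal(pairwise_aai(c(a = "AAAA", b = "AAAT"))["a", "b"], 75)
  # gap vs residue is a mismatch; the column still counts
  expect_equal(pairwise_aai(c(a = "AA-A", b = "AAAA"))["a", "b"], 75)
  # gap-gap columns are excluded from the denominator
  expect_equal(pairwise_aai(c(a = "AA--", b = "AA--"))["a", "b"], 100)
  expect_error(pairwise_aai(character(0)), "empty alignment")
})

test_that("single-linkage clustering matches the graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    m <- matrix(stats::runif(n * n, 40, 100), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 100
    ids <- sprintf("t%02d", seq_len(n))
    dimnames(m) <- list(ids, ids)
    cl <- aai_cluster(structure(m, class = c("aai_matrix", "matrix", "array")),
                      tau = 86)
    g <- igraph::graph_from_adjacency_matrix(m >= 86, mode = "undirected",
                                             diag = FALSE)
    oracle <- igraph::components(g)$membership
    expect_equal(adjusted_rand_index(cl$class_of[ids], oracle[ids]), 1)
    expect_equal(cl$n_classes, igraph::components(g)$no)
  }
})

test_that("two well-separated blocks give two classes", {
  m <- rbind(c(100, 96, 60, 65), c(96, 100, 62, 61),
             c(60, 62, 100, 97), c(65, 61, 97, 100))
  dimnames(m) <- list(letters[1:4], letters[1:4])
  cl <- aai_cluster(structure(m, class = c("aai_matrix", "matrix", "array")))
  expect_equal(cl$n_classes, 2L)
  expect_equal(unname(cl$class_of["a"]), unname(cl$class_of["b"]))
  expect_false(cl$class_of[["a"]] == cl$class_of[["c"]])
})

test_that("class labels are canonical and order-invariant", {
  prot <- c(a = "MKLVMKLV", b = "MKLVMKLV", c = "MKLVMKLI",
            d = "WWWWWWWW", e = "WWWWWWWW")
  cl1 <- aai_cluster(pairwise_aai(prot), 86)
  cl2 <- aai_cluster(pairwise_aai(prot[c(4, 2, 5, 1, 3)]), 86)
  expect_identical(cl1$class_of[sort(names(cl1$class_of))],
                   cl2$class_of[sort(names(cl2$class_of))])
  # larger class gets label 1
  expect_equal(unname(cl1$class_of["a"]), 1L)
  expect_equal(unname(cl1$class_of["d"]), 2L)
})

test_that("clustering recovers planted lineages on balanced loci", {
  skip_if_not_installed("mclust")
  cfg <- sim_config(n_A = 10, n_B = 10, mode = "codon", omega = 1, k = 3,
                    d_bal = 0.3, theta_within = 0.5, L = 300, seed = 19)
  loc <- simulate_balanced_locus(cfg)
  cl <- aai_cluster(pairwise_aai(translate_seqs(loc$alignment)), 86)
  truth <- loc$truth_class_of
  ari <- adjusted_rand_index(cl$class_of[names(truth)], truth)
  expect_equal(ari, 1)
  expect_equal(ari, mclust::adjustedRandIndex(cl$class_of[names(truth)], truth))
  expect_equal(cl$n_classes, length(unique(truth)))
})

test_that("tau is validated and average linkage is available", {
  m <- pairwise_aai(c(a = "MKLV", b = "MKLV"))
  expect_error(aai_cluster(m, tau = 0), "tau")
  expect_error(aai_cluster(m, tau = 101), "tau")
  expect_equal(aai_cluster(m, 86, linkage = "average")$n_classes, 1L)
})

test_that("NJ recovers additive topologies and rejects tiny inputs", {
  # distances additive on ((a,b),(c,d)) with internal branch 0.1
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.04
  d["c", "d"] <- d["d", "c"] <- 0.06
  for (x in c("a", "b")) for (y in c("c", "d"))
    d[x, y] <- d[y, x] <- 0.25
  aai <- structure(100 - 100 * d, class = c("aai_matrix", "matrix", "array"))
  tr <- nj_tree(aai)
  expect_true(matloci:::is_split(tr, c("a", "b")))
  expect_true(matloci:::is_split(tr, c("c", "d")))
  expect_error(nj_tree(aai[1:2, 1:2]), "3 taxa")
})

test_that("NJ on random additive 6-taxon trees reproduces the topology", {
  skip_if_not_installed("igraph")  # unrelated guard keeps suite portable
  set.seed(8)
  for (i in 1:10) {
    true_tr <- ape::rtree(6)
    d <- ape::cophenetic.phylo(true_tr)
    d <- d / max(d) * 0.5
    ids <- rownames(d)
    aai <- structure(100 - 100 * d, class = c("aai_matrix", "matrix", "array"))
    rec <- nj_tree(aai)
    expect_equal(ape::dist.topo(ape::unroot(true_tr), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("equal distances resolve deterministically", {
  m <- matrix(50, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(m) <- 100
  aai <- structure(m, class = c("aai_matrix", "matrix", "array"))
  expect_identical(ape::write.tree(nj_tree(aai)), ape::write.tree(nj_tree(aai)))
})

test_that("clade concordance distinguishes clade and non-clade classes", {
  tree <- read_newick("((a,b),(c,d));")
  cls <- structure(list(class_of = c(a = 1L, b = 1L, c = 2L, d = 2L),
                        n_classes = 2L, tau = 86, linkage = "single"),
                   class = "allelic_classification")
  expect_true(all(clade_concordance(cls, tree)))
  bad <- cls
  bad$class_of <- c(a = 1L, c = 1L, b = 2L, d = 2L)
  expect_false(any(clade_concordance(bad, tree)))
  mism <- cls
  mism$class_of <- c(a = 1L, b = 1L, c = 2L, z = 2L)
  expect_error(clade_concordance(mism, tree), "mismatch")
})

test_that("concordance is total when lineages dominate within-class noise", {
  for (seed in c(3, 13, 23)) {
    cfg <- sim_config(n_A = 8, n_B = 8, mode = "codon", omega = 1, k = 3,
                      d_bal = 0.3, theta_within = 0.5, L = 300, seed = seed)
    loc <- simulate_balanced_locus(cfg)
    aai <- pairwise_aai(translate_seqs(loc$alignment))
    cl <- aai_cluster(aai, 86)
    expect_true(all(clade_concordance(cl, nj_tree(aai))))
  }
})

test_that("reciprocal monophyly with an outgroup matches the examples", {
  sp <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", OUT = "out")
  r1 <- reciprocal_monophyly("(((A1,A2),(B1,B2)),OUT);", sp, "OUT")
  expect_true(r1$overall)
  r2 <- reciprocal_monophyly("(((A1,B1),(A2,B2)),OUT);", sp, "OUT")
  expect_false(r2$per_species[["A"]])
  expect_false(r2$per_species[["B"]])
  r3 <- reciprocal_monophyly("((((B1,B2),A1),A2),OUT);", sp, "OUT")
  expect_true(r3$per_species[["B"]])
  expect_false(r3$per_species[["A"]])
  expect_false(r3$overall)
  expect_error(reciprocal_monophyly("((A1,A2),(B1,B2));", sp, "OUT"),
               "not in tree")
})
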