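# Genotype assignment, type enumeration, compatibility and parental
# unfolding.

demo_meta <- function(n, species = "spA", prefix = "s") {
  data.frame(strain_id = paste0(prefix, seq_len(n)), species = species,
             specimen_id = paste0("spec", rep(1:2, length.out = n)),
             stringsAsFactors = FALSE)
}

cls_vec <- function(ids, classes)
  stats::setNames(rep(classes, length.out = length(ids)), ids)

test_that("genotypes assemble complex tuples and flag typeability", {
  meta <- demo_meta(3)
  cls <- list(
    aHD1 = cls_vec(c("s1", "s2", "s3"), c(1, 2, 1)),
    aHD2 = cls_vec(c("s1", "s2", "s3"), c(9, 9, 3)),
    bHD1 = cls_vec(c("s1", "s3"), c(4, 4)),     # s2 lost bHD1
    bHD2 = cls_vec(c("s1", "s2", "s3"), c(2, 2, 2)),
    STE3.2 = cls_vec(c("s1", "s2", "s3"), c(5, 5, 1)),
    STE3.4 = cls_vec(c("s1", "s2", "s3"), c(10, 3, 10)))
  g <- assign_genotypes(cls, meta)
  expect_equal(nrow(g), 3L)
  expect_identical(g$alpha, c("1/9", "2/9", "1/3"))
  expect_true(is.na(g$beta[g$strain_id == "s2"]))  # lost bHD1 -> beta missing
  expect_true(all(g$typeable))                     # alpha still types s2
})

test_that("strains absent from all classifications are dropped with warning", {
  meta <- demo_meta(2)
  cls <- list(aHD1 = cls_vec("s1", 1), aHD2 = cls_vec("s1", 2),
              STE3.2 = cls_vec("s1", 1), STE3.4 = cls_vec("s1", 1))
  expect_warning(g <- assign_genotypes(cls, meta), "s2")
  expect_equal(g$strain_id, "s1")
  expect_error(suppressWarnings(
    assign_genotypes(list(aHD1 = cls_vec("zz", 1)), demo_meta(1))),
    "no strains")
})

test_that("type census counts distinct complexes and predicted products", {
  meta <- demo_meta(6)
  cls <- list(
    aHD1 = cls_vec(paste0("s", 1:6), c(1, 1, 2, 2, 3, 3)),
    aHD2 = cls_vec(paste0("s", 1:6), c(1, 1, 1, 1, 1, 1)),
    bHD1 = cls_vec(paste0("s", 1:6), c(1, 2, 1, 2, 1, 2)),
    bHD2 = cls_vec(paste0("s", 1:6), c(1, 1, 1, 1, 1, 1)),
    STE3.2 = cls_vec(paste0("s", 1:6), c(1, 2, 1, 2, 1, 2)),
    STE3.4 = cls_vec(paste0("s", 1:6), c(1, 1, 2, 2, 3, 3)))
  cen <- enumerate_types(assign_genotypes(cls, meta), "pooled")
  expect_equal(cen$n_alpha, 3L)   # (1,1) (2,1) (3,1)
  expect_equal(cen$n_beta, 2L)
  expect_equal(cen$n_MATA, 6L)
  expect_equal(cen$n_MATB, 2L * 3L)
  expect_equal(cen$n_types, 36L)
  expect_lte(cen$observed_MATA, cen$n_MATA)
  expect_lte(cen$observed_MATB, cen$n_MATB)
})

test_that("per-species scope yields one census per species", {
  meta <- rbind(demo_meta(2, "spA"), demo_meta(2, "spB", prefix = "t"))
  ids <- meta$strain_id
  cls <- list(aHD1 = cls_vec(ids, c(1, 2, 1, 1)), aHD2 = cls_vec(ids, 1),
              STE3.2 = cls_vec(ids, c(1, 2, 1, 2)),
              STE3.4 = cls_vec(ids, c(1, 1, 2, 2)))
  cen <- enumerate_types(assign_genotypes(cls, meta), "species")
  expect_named(cen, c("spA", "spB"))
  expect_equal(cen$spA$n_alpha, 2L)
  expect_equal(cen$spB$n_alpha, 1L)
})

test_that("compatibility requires a difference at both mating loci", {
  make_g <- function(alpha, beta, s2, s4, species = "spA", id = "x") {
    data.frame(strain_id = id, species = species, alpha = alpha, beta = beta,
               ste32 = s2, ste34 = s4, stringsAsFactors = FALSE)
  }
  g1 <- make_g("1/9", "4/2", "5", "10")
  expect_equal(predict_compatibility(g1, g1)$verdict, "incompatible")
  # alpha differs, receptors identical -> still incompatible
  g2 <- make_g("2/9", "4/2", "5", "10")
  expect_equal(predict_compatibility(g1, g2)$verdict, "incompatible")
  # alpha and STE3.4 differ -> compatible
  g3 <- make_g("2/9", "4/2", "5", "3")
  r <- predict_compatibility(g1, g3)
  expect_equal(r$verdict, "compatible")
  expect_match(r$reason, "alpha")
  expect_match(r$reason, "STE3.4")
  # decision hinging on a missing component -> indeterminate
  g4 <- make_g(NA_character_, "4/2", "5", "3")
  expect_equal(predict_compatibility(g1, g4)$verdict, "indeterminate")
  # but a present difference elsewhere can still decide
  g5 <- make_g(NA_character_, "7/7", "5", "3")
  expect_equal(predict_compatibility(g1, g5)$verdict, "compatible")
  # inter-species compatible crosses carry the cautionary note
  g6 <- make_g("2/9", "4/2", "5", "3", species = "spB")
  r6 <- predict_compatibility(g1, g6)
  expect_true(r6$interspecies)
  expect_match(r6$reason, "necessary, not sufficient")
})

test_that("compatibility is symmetric on random genotypes", {
  set.seed(33)
  rand_g <- function(id) data.frame(
    strain_id = id, species = sample(c("spA", "spB"), 1),
    alpha = sample(c("1/1", "2/1", NA), 1), beta = sample(c("1/1", "3/2", NA), 1),
    ste32 = sample(c("1", "2", NA), 1), ste34 = sample(c("1", "2", NA), 1),
    stringsAsFactors = FALSE)
  for (i in 1:50) {
    g1 <- rand_g("a"); g2 <- rand_g("b")
    expect_identical(predict_compatibility(g1, g2)$verdict,
                     predict_compatibility(g2, g1)$verdict)
  }
})

test_that("random-mating compatibility frequency matches the closed form", {
  set.seed(71)
  n <- 400
  alpha <- sample(3, n, replace = TRUE); beta <- sample(2, n, replace = TRUE)
  s2 <- sample(2, n, replace = TRUE); s4 <- sample(3, n, replace = TRUE)
  g <- data.frame(strain_id = paste0("s", 1:n), species = "spA",
                  alpha = paste0(alpha, "/1"), beta = paste0(beta, "/1"),
                  ste32 = as.character(s2), ste34 = as.character(s4),
                  stringsAsFactors = FALSE)
  # closed form from component class frequencies
  p_same <- function(x) sum((table(x) / length(x))^2)
  p_mata_same <- p_same(paste(g$alpha, g$beta))
  p_matb_same <- p_same(paste(g$ste32, g$ste34))
  expected <- (1 - p_mata_same) * (1 - p_matb_same)
  pairs <- cbind(sample(n, 2000, replace = TRUE), sample(n, 2000, replace = TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  emp <- mean(vapply(seq_len(nrow(pairs)), function(i)
    predict_compatibility(g[pairs[i, 1], ], g[pairs[i, 2], ])$verdict ==
      "compatible", logical(1)))
  expect_equal(emp, expected, tolerance = 0.05)
})

test_that("parental unfolding recovers the dikaryon's allele sets", {
  meta <- demo_meta(3)
  cls <- list(
    aHD1 = cls_vec(paste0("s", 1:3), c(1, 1, 2)),
    aHD2 = cls_vec(paste0("s", 1:3), c(1, 1, 1)),
    STE3.2 = cls_vec(paste0("s", 1:3), c(7, 7, 7)),
    STE3.4 = cls_vec(paste0("s", 1:3), c(2, 3, 2)))
  g <- assign_genotypes(cls, meta)
  up <- unfold_parental(g)
  expect_equal(up$per_gene$aHD1, c("1", "2"))
  expect_equal(up$per_gene$STE3.2, "7")
  expect_true(up$complete)  # two alleles seen at aHD1 and at STE3.4

  # all siblings identical at every receptor: MATB side unresolved
  cls2 <- cls
  cls2$STE3.4 <- cls_vec(paste0("s", 1:3), c(2, 2, 2))
  up2 <- unfold_parental(assign_genotypes(cls2, meta))
  expect_false(up2$complete)

  # three classes at one gene contradict a single dikaryotic parent
  cls3 <- cls
  cls3$aHD1 <- cls_vec(paste0("s", 1:3), c(1, 2, 3))
  expect_error(unfold_parental(assign_genotypes(cls3, meta)),
               "3 distinct classes")

  # a single sibling can never resolve the parent
  expect_false(unfold_parental(g[1, ])$complete)
})
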