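test_that("NJ recovers additive trees exactly", {
  # matrix from tree ((A:1,B:2):1,(C:3,D:1))
  ids <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 3
  D["B", "C"] <- 6; D["B", "D"] <- 4; D["C", "D"] <- 4
  D <- pmax(D, t(D))
  tr <- njTree(D)
  expect_setequal(tr$tip.label, ids)
  co <- ape::cophenetic.phylo(tr)[ids, ids]
  expect_lt(max(abs(co - D)), 1e-9)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1));")
  expect_equal(ape::dist.topo(ape::unroot(truth), ape::unroot(tr)), 0,
               ignore_attr = TRUE)

  # identical sequences: sister leaves at zero distance
  ids2 <- c("x", "y", "z")
  D2 <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8, 0), 3, 3,
               dimnames = list(ids2, ids2))
  tr2 <- njTree(D2)
  co2 <- ape::cophenetic.phylo(tr2)
  expect_equal(unname(co2["x", "y"]), 0)

  # malformed input
  Dns <- D; Dns[1, 2] <- 99
  expect_error(njTree(Dns), "symmetric")
  expect_error(njTree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ equals additive ground truth on random trees; ape agrees", {
  set.seed(31)
  for (ntaxa in c(4, 5, 6, 8)) {
    for (rep in seq_len(5)) {
      am <- random_additive_matrix(ntaxa)
      tr <- njTree(am$D)
      expect_setequal(tr$tip.label, rownames(am$D))
      co <- ape::cophenetic.phylo(tr)[rownames(am$D), colnames(am$D)]
      expect_lt(max(abs(co - am$D)), 1e-8)
      expect_equal(
        ape::dist.topo(ape::unroot(am$tree), ape::unroot(tr)), 0,
        ignore_attr = TRUE)
      # independent implementation agrees on the topology
      ref <- ape::nj(am$D)
      expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(tr)), 0,
                   ignore_attr = TRUE)
    }
  }
})

.toy_setup <- function(seed = 2, nPerClade = 3) {
  gp <- suppressMessages(generateProteome(
    cladeTemplates()[c(1, 3, 6), ], nPerClade = nPerClade, seed = seed))
  mats <- identityMatrix(gp$proteins)
  tree <- njTree(mats$distance)
  pf <- profileFeatures(gp$proteins)
  ex <- refClades(gp$proteins)
  list(gp = gp, mats = mats, tree = tree, pf = pf,
       ex = ex[!is.na(ex)])
}

test_that("clade assignment: exemplar identity, subtrees, consistency flags", {
  ts <- .toy_setup()
  asg <- assignClades(ts$tree, ts$pf, ts$ex, ts$mats$distance)
  truth <- ts$gp$manifest$clade[match(asg$protein_id,
                                      ts$gp$manifest$protein_id)]
  expect_equal(asg$clade, truth)
  # a query identical to an exemplar keeps that exemplar's clade, d = 0
  exid <- names(ts$ex)[1]
  row <- asg[asg$protein_id == exid, ]
  expect_equal(row$clade, unname(ts$ex[1]))
  expect_equal(row$nearest_distance, 0)
  # exemplars are required
  expect_error(assignClades(ts$tree, ts$pf, character(0),
                            ts$mats$distance), "exemplar")

  # clade/architecture mismatch keeps the label but raises the flag:
  # force a DUF4114 annotation onto a clade-1.3 member
  pf2 <- ts$pf
  m13 <- ts$gp$manifest$protein_id[ts$gp$manifest$clade == "1.3"][3]
  pf2$DUF4114[pf2$protein_id == m13] <- 1L
  pf2$vWFA[pf2$protein_id == m13] <- 0L
  asg2 <- assignClades(ts$tree, pf2, ts$ex, ts$mats$distance)
  r2 <- asg2[asg2$protein_id == m13, ]
  expect_equal(r2$clade, "1.3")
  expect_false(r2$feature_consistent)
  expect_true(all(asg2$feature_consistent[asg2$protein_id != m13]))
})

test_that("assignments are invariant under input permutation", {
  ts <- .toy_setup(seed = 4)
  asg <- assignClades(ts$tree, ts$pf, ts$ex, ts$mats$distance)
  perm <- sample(seq_len(length(ts$gp$proteins)))
  psP <- ts$gp$proteins[perm]
  matsP <- identityMatrix(psP)
  treeP <- njTree(matsP$distance)
  pfP <- profileFeatures(psP)
  asgP <- assignClades(treeP, pfP, ts$ex, matsP$distance)
  asgP <- asgP[match(asg$protein_id, asgP$protein_id), ]
  expect_equal(asgP$clade, asg$clade)
})

test_that("clade summaries use exact medians", {
  asg <- data.frame(protein_id = c("a", "b", "c", "d", "e"),
                    clade = c("1.1", "1.1", "1.1", "1.2", "1.2"))
  pf <- data.frame(protein_id = c("a", "b", "c", "d", "e"),
                   length = c(100L, 120L, 140L, 200L, 300L),
                   n_cys = c(22L, 23L, 24L, 10L, 11L),
                   has_RGD = c(1L, 0L, 0L, 1L, 1L))
  s <- cladeSummary(asg, pf)
  expect_equal(s$median_n_cys[s$clade == "1.1"], 23)
  # even-sized group: mean of the two central values
  expect_equal(s$median_n_cys[s$clade == "1.2"], 10.5)
  expect_equal(s$median_length[s$clade == "1.2"], 250)
  expect_equal(s$frac_RGD[s$clade == "1.1"], 1 / 3)
  expect_equal(s$n, c(3L, 2L))
})

test_that("identity-matrix PCA: centering, signs, separation, errors", {
  # closed-form cross-check on a small symmetric matrix
  ids <- c("u", "v", "w", "x")
  M <- matrix(c(100, 80, 20, 25,
                80, 100, 22, 24,
                20, 22, 100, 85,
                25, 24, 85, 100), 4, 4, byrow = TRUE,
              dimnames = list(ids, ids))
  p <- pcaIdentity(M, k = 2)
  C <- sweep(M, 2, colMeans(M))
  eg <- eigen(stats::cov(C))
  want1 <- C %*% eg$vectors[, 1]
  got1 <- p$coords[, 1]
  # same axis up to sign; our convention fixes the sign deterministically
  expect_lt(min(max(abs(got1 - want1)), max(abs(got1 + want1))), 1e-8)
  expect_equal(sum(p$explained), sum(eg$values[1:2]) / sum(eg$values),
               tolerance = 1e-8)
  l1 <- p$loadings[, 1]
  expect_gt(l1[which.max(abs(l1))], 0)
  # PC1 separates the two blocks by more than the within-block spread
  g1 <- p$coords[c("u", "v"), 1]; g2 <- p$coords[c("w", "x"), 1]
  expect_gt(abs(mean(g1) - mean(g2)),
            max(diff(range(g1)), diff(range(g2))))

  # identical rows collapse to the origin
  I3 <- matrix(50, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  p0 <- pcaIdentity(I3, k = 2)
  expect_lt(max(abs(p0$coords)), 1e-10)

  expect_error(pcaIdentity(M, k = 4), "smaller")
  # explained variance fractions sum to at most 1
  expect_lte(sum(p$explained), 1 + 1e-12)
})
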