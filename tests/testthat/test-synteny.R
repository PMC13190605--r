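test_that("minor-pilin cluster detection follows the gap rule", {
  # fimU-pilV-pilW-pilX-pilY1 plus a trailing non-role gene
  f <- make_features(c("fimU", "pilV", "pilW", "pilX", "pilY1", "other"))
  cl <- detectClusters(f)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$cluster_type, "minor_cluster")
  expect_equal(cl$pilY1_tags, "g05")
  expect_equal(strsplit(cl$members, ",")[[1]],
               sprintf("g%02d", 1:5))

  # pilY1 and minor pilins inside the core-gene run
  f2 <- make_features(c("pilQ", "pilP", "pilO", "pilN", "pilM", "fimU",
                        "pilV", "pilW", "pilX", "pilY1", "pilB", "pilT",
                        "pilC", "pilA"))
  cl2 <- detectClusters(f2)
  expect_equal(cl2$cluster_type, "major_embedded_pilY1")

  # a pilY1 with the nearest role gene 10 genes away is solitary
  f3 <- make_features(c("pilY1", rep("other", 9), "pilX", "pilW", "pilV"))
  cl3 <- detectClusters(f3)
  expect_setequal(cl3$cluster_type, c("solitary_pilY1", "other"))
  expect_equal(cl3$pilY1_tags[cl3$cluster_type == "solitary_pilY1"], "g01")

  # the bp gap rule splits a chain even with few intervening genes
  f4 <- make_features(c("pilX", "pilY1"), gap = 5000)
  cl4 <- detectClusters(f4)
  expect_equal(nrow(cl4), 2L)

  # unsorted input is rejected
  f5 <- make_features(c("pilX", "pilY1"))
  expect_error(detectClusters(rev(f5)), "sorted")
})

test_that("cluster calls partition role genes and survive mirroring", {
  f <- make_features(c("fimU", "pilV", "other", "pilW", "pilX", "pilY1",
                       rep("other", 3), "pilY1", "other", "pilA", "pilB",
                       "pilT", "pilC", "pilM", "pilN", "pilO", "pilP",
                       "pilQ"))
  cl <- detectClusters(f)
  members <- unlist(strsplit(cl$members, ","))
  expect_equal(anyDuplicated(members), 0L)

  L <- max(GenomicRanges::end(f)) + 1000L
  fm <- mirror_features(f, L)
  clm <- detectClusters(fm)
  expect_setequal(
    vapply(strsplit(clm$members, ","), function(x)
      paste(sort(x), collapse = ","), ""),
    vapply(strsplit(cl$members, ","), function(x)
      paste(sort(x), collapse = ","), ""))
  expect_setequal(clm$cluster_type, cl$cluster_type)
})

test_that("linkage: window rule, evidence, exhaustive partition", {
  # pilY1 immediately downstream of pilX
  f <- make_features(c("other", "pilX", "pilY1", "other"))
  lk <- classifyLinkage(f)
  expect_equal(nrow(lk), 1L)
  expect_equal(lk$status, "linked")
  expect_equal(lk$evidence, "pilX:-1")

  # contig with only pilY1 and `other` genes
  f2 <- make_features(c("other", "other", "pilY1", "other"))
  expect_equal(classifyLinkage(f2)$status, "unlinked")

  # minor pilin just outside the 5-gene window
  f3 <- make_features(c("pilX", rep("other", 5), "pilY1"))
  expect_equal(classifyLinkage(f3)$status, "unlinked")
  expect_equal(classifyLinkage(f3, windowGenes = 6)$status, "linked")

  # every pilY1 gets exactly one call; linked/unlinked partition the set
  f4 <- make_features(c("pilY1", "pilX", rep("other", 6), "pilY1"))
  lk4 <- classifyLinkage(f4)
  expect_equal(nrow(lk4), 2L)
  expect_setequal(lk4$status, c("linked", "unlinked"))
})

test_that("translational coupling thresholds and strand requirement", {
  gr <- GenomicRanges::GRanges(
    seqnames = "c", strand = c("+", "+", "+", "+", "-"),
    ranges = IRanges::IRanges(start = c(100, 397, 1200, 1605, 2400),
                              end = c(400, 900, 1600, 2000, 2800)),
    locus_tag = paste0("t", 1:5), role = rep("other", 5))
  cp <- detectTranslationalCoupling(gr)
  # t1-t2: ATGA-style 4-bp overlap (g = -4); t3-t4: g = 4 boundary case
  expect_equal(cp$upstream_tag, c("t1", "t3"))
  expect_equal(cp$gap_bp, c(-4L, 4L))
  # g just over the threshold is not coupled
  expect_equal(nrow(detectTranslationalCoupling(gr, maxOverlapGap = 3)), 1L)
  # opposite strand pairs are never coupled (t4-t5 overlap ignored)
  expect_false("t4" %in% cp$upstream_tag)

  # a 200-bp gap is not coupled
  gr2 <- make_features(c("other", "other"), gap = 200)
  expect_equal(nrow(detectTranslationalCoupling(gr2)), 0L)
})

test_that("contig-edge flag uses sequence-region lengths", {
  f <- make_features(c("pilY1"), start0 = 5000, seqlen = 1000000L)
  expect_false(edgeFlag(f, "g01"))
  f2 <- make_features(c("pilY1"), start0 = 999000, gene_len = 500,
                      seqlen = 1000000L)
  expect_true(edgeFlag(f2, "g01"))
  f3 <- make_features(c("pilY1"), start0 = 5000)
  expect_warning(fl <- edgeFlag(f3, "g01"), "unknown")
  expect_true(is.na(fl))
  expect_error(edgeFlag(f, "nope"), "locus_tag")
})
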