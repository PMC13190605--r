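test_that("pattern compilation: tokens, alternation, malformed specs", {
  m1 <- compilePattern("Dx(D/N)xDGxxD", name = "motif1")
  expect_length(m1@tokens, 9L)
  expect_equal(sort(m1@tokens[[3]]), c("D", "N"))
  expect_equal(m1@tokens[[1]], "D")
  expect_length(m1@tokens[[2]], 0L)  # wildcard

  m3 <- compilePattern("DxD/NxDxxxxxxD/E", name = "motif3")
  expect_length(m3@tokens, 12L)
  expect_equal(sort(m3@tokens[[3]]), c("D", "N"))
  expect_equal(sort(m3@tokens[[12]]), c("D", "E"))

  rgd <- compilePattern("RGD")
  expect_length(rgd@tokens, 3L)
  expect_true(all(lengths(rgd@tokens) == 1L))

  midas <- defaultMotifs()[["MIDAS"]]
  expect_length(midas@tokens, 5L)
  expect_equal(nrow(midas@tail), 2L)
  expect_false(any(midas@tail$required))  # annotated, not required

  expect_error(compilePattern("Dx(D/N"), "alternation")
  expect_error(compilePattern("D/"), "alternation")
  expect_error(compilePattern("Dx?"), "unexpected")
})

test_that("scanning: known positions, overlap, X semantics", {
  rgd <- compilePattern("RGD")
  h <- scanMotif("AARGDKK", rgd)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(3L, 5L))
  expect_equal(h$matched, "RGD")

  m2 <- defaultMotifs()[["motif2"]]
  h2 <- scanMotif("DADANAAAD", m2)
  expect_equal(c(h2$start, h2$end), c(1L, 9L))

  # overlapping matches are all reported, ascending
  hh <- scanMotif("RGRGDGD", rgd)
  expect_equal(hh$start, 3L)
  hov <- scanMotif(strrep("DD", 8), compilePattern("DxD"))
  expect_equal(hov$start, seq_len(14L))

  # X never satisfies a fixed position but does satisfy a wildcard
  expect_equal(nrow(scanMotif("RGX", rgd)), 0L)
  expect_equal(nrow(scanMotif("DXDXNXXXD", m2)), 1L)

  # matched equals the sequence slice; hit width = token count
  h3 <- scanMotif("KKDADANAAADKK", m2)
  expect_equal(h3$matched, substring("KKDADANAAADKK", h3$start, h3$end))
  expect_equal(h3$end - h3$start + 1L, 9L)
})

test_that("scanner equals the per-offset brute-force oracle", {
  pats <- defaultMotifs()
  set.seed(101)
  alpha <- c(AA20, "X")
  for (trial in seq_len(200)) {
    seq <- paste(sample(alpha, 200, replace = TRUE, prob = c(rep(1, 2),
      rep(4, 2), rep(1, 16), 0.5)), collapse = "")
    for (nm in names(oracle_tokens)) {
      expect_identical(scanMotif(seq, pats[[nm]])$start,
                       oracle_scan_starts(seq, oracle_tokens[[nm]]),
                       label = paste("motif", nm, "trial", trial))
    }
  }
})

test_that("prepending k residues shifts every hit start by exactly k", {
  pats <- defaultMotifs()
  set.seed(7)
  for (trial in seq_len(20)) {
    seq <- paste(sample(AA20, 150, replace = TRUE), collapse = "")
    k <- sample(1:12, 1)
    padded <- paste0(strrep("P", k), seq)  # P opens none of the motifs
    for (nm in names(pats)) {
      expect_identical(scanMotif(padded, pats[[nm]])$start,
                       scanMotif(seq, pats[[nm]])$start + k)
    }
  }
})

test_that("cysteine census is exact and positional", {
  expect_equal(cysteineCensus("CACC"),
               list(length = 4L, n_cys = 3L, cys_positions = c(1L, 3L, 4L)))
  noc <- cysteineCensus("ADGKLM")
  expect_equal(noc$n_cys, 0L)
  expect_equal(noc$cys_positions, integer(0))
  # census is invariant under motif content at other positions
  expect_equal(cysteineCensus("CRGDC")$n_cys, 2L)
})

test_that("profiles aggregate motifs, census, domains and all_three_ca", {
  seq1 <- paste0("DADYDGAKD", "KKK", "DADANAAAD", "KKK", "DADKDAAAAAAE",
                 "KKKCC")
  ps <- ProteinSet(c(trip = seq1, rgdonly = "AAARGDAAA"),
                   domains = data.frame(
                     protein_id = c("trip", "trip"),
                     name = c("vWFA", "beta_propeller"),
                     start = c(1L, 10L), end = c(9L, 30L)))
  pf <- profileFeatures(ps)
  tr <- pf[pf$protein_id == "trip", ]
  expect_equal(tr$has_motif1, 1L)
  expect_equal(tr$has_motif2, 1L)
  expect_equal(tr$has_motif3, 1L)
  expect_equal(tr$all_three_ca, 1L)
  expect_equal(tr$n_cys, 2L)
  expect_equal(tr$vWFA, 1L)
  expect_equal(tr$beta_propeller, 1L)
  expect_equal(tr$DUF4114, 0L)
  ro <- pf[pf$protein_id == "rgdonly", ]
  expect_equal(unlist(ro[c("has_motif1", "has_motif2", "has_motif3",
                           "has_MIDAS", "has_RGD")], use.names = FALSE),
               c(0L, 0L, 0L, 0L, 1L))
  expect_equal(ro$all_three_ca, 0L)
  # flags are monotone under concatenation: adding sequence only adds hits
  ps2 <- ProteinSet(c(trip = paste0(seq1, "RGD")))
  pf2 <- profileFeatures(ps2)
  expect_gte(pf2$has_RGD, tr$has_RGD)
  expect_equal(pf2$all_three_ca, 1L)
})
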