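test_that("FASTA reading: ids, case folding, ambiguity letters, round-trip", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "ac", "dc", ">p2", "MKLY"), fa)
  ps <- readFasta(fa, organism = "toy")
  expect_s4_class(ps, "ProteinSet")
  expect_equal(proteinIds(ps), c("p1", "p2"))
  expect_equal(as.character(sequences(ps))[["p1"]], "ACDC")
  expect_equal(organisms(ps), c("toy", "toy"))

  # round-trip: write then re-read reproduces records exactly
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(ps, fa2)
  ps2 <- readFasta(fa2, organism = "toy")
  expect_identical(as.character(sequences(ps2)), as.character(sequences(ps)))

  # ambiguity letters fold to X with a warning
  writeLines(c(">p1", "ACUBZJ"), fa)
  expect_warning(psx <- readFasta(fa), "U/B/Z/J")
  expect_equal(as.character(sequences(psx))[["p1"]], "ACXXXX")

  # duplicate ids rejected, naming the id
  writeLines(c(">p1", "ACDC", ">p1 again", "MKLY"), fa)
  expect_error(readFasta(fa), "p1")
  # empty sequence rejected
  writeLines(c(">p1", "", ">p2", "MK"), fa)
  expect_error(readFasta(fa), "empty")
})

test_that("GFF3 reading: roles, coordinates, strand and CDS preference", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region ctg1 1 50000",
    "ctg1\tsrc\tCDS\t100\t400\t.\t+\t0\tID=A;locus_tag=A;gene=pilY1",
    "ctg1\tsrc\tCDS\t500\t900\t.\t-\t0\tID=B;locus_tag=B;gene=PilW",
    "ctg1\tsrc\tgene\t1000\t1500\t.\t+\t.\tID=C;locus_tag=C;role=tfcP",
    "ctg1\tsrc\tCDS\t2000\t2500\t.\t+\t0\tID=D;locus_tag=D;gene=unknownthing"),
    gff)
  gr <- readGff3(gff)
  expect_equal(length(gr), 4L)
  expect_equal(GenomicRanges::start(gr)[gr$locus_tag == "A"], 100L)
  expect_equal(GenomicRanges::end(gr)[gr$locus_tag == "A"], 400L)
  expect_equal(gr$role[gr$locus_tag == "A"], "pilY1")
  # case-insensitive gene= mapping
  expect_equal(gr$role[gr$locus_tag == "B"], "pilW")
  # role= attribute wins and maps
  expect_equal(gr$role[gr$locus_tag == "C"], "tfcP")
  # unknown names fall to `other`
  expect_equal(gr$role[gr$locus_tag == "D"], "other")
  # contig length from the pragma
  expect_equal(unname(GenomeInfoDb::seqlengths(gr)["ctg1"]), 50000L)

  # CDS preferred when both CDS and gene carry one locus_tag
  writeLines(c(
    "##gff-version 3",
    "ctg1\tsrc\tgene\t90\t410\t.\t+\t.\tID=Ag;locus_tag=A;gene=pilY1",
    "ctg1\tsrc\tCDS\t100\t400\t.\t+\t0\tID=Ac;locus_tag=A;gene=pilY1"),
    gff)
  gr2 <- readGff3(gff)
  expect_equal(length(gr2), 1L)
  expect_equal(GenomicRanges::start(gr2), 100L)

  # unknown strand symbol is an error
  writeLines(c(
    "##gff-version 3",
    "ctg1\tsrc\tCDS\t100\t400\t.\t.\t0\tID=A;locus_tag=A;gene=pilY1"),
    gff)
  expect_error(readGff3(gff), "strand")
})

test_that("PDB reading: fixed columns, altloc filter, HETATM; bio3d agrees", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(
    res_index = c(1, 1, 2, 2, 3), res_name = c("ALA", "ALA", "CYS", "CYS",
                                               "GLY"),
    atom_name = c("CA", "CA", "CA", "SG", "CA"),
    altloc = c("", "B", "", "", ""),
    x = c(1.0, 9.9, 4.5, 5.5, 8.0), y = c(2.0, 9.9, 5.5, 6.5, 9.0),
    z = c(3.0, 9.9, 6.5, 7.5, 10.0))
  write_toy_pdb(pdb, atoms)
  m <- readPdb(pdb)
  # altloc B duplicate dropped; 4 atoms remain in file order
  expect_equal(nrow(m@atoms), 4L)
  expect_equal(m@atoms$x[1], 1.000)
  expect_equal(m@atoms$atom_name, c("CA", "CA", "SG", "CA"))
  expect_equal(m@atoms$res_name[2], "CYS")

  # independent parser cross-check on the kept atoms
  bp <- bio3d::read.pdb(pdb)
  kept <- bp$atom[bp$atom$alt %in% c(NA, "A"), ]
  expect_equal(m@atoms$x, kept$x)
  expect_equal(m@atoms$res_index, kept$resno)

  # HETATM ignored; file with no ATOM records errors
  writeLines(c("HETATM    1  O   HOH A   1       1.0     2.0     3.0",
               "END"), pdb)
  expect_error(readPdb(pdb), "no ATOM")

  # round-trip through writePdb
  write_toy_pdb(pdb, atoms[atoms$altloc == "", names(atoms) != "altloc"])
  m1 <- readPdb(pdb)
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  writePdb(m1, pdb2)
  m2 <- readPdb(pdb2)
  expect_equal(m1@atoms, m2@atoms)
})

test_that("writeOutputs is deterministic and handles empty inputs", {
  ps <- ProteinSet(c(b1 = "DADANAAADCC", a1 = "AARGDKKC"))
  pf <- profileFeatures(ps)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeOutputs(pf, outdir = d1)
  writeOutputs(pf, outdir = d2)
  for (f in c("feature_table.tsv", "clusters.tsv", "report.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # rows sorted by id
  ft <- read.delim(file.path(d1, "feature_table.tsv"))
  expect_equal(ft$protein_id, c("a1", "b1"))
  # profile with no motifs: all flags 0, empty position fields
  expect_equal(ft$has_motif1, c(0L, 0L))
  expect_true(is.na(ft$motif2_starts[1]) || ft$motif2_starts[1] == "")
  # empty inputs: headers-only TSV, empty tree flagged in the report
  d3 <- withr::local_tempdir()
  writeOutputs(pf[0, ], outdir = d3)
  expect_equal(length(readLines(file.path(d3, "feature_table.tsv"))), 1L)
  rep <- jsonlite::read_json(file.path(d3, "report.json"))
  expect_match(rep$tree, "empty")
})
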