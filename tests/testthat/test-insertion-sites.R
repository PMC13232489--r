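featSet <- function(len = 200L, ...) ProteinFeatureSet(proteinLength = len, ...)

test_that("mature start lies downstream of all N-terminal processing", {
  expect_equal(inferMatureStart(
    featSet(signalEnd = 20L, initMetRemoved = TRUE)), 21L)
  expect_equal(inferMatureStart(featSet()), 1L)
  expect_equal(inferMatureStart(featSet(initMetRemoved = TRUE)), 2L)
  # chained propeptide after a signal peptide
  expect_equal(inferMatureStart(
    featSet(signalEnd = 20L, propeptides = rbind(c(21L, 30L)))), 31L)
  # chain start dominates when further downstream
  expect_equal(inferMatureStart(featSet(chainStart = 25L, chainEnd = 180L)),
               25L)
})

test_that("mature end lies upstream of C-terminal processing", {
  expect_equal(inferMatureEnd(
    featSet(200L, propeptides = rbind(c(181L, 200L)))), 180L)
  expect_equal(inferMatureEnd(featSet(200L)), 200L)
  expect_equal(inferMatureEnd(featSet(320L, chainStart = 23L,
                                      chainEnd = 305L)), 305L)
})

test_that("lipidation sites push the boundary five residues away", {
  lipC <- data.frame(pos = 200L, class = "C")
  r <- applyLipidationOffset(200L, lipC, "C")
  expect_equal(r$boundary, 194L)
  expect_true(r$adjusted)

  lipN <- data.frame(pos = 2L, class = "N")
  r2 <- applyLipidationOffset(2L, lipN, "N")
  expect_equal(r2$boundary, 8L)
  expect_true(r2$adjusted)

  r3 <- applyLipidationOffset(10L, data.frame(pos = integer(0),
                                              class = character(0)), "N")
  expect_equal(r3$boundary, 10L)
  expect_false(r3$adjusted)
  # distant site: no adjustment
  r4 <- applyLipidationOffset(100L, lipC, "C")
  expect_false(r4$adjusted)
})

test_that("sorting-motif scan flags canonical patterns, warning-only", {
  expect_equal(scanSortingMotifs("MAAAAAAAAAAAAAAAASKL"), "PTS1")
  expect_equal(scanSortingMotifs("MAAAAAAAAAAAAAAAKDEL"), "KDEL")
  expect_equal(scanSortingMotifs("MAAAAAAAAAAAAAAACVIM"), "CAAX")
  expect_true("PTS2" %in% scanSortingMotifs(
    paste0("MRLAAVS", strrep("E", 60))))
  expect_true("DILYS" %in% scanSortingMotifs("MAAAAAAAAAAAAAAKKAA"))
  expect_equal(scanSortingMotifs(strrep("E", 50)), character(0))
  expect_equal(scanSortingMotifs("MA"), character(0))
})

test_that("insertion specs honor the codon-boundary conventions", {
  # toy single-exon plus-strand gene: M A C D E * starting at 1-based 51
  cds <- "ATGGCTTGCGATGAA TAA"
  cds <- gsub(" ", "", cds)
  chrom <- paste0(strrep("T", 50), cds, strrep("T", 50))
  g <- GenomeAssembly(c(chrI = chrom))
  tr <- TranscriptModel("t", "g", "chrI", "+", 50L, 50L + nchar(cds))
  ft <- ProteinFeatureSet(geneId = "g", proteinLength = 5L,
                          initMetRemoved = TRUE)
  sp <- makeInsertionSpecs(tr, ft, g)
  # N boundary before residue 2: immediately after codon 1 -> its last base
  expect_equal(sp$N$boundaryResidue, 2L)
  expect_equal(sp$N$paperCoord, 53L)
  # C boundary after residue 5: immediately 5' of the stop codon
  expect_equal(sp$C$boundaryResidue, 5L)
  expect_equal(sp$C$interbase, 50L + 15L)
  expect_equal(sp$C$paperCoord, 65L)

  # protein-length mismatch is an error
  ftBad <- ProteinFeatureSet(geneId = "g", proteinLength = 7L)
  expect_error(makeInsertionSpecs(tr, ftBad, g), "mismatch")

  # no processing info at all: flagged, boundary before residue 1
  ftNone <- ProteinFeatureSet(geneId = "g", proteinLength = 5L)
  spN <- makeInsertionSpecs(tr, ftNone, g)
  expect_equal(spN$N$boundaryResidue, 1L)
  expect_true("NO_PROCESSING_INFO" %in% spN$N$flags)
})

test_that("boundaries stay ordered and motif scanning never moves them", {
  sf <- smallFixture()
  for (gid in names(sf$transcripts)) {
    tr <- sf$transcripts[[gid]]
    sp1 <- makeInsertionSpecs(tr, sf$features[[gid]], sf$genome,
                              scanMotifs = TRUE)
    sp2 <- makeInsertionSpecs(tr, sf$features[[gid]], sf$genome,
                              scanMotifs = FALSE)
    expect_lte(sp1$N$boundaryResidue, sp1$C$boundaryResidue)
    expect_gte(sp1$N$boundaryResidue, 1L)
    expect_lte(sp1$C$boundaryResidue, proteinLength(tr))
    expect_equal(sp1$N$interbase, sp2$N$interbase)
    expect_equal(sp1$C$interbase, sp2$C$interbase)
  }
})

test_that("an in-frame tag inserted at either point preserves the protein", {
  sf <- smallFixture()
  for (gid in names(sf$transcripts)[1:8]) {
    tr <- sf$transcripts[[gid]]
    sp <- makeInsertionSpecs(tr, sf$features[[gid]], sf$genome)
    prot <- sub("\\*$", "", translateDNA(splicedCDS(tr, sf$genome)))
    for (term in c("N", "C")) {
      spec <- sp[[term]]
      ed <- applyEditToLocus(sf$genome, tr, spec$interbase,
                             list(mutations = NULL), tagTx = "GCTGCA")
      prot2 <- sub("\\*$", "", translateDNA(splicedCDS(ed$transcript,
                                                       ed$genome)))
      b <- spec$boundaryResidue
      ins <- if (term == "N") b - 1L else b   # residues before the tag
      expected <- paste0(substr(prot, 1, ins), "AA",
                         substr(prot, ins + 1L, nchar(prot)))
      expect_equal(prot2, expected, label = paste(gid, term))
    }
  }
})

test_that("feature tables round-trip through the TSV dialect", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "uniprot_id\tgene_id\tlength\tinit_met_removed\tsignal_end\ttransit_end\tpropeptides\tchain\tlipidation",
    "U1\tg1\t200\t1\t20\t\t25-40;181-200\t41-180\t2:N",
    "U2\tg2\t100\t0\t\t\t\t\t"), f)
  ft <- readProteinFeatures(f)
  expect_equal(ft$g1@signalEnd, 20L)
  expect_equal(nrow(ft$g1@propeptides), 2L)
  expect_equal(ft$g1@chainEnd, 180L)
  expect_equal(ft$g1@lipidation$class, "N")
  expect_true(is.na(ft$g2@signalEnd))
  expect_false(ft$g2@initMetRemoved)
})
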