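test_that("window extraction truncates at contig ends and flags it", {
  g <- GenomeAssembly(c(chrI = randomWindow(2000L)))
  w <- extractWindow(g, "chrI", 1000L, 50L)
  expect_equal(nchar(w$seq), 100L)
  expect_equal(w$start0, 950L)
  expect_false(w$truncated)

  wL <- extractWindow(g, "chrI", 10L, 50L)
  expect_equal(w$start0 >= 0, TRUE)
  expect_equal(nchar(wL$seq), 60L)
  expect_true(wL$truncated)

  wR <- extractWindow(g, "chrI", 1990L, 50L)
  expect_equal(nchar(wR$seq), 60L)
  expect_true(wR$truncated)
})

test_that("enumeration equals the brute-force 23-mer scan", {
  set.seed(42)
  for (i in 1:25) {
    seq <- randomWindow(200L)
    win <- list(seq = seq, chrom = "w", start0 = 0L, truncated = FALSE,
                padLeft = "", padRight = "")
    got <- enumerateGuides(win)
    want <- bruteForceGuides(seq)
    keyG <- sort(paste(got$proto, got$pam, got$strand, got$protoStart0))
    keyW <- sort(paste(want$proto, want$pam, want$strand, want$protoStart0))
    expect_equal(keyG, keyW)
  }
  # window of all A's: nothing
  winA <- list(seq = strrep("A", 100L), chrom = "w", start0 = 0L,
               truncated = FALSE, padLeft = "", padRight = "")
  expect_equal(nrow(enumerateGuides(winA)), 0L)
  # reverse complement: same count, strands swapped
  seq <- randomWindow(200L)
  win <- list(seq = seq, chrom = "w", start0 = 0L, truncated = FALSE,
              padLeft = "", padRight = "")
  winRC <- list(seq = oracleRevComp(seq), chrom = "w", start0 = 0L,
                truncated = FALSE, padLeft = "", padRight = "")
  a <- enumerateGuides(win); b <- enumerateGuides(winRC)
  expect_equal(nrow(a), nrow(b))
  expect_equal(sum(a$strand == "+"), sum(b$strand == "-"))
  expect_equal(sort(a$proto), sort(b$proto))
})

test_that("composition and PAM-context filters match the stated rules", {
  cand <- function(proto, pam = "AGG", pamNext = "A") {
    data.frame(proto = proto, pam = pam, pamNext = pamNext, strand = "+",
               protoStart0 = 0L, cutInterbase = 17L)
  }
  f <- function(...) applyGuideFilters(cand(...))
  ok <- f("ATGCATGCATGCATGCATGC")           # GC 50
  expect_equal(ok$rejectReasons, "")
  expect_equal(ok$transcriptionClass, "in_vivo")
  expect_equal(ok$gc, 50)

  expect_match(f("AAAAAAATGCATGCATGCGC")$rejectReasons, "HOMOPOLYMER")
  tttt <- f("TTTTAGCATGCATGCATGGC")
  expect_equal(tttt$rejectReasons, "")
  expect_equal(tttt$transcriptionClass, "in_vitro_only")
  expect_match(f("ATGCATGCATGCATGCATGC", pam = "GGG")$rejectReasons,
               "PAM_GGG")
  expect_match(f("ATGCATGCATGCATGCATGC", pam = "TGG",
                 pamNext = "G")$rejectReasons, "PAM_NEXT_G")
  # GC bounds inclusive: exactly 25% and 80% pass
  expect_equal(f("GGGCCATATATATATATATA")$rejectReasons, "")    # GC 25
  gc80 <- f("GCGCGCGCGCGCGCGCATAT")                            # GC 80
  expect_equal(gc80$rejectReasons, "")
  expect_match(f("GCGCGCGCGCGCGCGCGCAT")$rejectReasons, "GC_HIGH")
  expect_match(f("ATATATATATATATATATGC")$rejectReasons, "GC_LOW")
  # missing PAM context (contig end) fails conservatively
  expect_match(f("ATGCATGCATGCATGCATGC", pamNext = "")$rejectReasons,
               "PAM_NEXT_G")
})

test_that("cut coordinates sit 3 nt 5' of the PAM on either strand", {
  plus <- data.frame(strand = "+", protoStart0 = 100L)
  expect_equal(cutCoordinate(plus), 117L)
  # minus-strand candidate whose PAM occupies plus-strand [97,100)
  minus <- data.frame(strand = "-", protoStart0 = 100L)
  expect_equal(cutCoordinate(minus), 103L)
  # every enumerated candidate: |PAM 5' boundary - cut| == 3
  seq <- randomWindow(300L)
  win <- list(seq = seq, chrom = "w", start0 = 0L, truncated = FALSE,
              padLeft = "", padRight = "")
  cands <- enumerateGuides(win)
  pam5 <- ifelse(cands$strand == "+", cands$protoStart0 + 20L,
                 cands$protoStart0)
  expect_true(all(abs(pam5 - cands$cutInterbase) == 3L))
})

test_that("ranking prefers fewest off-targets then proximity", {
  mk <- function(ot, d, class, strand = "+", start = d) {
    data.frame(proto = strrep("A", 20), pam = "TGG", pamNext = "A",
               strand = strand, protoStart0 = start,
               cutInterbase = 100L + d, gc = 50, rejectReasons = "",
               transcriptionClass = class, offtargetCount = ot)
  }
  cands <- rbind(mk(0, 10, "in_vivo"), mk(0, 4, "in_vivo"),
                 mk(2, 1, "in_vivo"))
  sel <- rankAndSelect(cands, 100L)
  expect_equal(sel$inVivoBest$offtargetCount, 0)
  expect_equal(sel$inVivoBest$distance, 4)

  # in-vitro-only guide reported only when strictly closer
  cands2 <- rbind(mk(0, 9, "in_vivo"), mk(0, 3, "in_vitro_only"))
  sel2 <- rankAndSelect(cands2, 100L)
  expect_equal(sel2$inVitroExtra$distance, 3)
  cands3 <- rbind(mk(0, 9, "in_vivo"), mk(0, 12, "in_vitro_only"))
  sel3 <- rankAndSelect(cands3, 100L)
  expect_null(sel3$inVitroExtra)

  # empty candidate list -> no-guide flag
  sel4 <- rankAndSelect(cands3[0, ], 100L)
  expect_true(sel4$noGuide)

  # tie-break: plus strand before minus, then smaller start
  tie <- rbind(mk(0, 5, "in_vivo", "-", 200L), mk(0, 5, "in_vivo", "+", 300L),
               mk(0, 5, "in_vivo", "+", 250L))
  selT <- rankAndSelect(tie, 100L)
  expect_equal(selT$inVivoBest$strand, "+")
  expect_equal(selT$inVivoBest$protoStart0, 250L)
})

test_that("guide design is deterministic and respects the no-guide path", {
  sf <- smallFixture()
  tr <- sf$transcripts[[1L]]
  sp <- makeInsertionSpecs(tr, sf$features[[1L]], sf$genome)
  a <- designGuides(sf$genome, sp$N, sf$index)
  b <- designGuides(sf$genome, sp$N, sf$index)
  expect_identical(a$selection$inVivoBest, b$selection$inVivoBest)
  expect_identical(a$candidates, b$candidates)

  # a window with no NGG at all yields a no-guide selection, not an error
  gA <- GenomeAssembly(c(chrI = strrep("A", 500)))
  idxA <- buildPamIndex(gA)
  des <- designGuides(gA, list(chrom = "chrI", interbase = 250L), idxA)
  expect_true(des$selection$noGuide)
})
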