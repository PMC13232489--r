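test_that("nearest-neighbor Tm matches frozen thermodynamic references", {
  # reference values computed from the SantaLucia unified parameters at
  # 50 mM monovalent salt, 250 nM total oligo
  expect_equal(meltingTemperature("ATGCATGCATGCATGCATGC"), 57.683,
               tolerance = 0.01)
  expect_equal(meltingTemperature("ACGTACGTACGTACGTACGTACGTAC"), 59.861,
               tolerance = 0.01)
  expect_equal(meltingTemperature("TTTTAAAACCCCGGGGATCG"), 54.553,
               tolerance = 0.01)
  expect_true(is.na(meltingTemperature("ACGT")))        # too short
  expect_true(is.na(meltingTemperature(strrep("AN", 10))))
})

test_that("silent-mutation plans are synonymous and hit the 4-5 target", {
  sf <- smallFixture()
  checked <- 0L
  for (gid in names(sf$transcripts)[1:8]) {
    tr <- sf$transcripts[[gid]]
    sp <- makeInsertionSpecs(tr, sf$features[[gid]], sf$genome)
    for (term in c("N", "C")) {
      des <- designGuides(sf$genome, sp[[term]], sf$index)
      best <- des$selection$inVivoBest
      if (is.null(best)) next
      plan <- planSilentMutations(best, tr, sf$genome)
      m <- plan$mutations
      expect_equal(plan$count, nrow(m))
      if (length(plan$warnings) == 0L)
        expect_true(plan$count >= 4L && plan$count <= 5L)
      # every codon-level mutation re-translates identically
      cm <- m[!is.na(m$codonIndex), , drop = FALSE]
      if (nrow(cm)) {
        same <- vapply(seq_len(nrow(cm)), function(i)
          oracleTranslate(cm$codonBefore[i]) ==
            oracleTranslate(cm$codonAfter[i]), logical(1))
        expect_true(all(same))
        expect_true(all(cm$codonBefore != cm$codonAfter))
      }
      # refs match the genome; alts differ
      for (i in seq_len(nrow(m))) {
        expect_equal(sliceSeq(sf$genome, tr@chrom, m$pos0[i], m$pos0[i] + 1L),
                     m$ref[i])
        expect_false(m$ref[i] == m$alt[i])
      }
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("single-codon amino acids cannot yield enough silent changes", {
  # CDS whose guide footprint is covered by Met/Trp codons only
  cds <- paste0("ATG", strrep("ATGTGG", 12), "TAA")
  chrom <- paste0(strrep("ACGTC", 12L), cds, strrep("ACGTC", 12L))
  g <- GenomeAssembly(c(chr = chrom))
  tr <- TranscriptModel("t", "g", "chr", "+", 60L, 60L + nchar(cds))
  # place the guide so its seed+PAM footprint (s0+12 .. s0+22) sits mid-CDS
  guide <- data.frame(proto = substr(chrom, 71L, 90L), pam = "NGG",
                      strand = "+", protoStart0 = 70L)
  plan <- planSilentMutations(guide, tr, g)
  expect_lt(plan$count, 4L)
  expect_true("INSUFFICIENT_SILENT_MUTATIONS" %in% plan$warnings)
})

test_that("split designs trigger exactly when mutations sit too deep", {
  expect_false(needsSplit(c(4, 7, 9, 11)))
  expect_true(needsSplit(c(22, 26)))
  expect_false(needsSplit(20))        # boundary case: 20 == 35 - 15
  expect_false(needsSplit(numeric(0)))
})

test_that("anchored primers cover the junction with the stated geometry", {
  set.seed(5)
  chrom <- randomWindow(600L)
  g <- GenomeAssembly(c(chr = chrom))
  ins <- 300L
  mkPlan <- function(d, strand = "+") {
    # left-side mutations at transcript distances d from the junction
    pos <- if (strand == "+") ins - d else ins + d - 1L
    ref <- vapply(pos, function(p) substr(chrom, p + 1L, p + 1L), "")
    alt <- chartr("ACGT", "CATG", ref)
    list(mutations = data.frame(pos0 = pos, ref = ref, alt = alt),
         count = length(d), pamDisrupted = TRUE, warnings = character(0))
  }

  # single design, mutations at d = {5, 8}
  plan <- mkPlan(c(5L, 8L))
  p2 <- anchoredPrimers("left", ins, plan, g, "chr", "+")
  expect_length(p2, 1L)
  expect_equal(p2[[1L]]$name, "P2")
  expect_equal(p2[[1L]]$length, 30L)
  # expected: reverse complement of the mutated 30-mer upstream slice
  up <- substr(chrom, ins - 30L + 1L, ins)
  ch <- strsplit(up, "")[[1L]]
  for (d in c(5L, 8L)) ch[30L - d + 1L] <- chartr("ACGT", "CATG",
                                                  ch[30L - d + 1L])
  expect_equal(p2[[1L]]$seq, oracleRevComp(paste(ch, collapse = "")))
  expect_equal(p2[[1L]]$mutatedOffsets, c(5L, 8L))

  # mutations at d = {22, 24}: split into P2A/P2B
  plan2 <- mkPlan(c(22L, 24L))
  pr <- anchoredPrimers("left", ins, plan2, g, "chr", "+")
  expect_length(pr, 2L)
  names_ <- vapply(pr, `[[`, "", "name")
  expect_setequal(names_, c("P2A", "P2B"))
  pA <- pr[[which(names_ == "P2A")]]
  pB <- pr[[which(names_ == "P2B")]]
  # all mutations inside P2A; overlap with P2B in [18, 22]
  expect_equal(length(pA$mutatedOffsets), 2L)
  expect_equal(length(pB$mutatedOffsets), 0L)
  overlap <- pB$dSpan[2L] - pA$dSpan[1L] + 1L
  expect_true(overlap >= 18L && overlap <= 22L)

  # no mutations: plain primer with zero mutated positions
  p3 <- anchoredPrimers("right", ins, list(mutations = data.frame(
    pos0 = integer(0), ref = character(0), alt = character(0)),
    count = 0L, pamDisrupted = FALSE, warnings = character(0)),
    g, "chr", "+")
  expect_equal(p3[[1L]]$name, "P3")
  expect_length(p3[[1L]]$mutatedOffsets, 0L)
  expect_equal(p3[[1L]]$seq, substr(chrom, ins + 1L, ins + 30L))
})

test_that("the 15-base rule holds for every emitted anchored primer", {
  sweep <- bigPrimerSweep()
  violations <- 0L
  for (item in sweep) {
    for (p in c(item$ps$left, item$ps$right)) {
      if (length(p$mutatedOffsets) &&
          any(p$mutatedOffsets > p$length - 15L))
        violations <- violations + 1L
    }
  }
  expect_equal(violations, 0L)
})

test_that("outer primers produce arms in range, expanding when necessary", {
  set.seed(9)
  chrom <- randomWindow(9000L)
  g <- GenomeAssembly(c(chr = chrom))
  ins <- 4000L
  partnerTm <- 62
  res <- pickOuterPrimer("left", partnerTm, ins, g, "chr", "+")
  expect_false(is.null(res$primer))
  expect_true(res$armLength >= 500L && res$armLength <= 1000L)
  expect_true(abs(res$primer$tm - partnerTm) <= 3)
  expect_equal(res$primer$name, "P1")
  # the primer sequence is the distal transcript-sense slice of the arm
  a <- res$armLength; l <- res$primer$length
  expect_equal(res$primer$seq,
               substr(chrom, ins - a + 1L, ins - a + l))

  # a dinucleotide-repeat arm forces expansion past the default window:
  # the first 1100 nt downstream (transcript sense, minus strand) are pure
  # AT repeat, so no candidate passes the GC bounds until the arm expands
  chrom2 <- paste0(randomWindow(5000L), strrep("AT", 550L),
                   randomWindow(3000L))
  g2 <- GenomeAssembly(c(chr = chrom2))
  res2 <- pickOuterPrimer("right", partnerTm, 6100L, g2, "chr", "-",
                          maxSpecificityChecks = 5L)
  expect_true("ARM_EXPANDED" %in% res2$warnings)
  expect_false(is.null(res2$primer))
  expect_true(res2$armLength > 1000L && res2$armLength <= 10000L)

  # specificity: unique primer accepted, planted duplicate flagged
  expect_true(checkPrimerSpecificity(substr(chrom, 101L, 124L), g))
  dup <- chrom
  substr(dup, 8001L, 8024L) <- substr(chrom, 101L, 124L)
  expect_false(checkPrimerSpecificity(substr(chrom, 101L, 124L),
                                      GenomeAssembly(c(chr = dup))))
})

test_that("genotyping primers strictly contain the edited region", {
  set.seed(13)
  chrom <- randomWindow(6000L)
  g <- GenomeAssembly(c(chr = chrom))
  res <- designGenotypingPrimers(2000L, 3500L, g, "chr")
  expect_false(is.null(res$forward))
  expect_false(is.null(res$reverse))
  expect_lte(res$forward$end0, 2000L)
  expect_gte(res$reverse$start0, 3500L)
  expect_equal(res$reverse$seq,
               oracleRevComp(substr(chrom, res$reverse$start0 + 1L,
                                    res$reverse$end0)))
  expect_true(abs(res$forward$tm - res$reverse$tm) <= 3)

  # off-contig margin warns
  res2 <- designGenotypingPrimers(100L, 5900L, g, "chr")
  expect_true("MARGIN_TRUNCATED" %in% res2$warnings)
})

test_that("repaired alleles translate cleanly and resist re-cutting", {
  sweep <- bigPrimerSweep()
  sf <- bigRun()
  tested <- 0L
  for (item in sweep[seq(1L, length(sweep), length.out = 30L)]) {
    tr <- sf$transcripts[[item$gene]]
    plan <- item$ps$plan
    spec <- list(chrom = item$row$chrom,
                 interbase = item$row$insertion_interbase)
    ed <- applyEditToLocus(sf$genome, tr, spec$interbase, plan,
                           tagTx = "GCTGCA")
    prot <- sub("\\*$", "", translateDNA(splicedCDS(tr, sf$genome)))
    prot2 <- sub("\\*$", "", translateDNA(splicedCDS(ed$transcript,
                                                     ed$genome)))
    # frame preservation: original protein with a contiguous 2-aa insert
    expect_equal(nchar(prot2), nchar(prot) + 2L)
    expect_true(grepl("AA", prot2, fixed = TRUE))
    both <- strsplit(c(prot, sub("AA", "", prot2)), "")
    # removing one AA insertion somewhere restores the original
    expect_true(sub("AA", "", prot2) == prot ||
                  any(vapply(seq_len(nchar(prot2) - 1L), function(i)
                    paste0(substr(prot2, 1, i - 1L),
                           substr(prot2, i + 2L, nchar(prot2))) == prot,
                    logical(1))))

    # guide immunity near the junction after mutations
    seedChanges <- sum(!is.na(plan$mutations$pos0))
    if (plan$pamDisrupted || plan$count >= 3L) {
      guide <- guideFromDesignRow(item$row)
      region <- sliceSeq(ed$genome, item$row$chrom,
                         spec$interbase - 80L, spec$interbase + 86L)
      hits <- bruteForceGuides(region)
      hitKey <- paste(hits$proto, substr(hits$pam, 2, 3))
      expect_false(paste(guide$proto, "GG") %in% hitKey,
                   label = paste(item$gene, item$terminus))
    }
    tested <- tested + 1L
  }
  expect_gte(tested, 25L)
})
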