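# Deterministic synthetic fixtures: genomes with known gene models and
# maturation features (plus analytically derived truth tables for the
# expected insertion coordinates), planted off-target sites, and tagged-
# allele inventories with known distribution/accrual parameters. Everything
# is reproducible from the manifest seed.

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- names(Biostrings::GENETIC_CODE)
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' Fixture manifest
#'
#' Collects the parameters of the synthetic genome generator. Defaults give
#' compact worm-like genes: AT-rich sequence (36 percent GC), 1-5 exons,
#' short introns with GT..AG ends, and maturation features planted at the
#' stated probabilities.
#'
#' @param seed integer RNG seed; identical seed and spec give byte-identical
#'   outputs.
#' @param nGenes number of genes.
#' @param nChromosomes chromosomes to spread genes over.
#' @param gc genomic GC fraction.
#' @param proteinLengthRange,exonCountRange,intronLengthRange,
#'   intergenicRange gene-structure parameters (residues / counts / nt).
#' @param pMinus probability of a minus-strand gene.
#' @param pInitMet,pSignal,pTransit,pPropeptideN,pPropeptideC,pChain,
#'   pLipidationN,pLipidationC feature-planting probabilities.
#' @return list of class "fixtureManifest".
#' @export
fixtureManifest <- function(seed = 1L, nGenes = 20L, nChromosomes = 2L,
                            gc = 0.36,
                            proteinLengthRange = c(80L, 300L),
                            exonCountRange = c(1L, 5L),
                            intronLengthRange = c(48L, 200L),
                            intergenicRange = c(1500L, 2500L),
                            pMinus = 0.5, pInitMet = 0.3, pSignal = 0.25,
                            pTransit = 0.05, pPropeptideN = 0.1,
                            pPropeptideC = 0.1, pChain = 0.15,
                            pLipidationN = 0.05, pLipidationC = 0.05) {
  m <- as.list(environment())
  class(m) <- "fixtureManifest"
  m
}

# generate one gene: codons, features and truth boundaries
generateGeneSpec <- function(m, gid) {
  L <- sample(seq.int(m$proteinLengthRange[1L], m$proteinLengthRange[2L]), 1L)
  codons <- c("ATG", sample(SENSE_CODONS, L - 1L, replace = TRUE),
              sample(STOP_CODONS, 1L))
  feat <- list(initMet = FALSE, signalEnd = NA_integer_,
               transitEnd = NA_integer_, propeptides = NULL,
               chain = c(NA_integer_, NA_integer_),
               lipidation = NULL)
  b <- 1L
  if (runif(1) < m$pInitMet) { feat$initMet <- TRUE; b <- 2L }
  if (runif(1) < m$pSignal) {
    feat$signalEnd <- sample(15:25, 1L)
    b <- feat$signalEnd + 1L
  } else if (runif(1) < m$pTransit) {
    feat$transitEnd <- sample(20:40, 1L)
    b <- feat$transitEnd + 1L
  }
  if (runif(1) < m$pPropeptideN) {
    k <- sample(5:15, 1L)
    feat$propeptides <- rbind(feat$propeptides, c(b, b + k - 1L))
    b <- b + k
  }
  e <- L
  if (runif(1) < m$pPropeptideC) {
    k <- sample(5:15, 1L)
    feat$propeptides <- rbind(feat$propeptides, c(L - k + 1L, L))
    e <- L - k
  }
  if (runif(1) < m$pChain && e - b > 30L) {
    feat$chain <- c(b, e)
  }
  nBoundary <- b
  cBoundary <- e
  flagsN <- character(0); flagsC <- character(0)
  if (runif(1) < m$pLipidationN && nBoundary + 20L < cBoundary) {
    feat$lipidation <- rbind(feat$lipidation,
                             data.frame(pos = nBoundary, class = "N"))
    nBoundary <- nBoundary + 6L   # site + 6 with site at the old boundary
    flagsN <- "LIPIDATION_ADJUSTED"
  }
  if (runif(1) < m$pLipidationC && cBoundary - 20L > nBoundary) {
    feat$lipidation <- rbind(feat$lipidation,
                             data.frame(pos = cBoundary, class = "C"))
    cBoundary <- cBoundary - 6L
    flagsC <- "LIPIDATION_ADJUSTED"
  }
  strand <- if (runif(1) < m$pMinus) "-" else "+"
  nExons <- sample(seq.int(m$exonCountRange[1L], m$exonCountRange[2L]), 1L)
  M <- 3L * (L + 1L)
  nExons <- min(nExons, M - 1L)
  cuts <- if (nExons > 1L) sort(sample(seq_len(M - 1L), nExons - 1L))
          else integer(0)
  exonLens <- diff(c(0L, cuts, M))
  intronLens <- if (nExons > 1L)
    sample(seq.int(m$intronLengthRange[1L], m$intronLengthRange[2L]),
           nExons - 1L, replace = TRUE) else integer(0)
  list(gid = gid, L = L, codons = codons, feat = feat, strand = strand,
       exonLens = exonLens, intronLens = intronLens,
       nBoundary = nBoundary, cBoundary = cBoundary,
       flagsN = flagsN, flagsC = flagsC)
}

# truth-side boundary mapping from the generator's coordinate array
# (independent of the pipeline's segment walker)
truthBoundary <- function(coord, cOff, strand) {
  n <- length(coord)
  if (strand == "+") {
    if (cOff == 0L) k <- coord[1L]
    else if (cOff == n) k <- coord[n] + 1L
    else if (coord[cOff + 1L] != coord[cOff] + 1L) k <- coord[cOff] + 1L
    else k <- coord[cOff + 1L]
    paper <- k
  } else {
    if (cOff == 0L) k <- coord[1L] + 1L
    else if (cOff == n) k <- coord[n]
    else if (coord[cOff + 1L] != coord[cOff] - 1L) k <- coord[cOff]
    else k <- coord[cOff + 1L] + 1L
    paper <- k + 1L
  }
  c(interbase = as.integer(k), paper = as.integer(paper))
}

#' Generate a synthetic genome fixture with ground truth
#'
#' Writes a FASTA genome, a GFF3 gene model file (one canonical mRNA per
#' gene, CDS including the stop codon), a protein-feature TSV, and a truth
#' table holding the analytically expected N-/C-terminal boundary residues
#' and insertion coordinates computed from the generator's own layout
#' bookkeeping (before the pipeline ever runs).
#'
#' @param manifest a [fixtureManifest()].
#' @param dir output directory (created if missing).
#' @return list(paths, truth, manifest) where paths names fasta/gff3/
#'   features/truth files.
#' @export
makeGenomeFixture <- function(manifest, dir) {
  m <- manifest
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withSeed(m$seed, {
    chromSeqs <- setNames(vector("list", m$nChromosomes),
                          paste0("chr", utils::as.roman(1:m$nChromosomes)))
    for (nm in names(chromSeqs)) chromSeqs[[nm]] <- character(0)
    gffRows <- list()
    featRows <- list()
    truthRows <- list()
    cursor <- setNames(rep(0L, m$nChromosomes), names(chromSeqs))

    for (gi in seq_len(m$nGenes)) {
      gid <- sprintf("gene%04d", gi)
      tid <- sprintf("tr%04d", gi)
      gs <- generateGeneSpec(m, gid)
      chromIdx <- ((gi - 1L) %% m$nChromosomes) + 1L
      chrom <- names(chromSeqs)[chromIdx]

      gap <- sample(seq.int(m$intergenicRange[1L], m$intergenicRange[2L]), 1L)
      pre <- randomDNA(gap, m$gc)
      geneStart0 <- cursor[[chrom]] + gap

      cds <- paste(gs$codons, collapse = "")
      M <- nchar(cds)
      # transcript-sense body with introns
      exonTxStart <- cumsum(c(0L, gs$exonLens[-length(gs$exonLens)]))
      parts <- character(0)
      bodyOffsets <- integer(0)   # transcript body offset of each CDS base
      off <- 0L
      for (ei in seq_along(gs$exonLens)) {
        el <- gs$exonLens[ei]
        parts <- c(parts, substring(cds, exonTxStart[ei] + 1L,
                                    exonTxStart[ei] + el))
        bodyOffsets <- c(bodyOffsets, seq.int(off, off + el - 1L))
        off <- off + el
        if (ei < length(gs$exonLens)) {
          il <- gs$intronLens[ei]
          parts <- c(parts, paste0("GT", randomDNA(il - 4L, m$gc), "AG"))
          off <- off + il
        }
      }
      bodyTx <- paste(parts, collapse = "")
      B <- nchar(bodyTx)
      bodyPlus <- if (gs$strand == "+") bodyTx else revComp(bodyTx)

      # plus-strand coordinate of each CDS base, transcript order
      coord <- if (gs$strand == "+") geneStart0 + bodyOffsets
               else geneStart0 + (B - 1L) - bodyOffsets

      # CDS segments in ascending plus order
      segTx <- cbind(start = exonTxStart, end = exonTxStart + gs$exonLens)
      bodyOfExon <- integer(0)
      segPlus <- t(apply(segTx, 1L, function(se) {
        # body offsets of this exon's first/last CDS base
        first <- bodyOffsets[se[1L] + 1L]
        last <- bodyOffsets[se[2L]]
        if (gs$strand == "+") c(geneStart0 + first, geneStart0 + last + 1L)
        else c(geneStart0 + (B - 1L) - last, geneStart0 + B - first)
      }))
      segPlus <- segPlus[order(segPlus[, 1L]), , drop = FALSE]

      chromSeqs[[chrom]] <- c(chromSeqs[[chrom]], pre, bodyPlus)
      cursor[[chrom]] <- geneStart0 + B

      # truth coordinates from the coordinate array
      tN <- truthBoundary(coord, 3L * (gs$nBoundary - 1L), gs$strand)
      tC <- truthBoundary(coord, 3L * gs$cBoundary, gs$strand)

      # GFF3 rows (1-based inclusive)
      phase <- integer(nrow(segPlus))
      segOrderTx <- if (gs$strand == "+") seq_len(nrow(segPlus))
                    else rev(seq_len(nrow(segPlus)))
      lens <- segPlus[, 2L] - segPlus[, 1L]
      cum <- 0L
      for (si in segOrderTx) {
        phase[si] <- (3L - (cum %% 3L)) %% 3L
        cum <- cum + lens[si]
      }
      gLo <- min(segPlus[, 1L]) + 1L; gHi <- max(segPlus[, 2L])
      gffRows[[length(gffRows) + 1L]] <- c(
        sprintf("%s\tceltag\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                chrom, gLo, gHi, gs$strand, gid),
        sprintf("%s\tceltag\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;canonical=1",
                chrom, gLo, gHi, gs$strand, tid, gid),
        vapply(seq_len(nrow(segPlus)), function(si)
          sprintf("%s\tceltag\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds.%s.%d;Parent=%s",
                  chrom, segPlus[si, 1L] + 1L, segPlus[si, 2L], gs$strand,
                  phase[si], tid, si, tid), character(1)))

      f <- gs$feat
      ppStr <- if (!is.null(f$propeptides))
        paste(apply(f$propeptides, 1L, paste, collapse = "-"),
              collapse = ";") else ""
      lpStr <- if (!is.null(f$lipidation))
        paste(paste0(f$lipidation$pos, ":", f$lipidation$class),
              collapse = ";") else ""
      chStr <- if (!is.na(f$chain[1L]))
        paste(f$chain, collapse = "-") else ""
      featRows[[length(featRows) + 1L]] <- data.frame(
        uniprot_id = paste0("U", gid), gene_id = gid, length = gs$L,
        init_met_removed = as.integer(f$initMet),
        signal_end = ifelse(is.na(f$signalEnd), "", f$signalEnd),
        transit_end = ifelse(is.na(f$transitEnd), "", f$transitEnd),
        propeptides = ppStr, chain = chStr, lipidation = lpStr)

      truthRows[[length(truthRows) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tid, chrom = chrom,
        strand = gs$strand, protein_length = gs$L,
        n_boundary_residue = gs$nBoundary, n_interbase = tN[["interbase"]],
        n_paper_coord = tN[["paper"]],
        c_boundary_residue = gs$cBoundary, c_interbase = tC[["interbase"]],
        c_paper_coord = tC[["paper"]],
        n_flags = paste(gs$flagsN, collapse = ","),
        c_flags = paste(gs$flagsC, collapse = ","))
    }

    # trailing intergenic tail on each chromosome
    seqs <- vapply(names(chromSeqs), function(nm) {
      paste(c(chromSeqs[[nm]], randomDNA(1000L, m$gc)), collapse = "")
    }, character(1))

    fastaPath <- file.path(dir, "genome.fasta")
    gffPath <- file.path(dir, "genes.gff3")
    featPath <- file.path(dir, "features.tsv")
    truthPath <- file.path(dir, "truth.tsv")
    dna <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(dna, fastaPath, width = 70L)
    writeLines(c("##gff-version 3", unlist(gffRows)), gffPath)
    feats <- do.call(rbind, featRows)
    write.table(feats, featPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    truth <- do.call(rbind, truthRows)
    write.table(truth, truthPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(paths = list(fasta = fastaPath, gff3 = gffPath,
                      features = featPath, truth = truthPath),
         truth = truth, manifest = m)
  })
}

#' Plant an off-target copy of a protospacer into a genome
#'
#' Writes a copy of the protospacer at the requested Hamming distance,
#' followed by a TGG PAM, at the given location and strand. The mismatched
#' positions are spread evenly across the 20-mer and mutated by
#' transversion, so the planted distance is exact by construction.
#'
#' @param genome a [GenomeAssembly-class].
#' @param protospacer 20-nt protospacer (protospacer sense).
#' @param mismatches Hamming distance to plant.
#' @param chrom,start0 plus-strand 0-based start of the 23-nt site.
#' @param strand strand of the planted site.
#' @param avoid optional data.frame(chrom, start0, end0) of spans that must
#'   not be overwritten (collision is an error).
#' @return modified [GenomeAssembly-class].
#' @export
plantOfftarget <- function(genome, protospacer, mismatches, chrom, start0,
                           strand = "+", avoid = NULL) {
  stopIfNot(nchar(protospacer) == 20L, "protospacer must be 20 nt")
  proto <- strsplit(protospacer, "", fixed = TRUE)[[1L]]
  if (mismatches > 0L) {
    at <- unique(round(seq(1L, 20L, length.out = mismatches)))
    while (length(at) < mismatches)
      at <- union(at, setdiff(1:20, at)[1L])
    proto[at] <- chartr("ACGT", "CATG", proto[at])
  }
  site <- paste0(paste(proto, collapse = ""), "TGG")
  plus <- if (strand == "+") site else revComp(site)
  end0 <- start0 + nchar(plus)
  if (!is.null(avoid) && nrow(avoid)) {
    hit <- avoid$chrom == chrom & start0 < avoid$end0 & end0 > avoid$start0
    if (any(hit)) stop("planted site collides with a protected span")
  }
  len <- chromLengths(genome)[[chrom]]
  stopIfNot(start0 >= 0L && end0 <= len, "site outside chromosome")
  s <- as.character(genome@sequences[[chrom]])
  substr(s, start0 + 1L, end0) <- plus
  seqs <- as.character(genome@sequences)
  seqs[[chrom]] <- s
  GenomeAssembly(seqs, assembly = genome@assembly)
}

#' Generate a tagged-allele inventory fixture with known truth
#'
#' Deterministically composes an inventory whose alleles-per-gene,
#' tag-position and tag-type distributions match the manifest proportions
#' exactly (largest-remainder allocation), with yearly accrual that ramps
#' up to a steady linear rate over the final years.
#'
#' @param seed RNG seed.
#' @param nGenes,nAlleles inventory size.
#' @param allelesPerGeneProps proportions of genes with 1/2/3/4+ alleles.
#' @param positionProps proportions of alleles tagged at C/N/internal/
#'   multiple positions.
#' @param tagProps named tag-type proportions over alleles.
#' @param rampYears named integer vector of new genes per pre-steady year
#'   (absorbs rounding so totals match).
#' @param linearYears steady-state years.
#' @param ratePerYear,rateSd steady accrual rate (new genes/year) and its
#'   year-to-year jitter.
#' @param pDesignation fraction of alleles with an allele designation.
#' @param dir optional output directory; writes inventory.tsv when given.
#' @return list(records, truth, path).
#' @export
makeInventoryFixture <- function(seed = 1L, nGenes = 1554L, nAlleles = 2812L,
                                 allelesPerGeneProps =
                                   c(`1` = 0.631, `2` = 0.197, `3` = 0.083,
                                     `4+` = 0.089),
                                 positionProps =
                                   c(C = 0.629, N = 0.337,
                                     internal = 0.029, multiple = 0.005),
                                 tagProps =
                                   c(GFP = 0.440, FLAG = 0.301,
                                     mNeonGreen = 0.170, mCherry = 0.050,
                                     HA = 0.039),
                                 rampYears = c(`2013` = 2, `2014` = 8,
                                               `2015` = 20, `2016` = 40,
                                               `2017` = 66, `2018` = 90,
                                               `2019` = 110),
                                 linearYears = 2020:2025,
                                 ratePerYear = 203, rateSd = 5,
                                 pDesignation = 0.92, dir = NULL) {
  withSeed(seed, {
    geneCounts <- allocateCounts(nGenes, allelesPerGeneProps)
    perGene <- rep(c(1L, 2L, 3L, 4L), geneCounts)
    extra <- nAlleles - sum(perGene)
    stopIfNot(extra >= 0, "nAlleles too small for the allele distribution")
    i4 <- which(perGene >= 4L)
    if (length(i4)) {
      add <- rep(0L, length(i4))
      if (extra > 0) {
        idx <- rep(seq_along(i4), length.out = extra)
        add <- tabulate(idx, nbins = length(i4))
      }
      perGene[i4] <- perGene[i4] + add
    }
    geneIds <- sprintf("wtg-%04d", seq_len(nGenes))
    perGene <- sample(perGene)                 # shuffle gene sizes

    # accrual: new genes per year
    linCounts <- pmax(0L, round(ratePerYear + rnorm(length(linearYears),
                                                    0, rateSd)))
    preTotal <- nGenes - sum(linCounts)
    stopIfNot(preTotal > 0, "linear years exhaust the gene budget")
    preCounts <- allocateCounts(preTotal, rampYears)
    yearOfGene <- rep(c(as.integer(names(rampYears)), linearYears),
                      c(preCounts, linCounts))
    stopIfNot(length(yearOfGene) == nGenes, "year allocation mismatch")

    alleleGene <- rep(seq_len(nGenes), perGene)
    firstOfGene <- !duplicated(alleleGene)
    years <- integer(length(alleleGene))
    years[firstOfGene] <- yearOfGene[alleleGene[firstOfGene]]
    later <- which(!firstOfGene)
    for (i in later) {
      y0 <- yearOfGene[alleleGene[i]]
      years[i] <- if (y0 >= max(linearYears)) y0
                  else sample(seq.int(y0, max(linearYears)), 1L)
    }

    nA <- length(alleleGene)
    posCounts <- allocateCounts(nA, positionProps)
    posClass <- sample(rep(names(positionProps), posCounts))
    positions <- lapply(posClass, function(p)
      if (p == "multiple") c("N", "C") else p)

    tagCounts <- allocateCounts(nA, tagProps)
    tags <- as.list(sample(rep(names(tagProps), tagCounts)))

    hasDesig <- runif(nA) < pDesignation
    desig <- ifelse(hasDesig, sprintf("syn%04d", seq_len(nA)), "")
    source <- sample(c("literature", "CGC"), nA, replace = TRUE,
                     prob = c(0.8, 0.2))

    records <- data.frame(
      gene_id = geneIds[alleleGene],
      gene_name = geneIds[alleleGene],
      allele = desig,
      tags = I(tags), positions = I(positions),
      source = source, year = years,
      reference = ifelse(source == "literature",
                         sprintf("ref%04d", alleleGene), ""))

    truth <- list(
      allelesPerGenePct = setNames(
        roundHalfAway(100 * geneCounts / nGenes, 1),
        names(allelesPerGeneProps)),
      positionPct = setNames(roundHalfAway(100 * posCounts / nA, 1),
                             names(positionProps)),
      tagPct = setNames(roundHalfAway(100 * tagCounts / nA, 1),
                        names(tagProps)),
      ratePerYear = ratePerYear, linearYears = linearYears,
      newPerYear = setNames(c(preCounts, linCounts),
                            c(names(rampYears), linearYears)))

    path <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(dir, "inventory.tsv")
      out <- records
      out$tags <- vapply(records$tags, paste, "", collapse = ";")
      out$positions <- vapply(records$positions, paste, "", collapse = ";")
      write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(records = records, truth = truth, path = path)
  })
}

#' Generate a noisy discovery-curve series
#'
#' Cumulative newly discovered genes versus papers examined, following an
#' exponential saturation law with additive Gaussian noise.
#'
#' @param seed RNG seed.
#' @param nPapers number of papers on the x axis.
#' @param gMax,tau saturation parameters.
#' @param noiseFrac noise standard deviation as a fraction of gMax.
#' @param step sampling interval along the paper axis.
#' @return data.frame(papers, cumulative).
#' @export
makeDiscoverySeries <- function(seed = 1L, nPapers = 2500L, gMax = 1713,
                                tau = 1052.7, noiseFrac = 0.02,
                                step = 25L) {
  withSeed(seed, {
    n <- seq.int(step, nPapers, by = step)
    g <- gMax * (1 - exp(-n / tau)) + rnorm(length(n), 0, noiseFrac * gMax)
    data.frame(papers = n, cumulative = pmax(0, g))
  })
}

#' Generate a category-annotation fixture
#'
#' Random gene-set categories over a gene universe, plus optional fully
#' tagged and fully untagged categories to exercise odds-ratio capping.
#'
#' @param seed RNG seed.
#' @param genes gene universe.
#' @param taggedGenes tagged subset.
#' @param nTerms number of random terms.
#' @param sizeRange category size range.
#' @param addExtremes add a fully tagged and a fully untagged category.
#' @return data.frame(term_id, term_name, gene_id).
#' @export
makeCategoryFixture <- function(seed, genes, taggedGenes, nTerms = 30L,
                                sizeRange = c(10L, 120L),
                                addExtremes = TRUE) {
  withSeed(seed, {
    rows <- lapply(seq_len(nTerms), function(i) {
      sz <- sample(seq.int(sizeRange[1L], sizeRange[2L]), 1L)
      data.frame(term_id = sprintf("CAT:%04d", i),
                 term_name = sprintf("category %d", i),
                 gene_id = sample(genes, min(sz, length(genes))))
    })
    if (addExtremes) {
      untagged <- setdiff(genes, taggedGenes)
      rows <- c(rows, list(
        data.frame(term_id = "CAT:FULL", term_name = "fully tagged",
                   gene_id = head(taggedGenes, 25L)),
        data.frame(term_id = "CAT:EMPTY", term_name = "fully untagged",
                   gene_id = head(untagged, 40L))))
    }
    do.call(rbind, rows)
  })
}
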