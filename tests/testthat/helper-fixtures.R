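# Shared fixtures, built lazily once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

# small genome fixture (12 genes) shared by unit tests
smallFixture <- function() {
  cached("small", function() {
    dir <- file.path(tempdir(), "celtag-small-fixture")
    fx <- makeGenomeFixture(fixtureManifest(seed = 7L, nGenes = 12L), dir)
    genome <- loadGenome(fx$paths$fasta)
    transcripts <- loadTranscripts(fx$paths$gff3, genome)
    features <- readProteinFeatures(fx$paths$features)
    list(fx = fx, genome = genome, transcripts = transcripts,
         features = features, truth = fx$truth,
         index = buildPamIndex(genome))
  })
}

# the large synthetic study: 1000 genes spanning both strands, 1-5 exons
# and all feature combinations; guides selected genome-wide. Built once.
bigRun <- function() {
  cached("big", function() {
    dir <- file.path(tempdir(), "celtag-big-fixture")
    fx <- makeGenomeFixture(
      fixtureManifest(seed = 101L, nGenes = 1000L, nChromosomes = 6L), dir)
    genome <- loadGenome(fx$paths$fasta)
    transcripts <- loadTranscripts(fx$paths$gff3, genome)
    features <- readProteinFeatures(fx$paths$features)
    index <- buildPamIndex(genome)
    res <- runDesign(genome, transcripts, features, index = index,
                     withPrimers = FALSE)
    list(fx = fx, genome = genome, transcripts = transcripts,
         features = features, truth = fx$truth, index = index,
         design = res$designTable, errors = res$errors)
  })
}

# guide row (as used by planSilentMutations) from a design-table row
guideFromDesignRow <- function(row) {
  data.frame(proto = row$guide_seq, pam = row$guide_pam,
             strand = row$guide_strand,
             protoStart0 = row$guide_start - 1L,
             cutInterbase = row$guide_cut_interbase)
}

# anchored-primer designs (with mutation plans) across the big run;
# computed once, used by the silent-mutation and 15-base-rule sweeps
bigPrimerSweep <- function() {
  cached("bigPrimers", function() {
    br <- bigRun()
    rows <- br$design[!br$design$no_guide & br$design$guide_seq != "", ]
    out <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
      row <- rows[i, ]
      tr <- br$transcripts[[row$gene_id]]
      spec <- list(chrom = row$chrom, interbase = row$insertion_interbase)
      ps <- designPrimerSet(br$genome, tr, spec, guideFromDesignRow(row),
                            withOuter = FALSE, withGenotyping = FALSE)
      out[[i]] <- list(gene = row$gene_id, terminus = row$terminus,
                       strand = row$strand, ps = ps, row = row)
    }
    out
  })
}

# simulate an edited allele: apply a mutation plan and insert an in-frame
# tag at the insertion point; returns edited genome and shifted transcript
applyEditToLocus <- function(genome, transcript, interbase, plan,
                             tagTx = "GCTGCA") {
  chrom <- transcript@chrom
  s <- as.character(genome@sequences[[chrom]])
  muts <- plan$mutations
  if (!is.null(muts) && nrow(muts)) {
    for (i in seq_len(nrow(muts))) {
      p <- muts$pos0[i]
      stopifnot(substr(s, p + 1L, p + 1L) == muts$ref[i])
      substr(s, p + 1L, p + 1L) <- muts$alt[i]
    }
  }
  tagPlus <- if (transcript@strand == "-") oracleRevComp(tagTx) else tagTx
  len <- nchar(tagPlus)
  k <- interbase
  s2 <- paste0(substr(s, 1L, k), tagPlus, substr(s, k + 1L, nchar(s)))
  st <- transcript@cdsStart0; en <- transcript@cdsEnd0
  cand <- which(st <= k & k <= en)
  stopifnot(length(cand) >= 1L)
  ab <- cand[1L]
  newSt <- st; newEn <- en
  for (i in seq_along(st)) {
    if (i == ab) {
      newEn[i] <- en[i] + len
    } else if (st[i] >= k) {
      newSt[i] <- st[i] + len
      newEn[i] <- en[i] + len
    }
  }
  seqsEdit <- vapply(chromNames(genome), function(cn)
    if (cn == chrom) s2 else as.character(genome@sequences[[cn]]),
    character(1))
  g2 <- GenomeAssembly(seqsEdit)
  tr2 <- TranscriptModel(transcript@transcriptId, transcript@geneId,
                         chrom, transcript@strand, newSt, newEn)
  list(genome = g2, transcript = tr2)
}
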