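# Genome and gene-model loading plus strand- and exon-aware coordinate
# conversion between protein, CDS and genomic space.
#
# Conventions: internal coordinates are 0-based half-open on the plus strand;
# insertion points are inter-base (offset k = boundary between plus-strand
# bases k-1 and k, 0-based); all user-facing output is 1-based inclusive.
# GFF3 input (1-based) is converted at the parser boundary. CDS segments
# include the stop codon.

#' Load a genome from FASTA
#'
#' Every FASTA record becomes one chromosome; lowercase input is uppercased.
#' Record names are the first whitespace-delimited token of the header.
#'
#' @param fastaPath path to a (multi-record) FASTA file.
#' @param assembly assembly label stored as metadata.
#' @return a [GenomeAssembly-class].
#' @export
loadGenome <- function(fastaPath, assembly = "synthetic") {
  stopIfNot(file.exists(fastaPath), paste("no such file:", fastaPath))
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty FASTA record: ", paste(nm[Biostrings::width(seqs) == 0L],
                                       collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- nm
  GenomeAssembly(seqs, assembly = assembly)
}

#' Load canonical transcript models from GFF3
#'
#' Expects gene/mRNA/CDS features linked by ID/Parent attributes. One
#' [TranscriptModel-class] is returned per gene, chosen by
#' \code{canonicalSelector}: either the name of an mRNA attribute whose value
#' must be "1" (default \code{"canonical"}), or a named character vector /
#' two-column data.frame mapping gene id to transcript id.
#'
#' Violations of the coding invariants (CDS length divisible by 3, ATG start,
#' stop end, consistent phase) produce per-gene warnings recorded on the
#' model, not errors.
#'
#' @param gff3Path path to a GFF3 file.
#' @param genome optional [GenomeAssembly-class]; when supplied, start/stop
#'   codons are checked and flagged.
#' @param canonicalSelector attribute tag or explicit gene->transcript map.
#' @return named list of [TranscriptModel-class], one per gene.
#' @export
loadTranscripts <- function(gff3Path, genome = NULL,
                            canonicalSelector = "canonical") {
  stopIfNot(file.exists(gff3Path), paste("no such file:", gff3Path))
  gr <- rtracklayer::import(gff3Path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  genes <- gr[type == "gene"]
  mrnas <- gr[type == "mRNA"]
  cdss  <- gr[type == "CDS"]
  if (length(genes) == 0L) stop("GFF3 contains no gene features")

  mrnaParent <- vapply(S4Vectors::mcols(mrnas)$Parent,
                       function(p) as.character(p)[1L], character(1))
  mrnaId <- as.character(S4Vectors::mcols(mrnas)$ID)
  cdsParent <- vapply(S4Vectors::mcols(cdss)$Parent,
                      function(p) as.character(p)[1L], character(1))
  mrnaByGene <- split(seq_along(mrnas), mrnaParent)
  cdsByTx <- split(seq_along(cdss), cdsParent)
  # plain vectors: GRanges subsetting inside the per-gene loop is costly
  cdsChrom <- as.character(GenomicRanges::seqnames(cdss))
  cdsStrand <- as.character(GenomicRanges::strand(cdss))
  cdsStart <- GenomicRanges::start(cdss)
  cdsEnd <- GenomicRanges::end(cdss)
  cdsPhase <- S4Vectors::mcols(cdss)$phase
  cdsPhase <- if (is.null(cdsPhase)) rep(NA_integer_, length(cdss))
              else suppressWarnings(as.integer(as.character(cdsPhase)))
  geneIds <- as.character(S4Vectors::mcols(genes)$ID)
  canonAttr <- if (is.character(canonicalSelector) &&
                   length(canonicalSelector) == 1L &&
                   is.null(names(canonicalSelector)))
    S4Vectors::mcols(mrnas)[[canonicalSelector]] else NULL

  # canonical transcript per gene
  explicit <- NULL
  if (is.data.frame(canonicalSelector)) {
    explicit <- setNames(as.character(canonicalSelector[[2L]]),
                         as.character(canonicalSelector[[1L]]))
  } else if (length(canonicalSelector) > 1L ||
             !is.null(names(canonicalSelector))) {
    explicit <- canonicalSelector
  }

  out <- list()
  for (i in seq_along(genes)) {
    gid <- geneIds[i]
    mi <- mrnaByGene[[gid]]
    if (is.null(mi)) mi <- integer(0)
    if (length(mi) == 0L) stop("gene with no mRNA/CDS: ", gid)
    if (!is.null(explicit)) {
      tid <- explicit[[gid]]
      if (is.null(tid) || !tid %in% mrnaId[mi])
        stop("canonical transcript missing for gene: ", gid)
    } else {
      canon <- if (is.null(canonAttr)) rep(NA_character_, length(mrnas))
               else as.character(canonAttr)
      ci <- mi[!is.na(canon[mi]) & canon[mi] == "1"]
      if (length(ci) == 0L) {
        if (length(mi) == 1L) ci <- mi
        else stop("canonical transcript missing for gene: ", gid)
      }
      tid <- mrnaId[ci[1L]]
    }
    ki <- cdsByTx[[tid]]
    if (is.null(ki)) ki <- integer(0)
    if (length(ki) == 0L) stop("gene with no CDS: ", gid)
    chrom <- cdsChrom[ki]
    if (length(unique(chrom)) != 1L)
      stop("CDS segments on multiple chromosomes for ", tid)
    strand <- cdsStrand[ki][1L]
    if (!strand %in% c("+", "-")) strand <- "+"
    o <- order(cdsStart[ki])
    s0 <- cdsStart[ki][o] - 1L   # GFF3 is 1-based inclusive
    e0 <- cdsEnd[ki][o]
    warnings <- character()

    tot <- sum(e0 - s0)
    if (tot %% 3L != 0L) warnings <- c(warnings, "NONCANONICAL_CDS_LENGTH")

    ph <- cdsPhase[ki]
    if (!is.null(ph) && !all(is.na(ph))) {
      ph <- ph[o]
      if (strand == "-") ph <- rev(ph)
      w <- e0 - s0; if (strand == "-") w <- rev(w)
      expct <- cumsum(c(0L, w[-length(w)])) %% 3L
      expct <- (3L - expct) %% 3L
      if (!all(is.na(ph)) && any(ph != expct, na.rm = TRUE))
        warnings <- c(warnings, "INCONSISTENT_PHASE")
    }

    tm <- TranscriptModel(tid, gid, chrom[1L], strand, s0, e0,
                          isCanonical = TRUE, warnings = warnings)
    if (!is.null(genome)) {
      cds <- splicedCDS(tm, genome)
      if (substr(cds, 1L, 3L) != "ATG")
        tm@warnings <- c(tm@warnings, "NO_ATG")
      if (nchar(cds) >= 3L && tot %% 3L == 0L &&
          !substr(cds, nchar(cds) - 2L, nchar(cds)) %in% c("TAA", "TAG", "TGA"))
        tm@warnings <- c(tm@warnings, "NO_STOP")
    }
    out[[gid]] <- tm
  }
  out
}

#' Spliced CDS sequence in transcript orientation
#'
#' Concatenates the CDS segments and reverse-complements for minus-strand
#' transcripts.
#'
#' @param transcript a [TranscriptModel-class].
#' @param genome a [GenomeAssembly-class].
#' @return DNA string in transcript orientation.
#' @export
splicedCDS <- function(transcript, genome) {
  s <- transcript@cdsStart0; e <- transcript@cdsEnd0
  stopIfNot(length(s) > 0L, "empty CDS segment list")
  len <- chromLengths(genome)[[transcript@chrom]]
  stopIfNot(all(s >= 0L) && all(e <= len), "CDS segment out of bounds")
  parts <- vapply(seq_along(s), function(i)
    sliceSeq(genome, transcript@chrom, s[i], e[i]), character(1))
  x <- paste(parts, collapse = "")
  if (transcript@strand == "-") revComp(x) else x
}

# 0-based plus-strand genomic position of every CDS base, in transcript
# order (minus-strand transcripts run from high to low coordinates).
cdsCoordMap <- function(transcript) {
  pos <- unlist(lapply(seq_along(transcript@cdsStart0), function(i)
    seq.int(transcript@cdsStart0[i], transcript@cdsEnd0[i] - 1L)),
    use.names = FALSE)
  if (transcript@strand == "-") rev(pos) else pos
}

#' Map an amino-acid codon boundary to a genomic inter-base coordinate
#'
#' The boundary before residue r lies at CDS offset 3(r-1); after residue r,
#' at 3r. The offset is walked through the CDS segments, strand-aware, to an
#' inter-base point on the plus strand. When the codon boundary coincides
#' with an exon-intron junction the insertion point is placed at the
#' exon-side base adjacent in transcript orientation (the last exonic base
#' of the upstream codon) and flagged.
#'
#' @param transcript a [TranscriptModel-class].
#' @param residueIndex 1-based residue index; \code{proteinLength + 1} is
#'   allowed with \code{side = "before"} for the stop boundary.
#' @param side \code{"before"} or \code{"after"} the residue.
#' @return list with \code{chrom}, \code{interbase} (0-based inter-base
#'   offset), \code{paperCoord} (1-based plus-strand position of the
#'   nucleotide immediately 5' of the boundary in transcript orientation; NA
#'   if off-contig), and \code{junctionAdjusted}.
#' @export
aaBoundaryToGenomic <- function(transcript, residueIndex,
                                side = c("before", "after")) {
  side <- match.arg(side)
  L <- proteinLength(transcript)
  stopIfNot(residueIndex >= 1L &&
            residueIndex <= L + if (side == "before") 1L else 0L,
            "residue index outside protein")
  cOff <- if (side == "before") 3L * (residueIndex - 1L) else 3L * residueIndex
  cdsOffsetToInterbase(transcript, cOff)
}

# Shared walker: CDS offset (0..cdsLength) -> inter-base point.
cdsOffsetToInterbase <- function(transcript, cOff) {
  map <- cdsCoordMap(transcript)
  n <- length(map)
  stopIfNot(cOff >= 0L && cOff <= n, "offset outside CDS")
  plus <- transcript@strand == "+"
  junction <- FALSE
  if (cOff == 0L) {
    g <- map[1L]
    k <- if (plus) g else g + 1L
  } else if (cOff == n) {
    g <- map[n]
    k <- if (plus) g + 1L else g
  } else {
    gPrev <- map[cOff]        # transcript base cOff-1 (0-based)
    gNext <- map[cOff + 1L]   # transcript base cOff
    step <- if (plus) 1L else -1L
    if (gNext != gPrev + step) {
      # boundary falls in an intron gap: stick to the upstream exon side
      junction <- TRUE
      k <- if (plus) gPrev + 1L else gPrev
    } else {
      k <- if (plus) gNext else gNext + 1L
    }
  }
  paperCoord <- if (plus) k else k + 1L
  if (paperCoord < 1L ||
      paperCoord > .Machine$integer.max) paperCoord <- NA_integer_
  list(chrom = transcript@chrom, interbase = as.integer(k),
       paperCoord = as.integer(paperCoord), junctionAdjusted = junction)
}

#' Translate a DNA string (standard genetic code)
#'
#' @param x DNA string in transcript orientation; trailing partial codon is
#'   dropped. Stops are "*".
#' @return amino-acid string.
#' @export
translateDNA <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return("")
  codons <- substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Write a BED6 file (0-based half-open)
#'
#' @param df data.frame with columns chrom, start0, end0, name, score,
#'   strand (score/strand optional; defaults 0 and ".").
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeBED6 <- function(df, path) {
  if (is.null(df$score)) df$score <- 0L
  if (is.null(df$strand)) df$strand <- "."
  out <- df[, c("chrom", "start0", "end0", "name", "score", "strand")]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
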