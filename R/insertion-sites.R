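# Mature-protein boundary inference from curated processing features and
# emission of N-/C-terminal insertion specifications with warning flags.

INSERTION_FLAGS <- c("PTS1", "PTS2", "KDEL", "DILYS", "CAAX", "NO_ATG",
                     "NONCANONICAL_CDS_LENGTH", "LIPIDATION_ADJUSTED",
                     "NO_PROCESSING_INFO", "TRUNCATED")

#' First mature residue after all N-terminal processing
#'
#' The mature start is the maximum of: 1; 2 when the initiator Met is
#' removed; one past the signal or transit peptide end; one past every
#' propeptide that begins at or before the running boundary; and the
#' annotated chain start.
#'
#' @param features a [ProteinFeatureSet-class].
#' @return residue index of the first mature residue.
#' @export
inferMatureStart <- function(features) {
  L <- features@proteinLength
  b <- 1L
  if (isTRUE(features@initMetRemoved)) b <- max(b, 2L)
  if (!is.na(features@signalEnd)) b <- max(b, features@signalEnd + 1L)
  if (!is.na(features@transitEnd)) b <- max(b, features@transitEnd + 1L)
  pp <- features@propeptides
  if (nrow(pp)) {
    repeat {
      hit <- which(pp[, 1L] <= b & pp[, 2L] + 1L > b)
      if (length(hit) == 0L) break
      b <- max(pp[hit, 2L]) + 1L
    }
  }
  if (!is.na(features@chainStart)) b <- max(b, features@chainStart)
  stopIfNot(b <= L, "mature start beyond protein end")
  as.integer(b)
}

#' Last retained residue before C-terminal processing
#'
#' Minimum of: the protein length; the annotated chain end; one before any
#' propeptide that extends to the protein's C-terminus.
#'
#' @param features a [ProteinFeatureSet-class].
#' @return residue index of the last retained residue.
#' @export
inferMatureEnd <- function(features) {
  L <- features@proteinLength
  b <- L
  if (!is.na(features@chainEnd)) b <- min(b, features@chainEnd)
  pp <- features@propeptides
  if (nrow(pp)) {
    repeat {
      hit <- which(pp[, 2L] >= b & pp[, 1L] - 1L < b)
      if (length(hit) == 0L) break
      b <- min(pp[hit, 1L]) - 1L
    }
  }
  as.integer(b)
}

#' Offset a terminal boundary away from a lipidation site
#'
#' When a lipidation site of the matching terminal class lies within five
#' residues of the boundary, the boundary is moved so that exactly five
#' native residues remain between the insertion point and the lipidated
#' residue: for the N-terminus the first mature residue becomes site + 6,
#' for the C-terminus the last retained residue becomes site - 6.
#'
#' @param boundary residue boundary from [inferMatureStart()] /
#'   [inferMatureEnd()].
#' @param lipidation data.frame with columns pos, class.
#' @param terminus "N" or "C".
#' @return list(boundary, adjusted).
#' @export
applyLipidationOffset <- function(boundary, lipidation, terminus) {
  adjusted <- FALSE
  if (nrow(lipidation)) {
    sites <- lipidation$pos[lipidation$class == terminus]
    for (s in sites) {
      if (terminus == "N" && s >= boundary - 5L && boundary < s + 6L) {
        boundary <- s + 6L; adjusted <- TRUE
      } else if (terminus == "C" && s <= boundary + 5L && boundary > s - 6L) {
        boundary <- s - 6L; adjusted <- TRUE
      }
    }
  }
  list(boundary = as.integer(boundary), adjusted = adjusted)
}

#' Scan a protein for sorting/modification motifs (warning-only)
#'
#' Patterns: PTS1 = C-terminal [SAC][KRH][LM]; PTS2 = [RK][LVIQ]..[LVIHQ][SGAK]
#' within residues 1-40; KDEL = C-terminal [KHRQ][DE]EL; di-lysine = K at -3
#' and K at -4 or -5; CAAX = C then two aliphatic then any at the last four
#' positions. These flags never alter insertion coordinates.
#'
#' @param proteinSequence amino-acid string.
#' @return character vector of flags (possibly empty).
#' @export
scanSortingMotifs <- function(proteinSequence) {
  p <- proteinSequence
  n <- nchar(p)
  flags <- character()
  if (n >= 3L && grepl("[SAC][KRH][LM]$", p)) flags <- c(flags, "PTS1")
  if (n >= 6L) {
    head40 <- substr(p, 1L, min(40L, n))
    if (grepl("[RK][LVIQ]..[LVIHQ][SGAK]", head40)) flags <- c(flags, "PTS2")
  }
  if (n >= 4L && grepl("[KHRQ][DE]EL$", p)) flags <- c(flags, "KDEL")
  if (n >= 5L) {
    m3 <- substr(p, n - 2L, n - 2L)
    m4 <- substr(p, n - 3L, n - 3L)
    m5 <- substr(p, n - 4L, n - 4L)
    if (m3 == "K" && (m4 == "K" || m5 == "K")) flags <- c(flags, "DILYS")
  }
  if (n >= 4L && grepl("C[AVILMF][AVILMF].$", p)) flags <- c(flags, "CAAX")
  flags
}

#' Build N- and C-terminal insertion specifications for one gene
#'
#' The N-terminal insertion point is the codon boundary before the first
#' mature residue; the C-terminal point is the boundary after the last
#' retained residue (immediately 5' of the stop codon when no C-terminal
#' processing is annotated). Coordinates are inter-base; the paper-style
#' coordinate is the 1-based position of the nucleotide immediately 5' of
#' the boundary in transcript orientation.
#'
#' @param transcript a [TranscriptModel-class].
#' @param features a [ProteinFeatureSet-class] for the same protein; a
#'   protein-length mismatch is an error.
#' @param genome a [GenomeAssembly-class].
#' @param scanMotifs set FALSE to skip motif warnings (coordinates are
#'   unaffected either way).
#' @return list with elements \code{N} and \code{C}, each a list(geneId,
#'   transcriptId, terminus, boundaryResidue, chrom, strand, interbase,
#'   paperCoord, flags).
#' @export
makeInsertionSpecs <- function(transcript, features, genome,
                               scanMotifs = TRUE) {
  L <- proteinLength(transcript)
  if (L != features@proteinLength)
    stop("protein length mismatch for ", transcript@geneId, ": CDS implies ",
         L, ", feature table says ", features@proteinLength)

  common <- intersect(transcript@warnings,
                      c("NO_ATG", "NONCANONICAL_CDS_LENGTH"))
  motifFlags <- character()
  if (scanMotifs) {
    prot <- translateDNA(splicedCDS(transcript, genome))
    prot <- sub("\\*$", "", prot)
    motifFlags <- scanSortingMotifs(prot)
  }

  nStart <- inferMatureStart(features)
  nAdj <- applyLipidationOffset(nStart, features@lipidation, "N")
  noInfo <- !isTRUE(features@initMetRemoved) &&
    is.na(features@signalEnd) && is.na(features@transitEnd) &&
    nrow(features@propeptides) == 0L && is.na(features@chainStart)
  nFlags <- c(common, motifFlags,
              if (nAdj$adjusted) "LIPIDATION_ADJUSTED",
              if (noInfo) "NO_PROCESSING_INFO")
  nBoundary <- nAdj$boundary
  stopIfNot(nBoundary <= L, "N boundary beyond protein end")
  nPt <- aaBoundaryToGenomic(transcript, nBoundary, "before")

  cEnd <- inferMatureEnd(features)
  cAdj <- applyLipidationOffset(cEnd, features@lipidation, "C")
  cBoundary <- cAdj$boundary
  stopIfNot(cBoundary >= 1L && cBoundary >= nBoundary,
            "C boundary before N boundary")
  cFlags <- c(common, motifFlags, if (cAdj$adjusted) "LIPIDATION_ADJUSTED")
  cPt <- aaBoundaryToGenomic(transcript, cBoundary, "after")

  spec <- function(terminus, boundary, pt, flags) {
    list(geneId = transcript@geneId, transcriptId = transcript@transcriptId,
         terminus = terminus, boundaryResidue = boundary,
         chrom = pt$chrom, strand = transcript@strand,
         interbase = pt$interbase, paperCoord = pt$paperCoord,
         junctionAdjusted = pt$junctionAdjusted,
         flags = unique(flags))
  }
  list(N = spec("N", nBoundary, nPt, nFlags),
       C = spec("C", cBoundary, cPt, cFlags))
}

#' Read a protein-processing feature table
#'
#' TSV dialect: columns uniprot_id, gene_id, length, init_met_removed (0/1),
#' signal_end, transit_end, propeptides (semicolon-separated a-b), chain
#' (a-b), lipidation (semicolon-separated pos:class). Empty fields mean
#' "absent".
#'
#' @param path TSV path.
#' @return named list of [ProteinFeatureSet-class], keyed by gene_id.
#' @export
readProteinFeatures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  out <- list()
  toInt <- function(x) if (is.na(x) || x == "") NA_integer_ else as.integer(x)
  for (i in seq_len(nrow(df))) {
    pp <- df$propeptides[i]
    ppm <- if (!is.na(pp) && nzchar(pp)) {
      parts <- strsplit(strsplit(pp, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
      m <- do.call(rbind, lapply(parts, as.integer))
      colnames(m) <- c("start", "end"); m
    } else NULL
    ch <- df$chain[i]
    chv <- if (!is.na(ch) && nzchar(ch))
      as.integer(strsplit(ch, "-", fixed = TRUE)[[1L]]) else c(NA, NA)
    lp <- df$lipidation[i]
    lpd <- if (!is.na(lp) && nzchar(lp)) {
      parts <- strsplit(strsplit(lp, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
      data.frame(pos = as.integer(vapply(parts, `[`, "", 1L)),
                 class = vapply(parts, `[`, "", 2L))
    } else NULL
    out[[df$gene_id[i]]] <- ProteinFeatureSet(
      uniprotId = df$uniprot_id[i], geneId = df$gene_id[i],
      proteinLength = as.integer(df$length[i]),
      initMetRemoved = df$init_met_removed[i] %in% c("1", "TRUE", "true"),
      signalEnd = toInt(df$signal_end[i]),
      transitEnd = toInt(df$transit_end[i]),
      propeptides = ppm, chainStart = chv[1L], chainEnd = chv[2L],
      lipidation = lpd)
  }
  out
}
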