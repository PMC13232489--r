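#' @importClassesFrom Biostrings DNAStringSet
NULL

# ---------------------------------------------------------------------------
# GenomeAssembly: named chromosome sequences, the substrate for all scanning
# and coordinate arithmetic. Internal coordinates throughout the package are
# 0-based half-open on the plus strand; insertion points are inter-base.
# ---------------------------------------------------------------------------

#' GenomeAssembly class
#'
#' Holds named chromosome sequences (uppercase DNA over A/C/G/T/N) together
#' with an assembly label. Construct with [loadGenome()] or
#' [GenomeAssembly()].
#'
#' @slot sequences a [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot assembly single character, assembly label (metadata only).
#' @export
setClass("GenomeAssembly",
  slots = c(sequences = "DNAStringSet", assembly = "character"))

setValidity("GenomeAssembly", function(object) {
  nm <- names(object@sequences)
  if (is.null(nm) || any(!nzchar(nm))) return("chromosome names must be nonempty")
  if (anyDuplicated(nm)) return("duplicate chromosome names")
  if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0L))
    return("empty chromosome sequence")
  af <- Biostrings::alphabetFrequency(object@sequences)
  bad <- setdiff(colnames(af), c("A", "C", "G", "T", "N"))
  if (length(object@sequences) && any(af[, bad, drop = FALSE] > 0))
    return("sequences must contain only A, C, G, T, N")
  if (length(object@assembly) != 1L) return("assembly must be a single string")
  TRUE
})

#' Construct a GenomeAssembly from character sequences
#'
#' @param sequences named character vector or DNAStringSet of chromosomes.
#' @param assembly assembly label.
#' @return a [GenomeAssembly-class] object.
#' @export
GenomeAssembly <- function(sequences, assembly = "synthetic") {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  new("GenomeAssembly", sequences = sequences, assembly = assembly)
}

#' @describeIn GenomeAssembly chromosome names.
#' @param x a GenomeAssembly.
#' @export
chromNames <- function(x) names(x@sequences)

#' @describeIn GenomeAssembly named integer vector of chromosome lengths.
#' @export
chromLengths <- function(x) setNames(Biostrings::width(x@sequences),
                                     names(x@sequences))

#' Extract a plus-strand slice of a chromosome
#'
#' @param x a [GenomeAssembly-class].
#' @param chrom chromosome name.
#' @param start0,end0 0-based half-open interval; clipped to the chromosome.
#' @return the slice as a character string (possibly shorter than requested
#'   when clipped at contig ends).
#' @export
sliceSeq <- function(x, chrom, start0, end0) {
  len <- chromLengths(x)[[chrom]]
  s <- max(0L, as.integer(start0))
  e <- min(len, as.integer(end0))
  if (e <= s) return("")
  as.character(Biostrings::subseq(x@sequences[[chrom]], start = s + 1L, end = e))
}

setMethod("show", "GenomeAssembly", function(object) {
  cat("GenomeAssembly '", object@assembly, "' with ",
      length(object@sequences), " chromosome(s), total ",
      sum(Biostrings::width(object@sequences)), " bp\n", sep = "")
})

# ---------------------------------------------------------------------------
# TranscriptModel: CDS structure of one (canonical) transcript. Segments are
# stored 0-based half-open in ascending plus-strand order regardless of
# strand; they INCLUDE the stop codon, so protein length = CDS/3 - 1.
# ---------------------------------------------------------------------------

#' TranscriptModel class
#'
#' Exon/CDS structure and strand for one transcript; maps amino-acid indices
#' to genomic positions. CDS segments include the stop codon.
#'
#' @slot transcriptId,geneId,chrom identifiers.
#' @slot strand "+" or "-".
#' @slot cdsStart0,cdsEnd0 integer vectors, 0-based half-open plus-strand
#'   segment bounds, sorted ascending and non-overlapping.
#' @slot isCanonical logical flag.
#' @slot warnings character vector of per-gene warnings (e.g. CDS length not
#'   divisible by 3, missing ATG/stop).
#' @export
setClass("TranscriptModel",
  slots = c(transcriptId = "character", geneId = "character",
            chrom = "character", strand = "character",
            cdsStart0 = "integer", cdsEnd0 = "integer",
            isCanonical = "logical", warnings = "character"))

setValidity("TranscriptModel", function(object) {
  s <- object@cdsStart0; e <- object@cdsEnd0
  if (length(s) != length(e)) return("segment start/end length mismatch")
  if (length(s) == 0L) return("transcript must have at least one CDS segment")
  if (any(e <= s)) return("empty CDS segment")
  if (is.unsorted(s, strictly = TRUE)) return("segments must be sorted ascending")
  if (length(s) > 1L && any(s[-1L] < e[-length(e)]))
    return("segments must not overlap")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  TRUE
})

TranscriptModel <- function(transcriptId, geneId, chrom, strand,
                            cdsStart0, cdsEnd0, isCanonical = TRUE,
                            warnings = character()) {
  new("TranscriptModel", transcriptId = transcriptId, geneId = geneId,
      chrom = chrom, strand = strand,
      cdsStart0 = as.integer(cdsStart0), cdsEnd0 = as.integer(cdsEnd0),
      isCanonical = isCanonical, warnings = warnings)
}

#' @describeIn TranscriptModel total CDS length in nucleotides.
#' @param x a TranscriptModel.
#' @export
cdsLength <- function(x) sum(x@cdsEnd0 - x@cdsStart0)

#' @describeIn TranscriptModel protein length in residues (CDS includes the
#'   stop codon, so this is CDS/3 - 1).
#' @export
proteinLength <- function(x) cdsLength(x) %/% 3L - 1L

#' @describeIn TranscriptModel CDS segments as an [IRanges::IRanges]
#'   (1-based, for interoperability).
#' @export
cdsRanges <- function(x) IRanges::IRanges(start = x@cdsStart0 + 1L,
                                          end = x@cdsEnd0)

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", object@transcriptId, " (gene ", object@geneId,
      ", ", object@chrom, object@strand, "), ",
      length(object@cdsStart0), " CDS segment(s), ", cdsLength(object),
      " nt", if (length(object@warnings))
        paste0(" [", paste(object@warnings, collapse = ","), "]") else "",
      "\n", sep = "")
})

# ---------------------------------------------------------------------------
# ProteinFeatureSet: curated maturation features for one protein.
# ---------------------------------------------------------------------------

#' ProteinFeatureSet class
#'
#' Curated protein-processing annotations used to delineate the mature
#' polypeptide: initiator-Met removal, signal/transit peptides, propeptides,
#' the annotated chain, and terminal lipidation sites.
#'
#' @slot uniprotId,geneId identifiers.
#' @slot proteinLength residues.
#' @slot initMetRemoved logical.
#' @slot signalEnd,transitEnd last residue of the signal/transit peptide
#'   (both start at residue 1); NA when absent.
#' @slot propeptides integer matrix with columns start,end (0 rows if none).
#' @slot chainStart,chainEnd annotated mature-chain interval; NA when absent.
#' @slot lipidation data.frame with columns pos (residue) and class
#'   ("N", "C" or "internal").
#' @export
setClass("ProteinFeatureSet",
  slots = c(uniprotId = "character", geneId = "character",
            proteinLength = "integer", initMetRemoved = "logical",
            signalEnd = "integer", transitEnd = "integer",
            propeptides = "matrix", chainStart = "integer",
            chainEnd = "integer", lipidation = "data.frame"))

setValidity("ProteinFeatureSet", function(object) {
  L <- object@proteinLength
  if (length(L) != 1L || is.na(L) || L < 1L) return("invalid protein length")
  inL <- function(v) all(is.na(v) | (v >= 1L & v <= L))
  if (!inL(object@signalEnd) || !inL(object@transitEnd))
    return("signal/transit end outside protein")
  pp <- object@propeptides
  if (nrow(pp) && (any(pp < 1L | pp > L) || any(pp[, 2L] < pp[, 1L])))
    return("propeptide interval outside protein")
  if (!inL(object@chainStart) || !inL(object@chainEnd))
    return("chain interval outside protein")
  if (!is.na(object@chainStart) && !is.na(object@chainEnd) &&
      object@chainEnd < object@chainStart) return("chain end before start")
  lp <- object@lipidation
  if (nrow(lp) && (!all(c("pos", "class") %in% names(lp)) ||
                   any(lp$pos < 1L | lp$pos > L) ||
                   !all(lp$class %in% c("N", "C", "internal"))))
    return("invalid lipidation table")
  TRUE
})

ProteinFeatureSet <- function(uniprotId = "", geneId = "", proteinLength,
                              initMetRemoved = FALSE, signalEnd = NA,
                              transitEnd = NA, propeptides = NULL,
                              chainStart = NA, chainEnd = NA,
                              lipidation = NULL) {
  if (is.null(propeptides))
    propeptides <- matrix(integer(0), ncol = 2,
                          dimnames = list(NULL, c("start", "end")))
  storage.mode(propeptides) <- "integer"
  if (is.null(lipidation))
    lipidation <- data.frame(pos = integer(0), class = character(0))
  lipidation$pos <- as.integer(lipidation$pos)
  new("ProteinFeatureSet", uniprotId = uniprotId, geneId = geneId,
      proteinLength = as.integer(proteinLength),
      initMetRemoved = initMetRemoved,
      signalEnd = as.integer(signalEnd), transitEnd = as.integer(transitEnd),
      propeptides = propeptides, chainStart = as.integer(chainStart),
      chainEnd = as.integer(chainEnd), lipidation = lipidation)
}

setMethod("show", "ProteinFeatureSet", function(object) {
  cat("ProteinFeatureSet ", object@uniprotId, " (gene ", object@geneId,
      "), ", object@proteinLength, " aa\n", sep = "")
})

# ---------------------------------------------------------------------------
# PamSiteIndex: every NGG-adjacent 20-mer in a genome, both strands.
# ---------------------------------------------------------------------------

#' PamSiteIndex class
#'
#' Genome-wide index of SpCas9 NGG protospacer sites (20-mer + PAM, both
#' strands), used for mismatch-tolerant off-target counting. Build with
#' [buildPamIndex()].
#'
#' @slot sites data.frame with columns chrom, strand, start0 (0-based
#'   plus-strand protospacer start), proto (20-mer in protospacer sense),
#'   pam (3-mer).
#' @slot assembly label of the indexed genome.
#' @export
setClass("PamSiteIndex",
  slots = c(sites = "data.frame", assembly = "character",
            cache = "environment"))

setValidity("PamSiteIndex", function(object) {
  need <- c("chrom", "strand", "start0", "proto", "pam")
  if (!all(need %in% names(object@sites))) return("missing site columns")
  if (nrow(object@sites) &&
      any(nchar(object@sites$proto) != 20L)) return("protospacers must be 20 nt")
  TRUE
})

setMethod("show", "PamSiteIndex", function(object) {
  cat("PamSiteIndex over '", object@assembly, "': ", nrow(object@sites),
      " NGG sites\n", sep = "")
})

#' @describeIn PamSiteIndex number of indexed sites.
#' @param x a PamSiteIndex.
#' @export
siteCount <- function(x) nrow(x@sites)
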