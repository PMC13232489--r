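# Genome-wide NGG site index, mismatch-tolerant off-target counting, and
# exact-occurrence counting for primer specificity.
#
# Off-target distance is ungapped (Hamming); the default budget of 3
# mismatches with an NGG-only PAM at the off-target site is a documented,
# overridable convention. Sites containing N are excluded from the index.

# Enumerate NGG protospacer sites on both strands of one plus-strand
# sequence. Returns 0-based plus-strand protospacer starts.
scanPamSites <- function(seqChar) {
  ch <- strsplit(seqChar, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 23L) {
    return(list(plus = integer(0), minus = integer(0)))
  }
  isG <- ch == "G"
  isC <- ch == "C"
  # plus strand: protospacer 0-based start p0, PAM 1-based [p0+21, p0+23]
  # with GG 1-based start j = p0+22; need p0 >= 0 and PAM end <= n
  gg <- which(isG[-n] & isG[-1L])            # 1-based start of "GG"
  pPlus <- gg[gg >= 22L & gg + 1L <= n] - 22L
  # minus strand: plus-pattern CCN + 20-mer; "CC" 1-based start j with
  # protospacer plus-span [j+3-1 .. j+22-1] 0-based start = j+2
  cc <- which(isC[-n] & isC[-1L])
  pMinus <- cc[cc + 22L <= n] + 2L
  list(plus = as.integer(pPlus), minus = as.integer(pMinus))
}

#' Build a genome-wide NGG protospacer index
#'
#' Records every NGG-adjacent 20-mer on both strands of every chromosome.
#' Enumerating the index reproduces a naive scan exactly; sites containing N
#' are excluded.
#'
#' @param genome a [GenomeAssembly-class].
#' @return a [PamSiteIndex-class].
#' @export
buildPamIndex <- function(genome) {
  rows <- lapply(chromNames(genome), function(chrom) {
    s <- as.character(genome@sequences[[chrom]])
    hits <- scanPamSites(s)
    res <- list()
    if (length(hits$plus)) {
      proto <- substring(s, hits$plus + 1L, hits$plus + 20L)
      pam <- substring(s, hits$plus + 21L, hits$plus + 23L)
      res$p <- data.frame(chrom = chrom, strand = "+", start0 = hits$plus,
                          proto = proto, pam = pam)
    }
    if (length(hits$minus)) {
      proto <- revComp(substring(s, hits$minus + 1L, hits$minus + 20L))
      pam <- revComp(substring(s, hits$minus - 2L, hits$minus))
      res$m <- data.frame(chrom = chrom, strand = "-", start0 = hits$minus,
                          proto = proto, pam = pam)
    }
    do.call(rbind, res)
  })
  sites <- do.call(rbind, rows)
  if (is.null(sites))
    sites <- data.frame(chrom = character(0), strand = character(0),
                        start0 = integer(0), proto = character(0),
                        pam = character(0))
  keep <- !grepl("N", paste0(sites$proto, sites$pam), fixed = TRUE)
  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  sites$key <- paste(sites$chrom, sites$strand, sites$start0)
  new("PamSiteIndex", sites = sites, assembly = genome@assembly,
      cache = new.env(parent = emptyenv()))
}

#' Count off-target sites for protospacers
#'
#' Number of indexed NGG sites whose 20-mer lies within Hamming distance
#' \code{maxMismatches} of each protospacer, excluding the on-target
#' location itself when given.
#'
#' @param protospacers character vector of 20-nt protospacers.
#' @param index a [PamSiteIndex-class].
#' @param maxMismatches mismatch budget (default 3).
#' @param onTarget optional data.frame with columns chrom, strand, start0
#'   (one row per protospacer) identifying the on-target site to exclude.
#' @return integer vector of off-target counts.
#' @export
countOfftargets <- function(protospacers, index, maxMismatches = 3,
                            onTarget = NULL) {
  stopIfNot(all(nchar(protospacers) == 20L), "protospacers must be 20 nt")
  stopIfNot(maxMismatches >= 0, "maxMismatches must be >= 0")
  sites <- index@sites
  if (nrow(sites) == 0L) return(integer(length(protospacers)))
  clean <- !grepl("N", protospacers, fixed = TRUE)
  counts <- integer(length(protospacers))
  if (any(clean)) {
    # fast path: 2-bit packed popcount scan (index sites are N-free)
    if (is.null(index@cache$packed))
      index@cache$packed <- pack_2bit(sites$proto)
    counts[clean] <- hamming_count_packed(protospacers[clean],
                                          index@cache$packed,
                                          as.integer(maxMismatches))
  }
  if (any(!clean))
    counts[!clean] <- hamming_count_batch(protospacers[!clean], sites$proto,
                                          as.integer(maxMismatches))
  if (!is.null(onTarget)) {
    key <- if (!is.null(sites$key)) sites$key
           else paste(sites$chrom, sites$strand, sites$start0)
    selfKey <- paste(onTarget$chrom, onTarget$strand, onTarget$start0)
    hit <- match(selfKey, key)
    present <- !is.na(hit)
    if (any(present)) {
      d <- vapply(which(present), function(i)
        hamming_distance_cpp(protospacers[i], sites$proto[hit[i]]),
        integer(1))
      counts[which(present)[d <= maxMismatches]] <-
        counts[which(present)[d <= maxMismatches]] - 1L
    }
  }
  as.integer(counts)
}

#' Count exact occurrences of an oligo in a genome (both strands)
#'
#' Functional stand-in for a genome-wide exact-match search: counts exact,
#' possibly overlapping, matches of the oligo and of its reverse complement
#' across all chromosomes. A palindromic oligo at one locus counts twice.
#'
#' @param oligo DNA string, length >= 10.
#' @param genome a [GenomeAssembly-class].
#' @return integer count.
#' @export
exactOccurrences <- function(oligo, genome) {
  stopIfNot(nchar(oligo) >= 10L, "oligo must be at least 10 nt")
  fwd <- Biostrings::DNAString(oligo)
  rev <- Biostrings::reverseComplement(fwd)
  sum(Biostrings::vcountPattern(fwd, genome@sequences)) +
    sum(Biostrings::vcountPattern(rev, genome@sequences))
}

#' Hamming distance between equal-length DNA strings
#'
#' @param a,b equal-length strings; N mismatches everything.
#' @return integer distance.
#' @export
hammingDistance <- function(a, b) hamming_distance_cpp(a, b)
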