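# SpCas9 guide enumeration in windows around insertion points, composition
# filters, transcription-suitability classification, and ranked selection.

#' Guide design parameters
#'
#' Defaults: +/-50 nt window, 20 nt protospacer, NGG PAM, blunt cut 3 nt 5'
#' of the PAM, GC in [25, 80] percent (inclusive, protospacer only),
#' homopolymers of 7+ rejected, 4+ consecutive Ts mark a guide as suitable
#' for in vitro transcription only, off-target budget 3 mismatches.
#'
#' @param windowHalfwidth,protospacerLength,cutOffset,gcMin,gcMax
#'   numeric parameters, see description.
#' @param homopolymerLength minimal homopolymer run that rejects a guide.
#' @param polyTRun run of Ts that demotes a guide to in-vitro-only.
#' @param maxMismatches off-target Hamming budget.
#' @return list of class "designParameters".
#' @export
designParameters <- function(windowHalfwidth = 50L, protospacerLength = 20L,
                             cutOffset = 3L, gcMin = 25, gcMax = 80,
                             homopolymerLength = 7L, polyTRun = 4L,
                             maxMismatches = 3L) {
  stopIfNot(gcMin < gcMax, "gcMin must be below gcMax")
  p <- list(windowHalfwidth = as.integer(windowHalfwidth),
            protospacerLength = as.integer(protospacerLength),
            pam = "NGG", cutOffset = as.integer(cutOffset),
            gcMin = gcMin, gcMax = gcMax,
            homopolymerLength = as.integer(homopolymerLength),
            polyTRun = as.integer(polyTRun),
            maxMismatches = as.integer(maxMismatches))
  class(p) <- "designParameters"
  p
}

#' Extract the guide-search window around an insertion point
#'
#' Plus-strand slice \code{[ins - halfwidth, ins + halfwidth)}, truncated at
#' contig ends (flagged), with one extra base fetched on each side for
#' PAM-context checks.
#'
#' @param genome a [GenomeAssembly-class].
#' @param chrom chromosome name.
#' @param interbase insertion point (0-based inter-base offset).
#' @param halfwidth window half-width in nt.
#' @return list(seq, start0, truncated, padLeft, padRight).
#' @export
extractWindow <- function(genome, chrom, interbase, halfwidth = 50L) {
  len <- chromLengths(genome)[[chrom]]
  s <- max(0L, interbase - halfwidth)
  e <- min(len, interbase + halfwidth)
  list(seq = sliceSeq(genome, chrom, s, e),
       chrom = chrom, start0 = as.integer(s),
       truncated = (s > interbase - halfwidth) || (e < interbase + halfwidth),
       padLeft = if (s > 0L) sliceSeq(genome, chrom, s - 1L, s) else "",
       padRight = if (e < len) sliceSeq(genome, chrom, e, e + 1L) else "")
}

#' Enumerate unfiltered guide candidates in a window
#'
#' Both strands are scanned for 20-mer + NGG placements that fit fully
#' inside the window; minus-strand candidates appear as CCN + 20-mer on the
#' plus strand and are reported in protospacer sense. The PAM-context base
#' (first base 3' of the PAM on the protospacer strand) is taken from the
#' window or its 1-nt padding; when off-contig it is "".
#'
#' @param window result of [extractWindow()].
#' @return data.frame of candidates: proto, pam, pamNext, strand,
#'   protoStart0 (genomic, plus strand), cutInterbase, gc.
#' @export
enumerateGuides <- function(window) {
  w <- window$seq
  o <- window$start0
  n <- nchar(w)
  empty <- data.frame(proto = character(0), pam = character(0),
                      pamNext = character(0), strand = character(0),
                      protoStart0 = integer(0), cutInterbase = integer(0),
                      gc = numeric(0))
  if (n < 23L) return(empty)
  hits <- scanPamSites(w)
  res <- list()
  if (length(hits$plus)) {
    p0 <- hits$plus
    nextIdx <- p0 + 24L                       # 1-based pos after PAM
    pamNext <- ifelse(nextIdx <= n, substring(w, nextIdx, nextIdx),
                      window$padRight)
    res$p <- data.frame(
      proto = substring(w, p0 + 1L, p0 + 20L),
      pam = substring(w, p0 + 21L, p0 + 23L),
      pamNext = pamNext, strand = "+",
      protoStart0 = o + p0,
      cutInterbase = o + p0 + 17L)
  }
  if (length(hits$minus)) {
    p0 <- hits$minus                          # 0-based plus start of 20-mer
    prevIdx <- p0 - 3L                        # 1-based plus base 5' of CCN
    pamNext <- vapply(prevIdx, function(j) {
      if (j >= 1L) complementBase(substring(w, j, j))
      else if (j == 0L && nzchar(window$padLeft))
        complementBase(window$padLeft)
      else ""
    }, character(1))
    res$m <- data.frame(
      proto = revComp(substring(w, p0 + 1L, p0 + 20L)),
      pam = revComp(substring(w, p0 - 2L, p0)),
      pamNext = pamNext, strand = "-",
      protoStart0 = o + p0,
      cutInterbase = o + p0 + 3L)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

#' Apply composition and PAM-context filters to guide candidates
#'
#' GC is computed on the 20-nt protospacer with inclusive bounds; the
#' homopolymer and poly-T checks apply to the protospacer in its own sense
#' (the transcribed sgRNA); GGG PAMs and PAMs whose next non-guide base is G
#' are rejected; windows containing N disqualify overlapping guides.
#'
#' @param candidates data.frame from [enumerateGuides()].
#' @param params [designParameters()].
#' @return the data.frame with columns gc, rejectReasons (comma string, ""
#'   if kept) and transcriptionClass ("in_vivo"/"in_vitro_only").
#' @export
applyGuideFilters <- function(candidates, params = designParameters()) {
  if (nrow(candidates) == 0L) {
    candidates$rejectReasons <- character(0)
    candidates$transcriptionClass <- character(0)
    return(candidates)
  }
  gc <- gcPercent(candidates$proto)
  homopoly <- paste0("A{", params$homopolymerLength, "}|C{",
                     params$homopolymerLength, "}|G{",
                     params$homopolymerLength, "}|T{",
                     params$homopolymerLength, "}")
  reasons <- lapply(seq_len(nrow(candidates)), function(i) {
    r <- character()
    if (grepl("N", candidates$proto[i], fixed = TRUE) ||
        grepl("N", candidates$pam[i], fixed = TRUE)) r <- c(r, "N_IN_SITE")
    if (gc[i] < params$gcMin) r <- c(r, "GC_LOW")
    if (gc[i] > params$gcMax) r <- c(r, "GC_HIGH")
    if (grepl(homopoly, candidates$proto[i])) r <- c(r, "HOMOPOLYMER")
    if (candidates$pam[i] == "GGG") r <- c(r, "PAM_GGG")
    if (candidates$pamNext[i] == "G" || !nzchar(candidates$pamNext[i]))
      r <- c(r, "PAM_NEXT_G")
    r
  })
  polyT <- strrep("T", params$polyTRun)
  candidates$gc <- gc
  candidates$rejectReasons <- vapply(reasons, paste, "", collapse = ",")
  candidates$transcriptionClass <-
    ifelse(grepl(polyT, candidates$proto, fixed = TRUE),
           "in_vitro_only", "in_vivo")
  candidates
}

#' Blunt-cut coordinate of a candidate
#'
#' The cut is between protospacer positions 17 and 18 (protospacer sense),
#' 3 nt 5' of the PAM: inter-base \code{protoStart0 + 17} on the plus
#' strand, \code{protoStart0 + 3} for minus-strand candidates.
#'
#' @param candidates data.frame with protoStart0 and strand.
#' @return integer vector of inter-base cut offsets.
#' @export
cutCoordinate <- function(candidates) {
  ifelse(candidates$strand == "+",
         candidates$protoStart0 + 17L,
         candidates$protoStart0 + 3L)
}

#' Rank filtered candidates and select guides
#'
#' Candidates are sorted by off-target count, then cut-to-insertion
#' distance, then plus strand before minus, then smaller genomic start. The
#' best in-vivo-transcription guide is selected; an additional
#' in-vitro-only guide is reported iff its cut site is strictly closer to
#' the insertion point (or no in-vivo candidate exists).
#'
#' @param candidates filtered data.frame carrying offtargetCount.
#' @param insertionInterbase the insertion point.
#' @return list(inVivoBest, inVitroExtra, noGuide); the first two are
#'   one-row data.frames or NULL.
#' @export
rankAndSelect <- function(candidates, insertionInterbase) {
  keep <- candidates[candidates$rejectReasons == "", , drop = FALSE]
  if (nrow(keep) == 0L)
    return(list(inVivoBest = NULL, inVitroExtra = NULL, noGuide = TRUE))
  keep$distance <- abs(keep$cutInterbase - insertionInterbase)
  ord <- order(keep$offtargetCount, keep$distance,
               keep$strand != "+", keep$protoStart0)
  keep <- keep[ord, , drop = FALSE]
  vivo <- keep[keep$transcriptionClass == "in_vivo", , drop = FALSE]
  vitro <- keep[keep$transcriptionClass == "in_vitro_only", , drop = FALSE]
  best <- if (nrow(vivo)) vivo[1L, , drop = FALSE] else NULL
  extra <- NULL
  if (nrow(vitro)) {
    cand <- vitro[1L, , drop = FALSE]
    if (is.null(best) || cand$distance < best$distance) extra <- cand
  }
  list(inVivoBest = best, inVitroExtra = extra,
       noGuide = is.null(best) && is.null(extra))
}

#' Design guides for one insertion point
#'
#' Convenience wrapper: window extraction, enumeration, filtering,
#' off-target counting and selection.
#'
#' @param genome a [GenomeAssembly-class].
#' @param spec insertion spec (list with chrom, interbase).
#' @param index a [PamSiteIndex-class] for the same genome.
#' @param params [designParameters()].
#' @return list(selection, candidates, window).
#' @export
designGuides <- function(genome, spec, index, params = designParameters()) {
  win <- extractWindow(genome, spec$chrom, spec$interbase,
                       params$windowHalfwidth)
  cands <- applyGuideFilters(enumerateGuides(win), params)
  pass <- cands$rejectReasons == ""
  cands$offtargetCount <- rep(NA_integer_, nrow(cands))
  if (any(pass)) {
    cands$offtargetCount[pass] <- countOfftargets(
      cands$proto[pass], index, params$maxMismatches,
      onTarget = data.frame(chrom = spec$chrom,
                            strand = cands$strand[pass],
                            start0 = cands$protoStart0[pass]))
  }
  sel <- rankAndSelect(cands, spec$interbase)
  list(selection = sel, candidates = cands, window = win)
}
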