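# Homology-arm and genotyping primer design: junction-anchored primers
# carrying silent mutations (split into A/B pairs when the mutations sit too
# far from the junction), outer primers chosen by amplicon length and
# melting-temperature match, and genotyping primers flanking the edited
# region.

# --- nearest-neighbor melting temperature -----------------------------------
# SantaLucia (unified) parameters; fixed conditions documented in the
# methods vignette: 50 mM monovalent salt, 250 nM oligo, entropic salt
# correction 0.368 * (N-1) * ln[Na+].

NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Thermodynamic Tm estimate (degrees C) with fixed, documented salt and
#' oligo concentrations; deterministic by construction.
#'
#' @param seqs character vector of primer sequences (ACGT).
#' @param monovalent monovalent cation concentration, mol/L.
#' @param oligo oligo concentration, mol/L.
#' @return numeric vector of Tm in degrees Celsius.
#' @export
meltingTemperature <- function(seqs, monovalent = 0.05, oligo = 250e-9) {
  R <- 1.9872
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 8L || grepl("N", s, fixed = TRUE)) return(NA_real_)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    di <- paste0(ch[-n], ch[-1L])
    dH <- sum(NN_DH[di]) * 1000
    dS <- sum(NN_DS[di])
    for (term in c(ch[1L], ch[n])) {
      if (term %in% c("G", "C")) { dH <- dH + 100;  dS <- dS - 2.8 }
      else                       { dH <- dH + 2300; dS <- dS + 4.1 }
    }
    dS <- dS + 0.368 * (n - 1L) * log(monovalent)
    dH / (dS + R * log(oligo / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# --- silent mutation planning ----------------------------------------------

# synonymous alternatives for each codon, standard code
synonymousCodons <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  alts <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
  setdiff(alts, codon)
}

# positions (0-based plus-strand) within `dist` of an exon-intron junction,
# on the exon side (`exonGuard` nt) and intron side (`intronGuard` nt)
spliceGuardZone <- function(transcript, exonGuard = 3L, intronGuard = 6L) {
  s <- transcript@cdsStart0; e <- transcript@cdsEnd0
  if (length(s) < 2L) return(integer(0))
  z <- integer(0)
  for (i in seq_len(length(s) - 1L)) {
    # junction after segment i (plus orientation)
    z <- c(z, seq.int(e[i] - exonGuard, e[i] - 1L),        # exon side
              seq.int(e[i], e[i] + intronGuard - 1L),      # intron side
              seq.int(s[i + 1L] - intronGuard, s[i + 1L] - 1L),
              seq.int(s[i + 1L], s[i + 1L] + exonGuard - 1L))
  }
  unique(z)
}

#' Plan silent mutations over a guide's seed/PAM footprint
#'
#' Mutable positions are the two PAM G bases and the eight PAM-proximal
#' protospacer bases (the seed). Codons overlapping those positions are
#' replaced by synonymous codons maximizing changed bases within the
#' footprint; changes accumulate until 4-5 nucleotide substitutions are
#' reached or positions are exhausted. Footprint bases outside the CDS are
#' changed freely (transversion), except within 6 nt of a splice junction;
#' coding bases within 3 nt of an exonic splice boundary are never touched.
#'
#' @param guide one-row data.frame (proto, pam, strand, protoStart0) from
#'   guide selection.
#' @param transcript the [TranscriptModel-class] being edited.
#' @param genome a [GenomeAssembly-class].
#' @param targetMin,targetMax nucleotide-substitution target (4-5).
#' @return list with \code{mutations} (data.frame: pos0, ref, alt,
#'   codonIndex, codonBefore, codonAfter), \code{count},
#'   \code{pamDisrupted}, \code{warnings}.
#' @export
planSilentMutations <- function(guide, transcript, genome,
                                targetMin = 4L, targetMax = 5L) {
  chrom <- transcript@chrom
  s0 <- guide$protoStart0
  if (guide$strand == "+") {
    pamG <- c(s0 + 21L, s0 + 22L)             # the two G bases of NGG
    seed <- seq.int(s0 + 19L, s0 + 12L)       # PAM-proximal first
  } else {
    pamG <- c(s0 - 2L, s0 - 3L)
    seed <- seq.int(s0, s0 + 7L)
  }
  footprint <- c(pamG, seed)

  map <- cdsCoordMap(transcript)              # transcript order
  posToCdsIdx <- match(footprint, map)        # CDS offset (1-based) or NA
  guard <- spliceGuardZone(transcript)

  chromSeq <- genome@sequences[[chrom]]
  plusBase <- function(p) as.character(Biostrings::subseq(chromSeq, p + 1L,
                                                          p + 1L))
  minus <- transcript@strand == "-"

  codonAt <- function(ci) {
    idx <- (3L * (ci - 1L) + 1L):(3L * ci)    # CDS offsets, 1-based
    pos <- map[idx]
    b <- vapply(pos, plusBase, character(1))
    if (minus) b <- complementBase(b)
    list(pos = pos, codon = paste(b, collapse = ""))
  }

  # build prioritized mutation units: PAM codons/bases first, then seed
  unitKeys <- character(0)
  units <- list()
  addUnit <- function(key, u) {
    if (!key %in% unitKeys) {
      unitKeys <<- c(unitKeys, key)
      units[[key]] <<- u
    }
  }
  for (p in footprint) {
    i <- match(p, map)
    if (!is.na(i)) {
      ci <- (i - 1L) %/% 3L + 1L
      if (ci > proteinLength(transcript) + 1L) next
      addUnit(paste0("codon", ci), list(type = "codon", ci = ci))
    } else {
      if (p %in% guard) next
      if (p < 0L || p >= Biostrings::nchar(chromSeq)) next
      addUnit(paste0("base", p), list(type = "base", pos = p))
    }
  }

  muts <- list()
  count <- 0L
  pamDisrupted <- FALSE
  for (key in unitKeys) {
    if (count >= targetMin) break
    u <- units[[key]]
    if (u$type == "base") {
      if (count + 1L > targetMax) next
      ref <- plusBase(u$pos)
      alt <- chartr("ACGT", "CATG", ref)      # transversion map
      muts[[length(muts) + 1L]] <-
        data.frame(pos0 = u$pos, ref = ref, alt = alt,
                   codonIndex = NA_integer_, codonBefore = NA_character_,
                   codonAfter = NA_character_)
      count <- count + 1L
      if (u$pos %in% pamG) pamDisrupted <- TRUE
      next
    }
    ca <- codonAt(u$ci)
    # skip codons with any base inside the splice guard
    if (any(ca$pos %in% guard)) next
    alts <- synonymousCodons(ca$codon)
    if (length(alts) == 0L) next
    before <- strsplit(ca$codon, "", fixed = TRUE)[[1L]]
    scored <- lapply(alts, function(a) {
      after <- strsplit(a, "", fixed = TRUE)[[1L]]
      changed <- which(after != before)
      fpChanged <- sum(ca$pos[changed] %in% footprint)
      list(alt = a, changed = changed, fp = fpChanged, tot = length(changed))
    })
    ord <- order(-vapply(scored, `[[`, 0L, "fp"),
                 -vapply(scored, `[[`, 0L, "tot"),
                 vapply(scored, `[[`, "", "alt"))
    pick <- NULL
    for (j in ord) {
      if (count + scored[[j]]$tot <= targetMax) { pick <- scored[[j]]; break }
    }
    if (is.null(pick)) next
    after <- strsplit(pick$alt, "", fixed = TRUE)[[1L]]
    for (k in pick$changed) {
      pos <- ca$pos[k]
      refPlus <- plusBase(pos)
      altTx <- after[k]
      altPlus <- if (minus) complementBase(altTx) else altTx
      muts[[length(muts) + 1L]] <-
        data.frame(pos0 = pos, ref = refPlus, alt = altPlus,
                   codonIndex = u$ci, codonBefore = ca$codon,
                   codonAfter = pick$alt)
      if (pos %in% pamG) pamDisrupted <- TRUE
    }
    count <- count + pick$tot
  }
  mutations <- if (length(muts)) do.call(rbind, muts) else
    data.frame(pos0 = integer(0), ref = character(0), alt = character(0),
               codonIndex = integer(0), codonBefore = character(0),
               codonAfter = character(0))
  rownames(mutations) <- NULL
  warnings <- if (count < targetMin) "INSUFFICIENT_SILENT_MUTATIONS"
              else character(0)
  list(mutations = mutations, count = count, pamDisrupted = pamDisrupted,
       warnings = warnings)
}

# --- anchored primers -------------------------------------------------------

# transcript-sense base at distance d from the junction on the given side
# ("up" = 5' of junction in transcript orientation, d=1 adjacent), as a
# plus-strand 0-based position
dToPlusPos <- function(side, strand, interbase, d) {
  if (side == "up") {
    if (strand == "+") interbase - d else interbase + d - 1L
  } else {
    if (strand == "+") interbase + d - 1L else interbase - d
  }
}

# transcript-sense sequence over d in [dLo, dHi], ordered 5'->3' in
# transcript orientation; mutated bases substituted from `mutLookup`
# (named plus-strand alt bases keyed by pos0). Returns "" when the span
# runs off the contig.
sliceByD <- function(genome, chrom, strand, side, interbase, dLo, dHi,
                     mutLookup = NULL) {
  up <- side == "up"
  plusLow <- if ((up && strand == "+") || (!up && strand == "-"))
    interbase - dHi else interbase + dLo - 1L
  width <- dHi - dLo + 1L
  s <- sliceSeq(genome, chrom, plusLow, plusLow + width)
  if (nchar(s) != width) return("")
  if (!is.null(mutLookup) && length(mutLookup)) {
    mp <- as.integer(names(mutLookup))
    inside <- which(mp >= plusLow & mp < plusLow + width)
    if (length(inside)) {
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      ch[mp[inside] - plusLow + 1L] <- unname(mutLookup[inside])
      s <- paste(ch, collapse = "")
    }
  }
  if (strand == "-") s <- revComp(s)
  s
}

#' Does a mutation set force a split (A/B) anchored-primer design?
#'
#' True iff the farthest mutation distance from the junction exceeds
#' \code{maxLen - minUnmodified3prime} (20 at the defaults), i.e. the
#' mutation cannot sit in a 30-35 nt anchored primer while leaving 15
#' unmodified 3'-terminal bases.
#'
#' @param distances mutation distances from the junction (d = 1 adjacent).
#' @param maxLen maximal anchored primer length.
#' @param minUnmodified3prime protected 3' bases.
#' @return logical.
#' @export
needsSplit <- function(distances, maxLen = 35L, minUnmodified3prime = 15L) {
  if (length(distances) == 0L) return(FALSE)
  max(distances) > maxLen - minUnmodified3prime
}

#' Design the junction-anchored primer(s) for one side
#'
#' Single design: the anchored primer covers the 30-35 nt immediately
#' adjacent to the junction (upstream for the left side, downstream for the
#' right), points away from the junction, carries the side's silent
#' mutations, and is the shortest length satisfying the 15-unmodified-3'-
#' bases rule. Split design (triggered by [needsSplit()]): the inner B
#' primer is anchored at the junction and carries only mutations within its
#' allowance; the auxiliary A primer covers the remaining mutations plus 15
#' junction-distal bases and overlaps the B primer by 20 nt.
#'
#' @param side "left" or "right" (transcript orientation).
#' @param interbase insertion point.
#' @param plan mutation plan from [planSilentMutations()].
#' @param genome,chrom,strand locus context.
#' @param minLen,maxLen,minUnmod anchored-primer geometry.
#' @return list of primer records (name, seq, tm, length, side, split,
#'   mutatedOffsets: 1-based from the primer 5' end).
#' @export
anchoredPrimers <- function(side, interbase, plan, genome, chrom, strand,
                            minLen = 30L, maxLen = 35L, minUnmod = 15L) {
  dSide <- if (side == "left") "up" else "down"
  muts <- plan$mutations
  dOf <- function(pos) {
    if (dSide == "up") {
      if (strand == "+") interbase - pos else pos - interbase + 1L
    } else {
      if (strand == "+") pos - interbase + 1L else interbase - pos
    }
  }
  dAll <- if (nrow(muts)) vapply(muts$pos0, dOf, integer(1)) else integer(0)
  onSide <- which(dAll >= 1L)
  dSideMuts <- dAll[onSide]
  lookAll <- if (nrow(muts)) setNames(muts$alt, muts$pos0) else character(0)

  baseName <- if (side == "left") "P2" else "P3"
  mkPrimer <- function(name, dLo, dHi, look) {
    seq <- sliceByD(genome, chrom, strand, dSide, interbase, dLo, dHi, look)
    if (dSide == "up") seq <- revComp(seq)   # left primer points upstream
    # offsets (from the junction-proximal 5' end) of mutations actually
    # applied to this primer
    dApplied <- if (length(look))
      vapply(as.integer(names(look)), dOf, integer(1)) else integer(0)
    dm <- dApplied[dApplied >= dLo & dApplied <= dHi]
    list(name = name, seq = seq, tm = meltingTemperature(seq),
         length = nchar(seq), side = side,
         orientation = if (side == "left") "reverse" else "forward",
         dSpan = c(dLo, dHi),
         mutatedOffsets = sort(dm - dLo + 1L))
  }

  if (!needsSplit(dSideMuts, maxLen, minUnmod)) {
    L <- minLen
    if (length(dSideMuts))
      L <- max(minLen, min(maxLen, max(dSideMuts) + minUnmod))
    p <- mkPrimer(baseName, 1L, L, lookAll)
    p$split <- FALSE
    return(list(p))
  }
  # split design
  LB <- minLen
  allowance <- LB - minUnmod
  dmax <- max(dSideMuts)
  lookB <- lookAll[as.character(muts$pos0[onSide][dSideMuts <= allowance])]
  pB <- mkPrimer(paste0(baseName, "B"), 1L, LB, lookB)
  pB$split <- TRUE
  aLo <- LB - 19L                             # 20-nt overlap with B
  aHi <- dmax + minUnmod
  lookA <- lookAll[as.character(muts$pos0[onSide])]
  pA <- mkPrimer(paste0(baseName, "A"), aLo, aHi, lookA)
  pA$split <- TRUE
  list(pA, pB)
}

# --- outer and genotyping primers ------------------------------------------

#' Pick the outer primer (P1 or P4) for a homology arm
#'
#' Candidates of 18-27 nt are placed so the homology-arm amplicon falls in
#' [armMin, armMax] bp, filtered by GC in [30, 70] percent, scored by
#' |Tm - partner Tm| (must be within \code{tmTol}), tie-broken by amplicon
#' length closest to armMin then by leftmost start, and checked for
#' genome-wide uniqueness. On failure the allowable arm length grows in
#' 500-nt steps up to 10 kb; if still nothing qualifies the best-scoring
#' candidate is returned with a warning.
#'
#' @param side "left" or "right".
#' @param partnerTm melting temperature of the anchored partner primer.
#' @param interbase insertion point.
#' @param genome,chrom,strand locus context.
#' @param armMin,armMax initial amplicon-length window (bp).
#' @param lenRange primer length range.
#' @param tmTol maximal Tm mismatch to the partner (degrees C).
#' @param gcBounds GC bounds (percent).
#' @param expandStep,maxArm expansion schedule.
#' @param maxSpecificityChecks cap on genome-uniqueness lookups.
#' @return list(primer = record or NULL, armLength, warnings).
#' @export
pickOuterPrimer <- function(side, partnerTm, interbase, genome, chrom,
                            strand, armMin = 500L, armMax = 1000L,
                            lenRange = 18:27, tmTol = 3, gcBounds = c(30, 70),
                            expandStep = 500L, maxArm = 10000L,
                            maxSpecificityChecks = 25L) {
  dSide <- if (side == "left") "up" else "down"
  chromLen <- chromLengths(genome)[[chrom]]
  warnings <- character(0)

  evalRange <- function(loArm, hiArm) {
    cands <- list()
    # fetch the whole reachable region once, transcript sense
    reach <- hiArm
    while (reach > 0L) {
      p <- dToPlusPos(dSide, strand, interbase, reach)
      if (p >= 0L && p < chromLen) break
      reach <- reach - 1L
    }
    if (reach < loArm) return(cands)
    region <- sliceByD(genome, chrom, strand, dSide, interbase, 1L, reach)
    if (!nzchar(region)) return(cands)
    for (arm in seq.int(loArm, reach)) {
      for (l in lenRange) {
        if (arm - l + 1L < 1L) next
        # string index i corresponds to d = i ("down") or reach - i + 1 ("up")
        seq <- if (dSide == "up")
          substring(region, reach - arm + 1L, reach - arm + l)
        else revComp(substring(region, arm - l + 1L, arm))
        if (nchar(seq) != l || grepl("N", seq, fixed = TRUE)) next
        gc <- gcPercent(seq)
        if (gc < gcBounds[1L] || gc > gcBounds[2L]) next
        cands[[length(cands) + 1L]] <- list(seq = seq, arm = arm, len = l)
      }
    }
    cands
  }

  chooseFrom <- function(cands) {
    if (length(cands) == 0L) return(NULL)
    seqs <- vapply(cands, `[[`, "", "seq")
    tms <- meltingTemperature(seqs)
    score <- abs(tms - partnerTm)
    arms <- vapply(cands, `[[`, 0L, "arm")
    ok <- which(!is.na(score) & score <= tmTol)
    ordSet <- if (length(ok)) ok else order(score)[1L]
    ord <- ordSet[order(score[ordSet], arms[ordSet],
                        vapply(cands[ordSet], `[[`, 0L, "len"))]
    checked <- 0L
    bestFallback <- NULL
    for (i in ord) {
      rec <- list(seq = seqs[i], tm = tms[i], length = cands[[i]]$len,
                  armLength = arms[i], score = score[i])
      if (checked >= maxSpecificityChecks) break
      checked <- checked + 1L
      if (exactOccurrences(seqs[i], genome) == 1L) {
        rec$specific <- TRUE
        return(rec)
      }
      if (is.null(bestFallback)) bestFallback <- rec
    }
    if (!is.null(bestFallback)) {
      bestFallback$specific <- FALSE
      return(bestFallback)
    }
    NULL
  }

  res <- chooseFrom(evalRange(armMin, armMax))
  hi <- armMax
  while (is.null(res) && hi < maxArm) {
    lo <- hi + 1L
    hi <- min(maxArm, hi + expandStep)
    warnings <- union(warnings, "ARM_EXPANDED")
    res <- chooseFrom(evalRange(lo, hi))
  }
  if (is.null(res)) {
    return(list(primer = NULL, armLength = NA_integer_,
                warnings = union(warnings, "NO_VALID_OUTER_PRIMER")))
  }
  if (!isTRUE(res$specific)) warnings <- union(warnings, "NONSPECIFIC_PRIMER")
  if (res$score > tmTol) warnings <- union(warnings, "NO_VALID_OUTER_PRIMER")
  name <- if (side == "left") "P1" else "P4"
  primer <- list(name = name, seq = res$seq, tm = res$tm,
                 length = res$length, side = side,
                 orientation = if (side == "left") "forward" else "reverse",
                 specific = isTRUE(res$specific))
  list(primer = primer, armLength = res$armLength, warnings = warnings)
}

#' Check primer specificity by exact genome occurrence
#'
#' @param seq primer sequence.
#' @param genome a [GenomeAssembly-class].
#' @return TRUE iff the primer occurs exactly once (both strands counted).
#' @export
checkPrimerSpecificity <- function(seq, genome) {
  exactOccurrences(seq, genome) == 1L
}

#' Design genotyping primers flanking the edited region
#'
#' A forward primer within \code{margin} nt 5' of the left arm's outer end
#' and a reverse primer within \code{margin} nt 3' of the right arm's outer
#' end (plus-strand orientation), Tm-matched near \code{tmTarget} and
#' specificity-checked; the genotyping amplicon strictly contains both
#' homology arms, supporting a nested two-step PCR.
#'
#' @param regionStart0,regionEnd0 plus-strand 0-based half-open span of the
#'   edited region (union of both arms).
#' @param genome,chrom locus context.
#' @param margin search margin (nt).
#' @param lenRange candidate lengths.
#' @param tmTarget,tmTol pairing parameters.
#' @return list(forward, reverse, warnings); primers are records or NULL.
#' @export
designGenotypingPrimers <- function(regionStart0, regionEnd0, genome, chrom,
                                    margin = 500L, lenRange = 18:27,
                                    tmTarget = 60, tmTol = 3) {
  chromLen <- chromLengths(genome)[[chrom]]
  warnings <- character(0)

  collect <- function(lo, hi, reverse) {
    cands <- list()
    lo <- max(0L, lo); hi <- min(chromLen, hi)
    if (hi - lo < min(lenRange)) return(cands)
    region <- sliceSeq(genome, chrom, lo, hi)
    for (st in seq.int(lo, hi - min(lenRange))) {
      for (l in lenRange) {
        if (st + l > hi) next
        seq <- substring(region, st - lo + 1L, st - lo + l)
        if (grepl("N", seq, fixed = TRUE)) next
        if (reverse) seq <- revComp(seq)
        cands[[length(cands) + 1L]] <-
          list(seq = seq, start0 = st, end0 = st + l)
      }
    }
    cands
  }
  pick <- function(cands, targetTm) {
    if (length(cands) == 0L) return(NULL)
    seqs <- vapply(cands, `[[`, "", "seq")
    tms <- meltingTemperature(seqs)
    ord <- order(abs(tms - targetTm))
    checked <- 0L; fallback <- NULL
    for (i in ord) {
      if (is.na(tms[i])) next
      rec <- c(cands[[i]], list(tm = tms[i]))
      if (checked < 25L) {
        checked <- checked + 1L
        if (checkPrimerSpecificity(rec$seq, genome)) {
          rec$specific <- TRUE
          return(rec)
        }
        if (is.null(fallback)) fallback <- rec
      }
    }
    if (!is.null(fallback)) fallback$specific <- FALSE
    fallback
  }

  if (regionStart0 - margin < 0L || regionEnd0 + margin > chromLen)
    warnings <- union(warnings, "MARGIN_TRUNCATED")
  fwd <- pick(collect(regionStart0 - margin, regionStart0, FALSE), tmTarget)
  revTarget <- if (!is.null(fwd)) fwd$tm else tmTarget
  rev <- pick(collect(regionEnd0, regionEnd0 + margin, TRUE), revTarget)
  if (is.null(fwd) || is.null(rev))
    warnings <- union(warnings, "NO_GENOTYPING_PRIMER")
  if (!is.null(fwd) && !isTRUE(fwd$specific))
    warnings <- union(warnings, "NONSPECIFIC_PRIMER")
  if (!is.null(rev) && !isTRUE(rev$specific))
    warnings <- union(warnings, "NONSPECIFIC_PRIMER")
  if (!is.null(fwd)) fwd$name <- "GENO_F"
  if (!is.null(rev)) rev$name <- "GENO_R"
  list(forward = fwd, reverse = rev, warnings = warnings)
}

#' Design the full primer set for one insertion
#'
#' Orchestrates the silent-mutation plan, both anchored primers (split into
#' A/B pairs when needed), both outer primers, and the genotyping pair.
#'
#' @param genome a [GenomeAssembly-class].
#' @param transcript the [TranscriptModel-class].
#' @param spec insertion spec (list with chrom, interbase).
#' @param guide selected guide (one-row data.frame) or NULL to skip the
#'   mutation plan.
#' @param withOuter,withGenotyping stages to run (outer/genotyping searches
#'   dominate run time).
#' @return list(plan, left, right, outerLeft, outerRight, genotyping,
#'   armLengths, warnings).
#' @export
designPrimerSet <- function(genome, transcript, spec, guide,
                            withOuter = TRUE, withGenotyping = TRUE) {
  chrom <- spec$chrom
  strand <- transcript@strand
  plan <- if (!is.null(guide))
    planSilentMutations(guide, transcript, genome)
  else list(mutations = data.frame(pos0 = integer(0), ref = character(0),
                                   alt = character(0)),
            count = 0L, pamDisrupted = FALSE, warnings = character(0))
  left <- anchoredPrimers("left", spec$interbase, plan, genome, chrom, strand)
  right <- anchoredPrimers("right", spec$interbase, plan, genome, chrom,
                           strand)
  warnings <- plan$warnings
  outerLeft <- outerRight <- NULL
  armLengths <- c(left = NA_integer_, right = NA_integer_)
  if (withOuter) {
    innerTmL <- left[[length(left)]]$tm       # B (or single) primer
    innerTmR <- right[[length(right)]]$tm
    outerLeft <- pickOuterPrimer("left", innerTmL, spec$interbase, genome,
                                 chrom, strand)
    outerRight <- pickOuterPrimer("right", innerTmR, spec$interbase, genome,
                                  chrom, strand)
    warnings <- union(warnings, c(outerLeft$warnings, outerRight$warnings))
    armLengths <- c(left = outerLeft$armLength, right = outerRight$armLength)
  }
  genotyping <- NULL
  if (withGenotyping && withOuter &&
      !is.null(outerLeft$primer) && !is.null(outerRight$primer)) {
    upArm <- armLengths[[if (strand == "+") "left" else "right"]]
    dnArm <- armLengths[[if (strand == "+") "right" else "left"]]
    regionStart0 <- spec$interbase - upArm
    regionEnd0 <- spec$interbase + dnArm
    genotyping <- designGenotypingPrimers(regionStart0, regionEnd0, genome,
                                          chrom)
    warnings <- union(warnings, genotyping$warnings)
  }
  list(plan = plan, left = left, right = right,
       outerLeft = outerLeft, outerRight = outerRight,
       genotyping = genotyping, armLengths = armLengths,
       warnings = warnings)
}
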