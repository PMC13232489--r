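# Independent oracles used by the tests. These deliberately avoid the
# package's scanning/counting code paths: plain R loops and string ops.

oracleRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

# brute-force guide enumeration: every 23-mer placement on both strands
bruteForceGuides <- function(windowSeq, offset0 = 0L) {
  n <- nchar(windowSeq)
  out <- list()
  if (n >= 23L) {
    for (i in seq_len(n - 22L)) {
      s23 <- substr(windowSeq, i, i + 22L)
      if (substr(s23, 22L, 23L) == "GG") {
        out[[length(out) + 1L]] <- data.frame(
          proto = substr(s23, 1L, 20L), pam = substr(s23, 21L, 23L),
          strand = "+", protoStart0 = offset0 + i - 1L)
      }
      if (substr(s23, 1L, 2L) == "CC") {
        out[[length(out) + 1L]] <- data.frame(
          proto = oracleRevComp(substr(s23, 4L, 23L)),
          pam = oracleRevComp(substr(s23, 1L, 3L)),
          strand = "-", protoStart0 = offset0 + i + 2L)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(proto = character(0), pam = character(0),
                      strand = character(0), protoStart0 = integer(0)))
  do.call(rbind, out)
}

oracleHamming <- function(a, b) {
  x <- strsplit(a, "")[[1L]]; y <- strsplit(b, "")[[1L]]
  sum(x != y | x == "N")
}

# naive position-by-position NGG site scan over plain character
# chromosomes: every 23-mer placement on both strands, N-containing sites
# dropped (matches the stated index contract)
oracleSiteTable <- function(chromList) {
  out <- list()
  for (chrom in names(chromList)) {
    s <- chromList[[chrom]]
    n <- nchar(s)
    if (n < 23L) next
    i <- seq_len(n - 22L)
    s23 <- substring(s, i, i + 22L)
    clean <- !grepl("N", s23, fixed = TRUE)
    plus <- clean & substring(s23, 22L, 23L) == "GG"
    minus <- clean & substring(s23, 1L, 2L) == "CC"
    if (any(plus))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, strand = "+", start0 = i[plus] - 1L,
        site = substring(s23[plus], 1L, 20L))
    if (any(minus))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, strand = "-", start0 = i[minus] + 2L,
        site = vapply(substring(s23[minus], 4L, 23L), oracleRevComp, "",
                      USE.NAMES = FALSE))
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), strand = character(0),
                      start0 = integer(0), site = character(0)))
  do.call(rbind, out)
}

# Hamming distance of proto to every oracle site (column-matrix compare)
oracleSiteDistances <- function(proto, siteTable) {
  if (nrow(siteTable) == 0L) return(integer(0))
  q <- strsplit(proto, "")[[1L]]
  m <- matrix(unlist(strsplit(siteTable$site, ""), use.names = FALSE),
              nrow = 20L)
  colSums(m != q | q == "N")
}

naiveOfftargetCount <- function(proto, chromList, maxMM, onTarget = NULL,
                                siteTable = NULL) {
  if (is.null(siteTable)) siteTable <- oracleSiteTable(chromList)
  d <- oracleSiteDistances(proto, siteTable)
  keep <- d <= maxMM
  if (!is.null(onTarget)) {
    self <- siteTable$chrom == onTarget$chrom &
      siteTable$strand == onTarget$strand &
      siteTable$start0 == onTarget$start0
    keep <- keep & !self
  }
  sum(keep)
}

# exhaustive two-sided Fisher p over all tables with the observed margins,
# using choose() directly
enumFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  N <- r1 + r2
  xs <- max(0L, c1 - r2):min(c1, r1)
  prob <- vapply(xs, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1)), numeric(1))
  pObs <- prob[match(a, xs)]
  sum(prob[prob <= pObs * (1 + 1e-7)])
}

# standard genetic code as a plain named vector for independent translation
oracleTranslate <- function(dna) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(dna) %/% 3L
  paste(vapply(seq_len(n), function(i)
    unname(code[substr(dna, 3L * i - 2L, 3L * i)]), character(1)),
    collapse = "")
}

randomWindow <- function(n = 200L) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
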