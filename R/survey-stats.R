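# Tagged-allele inventory curation and survey statistics: deduplication and
# source merging, summary distributions, linear and exponential-saturation
# accrual models, and category enrichment with capped log2 odds ratios.

#' Read a tagged-allele inventory TSV
#'
#' Columns: gene_id, gene_name, allele, tags (semicolon-separated),
#' positions (semicolon-separated, drawn from N/C/internal), source
#' ("literature" or "CGC"), year, reference.
#'
#' @param path TSV path.
#' @return data.frame with list-columns tags and positions.
#' @export
readInventory <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  df$tags <- strsplit(df$tags, ";", fixed = TRUE)
  df$positions <- strsplit(df$positions, ";", fixed = TRUE)
  df$year <- suppressWarnings(as.integer(df$year))
  df
}

alleleKey <- function(records) {
  paste(records$gene_id,
        vapply(records$tags, function(t) paste(sort(t), collapse = ";"), ""),
        vapply(records$positions, function(p) paste(sort(p), collapse = ";"),
               ""),
        sep = "|")
}

#' Deduplicate functionally identical alleles
#'
#' Records sharing (gene, tag set, position set) are collapsed to one
#' representative: the earliest publication year wins; ties break on the
#' lexicographically smallest allele designation (missing designations
#' last), then on row order, so the result is deterministic.
#'
#' @param records inventory data.frame (see [readInventory()]).
#' @return deduplicated data.frame.
#' @export
dedupAlleles <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- alleleKey(records)
  yr <- records$year
  yr[is.na(yr)] <- .Machine$integer.max
  desig <- records$allele
  missingDesig <- is.na(desig) | desig == ""
  ord <- order(key, yr, missingDesig, desig, seq_len(nrow(records)))
  keep <- ord[!duplicated(key[ord])]
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge literature and CGC inventories
#'
#' Alleles are matched by allele designation where present, falling back to
#' the (gene, tags, positions) key. Each allele and each gene is classified
#' as literature_only, cgc_only or both. When one designation maps to
#' conflicting genes the literature assignment wins (with a warning).
#'
#' @param literature,cgc inventory data.frames.
#' @return list(records, alleleOverlap, geneOverlap); overlaps are named
#'   counts (literature_only, cgc_only, both).
#' @export
mergeSources <- function(literature, cgc) {
  lit <- literature; lit$source <- "literature"
  cg <- cgc; if (nrow(cg)) cg$source <- "CGC"
  idOf <- function(df) {
    d <- df$allele
    fb <- alleleKey(df)
    ifelse(is.na(d) | d == "", paste0("key:", fb), paste0("desig:", d))
  }
  litId <- idOf(lit); cgId <- if (nrow(cg)) idOf(cg) else character(0)
  conflict <- intersect(litId, cgId)
  if (length(conflict)) {
    litGene <- setNames(lit$gene_id, litId)
    bad <- conflict[cg$gene_id[match(conflict, cgId)] !=
                      litGene[conflict]]
    if (length(bad))
      warning(length(bad), " designation(s) with conflicting gene ",
              "assignments; literature wins")
  }
  both <- intersect(litId, cgId)
  records <- rbind(lit, if (nrow(cg)) cg[!cgId %in% both, , drop = FALSE])
  records$source_class <- "literature_only"
  records$source_class[idOf(records) %in% both] <- "both"
  records$source_class[records$source == "CGC"] <- "cgc_only"
  alleleOverlap <- c(literature_only = sum(!litId %in% both),
                     cgc_only = sum(!cgId %in% both),
                     both = length(both))
  litGenes <- unique(lit$gene_id)
  cgGenes <- unique(cg$gene_id)
  geneOverlap <- c(literature_only = length(setdiff(litGenes, cgGenes)),
                   cgc_only = length(setdiff(cgGenes, litGenes)),
                   both = length(intersect(litGenes, cgGenes)))
  list(records = records, alleleOverlap = alleleOverlap,
       geneOverlap = geneOverlap)
}

#' Summary distributions of a deduplicated inventory
#'
#' Percentages (one decimal, half away from zero) of genes by distinct
#' allele count (1/2/3/4+), of alleles by tag, and of alleles by insertion
#' position (N/C/internal; alleles tagged at more than one position count
#' once under "multiple").
#'
#' @param records deduplicated inventory.
#' @return list(allelesPerGene, tagTypes, positions) of named percentage
#'   vectors (empty inventory gives empty vectors).
#' @export
summarizeInventory <- function(records) {
  if (nrow(records) == 0L)
    return(list(allelesPerGene = numeric(0), tagTypes = numeric(0),
                positions = numeric(0)))
  perGene <- table(records$gene_id)
  bucket <- cut(as.integer(perGene), c(0, 1, 2, 3, Inf),
                labels = c("1", "2", "3", "4+"))
  apgTab <- table(bucket)
  apg <- setNames(100 * as.numeric(apgTab) / length(perGene),
                  names(apgTab))

  tagTab <- table(unlist(lapply(records$tags, unique)))
  tags <- setNames(100 * as.numeric(tagTab) / nrow(records), names(tagTab))

  posClass <- vapply(records$positions, function(p) {
    u <- unique(p)
    if (length(u) > 1L) "multiple" else u
  }, character(1))
  posClass <- factor(posClass, levels = c("N", "C", "internal", "multiple"))
  posTab <- table(posClass)
  pos <- setNames(100 * as.numeric(posTab) / nrow(records), names(posTab))

  list(allelesPerGene = roundHalfAway(apg, 1),
       tagTypes = roundHalfAway(sort(tags, decreasing = TRUE), 1),
       positions = roundHalfAway(pos, 1))
}

#' Proportion of tagged genes in a category, printed style
#'
#' \code{round(100 t / n, 1)} with halves away from zero.
#'
#' @param t tagged genes in the category.
#' @param n category size (> 0).
#' @return percentage with one decimal.
#' @export
categoryProportion <- function(t, n) {
  stopIfNot(all(n > 0), "category size must be positive")
  stopIfNot(all(t >= 0 & t <= n), "need 0 <= t <= n")
  roundHalfAway(100 * t / n, 1)
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Sums hypergeometric probabilities no larger than the observed table's
#' (with the customary (1 + 1e-7) tolerance against floating-point ties).
#'
#' @param a,b,c,d cell counts, table [[a, b], [c, d]].
#' @return p value.
#' @export
fisherExactP <- function(a, b, c, d) {
  stopIfNot(all(c(a, b, c, d) >= 0), "negative cell")
  m <- a + b          # row 1 total
  n2 <- c + d
  k <- a + c          # column 1 total
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  p <- stats::dhyper(x, m, n2, k)
  pObs <- stats::dhyper(a, m, n2, k)
  min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted q values
#'
#' Step-up FDR adjustment, original order restored.
#'
#' @param p vector of p values in [0, 1].
#' @return q values.
#' @export
benjaminiHochberg <- function(p) {
  stopIfNot(all(p >= 0 & p <= 1, na.rm = TRUE), "p values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Category enrichment with capped log2 odds ratios
#'
#' For each category with t tagged genes of n, against a background of T
#' tagged among N, the 2x2 table [[t, n-t], [T-t, (N-n)-(T-t)]] yields an
#' odds ratio (log2-transformed; +/-7 substituted for infinite values and
#' used as a symmetric cap), a two-sided Fisher exact p, and a BH q with a
#' significance flag at FDR \code{alpha}.
#'
#' @param categories data.frame with columns term_id, term_name, t, n.
#' @param T background tagged genes.
#' @param N background size.
#' @param alpha FDR threshold for the significance flag.
#' @param cap cap for |log2 OR|.
#' @return data.frame of per-category enrichment statistics.
#' @export
enrichmentTable <- function(categories, T, N, alpha = 0.05, cap = 7) {
  t <- categories$t; n <- categories$n
  stopIfNot(all(t >= 0 & t <= n & n <= N & t <= T), "inconsistent counts")
  a <- t; b <- n - t; c <- T - t; d <- (N - n) - (T - t)
  stopIfNot(all(d >= 0), "background smaller than category union")
  or <- (a * d) / (b * c)
  log2or <- log2(or)
  capped <- pmin(cap, pmax(-cap, log2or))
  capped[is.nan(log2or)] <- 0        # 0/0: no information
  p <- vapply(seq_along(a), function(i)
    fisherExactP(a[i], b[i], c[i], d[i]), numeric(1))
  q <- benjaminiHochberg(p)
  data.frame(term_id = categories$term_id,
             term_name = if (!is.null(categories$term_name))
               categories$term_name else categories$term_id,
             tagged = t, size = n,
             background_tagged = T, background_size = N,
             proportion = categoryProportion(t, n),
             odds_ratio = or, log2_or_capped = capped,
             p_value = p, q_value = q,
             significant = q < alpha)
}

#' Enrichment from an inventory and a category annotation table
#'
#' @param taggedGenes character vector of tagged gene ids.
#' @param categories data.frame with columns term_id, term_name, gene_id
#'   (one row per term-gene association).
#' @param background character vector of background gene ids (categories are
#'   intersected with it).
#' @param ... passed to [enrichmentTable()].
#' @return enrichment data.frame.
#' @export
enrichFromInventory <- function(taggedGenes, categories, background, ...) {
  background <- unique(background)
  taggedGenes <- intersect(unique(taggedGenes), background)
  categories <- categories[categories$gene_id %in% background, , drop = FALSE]
  split_ <- split(categories$gene_id, categories$term_id)
  nm <- if (!is.null(categories$term_name))
    tapply(categories$term_name, categories$term_id, `[`, 1L)[names(split_)]
  else names(split_)
  counts <- data.frame(
    term_id = names(split_), term_name = as.character(nm),
    t = vapply(split_, function(g) length(intersect(unique(g), taggedGenes)),
               integer(1)),
    n = vapply(split_, function(g) length(unique(g)), integer(1)))
  counts <- counts[counts$n > 0, , drop = FALSE]
  enrichmentTable(counts, T = length(taggedGenes), N = length(background),
                  ...)
}

#' Cumulative accrual of unique tagged genes by year
#'
#' Each gene counts once, in its earliest year.
#'
#' @param records inventory with gene_id and year.
#' @return data.frame(year, new_genes, cumulative).
#' @export
cumulativeAccrual <- function(records) {
  recs <- records[!is.na(records$year), , drop = FALSE]
  firstYear <- tapply(recs$year, recs$gene_id, min)
  tab <- table(firstYear)
  years <- as.integer(names(tab))
  full <- seq.int(min(years), max(recs$year))
  newGenes <- as.integer(tab[match(full, years)])
  newGenes[is.na(newGenes)] <- 0L
  data.frame(year = full, new_genes = newGenes,
             cumulative = cumsum(newGenes))
}

#' Ordinary least-squares fit of cumulative accrual vs year
#'
#' @param accrual data.frame from [cumulativeAccrual()].
#' @param yearMin,yearMax inclusive fit range.
#' @return list(slope, intercept, r_squared, n).
#' @export
linearAccrualFit <- function(accrual, yearMin = -Inf, yearMax = Inf) {
  d <- accrual[accrual$year >= yearMin & accrual$year <= yearMax, ,
               drop = FALSE]
  stopIfNot(length(unique(d$year)) >= 2L, "need at least 2 distinct years")
  fit <- lm(cumulative ~ year, data = d)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = summary(fit)$r.squared, n = nrow(d))
}

#' Exponential-saturation discovery curve fit
#'
#' Least-squares fit of \eqn{G(n) = G_{max} (1 - e^{-n/\tau})} to cumulative
#' newly discovered genes versus papers examined. The returned object's
#' \code{papersForFraction(f)} gives \eqn{-\tau \log(1 - f)}, the number of
#' papers needed to reach a fraction f of \eqn{G_{max}}.
#'
#' @param papers,cumulative numeric vectors of equal length.
#' @return list(gMax, tau, r_squared, papersForFraction, converged).
#' @export
discoveryCurveFit <- function(papers, cumulative) {
  stopIfNot(length(papers) == length(cumulative) && length(papers) >= 3L,
            "need at least 3 points")
  d <- data.frame(n = papers, G = cumulative)
  gMax0 <- max(d$G) * 1.05
  tau0 <- {
    target <- 0.632 * max(d$G)
    d$n[which.min(abs(d$G - target))]
  }
  fit <- try(minpack.lm::nlsLM(G ~ gmax * (1 - exp(-n / tau)), data = d,
                               start = list(gmax = gMax0, tau = max(tau0, 1)),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(gMax = NA_real_, tau = NA_real_, r_squared = NA_real_,
                papersForFraction = function(f) NA_real_, converged = FALSE))
  cf <- coef(fit)
  resid <- d$G - predict(fit)
  r2 <- 1 - sum(resid^2) / sum((d$G - mean(d$G))^2)
  tau <- unname(cf[["tau"]])
  list(gMax = unname(cf[["gmax"]]), tau = tau, r_squared = r2,
       papersForFraction = function(f) -tau * log(1 - f),
       converged = TRUE)
}
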