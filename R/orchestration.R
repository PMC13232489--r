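# Pipeline orchestration: configuration handling, the per-gene design run,
# the survey/enrichment run, and report writers. These functions are the
# programmatic interface; inst/cli/celtag.R wraps them for shell use.

#' Read a flat key=value configuration file
#'
#' Lines of the form key=value; blank lines and #-comments ignored.
#' \code{overrides} (a named list) take precedence.
#'
#' @param path config file path, or NULL for overrides only.
#' @param overrides named list of values overriding the file.
#' @return named list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    stopIfNot(file.exists(path), paste("no such config file:", path))
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      stopIfNot(length(kv) >= 2L, paste("malformed config line:", ln))
      cfg[[trimws(kv[1L])]] <- trimws(paste(kv[-1L], collapse = "="))
    }
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg
}

designHeader <- function(seed = NA) {
  c(paste0("# celtag ", as.character(utils::packageVersion("celtag"))),
    paste0("# seed: ", seed))
}

#' Run the knock-in design pipeline over a gene set
#'
#' For every requested gene, infers the N- and C-terminal insertion specs,
#' designs and selects guides in the +/-50 bp windows, and (optionally)
#' designs the primer sets. Per-gene failures are recorded and the run
#' continues; genes with no acceptable guide are reported with
#' \code{no_guide} set rather than dropped.
#'
#' @param genome a [GenomeAssembly-class].
#' @param transcripts named list of [TranscriptModel-class].
#' @param features named list of [ProteinFeatureSet-class].
#' @param genes gene ids to design (default: all with both a transcript and
#'   features).
#' @param params [designParameters()].
#' @param index optional prebuilt [PamSiteIndex-class] (built when NULL).
#' @param withPrimers design primer sets for selected guides.
#' @param withOuter,withGenotyping primer stages (see [designPrimerSet()]).
#' @return list(designTable, primerTable, errors); designTable has one row
#'   per gene per terminus.
#' @export
runDesign <- function(genome, transcripts, features, genes = NULL,
                      params = designParameters(), index = NULL,
                      withPrimers = FALSE, withOuter = TRUE,
                      withGenotyping = TRUE) {
  if (is.null(genes))
    genes <- intersect(names(transcripts), names(features))
  if (is.null(index)) index <- buildPamIndex(genome)
  rows <- list()
  primerRows <- list()
  errors <- character(0)
  for (g in genes) {
    tr <- transcripts[[g]]
    ft <- features[[g]]
    if (is.null(tr) || is.null(ft)) {
      errors <- c(errors, paste0(g, ": missing transcript or features"))
      next
    }
    specs <- tryCatch(makeInsertionSpecs(tr, ft, genome),
                      error = function(e) e)
    if (inherits(specs, "error")) {
      errors <- c(errors, paste0(g, ": ", conditionMessage(specs)))
      next
    }
    for (term in c("N", "C")) {
      sp <- specs[[term]]
      des <- designGuides(genome, sp, index, params)
      sel <- des$selection
      best <- sel$inVivoBest
      extra <- sel$inVitroExtra
      fmtGuide <- function(gd) {
        if (is.null(gd)) return(list(seq = "", pam = "", strand = "",
                                     start1 = NA_integer_,
                                     cut = NA_integer_, gc = NA_real_,
                                     ot = NA_integer_, dist = NA_integer_))
        list(seq = gd$proto, pam = gd$pam, strand = gd$strand,
             start1 = gd$protoStart0 + 1L, cut = gd$cutInterbase,
             gc = gd$gc, ot = gd$offtargetCount, dist = gd$distance)
      }
      fb <- fmtGuide(best); fe <- fmtGuide(extra)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, terminus = term, chrom = sp$chrom, strand = sp$strand,
        boundary_residue = sp$boundaryResidue,
        insertion_interbase = sp$interbase,
        insertion_coord = sp$paperCoord,
        flags = paste(sp$flags, collapse = ","),
        window_truncated = des$window$truncated,
        no_guide = sel$noGuide,
        guide_seq = fb$seq, guide_pam = fb$pam, guide_strand = fb$strand,
        guide_start = fb$start1, guide_cut_interbase = fb$cut,
        guide_gc = fb$gc, guide_offtargets = fb$ot,
        guide_distance = fb$dist,
        vitro_guide_seq = fe$seq, vitro_guide_distance = fe$dist)
      if (withPrimers && !is.null(best)) {
        ps <- tryCatch(
          designPrimerSet(genome, tr, sp, best, withOuter = withOuter,
                          withGenotyping = withGenotyping),
          error = function(e) e)
        if (inherits(ps, "error")) {
          errors <- c(errors, paste0(g, "/", term, ": ",
                                     conditionMessage(ps)))
        } else {
          primerRows[[length(primerRows) + 1L]] <-
            primerSetToTable(g, term, ps)
        }
      }
    }
  }
  designTable <- if (length(rows)) do.call(rbind, rows) else NULL
  primerTable <- if (length(primerRows)) do.call(rbind, primerRows) else NULL
  list(designTable = designTable, primerTable = primerTable,
       errors = errors)
}

# flatten a designPrimerSet() result to one row per primer
primerSetToTable <- function(gene, terminus, ps) {
  recs <- c(ps$left, ps$right,
            if (!is.null(ps$outerLeft$primer)) list(ps$outerLeft$primer),
            if (!is.null(ps$outerRight$primer)) list(ps$outerRight$primer),
            if (!is.null(ps$genotyping$forward)) list(ps$genotyping$forward),
            if (!is.null(ps$genotyping$reverse)) list(ps$genotyping$reverse))
  do.call(rbind, lapply(recs, function(p) data.frame(
    gene_id = gene, terminus = terminus, primer = p$name,
    sequence = p$seq, tm = round(p$tm, 2), length = nchar(p$seq),
    mutated_offsets = paste(p$mutatedOffsets, collapse = ";"),
    n_mutations = ps$plan$count,
    pam_disrupted = ps$plan$pamDisrupted,
    warnings = paste(ps$warnings, collapse = ","))))
}

#' Write the design and primer tables
#'
#' TSVs carry a header comment with the package version and seed for
#' provenance.
#'
#' @param result list from [runDesign()].
#' @param dir output directory.
#' @param seed seed recorded in the header.
#' @return invisibly, the output paths.
#' @export
writeDesignReport <- function(result, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dPath <- file.path(dir, "designs.tsv")
  con <- file(dPath, "w")
  writeLines(designHeader(seed), con)
  suppressWarnings(write.table(result$designTable, con, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  close(con)
  paths <- dPath
  if (!is.null(result$primerTable)) {
    pPath <- file.path(dir, "primers.tsv")
    con <- file(pPath, "w")
    writeLines(designHeader(seed), con)
    suppressWarnings(write.table(result$primerTable, con, sep = "\t",
                                 quote = FALSE, row.names = FALSE))
    close(con)
    paths <- c(paths, pPath)
  }
  bed <- result$designTable
  if (!is.null(bed)) {
    bedPath <- file.path(dir, "insertions.bed")
    writeBED6(data.frame(chrom = bed$chrom, start0 = bed$insertion_interbase,
                         end0 = bed$insertion_interbase,
                         name = paste0(bed$gene_id, "_", bed$terminus),
                         score = 0L, strand = bed$strand), bedPath)
    paths <- c(paths, bedPath)
  }
  invisible(paths)
}

#' Run the tagged-allele survey
#'
#' Deduplicates the inventory, computes the summary distributions and the
#' accrual fit, and (when categories are given) the enrichment table.
#'
#' @param inventory inventory data.frame (see [readInventory()]).
#' @param categories optional category annotations (term_id, term_name,
#'   gene_id).
#' @param background optional background gene universe; defaults to all
#'   genes in \code{categories}.
#' @param linearFrom first year of the linear accrual fit.
#' @return list(records, summary, accrual, linearFit, enrichment).
#' @export
runSurvey <- function(inventory, categories = NULL, background = NULL,
                      linearFrom = 2020L) {
  records <- dedupAlleles(inventory)
  summary <- summarizeInventory(records)
  accrual <- cumulativeAccrual(records)
  linearFit <- tryCatch(linearAccrualFit(accrual, yearMin = linearFrom),
                        error = function(e) NULL)
  enrichment <- NULL
  if (!is.null(categories)) {
    if (is.null(background)) background <- unique(categories$gene_id)
    enrichment <- enrichFromInventory(unique(records$gene_id), categories,
                                      background)
  }
  list(records = records, summary = summary, accrual = accrual,
       linearFit = linearFit, enrichment = enrichment)
}

#' Write survey outputs
#'
#' @param survey list from [runSurvey()].
#' @param dir output directory.
#' @param seed seed recorded in headers.
#' @return invisibly, the output paths.
#' @export
writeSurveyReport <- function(survey, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  sPath <- file.path(dir, "summary.tsv")
  s <- survey$summary
  df <- rbind(
    data.frame(metric = "alleles_per_gene",
               key = names(s$allelesPerGene),
               percent = as.numeric(s$allelesPerGene)),
    data.frame(metric = "tag_type", key = names(s$tagTypes),
               percent = as.numeric(s$tagTypes)),
    data.frame(metric = "tag_position", key = names(s$positions),
               percent = as.numeric(s$positions)))
  con <- file(sPath, "w")
  writeLines(designHeader(seed), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  paths <- c(paths, sPath)
  aPath <- file.path(dir, "accrual.tsv")
  write.table(survey$accrual, aPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, aPath)
  if (!is.null(survey$enrichment)) {
    ePath <- file.path(dir, "enrichment.tsv")
    write.table(survey$enrichment, ePath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, ePath)
  }
  invisible(paths)
}

#' Generate fixture files (simulate subcommand)
#'
#' @param seed RNG seed.
#' @param dir output directory.
#' @param nGenes genes in the genome fixture.
#' @param withInventory also write an inventory fixture.
#' @param ... passed to [fixtureManifest()].
#' @return list of fixture results.
#' @export
runSimulate <- function(seed, dir, nGenes = 20L, withInventory = TRUE, ...) {
  gfx <- makeGenomeFixture(fixtureManifest(seed = seed, nGenes = nGenes,
                                           ...), dir)
  inv <- if (withInventory) makeInventoryFixture(seed = seed, dir = dir)
         else NULL
  list(genome = gfx, inventory = inv)
}
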