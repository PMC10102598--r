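# Essential-gene calling from transposon insertion statistics. Two
# median-scaled metrics per gene -- central insertion density (dens) and
# GC-corrected central reads per kb (normreads) -- with essentiality called
# when both fall below 0.2 and the gene's mutants are absent from Time0.

#' Per-gene transposon insertion statistics
#'
#' For every gene with at least 100 non-repetitive nucleotides
#' ("analyzable"; insertions in repeats cannot be mapped unambiguously):
#' the number of distinct central insertion positions (10--90\% of gene
#' length, deduplicated ignoring strand), total Tn-seq reads at those
#' positions, \code{dens} (central positions per non-repetitive nt, scaled
#' so the median over analyzable genes is 1) and \code{normreads} (central
#' reads per non-repetitive kb, corrected for GC content by dividing by the
#' median of the gene's 0.05-wide GC bin, then scaled so the median is 1).
#'
#' @param pool an \linkS4class{InsertionPool} (gene assignments are
#'   recomputed from the genome).
#' @param genome a \linkS4class{GenomeModel}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame with one row per gene: \code{gene_id},
#'   \code{analyzable}, \code{n_central_positions}, \code{central_reads},
#'   \code{dens}, \code{normreads} (\code{NA} for non-analyzable genes).
#' @export
computeInsertionStats <- function(pool, genome, config = analysisConfig()) {
  stopifnot(is(pool, "InsertionPool"), is(genome, "GenomeModel"))
  pool <- mapStrainsToGenes(pool, genome)
  s <- pool@strains
  g <- genome@genes
  central <- !is.na(s$gene_id) & s$gene_fraction >= 0.1 &
    s$gene_fraction <= 0.9
  sc <- s[central, , drop = FALSE]
  # distinct positions ignoring strand; reads summed over all central strains
  key <- paste(sc$replicon, sc$pos)
  posPerGene <- tapply(key, sc$gene_id, function(k) length(unique(k)))
  readsPerGene <- tapply(sc$n_reads, sc$gene_id, sum)
  nCentral <- as.integer(posPerGene[g$gene_id])
  nCentral[is.na(nCentral)] <- 0L
  cReads <- as.numeric(readsPerGene[g$gene_id])
  cReads[is.na(cReads)] <- 0
  analyzable <- g$nonrepetitive_nt >= config@minNonrepetitiveNt
  rawDens <- ifelse(analyzable, nCentral / g$nonrepetitive_nt, NA_real_)
  rawRpk <- ifelse(analyzable, cReads / (g$nonrepetitive_nt / 1000),
                   NA_real_)
  medDens <- median(rawDens[analyzable])
  if (!any(analyzable) || is.na(medDens) || medDens == 0)
    stop("degenerate library: median insertion density over analyzable ",
         "genes is zero")
  dens <- rawDens / medDens
  # GC correction: bins of width 0.05; bins with < 10 analyzable genes fall
  # back to the global median
  bin <- findInterval(g$gc, seq(0, 1, by = 0.05), rightmost.closed = TRUE)
  globalMed <- median(rawRpk[analyzable])
  if (globalMed == 0)
    stop("degenerate library: median central reads per kb is zero")
  corrected <- rep(NA_real_, nrow(g))
  for (b in unique(bin[analyzable])) {
    sel <- analyzable & bin == b
    div <- if (sum(sel) >= 10) median(rawRpk[sel]) else globalMed
    if (div == 0) div <- globalMed
    corrected[sel] <- rawRpk[sel] / div
  }
  medCorr <- median(corrected[analyzable])
  if (medCorr == 0)
    stop("degenerate library: median GC-corrected reads per kb is zero")
  normreads <- corrected / medCorr
  data.frame(gene_id = g$gene_id, analyzable = analyzable,
             n_central_positions = nCentral, central_reads = cReads,
             dens = dens, normreads = normreads, stringsAsFactors = FALSE)
}

#' Call genes essential, nearly essential or dispensable
#'
#' A gene is called \code{essential} when both its normalized central
#' insertion density (\code{dens}) and its GC-corrected normalized reads
#' per kb (\code{normreads}) are below the threshold (default 0.2) and its
#' mutants lacked sufficient Time0 abundance for fitness estimation.
#' \code{nearly_essential}: exactly one of the two metrics is below
#' threshold, or both are but the gene nevertheless has fitness data.
#' Analyzable genes meeting neither pattern are \code{dispensable}; genes
#' with under 100 non-repetitive nt are \code{not_analyzable}.
#'
#' @param stats output of \code{\link{computeInsertionStats}}.
#' @param fitnessAvailability named logical vector, gene_id -> has fitness
#'   data (see \code{\link{fitnessAvailability}}); genes absent from the
#'   vector are treated as lacking fitness.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return \code{stats} with columns \code{has_fitness} and \code{call}
#'   appended.
#' @export
callEssentiality <- function(stats, fitnessAvailability = logical(),
                             config = analysisConfig()) {
  need <- c("gene_id", "analyzable", "dens", "normreads")
  stopifnot(all(need %in% names(stats)))
  if (any(stats$analyzable & (is.na(stats$dens) | is.na(stats$normreads))))
    stop("analyzable gene with missing dens/normreads; ",
         "compute insertion stats first")
  hasFit <- rep(FALSE, nrow(stats))
  known <- stats$gene_id %in% names(fitnessAvailability)
  hasFit[known] <- fitnessAvailability[stats$gene_id[known]]
  th <- config@essThreshold
  lowD <- stats$dens < th
  lowN <- stats$normreads < th
  call <- rep("dispensable", nrow(stats))
  call[stats$analyzable & lowD & lowN & !hasFit] <- "essential"
  call[stats$analyzable & (xor(lowD, lowN) | (lowD & lowN & hasFit))] <-
    "nearly_essential"
  call[!stats$analyzable] <- "not_analyzable"
  stats$has_fitness <- hasFit
  stats$call <- call
  stats
}

#' Dispensability from per-position insertion evidence
#'
#' The direct criterion used with conventional Tn-seq data: a gene is
#' considered dispensable for viability when it carries at least 10
#' distinct central insertion positions (10--90\% of gene length) and at
#' least 100 total reads at those positions, ignoring positions supported
#' by only a single read.
#'
#' @param positionReads data.frame with columns \code{position},
#'   \code{reads}; duplicate positions are aggregated by summing reads.
#' @param gene a single-row gene record with \code{begin} and \code{end}.
#' @param minPositions,minReads,minReadsPerPosition rule parameters.
#' @return logical flag.
#' @export
dispensableFromPositions <- function(positionReads, gene,
                                     minPositions = 10, minReads = 100,
                                     minReadsPerPosition = 2) {
  if (is.null(positionReads) || nrow(positionReads) == 0) return(FALSE)
  stopifnot(all(c("position", "reads") %in% names(positionReads)))
  len <- gene$end - gene$begin + 1
  if (any(positionReads$position < gene$begin |
          positionReads$position > gene$end))
    stop("position outside the gene")
  agg <- tapply(positionReads$reads, positionReads$position, sum)
  pos <- as.numeric(names(agg))
  frac <- (pos - gene$begin + 1) / len
  qual <- frac >= 0.1 & frac <= 0.9 & agg >= minReadsPerPosition
  sum(qual) >= minPositions && sum(agg[qual]) >= minReads
}

#' Write essentiality calls to a TSV
#'
#' @param calls output of \code{\link{callEssentiality}}.
#' @param path output path.
#' @export
writeEssentiality <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
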